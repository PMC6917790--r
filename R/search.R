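# k-mismatch search of expanded oligos against reference contigs.
# Native backend: exact Aho-Corasick over Hamming-ball enumerated patterns.
# Oracle backend: naive sliding-window scan (brute_force_*), used as ground
# truth in tests and as the documented fallback above the pattern cap.

#' Search configuration
#'
#' @param method `"aho_corasick"` (native), `"blast"` or `"bowtie"`
#'   (external adapters, see [run_external_adapter()]).
#' @param max_mm_primer,max_mm_probe maximum mismatches (0-3) for primer and
#'   probe hits.
#' @param pattern_cap global cap on the number of Hamming-ball expanded
#'   patterns; above it the native backend falls back to the brute-force
#'   scanner (same results, no automaton).
#' @param expand_cap per-oligo degenerate expansion cap.
#' @param blast,bowtie named lists of pass-through parameters for the
#'   external adapters.
#' @return a `search_config` list.
#' @export
search_config <- function(method = c("aho_corasick", "blast", "bowtie"),
                          max_mm_primer = 0L, max_mm_probe = 0L,
                          pattern_cap = 5e6, expand_cap = 1024L,
                          blast = list(), bowtie = list()) {
  method <- match.arg(method)
  stopifnot(max_mm_primer >= 0L, max_mm_primer <= 3L,
            max_mm_probe >= 0L, max_mm_probe <= 3L)
  structure(list(method = method,
                 max_mm_primer = as.integer(max_mm_primer),
                 max_mm_probe = as.integer(max_mm_probe),
                 pattern_cap = pattern_cap, expand_cap = expand_cap,
                 blast = blast, bowtie = bowtie),
            class = "search_config")
}

#' Expand an oligo table into concrete variants
#'
#' @param oligos data.frame from [load_oligo_sets()].
#' @param cap per-oligo expansion cap.
#' @return data.frame with `oligo_name` (parent), `variant_index` (0-based),
#'   `sequence` (ACGT), `role`, `set_id`.
#' @export
expand_oligos <- function(oligos, cap = 1024L) {
  out <- lapply(seq_len(nrow(oligos)), function(i) {
    v <- expand_degenerate(oligos$sequence[i], cap = cap,
                           name = oligos$name[i])
    data.frame(oligo_name = oligos$name[i],
               variant_index = seq_along(v) - 1L,
               sequence = v, role = oligos$role[i],
               set_id = oligos$set_id[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build an Aho-Corasick multi-pattern matcher
#'
#' Classic goto/failure/output automaton over the A,C,G,T,N alphabet. All
#' occurrences of all patterns are reported in one pass over a text,
#' including overlapping occurrences and duplicate pattern strings under
#' different ids.
#'
#' @param patterns character vector of non-empty A/C/G/T(/N) pattern strings;
#'   names are the pattern ids (defaulting to the index).
#' @return an `aho_automaton` object.
#' @export
#' @examples
#' ac <- build_automaton(c(a = "AC", b = "CG"))
#' scan_automaton(ac, "ACG")
build_automaton <- function(patterns) {
  if (length(patterns) == 0L) stop("empty pattern list", call. = FALSE)
  ids <- names(patterns)
  if (is.null(ids)) ids <- as.character(seq_along(patterns))
  if (any(is.na(patterns) | nchar(patterns) == 0L)) {
    stop("patterns must be non-empty strings", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", patterns))) {
    stop("patterns must be A/C/G/T/N only", call. = FALSE)
  }
  obj <- list(ptr = .cpp_ac_build(unname(patterns)),
              ids = ids, lengths = nchar(patterns))
  class(obj) <- "aho_automaton"
  obj
}

#' Scan a text with a built automaton
#'
#' @param autom an [build_automaton()] object.
#' @param text a single A/C/G/T/N string.
#' @return data.frame with `pattern_id`, `start`, `end` (1-based inclusive),
#'   one row per occurrence.
#' @export
scan_automaton <- function(autom, text) {
  stopifnot(inherits(autom, "aho_automaton"), is.character(text),
            length(text) == 1L)
  res <- .cpp_ac_scan(autom$ptr, text)
  len <- autom$lengths[res$pattern]
  data.frame(pattern_id = autom$ids[res$pattern],
             start = res$end - len + 1L, end = res$end,
             stringsAsFactors = FALSE)
}

#' Enumerate the Hamming ball of a pattern
#'
#' Every ACGT string at Hamming distance at most `k` from `pattern`,
#' annotated with its distance; the count is `sum(choose(L, 0:k) * 3^(0:k))`.
#' This is the mechanism by which the exact-matching automaton gains
#' k-mismatch capability.
#'
#' @param pattern ACGT string.
#' @param k maximum Hamming distance.
#' @param cap maximum ball size before aborting.
#' @return data.frame with `sequence` and `mismatches`.
#' @export
#' @examples
#' nrow(enumerate_mismatch_variants("ACGT", 1))  # 13
enumerate_mismatch_variants <- function(pattern, k, cap = 5e6) {
  stopifnot(is.character(pattern), length(pattern) == 1L, k >= 0)
  if (grepl("[^ACGT]", pattern)) stop("pattern must be ACGT only", call. = FALSE)
  res <- .cpp_hamming_ball(pattern, as.integer(k), FALSE, cap)
  data.frame(sequence = res$sequence, mismatches = res$mismatches,
             stringsAsFactors = FALSE)
}

# analytic ball size (s substitution letters per position)
ball_size <- function(L, k, s = 3) {
  sum(choose(L, 0:k) * s^(0:k))
}

# mismatch description shared by all backends: offsets are 1-based from the
# oligo's 5' end; refBase is the reference base the oligo faces, read in the
# oligo's orientation (i.e. from the plus strand for plus hits, from the
# reverse complement of the matched window for minus hits)
describe_mismatches <- function(oligo_seq, aligned_ref) {
  a <- strsplit(oligo_seq, "", fixed = TRUE)
  b <- strsplit(aligned_ref, "", fixed = TRUE)
  vapply(seq_along(a), function(i) {
    off <- which(a[[i]] != b[[i]] | !(b[[i]] %in% c("A", "C", "G", "T")))
    if (length(off) == 0L) return("")
    paste(sprintf("%d:%s>%s", off, b[[i]][off], a[[i]][off]), collapse = ";")
  }, character(1L))
}

count_mismatches <- function(oligo_seq, aligned_ref) {
  a <- strsplit(oligo_seq, "", fixed = TRUE)
  b <- strsplit(aligned_ref, "", fixed = TRUE)
  vapply(seq_along(a), function(i) {
    sum(a[[i]] != b[[i]] | !(b[[i]] %in% c("A", "C", "G", "T")))
  }, integer(1L))
}

# canonical ordering of a hit table
sort_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$contig_id, hits$start, hits$oligo_name,
                     hits$strand, hits$variant_index, hits$mismatches), ]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(oligo_name = character(), variant_index = integer(),
             role = character(), set_id = character(),
             contig_id = character(), strand = character(),
             start = integer(), end = integer(), mismatches = integer(),
             mismatch_repr = character(), matched_ref_seq = character(),
             stringsAsFactors = FALSE)
}

# assemble full hit records from raw (meta row, start) placements
assemble_hits <- function(meta, meta_idx, starts, contig_id, contig_seq) {
  if (length(meta_idx) == 0L) return(empty_hits())
  L <- nchar(meta$sequence[meta_idx])
  ends <- starts + L - 1L
  window <- substring(contig_seq, starts, ends)
  aligned <- ifelse(meta$strand[meta_idx] == "-", rc_acgt(window), window)
  data.frame(oligo_name = meta$oligo_name[meta_idx],
             variant_index = meta$variant_index[meta_idx],
             role = meta$role[meta_idx], set_id = meta$set_id[meta_idx],
             contig_id = contig_id, strand = meta$strand[meta_idx],
             start = starts, end = ends,
             mismatches = count_mismatches(meta$sequence[meta_idx], aligned),
             mismatch_repr = describe_mismatches(meta$sequence[meta_idx], aligned),
             matched_ref_seq = window, stringsAsFactors = FALSE)
}

# expanded oligo table -> one row per (variant, strand) with the plus-strand
# pattern to scan for
search_meta <- function(expanded, config) {
  k <- ifelse(expanded$role == "probe", config$max_mm_probe,
              config$max_mm_primer)
  meta <- rbind(
    transform(expanded, strand = "+", pattern = sequence, k = k),
    transform(expanded, strand = "-", pattern = rc_acgt(sequence), k = k))
  rownames(meta) <- NULL
  meta
}

#' Search references for all oligo placements
#'
#' Finds every ungapped placement of every expanded oligo variant on every
#' contig, on both strands, with up to the role-specific number of
#' mismatches. Minus-strand placements are found by scanning for the reverse
#' complement of the variant on the plus-strand text; coordinates are always
#' reported on the plus strand. Reference N always counts as a mismatch.
#'
#' The native backend enumerates the Hamming ball of every pattern and runs
#' one exact Aho-Corasick pass per contig. If the total ball size exceeds
#' `config$pattern_cap` the brute-force scanner is used instead (identical
#' results).
#'
#' @param expanded expanded oligo table from [expand_oligos()].
#' @param references data.frame from [load_references()].
#' @param config a [search_config()].
#' @return hit data.frame sorted by (contig_id, start, oligo_name, strand):
#'   `oligo_name`, `variant_index`, `role`, `set_id`, `contig_id`, `strand`
#'   (`+`/`-`), `start`, `end` (1-based inclusive, plus strand),
#'   `mismatches`, `mismatch_repr` (semicolon-joined
#'   `offset:refBase>oligoBase`, offsets from the oligo 5' end),
#'   `matched_ref_seq` (plus-strand window).
#' @export
search_references <- function(expanded, references, config = search_config()) {
  stopifnot(nrow(expanded) >= 1L, nrow(references) >= 1L)
  meta <- search_meta(expanded, config)
  include_n <- any(grepl("N", references$sequence, fixed = TRUE))
  s_sub <- if (include_n) 4 else 3
  sizes <- mapply(ball_size, nchar(meta$pattern), meta$k,
                  MoreArgs = list(s = s_sub))
  if (sum(sizes) > config$pattern_cap) {
    return(brute_force_search(expanded, references, config))
  }
  m <- .cpp_search_mm(meta$pattern, meta$k, include_n, references$sequence)
  out <- lapply(seq_len(nrow(references)), function(r) {
    sel <- m$text == r
    idx <- m$pattern[sel]
    starts <- m$end[sel] - nchar(meta$sequence[idx]) + 1L
    assemble_hits(meta, idx, starts, references$contig_id[r],
                  references$sequence[r])
  })
  sort_hits(do.call(rbind, out))
}

#' Brute-force oracle scan of one pattern against one reference
#'
#' Sliding-window Hamming comparison at every position on both strands;
#' intentionally simple and independent of the automaton path, used as
#' ground truth in tests.
#'
#' @param pattern ACGT string (one concrete oligo variant, 5'->3').
#' @param reference a single-row data.frame from [load_references()] (or a
#'   list with `contig_id` and `sequence`).
#' @param k maximum mismatches.
#' @return data.frame with `contig_id`, `strand`, `start`, `end`,
#'   `mismatches`.
#' @export
brute_force_scan <- function(pattern, reference, k) {
  stopifnot(!grepl("[^ACGT]", pattern))
  scan1 <- function(pat, strand) {
    r <- .cpp_brute_scan(pat, reference$sequence, as.integer(k))
    if (length(r$start) == 0L) return(NULL)
    data.frame(contig_id = reference$contig_id, strand = strand,
               start = r$start, end = r$start + nchar(pat) - 1L,
               mismatches = r$mismatches, stringsAsFactors = FALSE)
  }
  out <- rbind(scan1(pattern, "+"), scan1(rc_acgt(pattern), "-"))
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Brute-force search over a full oligo/reference collection
#'
#' Same Hit contract as [search_references()], computed by the naive scanner.
#'
#' @inheritParams search_references
#' @return hit data.frame, identical in layout and sorting to
#'   [search_references()].
#' @export
brute_force_search <- function(expanded, references, config = search_config()) {
  meta <- search_meta(expanded, config)
  out <- lapply(seq_len(nrow(references)), function(r) {
    per_meta <- lapply(seq_len(nrow(meta)), function(i) {
      res <- .cpp_brute_scan(meta$pattern[i], references$sequence[r],
                             meta$k[i])
      if (length(res$start) == 0L) return(NULL)
      assemble_hits(meta, rep.int(i, length(res$start)), res$start,
                    references$contig_id[r], references$sequence[r])
    })
    do.call(rbind, per_meta)
  })
  hits <- do.call(rbind, out)
  if (is.null(hits)) return(empty_hits())
  sort_hits(hits)
}

#' Collapse degenerate-variant hits to one hit per placement
#'
#' Keeps at most one hit per (oligo_name, contig_id, start, strand): the one
#' with the fewest mismatches, ties broken by lowest variant index. This is
#' what makes each reference position count once per parent oligo even when
#' many expanded variants match it.
#'
#' @param hits hit data.frame.
#' @return deduplicated, sorted hit data.frame.
#' @export
deduplicate_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$oligo_name, hits$contig_id, hits$start, hits$strand,
             hits$mismatches, hits$variant_index)
  hits <- hits[o, ]
  key <- paste(hits$oligo_name, hits$contig_id, hits$start, hits$strand,
               sep = "\r")
  sort_hits(hits[!duplicated(key), , drop = FALSE])
}
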