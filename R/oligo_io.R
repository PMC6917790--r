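# Reading and writing external data: FASTA references, primer/probe sets
# (with the "_probes" filename association convention), the mapping CSV.

#' Parse a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that uppercases
#' sequences, joins wrapped lines, preserves record order, and turns the
#' malformed-input cases (missing file, empty sequence, zero records) into
#' clear fatal errors.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `header` (full header line, '>' stripped)
#'   and `sequence`.
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records in ", path, call. = FALSE)
  }
  headers <- names(set)
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) {
    stop(sprintf("empty sequence for '%s' in %s", headers[empty[1L]], path),
         call. = FALSE)
  }
  data.frame(header = headers, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records data.frame with `header` and `sequence` columns (as returned
#'   by [parse_fasta()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$header))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Load reference sequences
#'
#' Reads one or more multi-FASTA files of reference contigs. The contig id is
#' the first whitespace-delimited token of the header; characters outside
#' A/C/G/T/N are normalized to N (with a message), so dirty assembly
#' characters never match any oligo base.
#'
#' @param paths character vector of FASTA paths.
#' @return data.frame with columns `contig_id`, `sequence`, `source_file`.
#' @export
load_references <- function(paths) {
  refs <- do.call(rbind, lapply(paths, function(p) {
    rec <- parse_fasta(p)
    cleaned <- vapply(rec$sequence, function(s) {
      gsub("[^ACGTN]", "N", s)
    }, character(1L), USE.NAMES = FALSE)
    n_fixed <- sum(nchar(gsub("[^ACGTN]", "", rec$sequence)) != nchar(rec$sequence))
    if (n_fixed > 0L) {
      message(sprintf("%s: non-ACGTN characters in %d contig(s) normalized to N",
                      p, n_fixed))
    }
    data.frame(contig_id = sub("\\s.*$", "", rec$header),
               sequence = cleaned, source_file = p,
               stringsAsFactors = FALSE)
  }))
  dup <- duplicated(refs$contig_id)
  if (any(dup)) {
    stop("duplicate contig id(s): ",
         paste(unique(refs$contig_id[dup]), collapse = ", "), call. = FALSE)
  }
  refs
}

#' Load primer and probe sets
#'
#' Each primer FASTA defines one multiplex set, identified by the file's
#' basename without extension. Primer roles are inferred from oligo-name
#' suffixes (`_F` forward, `_R` reverse by default). A probe file is
#' associated to the primer set whose basename equals its own basename minus
#' the `_probes` suffix; its oligos get role `probe`.
#'
#' @param primer_paths character vector of primer FASTA paths.
#' @param probe_paths character vector of probe FASTA paths (may be empty).
#' @param forward_suffix,reverse_suffix oligo-name suffixes marking primer
#'   roles.
#' @param probe_suffix basename suffix marking a probe file.
#' @return data.frame of oligos: `name`, `sequence`, `role`
#'   (`forward_primer` / `reverse_primer` / `probe`), `set_id`,
#'   `is_degenerate`.
#' @export
load_oligo_sets <- function(primer_paths, probe_paths = character(),
                            forward_suffix = "_F", reverse_suffix = "_R",
                            probe_suffix = "_probes") {
  base_noext <- function(p) tools::file_path_sans_ext(basename(p))
  set_ids <- vapply(primer_paths, base_noext, character(1L),
                    USE.NAMES = FALSE)

  read_set <- function(path, set_id, probe_file) {
    rec <- parse_fasta(path)
    name <- sub("\\s.*$", "", rec$header)
    seq <- vapply(seq_along(name), function(i) {
      check_iupac(rec$sequence[i], what = paste0("oligo '", name[i], "'"))
    }, character(1L))
    if (probe_file) {
      role <- rep("probe", length(name))
    } else {
      role <- ifelse(endsWith(name, forward_suffix), "forward_primer",
                     ifelse(endsWith(name, reverse_suffix), "reverse_primer",
                            NA_character_))
      if (anyNA(role)) {
        stop(sprintf(
          "cannot infer role for primer(s) %s in %s (expected name suffix '%s' or '%s')",
          paste(sQuote(name[is.na(role)]), collapse = ", "), path,
          forward_suffix, reverse_suffix), call. = FALSE)
      }
    }
    data.frame(name = name, sequence = unname(seq), role = role,
               set_id = set_id, stringsAsFactors = FALSE)
  }

  primers <- do.call(rbind, lapply(seq_along(primer_paths), function(i) {
    read_set(primer_paths[i], set_ids[i], probe_file = FALSE)
  }))

  probes <- NULL
  if (length(probe_paths) > 0L) {
    probes <- do.call(rbind, lapply(probe_paths, function(p) {
      b <- base_noext(p)
      if (!endsWith(b, probe_suffix)) {
        stop(sprintf("probe file '%s' lacks the '%s' basename suffix",
                     p, probe_suffix), call. = FALSE)
      }
      set_id <- substr(b, 1L, nchar(b) - nchar(probe_suffix))
      if (!(set_id %in% set_ids)) {
        stop(sprintf("probe file '%s' has no matching primer set '%s'",
                     p, set_id), call. = FALSE)
      }
      read_set(p, set_id, probe_file = TRUE)
    }))
  }

  oligos <- rbind(primers, probes)
  dup <- duplicated(oligos$name)
  if (any(dup)) {
    stop("duplicate oligo name(s) across files: ",
         paste(unique(oligos$name[dup]), collapse = ", "), call. = FALSE)
  }
  oligos$is_degenerate <- is_degenerate(oligos$sequence)
  rownames(oligos) <- NULL
  oligos
}

#' Load the oligo-to-gene mapping CSV
#'
#' Comma-separated, header row required. The first three columns are oligo
#' name, gene name, and expected product size (bp, may be empty); any further
#' columns are free-form information fields carried through to the outputs
#' verbatim.
#'
#' @param path CSV path.
#' @return data.frame with columns `oligo_name`, `gene_name`,
#'   `expected_product_size` (integer, NA when absent) plus any extra columns
#'   under their original header names.
#' @export
load_mapping_csv <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 3L) {
    stop("mapping file needs at least 3 columns (oligo, gene, expected size)",
         call. = FALSE)
  }
  size_chr <- trimws(raw[[3L]])
  size <- suppressWarnings(as.integer(size_chr))
  bad <- which(size_chr != "" & (is.na(size) | as.character(size) != size_chr))
  if (length(bad) > 0L) {
    stop(sprintf("mapping row %d: expected product size '%s' is not an integer",
                 bad[1L] + 1L, size_chr[bad[1L]]), call. = FALSE)
  }
  if (any(!is.na(size) & size <= 0L)) {
    stop("mapping: expected product sizes must be positive", call. = FALSE)
  }
  out <- data.frame(oligo_name = trimws(raw[[1L]]),
                    gene_name = raw[[2L]],
                    expected_product_size = ifelse(size_chr == "", NA_integer_, size),
                    stringsAsFactors = FALSE)
  dup <- duplicated(out$oligo_name)
  if (any(dup)) {
    stop("duplicate oligo name(s) in mapping: ",
         paste(unique(out$oligo_name[dup]), collapse = ", "), call. = FALSE)
  }
  if (ncol(raw) > 3L) out <- cbind(out, raw[, -(1:3), drop = FALSE])
  out
}
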