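# Amplicon prediction: orienting primer hits, pairing them into products
# (including cross-set by-products), attaching probes, classifying unpaired
# hits, summarizing degenerate oligos, annotating with the user mapping.

#' Tag primer hits with their amplifying orientation
#'
#' An amplifying orientation is determined by strand alone: a plus-strand
#' primer hit extends rightward, a minus-strand hit extends leftward. Role
#' labels (forward/reverse) are carried through for reporting only, so that
#' unintended pairings — a "forward" primer acting as the leftward side of a
#' by-product — are exposed rather than hidden. Probe hits get no
#' orientation.
#'
#' @param hits hit data.frame from [search_references()].
#' @return the hits with an `orientation` column (`rightward`, `leftward`,
#'   or NA for probes).
#' @export
orient_hits <- function(hits) {
  hits$orientation <- ifelse(hits$role == "probe", NA_character_,
                             ifelse(hits$strand == "+", "rightward",
                                    "leftward"))
  hits
}

empty_products <- function() {
  data.frame(product_id = character(), contig_id = character(),
             set_id = character(), cross_set = logical(),
             fwd_name = character(), fwd_start = integer(),
             fwd_end = integer(), fwd_mismatches = integer(),
             fwd_mismatch_repr = character(),
             rev_name = character(), rev_start = integer(),
             rev_end = integer(), rev_mismatches = integer(),
             rev_mismatch_repr = character(),
             start = integer(), end = integer(), length = integer(),
             sequence = character(), stringsAsFactors = FALSE)
}

#' Pair oriented primer hits into predicted products
#'
#' Emits one product for every ordered combination of a rightward-extending
#' primer hit `f` and a leftward-extending primer hit `r` on the same contig
#' with `f$start <= r$start` and product length
#' `r$end - f$start + 1 <= max_product_size`. All combinations are emitted —
#' overlapping and cross-set products are expected output, not errors. The
#' product's `set_id` is the rightward primer's set, with `cross_set = TRUE`
#' when the two primers belong to different sets.
#'
#' @param hits deduplicated, mismatch-filtered hit data.frame (probe hits
#'   are ignored here).
#' @param max_product_size maximum product length, bp.
#' @param references optional reference data.frame; when given, the product
#'   sequence (plus strand, inclusive of both primer footprints) is attached.
#' @return product data.frame sorted by (contig_id, start, end, set_id).
#' @export
pair_hits <- function(hits, max_product_size, references = NULL) {
  hits <- orient_hits(hits)
  prim <- hits[!is.na(hits$orientation), , drop = FALSE]
  out <- list()
  for (contig in unique(prim$contig_id)) {
    h <- prim[prim$contig_id == contig, , drop = FALSE]
    f <- h[h$orientation == "rightward", , drop = FALSE]
    r <- h[h$orientation == "leftward", , drop = FALSE]
    if (nrow(f) == 0L || nrow(r) == 0L) next
    grid <- expand.grid(fi = seq_len(nrow(f)), ri = seq_len(nrow(r)))
    len <- r$end[grid$ri] - f$start[grid$fi] + 1L
    ok <- f$start[grid$fi] <= r$start[grid$ri] & len <= max_product_size
    if (!any(ok)) next
    grid <- grid[ok, , drop = FALSE]
    len <- len[ok]
    out[[contig]] <- data.frame(
      contig_id = contig,
      set_id = f$set_id[grid$fi],
      cross_set = f$set_id[grid$fi] != r$set_id[grid$ri],
      fwd_name = f$oligo_name[grid$fi],
      fwd_start = f$start[grid$fi], fwd_end = f$end[grid$fi],
      fwd_mismatches = f$mismatches[grid$fi],
      fwd_mismatch_repr = f$mismatch_repr[grid$fi],
      rev_name = r$oligo_name[grid$ri],
      rev_start = r$start[grid$ri], rev_end = r$end[grid$ri],
      rev_mismatches = r$mismatches[grid$ri],
      rev_mismatch_repr = r$mismatch_repr[grid$ri],
      start = f$start[grid$fi], end = r$end[grid$ri], length = len,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_products())
  prod <- do.call(rbind, out)
  prod <- prod[order(prod$contig_id, prod$start, prod$end, prod$set_id,
                     prod$fwd_name, prod$rev_name), , drop = FALSE]
  rownames(prod) <- NULL
  prod <- cbind(product_id = sprintf("P%04d", seq_len(nrow(prod))), prod,
                stringsAsFactors = FALSE)
  if (!is.null(references)) {
    seqs <- setNames(references$sequence, references$contig_id)
    prod$sequence <- substring(seqs[prod$contig_id], prod$start, prod$end)
  } else {
    prod$sequence <- NA_character_
  }
  prod
}

#' Attach probe hits to products
#'
#' A probe hit is attached to every product whose span fully contains the
#' probe's span on the same contig, regardless of probe strand (hybridization
#' probes can target either strand of the double-stranded amplicon). One
#' probe may be attached to many products and one product may carry many
#' probes.
#'
#' @param products product data.frame from [pair_hits()].
#' @param probe_hits probe hit data.frame (filtered at the probe mismatch
#'   limit).
#' @return data.frame with one row per (product, probe) attachment:
#'   `product_id`, `probe_name`, `probe_start`, `probe_end`, `probe_strand`,
#'   `probe_mismatches`, `probe_mismatch_repr`.
#' @export
attach_probes <- function(products, probe_hits) {
  probe_hits <- probe_hits[probe_hits$role == "probe", , drop = FALSE]
  empty <- data.frame(product_id = character(), probe_name = character(),
                      probe_start = integer(), probe_end = integer(),
                      probe_strand = character(),
                      probe_mismatches = integer(),
                      probe_mismatch_repr = character(),
                      stringsAsFactors = FALSE)
  if (nrow(products) == 0L || nrow(probe_hits) == 0L) return(empty)
  out <- lapply(seq_len(nrow(probe_hits)), function(i) {
    p <- probe_hits[i, ]
    inside <- products$contig_id == p$contig_id &
      products$start <= p$start & p$end <= products$end
    if (!any(inside)) return(NULL)
    data.frame(product_id = products$product_id[inside],
               probe_name = p$oligo_name, probe_start = p$start,
               probe_end = p$end, probe_strand = p$strand,
               probe_mismatches = p$mismatches,
               probe_mismatch_repr = p$mismatch_repr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$product_id, out$probe_start, out$probe_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify hits that ended up in no product
#'
#' Every primer hit participating in no product becomes
#' `forward_without_reverse` (rightward) or `reverse_without_forward`
#' (leftward); every probe hit attached to no product becomes
#' `probe_without_product`. Hits inside products never appear here, so
#' products and the unpaired list partition the filtered hits.
#'
#' @param hits deduplicated hit data.frame.
#' @param products product data.frame from [pair_hits()].
#' @param product_probes attachment data.frame from [attach_probes()].
#' @return the unpaired subset of `hits` with a `category` column.
#' @export
classify_unpaired <- function(hits, products, product_probes = NULL) {
  hits <- orient_hits(hits)
  hit_key <- paste(hits$oligo_name, hits$contig_id, hits$start, hits$strand,
                   sep = "\r")
  used <- character()
  if (nrow(products) > 0L) {
    used <- c(paste(products$fwd_name, products$contig_id, products$fwd_start,
                    "+", sep = "\r"),
              paste(products$rev_name, products$contig_id, products$rev_start,
                    "-", sep = "\r"))
  }
  if (!is.null(product_probes) && nrow(product_probes) > 0L) {
    pk <- merge(product_probes, products[, c("product_id", "contig_id")],
                by = "product_id")
    used <- c(used, paste(pk$probe_name, pk$contig_id, pk$probe_start,
                          pk$probe_strand, sep = "\r"))
  }
  un <- hits[!(hit_key %in% used), , drop = FALSE]
  if (nrow(un) == 0L) {
    un$category <- character(0L)
    return(un)
  }
  un$category <- ifelse(un$role == "probe", "probe_without_product",
                        ifelse(un$orientation == "rightward",
                               "forward_without_reverse",
                               "reverse_without_forward"))
  rownames(un) <- NULL
  un
}

#' Summarize degenerate oligos
#'
#' One row per degenerate parent oligo (even with zero hits), aggregating the
#' total number of expanded variants, how many of them produced at least one
#' hit, the number of distinct placements after deduplication, and the best
#' (lowest) mismatch count observed. Non-degenerate oligos are omitted.
#'
#' @param oligos oligo data.frame from [load_oligo_sets()].
#' @param raw_hits hit data.frame before deduplication.
#' @param dedup_hits hit data.frame after [deduplicate_hits()].
#' @param cap expansion cap (for the analytic variant count).
#' @return data.frame with `parent_name`, `n_variants_total`,
#'   `n_variants_with_hits`, `n_distinct_placements`, `best_mismatch_count`
#'   (NA when the oligo hit nothing).
#' @export
summarize_degenerate <- function(oligos, raw_hits, dedup_hits = NULL,
                                 cap = 1024L) {
  if (is.null(dedup_hits)) dedup_hits <- deduplicate_hits(raw_hits)
  deg <- oligos[oligos$is_degenerate, , drop = FALSE]
  out <- lapply(seq_len(nrow(deg)), function(i) {
    name <- deg$name[i]
    raw <- raw_hits[raw_hits$oligo_name == name, , drop = FALSE]
    ded <- dedup_hits[dedup_hits$oligo_name == name, , drop = FALSE]
    data.frame(parent_name = name,
               n_variants_total = degeneracy(deg$sequence[i]),
               n_variants_with_hits = length(unique(raw$variant_index)),
               n_distinct_placements = nrow(ded),
               best_mismatch_count = if (nrow(ded) > 0L) min(ded$mismatches)
                 else NA_integer_,
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0L) {
    return(data.frame(parent_name = character(), n_variants_total = integer(),
                      n_variants_with_hits = integer(),
                      n_distinct_placements = integer(),
                      best_mismatch_count = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Annotate products with the user mapping
#'
#' Attaches each primer's gene name, expected product size and extra mapping
#' fields to its products, and sets `size_match`: TRUE iff an expected size
#' exists for either primer and equals the predicted length within
#' `size_tolerance` (exact by default); NA when neither primer has an
#' expectation. Oligo names present in the mapping but absent from the run
#' are ignored; unmapped oligos leave their fields empty and the run
#' continues.
#'
#' @param products product data.frame.
#' @param mapping data.frame from [load_mapping_csv()].
#' @param size_tolerance allowed absolute deviation in bp (default 0: exact).
#' @return the products with `fwd_gene`, `rev_gene`, `fwd_expected_size`,
#'   `rev_expected_size`, `size_match`, and `fwd_`/`rev_`-prefixed extra
#'   mapping columns.
#' @export
annotate_products <- function(products, mapping, size_tolerance = 0L) {
  extra_cols <- setdiff(names(mapping),
                        c("oligo_name", "gene_name", "expected_product_size"))
  lookup <- function(names_vec, col) {
    idx <- match(names_vec, mapping$oligo_name)
    mapping[[col]][idx]
  }
  for (side in c("fwd", "rev")) {
    nm <- products[[paste0(side, "_name")]]
    products[[paste0(side, "_gene")]] <- lookup(nm, "gene_name")
    products[[paste0(side, "_expected_size")]] <-
      lookup(nm, "expected_product_size")
    for (ec in extra_cols) {
      products[[paste0(side, "_", ec)]] <- lookup(nm, ec)
    }
  }
  fs <- products$fwd_expected_size
  rs <- products$rev_expected_size
  match1 <- function(exp_size) {
    ifelse(is.na(exp_size), NA, abs(products$length - exp_size) <= size_tolerance)
  }
  mf <- match1(fs); mr <- match1(rs)
  products$size_match <- ifelse(is.na(mf) & is.na(mr), NA,
                                (!is.na(mf) & mf) | (!is.na(mr) & mr))
  products
}

#' Melting temperature of a PCR product
#'
#' For products of at least `min_len` bp, the long-duplex empirical formula
#' `Tm = 81.5 + 16.6*log10([Na+_eq] in mol/L) + 0.41*%GC - 675/N` with the
#' monovalent-equivalent salt from [salt_correction()]. Shorter sequences
#' fall back to the nearest-neighbor Tm of the perfect duplex.
#'
#' @param sequence product sequence (ACGT/N; N is ignored in the GC count).
#' @param cond a [conditions()] object.
#' @param min_len minimum length for the long-duplex formula, bp.
#' @return Tm in degrees C.
#' @export
#' @examples
#' cond <- conditions("amplification", 55, monovalent = 50, oligo_conc = 111)
#' seq100 <- strrep("AGCT", 25)  # 100 bp, 50% GC
#' product_tm(seq100, cond)  # 73.65
product_tm <- function(sequence, cond, min_len = 50L) {
  vapply(sequence, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n == 0L) stop("zero-length product sequence", call. = FALSE)
    if (n >= min_len) {
      na_eq <- salt_correction(cond$monovalent, cond$divalent, cond$dntp)
      gc <- 100 * nchar(gsub("[^GC]", "", s)) / n
      81.5 + 16.6 * log10(na_eq / 1000) + 0.41 * gc - 675 / n
    } else {
      s <- gsub("N", "A", s, fixed = TRUE)
      duplex_thermo(s, chartr("ACGT", "TGCA", s), cond)$tm
    }
  }, numeric(1L), USE.NAMES = FALSE)
}
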