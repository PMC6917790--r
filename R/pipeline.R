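# Single-entry pipeline: configuration, orchestration of
# search -> pairing -> probes -> summaries -> annotation -> thermodynamics,
# and byte-stable CSV output.

#' Pipeline run configuration
#'
#' Validates inputs and bundles every tunable of a run. All referenced paths
#' must exist at validation time.
#'
#' @param references,primers,probes character vectors of FASTA paths
#'   (`probes` may be empty).
#' @param mapping optional mapping CSV path.
#' @param search a [search_config()].
#' @param max_product_size maximum amplicon length, bp.
#' @param amplification,hybridization [conditions()] for the two assay
#'   steps; `hybridization` may be NULL for primer-only assays.
#' @param cross_dg,self_dg,hairpin_dg,hairpin_tm_margin flagging thresholds
#'   (kcal/mol; degC margin) passed to [screen_panel()].
#' @param size_tolerance bp tolerance for [annotate_products()] size match.
#' @param out_dir output directory (created if missing).
#' @param forward_suffix,reverse_suffix,probe_suffix naming conventions for
#'   [load_oligo_sets()].
#' @return a `run_config` object.
#' @export
run_config <- function(references, primers, probes = character(),
                       mapping = NULL, search = search_config(),
                       max_product_size = 1000L,
                       amplification = conditions("amplification", 55,
                                                  monovalent = 50,
                                                  divalent = 1.5, dntp = 0.8,
                                                  oligo_conc = 111),
                       hybridization = NULL,
                       cross_dg = -9, self_dg = -5, hairpin_dg = -5,
                       hairpin_tm_margin = 3, size_tolerance = 0L,
                       out_dir = NULL,
                       forward_suffix = "_F", reverse_suffix = "_R",
                       probe_suffix = "_probes") {
  stopifnot(max_product_size > 0)
  for (p in c(references, primers, probes, mapping)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  stopifnot(inherits(search, "search_config"),
            inherits(amplification, "plex_conditions"),
            is.null(hybridization) || inherits(hybridization, "plex_conditions"))
  structure(list(references = references, primers = primers, probes = probes,
                 mapping = mapping, search = search,
                 max_product_size = as.integer(max_product_size),
                 amplification = amplification, hybridization = hybridization,
                 cross_dg = cross_dg, self_dg = self_dg,
                 hairpin_dg = hairpin_dg,
                 hairpin_tm_margin = hairpin_tm_margin,
                 size_tolerance = as.integer(size_tolerance),
                 out_dir = out_dir, forward_suffix = forward_suffix,
                 reverse_suffix = reverse_suffix, probe_suffix = probe_suffix),
            class = "run_config")
}

# per-primer duplex thermodynamics against its (possibly mismatched) target;
# terminal mismatch columns are trimmed first; duplexes the nearest-neighbor
# model cannot score (tandem mismatches, too short after trimming) give NA
primer_target_thermo <- function(oligo_seq, aligned_ref, cond) {
  a <- strsplit(oligo_seq, "", fixed = TRUE)[[1L]]
  b <- strsplit(chartr("ACGTN", "TGCAN", aligned_ref), "",
                fixed = TRUE)[[1L]]
  wc <- chartr("ACGT", "TGCA", a) == b & b %in% c("A", "C", "G", "T")
  lo <- which(wc)[1L]
  hi <- rev(which(wc))[1L]
  if (is.na(lo) || hi - lo + 1L < 2L) return(list(dG = NA_real_, tm = NA_real_))
  res <- tryCatch(
    duplex_thermo(paste(a[lo:hi], collapse = ""),
                  paste(b[lo:hi], collapse = ""), cond),
    error = function(e) NULL)
  if (is.null(res)) return(list(dG = NA_real_, tm = NA_real_))
  list(dG = res$dG_at_temp, tm = res$tm)
}

# oriented reference sequence an oligo hit faces (oligo 5'->3' coordinates)
hit_aligned_ref <- function(hits) {
  ifelse(hits$strand == "-", rc_acgt(hits$matched_ref_seq),
         hits$matched_ref_seq)
}

#' Attach thermodynamic annotations to products
#'
#' For each product, the dG (at the amplification step's annealing
#' temperature) and Tm of each primer hybridized to its genomic target
#' (mismatches included via the single-internal-mismatch parameters), and
#' the product Tm from [product_tm()].
#'
#' @param products product data.frame with `sequence` populated.
#' @param hits deduplicated hit data.frame (provides the matched windows).
#' @param cond amplification-step [conditions()].
#' @return products with `fwd_dg`, `fwd_tm`, `rev_dg`, `rev_tm`,
#'   `product_tm` columns.
#' @export
annotate_thermo <- function(products, hits, cond) {
  if (nrow(products) == 0L) {
    for (cc in c("fwd_dg", "fwd_tm", "rev_dg", "rev_tm", "product_tm"))
      products[[cc]] <- numeric(0L)
    return(products)
  }
  key <- paste(hits$oligo_name, hits$contig_id, hits$start, hits$strand,
               sep = "\r")
  aligned <- hit_aligned_ref(hits)
  variant_seq <- vapply(seq_len(nrow(hits)), function(i) {
    # reconstruct the variant as it matched: aligned target corrected at the
    # reported mismatch offsets equals the oligo variant itself
    a <- strsplit(aligned[i], "", fixed = TRUE)[[1L]]
    if (nzchar(hits$mismatch_repr[i])) {
      for (m in strsplit(hits$mismatch_repr[i], ";", fixed = TRUE)[[1L]]) {
        off <- as.integer(sub(":.*", "", m))
        a[off] <- sub(".*>", "", m)
      }
    }
    paste(a, collapse = "")
  }, character(1L))

  side_thermo <- function(names_, contigs, starts, strand) {
    idx <- match(paste(names_, contigs, starts, strand, sep = "\r"), key)
    t(vapply(idx, function(i) {
      if (is.na(i)) return(c(NA_real_, NA_real_))
      r <- primer_target_thermo(variant_seq[i], aligned[i], cond)
      c(r$dG, r$tm)
    }, numeric(2L)))
  }
  fw <- side_thermo(products$fwd_name, products$contig_id,
                    products$fwd_start, "+")
  rv <- side_thermo(products$rev_name, products$contig_id,
                    products$rev_start, "-")
  products$fwd_dg <- fw[, 1L]; products$fwd_tm <- fw[, 2L]
  products$rev_dg <- rv[, 1L]; products$rev_tm <- rv[, 2L]
  products$product_tm <- product_tm(products$sequence, cond)
  products
}

#' Run the full evaluation pipeline
#'
#' Loads all inputs, searches for oligo placements, filters and
#' deduplicates hits, pairs primers into products, attaches probes,
#' classifies unpaired hits, summarizes degenerate oligos, annotates with
#' the user mapping, attaches thermodynamic values, screens the panel for
#' secondary structures, and (when `config$out_dir` is set) writes the
#' deterministic CSV bundle, a run log and a config echo.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list: `oligos`, `expanded`, `references`,
#'   `raw_hits`, `hits`, `products`, `product_probes`, `unpaired`,
#'   `degenerate_summary`, `screen`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  logline <- character()
  say <- function(fmt, ...) {
    logline <<- c(logline, sprintf(fmt, ...))
  }

  references <- load_references(config$references)
  oligos <- load_oligo_sets(config$primers, config$probes,
                            forward_suffix = config$forward_suffix,
                            reverse_suffix = config$reverse_suffix,
                            probe_suffix = config$probe_suffix)
  mapping <- if (!is.null(config$mapping)) load_mapping_csv(config$mapping)
  say("references: %d contig(s), %d bp", nrow(references),
      sum(nchar(references$sequence)))
  say("oligos: %d (%d degenerate)", nrow(oligos), sum(oligos$is_degenerate))

  expanded <- expand_oligos(oligos, cap = config$search$expand_cap)
  say("expanded variants: %d", nrow(expanded))

  raw_hits <- switch(config$search$method,
                     aho_corasick = search_references(expanded, references,
                                                      config$search),
                     run_external_adapter(config$search$method, expanded,
                                          references, config$search))
  say("raw hits: %d", nrow(raw_hits))
  hits <- deduplicate_hits(raw_hits)
  say("deduplicated hits: %d", nrow(hits))

  primer_hits <- hits[hits$role != "probe", , drop = FALSE]
  probe_hits <- hits[hits$role == "probe", , drop = FALSE]
  products <- pair_hits(primer_hits, config$max_product_size, references)
  say("products: %d", nrow(products))
  product_probes <- attach_probes(products, probe_hits)
  say("probe attachments: %d", nrow(product_probes))
  unpaired <- classify_unpaired(hits, products, product_probes)
  say("unpaired hits: %d", nrow(unpaired))
  degenerate <- summarize_degenerate(oligos, raw_hits, hits,
                                     cap = config$search$expand_cap)
  say("degenerate parents summarized: %d", nrow(degenerate))

  if (!is.null(mapping)) {
    products <- annotate_products(products, mapping,
                                  size_tolerance = config$size_tolerance)
  }
  products <- annotate_thermo(products, hits, config$amplification)

  cond_list <- Filter(Negate(is.null),
                      list(config$amplification, config$hybridization))
  screen <- screen_panel(oligos, cond_list,
                         cross_dg = config$cross_dg,
                         self_dg = config$self_dg,
                         hairpin_dg = config$hairpin_dg,
                         hairpin_tm_margin = config$hairpin_tm_margin,
                         expand_cap = config$search$expand_cap)
  say("flagged structures: %d", nrow(screen$flagged))

  result <- list(oligos = oligos, expanded = expanded,
                 references = references, raw_hits = raw_hits, hits = hits,
                 products = products, product_probes = product_probes,
                 unpaired = unpaired, degenerate_summary = degenerate,
                 screen = screen, log = logline)
  if (!is.null(config$out_dir)) {
    write_output_bundle(result, config)
  }
  invisible(result)
}

# fixed two-decimal formatting for kcal/mol and degC columns
fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))

prepare_products_long <- function(products, product_probes) {
  probe_cols <- c("probe_name", "probe_start", "probe_end", "probe_strand",
                  "probe_mismatches", "probe_mismatch_repr")
  if (nrow(products) == 0L) {
    long <- cbind(products,
                  as.data.frame(setNames(rep(list(character(0L)), 6L),
                                         probe_cols)))
    return(long)
  }
  long <- merge(products, product_probes, by = "product_id", all.x = TRUE,
                sort = FALSE)
  for (cc in c("fwd_dg", "fwd_tm", "rev_dg", "rev_tm", "product_tm")) {
    if (cc %in% names(long)) long[[cc]] <- fmt_num(long[[cc]])
  }
  long <- long[order(long$contig_id, long$start, long$end, long$product_id,
                     long$probe_start, long$probe_name,
                     method = "radix"), , drop = FALSE]
  rownames(long) <- NULL
  long
}

write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' Write the output bundle of a pipeline run
#'
#' Writes `products.csv` (long format: one row per product-probe
#' combination, probe columns empty for probe-less products),
#' `unpaired.csv`, `degenerate_summary.csv`, per-step square
#' `dimers_matrix_<step>.csv`, `dimers_flagged.csv`, `hairpins.csv`,
#' `run.log` and `config.echo`. Rows are deterministically sorted and
#' kcal/mol / degC values carry two decimals, so re-running an identical
#' config reproduces the bundle byte for byte.
#'
#' @param result list returned by [run_pipeline()].
#' @param config the [run_config()] used.
#' @return (invisibly) the output directory.
#' @export
write_output_bundle <- function(result, config) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  long <- prepare_products_long(result$products, result$product_probes)
  write_csv_stable(long, file.path(dir, "products.csv"))
  write_csv_stable(result$unpaired, file.path(dir, "unpaired.csv"))
  write_csv_stable(result$degenerate_summary,
                   file.path(dir, "degenerate_summary.csv"))

  sc <- result$screen
  for (step in names(sc$matrix)) {
    m <- sc$matrix[[step]]
    df <- data.frame(oligo = rownames(m),
                     apply(m, 2L, fmt_num),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_csv_stable(df, file.path(dir, sprintf("dimers_matrix_%s.csv", step)))
  }
  fl <- sc$flagged
  fl$dG <- fmt_num(fl$dG); fl$tm <- fmt_num(fl$tm)
  write_csv_stable(fl, file.path(dir, "dimers_flagged.csv"))
  hp <- sc$hairpins
  for (cc in c("dG", "dG37", "tm")) hp[[cc]] <- fmt_num(hp[[cc]])
  write_csv_stable(hp, file.path(dir, "hairpins.csv"))

  writeLines(result$log, file.path(dir, "run.log"))
  writeLines(echo_config(config), file.path(dir, "config.echo"))
  invisible(dir)
}

# serialize the config as key = value lines (reproducibility record)
echo_config <- function(config) {
  flat <- c(
    references = paste(config$references, collapse = ","),
    primers = paste(config$primers, collapse = ","),
    probes = paste(config$probes, collapse = ","),
    mapping = if (is.null(config$mapping)) "" else config$mapping,
    method = config$search$method,
    max_mm_primer = config$search$max_mm_primer,
    max_mm_probe = config$search$max_mm_probe,
    max_product_size = config$max_product_size,
    amp_temp = config$amplification$annealing_temp,
    hyb_temp = if (is.null(config$hybridization)) "" else
      config$hybridization$annealing_temp,
    monovalent = config$amplification$monovalent,
    divalent = config$amplification$divalent,
    dntp = config$amplification$dntp,
    oligo_conc = config$amplification$oligo_conc,
    cross_dg = config$cross_dg, self_dg = config$self_dg,
    hairpin_dg = config$hairpin_dg,
    hairpin_tm_margin = config$hairpin_tm_margin,
    size_tolerance = config$size_tolerance)
  paste(names(flat), unname(flat), sep = " = ")
}
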