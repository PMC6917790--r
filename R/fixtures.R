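# Deterministic synthetic data: random reference contigs with planted
# primer/probe binding sites at known coordinates, plus the ground-truth
# tables tests assert against. Planting overwrites the background (never
# inserts), so every truth coordinate is known a priori.

# run code under a private RNG stream; the caller's global random state is
# untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a reproducible random reference contig
#'
#' @param seed integer seed; same seed, same sequence.
#' @param length contig length, bp.
#' @param gc expected GC fraction (0-1).
#' @param contig_id id for the resulting contig.
#' @return single-row data.frame as from [load_references()].
#' @export
#' @examples
#' generate_reference(42, 100, 0.5)
generate_reference <- function(seed, length, gc = 0.5,
                               contig_id = sprintf("contig_s%d", seed)) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  seq <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
  data.frame(contig_id = contig_id, sequence = seq,
             source_file = "<generated>", stringsAsFactors = FALSE)
}

#' Specify a planted oligo binding site
#'
#' @param oligo_name name of the oligo to plant.
#' @param contig_id target contig.
#' @param position 1-based position of the leftmost planted base.
#' @param strand `"+"` or `"-"`.
#' @param mismatch_offsets integer offsets (1-based from the oligo 5' end)
#'   at which a mismatching base is forced into the reference.
#' @param allow_overlap permit this site to overlap previously planted ones
#'   (for deliberately overlapping product topologies).
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(oligo_name, contig_id, position, strand = "+",
                       mismatch_offsets = integer(), allow_overlap = FALSE) {
  stopifnot(strand %in% c("+", "-"), position >= 1)
  structure(list(oligo_name = oligo_name, contig_id = contig_id,
                 position = as.integer(position), strand = strand,
                 mismatch_offsets = as.integer(mismatch_offsets),
                 allow_overlap = allow_overlap),
            class = "plant_spec")
}

# deterministic mismatching substitution: next base in ACGT order
mismatch_base <- function(base) {
  bases <- c("A", "C", "G", "T")
  bases[match(base, bases) %% 4L + 1L]
}

#' Plant oligo binding sites into references
#'
#' Each planted window is overwritten with the oligo sequence (the reverse
#' complement for minus-strand sites; degenerate codes resolved to their
#' first expansion) with the forced mismatches substituted at the stated
#' offsets. Returns the modified references and a truth table of the hits a
#' correct search must report.
#'
#' @param references reference data.frame.
#' @param specs list of [plant_spec()] objects.
#' @param oligos oligo data.frame from [load_oligo_sets()].
#' @return list with `references` (modified) and `truth_hits` (data.frame:
#'   `oligo_name`, `contig_id`, `strand`, `start`, `end`, `mismatches`).
#' @export
plant_sites <- function(references, specs, oligos) {
  occupied <- list()
  truth <- list()
  for (sp in specs) {
    stopifnot(inherits(sp, "plant_spec"))
    oi <- match(sp$oligo_name, oligos$name)
    if (is.na(oi)) stop("unknown oligo: ", sp$oligo_name, call. = FALSE)
    oseq <- expand_degenerate(oligos$sequence[oi])[1L]
    L <- nchar(oseq)
    ri <- match(sp$contig_id, references$contig_id)
    if (is.na(ri)) stop("unknown contig: ", sp$contig_id, call. = FALSE)
    start <- sp$position
    end <- start + L - 1L
    if (end > nchar(references$sequence[ri])) {
      stop("planted window exceeds contig bounds: ", sp$oligo_name,
           call. = FALSE)
    }
    if (any(sp$mismatch_offsets < 1L | sp$mismatch_offsets > L)) {
      stop("forced mismatch offset outside oligo length: ", sp$oligo_name,
           call. = FALSE)
    }
    prev <- occupied[[sp$contig_id]]
    if (!sp$allow_overlap && !is.null(prev) &&
        any(start <= prev$end & end >= prev$start)) {
      stop("planted window overlaps an existing site: ", sp$oligo_name,
           " (set allow_overlap for deliberate overlap)", call. = FALSE)
    }
    occupied[[sp$contig_id]] <- rbind(prev, data.frame(start = start, end = end))

    # oligo as it reads along the plus strand
    planted <- if (sp$strand == "+") oseq else rc_acgt(oseq)
    if (length(sp$mismatch_offsets) > 0L) {
      chars <- strsplit(planted, "", fixed = TRUE)[[1L]]
      # offsets are in oligo coordinates (5' end); map to plus-strand window
      pos <- if (sp$strand == "+") sp$mismatch_offsets
             else L - sp$mismatch_offsets + 1L
      chars[pos] <- vapply(chars[pos], mismatch_base, character(1L))
      planted <- paste(chars, collapse = "")
    }
    s <- references$sequence[ri]
    references$sequence[ri] <- paste0(substr(s, 1L, start - 1L), planted,
                                      substr(s, end + 1L, nchar(s)))
    truth[[length(truth) + 1L]] <- data.frame(
      oligo_name = sp$oligo_name, contig_id = sp$contig_id,
      strand = sp$strand, start = start, end = end,
      mismatches = length(sp$mismatch_offsets), stringsAsFactors = FALSE)
  }
  list(references = references,
       truth_hits = do.call(rbind, truth))
}

# --- the bundled demo assay -------------------------------------------------

#' Paths to the bundled demo fixture files
#'
#' The files shipped with the package are byte-identical to
#' `demo_fixture(dir, seed = 42)` output and are used by the examples and
#' smoke tests.
#'
#' @return named list of file paths (`references`, `primers`, `probes`,
#'   `mapping`, `truth_hits`).
#' @export
demo_fixture_paths <- function() {
  d <- system.file("extdata", "demo", package = "plexscreen", mustWork = TRUE)
  list(references = file.path(d, "refs.fasta"),
       primers = file.path(d, "setA.fasta"),
       probes = file.path(d, "setA_probes.fasta"),
       mapping = file.path(d, "mapping.csv"),
       truth_hits = file.path(d, "truth_hits.csv"))
}

demo_oligos <- function() {
  data.frame(
    name = c("amrA_F", "amrA_R", "blaT_F", "blaT_R", "vanX_F", "vanX_R",
             "amrA_P", "blaT_P"),
    sequence = c(
      "GATCCTGAACGCTTAACGGC",   # amrA_F
      "TTCGGCATGACCATTGCGAA",   # amrA_R
      "CAGTTGCGCCTAGGTTAAGC",   # blaT_F
      "GGAACCTTGCACGATTGCTA",   # blaT_R
      "ACGTRGGCCATATTCGACTG",   # vanX_F (degenerate: R at offset 5)
      "TCCATGGCGTTAAGCTTGCA",   # vanX_R
      "AGGCTTACCGGCGATATCCA",   # amrA_P
      "CCTTAGCGGCAATTCGATGG"),  # blaT_P
    role = c("forward_primer", "reverse_primer", "forward_primer",
             "reverse_primer", "forward_primer", "reverse_primer",
             "probe", "probe"),
    set_id = "setA",
    stringsAsFactors = FALSE)
}

demo_plants <- function() {
  list(
    # contig c1: clean amrA amplicon with its probe, and a lone forward
    plant_spec("amrA_F", "c1", 301, "+"),
    plant_spec("amrA_P", "c1", 361, "+"),
    plant_spec("amrA_R", "c1", 520, "-", mismatch_offsets = 5L),
    plant_spec("blaT_F", "c1", 1200, "+"),
    # contig c2: two rightward blaT_F placements sharing one blaT_R
    # (at-least-two-amplicons topology) and two probes inside the amplicons
    plant_spec("blaT_F", "c2", 401, "+"),
    plant_spec("blaT_F", "c2", 431, "+"),
    plant_spec("blaT_P", "c2", 500, "+"),
    plant_spec("amrA_P", "c2", 540, "-"),
    plant_spec("blaT_R", "c2", 700, "-"),
    # contig c3: degenerate vanX amplicon, a lone reverse, a homeless probe
    plant_spec("vanX_F", "c3", 250, "+"),
    plant_spec("vanX_R", "c3", 450, "-"),
    plant_spec("amrA_R", "c3", 800, "-"),
    plant_spec("blaT_P", "c3", 1100, "+"))
}

#' Build the bundled demo fixture
#'
#' A complete miniature assay: 3 contigs, one multiplex set of 6 primers
#' (one degenerate) and 2 probes, planted so that every product/hit topology
#' occurs at least once — a clean amplicon with probe, a planted primer site
#' carrying one forced mismatch, two same-sense primers sharing one reverse
#' primer (two overlapping amplicons with two probes each), a degenerate
#' amplicon, lone forward/reverse primers, and a probe without any product.
#'
#' @param dir if non-NULL, the fixture files (`refs.fasta`, `setA.fasta`,
#'   `setA_probes.fasta`, `mapping.csv`, `truth_hits.csv`) are written there.
#' @param seed seed for the background sequence (default 42, the bundled
#'   fixture).
#' @return list with `references`, `oligos`, `mapping`, `truth_hits`,
#'   `max_product_size` and (when written) `paths`.
#' @export
demo_fixture <- function(dir = NULL, seed = 42) {
  refs <- rbind(generate_reference(seed, 2000L, 0.5, "c1"),
                generate_reference(seed + 1L, 1800L, 0.45, "c2"),
                generate_reference(seed + 2L, 1500L, 0.55, "c3"))
  oligos <- demo_oligos()
  oligos$is_degenerate <- is_degenerate(oligos$sequence)
  planted <- plant_sites(refs, demo_plants(), oligos)
  mapping <- data.frame(
    oligo_name = c("amrA_F", "amrA_R", "amrA_P", "blaT_F", "blaT_R",
                   "blaT_P", "vanX_F", "vanX_R"),
    gene_name = c("amrA", "amrA", "amrA", "blaT", "blaT", "blaT",
                  "vanX", "vanX"),
    expected_product_size = c(239L, 239L, NA, 319L, 319L, NA, NA, NA),
    resistance = c("aminoglycoside", "aminoglycoside", "aminoglycoside",
                   "beta-lactam", "beta-lactam", "beta-lactam",
                   "glycopeptide", "glycopeptide"),
    stringsAsFactors = FALSE)
  out <- list(references = planted$references, oligos = oligos,
              mapping = mapping, truth_hits = planted$truth_hits,
              max_product_size = 500L)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      references = file.path(dir, "refs.fasta"),
      primers = file.path(dir, "setA.fasta"),
      probes = file.path(dir, "setA_probes.fasta"),
      mapping = file.path(dir, "mapping.csv"),
      truth_hits = file.path(dir, "truth_hits.csv"))
    write_fasta(data.frame(header = out$references$contig_id,
                           sequence = out$references$sequence),
                paths$references)
    prim <- oligos[oligos$role != "probe", ]
    prob <- oligos[oligos$role == "probe", ]
    write_fasta(data.frame(header = prim$name, sequence = prim$sequence),
                paths$primers)
    write_fasta(data.frame(header = prob$name, sequence = prob$sequence),
                paths$probes)
    utils::write.csv(mapping, paths$mapping, row.names = FALSE, na = "")
    utils::write.csv(out$truth_hits, paths$truth_hits, row.names = FALSE)
    out$paths <- paths
  }
  out
}
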