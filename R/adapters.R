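# Optional external search backends. Both adapters invoke the tool on
# temporary files, parse its native tabular output, convert to the unified
# hit contract (same coordinates, strand and mismatch conventions as the
# native backend), discard gapped or partial-coverage alignments, then apply
# the same mismatch filter and deduplication. They are best-effort
# compatibility shims: the native backend never requires them.

require_exec <- function(bin) {
  path <- Sys.which(bin)
  if (path == "") stop(sprintf("%s not found on PATH", bin), call. = FALSE)
  path
}

run_tool <- function(bin, args) {
  out <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop(sprintf("%s exited with status %d:\n%s", bin, status,
                 paste(utils::tail(out, 20L), collapse = "\n")),
         call. = FALSE)
  }
  out
}

#' Run an external search backend
#'
#' Maps every expanded oligo variant to the references with BLAST+
#' (`blastn -task blastn-short`) or bowtie, and normalizes the tool's output
#' to the same hit format as [search_references()]: ungapped, full-length
#' alignments only, plus-strand coordinates, role-specific mismatch limits,
#' variant deduplication. External tools are heuristic; they may miss
#' placements the native backend finds.
#'
#' @param method `"blast"` or `"bowtie"`.
#' @param expanded expanded oligo table from [expand_oligos()].
#' @param references reference data.frame from [load_references()].
#' @param config a [search_config()]; `config$blast` / `config$bowtie` carry
#'   tool parameters (`blast`: `word_size` (7), `perc_identity` (75),
#'   `qcov_hsp_perc` (100), `evalue` (1000); `bowtie`: `seedlen` (28),
#'   `maqerr` (70), `seedmms` (= primer mismatch limit)).
#' @return deduplicated hit data.frame (see [search_references()]).
#' @export
run_external_adapter <- function(method = c("blast", "bowtie"), expanded,
                                 references, config = search_config()) {
  method <- match.arg(method)
  switch(method,
         blast = blast_adapter(expanded, references, config),
         bowtie = bowtie_adapter(expanded, references, config))
}

adapter_finalize <- function(meta, idx, starts, contig_ids, references,
                             config) {
  if (length(idx) == 0L) return(empty_hits())
  out <- lapply(unique(contig_ids), function(cid) {
    sel <- contig_ids == cid
    ref_seq <- references$sequence[references$contig_id == cid]
    assemble_hits(meta, idx[sel], starts[sel], cid, ref_seq)
  })
  hits <- do.call(rbind, out)
  hits <- hits[hits$mismatches <= ifelse(hits$role == "probe",
                                         config$max_mm_probe,
                                         config$max_mm_primer), , drop = FALSE]
  deduplicate_hits(sort_hits(hits))
}

blast_adapter <- function(expanded, references, config) {
  blastn <- require_exec("blastn")
  makedb <- require_exec("makeblastdb")
  p <- utils::modifyList(list(word_size = 7L, perc_identity = 75,
                              qcov_hsp_perc = 100, evalue = 1000),
                         config$blast)
  td <- tempfile("blastdb")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  ref_fa <- file.path(td, "refs.fasta")
  qry_fa <- file.path(td, "query.fasta")
  write_fasta(data.frame(header = references$contig_id,
                         sequence = references$sequence), ref_fa)
  write_fasta(data.frame(header = sprintf("q%d", seq_len(nrow(expanded))),
                         sequence = expanded$sequence), qry_fa)
  run_tool(makedb, c("-in", ref_fa, "-dbtype", "nucl"))
  tab <- file.path(td, "hits.tsv")
  run_tool(blastn, c(
    "-task", "blastn-short", "-query", qry_fa, "-db", ref_fa,
    "-word_size", p$word_size, "-perc_identity", p$perc_identity,
    "-qcov_hsp_perc", p$qcov_hsp_perc, "-evalue", p$evalue,
    "-dust", "no", "-out", tab,
    "-outfmt", shQuote("6 qseqid sseqid sstart send mismatch gaps qstart qend qlen")))
  raw <- tryCatch(utils::read.delim(tab, header = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) NULL)
  meta <- search_meta(expanded, config)
  n <- nrow(expanded)
  if (is.null(raw) || nrow(raw) == 0L) return(empty_hits())
  names(raw) <- c("qseqid", "sseqid", "sstart", "send", "mismatch", "gaps",
                  "qstart", "qend", "qlen")
  # full-coverage, ungapped alignments only
  raw <- raw[raw$gaps == 0L & raw$qstart == 1L & raw$qend == raw$qlen, ,
             drop = FALSE]
  if (nrow(raw) == 0L) return(empty_hits())
  qi <- as.integer(sub("^q", "", raw$qseqid))
  minus <- raw$sstart > raw$send
  idx <- ifelse(minus, qi + n, qi)  # search_meta: plus rows 1..n, minus n+1..2n
  starts <- ifelse(minus, raw$send, raw$sstart)
  adapter_finalize(meta, idx, as.integer(starts), raw$sseqid, references,
                   config)
}

bowtie_adapter <- function(expanded, references, config) {
  bowtie <- require_exec("bowtie")
  build <- require_exec("bowtie-build")
  p <- utils::modifyList(list(seedlen = 28L, maqerr = 70L,
                              seedmms = config$max_mm_primer),
                         config$bowtie)
  td <- tempfile("bowtie")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  ref_fa <- file.path(td, "refs.fasta")
  qry_fa <- file.path(td, "query.fasta")
  write_fasta(data.frame(header = references$contig_id,
                         sequence = references$sequence), ref_fa)
  write_fasta(data.frame(header = sprintf("q%d", seq_len(nrow(expanded))),
                         sequence = expanded$sequence), qry_fa)
  idxbase <- file.path(td, "idx")
  run_tool(build, c(shQuote(ref_fa), shQuote(idxbase)))
  out_tab <- file.path(td, "hits.map")
  run_tool(bowtie, c("-f", "-a", "-v", p$seedmms, "-l", p$seedlen,
                     "-e", p$maqerr, shQuote(idxbase), shQuote(qry_fa),
                     shQuote(out_tab)))
  if (!file.exists(out_tab) || file.size(out_tab) == 0) return(empty_hits())
  raw <- utils::read.delim(out_tab, header = FALSE,
                           stringsAsFactors = FALSE)
  names(raw)[1:5] <- c("qseqid", "strand", "sseqid", "offset0", "seq")
  meta <- search_meta(expanded, config)
  n <- nrow(expanded)
  qi <- as.integer(sub("^q", "", raw$qseqid))
  idx <- ifelse(raw$strand == "-", qi + n, qi)
  adapter_finalize(meta, idx, raw$offset0 + 1L, raw$sseqid, references,
                   config)
}
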