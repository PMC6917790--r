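# shared test utilities: small random generators and temp-file writers

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_iupac <- function(n, codes = c("A", "C", "G", "T", "R", "Y", "S", "W",
                                      "K", "M", "B", "D", "H", "V", "N")) {
  paste(sample(codes, n, replace = TRUE,
               prob = c(rep(10, 4), rep(1, 11))), collapse = "")
}

tmp_fasta <- function(..., dir = withr::local_tempdir(.local_envir = parent.frame())) {
  recs <- list(...)
  path <- file.path(dir, paste0(recs$file %||% "seqs", ".fasta"))
  recs$file <- NULL
  writeLines(unlist(lapply(names(recs), function(h) {
    c(paste0(">", h), recs[[h]])
  })), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random expanded-oligo table for search tests
random_expanded <- function(n_pat, len_range = c(15L, 30L)) {
  lens <- sample(seq(len_range[1L], len_range[2L]), n_pat, replace = TRUE)
  data.frame(oligo_name = sprintf("p%02d", seq_len(n_pat)),
             variant_index = 0L,
             sequence = vapply(lens, random_acgt, character(1L)),
             role = "forward_primer", set_id = "s",
             stringsAsFactors = FALSE)
}

as_ref <- function(seq, id = "ref1") {
  data.frame(contig_id = id, sequence = seq, source_file = "<test>",
             stringsAsFactors = FALSE)
}

# IUPAC membership used by expansion property tests (independent table)
iupac_members <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
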