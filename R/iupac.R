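# IUPAC nucleotide code handling: validation, degenerate expansion,
# reverse complement.

# members of each IUPAC code, alphabetically sorted
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_CODES)

#' Check a sequence for IUPAC validity
#'
#' @param seq a single character string.
#' @param what label used in error messages.
#' @return the uppercased sequence, invisibly usable.
#' @keywords internal
check_iupac <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single string", call. = FALSE)
  }
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop(what, " is empty", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% IUPAC_LETTERS))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC character '%s' at position %d in %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  seq
}

#' Is an oligo sequence degenerate?
#'
#' @param seq IUPAC string (or vector of them).
#' @return logical: `TRUE` iff the sequence contains a non-ACGT code.
#' @export
#' @examples
#' is_degenerate(c("ACGT", "ACRT"))
is_degenerate <- function(seq) {
  grepl("[^ACGT]", toupper(seq))
}

#' Expand a degenerate oligo into all concrete ACGT variants
#'
#' Every IUPAC code is substituted by each of its member bases; the result is
#' the full Cartesian product over positions, in lexicographic order of the
#' variant strings (members of each code expanded in alphabetical order, with
#' the 5'-most position varying slowest). A non-degenerate sequence returns
#' itself as the single variant.
#'
#' @param seq IUPAC string, 5'->3'.
#' @param cap maximum number of variants allowed before aborting; guards the
#'   search stage against combinatorial blow-up on pathological oligos.
#' @param name oligo name used in error messages.
#' @return character vector of ACGT strings; variant index is position - 1.
#' @export
#' @examples
#' expand_degenerate("AYGT")  # "ACGT" "ATGT"
#' length(expand_degenerate("NR"))  # 8
expand_degenerate <- function(seq, cap = 1024L, name = seq) {
  seq <- check_iupac(seq, what = paste0("oligo '", name, "'"))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  members <- IUPAC_CODES[chars]
  n <- prod(lengths(members))
  if (n > cap) {
    stop(sprintf("oligo '%s' expands to %d variants (cap %d)", name, n, cap),
         call. = FALSE)
  }
  if (n == 1L) return(seq)
  # 5'-most position varies slowest => lexicographic order of variants
  grid <- expand.grid(rev(members), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  variants <- do.call(paste0, rev(grid))
  sort(variants)
}

#' Analytic degeneracy of an IUPAC string
#'
#' Product over positions of the IUPAC member counts; equals the number of
#' variants [expand_degenerate()] returns.
#'
#' @param seq IUPAC string.
#' @return integer count.
#' @export
degeneracy <- function(seq) {
  seq <- check_iupac(seq)
  prod(lengths(IUPAC_CODES[strsplit(seq, "", fixed = TRUE)[[1L]]]))
}

#' Reverse complement of an IUPAC sequence
#'
#' Handles all 15 IUPAC codes (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H;
#' S, W, N are self-complementary) and is an involution.
#'
#' @param seq IUPAC string (vectorized).
#' @return reverse-complemented string(s).
#' @export
#' @examples
#' reverse_complement("GATTACA")  # "TGTAATC"
#' reverse_complement("AAR")      # "YTT"
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- check_iupac(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1L), USE.NAMES = FALSE)
}

# fast ACGT-only reverse complement used in inner loops (no validation)
rc_acgt <- function(seq) {
  chartr("ACGT", "TGCA", vapply(strsplit(seq, "", fixed = TRUE),
                                function(x) paste(rev(x), collapse = ""),
                                character(1L)))
}
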