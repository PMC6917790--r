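# Nearest-neighbor thermodynamics: SantaLucia unified Watson-Crick
# parameters plus the Allawi/SantaLucia/Peyret single-internal-mismatch
# extensions, entropy salt correction, duplex/dimer/hairpin free energies
# and melting temperatures.

R_GAS <- 1.9872  # cal/(mol*K)
T37_K <- 310.15

#' Assay-step conditions
#'
#' Temperature and ion/oligo concentrations for one assay step.
#'
#' @param step `"amplification"` or `"hybridization"`.
#' @param annealing_temp annealing temperature, degrees C (0-100).
#' @param monovalent monovalent cation concentration, mM.
#' @param divalent divalent cation (Mg2+) concentration, mM.
#' @param dntp total dNTP concentration, mM (chelates Mg2+).
#' @param oligo_conc oligonucleotide concentration, nM.
#' @return a `plex_conditions` object.
#' @export
#' @examples
#' conditions("amplification", 55, monovalent = 50, divalent = 1.5,
#'            dntp = 0.8, oligo_conc = 111)
conditions <- function(step = c("amplification", "hybridization"),
                       annealing_temp, monovalent = 50, divalent = 0,
                       dntp = 0, oligo_conc = 250) {
  step <- match.arg(step)
  stopifnot(is.numeric(annealing_temp), length(annealing_temp) == 1L,
            annealing_temp >= 0, annealing_temp <= 100,
            monovalent >= 0, divalent >= 0, dntp >= 0, oligo_conc >= 0)
  structure(list(step = step, annealing_temp = annealing_temp,
                 monovalent = monovalent, divalent = divalent, dntp = dntp,
                 oligo_conc = oligo_conc),
            class = "plex_conditions")
}

#' Monovalent-equivalent salt concentration
#'
#' Converts divalent cations to a monovalent equivalent (von Ahsen-style):
#' `Na_eq = monovalent + 120 * sqrt(max(0, divalent - dntp))`, all in mM.
#' dNTPs chelate Mg2+, hence the subtraction with a floor at zero.
#'
#' @param monovalent,divalent,dntp concentrations in mM.
#' @return equivalent monovalent concentration, mM.
#' @export
#' @examples
#' salt_correction(50, 1.5, 0.8)  # 150.4 mM
salt_correction <- function(monovalent, divalent = 0, dntp = 0) {
  stopifnot(monovalent >= 0, divalent >= 0, dntp >= 0)
  na_eq <- monovalent + 120 * sqrt(pmax(0, divalent - dntp))
  if (any(na_eq == 0)) {
    stop("equivalent salt concentration is zero; supply monovalent or divalent ions",
         call. = FALSE)
  }
  na_eq
}

# per-stack entropic salt term: 0.368 * ln([Na+_eq] in mol/L), applied once
# per phosphate-phosphate step (N-1 for an N-bp helix)
salt_ds_per_stack <- function(cond) {
  na_eq <- salt_correction(cond$monovalent, cond$divalent, cond$dntp)
  0.368 * log(na_eq / 1000)
}

.base_code4 <- c(A = 0L, C = 1L, G = 2L, T = 3L)

stack_index <- function(a1, a2, c1, c2) {
  ((.base_code4[a1] * 4L + .base_code4[a2]) * 4L +
     .base_code4[c1]) * 4L + .base_code4[c2] + 1L
}

# flip a stack key to its equivalent antiparallel representation:
# "XY/ZW" (top 5'->3' / bottom 3'->5') == "WZ/YX"
flip_stack_key <- function(key) {
  top <- substr(key, 1L, 2L)
  bot <- substr(key, 4L, 5L)
  paste0(substr(bot, 2L, 2L), substr(bot, 1L, 1L), "/",
         substr(top, 2L, 2L), substr(top, 1L, 1L))
}

#' Nearest-neighbor parameter tables
#'
#' Loads (and caches) the versioned stack parameter tables shipped under
#' `inst/extdata`: the unified Watson-Crick set, the single-internal-mismatch
#' extensions, duplex initiation/symmetry terms and hairpin loop penalties.
#' Both antiparallel orientations of every stack are materialized, so the
#' table satisfies the strand-symmetry identity by construction.
#'
#' @return list with `stack_dH`/`stack_dS` (256-entry lookup vectors, NA for
#'   unparameterized stacks), `init_AT`, `init_GC`, `sym` (each `c(dH, dS)`),
#'   `wc` and `mismatch` data.frames, `loops` data.frame, and `versions`.
#' @export
nn_params <- function() {
  cached <- get0("nn", envir = .plexscreen_env)
  if (!is.null(cached)) return(cached)
  ext <- function(f) system.file("extdata", f, package = "plexscreen",
                                 mustWork = TRUE)
  rd <- function(f) utils::read.delim(ext(f), comment.char = "#",
                                      stringsAsFactors = FALSE)
  wc <- rd("nn_stack_wc.tsv")
  mm <- rd("nn_stack_mismatch.tsv")
  init <- rd("nn_init.tsv")
  loops <- rd("nn_loop_hairpin.tsv")

  version_of <- function(f) {
    ln <- grep("table_version", readLines(ext(f), n = 10L), value = TRUE)
    sub(".*table_version:\\s*", "", ln[1L])
  }

  stack_dH <- rep(NA_real_, 256L)
  stack_dS <- rep(NA_real_, 256L)
  put <- function(key, dH, dS) {
    for (k in unique(c(key, flip_stack_key(key)))) {
      i <- stack_index(substr(k, 1L, 1L), substr(k, 2L, 2L),
                       substr(k, 4L, 4L), substr(k, 5L, 5L))
      stack_dH[i] <<- dH
      stack_dS[i] <<- dS
    }
  }
  for (r in seq_len(nrow(wc))) put(wc$stack[r], wc$dH[r], wc$dS[r])
  for (r in seq_len(nrow(mm))) put(mm$stack[r], mm$dH[r], mm$dS[r])

  term <- function(name) {
    r <- init[init$term == name, ]
    c(dH = r$dH, dS = r$dS)
  }
  out <- list(stack_dH = stack_dH, stack_dS = stack_dS,
              init_AT = term("init_AT"), init_GC = term("init_GC"),
              sym = term("sym"), wc = wc, mismatch = mm, loops = loops,
              versions = c(wc = version_of("nn_stack_wc.tsv"),
                           mismatch = version_of("nn_stack_mismatch.tsv"),
                           loops = version_of("nn_loop_hairpin.tsv")))
  assign("nn", out, envir = .plexscreen_env)
  out
}

# hairpin loop penalty dG37 for sizes 1..max_size, Jacobson-Stockmayer
# extrapolation between/beyond tabulated sizes; entropic only (dH = 0)
loop_dg37 <- function(max_size) {
  tab <- nn_params()$loops
  js <- 2.44 * R_GAS * T37_K / 1000
  vapply(seq_len(max_size), function(n) {
    if (n < min(tab$loop_size)) return(NA_real_)
    x <- max(tab$loop_size[tab$loop_size <= n])
    tab$dG37[tab$loop_size == x] + js * log(n / x)
  }, numeric(1L))
}

#' Free-energy contribution of a single internal mismatch
#'
#' For a given mismatched base pair (top base vs bottom base), sums the dG37
#' of its two nearest-neighbor stacks in every Watson-Crick flanking context
#' `5'-L m R-3' / 3'-L' m' R'-5'`. This quantifies how stabilizing (or
#' destabilizing) a mismatch can be: a G.G mismatch flanked by G and C, for
#' example, contributes about -2.2 kcal/mol.
#'
#' @param top_base,bottom_base the mismatched pair (top strand base and the
#'   base it faces on the bottom strand), e.g. `"G", "G"`.
#' @return data.frame with `left`, `right` (the flanking top-strand bases),
#'   and `dG37` (kcal/mol) of the two mismatch stacks combined; NA where the
#'   parameter set has no entry.
#' @export
#' @examples
#' gg <- mismatch_contribution("G", "G")
#' min(gg$dG37)  # about -2.2
mismatch_contribution <- function(top_base, bottom_base) {
  stopifnot(top_base %in% c("A", "C", "G", "T"),
            bottom_base %in% c("A", "C", "G", "T"))
  nn <- nn_params()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (comp[top_base] == bottom_base) {
    stop("that pair is Watson-Crick, not a mismatch", call. = FALSE)
  }
  grid <- expand.grid(left = c("A", "C", "G", "T"),
                      right = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  dg <- vapply(seq_len(nrow(grid)), function(i) {
    l <- grid$left[i]; r <- grid$right[i]
    i1 <- stack_index(l, top_base, comp[l], bottom_base)
    i2 <- stack_index(top_base, r, bottom_base, comp[r])
    dh <- nn$stack_dH[i1] + nn$stack_dH[i2]
    ds <- nn$stack_dS[i1] + nn$stack_dS[i2]
    dh - T37_K * ds / 1000
  }, numeric(1L))
  grid$dG37 <- dg
  grid
}

make_thermo_result <- function(dH, dS_raw, nstacks, cond, x = 4,
                               structure = "", unimolecular = FALSE) {
  salt <- salt_ds_per_stack(cond)
  dS_corr <- dS_raw + nstacks * salt
  t_k <- cond$annealing_temp + 273.15
  dG_at_temp <- dH - t_k * dS_corr / 1000
  dG37 <- dH - T37_K * dS_corr / 1000
  tm <- if (unimolecular) {
    if (dS_corr == 0) NA_real_ else 1000 * dH / dS_corr - 273.15
  } else {
    ct <- cond$oligo_conc * 1e-9
    denom <- dS_corr + R_GAS * log(ct / x)
    if (ct <= 0 || denom == 0) NA_real_ else 1000 * dH / denom - 273.15
  }
  res <- list(dH = dH, dS = dS_raw, dS_corr = dS_corr,
              dG_at_temp = dG_at_temp, dG37 = dG37, tm = tm,
              structure = structure)
  class(res) <- "thermo_result"
  res
}

null_thermo_result <- function() {
  res <- list(dH = 0, dS = 0, dS_corr = 0, dG_at_temp = 0, dG37 = 0,
              tm = NA_real_, structure = "")
  class(res) <- "thermo_result"
  res
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("dH = %.2f kcal/mol, dS = %.2f cal/(mol*K) (salt-corrected %.2f)\n",
              x$dH, x$dS, x$dS_corr))
  cat(sprintf("dG(step T) = %.2f kcal/mol, dG37 = %.2f kcal/mol, Tm = %s degC\n",
              x$dG_at_temp, x$dG37,
              if (is.na(x$tm)) "NA" else sprintf("%.2f", x$tm)))
  if (nzchar(x$structure)) cat(x$structure, "\n")
  invisible(x)
}

#' Thermodynamics of a fully aligned duplex
#'
#' Sums nearest-neighbor stack enthalpies/entropies plus initiation terms
#' (and the symmetry correction for self-complementary duplexes) over a
#' base-by-base aligned duplex. Every column must be a Watson-Crick pair or a
#' single internal mismatch flanked by Watson-Crick pairs on both sides;
#' terminal or tandem mismatches are rejected.
#'
#' @param top top strand, 5'->3', ACGT.
#' @param bottom bottom strand, 3'->5', aligned column-by-column under `top`.
#' @param cond a [conditions()] object.
#' @return a `thermo_result`: `dH` (kcal/mol), `dS` and salt-corrected
#'   `dS_corr` (cal/mol/K), `dG_at_temp` (at the step's annealing
#'   temperature), `dG37`, `tm` (degC; bimolecular, CT from `oligo_conc`,
#'   symmetry factor 1 for self-complementary duplexes, else 4).
#' @export
#' @examples
#' cond <- conditions("amplification", 37, monovalent = 1000, oligo_conc = 250)
#' duplex_thermo("GCGC", "CGCG", cond)
duplex_thermo <- function(top, bottom, cond) {
  top <- check_iupac(top, "top strand")
  bottom <- check_iupac(bottom, "bottom strand")
  if (grepl("[^ACGT]", top) || grepl("[^ACGT]", bottom)) {
    stop("duplex strands must be concrete ACGT sequences", call. = FALSE)
  }
  n <- nchar(top)
  if (nchar(bottom) != n) stop("aligned strands must have equal length", call. = FALSE)
  if (n < 2L) stop("duplex must have at least 2 base pairs", call. = FALSE)
  a <- strsplit(top, "", fixed = TRUE)[[1L]]
  b <- strsplit(bottom, "", fixed = TRUE)[[1L]]
  wc <- chartr("ACGT", "TGCA", a) == b
  if (!wc[1L] || !wc[n]) stop("terminal mismatch not supported; trim the duplex first",
                              call. = FALSE)
  if (any(!wc[-n] & !wc[-1L])) stop("tandem mismatch unsupported", call. = FALSE)
  nn <- nn_params()
  idx <- stack_index(a[-n], a[-1L], b[-n], b[-1L])
  dH <- nn$stack_dH[idx]
  dS <- nn$stack_dS[idx]
  if (anyNA(dH)) {
    stop("unparameterized stack in duplex (column ", which(is.na(dH))[1L], ")",
         call. = FALSE)
  }
  init_of <- function(base) if (base %in% c("A", "T")) nn$init_AT else nn$init_GC
  dH_tot <- sum(dH) + init_of(a[1L])[["dH"]] + init_of(a[n])[["dH"]]
  dS_tot <- sum(dS) + init_of(a[1L])[["dS"]] + init_of(a[n])[["dS"]]
  b5 <- paste(rev(b), collapse = "")
  selfcomp <- identical(top, b5) && identical(top, rc_acgt(top))
  if (selfcomp) {
    dH_tot <- dH_tot + nn$sym[["dH"]]
    dS_tot <- dS_tot + nn$sym[["dS"]]
  }
  make_thermo_result(dH_tot, dS_tot, nstacks = n - 1L, cond = cond,
                     x = if (selfcomp) 1 else 4,
                     structure = paste0("5'-", top, "-3'\n3'-", bottom, "-5'"))
}

# shared driver for self/cross dimer scans
dimer_scan <- function(s1, s2, cond) {
  nn <- nn_params()
  res <- .cpp_dimer_scan(s1, s2, nn$stack_dH, nn$stack_dS,
                         nn$init_AT[["dH"]], nn$init_AT[["dS"]],
                         nn$init_GC[["dH"]], nn$init_GC[["dS"]],
                         nn$sym[["dH"]], nn$sym[["dS"]],
                         cond$annealing_temp + 273.15,
                         salt_ds_per_stack(cond),
                         identical(s1, s2))
  if (!res$found) return(null_thermo_result())
  make_thermo_result(res$dH, res$dS, res$nstacks, cond,
                     x = if (res$selfcomp) 1 else 4,
                     structure = dimer_structure(s1, s2, res$offset,
                                                 res$i, res$j))
}

# ASCII rendering of the best antiparallel alignment window
dimer_structure <- function(s1, s2, offset, i, j) {
  b <- paste(rev(strsplit(s2, "", fixed = TRUE)[[1L]]), collapse = "")
  pad1 <- strrep(" ", max(0L, -offset))
  pad2 <- strrep(" ", max(0L, offset))
  lo <- max(0L, offset)
  a_chars <- strsplit(s1, "", fixed = TRUE)[[1L]]
  b_chars <- strsplit(b, "", fixed = TRUE)[[1L]]
  marks <- character(max(nchar(pad1) + nchar(s1), nchar(pad2) + nchar(b)))
  marks[] <- " "
  for (t in seq(i, j)) {
    col <- lo + t - 1L        # 0-based alignment column = lo + (t-1)
    top_c <- a_chars[col + 1L]
    bot_c <- b_chars[col - offset + 1L]
    marks[max(0L, -offset) + col + 1L] <-
      if (chartr("ACGT", "TGCA", top_c) == bot_c) "|" else ":"
  }
  paste0("5'-", pad1, s1, "-3'\n   ",
         paste(marks[seq_len(nchar(pad1) + nchar(s1))], collapse = ""),
         "\n3'-", pad2, b, "-5'")
}

#' Most stable self-dimer of an oligo
#'
#' Scans every antiparallel ungapped offset of the sequence against itself
#' and every trimmed window whose ends are Watson-Crick pairs and whose
#' interior contains at most isolated single mismatches, and returns the
#' window minimizing dG at the step's annealing temperature. Windows with
#' non-negative dG are never reported; with no stable window the result has
#' dG = 0 and an empty structure.
#'
#' @param seq oligo sequence 5'->3', ACGT.
#' @param cond a [conditions()] object.
#' @return a `thermo_result` (see [duplex_thermo()]).
#' @export
self_dimer <- function(seq, cond) {
  seq <- check_iupac(seq)
  dimer_scan(seq, seq, cond)
}

#' Most stable cross-dimer of two oligos
#'
#' Same windowed-minimum contract as [self_dimer()], over all antiparallel
#' offsets of `seq1` against `seq2`. Symmetric in its arguments.
#'
#' @param seq1,seq2 oligo sequences 5'->3', ACGT.
#' @param cond a [conditions()] object.
#' @return a `thermo_result`.
#' @export
cross_dimer <- function(seq1, seq2, cond) {
  seq1 <- check_iupac(seq1)
  seq2 <- check_iupac(seq2)
  dimer_scan(seq1, seq2, cond)
}

#' Most stable hairpin of an oligo
#'
#' Enumerates all stem/loop decompositions (stem >= `min_stem` bp, strictly
#' Watson-Crick; loop >= `min_loop` nt with a tabulated, entropic loop
#' penalty) and returns the minimum-dG structure. The hairpin is
#' unimolecular: Tm = 1000*dH/dS_corr - 273.15, no concentration term.
#'
#' @param seq oligo sequence 5'->3', ACGT.
#' @param cond a [conditions()] object.
#' @param min_stem minimum stem length, bp.
#' @param min_loop minimum loop length, nt.
#' @return a `thermo_result`; dG = 0 with empty structure when no stable
#'   hairpin exists.
#' @export
#' @examples
#' cond <- conditions("amplification", 55, monovalent = 50, oligo_conc = 111)
#' hairpin("GCGCGCAAAAGCGCGC", cond)
hairpin <- function(seq, cond, min_stem = 3L, min_loop = 3L) {
  seq <- check_iupac(seq)
  stopifnot(min_stem >= 2L, min_loop >= 3L)
  L <- nchar(seq)
  if (L < 2L * min_stem + min_loop) return(null_thermo_result())
  max_loop <- L - 2L * min_stem
  dg37 <- loop_dg37(max_loop)
  loop_ds <- -1000 * dg37 / T37_K
  loop_ds[is.na(loop_ds)] <- Inf  # undefined (too-small) loops never stabilize
  nn <- nn_params()
  res <- .cpp_hairpin_scan(seq, as.integer(min_stem), as.integer(min_loop),
                           loop_ds, nn$stack_dH, nn$stack_dS,
                           cond$annealing_temp + 273.15,
                           salt_ds_per_stack(cond))
  if (!res$found) return(null_thermo_result())
  bracket <- rep("-", L)
  bracket[seq(res$i, res$i + res$stem - 1L)] <- "("
  bracket[seq(res$i + res$stem, res$i + res$stem + res$loop - 1L)] <- "."
  bracket[seq(res$i + res$stem + res$loop,
              res$i + 2L * res$stem + res$loop - 1L)] <- ")"
  make_thermo_result(res$dH, res$dS, res$nstacks, cond, unimolecular = TRUE,
                     structure = paste0(seq, "\n", paste(bracket, collapse = "")))
}

#' Screen an oligo panel for secondary structures
#'
#' Computes the best self-dimer and hairpin for every oligo and the best
#' cross-dimer for every unordered pair, at each supplied step's conditions,
#' and flags candidates: cross-dimers at dG <= `cross_dg` kcal/mol,
#' self-dimers at dG <= `self_dg`, hairpins at dG <= `hairpin_dg` OR
#' Tm + `hairpin_tm_margin` >= the step's annealing temperature. Degenerate
#' oligos are screened through their thermodynamically most stable expanded
#' variant, which is recorded in the output.
#'
#' @param oligos data.frame with `name` and `sequence` columns (IUPAC), as
#'   from [load_oligo_sets()], or a named character vector of sequences.
#' @param cond_list a single [conditions()] object or a list of them (one per
#'   assay step).
#' @param cross_dg,self_dg,hairpin_dg flagging thresholds, kcal/mol.
#' @param hairpin_tm_margin degC margin for the hairpin Tm rule.
#' @param expand_cap degenerate expansion cap passed to [expand_degenerate()].
#' @return list with data.frames `self`, `cross`, `hairpins`, `flagged`, and
#'   `matrix` (one square dG matrix per step; self-dimer dG on the diagonal).
#' @export
screen_panel <- function(oligos, cond_list,
                         cross_dg = -9, self_dg = -5, hairpin_dg = -5,
                         hairpin_tm_margin = 3, expand_cap = 1024L) {
  if (is.character(oligos)) {
    oligos <- data.frame(name = if (is.null(names(oligos)))
      paste0("oligo", seq_along(oligos)) else names(oligos),
      sequence = unname(oligos), stringsAsFactors = FALSE)
  }
  if (inherits(cond_list, "plex_conditions")) cond_list <- list(cond_list)
  stopifnot(nrow(oligos) >= 1L, !anyDuplicated(oligos$name))

  variants <- lapply(oligos$sequence, expand_degenerate, cap = expand_cap)

  best_over_variants <- function(fun, idx1, idx2 = NULL, cond) {
    best <- NULL
    best_v <- c(NA_integer_, NA_integer_)
    for (v1 in seq_along(variants[[idx1]])) {
      s1 <- variants[[idx1]][v1]
      if (is.null(idx2)) {
        r <- fun(s1, cond)
        if (is.null(best) || r$dG_at_temp < best$dG_at_temp) {
          best <- r
          best_v <- c(v1 - 1L, NA_integer_)
        }
      } else {
        for (v2 in seq_along(variants[[idx2]])) {
          r <- fun(s1, variants[[idx2]][v2], cond)
          if (is.null(best) || r$dG_at_temp < best$dG_at_temp) {
            best <- r
            best_v <- c(v1 - 1L, v2 - 1L)
          }
        }
      }
    }
    list(res = best, variants = best_v)
  }

  self_rows <- list(); cross_rows <- list(); hp_rows <- list()
  matrices <- list()
  n <- nrow(oligos)
  for (cond in cond_list) {
    m <- matrix(0, n, n, dimnames = list(oligos$name, oligos$name))
    for (i in seq_len(n)) {
      b <- best_over_variants(self_dimer, i, cond = cond)
      self_rows[[length(self_rows) + 1L]] <- data.frame(
        step = cond$step, oligo = oligos$name[i],
        variant_index = b$variants[1L],
        dG = b$res$dG_at_temp, dG37 = b$res$dG37, tm = b$res$tm,
        stringsAsFactors = FALSE)
      m[i, i] <- b$res$dG_at_temp
      h <- best_over_variants(hairpin, i, cond = cond)
      hp_rows[[length(hp_rows) + 1L]] <- data.frame(
        step = cond$step, oligo = oligos$name[i],
        variant_index = h$variants[1L],
        dG = h$res$dG_at_temp, dG37 = h$res$dG37, tm = h$res$tm,
        stringsAsFactors = FALSE)
      if (i < n) for (j in seq(i + 1L, n)) {
        b2 <- best_over_variants(cross_dimer, i, j, cond = cond)
        cross_rows[[length(cross_rows) + 1L]] <- data.frame(
          step = cond$step, oligo1 = oligos$name[i], oligo2 = oligos$name[j],
          variant_index1 = b2$variants[1L], variant_index2 = b2$variants[2L],
          dG = b2$res$dG_at_temp, dG37 = b2$res$dG37, tm = b2$res$tm,
          stringsAsFactors = FALSE)
        m[i, j] <- m[j, i] <- b2$res$dG_at_temp
      }
    }
    matrices[[cond$step]] <- m
  }
  self <- do.call(rbind, self_rows)
  cross <- if (length(cross_rows)) do.call(rbind, cross_rows) else
    data.frame(step = character(), oligo1 = character(), oligo2 = character(),
               variant_index1 = integer(), variant_index2 = integer(),
               dG = numeric(), dG37 = numeric(), tm = numeric())
  hps <- do.call(rbind, hp_rows)

  step_temp <- setNames(vapply(cond_list, `[[`, numeric(1L), "annealing_temp"),
                        vapply(cond_list, `[[`, character(1L), "step"))
  flag <- rbind(
    if (nrow(self)) data.frame(type = "self_dimer", step = self$step,
                               oligo1 = self$oligo, oligo2 = NA_character_,
                               dG = self$dG, tm = self$tm,
                               flagged = self$dG <= self_dg,
                               rule = sprintf("dG <= %g", self_dg),
                               stringsAsFactors = FALSE),
    if (nrow(cross)) data.frame(type = "cross_dimer", step = cross$step,
                                oligo1 = cross$oligo1, oligo2 = cross$oligo2,
                                dG = cross$dG, tm = cross$tm,
                                flagged = cross$dG <= cross_dg,
                                rule = sprintf("dG <= %g", cross_dg),
                                stringsAsFactors = FALSE),
    if (nrow(hps)) data.frame(type = "hairpin", step = hps$step,
                              oligo1 = hps$oligo, oligo2 = NA_character_,
                              dG = hps$dG, tm = hps$tm,
                              flagged = hps$dG <= hairpin_dg |
                                (!is.na(hps$tm) &
                                   hps$tm + hairpin_tm_margin >= step_temp[hps$step]),
                              rule = sprintf("dG <= %g | Tm + %g >= step T",
                                             hairpin_dg, hairpin_tm_margin),
                              stringsAsFactors = FALSE))
  list(self = self, cross = cross, hairpins = hps,
       flagged = flag[flag$flagged, , drop = FALSE], all_structures = flag,
       matrix = matrices)
}
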