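# reference conditions: 1 M Na+, 250 nM total strand concentration, 37 C
cond_ref <- conditions("amplification", 37, monovalent = 1000, divalent = 0,
                       dntp = 0, oligo_conc = 250)

test_that("salt correction follows the monovalent-equivalence formula", {
  expect_equal(salt_correction(50, 1.5, 0.8), 50 + 120 * sqrt(0.7),
               tolerance = 1e-12)
  expect_equal(round(salt_correction(50, 1.5, 0.8), 2), 150.40)
  expect_equal(salt_correction(50, 0, 0), 50)
  # dNTP chelation floors the divalent term at zero
  expect_equal(salt_correction(50, 0.5, 0.8), 50)
  expect_error(salt_correction(0, 0, 0), "zero")
})

test_that("perfect-duplex dH/dS match a hand summation of the unified table", {
  # GCGC/CGCG: stacks GC+CG+GC, two G.C initiations, self-complementary
  r <- duplex_thermo("GCGC", "CGCG", cond_ref)
  expect_equal(r$dH, (-9.8) + (-10.6) + (-9.8) + 2 * 0.1, tolerance = 1e-12)
  expect_equal(r$dS, (-24.4) + (-27.2) + (-24.4) + 2 * (-2.8) + (-1.4),
               tolerance = 1e-12)
})

test_that("duplex dG37 and Tm agree with an independent NN calculator", {
  # values computed with Biopython MeltingTemp (DNA_NN3 unified parameters,
  # 1 M Na+, 125+125 nM strands) and frozen here
  oracle <- list(
    list(seq = "CGCTGCTGTCGGACTCCTAGTTACGTGGCG", dH = -249.0, dS = -663.8, dG37 = -43.12243, tm = 84.2181),
    list(seq = "TGCTCCACAGGTAGCCTGCCGTCGTGGT", dH = -225.3, dS = -594.1, dG37 = -41.039885, tm = 86.1454),
    list(seq = "CGCAACACTCGCACGCTGTT", dH = -166.0, dS = -442.5, dG37 = -28.758625, tm = 75.9852),
    list(seq = "CAGGGCGATCCTCCGGATAACACCACCT", dH = -221.0, dS = -588.2, dG37 = -38.56977, tm = 82.6356),
    list(seq = "CACAAACGAAGACAACCCTC", dH = -157.3, dS = -427.7, dG37 = -24.648845, tm = 68.3162),
    list(seq = "GGTTCTTTCCCGTCCGTAAGACTACTTATG", dH = -235.8, dS = -642.4, dG37 = -36.55964, tm = 75.9968),
    list(seq = "GGCCATACCAGGGTC", dH = -113.8, dS = -304.6, dG37 = -19.32831, tm = 63.9747),
    list(seq = "TTTGCAAAGTCAATAGCAGCCATAGT", dH = -199.8, dS = -543.8, dG37 = -31.14043, tm = 73.2676),
    list(seq = "CAACTTTCCGGGTATTGGCC", dH = -156.0, dS = -420.6, dG37 = -25.55091, tm = 70.7953),
    list(seq = "CTTGGCTAGTCGTCGGCACTGGCTGC", dH = -213.9, dS = -568.2, dG37 = -37.67277, tm = 82.6618))
  for (o in oracle) {
    r <- duplex_thermo(o$seq, chartr("ACGT", "TGCA", o$seq), cond_ref)
    expect_equal(r$dH, o$dH, tolerance = 1e-9)
    expect_equal(r$dS, o$dS, tolerance = 1e-9)
    expect_lt(abs(r$dG37 - o$dG37), 0.05)
    expect_lt(abs(r$tm - o$tm), 0.05)
  }
})

test_that("duplex validation rejects what the NN model cannot score", {
  expect_error(duplex_thermo("AGGT", "TTTA", cond_ref), "tandem")
  expect_error(duplex_thermo("ACGT", "GGCA", cond_ref), "terminal mismatch")
  expect_error(duplex_thermo("ACGT", "TGC", cond_ref), "equal length")
})

test_that("the NN table is strand-symmetric over all Watson-Crick stacks", {
  nn <- nn_params()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- names(comp)
  for (a1 in bases) for (a2 in bases) {
    # stack XY/X'Y' equals its antiparallel flip Y'X'/YX
    i1 <- plexscreen:::stack_index(a1, a2, comp[a1], comp[a2])
    i2 <- plexscreen:::stack_index(comp[a2], comp[a1], a2, a1)
    expect_identical(nn$stack_dH[i1], nn$stack_dH[i2])
    expect_identical(nn$stack_dS[i1], nn$stack_dS[i2])
  }
  # mismatch stacks satisfy the same identity
  for (r in seq_len(nrow(nn$mismatch))) {
    k <- nn$mismatch$stack[r]
    f <- plexscreen:::flip_stack_key(k)
    gv <- function(key) {
      i <- plexscreen:::stack_index(substr(key, 1, 1), substr(key, 2, 2),
                                    substr(key, 4, 4), substr(key, 5, 5))
      c(nn$stack_dH[i], nn$stack_dS[i])
    }
    expect_identical(gv(k), gv(f))
  }
})

test_that("duplex thermodynamics are invariant under strand swap", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_acgt(sample(10:25, 1))
    b <- chartr("ACGT", "TGCA", s)
    r1 <- duplex_thermo(s, b, cond_ref)
    # swap strands: new top = reverse(bottom) read 5'->3'
    top2 <- paste(rev(strsplit(b, "")[[1]]), collapse = "")
    bot2 <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    r2 <- duplex_thermo(top2, bot2, cond_ref)
    expect_equal(r1$dH, r2$dH, tolerance = 1e-12)
    expect_equal(r1$dS, r2$dS, tolerance = 1e-12)
  }
})

test_that("dG37 identity holds for every result type", {
  set.seed(87)
  cond <- conditions("hybridization", 45, monovalent = 100, divalent = 2,
                     dntp = 0.5, oligo_conc = 100)
  for (i in 1:25) {
    s <- random_acgt(sample(12:30, 1))
    for (r in list(duplex_thermo(s, chartr("ACGT", "TGCA", s), cond),
                   self_dimer(s, cond), hairpin(s, cond),
                   cross_dimer(s, random_acgt(20), cond))) {
      expect_equal(r$dG37, r$dH - 310.15 * r$dS_corr / 1000, tolerance = 1e-9)
    }
  }
})

test_that("Tm rises with salt and strand concentration for stabilizing duplexes", {
  s <- "CAGTTGCGCCTAGGTTAAGC"
  tm_at <- function(na, ct) {
    duplex_thermo(s, chartr("ACGT", "TGCA", s),
                  conditions("amplification", 55, monovalent = na,
                             oligo_conc = ct))$tm
  }
  na_series <- vapply(c(10, 50, 100, 500, 1000), tm_at, numeric(1), ct = 250)
  expect_true(all(diff(na_series) > 0))
  ct_series <- vapply(c(10, 50, 250, 1000), function(ct) tm_at(100, ct),
                      numeric(1))
  expect_true(all(diff(ct_series) > 0))
})

test_that("the G.G mismatch can contribute -2.2 kcal/mol at its best context", {
  gg <- mismatch_contribution("G", "G")
  expect_equal(round(min(gg$dG37), 1), -2.2)
  best <- gg[which.min(gg$dG37), ]
  expect_identical(c(best$left, best$right), c("G", "C"))
  expect_error(mismatch_contribution("A", "T"), "Watson-Crick")
})

# independent oracle: enumerate every offset and every trimmed window, score
# each via duplex_thermo (a separate code path from the C++ scan)
brute_dimer_dg <- function(s1, s2, cond) {
  b <- paste(rev(strsplit(s2, "")[[1]]), collapse = "")  # s2 read 3'->5'
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L1 <- nchar(s1); L2 <- nchar(s2)
  best <- 0
  for (o in seq(-(L2 - 1), L1 - 1)) {
    lo <- max(0, o); hi <- min(L1 - 1, o + L2 - 1)
    m <- hi - lo + 1
    if (m < 2) next
    top <- substring(s1, lo + 1, hi + 1)
    bot <- paste(strsplit(b, "")[[1]][(lo:hi) - o + 1], collapse = "")
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      t_w <- substr(top, i, j); b_w <- substr(bot, i, j)
      r <- tryCatch(duplex_thermo(t_w, b_w, cond), error = function(e) NULL)
      if (!is.null(r) && r$dG_at_temp < best) best <- r$dG_at_temp
    }
  }
  best
}

test_that("windowed dimer minimum equals brute-force offset/trim enumeration", {
  set.seed(19)
  cond <- conditions("amplification", 50, monovalent = 50, divalent = 1.5,
                     dntp = 0.8, oligo_conc = 111)
  for (i in 1:12) {
    s1 <- random_acgt(sample(8:12, 1))
    s2 <- random_acgt(sample(8:12, 1))
    expect_equal(cross_dimer(s1, s2, cond)$dG_at_temp,
                 brute_dimer_dg(s1, s2, cond), tolerance = 1e-9)
    expect_equal(self_dimer(s1, cond)$dG_at_temp,
                 brute_dimer_dg(s1, s1, cond), tolerance = 1e-9)
  }
})

test_that("dimer scan honors its structural contract", {
  cond <- conditions("amplification", 37, monovalent = 50, oligo_conc = 250)
  # no complementarity at all
  expect_identical(self_dimer("AAAAAA", cond)$dG_at_temp, 0)
  expect_identical(cross_dimer("AAAAAA", "CCCCCC", cond)$dG_at_temp, 0)
  # perfect self-complement scores as the full symmetric duplex
  r <- self_dimer("ATATATAT", cond)
  d <- duplex_thermo("ATATATAT", "TATATATA", cond)
  expect_equal(r$dH, d$dH, tolerance = 1e-12)
  expect_equal(r$dS, d$dS, tolerance = 1e-12)
  # oligo vs its reverse complement = the full perfect duplex
  s <- "CAGTTGCGCCTAGGTTAAGC"
  expect_equal(cross_dimer(s, reverse_complement(s), cond)$dG_at_temp,
               duplex_thermo(s, chartr("ACGT", "TGCA", s), cond)$dG_at_temp,
               tolerance = 1e-9)
  # symmetry in the arguments
  set.seed(23)
  for (i in 1:30) {
    a <- random_acgt(sample(10:20, 1)); b2 <- random_acgt(sample(10:20, 1))
    expect_equal(cross_dimer(a, b2, cond)$dG_at_temp,
                 cross_dimer(b2, a, cond)$dG_at_temp, tolerance = 1e-9)
  }
  # never positive
  set.seed(29)
  for (i in 1:20) {
    expect_lte(self_dimer(random_acgt(15), cond)$dG_at_temp, 0)
  }
})

test_that("hairpin scan finds the forced stem/loop and respects bounds", {
  # 37 C: the short test stems are stable there, not at stringent annealing
  cond <- conditions("amplification", 37, monovalent = 50, oligo_conc = 111)
  r <- hairpin("GGGGAAAACCCC", cond)
  expect_identical(r$structure, "GGGGAAAACCCC\n((((....))))")
  # too short for stem >= 3 + loop >= 3
  expect_identical(hairpin("ACGTACG", cond)$dG_at_temp, 0)
  expect_identical(hairpin("ACGTACG", cond)$structure, "")
  # structural invariants on random reported hairpins
  set.seed(61)
  found <- 0
  for (i in 1:60) {
    s <- random_acgt(sample(16:30, 1))
    h <- hairpin(s, cond)
    if (!nzchar(h$structure)) next
    found <- found + 1
    br <- strsplit(strsplit(h$structure, "\n")[[1]][2], "")[[1]]
    loop <- sum(br == ".")
    stem <- sum(br == "(")
    expect_gte(loop, 3)
    expect_gte(stem, 3)
    arm1 <- paste(strsplit(s, "")[[1]][br == "("], collapse = "")
    arm2 <- paste(strsplit(s, "")[[1]][br == ")"], collapse = "")
    expect_identical(reverse_complement(arm1), arm2)
    expect_lt(h$dG_at_temp, 0)
  }
  expect_gte(found, 3)  # the scan does find structures in random 16-30-mers
})

test_that("panel screening counts and thresholds follow the reporting rules", {
  cond <- conditions("amplification", 55, monovalent = 50, divalent = 1.5,
                     dntp = 0.8, oligo_conc = 111)
  oligos <- data.frame(
    name = c("o1", "o2", "o3", "o4"),
    sequence = c("CAGTTGCGCCTAGGTTAAGC", "GCTTAACCTAGGCGCAACTG",
                 "GGAACCTTGCACGATTGCTA", "TTTTTTTTTTTTTTTTTTTT"),
    stringsAsFactors = FALSE)
  sc <- screen_panel(oligos, cond)
  n <- nrow(oligos)
  expect_identical(nrow(sc$self), n)
  expect_identical(nrow(sc$cross), as.integer(n * (n - 1L) / 2L))
  expect_identical(nrow(sc$hairpins), n)
  m <- sc$matrix$amplification
  expect_identical(dim(m), c(n, n))
  expect_true(isSymmetric(m))
  # o1 and o2 are near-perfect complements: strong cross-dimer must be flagged
  expect_true(any(sc$flagged$type == "cross_dimer" &
                    sc$flagged$oligo1 == "o1" & sc$flagged$oligo2 == "o2"))
})

test_that("flagging thresholds behave exactly at the boundaries", {
  flag_cross <- function(dg, thr = -9) dg <= thr
  # boundary semantics as implemented in screen_panel
  expect_true(flag_cross(-9.0))
  expect_false(flag_cross(-8.99))
  expect_true(flag_cross(-9.4))
  # construct panels whose measured dG falls on either side of each rule and
  # confirm screen_panel's flag column agrees with a direct rule evaluation
  cond <- conditions("amplification", 55, monovalent = 50, divalent = 1.5,
                     dntp = 0.8, oligo_conc = 111)
  oligos <- data.frame(name = c("a", "b", "c"),
                       sequence = c("CAGTTGCGCCTAGGTTAAGC",
                                    "GCTTAACCTAGGCGCAACTG",
                                    "GGGGGCAAAAGCCCCC"),
                       stringsAsFactors = FALSE)
  sc <- screen_panel(oligos, cond)
  all_s <- sc$all_structures
  for (r in seq_len(nrow(all_s))) {
    expected <- switch(all_s$type[r],
      cross_dimer = all_s$dG[r] <= -9,
      self_dimer = all_s$dG[r] <= -5,
      hairpin = all_s$dG[r] <= -5 ||
        (!is.na(all_s$tm[r]) && all_s$tm[r] + 3 >= 55))
    expect_identical(all_s$flagged[r], expected)
  }
  # hairpin Tm rule: 53 + 3 >= 55 flags even at weak dG
  expect_true(53 + 3 >= 55)
  expect_false(51.9 + 3 >= 55)
})

test_that("degenerate oligos are screened via their most stable variant", {
  cond <- conditions("amplification", 55, monovalent = 50, oligo_conc = 111)
  # R expands to A or G; the G variant extends a G/C stem
  oligos <- data.frame(name = "dg", sequence = "GGGGRCAAAAGCCCCC",
                       stringsAsFactors = FALSE)
  sc <- screen_panel(oligos, cond)
  concrete <- expand_degenerate("GGGGRCAAAAGCCCCC")
  per_variant <- vapply(concrete, function(s) hairpin(s, cond)$dG_at_temp,
                        numeric(1))
  expect_equal(sc$hairpins$dG, min(per_variant), tolerance = 1e-9)
  expect_identical(sc$hairpins$variant_index,
                   as.integer(which.min(per_variant) - 1L))
})
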