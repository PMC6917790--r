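mk_hit <- function(name, contig, start, len, strand, role = "forward_primer",
                   set = "s", mm = 0L, variant = 0L) {
  data.frame(oligo_name = name, variant_index = variant, role = role,
             set_id = set, contig_id = contig, strand = strand,
             start = as.integer(start), end = as.integer(start + len - 1L),
             mismatches = mm, mismatch_repr = "", matched_ref_seq = "",
             stringsAsFactors = FALSE)
}

test_that("orientation is determined by strand alone, probes excluded", {
  h <- rbind(mk_hit("f", "c", 1, 20, "+"),
             mk_hit("f2", "c", 1, 20, "-"),
             mk_hit("p", "c", 1, 20, "+", role = "probe"))
  o <- orient_hits(h)
  expect_identical(o$orientation, c("rightward", "leftward", NA))
})

test_that("pairing emits every in-range rightward/leftward combination", {
  f <- mk_hit("f", "c1", 100, 20, "+")
  r <- mk_hit("r", "c1", 300, 20, "-", role = "reverse_primer")
  p <- pair_hits(rbind(f, r), 1000)
  expect_identical(nrow(p), 1L)
  expect_identical(p$length, 220L)
  expect_identical(c(p$start, p$end), c(100L, 319L))

  expect_identical(nrow(pair_hits(rbind(f, r), 200)), 0L)

  # two rightward hits sharing one leftward hit -> two products
  f2 <- mk_hit("f2", "c1", 110, 20, "+")
  p2 <- pair_hits(rbind(f, f2, r), 1000)
  expect_identical(nrow(p2), 2L)
  expect_setequal(p2$length, c(220L, 210L))

  # a forward-role primer on the minus strand acts as the leftward side
  fr <- mk_hit("f3", "c1", 400, 20, "-")
  p3 <- pair_hits(rbind(f, fr), 1000)
  expect_identical(nrow(p3), 1L)
  expect_identical(p3$rev_name, "f3")

  # different contigs never pair
  expect_identical(nrow(pair_hits(rbind(f, transform(r, contig_id = "c2")),
                                  1000)), 0L)
})

test_that("cross-set products are emitted and flagged", {
  f <- mk_hit("a_F", "c1", 100, 20, "+", set = "setA")
  r <- mk_hit("b_R", "c1", 400, 20, "-", role = "reverse_primer", set = "setB")
  p <- pair_hits(rbind(f, r), 1000)
  expect_identical(p$set_id, "setA")
  expect_true(p$cross_set)
})

test_that("product count equals exhaustive combination count on random hit sets", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    hits <- do.call(rbind, lapply(seq_len(n), function(j) {
      mk_hit(paste0("o", j), "c1", sample(1:2000, 1), 20,
             sample(c("+", "-"), 1))
    }))
    maxlen <- sample(c(200L, 500L, 1000L), 1)
    p <- pair_hits(hits, maxlen)
    # independent O(n^2) count
    cnt <- 0L
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (hits$strand[a] == "+" && hits$strand[b] == "-" &&
          hits$start[a] <= hits$start[b] &&
          hits$end[b] - hits$start[a] + 1L <= maxlen) cnt <- cnt + 1L
    }
    expect_identical(nrow(p), cnt)
  }
})

test_that("probe attachment requires full containment, any strand", {
  f <- mk_hit("f", "c1", 100, 20, "+")
  r <- mk_hit("r", "c1", 300, 20, "-", role = "reverse_primer")
  prods <- pair_hits(rbind(f, r), 1000)  # [100, 319]
  inside <- mk_hit("pr1", "c1", 150, 20, "+", role = "probe")
  overhang <- mk_hit("pr2", "c1", 310, 20, "-", role = "probe")  # ends 329
  att <- attach_probes(prods, rbind(inside, overhang))
  expect_identical(att$probe_name, "pr1")
  # minus-strand probe inside is attached too
  att2 <- attach_probes(prods, mk_hit("pr3", "c1", 200, 20, "-", role = "probe"))
  expect_identical(nrow(att2), 1L)
  # two probes in one product -> two attachments
  att3 <- attach_probes(prods, rbind(inside,
                                     mk_hit("pr4", "c1", 180, 20, "+",
                                            role = "probe")))
  expect_identical(nrow(att3), 2L)
})

test_that("unpaired classification partitions the filtered hits", {
  f <- mk_hit("f", "c1", 100, 20, "+")
  r <- mk_hit("r", "c1", 300, 20, "-", role = "reverse_primer")
  lone_f <- mk_hit("lf", "c2", 50, 20, "+")
  lone_r <- mk_hit("lr", "c2", 1500, 20, "-", role = "reverse_primer")
  pr_in <- mk_hit("pi", "c1", 150, 20, "+", role = "probe")
  pr_out <- mk_hit("po", "c2", 900, 20, "+", role = "probe")
  hits <- rbind(f, r, lone_f, lone_r, pr_in, pr_out)
  prods <- pair_hits(hits, 1000)  # lf..lr span 1470 > 1000: both stay lone
  att <- attach_probes(prods, hits[hits$role == "probe", ])
  un <- classify_unpaired(hits, prods, att)
  expect_setequal(un$oligo_name, c("lf", "lr", "po"))
  expect_identical(un$category[match(c("lf", "lr", "po"), un$oligo_name)],
                   c("forward_without_reverse", "reverse_without_forward",
                     "probe_without_product"))
  # partition: every primer hit is in >= 1 product XOR unpaired
  in_prod <- unique(c(paste(prods$fwd_name, prods$contig_id, prods$fwd_start),
                      paste(prods$rev_name, prods$contig_id, prods$rev_start)))
  prim <- hits[hits$role != "probe", ]
  keys <- paste(prim$oligo_name, prim$contig_id, prim$start)
  unkeys <- paste(un$oligo_name, un$contig_id, un$start)[un$role != "probe"]
  expect_setequal(keys, union(in_prod, unkeys))
  expect_length(intersect(in_prod, unkeys), 0L)
})

test_that("degenerate summary aggregates variants, placements, best mismatch", {
  ol <- data.frame(name = c("dg", "plain"),
                   sequence = c("ACGTRGGCCATATTCGACTG", "ACGTACGTACGTACGTACGT"),
                   role = "forward_primer", set_id = "s",
                   is_degenerate = c(TRUE, FALSE), stringsAsFactors = FALSE)
  raw <- rbind(mk_hit("dg", "c1", 100, 20, "+", mm = 0L, variant = 0L),
               mk_hit("dg", "c1", 100, 20, "+", mm = 1L, variant = 1L),
               mk_hit("plain", "c1", 500, 20, "+"))
  s <- summarize_degenerate(ol, raw)
  expect_identical(nrow(s), 1L)  # non-degenerate omitted
  expect_identical(s$parent_name, "dg")
  expect_identical(s$n_variants_total, 2)
  expect_identical(s$n_variants_with_hits, 2L)
  expect_identical(s$n_distinct_placements, 1L)
  expect_identical(s$best_mismatch_count, 0L)

  # zero hits still yields a summary row
  s0 <- summarize_degenerate(ol, raw[raw$oligo_name == "plain", ])
  expect_identical(s0$n_distinct_placements, 0L)
  expect_true(is.na(s0$best_mismatch_count))
})

test_that("mapping annotation sets gene names and exact size match", {
  f <- mk_hit("p1_F", "c1", 100, 20, "+")
  r <- mk_hit("p1_R", "c1", 181, 20, "-", role = "reverse_primer")
  prods <- pair_hits(rbind(f, r), 1000)  # length 101
  mapping <- data.frame(oligo_name = c("p1_F", "p1_R"),
                        gene_name = "blaTEM",
                        expected_product_size = c(101L, NA),
                        info1 = "beta-lactamase", stringsAsFactors = FALSE)
  a <- annotate_products(prods, mapping)
  expect_identical(a$fwd_gene, "blaTEM")
  expect_true(a$size_match)
  expect_identical(a$fwd_info1, "beta-lactamase")

  # no expectation for either primer -> size_match NA
  mapping2 <- transform(mapping, expected_product_size = NA_integer_)
  expect_true(is.na(annotate_products(prods, mapping2)$size_match))

  # unmapped oligos leave fields empty, run continues
  a3 <- annotate_products(prods, mapping[0, ])
  expect_true(is.na(a3$fwd_gene))

  # off-by-one size fails exact match but passes with tolerance
  mapping4 <- transform(mapping, expected_product_size = c(102L, NA))
  expect_false(annotate_products(prods, mapping4)$size_match)
  expect_true(annotate_products(prods, mapping4, size_tolerance = 1L)$size_match)
})

test_that("product Tm follows the long-duplex empirical formula", {
  cond <- conditions("amplification", 55, monovalent = 50, divalent = 0,
                     dntp = 0, oligo_conc = 111)
  seq100 <- strrep("AGCT", 25)      # 100 bp, 50% GC
  expect_equal(product_tm(seq100, cond),
               81.5 + 16.6 * log10(0.05) + 0.41 * 50 - 675 / 100,
               tolerance = 1e-12)
  expect_equal(product_tm(seq100, cond), 73.65, tolerance = 1e-3)
  seq_at <- strrep("AT", 50)        # 0% GC
  expect_equal(product_tm(seq_at, cond), 53.15, tolerance = 1e-3)
  # Tm strictly increases with GC at fixed N and salt
  tms <- vapply(c(0, 25, 50, 75, 100) / 100, function(gc) {
    s <- paste0(strrep("GC", round(gc * 50)), strrep("AT", 50 - round(gc * 50)))
    product_tm(s, cond)
  }, numeric(1))
  expect_true(all(diff(tms) > 0))
  expect_error(product_tm("", cond), "zero-length")
  # below the length threshold: falls back to nearest-neighbor duplex Tm
  short <- "ACGTGCATGGCATGCA"
  expect_equal(product_tm(short, cond),
               duplex_thermo(short, chartr("ACGT", "TGCA", short), cond)$tm)
})
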