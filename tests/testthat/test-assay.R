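# Shared fixture: a 100-kb circle with one isolated, eligible 1-kb direct
# repeat pair, simulated as a 30:70 recombinant:reference mixture.
assay_fixture <- local({
  g <- sim_genome(1, 100000,
                  repeat_plan = data.frame(copies = 2, length = 1000,
                                           identity = 1),
                  placements = data.frame(family = "R1", copy = 1:2,
                                          chrom = "chr1",
                                          start = c(20000, 70000)),
                  seed = 90)
  rr <- g$repeats
  a <- as.list(setNames(rr[1, c("chrom", "start", "end", "strand")],
                        c("chromA", "startA", "endA", "strandA")))
  b <- as.list(setNames(rr[2, c("chrom", "start", "end", "strand")],
                        c("chromB", "startB", "endB", "strandB")))
  pair <- c(a, b)
  conf <- derive_recombinant(
    g, as.list(rr[1, c("chrom", "start", "end", "strand")]),
    as.list(rr[2, c("chrom", "start", "end", "strand")]))
  lib <- library_spec("12kb")
  w <- 0.3
  rs <- sim_read_pairs(mix_conformations(g, list(conf), c(1 - w, w)),
                       lib, 2500, seed = 91)
  mp <- classify_pairs(dedup_pairs(map_read_pairs(rs, g)), lib, g)
  list(g = g, pair = pair, lib = lib, mp = mp, w = w)
})

test_that("the worked-example counts give a 2% recombinant frequency", {
  f <- recombinant_frequency(c(505, 481, 8, 12))
  expect_equal(f, 20 / 1006)
  expect_equal(percent_label(f), "2%")
  expect_equal(recombinant_frequency(c(10, 12, 0, 0)), 0)
  expect_equal(recombinant_frequency(c(7, 7, 7, 7)), 0.5)
  expect_true(is.na(recombinant_frequency(c(0, 0, 0, 0))))
})

test_that("support counting recovers a planted mixture weight", {
  fx <- assay_fixture
  cs <- count_support(fx$g, fx$pair, fx$mp, fx$lib$window)
  n <- cs$C1 + cs$C2 + cs$R1 + cs$R2
  expect_gte(n, 200)
  f <- recombinant_frequency(cs)
  se <- sqrt(fx$w * (1 - fx$w) / n)
  expect_lt(abs(f - fx$w), 3 * se)
})

test_that("frequency is invariant under relabelling copy A and copy B", {
  fx <- assay_fixture
  cs <- count_support(fx$g, fx$pair, fx$mp, fx$lib$window)
  swapped <- list(chromA = fx$pair$chromB, startA = fx$pair$startB,
                  endA = fx$pair$endB, strandA = fx$pair$strandB,
                  chromB = fx$pair$chromA, startB = fx$pair$startA,
                  endB = fx$pair$endA, strandB = fx$pair$strandA)
  cs2 <- count_support(fx$g, swapped, fx$mp, fx$lib$window)
  expect_equal(recombinant_frequency(cs2), recombinant_frequency(cs))
  expect_equal(cs2$C1 + cs2$C2, cs$C1 + cs$C2)
})

test_that("the reversed-orientation control stays at zero for direct
          recombination", {
  fx <- assay_fixture
  cc <- reversed_control(fx$g, fx$pair, fx$mp, fx$lib$window)
  expect_equal(cc$R1 + cc$R2, 0L)
  expect_gt(cc$C1 + cc$C2, 0L)  # reference junctions unaffected
})

test_that("a repeat longer than the library span is not assayable", {
  fx <- assay_fixture
  big <- fx$pair
  big$endA <- big$startA + 20000L
  big$endB <- big$startB + 20000L
  cs <- count_support(fx$g, big, fx$mp, fx$lib$window)
  expect_false(cs$assayable)
  expect_true(is.na(cs$C1))
})

test_that("eligibility rules record the documented exclusion reasons", {
  g <- sim_genome(1, 60000, seed = 92)
  mkcat <- function(...) {
    df <- data.frame(..., stringsAsFactors = FALSE)
    df
  }
  base <- list(chromA = "chr1", strandA = "+", chromB = "chr1",
               strandB = "+", identity = 100, score = 100)
  cat_df <- rbind(
    # 40 bp, perfectly isolated: too short
    mkcat(chromA = "chr1", startA = 1000, endA = 1039, strandA = "+",
          chromB = "chr1", startB = 30000, endB = 30039, strandB = "+",
          length = 40, identity = 100, score = 40),
    # 94% identity
    mkcat(chromA = "chr1", startA = 2000, endA = 2199, strandA = "+",
          chromB = "chr1", startB = 32000, endB = 32199, strandB = "+",
          length = 200, identity = 94, score = 150),
    # copies 2 kb apart with a 3-kb library (max 6 kb): separation
    mkcat(chromA = "chr1", startA = 5000, endA = 5099, strandA = "+",
          chromB = "chr1", startB = 7200, endB = 7299, strandB = "+",
          length = 100, identity = 100, score = 100),
    # isolated 1-kb pair, copies ~25 kb apart: eligible
    mkcat(chromA = "chr1", startA = 10000, endA = 10999, strandA = "+",
          chromB = "chr1", startB = 36000, endB = 36999, strandB = "+",
          length = 1000, identity = 100, score = 1000))
  ann <- filter_assayable(cat_df, g, library_spec("3kb"))
  expect_equal(ann$reason[1], "min_length")
  expect_equal(ann$reason[2], "min_identity")
  expect_equal(ann$reason[3], "separation")
  expect_true(ann$eligible[4])
})

test_that("a correlated larger pair excludes its smaller neighbour", {
  g <- sim_genome(1, 100000, seed = 93)
  cat_df <- data.frame(
    chromA = "chr1", startA = c(10000, 10600), endA = c(10099, 12599),
    strandA = "+", chromB = "chr1", startB = c(50000, 50500),
    endB = c(50099, 52499), strandB = "+",
    length = c(100, 2000), identity = 100, score = c(100, 2000),
    stringsAsFactors = FALSE)
  ann <- filter_assayable(cat_df, g, library_spec("3kb"),
                          adjacency_rule = FALSE)
  expect_equal(ann$reason[1], "correlated_repeat")
  expect_true(ann$eligible[2])
})

test_that("short-pair subsampling is seeded and marks exclusions", {
  g <- sim_genome(1, 200000, seed = 94)
  n <- 40
  starts <- seq(1000, by = 2000, length.out = n)
  cat_df <- data.frame(
    chromA = "chr1", startA = starts, endA = starts + 99, strandA = "+",
    chromB = "chr1", startB = starts + 100000, endB = starts + 100099,
    strandB = "+", length = 100L, identity = 100, score = 100,
    stringsAsFactors = FALSE)
  ann <- filter_assayable(cat_df, g, c(1000, 1500),
                          adjacency_rule = FALSE,
                          subsample_short = list(fraction = 0.05,
                                                 max_len = 200, seed = 8))
  kept <- sum(ann$eligible)
  expect_equal(kept, 2L)  # 5% of 40
  expect_equal(sum(ann$reason == "subsampled_out", na.rm = TRUE), 38L)
  ann2 <- filter_assayable(cat_df, g, c(1000, 1500),
                           adjacency_rule = FALSE,
                           subsample_short = list(fraction = 0.05,
                                                  max_len = 200, seed = 8))
  expect_identical(ann$eligible, ann2$eligible)
})

test_that("the assay object carries counts, frequency, and the control", {
  fx <- assay_fixture
  cat_df <- find_repeat_pairs(fx$g)
  asy <- recomb_assay(fx$g, cat_df, fx$mp, fx$lib)
  t <- asy$table
  expect_s3_class(asy, "recomb_assay")
  el <- which(t$eligible)
  expect_equal(length(el), 1L)
  expect_equal(t$length[el], 1000L)
  se <- sqrt(fx$w * (1 - fx$w) / t$n[el])
  expect_lt(abs(t$frequency[el] - fx$w), 3 * se)
  expect_equal(t$ctrl_frequency[el], 0)
  cf <- coef(asy)
  expect_equal(unname(cf[el]), t$frequency[el])
  ci <- confint(asy)
  expect_true(ci[el, 1] < fx$w && fx$w < ci[el, 2])
  expect_output(print(asy), "recomb_assay")
  expect_output(print(summary(asy)), "repeat pairs assayed")
})

test_that("insufficient spanning support is flagged, not reported as 0", {
  fx <- assay_fixture
  few <- fx$mp[seq_len(30), , drop = FALSE]
  attr(few, "read_length") <- attr(fx$mp, "read_length")
  class(few) <- class(fx$mp)
  cat_df <- find_repeat_pairs(fx$g)
  asy <- recomb_assay(fx$g, cat_df, few, fx$lib, min_support = 5)
  t <- asy$table
  expect_true(all(!t$eligible))
  expect_true("insufficient_support" %in% t$reason)
  expect_true(all(is.na(t$frequency)))
})
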