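test_that("the smallest tandem duplication is found at exact coordinates", {
  g <- genome_model(c(chr1 = "ACGTACGT"), circular = FALSE)
  cat_df <- find_exact_repeats(g, min_len = 4)
  df <- as.data.frame(cat_df)
  # one forward pair (1,4)/(5,8); the sequence is also its own reverse
  # complement, so palindromic inverted matches may be reported too
  fwd <- df[df$strandB == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(unlist(fwd[1, c("startA", "endA", "startB", "endB")],
                      use.names = FALSE), c(1, 4, 5, 8))
  expect_equal(fwd$identity, 100)
})

test_that("exact finder matches the diagonal-scan oracle on random genomes", {
  set.seed(70)
  for (k in 1:5) {
    g <- genome_model(c(chr1 = random_seq(2000)), circular = FALSE)
    got <- catalog_for_compare(find_exact_repeats(g, min_len = 8))
    want <- oracle_exact_repeats(g, min_len = 8)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("exact finder matches the oracle across two chromosomes", {
  set.seed(71)
  shared <- random_seq(40)
  c1 <- paste0(random_seq(500), shared, random_seq(500))
  c2 <- paste0(random_seq(300), revcomp(shared), random_seq(700))
  g <- genome_model(c(a = c1, b = c2), circular = FALSE)
  got <- catalog_for_compare(find_exact_repeats(g, min_len = 8))
  want <- oracle_exact_repeats(g, min_len = 8)
  expect_equal(got, want, ignore_attr = TRUE)
  expect_true(any(got$strandB == "-" & got$length >= 40))
})

test_that("repeats wrapping the circular origin are recovered", {
  set.seed(72)
  rep_seq <- random_seq(60)
  # copy 2 straddles the origin: last 30 bp at the end, first 30 at start
  body <- random_seq(1000)
  seq <- paste0(substr(rep_seq, 31, 60), body, random_seq(200), rep_seq,
                random_seq(150), substr(rep_seq, 1, 30))
  g <- genome_model(c(chr1 = seq), circular = TRUE)
  cat_df <- find_exact_repeats(g, min_len = 30)
  df <- as.data.frame(cat_df)
  expect_true(any(df$length >= 60 & (df$startA > df$endA | df$startB > df$endB)))
})

test_that("planted 30-bp perfect duplicates are reported and 29-bp are not", {
  g <- sim_genome(1, 12000,
                  repeat_plan = data.frame(family = c("f30", "f29"),
                                           copies = 2, length = c(30, 29),
                                           identity = 1),
                  seed = 73)
  cat_df <- find_repeat_pairs(g)
  expect_equal(nrow(cat_df), 1L)
  expect_equal(cat_df$length, 30L)
  expect_equal(cat_df$score, 30)
  expect_equal(cat_df$identity, 100)
})

test_that("planted identity is recovered within one point", {
  g <- sim_genome(1, 30000,
                  repeat_plan = data.frame(copies = 2, length = 100,
                                           identity = 0.96),
                  seed = 74)
  cat_df <- find_repeat_pairs(g)
  expect_equal(nrow(cat_df), 1L)
  expect_lt(abs(cat_df$identity - 96), 1 + 1e-9)
})

test_that("the catalogue is deterministic", {
  g <- sim_genome(1, 20000,
                  repeat_plan = data.frame(copies = 3, length = 400,
                                           identity = 0.97),
                  seed = 75)
  c1 <- find_repeat_pairs(g)
  c2 <- find_repeat_pairs(g)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("inverted planted copies are reported on the minus strand", {
  g <- sim_genome(1, 20000,
                  repeat_plan = data.frame(copies = 2, length = 300,
                                           orientation = "inverted"),
                  seed = 76)
  cat_df <- find_repeat_pairs(g)
  expect_equal(nrow(cat_df), 1L)
  expect_equal(cat_df$strandB, "-")
  expect_equal(cat_df$length, 300L)
})

test_that("every exact pair above threshold has a self-comparison hit", {
  g <- sim_genome(1, 15000,
                  repeat_plan = data.frame(family = c("x", "y"), copies = 2,
                                           length = c(50, 120), identity = 1),
                  seed = 77)
  ex <- find_exact_repeats(g, min_len = 30)
  bl <- find_repeat_pairs(g)
  for (i in seq_len(nrow(ex))) {
    covered <- any(
      bl$chromA == ex$chromA[i] & bl$chromB == ex$chromB[i] &
        bl$startA <= ex$startA[i] & bl$endA >= ex$endA[i] &
        bl$startB <= ex$startB[i] & bl$endB >= ex$endB[i] &
        bl$identity == 100)
    expect_true(covered)
  }
})
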