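test_that("error-free reads from single-copy sequence map at truth", {
  g <- sim_genome(1, 20000, seed = 61)
  lib <- library_spec("3kb", read_length = 80, error_rate = 0,
                      duplicate_rate = 0)
  rs <- sim_read_pairs(g, lib, 400, seed = 62)
  mp <- map_read_pairs(rs, g)
  expect_true(all(mp$status == "mapped"))
  expect_equal(mp$start1, rs$truth$frag_start)
  expect_true(all(mp$strand1 == "+" & mp$strand2 == "-"))
  L <- 20000L
  expect_equal(mp$pos5_2,
               as.integer(((rs$truth$frag_start + rs$truth$span - 2) %% L) + 1))
})

test_that("reads wholly inside a two-copy perfect repeat are ambiguous", {
  g <- sim_genome(1, 20000,
                  repeat_plan = data.frame(copies = 2, length = 500),
                  placements = data.frame(family = "R1", copy = 1:2,
                                          chrom = "chr1",
                                          start = c(4000, 12000)),
                  seed = 63)
  inside <- substr(g$chroms[[1]], 4100, 4179) # 80 bp inside copy 1
  outside <- substr(g$chroms[[1]], 1000, 1079)
  rs <- list(reads1 = c(p1 = inside), reads2 = c(p1 = revcomp(outside)))
  mp <- map_read_pairs(rs, g)
  expect_equal(mp$status, "ambiguous")
  expect_equal(mp$nbest1, 2L)
  expect_equal(mp$nbest2, 1L)
})

test_that("mapping tolerates the configured substitution error rate", {
  g <- sim_genome(1, 30000, seed = 64)
  lib <- library_spec("3kb", read_length = 100, error_rate = 0.01,
                      duplicate_rate = 0)
  rs <- sim_read_pairs(g, lib, 500, seed = 65)
  mp <- map_read_pairs(rs, g)
  at_truth <- mp$status == "mapped" & mp$start1 == rs$truth$frag_start
  expect_gte(mean(at_truth), 0.99)
})

test_that("duplicate flagging needs both ends to match", {
  p <- make_pairs(
    list(chrom1 = "c", start1 = 100L, strand1 = "+",
         chrom2 = "c", start2 = 2900L, strand2 = "-"),
    list(chrom1 = "c", start1 = 100L, strand1 = "+",
         chrom2 = "c", start2 = 2900L, strand2 = "-"),  # full duplicate
    list(chrom1 = "c", start1 = 100L, strand1 = "+",
         chrom2 = "c", start2 = 3400L, strand2 = "-"))  # left end only
  d <- dedup_pairs(p)
  expect_equal(d$duplicate, c(FALSE, TRUE, FALSE))
})

test_that("the windowed orientation test reproduces the library rules", {
  g <- genome_model(c(c = random_seq(50000)))
  mk <- function(start2) make_pairs(
    list(chrom1 = "c", start1 = 1000L, strand1 = "+",
         chrom2 = "c", start2 = start2, strand2 = "-"))
  lib3 <- library_spec("3kb")
  # proper orientation at span 5000 in a 3-kb library: consistent
  cp <- classify_pairs(dedup_pairs(mk(5900L)), lib3, g)
  expect_equal(cp$span, 5000L)
  expect_equal(cp$label, "consistent")
  # span 20000 in a 12-kb library: inconsistent
  cp2 <- classify_pairs(dedup_pairs(mk(20900L)), library_spec("12kb"), g)
  expect_equal(cp2$span, 20000L)
  expect_equal(cp2$label, "inconsistent")
  # same-strand pairs are never consistent
  ss <- make_pairs(list(chrom1 = "c", start1 = 1000L, strand1 = "+",
                        chrom2 = "c", start2 = 3000L, strand2 = "+"))
  expect_equal(classify_pairs(dedup_pairs(ss), lib3, g)$label, "inconsistent")
  # cross-chromosome pairs have no span and are inconsistent
  g2 <- genome_model(c(c = random_seq(10000), d = random_seq(10000)))
  xc <- make_pairs(list(chrom1 = "c", start1 = 1000L, strand1 = "+",
                        chrom2 = "d", start2 = 3000L, strand2 = "-"))
  cc <- classify_pairs(dedup_pairs(xc), lib3, g2)
  expect_true(is.na(cc$span))
  expect_equal(cc$label, "inconsistent")
})

test_that("window widening never turns a consistent pair inconsistent", {
  g <- sim_genome(1, 30000, seed = 66)
  rs <- sim_read_pairs(g, library_spec("3kb", read_length = 60), 300,
                       seed = 67)
  mp <- dedup_pairs(map_read_pairs(rs, g))
  narrow <- classify_pairs(mp, c(2000, 4000), g)
  wide <- classify_pairs(mp, c(1000, 6000), g)
  was_consistent <- narrow$label == "consistent"
  expect_true(all(wide$label[was_consistent] == "consistent"))
})

test_that("reference-only error-free reads are all consistent", {
  g <- sim_genome(1, 40000, seed = 68)
  lib <- library_spec("3kb", read_length = 80, error_rate = 0,
                      duplicate_rate = 0)
  rs <- sim_read_pairs(g, lib, 600, seed = 69)
  mp <- classify_pairs(dedup_pairs(map_read_pairs(rs, g)), lib, g)
  informative <- mp$label %in% c("consistent", "inconsistent")
  expect_equal(sum(mp$label == "inconsistent"), 0L)
  expect_gt(sum(informative), 590)
})

test_that("SAM ingestion reconstructs pair coordinates", {
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:c\tLN:50000",
    paste("q1", 99, "c", 1000, 60, "50M", "=", 3851, 2901,
          strrep("A", 50), strrep("I", 50), sep = "\t"),
    paste("q1", 147, "c", 3851, 60, "50M", "=", 1000, -2901,
          strrep("A", 50), strrep("I", 50), sep = "\t"))
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  mp <- read_sam_pairs(f)
  expect_equal(nrow(mp), 1L)
  expect_equal(mp$status, "mapped")
  expect_equal(mp$start1, 1000L)
  expect_equal(mp$strand2, "-")
  g <- genome_model(c(c = random_seq(50000)))
  cp <- classify_pairs(dedup_pairs(mp), library_spec("3kb"), g)
  expect_equal(cp$span, 2901L)
  expect_equal(cp$label, "consistent")
})
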