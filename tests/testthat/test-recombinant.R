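# String-surgery oracle: recombinant junctions built by explicit paste()
# on a toy circle, compared to the segment-map construction.

test_that("direct-repeat fission conserves length and matches string surgery", {
  set.seed(21)
  F1 <- random_seq(400); R <- random_seq(120); M <- random_seq(600)
  F2 <- random_seq(880)
  seq <- paste0(F1, R, M, R, F2)        # 2 kb toy circle
  g <- genome_model(c(chr1 = seq))
  a1 <- nchar(F1) + 1L; a2 <- a1 + nchar(R) - 1L
  b1 <- a2 + nchar(M) + 1L; b2 <- b1 + nchar(R) - 1L
  conf <- derive_recombinant(
    g, list(chrom = "chr1", start = a1, end = a2, strand = "+"),
    list(chrom = "chr1", start = b1, end = b2, strand = "+"))
  expect_equal(conf$kind, "fission")
  expect_equal(sum(nchar(conf$genome$chroms)), nchar(seq))
  # expected subcircles by cut-and-paste
  inner <- paste0(R, M)
  outer <- paste0(R, F2, F1)
  vs <- unname(conf$genome$chroms)
  expect_true(any(vapply(vs, function(x)
    mtrecomb:::is_rotation(x, inner), logical(1))))
  expect_true(any(vapply(vs, function(x)
    mtrecomb:::is_rotation(x, outer), logical(1))))
})

test_that("inverted-repeat crossover inverts the intervening segment", {
  set.seed(22)
  F1 <- random_seq(300); R <- random_seq(100); M <- random_seq(500)
  F2 <- random_seq(600)
  seq <- paste0(F1, R, M, revcomp(R), F2)
  g <- genome_model(c(chr1 = seq))
  a1 <- nchar(F1) + 1L; a2 <- a1 + 99L
  b1 <- a2 + nchar(M) + 1L; b2 <- b1 + 99L
  conf <- derive_recombinant(
    g, list(chrom = "chr1", start = a1, end = a2, strand = "+"),
    list(chrom = "chr1", start = b1, end = b2, strand = "-"))
  expect_equal(conf$kind, "inversion")
  expected <- paste0(F1, R, revcomp(M), revcomp(R), F2)
  expect_true(mtrecomb:::is_rotation(conf$genome$chroms[[1]], expected))
})

test_that("fusing two circles through a shared repeat is an involution", {
  g <- sim_genome(2, 8000,
                  repeat_plan = data.frame(copies = 2, length = 400,
                                           placement = "across"),
                  seed = 23, margin = 300)
  rr <- g$repeats
  fus <- derive_recombinant(
    g, as.list(rr[1, c("chrom", "start", "end", "strand")]),
    as.list(rr[2, c("chrom", "start", "end", "strand")]))
  expect_equal(fus$kind, "fusion")
  expect_equal(sum(nchar(fus$genome$chroms)), sum(nchar(g$chroms)))
  cps <- fus$copies
  back <- derive_recombinant(
    fus$genome,
    list(chrom = cps$vchrom[1], start = cps$start[1], end = cps$end[1],
         strand = "+"),
    list(chrom = cps$vchrom[2], start = cps$start[2], end = cps$end[2],
         strand = "+"))
  regen <- unname(back$genome$chroms)
  for (orig in unname(g$chroms)) {
    expect_true(any(vapply(regen, function(x)
      mtrecomb:::same_circle(x, orig), logical(1))))
  }
})

test_that("crossover between unequal-length copies fails", {
  g <- sim_genome(1, 5000, seed = 3)
  expect_error(derive_recombinant(
    g, list(chrom = "chr1", start = 100, end = 199, strand = "+"),
    list(chrom = "chr1", start = 3000, end = 3050, strand = "+")),
    "unequal")
})

test_that("position projection is the identity away from the crossover", {
  g <- sim_genome(1, 10000,
                  repeat_plan = data.frame(copies = 2, length = 200),
                  placements = data.frame(family = "R1", copy = 1:2,
                                          chrom = "chr1",
                                          start = c(2000, 6000)),
                  seed = 31)
  conf <- derive_recombinant(
    g, as.list(g$repeats[1, c("chrom", "start", "end", "strand")]),
    as.list(g$repeats[2, c("chrom", "start", "end", "strand")]))
  # a position between the copies lives on the inner subcircle
  p <- mtrecomb:::project_position(conf$map, "chr1", 4000, "+")
  expect_equal(nrow(p), 1L)
  expect_match(p$vchrom, "_sub2")
  vseq <- conf$genome$chroms[[p$vchrom]]
  expect_identical(substr(vseq, p$vpos, p$vpos),
                   substr(g$chroms[[1]], 4000, 4000))
})
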