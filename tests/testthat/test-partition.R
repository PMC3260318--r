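test_that("raw scores of perfect hits match the scoring arithmetic", {
  set.seed(120)
  seg50 <- random_seq(50)
  h <- local_align_score(seg50, c(db = seg50), profile_plastid())
  expect_equal(h$score, 250) # 50 x 5: the minimal perfect plastid hit
  seg35 <- random_seq(35)
  h2 <- local_align_score(seg35, c(db = seg35), profile_mt())
  expect_equal(h2$score, 70) # 35 x 2: the minimal perfect conserved hit
  # a 49-bp perfect segment cannot reach the 250 threshold
  seg49 <- random_seq(49)
  h3 <- local_align_score(seg49, c(db = seg49), profile_plastid())
  expect_equal(nrow(h3), 0L)
})

test_that("unrelated random sequences rarely reach the thresholds", {
  set.seed(121)
  n_hit <- 0L
  for (k in 1:30) {
    q <- random_seq(1000)
    s <- random_seq(1000)
    if (nrow(local_align_score(q, c(db = s), profile_mt())) > 0) {
      n_hit <- n_hit + 1L
    }
  }
  expect_lte(n_hit, 1L)
})

test_that("AT content counts unambiguous bases only", {
  expect_equal(at_content("ATAT"), 100)
  expect_equal(at_content("ACGT"), 50)
  set.seed(122)
  x <- random_seq(500)
  ch <- strsplit(x, "")[[1]]
  expect_equal(at_content(x), 100 * mean(ch %in% c("A", "T")))
  expect_error(at_content(""), "empty")
})

test_that("reverse-complement database hits are found", {
  set.seed(123)
  seg <- random_seq(120)
  h <- local_align_score(seg, c(db = revcomp(seg)), profile_mt())
  expect_gte(nrow(h), 1L)
  expect_equal(h$strand[1], "-")
  expect_gte(max(h$score), 240)
})

test_that("translated hits find protein homology through synonymous change", {
  set.seed(124)
  aa <- paste(sample(c("M", "K", "L", "V", "D", "E", "G", "W", "P", "F"),
                     80, replace = TRUE), collapse = "")
  codons <- c(M = "ATG", K = "AAA", L = "CTT", V = "GTT", D = "GAT",
              E = "GAA", G = "GGT", W = "TGG", P = "CCA", F = "TTT")
  nt <- paste(codons[strsplit(aa, "")[[1]]], collapse = "")
  h <- translated_align_score(nt, c(prot = aa), min_score = 140)
  expect_gte(nrow(h), 1L)
  expect_equal(h$frame[1], 1L)
  # and on the reverse strand
  h2 <- translated_align_score(revcomp(nt), c(prot = aa), min_score = 140)
  expect_gte(nrow(h2), 1L)
  expect_lt(h2$frame[1], 0L)
})

test_that("the cascade assigns precedence and conserves total length", {
  set.seed(125)
  pl_src <- random_seq(2000)
  mt_src <- random_seq(2000)
  block_pl <- substr(pl_src, 201, 1200)   # 1000 bp plastid
  block_mt <- substr(mt_src, 501, 1300)   # 800 bp mt-conserved
  sq <- paste0(random_seq(600), block_pl, random_seq(900), block_mt,
               random_seq(700))
  g <- genome_model(c(chr1 = sq), circular = FALSE)
  part <- classify_intergenic(g, plastid_db = c(pl = pl_src),
                              mt_db = c(mt = mt_src))
  s <- part$summary
  expect_equal(sum(s$bp), nchar(sq))     # exact conservation
  expect_equal(sum(s$percent), 100)
  pl_bp <- s$bp[s$category == "plastid"]
  mt_bp <- s$bp[s$category == "mt_conserved"]
  expect_lt(abs(pl_bp - 1000), 50)
  expect_lt(abs(mt_bp - 800), 50)
  # labels tile the interval without gaps or overlaps
  lb <- part$labels
  expect_equal(min(lb$start), 1L)
  expect_equal(max(lb$end), nchar(sq))
  expect_true(all(lb$start[-1] == head(lb$end, -1) + 1))
})

test_that("gene exclusion and the AT filter veto plastid hits", {
  set.seed(126)
  # AT-rich plastid-like segment (> 72% AT) must be discarded
  at_seg <- paste(sample(c("A", "T", "G"), 400, replace = TRUE,
                         prob = c(0.45, 0.45, 0.10)), collapse = "")
  sq <- paste0(random_seq(300), at_seg, random_seq(300))
  g <- genome_model(c(chr1 = sq), circular = FALSE)
  part <- classify_intergenic(g, plastid_db = c(atp_like = at_seg))
  expect_equal(part$summary$bp[part$summary$category == "plastid"], 0)
  # an excluded gene id is skipped even with a perfect hit
  seg <- random_seq(400)
  sq2 <- paste0(random_seq(300), seg, random_seq(300))
  g2 <- genome_model(c(chr1 = sq2), circular = FALSE)
  p_all <- classify_intergenic(g2, plastid_db = c(atpA = seg))
  p_exc <- classify_intergenic(g2, plastid_db = c(atpA = seg),
                               exclude_ids = "atpA")
  expect_gt(p_all$summary$bp[1], 0)
  expect_equal(p_exc$summary$bp[1], 0)
})

test_that("raising a threshold never invents conserved sequence", {
  set.seed(127)
  src <- random_seq(1500)
  sq <- paste0(random_seq(400), substr(src, 101, 700), random_seq(400))
  g <- genome_model(c(chr1 = sq), circular = FALSE)
  lo <- classify_intergenic(g, mt_db = c(db = src))
  strict <- profile_mt(); strict$min_score <- 500
  hi <- classify_intergenic(g, mt_db = c(db = src),
                            profiles = list(mt = strict))
  lo_cons <- sum(lo$summary$bp[lo$summary$category != "uncharacterized"])
  hi_cons <- sum(hi$summary$bp[hi$summary$category != "uncharacterized"])
  expect_lte(hi_cons, lo_cons)
})

test_that("empty databases leave everything uncharacterized", {
  g <- genome_model(c(chr1 = random_seq(1000)), circular = FALSE)
  part <- classify_intergenic(g)
  expect_equal(part$summary$bp[part$summary$category == "uncharacterized"],
               1000)
})
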