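## Dispersed-repeat detection by genome self-comparison.
##
## Seeding: every word of the configured size is indexed over all
## chromosomes (circular sequences are extended past the origin by one
## word so wrap-spanning repeats seed normally). Word matches between
## distinct loci, on the forward strand or between forward and reverse
## complement, are grouped on (anti)diagonals into clusters, extended
## ungapped (best-scoring contiguous stretch), and refined by gapped local
## alignment when that can improve the raw score. Hits at or above the raw
## score threshold form the repeat catalogue.

#' Scoring scheme for genome self-comparison
#'
#' Defaults are chosen so that the minimal perfect repeat reaching the
#' default raw-score threshold of 30 is exactly 30 bp long.
#'
#' @param match match reward (positive).
#' @param mismatch mismatch score (negative).
#' @param gap_open,gap_extend gap penalties as positive magnitudes.
#' @param word_size exact seed length in bp.
#' @return A list of class `repeat_scoring`.
#' @export
repeat_scoring <- function(match = 1L, mismatch = -2L, gap_open = 5L,
                           gap_extend = 2L, word_size = 11L) {
  fail_if(match <= 0, "match reward must be positive")
  fail_if(mismatch >= 0, "mismatch score must be negative")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = word_size),
            class = "repeat_scoring")
}

## Word tables for all chromosomes: forward-strand words and, at the same
## positions, the reverse complement of the window (so a key collision
## between a "+" entry and a "-" entry is a cross-strand match).
genome_words <- function(genome, w) {
  out <- lapply(names(genome$chroms), function(cn) {
    sq <- genome$chroms[[cn]]
    L <- nchar(sq)
    if (L < w) return(NULL)
    ext <- if (genome$circular[[cn]]) circ_ext(sq, w - 1L) else sq
    npos <- if (genome$circular[[cn]]) L else L - w + 1L
    pos <- seq_len(npos)
    fwd <- substring(ext, pos, pos + w - 1L)
    rcx <- revcomp(ext)
    ne <- nchar(ext)
    rev <- substring(rcx, ne - (pos + w - 1L) + 1L, ne - pos + 1L)
    data.frame(chrom = cn, pos = pos, fwd = fwd, rev = rev,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Pairs of entries sharing a forward word (same-strand seed matches).
seed_pairs_plus <- function(wt, max_word_hits) {
  dup <- duplicated(wt$fwd) | duplicated(wt$fwd, fromLast = TRUE)
  idx <- which(dup)
  if (!length(idx)) return(NULL)
  o <- idx[order(wt$fwd[idx], method = "radix")]
  k <- wt$fwd[o]
  r <- rle(k)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gi <- which(r$lengths >= 2L & r$lengths <= max_word_hits)
  if (!length(gi)) return(NULL)
  mats <- lapply(gi, function(g) combn(o[starts[g]:ends[g]], 2L))
  m <- do.call(cbind, mats)
  i <- m[1L, ]; j <- m[2L, ]
  # canonical: (chrom,pos) of the first entry <= second
  swap <- wt$chrom[i] > wt$chrom[j] |
    (wt$chrom[i] == wt$chrom[j] & wt$pos[i] > wt$pos[j])
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  data.frame(c1 = wt$chrom[i], p1 = wt$pos[i],
             c2 = wt$chrom[j], p2 = wt$pos[j], stringsAsFactors = FALSE)
}

## Pairs of entries where a forward word equals the reverse-complement
## word of another locus (cross-strand seed matches).
seed_pairs_minus <- function(wt, max_word_hits) {
  # restrict to keys present in both the forward and reverse tables
  selp <- which(!is.na(match(wt$fwd, wt$rev)))
  selm <- which(!is.na(match(wt$rev, wt$fwd)))
  if (!length(selp) || !length(selm)) return(NULL)
  keys <- c(wt$fwd[selp], wt$rev[selm])
  src <- rep(1:2, c(length(selp), length(selm)))
  idx <- c(selp, selm)
  o <- order(keys, method = "radix")
  k <- keys[o]
  r <- rle(k)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  res <- vector("list", length(r$lengths))
  for (g in seq_along(r$lengths)) {
    if (r$lengths[g] < 2L || r$lengths[g] > 2L * max_word_hits) next
    sel <- o[starts[g]:ends[g]]
    pi <- idx[sel[src[sel] == 1L]]
    mi <- idx[sel[src[sel] == 2L]]
    if (!length(pi) || !length(mi)) next
    eg <- expand.grid(i = pi, j = mi)
    res[[g]] <- eg
  }
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) return(NULL)
  i <- res$i; j <- res$j
  # canonical: keep one of the two mirror representations
  keep <- wt$chrom[i] < wt$chrom[j] |
    (wt$chrom[i] == wt$chrom[j] & wt$pos[i] <= wt$pos[j])
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(NULL)
  unique(data.frame(c1 = wt$chrom[i], p1 = wt$pos[i],
                    c2 = wt$chrom[j], p2 = wt$pos[j], stringsAsFactors = FALSE))
}

## Best-scoring contiguous subarray (Kadane via cumulative sums).
## Returns c(score, i1, i2) or NULL if all-negative.
best_subarray <- function(s) {
  cs <- cumsum(s)
  pre <- c(0, cs[-length(cs)])
  m <- cummin(pre)
  val <- cs - m
  i2 <- which.max(val)
  if (val[i2] <= 0) return(NULL)
  i1 <- which(pre[seq_len(i2)] == m[i2])[1L]
  c(score = val[i2], i1 = i1, i2 = i2)
}

## Split cluster members (sorted positions) at gaps larger than `gap`.
split_clusters <- function(p, gap) {
  o <- order(p)
  brk <- cumsum(c(0L, diff(p[o]) > gap))
  split(o, brk)
}

ext_seq <- function(genome, cn) {
  sq <- genome$chroms[[cn]]
  if (genome$circular[[cn]]) circ_ext(sq, nchar(sq) - 1L) else sq
}

## Reduce an interval found on the extended sequence onto 1..L; returns
## c(start, end) where end < start encodes a wrap through the origin.
reduce_interval <- function(s, e, L, circular) {
  if (!circular) return(c(s, e))
  s2 <- mod1(s, L)
  e2 <- mod1(e, L)
  c(s2, e2)
}

#' Find imperfect dispersed repeat pairs by genome self-comparison
#'
#' Seed-and-extend local alignment of a genome against itself, within and
#' between chromosomes and on both strands, honouring circular origins.
#' All local alignments between distinct loci with raw score at least
#' `min_score` are reported as repeat pairs, each with aligned length,
#' percent identity (matches per alignment column, gaps counted as
#' columns) and raw score. Overlapping hits are reported as distinct
#' pairs; no chaining or merging is performed. The only excluded hit is
#' the trivial self-alignment of a locus with itself.
#'
#' @param genome a [genome_model()].
#' @param scoring a [repeat_scoring()].
#' @param min_score raw-score threshold for reporting.
#' @param cluster_gap max distance (bp) between seeds merged into one
#'   candidate cluster on a diagonal.
#' @param pad flanking bases added around a seed cluster before extension.
#' @param max_word_hits seed words occurring more often than this are
#'   skipped (low-complexity guard).
#' @return A data frame of class `repeat_catalog`: one row per repeat pair
#'   with columns `chromA, startA, endA, strandA, chromB, startB, endB,
#'   strandB, length, identity, score`. `end < start` encodes an interval
#'   wrapping the circular origin.
#' @export
find_repeat_pairs <- function(genome, scoring = repeat_scoring(),
                              min_score = 30L, cluster_gap = 200L,
                              pad = 400L, max_word_hits = 100L) {
  w <- scoring$word_size
  wt <- genome_words(genome, w)
  if (is.null(wt)) return(empty_catalog(scoring, min_score))
  prefilter <- max(w, floor(min_score / 2))
  submat <- matrix(scoring$mismatch, 4L, 4L,
                   dimnames = list(DNA_BASES, DNA_BASES))
  diag(submat) <- scoring$match

  exts <- lapply(setNames(nm = names(genome$chroms)),
                 function(cn) ext_seq(genome, cn))
  hits <- list()
  add_hit <- function(c1, s1, e1, c2, s2, e2, strand2, len, ident, score) {
    hits[[length(hits) + 1L]] <<- data.frame(
      chromA = c1, startA = s1, endA = e1, strandA = "+",
      chromB = c2, startB = s2, endB = e2, strandB = strand2,
      length = len, identity = ident, score = score, stringsAsFactors = FALSE)
  }

  refine <- function(xA, xB, ungapped) {
    ## gapped local alignment; returns list(score, a1, a2, b1, b2, len, id)
    ## with b-range in coordinates of xB, or NULL to keep the ungapped hit
    pa <- Biostrings::pairwiseAlignment(
      xA, xB, type = "local", substitutionMatrix = submat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    sc <- Biostrings::score(pa)
    if (sc <= ungapped) return(NULL)
    gp <- as.character(Biostrings::pattern(pa))
    cols <- nchar(gp)
    rp <- Biostrings::pattern(pa)
    rs <- Biostrings::subject(pa)
    list(score = sc,
         a1 = Biostrings::start(rp), a2 = Biostrings::end(rp),
         b1 = Biostrings::start(rs), b2 = Biostrings::end(rs),
         len = cols, id = 100 * Biostrings::nmatch(pa) / cols)
  }

  process_cluster <- function(c1, c2, p1s, key2, antidiag) {
    LA <- nchar(genome$chroms[[c1]])
    LB <- nchar(genome$chroms[[c2]])
    extA <- exts[[c1]]
    extB <- exts[[c2]]
    aLo <- min(p1s) - pad
    aHi <- max(p1s) + w - 1L + pad
    if (!antidiag) {
      d <- key2
      bLo <- aLo + d; bHi <- aHi + d
      tLo <- max(0L, 1L - aLo, 1L - bLo)
      aLo <- aLo + tLo; bLo <- bLo + tLo
      tHi <- max(0L, aHi - nchar(extA), bHi - nchar(extB))
      aHi <- aHi - tHi; bHi <- bHi - tHi
      if (aHi <= aLo) return(invisible())
      xA <- substr(extA, aLo, aHi)
      xB <- substr(extB, bLo, bHi)
    } else {
      s <- key2
      bLo <- s + w - 1L - aHi; bHi <- s + w - 1L - aLo
      tLo <- max(0L, 1L - bLo)           # trims aHi
      bLo <- bLo + tLo; aHi <- aHi - tLo
      tLo2 <- max(0L, 1L - aLo)          # trims bHi
      aLo <- aLo + tLo2; bHi <- bHi - tLo2
      tHi <- max(0L, aHi - nchar(extA))
      aHi <- aHi - tHi; bLo <- bLo + tHi
      tHi2 <- max(0L, bHi - nchar(extB))
      bHi <- bHi - tHi2; aLo <- aLo + tHi2
      if (aHi <= aLo || bHi <= bLo) return(invisible())
      xA <- substr(extA, aLo, aHi)
      xB <- revcomp(substr(extB, bLo, bHi))
    }
    mvec <- charToRaw(xA) == charToRaw(xB)
    svec <- ifelse(mvec, scoring$match, scoring$mismatch)
    reg_len <- length(svec)
    # a diagonal region can carry several distinct repeats (e.g. a tandem
    # array); peel off non-overlapping best-scoring stretches in turn
    for (iter in seq_len(50L)) {
      bs <- best_subarray(svec)
      if (is.null(bs) || bs["score"] < prefilter) break
      i1 <- bs[["i1"]]; i2 <- bs[["i2"]]
      ug_score <- bs[["score"]]
      ug_len <- i2 - i1 + 1L
      ug_id <- 100 * sum(mvec[i1:i2]) / ug_len
      res <- list(score = ug_score, a1 = i1, a2 = i2,
                  b1 = i1, b2 = i2, len = ug_len, id = ug_id)
      # gapped refinement inside a window around the ungapped stretch
      w1 <- max(1L, i1 - 100L); w2 <- min(reg_len, i2 + 100L)
      g <- refine(substr(xA, w1, w2), substr(xB, w1, w2), ug_score)
      if (!is.null(g)) {
        res <- list(score = g$score, a1 = w1 + g$a1 - 1L, a2 = w1 + g$a2 - 1L,
                    b1 = w1 + g$b1 - 1L, b2 = w1 + g$b2 - 1L,
                    len = g$len, id = g$id)
      }
      # mask the extracted stretch (finite so cumulative sums stay valid)
      svec[min(res$a1, res$b1):max(res$a2, res$b2)] <- -1e9
      if (res$score < min_score) next
      sA <- aLo + res$a1 - 1L; eA <- aLo + res$a2 - 1L
      if (!antidiag) {
        sB <- bLo + res$b1 - 1L; eB <- bLo + res$b2 - 1L
        strand2 <- "+"
      } else {
        nB <- bHi - bLo + 1L
        sB <- bLo + (nB - res$b2)
        eB <- bLo + (nB - res$b1)
        strand2 <- "-"
      }
      if (eA - sA + 1L > LA || eB - sB + 1L > LB) next
      ia <- reduce_interval(sA, eA, LA, genome$circular[[c1]])
      ib <- reduce_interval(sB, eB, LB, genome$circular[[c2]])
      if (c1 == c2 && ia[1] == ib[1] && ia[2] == ib[2] && strand2 == "+") {
        next # trivial self-alignment
      }
      add_hit(c1, ia[1], ia[2], c2, ib[1], ib[2], strand2,
              res$len, res$id, res$score)
    }
  }

  pp <- seed_pairs_plus(wt, max_word_hits)
  if (!is.null(pp)) {
    pp <- pp[!(pp$c1 == pp$c2 & pp$p1 == pp$p2), , drop = FALSE]
    d <- pp$p2 - pp$p1
    grp <- paste(pp$c1, pp$c2, d, sep = "|")
    for (g in split(seq_len(nrow(pp)), grp)) {
      dd <- d[g[1L]]
      if (pp$c1[g[1L]] == pp$c2[g[1L]] && dd == 0L) next
      for (cl in split_clusters(pp$p1[g], cluster_gap)) {
        process_cluster(pp$c1[g[1L]], pp$c2[g[1L]], pp$p1[g][cl], dd,
                        antidiag = FALSE)
      }
    }
  }
  pm <- seed_pairs_minus(wt, max_word_hits)
  if (!is.null(pm)) {
    s <- pm$p1 + pm$p2
    grp <- paste(pm$c1, pm$c2, s, sep = "|")
    for (g in split(seq_len(nrow(pm)), grp)) {
      for (cl in split_clusters(pm$p1[g], cluster_gap)) {
        process_cluster(pm$c1[g[1L]], pm$c2[g[1L]], pm$p1[g][cl], s[g[1L]],
                        antidiag = TRUE)
      }
    }
  }
  finish_catalog(hits, scoring, min_score, dominance = TRUE)
}

empty_catalog <- function(scoring, min_score) {
  df <- data.frame(chromA = character(), startA = integer(), endA = integer(),
                   strandA = character(), chromB = character(),
                   startB = integer(), endB = integer(), strandB = character(),
                   length = integer(), identity = numeric(), score = numeric(),
                   stringsAsFactors = FALSE)
  attr(df, "provenance") <- list(scoring = scoring, min_score = min_score)
  class(df) <- c("repeat_catalog", "data.frame")
  df
}

finish_catalog <- function(hits, scoring, min_score, dominance = FALSE) {
  if (!length(hits)) return(empty_catalog(scoring, min_score))
  cat_df <- do.call(rbind, hits)
  # canonical copy order
  swap <- cat_df$chromA > cat_df$chromB |
    (cat_df$chromA == cat_df$chromB & cat_df$startA > cat_df$startB)
  if (any(swap)) {
    tmp <- cat_df[swap, c("chromB", "startB", "endB")]
    cat_df[swap, c("chromB", "startB", "endB")] <-
      cat_df[swap, c("chromA", "startA", "endA")]
    cat_df[swap, c("chromA", "startA", "endA")] <- tmp
  }
  cat_df <- unique(cat_df)
  # drop hits dominated by an identical-or-larger hit describing the same
  # alignment (same locus pair, same diagonal up to slack); distinct
  # diagonals are genuinely different repeat pairs (periodic arrays) and
  # are kept even when their intervals nest
  if (dominance && nrow(cat_df) > 1L) {
    keep <- rep(TRUE, nrow(cat_df))
    diag_of <- ifelse(cat_df$strandB == "+",
                      cat_df$startB - cat_df$startA,
                      cat_df$startA + cat_df$endB)
    key <- paste(cat_df$chromA, cat_df$chromB, cat_df$strandB)
    for (g in split(seq_len(nrow(cat_df)), key)) {
      if (length(g) < 2L) next
      for (i in g) for (j in g) {
        if (i == j || !keep[i]) next
        if (cat_df$score[j] >= cat_df$score[i] &&
            abs(diag_of[j] - diag_of[i]) <= 10L &&
            contains_iv(cat_df$startA[j], cat_df$endA[j],
                        cat_df$startA[i], cat_df$endA[i]) &&
            contains_iv(cat_df$startB[j], cat_df$endB[j],
                        cat_df$startB[i], cat_df$endB[i]) &&
            !(cat_df$score[j] == cat_df$score[i] && j > i)) {
          keep[i] <- FALSE
        }
      }
    }
    cat_df <- cat_df[keep, , drop = FALSE]
  }
  o <- order(cat_df$chromA, cat_df$startA, cat_df$chromB, cat_df$startB)
  cat_df <- cat_df[o, , drop = FALSE]
  rownames(cat_df) <- NULL
  attr(cat_df, "provenance") <- list(scoring = scoring, min_score = min_score)
  class(cat_df) <- c("repeat_catalog", "data.frame")
  cat_df
}

## containment for possibly-wrapping intervals on the same chromosome
## (plain containment when neither wraps; wrap-aware otherwise)
contains_iv <- function(s1, e1, s2, e2) {
  if (e1 >= s1 && e2 >= s2) return(s1 <= s2 && e1 >= e2)
  if (e1 < s1 && e2 < s2) return(s1 <= s2 && e1 >= e2)
  if (e1 < s1) return(s2 >= s1 || e2 <= e1)
  FALSE
}

#' @export
print.repeat_catalog <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("repeat_catalog: %d pair(s), raw score >= %s\n",
              nrow(x), pv$min_score))
  if (nrow(x)) {
    cat(sprintf("  lengths %d-%d bp, identity %.1f-%.1f%%\n",
                min(x$length), max(x$length),
                min(x$identity), max(x$identity)))
    print.data.frame(head(as.data.frame(x), 10L))
    if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' Find maximal perfect repeat pairs
#'
#' Reports every maximal exact repeat pair -- two distinct loci with
#' identical sequence (forward or reverse complement) that cannot be
#' extended in either direction -- of length at least `min_len`, within
#' and between chromosomes, honouring circular origins.
#'
#' @param genome a [genome_model()].
#' @param min_len minimum repeat length in bp (>= 2).
#' @param max_word_hits low-complexity guard on seed words.
#' @return A `repeat_catalog` with 100% identity for every pair and raw
#'   score equal to the repeat length (unit match reward).
#' @export
find_exact_repeats <- function(genome, min_len = 30L, max_word_hits = 5000L) {
  fail_if(min_len < 2L, "min_len must be >= 2")
  scoring <- repeat_scoring(word_size = as.integer(min(min_len, 12L)))
  w <- scoring$word_size
  wt <- genome_words(genome, w)
  if (is.null(wt)) return(empty_catalog(scoring, min_len))

  comp0 <- c(A = "T", C = "G", G = "C", T = "A")
  ## base at circular (or linear) coordinate i; "" past a linear boundary
  char_circ <- function(cn, i) {
    L <- nchar(genome$chroms[[cn]])
    if (genome$circular[[cn]]) return(substr(genome$chroms[[cn]],
                                             mod1(i, L), mod1(i, L)))
    if (i >= 1L && i <= L) substr(genome$chroms[[cn]], i, i) else ""
  }
  hits <- list()
  emit <- function(c1, s1, e1, c2, s2, e2, strand2) {
    LA <- nchar(genome$chroms[[c1]]); LB <- nchar(genome$chroms[[c2]])
    len <- e1 - s1 + 1L
    if (len < min_len || len > min(LA, LB)) return(invisible())
    # verify maximality on the circle; seed runs stopped at the unrolled
    # sequence boundary would otherwise leave non-maximal wrap artifacts
    if (strand2 == "+") {
      la <- char_circ(c1, s1 - 1L); lb <- char_circ(c2, s2 - 1L)
      ra <- char_circ(c1, e1 + 1L); rb <- char_circ(c2, e2 + 1L)
      if ((la != "" && la == lb) || (ra != "" && ra == rb)) return(invisible())
    } else {
      la <- char_circ(c1, s1 - 1L); lb <- char_circ(c2, e2 + 1L)
      ra <- char_circ(c1, e1 + 1L); rb <- char_circ(c2, s2 - 1L)
      if ((la != "" && lb != "" && la == comp0[[lb]]) ||
          (ra != "" && rb != "" && ra == comp0[[rb]])) return(invisible())
    }
    ia <- reduce_interval(s1, e1, LA, genome$circular[[c1]])
    ib <- reduce_interval(s2, e2, LB, genome$circular[[c2]])
    if (c1 == c2 && ia[1] == ib[1] && ia[2] == ib[2]) return(invisible())
    hits[[length(hits) + 1L]] <<- data.frame(
      chromA = c1, startA = ia[1], endA = ia[2], strandA = "+",
      chromB = c2, startB = ib[1], endB = ib[2], strandB = strand2,
      length = len, identity = 100, score = len * scoring$match,
      stringsAsFactors = FALSE)
  }
  char_at <- function(ext, i) if (i >= 1L && i <= nchar(ext)) substr(ext, i, i) else ""
  exts <- lapply(setNames(nm = names(genome$chroms)),
                 function(cn) ext_seq(genome, cn))

  pp <- seed_pairs_plus(wt, max_word_hits)
  if (!is.null(pp)) {
    pp <- pp[!(pp$c1 == pp$c2 & pp$p1 == pp$p2), , drop = FALSE]
    d <- pp$p2 - pp$p1
    grp <- paste(pp$c1, pp$c2, d, sep = "|")
    for (g in split(seq_len(nrow(pp)), grp)) {
      c1 <- pp$c1[g[1L]]; c2 <- pp$c2[g[1L]]; dd <- d[g[1L]]
      if (c1 == c2 && dd == 0L) next
      extA <- exts[[c1]]; extB <- exts[[c2]]
      LA <- nchar(genome$chroms[[c1]])
      for (cl in split_clusters(pp$p1[g], 1L)) {
        ps <- sort(pp$p1[g][cl])
        s1 <- ps[1L]; e1 <- ps[length(ps)] + w - 1L
        # char-level extension past the seed-indexed range
        while (e1 - s1 + 1L < LA) {
          a <- char_at(extA, e1 + 1L); b <- char_at(extB, e1 + dd + 1L)
          if (a == "" || b == "" || a != b) break
          e1 <- e1 + 1L
        }
        while (e1 - s1 + 1L < LA) {
          a <- char_at(extA, s1 - 1L); b <- char_at(extB, s1 + dd - 1L)
          if (a == "" || b == "" || a != b) break
          s1 <- s1 - 1L
        }
        emit(c1, s1, e1, c2, s1 + dd, e1 + dd, "+")
      }
    }
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pm <- seed_pairs_minus(wt, max_word_hits)
  if (!is.null(pm)) {
    s <- pm$p1 + pm$p2
    grp <- paste(pm$c1, pm$c2, s, sep = "|")
    for (g in split(seq_len(nrow(pm)), grp)) {
      c1 <- pm$c1[g[1L]]; c2 <- pm$c2[g[1L]]; ss <- s[g[1L]]
      extA <- exts[[c1]]; extB <- exts[[c2]]
      LA <- nchar(genome$chroms[[c1]])
      for (cl in split_clusters(pm$p1[g], 1L)) {
        ps <- sort(pm$p1[g][cl])
        a1 <- ps[1L]; a2 <- ps[length(ps)] + w - 1L
        # A right end pairs with B left end (antidiagonal)
        while (a2 - a1 + 1L < LA) {
          x <- char_at(extA, a2 + 1L); y <- char_at(extB, ss + w - 1L - (a2 + 1L))
          if (x == "" || y == "" || x != comp[[y]]) break
          a2 <- a2 + 1L
        }
        while (a2 - a1 + 1L < LA) {
          x <- char_at(extA, a1 - 1L); y <- char_at(extB, ss + w - 1L - (a1 - 1L))
          if (x == "" || y == "" || x != comp[[y]]) break
          a1 <- a1 - 1L
        }
        b1 <- ss + w - 1L - a2; b2 <- ss + w - 1L - a1
        emit(c1, a1, a2, c2, b1, b2, "-")
      }
    }
  }
  out <- finish_catalog(hits, scoring, min_len)
  attr(out, "provenance")$exact <- TRUE
  out
}
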