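## Seeded exact/near-exact read placement on circular references.
##
## Each read is seeded with a few exact k-mers (both orientations), seed
## hits are located with a Biostrings dictionary match against the
## origin-extended chromosome sequences, and candidate placements are
## scored by Hamming distance over the full read. Reads tying for the best
## score at more than one locus are ambiguous; the classification stages
## exclude them from every count.

map_single_end <- function(reads, genome, seed_len, n_seeds, max_mm,
                           max_seed_hits = 200L) {
  n <- length(reads)
  rl <- unique(nchar(reads))
  fail_if(length(rl) != 1L, "reads must have a single common length")
  fail_if(rl < seed_len, "reads shorter than the seed length cannot be mapped")
  revs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads)))
  offs <- unique(as.integer(round(seq(1L, rl - seed_len + 1L,
                                      length.out = n_seeds))))
  pats <- character(0); meta <- NULL
  for (o in c("+", "-")) {
    src <- if (o == "+") unname(reads) else unname(revs)
    for (off in offs) {
      pats <- c(pats, substring(src, off, off + seed_len - 1L))
      meta <- rbind(meta, cbind(read = seq_len(n), off = off,
                                orient = if (o == "+") 1L else 2L))
    }
  }
  pd <- Biostrings::PDict(pats)

  cand <- list()
  degenerate <- logical(n) # reads with a seed matching too many loci
  for (cn in names(genome$chroms)) {
    sq <- genome$chroms[[cn]]
    L <- nchar(sq)
    ext <- if (genome$circular[[cn]]) circ_ext(sq, rl - 1L) else sq
    mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(ext))
    st <- Biostrings::startIndex(mi)
    hitn <- lengths(st)
    # seeds hitting very many loci (low-complexity sequence) mark their
    # read as multi-mapping outright and are not expanded
    over <- hitn > max_seed_hits
    if (any(over)) {
      degenerate[meta[over, "read"]] <- TRUE
      st[over] <- list(integer(0))
      hitn[over] <- 0L
    }
    hit_pat <- rep.int(seq_along(st), hitn)
    hit_pos <- unlist(st, use.names = FALSE)
    if (!length(hit_pos)) next
    start <- hit_pos - meta[hit_pat, "off"] + 1L
    keep <- start >= 1L & start <= L & (start + rl - 1L) <= nchar(ext)
    if (!any(keep)) next
    cand[[cn]] <- data.frame(
      read = meta[hit_pat, "read"][keep], chrom = cn,
      start = start[keep], orient = meta[hit_pat, "orient"][keep],
      stringsAsFactors = FALSE)
  }
  empty <- data.frame(read = integer(), chrom = character(), start = integer(),
                      strand = character(), mm = integer(), n_best = integer())
  if (!length(cand)) {
    return(list(hits = empty, degenerate = degenerate))
  }
  cand <- do.call(rbind, cand)
  cand <- unique(cand)

  # score candidates: Hamming distance over the full read
  cand$mm <- NA_integer_
  for (cn in unique(cand$chrom)) {
    i <- which(cand$chrom == cn)
    sq <- genome$chroms[[cn]]
    ext <- if (genome$circular[[cn]]) circ_ext(sq, rl - 1L) else sq
    sub <- substring(ext, cand$start[i], cand$start[i] + rl - 1L)
    qry <- ifelse(cand$orient[i] == 1L, reads[cand$read[i]], revs[cand$read[i]])
    cand$mm[i] <- mapply(hamming, sub, qry, USE.NAMES = FALSE)
  }
  cand <- cand[cand$mm <= max_mm, , drop = FALSE]
  if (!nrow(cand)) {
    return(list(hits = empty, degenerate = degenerate))
  }
  best <- tapply(cand$mm, cand$read, min)
  cand <- cand[cand$mm == best[as.character(cand$read)], , drop = FALSE]
  nb <- table(cand$read)
  first <- !duplicated(cand$read)
  out <- cand[first, , drop = FALSE]
  out$n_best <- as.integer(nb[as.character(out$read)])
  out$strand <- ifelse(out$orient == 1L, "+", "-")
  list(hits = out[, c("read", "chrom", "start", "strand", "mm", "n_best")],
       degenerate = degenerate)
}

#' Map paired-end reads onto a reference genome
#'
#' Places each read by exact seed match plus full-length Hamming scoring,
#' honouring circular origins through doubled-sequence matching with
#' coordinate reduction. Reads that tie for their best placement at more
#' than one locus (e.g. reads lying wholly inside a multicopy repeat) are
#' labelled ambiguous; reads exceeding the mismatch budget are unmapped.
#'
#' @param rs a `read_set` from [sim_read_pairs()], or a list with
#'   `reads1`/`reads2` named character vectors.
#' @param genome the reference [genome_model()].
#' @param seed_len exact seed length in bp.
#' @param n_seeds number of seed positions per read orientation.
#' @param max_mismatch maximum Hamming distance accepted for a placement;
#'   default scales with read length and a 5% error allowance.
#' @return A data frame of class `mapped_pairs`, one row per read pair:
#'   placement (`chrom`, leftmost `start`, `strand`, mismatches) for each
#'   mate, 5' start positions `pos5_1`/`pos5_2` used for duplicate
#'   detection, and `status` in `mapped`, `ambiguous`, `unmapped`.
#' @export
map_read_pairs <- function(rs, genome, seed_len = 16L, n_seeds = 3L,
                           max_mismatch = NULL) {
  reads1 <- rs$reads1; reads2 <- rs$reads2
  stopifnot(length(reads1) == length(reads2))
  rl <- nchar(reads1[1])
  if (is.null(max_mismatch)) max_mismatch <- ceiling(0.05 * rl) + 2L
  r1 <- map_single_end(reads1, genome, seed_len, n_seeds, max_mismatch)
  r2 <- map_single_end(reads2, genome, seed_len, n_seeds, max_mismatch)
  m1 <- r1$hits; m2 <- r2$hits
  n <- length(reads1)
  take <- function(m, col, default) {
    out <- rep(default, n); out[m$read] <- m[[col]]; out
  }
  df <- data.frame(
    id = names(reads1),
    chrom1 = take(m1, "chrom", NA_character_),
    start1 = take(m1, "start", NA_integer_),
    strand1 = take(m1, "strand", NA_character_),
    mm1 = take(m1, "mm", NA_integer_),
    nbest1 = take(m1, "n_best", 0L),
    chrom2 = take(m2, "chrom", NA_character_),
    start2 = take(m2, "start", NA_integer_),
    strand2 = take(m2, "strand", NA_character_),
    mm2 = take(m2, "mm", NA_integer_),
    nbest2 = take(m2, "n_best", 0L),
    stringsAsFactors = FALSE)
  # reads with low-complexity seeds hitting very many loci are ambiguous
  df$nbest1[r1$degenerate] <- pmax(df$nbest1[r1$degenerate], 2L)
  df$nbest2[r2$degenerate] <- pmax(df$nbest2[r2$degenerate], 2L)
  df$status <- ifelse(df$nbest1 == 0L | df$nbest2 == 0L, "unmapped",
                      ifelse(df$nbest1 > 1L | df$nbest2 > 1L, "ambiguous",
                             "mapped"))
  Ls <- chrom_len(genome)
  # 5' positions (read start in sequencing direction), reduced to 1..L
  p5 <- function(start, strand, chrom) {
    out <- ifelse(strand == "+", start, start + rl - 1L)
    ok <- !is.na(out)
    out[ok] <- mod1(out[ok], Ls[chrom[ok]])
    as.integer(out)
  }
  df$pos5_1 <- p5(df$start1, df$strand1, df$chrom1)
  df$pos5_2 <- p5(df$start2, df$strand2, df$chrom2)
  attr(df, "read_length") <- rl
  class(df) <- c("mapped_pairs", "data.frame")
  df
}
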