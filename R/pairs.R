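#' Flag PCR duplicate read pairs
#'
#' Within each group of mapped pairs sharing identical 5' start positions
#' (chromosome, position, strand) for both the left and the right read,
#' one pair is retained and the rest are flagged as duplicates. Duplicates
#' are excluded from all downstream counts; only the dedup key they share
#' makes them non-independent observations of one library fragment.
#'
#' @param pairs a `mapped_pairs` data frame from [map_read_pairs()].
#' @return The input with a logical `duplicate` column added.
#' @export
dedup_pairs <- function(pairs) {
  key <- ifelse(pairs$status == "mapped",
                paste(pairs$chrom1, pairs$pos5_1, pairs$strand1,
                      pairs$chrom2, pairs$pos5_2, pairs$strand2, sep = "|"),
                NA_character_)
  dup <- duplicated(key) & !is.na(key)
  pairs$duplicate <- dup
  pairs
}

#' Classify read pairs as consistent or inconsistent with the reference
#'
#' A non-duplicate, unambiguously mapped pair is consistent with the
#' reference conformation if and only if both reads map to the same
#' chromosome, on opposite strands facing inward, and the implied fragment
#' span lies within the library window (edges inclusive). Everything else
#' -- cross-chromosome pairs, same-strand pairs, spans outside the window
#' -- is inconsistent. On a circle the implied span is the forward arc
#' from the forward read's 5' end to the reverse read's 5' end.
#'
#' @param pairs a `mapped_pairs` data frame, ideally after [dedup_pairs()].
#' @param lib a [library_spec()], or a length-2 numeric span window in bp.
#' @param genome the reference [genome_model()] (for circular arithmetic).
#' @return The input with `span` and `label` columns added; `label` is one
#'   of `consistent`, `inconsistent`, `duplicate`, `ambiguous`, `unmapped`.
#' @export
classify_pairs <- function(pairs, lib, genome) {
  window <- if (inherits(lib, "library_spec")) lib$window else as.integer(lib)
  fail_if(length(window) != 2L || window[1] >= window[2],
          "span window must be c(min, max) with min < max")
  if (is.null(pairs$duplicate)) pairs$duplicate <- FALSE
  Ls <- chrom_len(genome)
  n <- nrow(pairs)
  span <- rep(NA_integer_, n)
  same <- !is.na(pairs$chrom1) & !is.na(pairs$chrom2) &
    pairs$chrom1 == pairs$chrom2
  opp <- same & pairs$strand1 != pairs$strand2
  i <- which(opp)
  if (length(i)) {
    L <- Ls[pairs$chrom1[i]]
    fwd5 <- ifelse(pairs$strand1[i] == "+", pairs$pos5_1[i], pairs$pos5_2[i])
    rev5 <- ifelse(pairs$strand1[i] == "+", pairs$pos5_2[i], pairs$pos5_1[i])
    span[i] <- as.integer(((rev5 - fwd5) %% L) + 1L)
  }
  pairs$span <- span
  label <- rep("inconsistent", n)
  label[!is.na(span) & span >= window[1] & span <= window[2]] <- "consistent"
  label[pairs$status == "ambiguous"] <- "ambiguous"
  label[pairs$status == "unmapped"] <- "unmapped"
  label[pairs$duplicate] <- "duplicate"
  pairs$label <- label
  attr(pairs, "window") <- window
  pairs
}

#' Summary counts for classified read pairs
#'
#' @param pairs output of [classify_pairs()].
#' @return A named integer vector of label counts.
#' @export
pair_counts <- function(pairs) {
  lev <- c("consistent", "inconsistent", "duplicate", "ambiguous", "unmapped")
  out <- setNames(integer(length(lev)), lev)
  tab <- table(pairs$label)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Ingest mapped read pairs from a SAM file
#'
#' Reads only the coordinate fields of a SAM file (text format) and
#' reconstructs one row per read pair, so that orientation and span can be
#' recomputed by [classify_pairs()] from first principles rather than
#' trusted from stored flags. Records with mapping quality 0 are treated
#' as ambiguous placements.
#'
#' @param path SAM file (uncompressed text).
#' @return A `mapped_pairs` data frame (without mismatch counts).
#' @export
read_sam_pairs <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  f <- strsplit(ln, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, character(1), 1L)
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  rname <- vapply(f, `[[`, character(1), 3L)
  pos <- as.integer(vapply(f, `[[`, character(1), 4L))
  mapq <- as.integer(vapply(f, `[[`, character(1), 5L))
  seq <- vapply(f, `[[`, character(1), 10L)
  rl <- nchar(seq)
  unmapped <- bitwAnd(flag, 4L) > 0L
  rev <- bitwAnd(flag, 16L) > 0L
  first <- bitwAnd(flag, 64L) > 0L
  mate <- ifelse(first, 1L, 2L)

  ids <- unique(qname)
  pick <- function(m, col, default) {
    out <- rep(default, length(ids))
    i <- which(mate == m & !unmapped)
    out[match(qname[i], ids)] <- col[i]
    out
  }
  strand <- ifelse(rev, "-", "+")
  p5 <- ifelse(rev, pos + rl - 1L, pos)
  df <- data.frame(
    id = ids,
    chrom1 = pick(1L, rname, NA_character_),
    start1 = pick(1L, pos, NA_integer_),
    strand1 = pick(1L, strand, NA_character_),
    mm1 = NA_integer_,
    nbest1 = pick(1L, ifelse(mapq == 0L, 2L, 1L), 0L),
    chrom2 = pick(2L, rname, NA_character_),
    start2 = pick(2L, pos, NA_integer_),
    strand2 = pick(2L, strand, NA_character_),
    mm2 = NA_integer_,
    nbest2 = pick(2L, ifelse(mapq == 0L, 2L, 1L), 0L),
    stringsAsFactors = FALSE)
  df$status <- ifelse(df$nbest1 == 0L | df$nbest2 == 0L, "unmapped",
                      ifelse(df$nbest1 > 1L | df$nbest2 > 1L, "ambiguous",
                             "mapped"))
  df$pos5_1 <- pick(1L, p5, NA_integer_)
  df$pos5_2 <- pick(2L, p5, NA_integer_)
  attr(df, "read_length") <- max(rl)
  class(df) <- c("mapped_pairs", "data.frame")
  df
}
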