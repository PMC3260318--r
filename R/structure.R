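## Chromosome-level structure reports: autonomy, abundance evenness, and
## collapsed-tandem misassembly diagnostics.

#' Chromosome autonomy report
#'
#' A chromosome is autonomous when it shares no repeat longer than
#' `min_shared_len` with the rest of the genome, and for every shorter
#' shared repeat the fraction of read pairs supporting the standalone
#' (subgenomic) conformation exceeds `support_threshold`. Chromosomes with
#' no shared repeats at all are vacuously autonomous and flagged as such.
#'
#' @param genome the reference [genome_model()].
#' @param catalog a `repeat_catalog`.
#' @param pairs classified, deduplicated pairs ([classify_pairs()]).
#' @param lib a [library_spec()] or span window.
#' @param min_shared_len length above which any shared repeat forfeits
#'   autonomy outright.
#' @param support_threshold minimum subgenomic support fraction for
#'   shorter shared repeats.
#' @param min_support minimum consistent spanning pairs per copy for a
#'   shared repeat's assay to be informative; shared repeats that cannot
#'   be assayed (too long for the library, or too little support) leave
#'   the chromosome's support clause indeterminate and are counted in
#'   `n_unassayed`.
#' @return Data frame, one row per chromosome: `chrom`,
#'   `shared_gt` (shared repeats longer than the cutoff), `n_shared_short`,
#'   `n_unassayed`, `max_recomb_freq` (over assayed shared repeats),
#'   `autonomous`, `vacuous`.
#' @export
chromosome_autonomy <- function(genome, catalog, pairs, lib,
                                min_shared_len = 100L,
                                support_threshold = 0.995,
                                min_support = 5L) {
  window <- if (inherits(lib, "library_spec")) lib$window else as.integer(lib)
  cross <- which(catalog$chromA != catalog$chromB)
  out <- lapply(names(genome$chroms), function(cn) {
    mine <- cross[catalog$chromA[cross] == cn | catalog$chromB[cross] == cn]
    if (!length(mine)) {
      return(data.frame(chrom = cn, shared_gt = 0L, n_shared_short = 0L,
                        n_unassayed = 0L, max_recomb_freq = NA_real_,
                        autonomous = TRUE, vacuous = TRUE,
                        stringsAsFactors = FALSE))
    }
    big <- sum(catalog$length[mine] > min_shared_len)
    short <- mine[catalog$length[mine] <= min_shared_len]
    freqs <- numeric(0)
    unassayed <- 0L
    if (big == 0L) {
      for (i in short) {
        cs <- count_support(genome, catalog[i, ], pairs, window)
        if (!cs$assayable || min(cs$C1, cs$C2) < min_support) {
          unassayed <- unassayed + 1L
          next
        }
        freqs <- c(freqs, recombinant_frequency(cs))
      }
    }
    auto <- big == 0L &&
      (length(freqs) == 0L || all(1 - freqs > support_threshold))
    data.frame(chrom = cn, shared_gt = big, n_shared_short = length(short),
               n_unassayed = unassayed,
               max_recomb_freq = if (length(freqs)) max(freqs) else NA_real_,
               autonomous = auto, vacuous = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## per-chromosome read coverage (non-duplicate, uniquely mapped reads)
read_coverage <- function(pairs, genome) {
  rl <- attr(pairs, "read_length")
  Ls <- chrom_len(genome)
  use <- which(pairs$status == "mapped" & !pairs$duplicate)
  ivs <- list()
  for (m in 1:2) {
    ch <- pairs[[paste0("chrom", m)]][use]
    st <- pairs[[paste0("start", m)]][use]
    for (cn in unique(ch)) {
      i <- which(ch == cn)
      L <- Ls[[cn]]
      s <- st[i]; e <- st[i] + rl - 1L
      wrap <- e > L
      ivs[[length(ivs) + 1L]] <- data.frame(
        chrom = cn,
        start = c(s, rep(1L, sum(wrap))),
        end = c(ifelse(wrap, L, e), e[wrap] - L))
    }
  }
  ivs <- do.call(rbind, ivs)
  lapply(setNames(nm = names(genome$chroms)), function(cn) {
    x <- ivs[ivs$chrom == cn, , drop = FALSE]
    IRanges::coverage(IRanges::IRanges(x$start, x$end), width = Ls[[cn]])
  })
}

#' Read-depth evenness and GC content across chromosomes
#'
#' Mean read depth per chromosome over positions outside the repeat mask,
#' the max/min fold ratio of those means (a measure of how even the
#' relative abundance of the chromosomes is), and per-chromosome GC
#' content. Fully masked chromosomes are excluded from the ratio and
#' flagged.
#'
#' @param pairs classified, deduplicated pairs.
#' @param genome the reference [genome_model()].
#' @param mask repeat mask: a data frame `chrom, start, end` (e.g. the
#'   `masked` element of [repeat_coverage()]), or `NULL` for no masking.
#' @return A list with `per_chrom` (data frame: `chrom, length, unmasked,
#'   mean_depth, gc, fully_masked`) and `fold_ratio`.
#' @export
depth_evenness <- function(pairs, genome, mask = NULL) {
  Ls <- chrom_len(genome)
  covs <- read_coverage(pairs, genome)
  per <- lapply(names(genome$chroms), function(cn) {
    cov <- covs[[cn]]
    keep <- rep(TRUE, Ls[[cn]])
    if (!is.null(mask) && nrow(mask)) {
      mm <- mask[mask$chrom == cn, , drop = FALSE]
      for (j in seq_len(nrow(mm))) keep[mm$start[j]:mm$end[j]] <- FALSE
    }
    unmasked <- sum(keep)
    md <- if (unmasked > 0) mean(as.numeric(cov)[keep]) else NA_real_
    data.frame(chrom = cn, length = Ls[[cn]], unmasked = unmasked,
               mean_depth = md, gc = gc_content(genome$chroms[[cn]]),
               fully_masked = unmasked == 0L, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  ok <- !per$fully_masked & !is.na(per$mean_depth) & per$mean_depth > 0
  ratio <- if (sum(ok) >= 2L) {
    max(per$mean_depth[ok]) / min(per$mean_depth[ok])
  } else NA_real_
  list(per_chrom = per, fold_ratio = ratio)
}

#' Collapsed-tandem misassembly diagnostics
#'
#' A tandem duplication collapsed into a single copy in the reference
#' leaves two signatures: roughly doubled read depth over the collapsed
#' interval, and inconsistent read pairs clustering at its boundaries.
#' This scan flags windows whose depth is at least `depth_fold` times the
#' chromosome median and, for the merged intervals, counts inconsistent
#' read ends within `slop` bp of the interval boundaries; intervals with
#' at least `min_inconsistent` such ends are called candidate collapses.
#'
#' @param pairs classified, deduplicated pairs.
#' @param genome the reference [genome_model()].
#' @param window_size scan window in bp.
#' @param depth_fold depth threshold relative to the chromosome median.
#' @param min_inconsistent minimum boundary-clustered inconsistent ends.
#' @param slop boundary neighbourhood in bp.
#' @return Data frame of flagged intervals: `chrom, start, end,
#'   mean_depth, median_depth, n_inconsistent, flagged` (zero rows for a
#'   clean genome).
#' @export
collapse_diagnostics <- function(pairs, genome, window_size = 500L,
                                 depth_fold = 2, min_inconsistent = 3L,
                                 slop = 500L) {
  Ls <- chrom_len(genome)
  covs <- read_coverage(pairs, genome)
  out <- list()
  inc <- which(pairs$label == "inconsistent")
  inc_pos <- rbind(
    data.frame(chrom = pairs$chrom1[inc], pos = pairs$start1[inc]),
    data.frame(chrom = pairs$chrom2[inc], pos = pairs$start2[inc]))
  inc_pos <- inc_pos[!is.na(inc_pos$chrom), , drop = FALSE]
  for (cn in names(genome$chroms)) {
    cov <- as.numeric(covs[[cn]])
    L <- Ls[[cn]]
    med <- median(cov)
    if (med == 0) next
    starts <- seq(1L, max(1L, L - window_size + 1L), by = max(1L, window_size %/% 2L))
    wmean <- vapply(starts, function(s)
      mean(cov[s:min(L, s + window_size - 1L)]), numeric(1))
    hot <- wmean >= depth_fold * med
    if (!any(hot)) next
    hr <- IRanges::reduce(IRanges::IRanges(
      starts[hot], pmin(L, starts[hot] + window_size - 1L)))
    ip <- inc_pos$pos[inc_pos$chrom == cn]
    for (j in seq_along(hr)) {
      s <- IRanges::start(hr)[j]; e <- IRanges::end(hr)[j]
      nb <- sum(abs(ip - s) <= slop | abs(ip - e) <= slop)
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = s, end = e,
        mean_depth = mean(cov[s:e]), median_depth = med,
        n_inconsistent = nb, flagged = nb >= min_inconsistent,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_depth = numeric(), median_depth = numeric(),
                      n_inconsistent = integer(), flagged = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
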