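## Repeat-landscape statistics over a repeat catalogue.

## All copy intervals of selected catalog rows as non-wrapping pieces.
catalog_ranges <- function(catalog, genome, rows = seq_len(nrow(catalog))) {
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  Ls <- chrom_len(genome)
  out <- list()
  for (i in rows) {
    for (side in c("A", "B")) {
      cn <- catalog[[paste0("chrom", side)]][i]
      s <- catalog[[paste0("start", side)]][i]
      e <- catalog[[paste0("end", side)]][i]
      m <- split_wrap(s, e, Ls[[cn]])
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = m[, "start"], end = m[, "end"],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

ranges_by_chrom <- function(df, genome) {
  lapply(setNames(nm = names(genome$chroms)), function(cn) {
    x <- df[df$chrom == cn, , drop = FALSE]
    IRanges::IRanges(start = x$start, end = x$end)
  })
}

#' Fraction of the genome covered by repeats
#'
#' The union of all repeat-copy intervals meeting the length and identity
#' thresholds, divided by total genome length. Also reports the split
#' into large (> 1 kb) and small (<= 1 kb) repeat pairs and the masked
#' intervals themselves (for read-depth masking and BED export).
#'
#' @param genome a [genome_model()].
#' @param catalog a `repeat_catalog` computed on `genome`.
#' @param min_len,min_identity thresholds applied to pairs before taking
#'   the union.
#' @param large_cutoff pair length separating large from small repeats.
#' @return A list with `fraction`, `large_fraction`, `small_fraction`,
#'   `per_chrom` (named fractions), and `masked` (data frame
#'   `chrom, start, end`, 1-based closed, union of qualifying copies).
#' @export
repeat_coverage <- function(genome, catalog, min_len = 0L, min_identity = 0,
                            large_cutoff = 1000L) {
  Ls <- chrom_len(genome)
  total <- sum(Ls)
  sel <- which(catalog$length >= min_len & catalog$identity >= min_identity)
  cover_of <- function(rows) {
    rr <- catalog_ranges(catalog, genome, rows)
    byc <- ranges_by_chrom(rr, genome)
    red <- lapply(byc, IRanges::reduce)
    list(frac = sum(vapply(red, function(x) sum(IRanges::width(x)),
                           numeric(1))) / total,
         per_chrom = vapply(names(red), function(cn)
           sum(IRanges::width(red[[cn]])) / Ls[[cn]], numeric(1)),
         red = red)
  }
  all_cov <- cover_of(sel)
  large <- cover_of(sel[catalog$length[sel] > large_cutoff])
  small <- cover_of(sel[catalog$length[sel] <= large_cutoff])
  masked <- do.call(rbind, lapply(names(all_cov$red), function(cn) {
    x <- all_cov$red[[cn]]
    if (!length(x)) return(NULL)
    data.frame(chrom = cn, start = IRanges::start(x), end = IRanges::end(x),
               stringsAsFactors = FALSE)
  }))
  if (is.null(masked)) {
    masked <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  }
  list(fraction = all_cov$frac, large_fraction = large$frac,
       small_fraction = small$frac, per_chrom = all_cov$per_chrom,
       masked = masked)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data frame `chrom, start, end` (1-based closed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  bed <- data.frame(chrom = intervals$chrom, start = intervals$start - 1L,
                    end = intervals$end)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Cumulative genome coverage by repeat-match depth
#'
#' For each depth `d`, the fraction of genomic positions matching at most
#' `d - 1` other loci, where a position's match count is the number of
#' catalog pair intervals covering it. The value at `d = 1` is the
#' single-copy fraction of the genome; the curve is nondecreasing and
#' reaches 1 at the maximum depth.
#'
#' @param genome a [genome_model()].
#' @param catalog a `repeat_catalog` computed on `genome`.
#' @return Data frame with columns `depth` and `fraction`.
#' @export
repeat_depth_curve <- function(genome, catalog) {
  Ls <- chrom_len(genome)
  total <- sum(Ls)
  rr <- catalog_ranges(catalog, genome)
  counts <- integer(0) # tabulated coverage values across the genome
  maxd <- 0L
  tab <- numeric(1) # tab[k+1] = positions with coverage k
  tab[1] <- 0
  for (cn in names(genome$chroms)) {
    x <- rr[rr$chrom == cn, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(x$start, x$end),
                             width = Ls[[cn]])
    rv <- S4Vectors::runValue(cov)
    rlen <- S4Vectors::runLength(cov)
    for (j in seq_along(rv)) {
      k <- rv[j] + 1L
      if (k > length(tab)) tab[(length(tab) + 1L):k] <- 0
      tab[k] <- tab[k] + rlen[j]
    }
  }
  cum <- cumsum(tab) / total
  data.frame(depth = seq_along(cum), fraction = cum)
}

#' Length and identity distributions over repeat pairs
#'
#' Statistics are per *pair*, not per copy: a family with four copies
#' contributes six pairs, so the summed pair length can exceed the genome
#' size in highly multicopy genomes. The identity distribution is
#' restricted to pairs longer than `min_len_for_identity`.
#'
#' @param catalog a `repeat_catalog`.
#' @param min_len_for_identity length floor for the identity distribution.
#' @param breaks histogram breaks (bp) for the length distribution.
#' @return A list with `n_pairs`, `pair_lengths`, `total_pair_length`,
#'   `identities` (restricted), and `length_hist` (data frame per bin:
#'   `n_pairs`, `summed_length`).
#' @export
pair_statistics <- function(catalog, min_len_for_identity = 300L,
                            breaks = c(0, 50, 100, 300, 1000, 3000, 10000,
                                       Inf)) {
  len <- catalog$length
  bin <- cut(len, breaks, right = TRUE)
  hist <- data.frame(
    bin = levels(bin),
    n_pairs = as.integer(table(bin)),
    summed_length = as.numeric(tapply(len, bin, sum, default = 0)))
  hist$summed_length[is.na(hist$summed_length)] <- 0
  list(n_pairs = nrow(catalog),
       pair_lengths = len,
       total_pair_length = sum(len),
       identities = catalog$identity[len > min_len_for_identity],
       length_hist = hist)
}
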