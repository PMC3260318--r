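## Quantifying repeat-mediated recombination from paired-end mappings.
##
## For a two-copy repeat, read pairs spanning a copy (one read entirely on
## each side, neither touching the repeat) support one of four junction
## environments: the two reference environments around copy A and copy B,
## or the two recombinant environments predicted by a crossover between
## the copies. Reference support is counted directly from consistent
## pairs; recombinant support is counted by projecting inconsistent pairs
## through the segment map of the derived recombinant conformation and
## asking whether they become consistent, spanning pairs there.

## vectorised: is a read (leftmost start a, length rl) entirely outside
## the non-wrapping interval [s, e] on a circle of length L?
read_outside <- function(a, rl, s, e, L) {
  m <- L - (e - s + 1L)
  if (m < rl) return(rep(FALSE, length(a)))
  t <- (a - (e + 1L)) %% L
  t + rl <= m
}

## vectorised spanning test for consistent pairs: fragment from the
## forward read 5' end f1 with span sp covers [s, e], with both reads
## (length rl) clear of the interval.
frag_spans <- function(f1, sp, s, e, L, rl) {
  ds <- (s - f1) %% L
  de <- ds + (e - s)
  ds >= rl & de <= sp - rl - 1L
}

## consistent pairs spanning a repeat copy
count_spanning <- function(pairs, chrom, s, e, L, rl) {
  i <- which(pairs$label == "consistent" & pairs$chrom1 == chrom)
  if (!length(i)) return(0L)
  f1 <- ifelse(pairs$strand1[i] == "+", pairs$pos5_1[i], pairs$pos5_2[i])
  sp <- pairs$span[i]
  sum(frag_spans(f1, sp, s, e, L, rl))
}

#' Count read-pair support for the four junction environments
#'
#' @param genome the reference [genome_model()].
#' @param rep_row one catalog row (or a list) with `chromA, startA, endA,
#'   strandA, chromB, startB, endB, strandB`.
#' @param pairs classified pairs from [classify_pairs()] after
#'   [dedup_pairs()].
#' @param window span window `c(min, max)` in bp.
#' @return A list with integer counts `C1, C2` (consistent pairs spanning
#'   copy A / copy B), `R1, R2` (inconsistent pairs consistent with
#'   recombinant environment 1 / 2), and `assayable` (FALSE when the
#'   repeat is at least as long as the maximum library span, in which case
#'   counts are NA).
#' @export
count_support <- function(genome, rep_row, pairs, window) {
  r <- as.list(rep_row)
  rl <- attr(pairs, "read_length")
  fail_if(is.null(rl), "pairs must carry a read_length attribute")
  window <- as.integer(window)
  rep_len <- r$endA - r$startA + 1L
  if (rep_len >= window[2]) {
    return(list(C1 = NA_integer_, C2 = NA_integer_, R1 = NA_integer_,
                R2 = NA_integer_, assayable = FALSE))
  }
  LA <- nchar(genome$chroms[[r$chromA]])
  LB <- nchar(genome$chroms[[r$chromB]])
  C1 <- count_spanning(pairs, r$chromA, r$startA, r$endA, LA, rl)
  C2 <- count_spanning(pairs, r$chromB, r$startB, r$endB, LB, rl)

  conf <- derive_recombinant(
    genome,
    list(chrom = r$chromA, start = r$startA, end = r$endA, strand = r$strandA),
    list(chrom = r$chromB, start = r$startB, end = r$endB, strand = r$strandB))
  vg <- conf$genome

  # candidate pairs: mapped, deduplicated, inconsistent, with both reads
  # clear of both repeat copies in reference coordinates
  cand <- which(pairs$label == "inconsistent")
  R1 <- 0L; R2 <- 0L
  if (length(cand)) {
    ok <- rep(TRUE, length(cand))
    for (m in 1:2) {
      ch <- pairs[[paste0("chrom", m)]][cand]
      st <- pairs[[paste0("start", m)]][cand]
      onA <- ch == r$chromA
      onB <- ch == r$chromB
      outA <- rep(TRUE, length(cand))
      outA[onA] <- read_outside(st[onA], rl, r$startA, r$endA, LA)
      outB <- rep(TRUE, length(cand))
      outB[onB] <- read_outside(st[onB], rl, r$startB, r$endB, LB)
      ok <- ok & outA & outB
    }
    cand <- cand[ok]
    for (i in cand) {
      p1 <- project_position(conf$map, pairs$chrom1[i], pairs$pos5_1[i],
                             pairs$strand1[i])
      p2 <- project_position(conf$map, pairs$chrom2[i], pairs$pos5_2[i],
                             pairs$strand2[i])
      if (nrow(p1) != 1L || nrow(p2) != 1L) next
      if (p1$vchrom != p2$vchrom) next
      if (p1$vstrand == p2$vstrand) next
      Lv <- nchar(vg$chroms[[p1$vchrom]])
      f1 <- if (p1$vstrand == "+") p1$vpos else p2$vpos
      r5 <- if (p1$vstrand == "+") p2$vpos else p1$vpos
      sp <- ((r5 - f1) %% Lv) + 1L
      if (sp < window[1] || sp > window[2]) next
      for (k in seq_len(nrow(conf$copies))) {
        if (conf$copies$vchrom[k] != p1$vchrom) next
        if (frag_spans(f1, sp, conf$copies$start[k], conf$copies$end[k],
                       Lv, rl)) {
          if (k == 1L) R1 <- R1 + 1L else R2 <- R2 + 1L
          break
        }
      }
    }
  }
  list(C1 = C1, C2 = C2, R1 = R1, R2 = R2, assayable = TRUE)
}

#' Recombinant-conformation frequency from junction support counts
#'
#' The frequency of recombinant genome conformations for a repeat pair is
#' the recombinant support divided by all support:
#' `(R1 + R2) / (C1 + C2 + R1 + R2)`.
#'
#' @param counts numeric vector `c(C1, C2, R1, R2)` or the list returned
#'   by [count_support()].
#' @return The frequency as a fraction in `[0, 1]`; `NA` when all four
#'   counts are zero (undefined, not 0).
#' @examples
#' recombinant_frequency(c(505, 481, 8, 12)) # 20/1006, about 2%
#' @export
recombinant_frequency <- function(counts) {
  if (is.list(counts)) counts <- c(counts$C1, counts$C2, counts$R1, counts$R2)
  fail_if(length(counts) != 4L, "need the four counts C1, C2, R1, R2")
  if (any(is.na(counts))) return(NA_real_)
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  (counts[3] + counts[4]) / tot
}

#' Display a frequency as a whole-number percentage
#'
#' @param f frequency in `[0, 1]`.
#' @return Character like `"2%"` (rounded half-up).
#' @export
percent_label <- function(f) {
  ifelse(is.na(f), NA_character_, sprintf("%d%%", as.integer(floor(100 * f + 0.5))))
}

#' Reversed-orientation control assay
#'
#' Re-runs the junction-support count after reversing the coordinates of
#' one repeat copy, so that only recombination between the two sequences
#' in *opposite* relative orientation would be detected. On genuine
#' direct-repeat recombination the control frequency stays at the
#' chimera/artefact floor; a non-zero control indicates rearrangement or
#' library artefacts unrelated to the repeat's actual orientation.
#'
#' @inheritParams count_support
#' @return As [count_support()], for the orientation-reversed pair.
#' @export
reversed_control <- function(genome, rep_row, pairs, window) {
  r <- as.list(rep_row)
  r$strandB <- if (r$strandB == "+") "-" else "+"
  count_support(genome, r, pairs, window)
}

#' Eligibility filter for the recombination assay
#'
#' Annotates each repeat pair with whether it can be assayed
#' unambiguously, recording the first exclusion reason that applies:
#' `min_length` (< `min_len` bp), `min_identity` (< `min_identity`%),
#' `separation` (copies on one chromosome closer than the maximum library
#' span), `correlated_repeat` (a longer repeat pair with one copy within
#' the maximum span of each focal copy), `adjacent_repeat` (for
#' short-span libraries, a copy within `adjacency_dist` bp of the start
#' of another repeat copy longer than `adjacency_len` bp), or
#' `subsampled_out` (a seeded random subsample retains only a fraction of
#' short pairs). Support-based exclusion (`insufficient_support`) is
#' applied after counting, by [recomb_assay()].
#'
#' @param catalog a `repeat_catalog`.
#' @param genome the [genome_model()] the catalog was computed on.
#' @param lib a [library_spec()] or span window `c(min, max)`.
#' @param min_len,min_identity length and identity floors.
#' @param adjacency_rule apply the adjacent-repeat rule; defaults to TRUE
#'   for short-span libraries (window max <= 6000 bp).
#' @param adjacency_dist,adjacency_len parameters of that rule.
#' @param subsample_short `NULL`, or `list(fraction=, max_len=, seed=)`
#'   retaining a seeded random fraction of eligible pairs shorter than
#'   `max_len`.
#' @return The catalog with `eligible` and `reason` columns added.
#' @export
filter_assayable <- function(catalog, genome, lib, min_len = 50L,
                             min_identity = 95, adjacency_rule = NULL,
                             adjacency_dist = 100L, adjacency_len = 500L,
                             subsample_short = NULL) {
  window <- if (inherits(lib, "library_spec")) lib$window else as.integer(lib)
  if (is.null(adjacency_rule)) adjacency_rule <- window[2] <= 6000L
  n <- nrow(catalog)
  eligible <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  mark <- function(i, why) {
    sel <- i & eligible
    eligible[sel] <<- FALSE
    reason[sel] <<- why
  }
  mark(catalog$length < min_len, "min_length")
  mark(catalog$identity < min_identity, "min_identity")

  Ls <- chrom_len(genome)
  sep <- rep(NA_integer_, n)
  same <- catalog$chromA == catalog$chromB
  for (i in which(same)) {
    sep[i] <- circ_gap(catalog$startA[i], catalog$endA[i],
                       catalog$startB[i], catalog$endB[i],
                       Ls[[catalog$chromA[i]]])
  }
  mark(same & !is.na(sep) & sep < window[2], "separation")

  # correlated larger repeats: for each focal pair, any longer pair with
  # one copy near focal copy A and the other near focal copy B
  near <- function(ci, si, ei, cj, sj, ej) {
    if (ci != cj) return(FALSE)
    circ_gap(si, ei, sj, ej, Ls[[ci]]) <= window[2]
  }
  for (i in which(eligible)) {
    longer <- which(catalog$length > catalog$length[i])
    hit <- FALSE
    for (j in longer) {
      if ((near(catalog$chromA[i], catalog$startA[i], catalog$endA[i],
                catalog$chromA[j], catalog$startA[j], catalog$endA[j]) &&
           near(catalog$chromB[i], catalog$startB[i], catalog$endB[i],
                catalog$chromB[j], catalog$startB[j], catalog$endB[j])) ||
          (near(catalog$chromA[i], catalog$startA[i], catalog$endA[i],
                catalog$chromB[j], catalog$startB[j], catalog$endB[j]) &&
           near(catalog$chromB[i], catalog$startB[i], catalog$endB[i],
                catalog$chromA[j], catalog$startA[j], catalog$endA[j]))) {
        hit <- TRUE; break
      }
    }
    if (hit) mark(seq_len(n) == i, "correlated_repeat")
  }

  if (adjacency_rule) {
    big <- catalog[catalog$length > adjacency_len, , drop = FALSE]
    starts <- rbind(
      data.frame(chrom = big$chromA, pos = big$startA),
      data.frame(chrom = big$chromB, pos = big$startB))
    point_near <- function(ci, si, ei) {
      any(starts$chrom == ci &
            (starts$pos >= si - adjacency_dist & starts$pos <= ei + adjacency_dist))
    }
    for (i in which(eligible)) {
      own <- catalog$length[i] > adjacency_len
      nearA <- point_near(catalog$chromA[i], catalog$startA[i], catalog$endA[i])
      nearB <- point_near(catalog$chromB[i], catalog$startB[i], catalog$endB[i])
      # a copy is trivially near its own start; discount when focal is big
      if (own) next
      if (nearA || nearB) mark(seq_len(n) == i, "adjacent_repeat")
    }
  }

  if (!is.null(subsample_short)) {
    ss <- subsample_short
    if (!is.null(ss$seed)) set.seed(ss$seed)
    short <- which(eligible & catalog$length < ss$max_len)
    if (length(short)) {
      keep_n <- round(ss$fraction * length(short))
      keep <- if (keep_n > 0) sample(short, keep_n) else integer()
      drop <- setdiff(short, keep)
      mark(seq_len(n) %in% drop, "subsampled_out")
    }
  }

  catalog$eligible <- eligible
  catalog$reason <- reason
  catalog
}

#' Assay repeat-mediated recombination genome-wide
#'
#' The package's central estimator. For every eligible repeat pair it
#' counts deduplicated read pairs supporting the two reference and two
#' recombinant junction environments, estimates the recombinant
#' conformation frequency `(R1+R2)/(C1+C2+R1+R2)`, and (optionally) runs
#' the reversed-orientation control. Pairs with fewer than `min_support`
#' consistent read pairs spanning either copy are reported but flagged
#' ineligible (`insufficient_support`) with no frequency.
#'
#' @param genome the reference [genome_model()].
#' @param catalog a `repeat_catalog` (annotated by [filter_assayable()]
#'   internally if not already).
#' @param pairs classified, deduplicated pairs ([classify_pairs()]).
#' @param lib a [library_spec()] or span window.
#' @param min_support minimum consistent pairs spanning *each* copy.
#' @param control run the reversed-orientation control assay.
#' @param ... passed to [filter_assayable()].
#' @return An object of class `recomb_assay`: a list with `table` (one row
#'   per repeat pair: coordinates, length, identity, eligibility, counts
#'   `C1, C2, R1, R2`, informative total `n`, `frequency`, and
#'   `ctrl_frequency`/`ctrl_n` if requested), plus the window and
#'   parameters used. Methods: `print`, `summary`, `coef`, `confint`,
#'   `plot`.
#' @export
recomb_assay <- function(genome, catalog, pairs, lib, min_support = 5L,
                         control = TRUE, ...) {
  window <- if (inherits(lib, "library_spec")) lib$window else as.integer(lib)
  if (is.null(catalog$eligible)) {
    catalog <- filter_assayable(catalog, genome, window, ...)
  }
  n <- nrow(catalog)
  tab <- as.data.frame(catalog)
  tab$C1 <- tab$C2 <- tab$R1 <- tab$R2 <- NA_integer_
  tab$n <- NA_integer_
  tab$frequency <- NA_real_
  if (control) { tab$ctrl_n <- NA_integer_; tab$ctrl_frequency <- NA_real_ }
  for (i in seq_len(n)) {
    if (!tab$eligible[i]) next
    cs <- count_support(genome, catalog[i, ], pairs, window)
    if (!cs$assayable) {
      tab$eligible[i] <- FALSE
      tab$reason[i] <- "exceeds_library_span"
      next
    }
    tab$C1[i] <- cs$C1; tab$C2[i] <- cs$C2
    tab$R1[i] <- cs$R1; tab$R2[i] <- cs$R2
    tab$n[i] <- cs$C1 + cs$C2 + cs$R1 + cs$R2
    if (min(cs$C1, cs$C2) < min_support) {
      tab$eligible[i] <- FALSE
      tab$reason[i] <- "insufficient_support"
      next
    }
    tab$frequency[i] <- recombinant_frequency(cs)
    if (control) {
      cc <- reversed_control(genome, catalog[i, ], pairs, window)
      if (cc$assayable) {
        tab$ctrl_n[i] <- cc$C1 + cc$C2 + cc$R1 + cc$R2
        tab$ctrl_frequency[i] <- recombinant_frequency(cc)
      }
    }
  }
  structure(list(table = tab, window = window, min_support = min_support,
                 control = control),
            class = "recomb_assay")
}

#' @export
print.recomb_assay <- function(x, ...) {
  t <- x$table
  cat(sprintf("recomb_assay: %d repeat pair(s), %d eligible, window %d-%d bp\n",
              nrow(t), sum(t$eligible), x$window[1], x$window[2]))
  el <- t[t$eligible & !is.na(t$frequency), , drop = FALSE]
  if (nrow(el)) {
    cat(sprintf("  recombinant frequency: median %.4f, range %.4f-%.4f\n",
                median(el$frequency), min(el$frequency), max(el$frequency)))
  }
  invisible(x)
}

#' @export
summary.recomb_assay <- function(object, ...) {
  t <- object$table
  el <- t[t$eligible, , drop = FALSE]
  excl <- table(t$reason[!t$eligible], useNA = "no")
  out <- list(n_pairs = nrow(t), n_eligible = nrow(el),
              exclusions = excl,
              frequencies = el$frequency,
              ctrl_frequencies = if (object$control) el$ctrl_frequency)
  class(out) <- "summary.recomb_assay"
  out
}

#' @export
print.summary.recomb_assay <- function(x, ...) {
  cat(sprintf("repeat pairs assayed: %d (%d eligible)\n",
              x$n_pairs, x$n_eligible))
  if (length(x$exclusions)) {
    cat("exclusions:\n")
    for (nm in names(x$exclusions)) {
      cat(sprintf("  %-22s %d\n", nm, x$exclusions[[nm]]))
    }
  }
  if (length(x$frequencies)) {
    cat("recombinant frequency quantiles:\n")
    print(quantile(x$frequencies, na.rm = TRUE))
  }
  invisible(x)
}

#' @export
coef.recomb_assay <- function(object, ...) {
  t <- object$table
  setNames(t$frequency,
           sprintf("%s:%d-%d|%s:%d-%d", t$chromA, t$startA, t$endA,
                   t$chromB, t$startB, t$endB))
}

#' @export
confint.recomb_assay <- function(object, parm, level = 0.95, ...) {
  t <- object$table
  out <- matrix(NA_real_, nrow(t), 2L,
                dimnames = list(names(coef(object)),
                                sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                           1 - (1 - level) / 2))))
  for (i in seq_len(nrow(t))) {
    if (is.na(t$frequency[i]) || is.na(t$n[i]) || t$n[i] == 0) next
    k <- t$R1[i] + t$R2[i]
    out[i, ] <- stats::binom.test(k, t$n[i], conf.level = level)$conf.int
  }
  out
}

#' @export
plot.recomb_assay <- function(x, ...) {
  t <- x$table
  el <- t[t$eligible & !is.na(t$frequency), , drop = FALSE]
  graphics::plot(el$length, el$frequency, log = "x",
                 xlab = "repeat length (bp)",
                 ylab = "recombinant conformation frequency",
                 ylim = c(0, max(0.6, el$frequency)), pch = 19, ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}
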