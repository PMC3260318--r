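# Independent oracles and fixture builders used across the suite.

random_seq <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Brute-force maximal exact repeat pairs on LINEAR sequences by dense
# diagonal scanning: every diagonal of every sequence pair (both strands)
# is compared elementwise and runs of equality become matches. Entirely
# independent of the seed-indexed implementation.
oracle_exact_repeats <- function(genome, min_len) {
  chroms <- genome$chroms
  res <- list()
  emit <- function(c1, a1, a2, c2, b1, b2, strand2) {
    if (a2 - a1 + 1L < min_len) return(invisible())
    if (c1 == c2 && a1 == b1 && a2 == b2) return(invisible())
    res[[length(res) + 1L]] <<- data.frame(
      chromA = c1, startA = a1, endA = a2,
      chromB = c2, startB = b1, endB = b2, strandB = strand2,
      length = a2 - a1 + 1L, stringsAsFactors = FALSE)
  }
  scan <- function(x, y, f) {
    # f(a1, a2, d) called for each maximal run x[i] == y[i - d]
    nx <- length(x); ny <- length(y)
    for (d in (1L - ny):(nx - 1L)) {
      i1 <- max(1L, 1L + d); i2 <- min(nx, ny + d)
      if (i2 - i1 + 1L < min_len) next
      eq <- x[i1:i2] == y[(i1:i2) - d]
      r <- rle(eq)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (j in which(r$values & r$lengths >= min_len)) {
        f(i1 + starts[j] - 1L, i1 + ends[j] - 1L, d)
      }
    }
  }
  ids <- names(chroms)
  ivec <- lapply(chroms, utf8ToInt)
  rvec <- lapply(chroms, function(s) utf8ToInt(revcomp(s)))
  for (a in seq_along(ids)) {
    for (b in a:length(ids)) {
      c1 <- ids[a]; c2 <- ids[b]
      n2 <- nchar(chroms[[c2]])
      if (a == b) {
        scan(ivec[[a]], ivec[[a]], function(a1, a2, d) {
          if (d > 0L) emit(c1, a1 - d, a2 - d, c1, a1, a2, "+")
        })
      } else {
        scan(ivec[[a]], ivec[[b]], function(a1, a2, d) {
          emit(c1, a1, a2, c2, a1 - d, a2 - d, "+")
        })
      }
      scan(ivec[[a]], rvec[[b]], function(a1, a2, d) {
        b1r <- a1 - d; b2r <- a2 - d
        emit(c1, a1, a2, c2, n2 - b2r + 1L, n2 - b1r + 1L, "-")
      })
    }
  }
  if (!length(res)) {
    return(data.frame(chromA = character(), startA = integer(),
                      endA = integer(), chromB = character(),
                      startB = integer(), endB = integer(),
                      strandB = character(), length = integer()))
  }
  df <- do.call(rbind, res)
  canonical_pairs(df)
}

# canonical ordering + dedup used to compare catalogs
canonical_pairs <- function(df) {
  swap <- df$chromA > df$chromB |
    (df$chromA == df$chromB & df$startA > df$startB)
  if (any(swap)) {
    tmp <- df[swap, c("chromB", "startB", "endB")]
    df[swap, c("chromB", "startB", "endB")] <-
      df[swap, c("chromA", "startA", "endA")]
    df[swap, c("chromA", "startA", "endA")] <- tmp
  }
  df <- unique(df)
  df[order(df$chromA, df$startA, df$chromB, df$startB, df$strandB), ,
     drop = FALSE]
}

catalog_for_compare <- function(cat_df) {
  df <- as.data.frame(cat_df)[, c("chromA", "startA", "endA", "chromB",
                                  "startB", "endB", "strandB", "length")]
  canonical_pairs(df)
}

# per-position repeat-interval membership counts, by direct looping
oracle_position_depth <- function(genome, catalog) {
  out <- lapply(chrom_lengths(genome), function(L) integer(L))
  names(out) <- names(genome$chroms)
  for (i in seq_len(nrow(catalog))) {
    for (side in c("A", "B")) {
      cn <- catalog[[paste0("chrom", side)]][i]
      s <- catalog[[paste0("start", side)]][i]
      e <- catalog[[paste0("end", side)]][i]
      L <- nchar(genome$chroms[[cn]])
      pos <- if (e >= s) s:e else c(s:L, 1:e)
      out[[cn]][pos] <- out[[cn]][pos] + 1L
    }
  }
  out
}

chrom_lengths <- function(g) nchar(g$chroms)

# minimal classified-pairs data frame for unit tests of the classifier
make_pairs <- function(..., read_length = 100L) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  defaults <- list(mm1 = 0L, mm2 = 0L, nbest1 = 1L, nbest2 = 1L,
                   status = "mapped")
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (is.null(df$id)) df$id <- sprintf("p%03d", seq_len(nrow(df)))
  rl <- read_length
  df$pos5_1 <- ifelse(df$strand1 == "+", df$start1, df$start1 + rl - 1L)
  df$pos5_2 <- ifelse(df$strand2 == "+", df$start2, df$start2 + rl - 1L)
  attr(df, "read_length") <- rl
  class(df) <- c("mapped_pairs", "data.frame")
  df
}

# truth-coordinate pairs (perfect mapping) for simulator-level tests:
# converts a read_set truth table into a mapped_pairs frame against the
# conformation the fragments were drawn from, reference reads only.
truth_pairs_reference <- function(rs, genome) {
  tt <- rs$truth[rs$truth$conformation == "reference", , drop = FALSE]
  rl <- rs$lib$read_length
  Ls <- nchar(genome$chroms)
  L <- Ls[tt$chrom]
  r2_left <- ((tt$frag_start + tt$span - rl - 1L) %% L) + 1L
  df <- data.frame(
    id = tt$id,
    chrom1 = tt$chrom, start1 = tt$frag_start, strand1 = "+",
    mm1 = 0L, nbest1 = 1L,
    chrom2 = tt$chrom, start2 = as.integer(r2_left), strand2 = "-",
    mm2 = 0L, nbest2 = 1L,
    status = "mapped", stringsAsFactors = FALSE)
  df$pos5_1 <- df$start1
  df$pos5_2 <- as.integer(((df$start2 + rl - 2L) %% L) + 1L)
  attr(df, "read_length") <- rl
  class(df) <- c("mapped_pairs", "data.frame")
  df
}
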