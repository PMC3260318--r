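#' Describe a paired-end sequencing library
#'
#' Captures the fragment-span model of a sheared, size-selected paired-end
#' library: the nominal span, the window of spans accepted as consistent
#' with the reference conformation, the read length, the per-base
#' substitution error rate, and the PCR duplicate rate.
#'
#' The presets mirror the span windows used for classifying read pairs:
#' a 3-kb library accepts spans of 1--6 kb, a 12-kb library accepts spans
#' of 4--16 kb. Fragment spans are drawn from a normal distribution with
#' mean `nominal_span` and standard deviation `nominal_span / 6`, truncated
#' to `[read_length, 3 * nominal_span]`.
#'
#' @param kind `"3kb"`, `"12kb"`, or a numeric nominal span in bp.
#' @param window length-2 numeric `(min, max)` span window in bp;
#'   defaults to the preset for `kind`.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate in `[0, 1)`.
#' @param duplicate_rate fraction of emitted pairs that are PCR re-draws of
#'   an already-drawn fragment, in `[0, 1)`.
#' @return An object of class `library_spec`.
#' @examples
#' library_spec("3kb")
#' @export
library_spec <- function(kind = "3kb", window = NULL, read_length = 100L,
                         error_rate = 0.01, duplicate_rate = 0.05) {
  if (is.character(kind)) {
    nominal <- switch(kind, "3kb" = 3000L, "12kb" = 12000L,
                      stop("unknown library kind: ", kind))
    if (is.null(window)) {
      window <- switch(kind, "3kb" = c(1000L, 6000L), "12kb" = c(4000L, 16000L))
    }
  } else {
    nominal <- as.integer(kind)
    fail_if(is.null(window), "a custom library needs an explicit span window")
  }
  fail_if(!(window[1] < nominal && nominal < window[2]),
          "span window must bracket the nominal span")
  fail_if(error_rate < 0 || error_rate >= 1, "error_rate must be in [0,1)")
  fail_if(duplicate_rate < 0 || duplicate_rate >= 1,
          "duplicate_rate must be in [0,1)")
  structure(list(nominal_span = nominal, window = as.integer(window),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, duplicate_rate = duplicate_rate),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf(
    "library_spec: span %s bp (window %s-%s), reads %d bp, err %.3g, dup %.3g\n",
    x$nominal_span, x$window[1], x$window[2], x$read_length, x$error_rate,
    x$duplicate_rate))
  invisible(x)
}

## Truncated-normal fragment spans, by rejection.
draw_spans <- function(n, lib) {
  mu <- lib$nominal_span
  sd <- mu / 6
  lo <- max(lib$read_length, 1L)
  hi <- 3L * mu
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mu, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  as.integer(round(out[seq_len(n)]))
}

## Inject per-base substitution errors into a vector of read strings.
inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  rl <- nchar(reads)
  nerr <- rbinom(length(reads), rl, rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    pos <- sample.int(rl[i], nerr[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  reads
}

#' Simulate a paired-end read library from a mixture of conformations
#'
#' Draws fragments from circular chromosomes of a conformation mixture,
#' sequences both fragment ends inward (read 2 is the reverse complement
#' of the fragment's right end), injects substitution errors, and emits
#' PCR duplicates as exact coordinate re-draws of earlier fragments.
#' Fragments may wrap the circular origin. A truth table records, for
#' every pair, the source conformation, chromosome, fragment coordinates
#' and duplicate status.
#'
#' @param conformations a [mix_conformations()] object, or a single
#'   [genome_model()] (taken as a pure reference sample).
#' @param lib a [library_spec()].
#' @param n_pairs number of read pairs to emit (duplicates included).
#' @param seed integer seed.
#' @return A list of class `read_set` with elements `reads1`, `reads2`
#'   (named character vectors), `truth` (data frame: `id, conformation,
#'   chrom, frag_start, frag_end, span, duplicate`), and `lib`.
#' @export
sim_read_pairs <- function(conformations, lib, n_pairs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(conformations, "genome_model")) {
    conformations <- mix_conformations(conformations)
  }
  stopifnot(inherits(conformations, "conformation_set"),
            inherits(lib, "library_spec"))
  rl <- lib$read_length
  n_pairs <- as.integer(n_pairs)

  spans <- draw_spans(n_pairs, lib)
  fail_if(any(spans < rl), "read_length exceeds the minimum fragment span")

  # choose source conformation and chromosome (probability ~ weight x length)
  nmod <- length(conformations$models)
  conf <- sample.int(nmod, n_pairs, replace = TRUE,
                     prob = conformations$weights)
  chrom <- character(n_pairs); start <- integer(n_pairs)
  for (k in seq_len(nmod)) {
    i <- which(conf == k)
    if (!length(i)) next
    g <- conformations$models[[k]]
    Ls <- chrom_len(g)
    ci <- sample.int(length(Ls), length(i), replace = TRUE, prob = Ls)
    chrom[i] <- names(Ls)[ci]
    start[i] <- as.integer(floor(runif(length(i)) * Ls[ci])) + 1L
  }

  # PCR duplicates: re-draw coordinates of an earlier fragment
  dup <- c(FALSE, runif(n_pairs - 1L) < lib$duplicate_rate)
  for (i in which(dup)) {
    j <- sample.int(i - 1L, 1L)
    conf[i] <- conf[j]; chrom[i] <- chrom[j]
    start[i] <- start[j]; spans[i] <- spans[j]
  }

  ids <- sprintf("frag%06d", seq_len(n_pairs))
  reads1 <- character(n_pairs); reads2 <- character(n_pairs)
  for (k in seq_len(nmod)) {
    g <- conformations$models[[k]]
    for (cn in names(g$chroms)) {
      i <- which(conf == k & chrom == cn)
      if (!length(i)) next
      ext <- circ_ext(g$chroms[[cn]], max(spans[i]))
      reads1[i] <- substring(ext, start[i], start[i] + rl - 1L)
      r2fwd <- substring(ext, start[i] + spans[i] - rl, start[i] + spans[i] - 1L)
      reads2[i] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(r2fwd)))
    }
  }
  reads1 <- inject_errors(reads1, lib$error_rate)
  reads2 <- inject_errors(reads2, lib$error_rate)
  names(reads1) <- ids; names(reads2) <- ids

  Lsrc <- vapply(seq_len(n_pairs), function(i)
    nchar(conformations$models[[conf[i]]]$chroms[[chrom[i]]]), numeric(1))
  truth <- data.frame(
    id = ids, conformation = conformations$labels[conf], chrom = chrom,
    frag_start = start, frag_end = mod1(start + spans - 1L, as.integer(Lsrc)),
    span = spans, duplicate = dup, stringsAsFactors = FALSE)
  structure(list(reads1 = reads1, reads2 = reads2, truth = truth, lib = lib),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d pairs, %d bp reads, %d duplicate pairs\n",
              nrow(x$truth), x$lib$read_length, sum(x$truth$duplicate)))
  tab <- table(x$truth$conformation)
  for (nm in names(tab)) cat(sprintf("  %-12s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Write reads to a pair of FASTQ files
#'
#' @param rs a `read_set` from [sim_read_pairs()].
#' @param prefix output path prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written with constant quality `I`.
#' @return The two file paths, invisibly.
#' @export
write_fastq_pair <- function(rs, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    reads <- if (m == 1) rs$reads1 else rs$reads2
    qual <- strrep("I", nchar(reads))
    con <- file(paths[m], "w")
    writeLines(paste0("@", names(reads), "/", m, "\n", reads, "\n+\n", qual),
               con, sep = "\n")
    close(con)
  }
  invisible(paths)
}

#' Read a pair of FASTQ files into a read set
#'
#' @param path1,path2 FASTQ files for read 1 and read 2.
#' @return A list with `reads1` and `reads2` named character vectors.
#' @export
read_fastq_pair <- function(path1, path2) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    setNames(as.character(x), sub("/[12]$", "", sub("\\s.*$", "", names(x))))
  }
  list(reads1 = rd(path1), reads2 = rd(path2))
}
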