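#' Construct a genome model
#'
#' A genome model is the package's container for a (possibly
#' multichromosomal) genome: a set of chromosome sequences, a circularity
#' flag per chromosome, and, for simulated genomes, the table of planted
#' repeat copies that constitutes the ground truth for downstream analyses.
#'
#' @param chroms named character vector of chromosome sequences (ACGT).
#' @param circular logical, recycled to one flag per chromosome. Simulated
#'   genomes are circular; hand-built linear models are accepted for real
#'   input and for oracle tests.
#' @param repeats data frame of planted repeat copies with columns
#'   `family, copy, chrom, start, end, strand, length, identity`, or `NULL`.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chroms, circular = TRUE, repeats = NULL) {
  fail_if(is.null(names(chroms)) || anyDuplicated(names(chroms)) > 0,
          "chromosomes must have unique names")
  fail_if(any(nchar(chroms) < 1L), "chromosome length must be >= 1")
  bad <- grepl("[^ACGT]", chroms)
  fail_if(any(bad), "chromosome sequences must be over {A,C,G,T}")
  circular <- rep_len(as.logical(circular), length(chroms))
  names(circular) <- names(chroms)
  if (is.null(repeats)) repeats <- empty_repeat_truth()
  structure(list(chroms = chroms, circular = circular, repeats = repeats),
            class = "genome_model")
}

empty_repeat_truth <- function() {
  data.frame(family = character(), copy = integer(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             length = integer(), identity = numeric(),
             stringsAsFactors = FALSE)
}

chrom_len <- function(g) nchar(g$chroms)

#' @export
print.genome_model <- function(x, ...) {
  L <- chrom_len(x)
  cat(sprintf("genome_model: %d chromosome(s), %s bp total (%s)\n",
              length(L), format(sum(L), big.mark = ","),
              if (all(x$circular)) "circular" else "mixed/linear"))
  gc <- vapply(x$chroms, gc_content, numeric(1))
  for (i in seq_along(L)) {
    cat(sprintf("  %-12s %8d bp  GC %.1f%%\n", names(L)[i], L[i], gc[i]))
  }
  if (nrow(x$repeats) > 0) {
    cat(sprintf("  planted repeats: %d copies in %d family(ies)\n",
                nrow(x$repeats), length(unique(x$repeats$family))))
  }
  invisible(x)
}

## Apply `n_sub` substitutions at distinct positions of a sequence.
mutate_seq <- function(seq, n_sub) {
  if (n_sub <= 0L) return(seq)
  n <- nchar(seq)
  pos <- sample.int(n, min(n_sub, n))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Simulate a multichromosomal circular genome with planted repeats
#'
#' Generates random circular chromosomes at a target GC content and plants
#' dispersed repeat families of chosen copy number, length, identity and
#' orientation, recording the exact planted coordinates as ground truth.
#' Flanking bases around planted copies are forced to differ between copies
#' (in copy orientation) so that the planted boundaries are maximal: the
#' truth table then defines exactly the repeat a perfect-repeat finder
#' should recover.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths chromosome lengths in bp: a single value (recycled), one
#'   value per chromosome, or a `c(min, max)` range sampled uniformly when
#'   `n_chrom != 2`.
#' @param gc target GC fraction.
#' @param repeat_plan `NULL`, or a data frame with one row per repeat
#'   family and columns `copies` (>= 2), `length` (bp), and optionally
#'   `family` (label), `identity` (fraction, default 1), `orientation`
#'   (`"direct"` or `"inverted"`, default direct), `chrom` (chromosome to
#'   plant on; default random), `placement` (`"same"` places all copies on
#'   one chromosome, `"across"` cycles copies over chromosomes).
#' @param placements optional data frame `family, copy, chrom, start`
#'   pinning copy positions explicitly (strands still follow orientation).
#' @param seed integer seed; sets the RNG.
#' @param margin minimum distance (bp) kept between planted copies, and
#'   between any copy and the origin.
#' @param max_tries placement attempts per copy before the plan is declared
#'   infeasible.
#' @return A [genome_model()] with the planted-repeat truth table. Copies
#'   other than the first of each family carry
#'   `round((1 - identity) * length)` substitutions relative to the first.
#' @examples
#' g <- sim_genome(1, 10000, seed = 1)
#' nrow(g$repeats) # 0: empty plan
#' @export
sim_genome <- function(n_chrom = 1L, lengths, gc = 0.45, repeat_plan = NULL,
                       placements = NULL, seed = NULL, margin = 500L,
                       max_tries = 500L) {
  if (!is.null(seed)) set.seed(seed)
  if (length(lengths) == 2L && n_chrom != 2L) {
    lengths <- sample(lengths[1]:lengths[2], n_chrom, replace = TRUE)
  } else {
    lengths <- rep_len(as.integer(lengths), n_chrom)
  }
  ids <- sprintf("chr%d", seq_len(n_chrom))
  chroms <- setNames(vapply(lengths, random_dna, character(1), gc = gc), ids)

  truth <- empty_repeat_truth()
  if (!is.null(repeat_plan) && nrow(repeat_plan) > 0) {
    rp <- repeat_plan
    if (is.null(rp$family)) rp$family <- sprintf("R%d", seq_len(nrow(rp)))
    if (is.null(rp$identity)) rp$identity <- 1
    if (is.null(rp$orientation)) rp$orientation <- "direct"
    if (is.null(rp$placement)) rp$placement <- "same"
    if (is.null(rp$chrom)) rp$chrom <- NA_character_
    fail_if(any(rp$copies < 2L), "repeat families need >= 2 copies")
    fail_if(any(rp$length < 1L), "repeat length must be >= 1")

    occupied <- lapply(chroms, function(x) cbind(start = integer(), end = integer()))

    place_copy <- function(chrom_id, len) {
      L <- nchar(chroms[[chrom_id]])
      lo <- margin + 1L
      hi <- L - len - margin
      fail_if(hi < lo, "infeasible repeat plan: chromosome too short")
      for (k in seq_len(max_tries)) {
        s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        e <- s + len - 1L
        occ <- occupied[[chrom_id]]
        clash <- nrow(occ) > 0 &&
          any(s <= occ[, "end"] + margin & e >= occ[, "start"] - margin)
        if (!clash) {
          occupied[[chrom_id]] <<- rbind(occ, cbind(start = s, end = e))
          return(s)
        }
      }
      stop("infeasible repeat plan: could not place repeat copy without overlap",
           call. = FALSE)
    }

    for (f in seq_len(nrow(rp))) {
      fam <- rp$family[f]
      len <- as.integer(rp$length[f])
      n_cp <- as.integer(rp$copies[f])
      src <- random_dna(len, gc)
      n_sub <- round((1 - rp$identity[f]) * len)
      strands <- if (rp$orientation[f] == "inverted") {
        rep(c("+", "-"), length.out = n_cp)
      } else rep("+", n_cp)
      fam_chroms <- if (rp$placement[f] == "across") {
        ids[mod1(seq_len(n_cp), n_chrom)]
      } else {
        rep(if (is.na(rp$chrom[f])) sample(ids, 1L) else rp$chrom[f], n_cp)
      }
      for (j in seq_len(n_cp)) {
        cp_seq <- if (j == 1L) src else mutate_seq(src, n_sub)
        pin <- if (!is.null(placements)) {
          placements[placements$family == fam & placements$copy == j, , drop = FALSE]
        } else NULL
        if (!is.null(pin) && nrow(pin) == 1L) {
          chrom_id <- pin$chrom
          s <- as.integer(pin$start)
          occupied[[chrom_id]] <- rbind(occupied[[chrom_id]],
                                        cbind(start = s, end = s + len - 1L))
        } else {
          chrom_id <- fam_chroms[j]
          s <- place_copy(chrom_id, len)
        }
        e <- s + len - 1L
        ins <- if (strands[j] == "+") cp_seq else revcomp(cp_seq)
        substr(chroms[[chrom_id]], s, e) <- ins
        truth <- rbind(truth, data.frame(
          family = fam, copy = j, chrom = chrom_id, start = s, end = e,
          strand = strands[j], length = len, identity = rp$identity[f],
          stringsAsFactors = FALSE))
      }
    }
    chroms <- enforce_maximal_flanks(chroms, truth)
  }
  genome_model(chroms, circular = TRUE, repeats = truth)
}

## Force the `pad` bases flanking each planted copy (read in copy
## orientation) to differ across copies of a family, so planted boundaries
## are maximal and score-positive extension past them is (essentially)
## impossible under any local-alignment scoring. Exact for families of
## <= 4 copies; best effort beyond that.
enforce_maximal_flanks <- function(chroms, truth, pad = 4L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (fam in unique(truth$family)) {
    cps <- truth[truth$family == fam, , drop = FALSE]
    n <- nrow(cps)
    for (side in c("up", "down")) {
      for (o in seq_len(pad)) {
        letters_assigned <- DNA_BASES[mod1(seq_len(n) + o, 4L)]
        for (j in seq_len(n)) {
          want <- letters_assigned[j] # flank base in copy orientation
          if (cps$strand[j] == "+") {
            pos <- if (side == "up") cps$start[j] - o else cps$end[j] + o
            base <- want
          } else {
            pos <- if (side == "up") cps$end[j] + o else cps$start[j] - o
            base <- comp[[want]]
          }
          L <- nchar(chroms[[cps$chrom[j]]])
          pos <- mod1(pos, L)
          substr(chroms[[cps$chrom[j]]], pos, pos) <- base
        }
      }
    }
  }
  chroms
}

#' Write a genome model to FASTA
#'
#' One record per chromosome; the header carries a `circular=true/false`
#' key=value tag after the identifier.
#'
#' @param genome a [genome_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$chroms)
  names(x) <- sprintf("%s circular=%s", names(genome$chroms),
                      tolower(as.character(genome$circular)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genome FASTA into a genome model
#'
#' Recognises a `circular=true/false` tag on the header line; records
#' without a tag are treated as circular when `default_circular` is TRUE.
#'
#' @param path FASTA file.
#' @param default_circular circularity assumed when the header says nothing.
#' @return A [genome_model()] with an empty truth table.
#' @export
read_genome_fasta <- function(path, default_circular = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  ids <- sub("\\s.*$", "", hdr)
  circ <- rep(default_circular, length(x))
  has <- grepl("circular=", hdr)
  circ[has] <- grepl("circular=true", hdr[has], fixed = TRUE)
  genome_model(setNames(as.character(x), ids), circular = circ)
}
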