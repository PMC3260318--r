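## Recombinant genome conformations by string surgery on segment maps.
##
## A crossover between two copies of a repeat exchanges their flanking
## sequences. On one circle, a crossover between direct copies splits the
## circle into two subcircles (each retaining one copy); between inverted
## copies it inverts the intervening segment; between copies on two
## different circles it fuses them into one. Every derived conformation is
## represented both as sequence and as a segment map back to the reference,
## which is what lets read mappings be projected into the alternative
## conformation.

## A piece is (src_chrom, src_start, src_end, src_strand); src intervals are
## non-wrapping and 1-based closed; strand "-" means the reverse complement
## of the source interval is laid down.
build_variant_chrom <- function(genome, pieces) {
  pieces <- Filter(function(p) p$end >= p$start, pieces)
  seqs <- vapply(pieces, function(p) {
    s <- substr(genome$chroms[[p$chrom]], p$start, p$end)
    if (p$strand == "-") revcomp(s) else s
  }, character(1))
  lens <- nchar(seqs)
  vstart <- cumsum(c(1L, head(lens, -1L)))
  map <- data.frame(
    vstart = vstart, vend = vstart + lens - 1L,
    src_chrom = vapply(pieces, `[[`, character(1), "chrom"),
    src_start = vapply(pieces, function(p) as.integer(p$start), integer(1)),
    src_end = vapply(pieces, function(p) as.integer(p$end), integer(1)),
    src_strand = vapply(pieces, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  list(seq = paste(seqs, collapse = ""), map = map)
}

piece <- function(chrom, start, end, strand = "+") {
  list(chrom = chrom, start = as.integer(start), end = as.integer(end),
       strand = strand)
}

#' Derive the recombinant conformation for a repeat pair
#'
#' Performs the crossover between two equal-length repeat copies and
#' returns the resulting genome conformation together with a segment map
#' back to the reference. Direct copies on one circle yield two subcircles
#' (each retaining one repeat copy); copies in opposite orientation on one
#' circle yield an inversion of the intervening segment; copies on two
#' distinct circles yield a single fused circle. Chromosomes not involved
#' in the crossover are carried over unchanged.
#'
#' @param genome a [genome_model()].
#' @param copyA,copyB lists or one-row data frames with fields
#'   `chrom, start, end, strand`; intervals must not wrap the origin and
#'   must have equal lengths.
#' @return An object of class `conformation`: a list with elements
#'   `genome` (the variant [genome_model()]), `map` (segment map data frame
#'   with columns `vchrom, vstart, vend, src_chrom, src_start, src_end,
#'   src_strand`), `copies` (variant coordinates of the repeat copies, in a
#'   fixed order defining recombinant environments 1 and 2), and `kind`
#'   (`"fission"`, `"inversion"` or `"fusion"`).
#' @export
derive_recombinant <- function(genome, copyA, copyB) {
  a <- as.list(copyA); b <- as.list(copyB)
  for (cp in list(a, b)) {
    fail_if(cp$end < cp$start,
            "repeat copies wrapping the origin are not supported here")
  }
  lenA <- a$end - a$start + 1L
  lenB <- b$end - b$start + 1L
  fail_if(lenA != lenB, "crossover between copies of unequal length")
  same_chrom <- a$chrom == b$chrom
  if (same_chrom && a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  if (same_chrom) {
    fail_if(a$end >= b$start, "repeat copies overlap; crossover undefined")
  }
  L1 <- nchar(genome$chroms[[a$chrom]])

  vlist <- list()  # vchrom -> list(seq, map)
  copies <- NULL
  if (same_chrom && a$strand == b$strand) {
    kind <- "fission"
    c0 <- a$chrom
    outer_pieces <- list(piece(c0, b$start, L1), piece(c0, 1L, a$start - 1L))
    inner_pieces <- list(piece(c0, a$start, b$start - 1L))
    vlist[[paste0(c0, "_sub1")]] <- build_variant_chrom(genome, outer_pieces)
    vlist[[paste0(c0, "_sub2")]] <- build_variant_chrom(genome, inner_pieces)
    copies <- data.frame(
      vchrom = paste0(c0, c("_sub1", "_sub2")),
      start = c(1L, 1L), end = c(lenA, lenA), stringsAsFactors = FALSE)
    drop <- c0
  } else if (same_chrom) {
    kind <- "inversion"
    c0 <- a$chrom
    pieces <- list(piece(c0, 1L, a$end),
                   piece(c0, a$end + 1L, b$start - 1L, "-"),
                   piece(c0, b$start, L1))
    vlist[[paste0(c0, "_inv")]] <- build_variant_chrom(genome, pieces)
    copies <- data.frame(
      vchrom = rep(paste0(c0, "_inv"), 2L),
      start = c(a$start, b$start), end = c(a$end, b$end),
      stringsAsFactors = FALSE)
    drop <- c0
  } else {
    kind <- "fusion"
    L2 <- nchar(genome$chroms[[b$chrom]])
    rest1 <- list(piece(a$chrom, a$end + 1L, L1), piece(a$chrom, 1L, a$start - 1L))
    if (a$strand == b$strand) {
      restB <- list(piece(b$chrom, b$start, b$end),
                    piece(b$chrom, b$end + 1L, L2),
                    piece(b$chrom, 1L, b$start - 1L))
    } else {
      restB <- list(piece(b$chrom, b$start, b$end, "-"),
                    piece(b$chrom, 1L, b$start - 1L, "-"),
                    piece(b$chrom, b$end + 1L, L2, "-"))
    }
    pieces <- c(list(piece(a$chrom, a$start, a$end)), rest1, restB)
    vname <- paste0(a$chrom, "_", b$chrom, "_fus")
    vlist[[vname]] <- build_variant_chrom(genome, pieces)
    # variant position of copyB = 1 (copyA) + len(rest1) + offset
    posB <- lenA + (L1 - lenA) + 1L
    copies <- data.frame(
      vchrom = rep(vname, 2L), start = c(1L, posB),
      end = c(lenA, posB + lenB - 1L), stringsAsFactors = FALSE)
    drop <- c(a$chrom, b$chrom)
  }

  # carry over unchanged chromosomes with identity map rows
  keep <- setdiff(names(genome$chroms), drop)
  for (k in keep) {
    vlist[[k]] <- list(seq = genome$chroms[[k]], map = data.frame(
      vstart = 1L, vend = nchar(genome$chroms[[k]]), src_chrom = k,
      src_start = 1L, src_end = nchar(genome$chroms[[k]]), src_strand = "+",
      stringsAsFactors = FALSE))
  }

  map <- do.call(rbind, lapply(names(vlist), function(v) {
    cbind(vchrom = v, vlist[[v]]$map, stringsAsFactors = FALSE)
  }))
  chroms <- setNames(vapply(vlist, `[[`, character(1), "seq"), names(vlist))
  vg <- genome_model(chroms, circular = TRUE)
  structure(list(genome = vg, map = map, copies = copies, kind = kind,
                 source = list(copyA = a, copyB = b)),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation (%s): %d chromosome(s), %s bp\n", x$kind,
              length(x$genome$chroms),
              format(sum(chrom_len(x$genome)), big.mark = ",")))
  invisible(x)
}

## Project a reference position (and strand) through a segment map.
## Returns a data frame of hits (vchrom, vpos, vstrand); positions inside
## the exchanged repeat may project to several places, positions elsewhere
## project uniquely.
project_position <- function(map, chrom, pos, strand = "+") {
  hit <- map[map$src_chrom == chrom & map$src_start <= pos & map$src_end >= pos,
             , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(data.frame(vchrom = character(), vpos = integer(),
                      vstrand = character(), stringsAsFactors = FALSE))
  }
  vpos <- ifelse(hit$src_strand == "+",
                 hit$vstart + (pos - hit$src_start),
                 hit$vstart + (hit$src_end - pos))
  flip <- hit$src_strand == "-"
  vstrand <- ifelse(flip, ifelse(strand == "+", "-", "+"), strand)
  data.frame(vchrom = hit$vchrom, vpos = as.integer(vpos), vstrand = vstrand,
             stringsAsFactors = FALSE)
}

#' Mix a reference genome with recombinant conformations
#'
#' Bundles a reference genome model and derived variant conformations with
#' mixing weights, for use by [sim_read_pairs()]. The weights are the
#' relative molecular abundances of the conformations in the simulated
#' DNA sample.
#'
#' @param reference a [genome_model()].
#' @param variants list of `conformation` objects (or genome models).
#' @param weights numeric vector, one weight per conformation including the
#'   reference first; must sum to 1.
#' @return An object of class `conformation_set`.
#' @export
mix_conformations <- function(reference, variants = list(), weights = 1) {
  fail_if(length(weights) != 1L + length(variants),
          "need one weight for the reference plus one per variant")
  fail_if(abs(sum(weights) - 1) > 1e-8, "mixing weights must sum to 1")
  fail_if(any(weights < 0), "mixing weights must be nonnegative")
  models <- c(list(reference),
              lapply(variants, function(v) {
                if (inherits(v, "conformation")) v$genome else v
              }))
  labels <- c("reference",
              if (length(variants)) sprintf("variant%d", seq_along(variants)))
  structure(list(models = models, weights = weights, labels = labels),
            class = "conformation_set")
}
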