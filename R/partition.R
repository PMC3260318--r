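## Homology-based classification of intergenic sequence.
##
## Intergenic intervals are partitioned positionally through a fixed
## cascade: plastid-derived (high-stringency search against a plastid
## database, with a gene-exclusion list and an AT-content filter on hits),
## then conserved with other plant mitochondrial genomes, then conserved
## with a general database (nucleotide or translated protein search),
## else uncharacterized. Raw alignment scores, not E-values, gate every
## stage.

#' Scoring profile for a homology search stage
#'
#' @param reward match reward (positive).
#' @param penalty mismatch penalty as a positive magnitude.
#' @param gap_open,gap_extend gap costs as positive magnitudes.
#' @param word_size exact seed length.
#' @param min_score raw-score threshold for reporting a hit.
#' @param dust skip low-complexity seed words.
#' @return A list of class `score_profile`.
#' @export
score_profile <- function(reward, penalty, gap_open, gap_extend, word_size,
                          min_score, dust = FALSE) {
  fail_if(min_score <= 0, "min_score must be positive")
  fail_if(reward <= 0, "reward must be positive")
  structure(list(reward = reward, penalty = penalty, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = word_size,
                 min_score = min_score, dust = dust),
            class = "score_profile")
}

#' @rdname score_profile
#' @export
profile_plastid <- function() score_profile(5, 4, 8, 6, 7L, 250)

#' @rdname score_profile
#' @export
profile_mt <- function() score_profile(2, 3, 5, 2, 9L, 70)

#' @rdname score_profile
#' @export
profile_general_nt <- function() score_profile(2, 3, 5, 2, 9L, 70, dust = TRUE)

## low-complexity seed filter: a word built from <= 2 distinct bases
dusty_word <- function(words) {
  vapply(strsplit(words, "", fixed = TRUE),
         function(ch) length(unique(ch)) <= 2L, logical(1))
}

## local alignments of one query against one subject (both plain strings),
## forward orientation only; coordinates are 1-based in each input.
align_two <- function(q, s, prof, pad = 200L, cluster_gap = 100L) {
  w <- prof$word_size
  nq <- nchar(q); ns <- nchar(s)
  if (nq < w || ns < w) return(NULL)
  qp <- seq_len(nq - w + 1L)
  sp <- seq_len(ns - w + 1L)
  qw <- substring(q, qp, qp + w - 1L)
  sw <- substring(s, sp, sp + w - 1L)
  if (prof$dust) {
    keep <- !dusty_word(qw)
    qp <- qp[keep]; qw <- qw[keep]
  }
  m <- match(sw, qw)
  # expand: all query positions sharing each matched word
  hits <- which(!is.na(m))
  if (!length(hits)) return(NULL)
  seedlist <- split(qp, qw)
  pairs <- do.call(rbind, lapply(hits, function(si) {
    cbind(qpos = seedlist[[sw[si]]], spos = sp[si])
  }))
  submat <- matrix(-prof$penalty, 4L, 4L,
                   dimnames = list(DNA_BASES, DNA_BASES))
  diag(submat) <- prof$reward
  res <- list()
  d <- pairs[, "spos"] - pairs[, "qpos"]
  for (g in split(seq_len(nrow(pairs)), d)) {
    dd <- d[g[1L]]
    for (cl in split_clusters(pairs[g, "qpos"], cluster_gap)) {
      ps <- pairs[g, "qpos"][cl]
      qLo <- max(1L, min(ps) - pad)
      qHi <- min(nq, max(ps) + w - 1L + pad)
      sLo <- qLo + dd; sHi <- qHi + dd
      t1 <- max(0L, 1L - sLo); qLo <- qLo + t1; sLo <- sLo + t1
      t2 <- max(0L, sHi - ns); qHi <- qHi - t2; sHi <- sHi - t2
      if (qHi <= qLo) next
      xq <- substr(q, qLo, qHi)
      xs <- substr(s, sLo, sHi)
      mv <- charToRaw(xq) == charToRaw(xs)
      sv <- ifelse(mv, prof$reward, -prof$penalty)
      bs <- best_subarray(sv)
      if (is.null(bs)) next
      ug <- bs[["score"]]
      cur <- list(score = ug, q1 = bs[["i1"]], q2 = bs[["i2"]],
                  s1 = bs[["i1"]], s2 = bs[["i2"]],
                  len = bs[["i2"]] - bs[["i1"]] + 1L,
                  id = 100 * sum(mv[bs[["i1"]]:bs[["i2"]]]) /
                    (bs[["i2"]] - bs[["i1"]] + 1L))
      if (ug >= prof$min_score / 2) {
        pa <- Biostrings::pairwiseAlignment(
          xq, xs, type = "local", substitutionMatrix = submat,
          gapOpening = prof$gap_open, gapExtension = prof$gap_extend)
        if (Biostrings::score(pa) > ug) {
          gp <- as.character(Biostrings::pattern(pa))
          cur <- list(score = Biostrings::score(pa),
                      q1 = Biostrings::start(Biostrings::pattern(pa)),
                      q2 = Biostrings::end(Biostrings::pattern(pa)),
                      s1 = Biostrings::start(Biostrings::subject(pa)),
                      s2 = Biostrings::end(Biostrings::subject(pa)),
                      len = nchar(gp),
                      id = 100 * Biostrings::nmatch(pa) / nchar(gp))
        }
      }
      if (cur$score < prof$min_score) next
      res[[length(res) + 1L]] <- data.frame(
        q_start = qLo + cur$q1 - 1L, q_end = qLo + cur$q2 - 1L,
        s_start = sLo + cur$s1 - 1L, s_end = sLo + cur$s2 - 1L,
        length = cur$len, identity = cur$id, score = cur$score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(NULL)
  unique(do.call(rbind, res))
}

#' Local alignment hits of a query against a sequence database
#'
#' Seed-and-extend local alignment under a raw-score threshold, on both
#' strands of each database record. Raw score is the sum of match rewards
#' minus mismatch and gap costs, as in the classification cascade.
#'
#' @param query a DNA string.
#' @param db named character vector of database sequences.
#' @param prof a [score_profile()].
#' @return Data frame of hits: `subject, q_start, q_end, s_start, s_end,
#'   strand, length, identity, score` (zero rows if none).
#' @examples
#' seg <- paste(rep("ACGTG", 10), collapse = "") # 50 bp
#' local_align_score(seg, c(db1 = seg), score_profile(5, 4, 8, 6, 7, 250))
#' @export
local_align_score <- function(query, db, prof) {
  out <- list()
  for (nm in names(db)) {
    h <- align_two(query, db[[nm]], prof)
    if (!is.null(h)) {
      h$subject <- nm; h$strand <- "+"
      out[[length(out) + 1L]] <- h
    }
    rc <- revcomp(db[[nm]])
    h2 <- align_two(query, rc, prof)
    if (!is.null(h2)) {
      ns <- nchar(rc)
      tmp <- h2$s_start
      h2$s_start <- ns - h2$s_end + 1L
      h2$s_end <- ns - tmp + 1L
      h2$subject <- nm; h2$strand <- "-"
      out[[length(out) + 1L]] <- h2
    }
  }
  if (!length(out)) {
    return(data.frame(subject = character(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), strand = character(),
                      length = integer(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[, c("subject", "q_start", "q_end", "s_start", "s_end", "strand",
         "length", "identity", "score")]
}

## BLOSUM62 with a stop-codon row/column (score -4) if absent.
blosum62_star <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  if (!("*" %in% rownames(m))) {
    m <- rbind(cbind(m, `*` = -4L), `*` = c(rep(-4L, ncol(m)), 1L))
  }
  m
}

#' Translated (six-frame) homology hits against a protein database
#'
#' Translates the query in all six frames and locally aligns each frame
#' against each database protein with a standard substitution matrix,
#' reporting hits at or above the raw-score threshold with their query
#' nucleotide coordinates.
#'
#' @param query DNA string.
#' @param prot_db named character vector of protein sequences.
#' @param min_score raw-score threshold.
#' @param gap_open,gap_extend gap costs (positive magnitudes).
#' @return Data frame: `subject, frame, q_start, q_end, score` with
#'   `q_start`/`q_end` in nucleotide coordinates of the query.
#' @export
translated_align_score <- function(query, prot_db, min_score = 140,
                                   gap_open = 11, gap_extend = 1) {
  n <- nchar(query)
  if (n < 3L) {
    return(data.frame(subject = character(), frame = integer(),
                      q_start = integer(), q_end = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  mat <- blosum62_star()
  out <- list()
  rc <- revcomp(query)
  for (fr in 1:6) {
    fwd <- fr <= 3L
    off <- ((fr - 1L) %% 3L) + 1L
    src <- if (fwd) query else rc
    len <- ((nchar(src) - off + 1L) %/% 3L) * 3L
    if (len < 3L) next
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(substr(src, off, off + len - 1L)),
      if.fuzzy.codon = "X")))
    for (nm in names(prot_db)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(aa), Biostrings::AAString(prot_db[[nm]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = gap_open, gapExtension = gap_extend)
      sc <- Biostrings::score(pa)
      if (sc < min_score) next
      a1 <- Biostrings::start(Biostrings::pattern(pa))
      a2 <- Biostrings::end(Biostrings::pattern(pa))
      nt1 <- off + 3L * (a1 - 1L)
      nt2 <- off + 3L * a2 - 1L
      if (!fwd) { tmp <- nt1; nt1 <- n - nt2 + 1L; nt2 <- n - tmp + 1L }
      out[[length(out) + 1L]] <- data.frame(
        subject = nm, frame = if (fwd) fr else -(fr - 3L),
        q_start = nt1, q_end = nt2, score = sc, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(subject = character(), frame = integer(),
                      q_start = integer(), q_end = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify intergenic sequence into origin categories
#'
#' Positional cascade over intergenic intervals: positions covered by a
#' surviving plastid hit (raw score >= the plastid threshold, subject not
#' on the gene-exclusion list, hit AT content <= `at_max` %) are
#' plastid-derived; remaining positions covered by a hit against other
#' plant mitochondrial genomes are mt-conserved; remaining positions
#' covered by a general nucleotide hit or a translated protein hit are
#' other-conserved; the rest are uncharacterized. Because assignment is
#' per position with fixed precedence, the per-category totals sum
#' exactly to the total intergenic length.
#'
#' @param genome a [genome_model()].
#' @param intervals data frame `chrom, start, end` of intergenic
#'   intervals (1-based closed, non-wrapping), or `NULL` for whole
#'   chromosomes.
#' @param plastid_db,mt_db,general_nt_db named character vectors of DNA
#'   sequences (any may be `NULL`/empty).
#' @param general_prot_db named character vector of protein sequences for
#'   the translated search, or `NULL`.
#' @param exclude_ids database record names excluded from the plastid
#'   stage (genes with ancient plastid homologs).
#' @param at_max AT-content ceiling (%) for plastid hits.
#' @param profiles list with elements `plastid`, `mt`, `general`
#'   ([score_profile()]s) overriding the defaults.
#' @param min_prot_score raw-score threshold of the translated search.
#' @return A list of class `intergenic_partition`: `labels` (data frame
#'   of maximal runs: `chrom, start, end, category`), and `summary`
#'   (data frame: `category, bp, kb, percent`), where categories are
#'   `plastid`, `mt_conserved`, `other_conserved`, `uncharacterized`.
#' @export
classify_intergenic <- function(genome, intervals = NULL, plastid_db = NULL,
                                mt_db = NULL, general_nt_db = NULL,
                                general_prot_db = NULL,
                                exclude_ids = character(), at_max = 72,
                                profiles = list(), min_prot_score = 140) {
  p_pl <- profiles$plastid %||% profile_plastid()
  p_mt <- profiles$mt %||% profile_mt()
  p_gn <- profiles$general %||% profile_general_nt()
  if (is.null(intervals)) {
    intervals <- data.frame(chrom = names(genome$chroms), start = 1L,
                            end = unname(chrom_len(genome)),
                            stringsAsFactors = FALSE)
  }
  cats <- c("plastid", "mt_conserved", "other_conserved", "uncharacterized")
  labels <- list()
  totals <- setNames(numeric(4), cats)
  for (k in seq_len(nrow(intervals))) {
    cn <- intervals$chrom[k]
    s0 <- intervals$start[k]; e0 <- intervals$end[k]
    sq <- substr(genome$chroms[[cn]], s0, e0)
    len <- nchar(sq)
    assign_cat <- rep("uncharacterized", len)

    cover <- function(hits_q) {
      # hits_q: data frame with q_start/q_end in interval-local coords
      cov <- rep(FALSE, len)
      for (j in seq_len(nrow(hits_q))) {
        cov[hits_q$q_start[j]:hits_q$q_end[j]] <- TRUE
      }
      cov
    }

    if (!is.null(plastid_db) && length(plastid_db)) {
      db <- plastid_db[setdiff(names(plastid_db), exclude_ids)]
      if (length(db)) {
        h <- local_align_score(sq, db, p_pl)
        if (nrow(h)) {
          keep <- vapply(seq_len(nrow(h)), function(j)
            at_content(substr(sq, h$q_start[j], h$q_end[j])) <= at_max,
            logical(1))
          h <- h[keep, , drop = FALSE]
        }
        if (nrow(h)) assign_cat[cover(h)] <- "plastid"
      }
    }
    open <- assign_cat == "uncharacterized"
    if (any(open) && !is.null(mt_db) && length(mt_db)) {
      h <- local_align_score(sq, mt_db, p_mt)
      if (nrow(h)) {
        cov <- cover(h)
        assign_cat[cov & open] <- "mt_conserved"
      }
    }
    open <- assign_cat == "uncharacterized"
    if (any(open)) {
      cov <- rep(FALSE, len)
      if (!is.null(general_nt_db) && length(general_nt_db)) {
        h <- local_align_score(sq, general_nt_db, p_gn)
        if (nrow(h)) cov <- cov | cover(h)
      }
      if (!is.null(general_prot_db) && length(general_prot_db)) {
        h <- translated_align_score(sq, general_prot_db,
                                    min_score = min_prot_score)
        if (nrow(h)) cov <- cov | cover(h)
      }
      assign_cat[cov & open] <- "other_conserved"
    }

    r <- rle(assign_cat)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    labels[[k]] <- data.frame(
      chrom = cn, start = s0 + starts - 1L, end = s0 + ends - 1L,
      category = r$values, stringsAsFactors = FALSE)
    tt <- tapply(r$lengths, r$values, sum)
    totals[names(tt)] <- totals[names(tt)] + tt
  }
  labels <- do.call(rbind, labels)
  total_bp <- sum(totals)
  summary <- data.frame(
    category = cats, bp = as.numeric(totals[cats]),
    kb = as.numeric(totals[cats]) / 1000,
    percent = 100 * as.numeric(totals[cats]) / total_bp,
    stringsAsFactors = FALSE)
  structure(list(labels = labels, summary = summary, total_bp = total_bp),
            class = "intergenic_partition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.intergenic_partition <- function(x, ...) {
  cat(sprintf("intergenic_partition: %.1f kb classified\n", x$total_bp / 1000))
  print.data.frame(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
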