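## Species-unique indel census from a multiple sequence alignment.

## alignment as a character matrix (rows = taxa, columns = positions)
aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (inherits(alignment, "XStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  lens <- nchar(alignment)
  fail_if(length(unique(lens)) != 1L,
          "ragged alignment: all rows must have equal length")
  m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA (gaps as `-`).
#' @return A character matrix, rows named by taxon.
#' @export
read_alignment <- function(path) {
  aln_matrix(Biostrings::readBStringSet(path))
}

#' Call gap events (indels) per taxon from a multiple alignment
#'
#' Each maximal run of gap columns in one taxon, outside the masked
#' column ranges, is one event. Events abutting a mask edge are truncated
#' there and flagged. Polarity is read off the designated outgroup: if
#' the outgroup is ungapped over the event the gapped taxon carries a
#' deletion; if the outgroup is gapped too the polarity is undetermined
#' (the event still counts). Additionally, maximal runs where exactly one
#' taxon has sequence while every other taxon is gapped are emitted as
#' insertion events owned by that taxon.
#'
#' @param alignment character matrix, named character vector, or
#'   `XStringSet` of equal-length aligned sequences.
#' @param outgroup taxon name used to polarise events, or `NULL`.
#' @param mask_ranges data frame `start, end` of alignment columns to
#'   exclude (e.g. unalignable gene ends), or `NULL`.
#' @return Data frame of class `indel_events`: `taxon, start, end, length,
#'   kind` (`deletion`, `insertion`, `undetermined`), `truncated`.
#' @export
call_indels <- function(alignment, outgroup = NULL, mask_ranges = NULL) {
  m <- aln_matrix(alignment)
  taxa <- rownames(m)
  fail_if(is.null(taxa), "alignment rows must be named by taxon")
  nc <- ncol(m)
  masked <- rep(FALSE, nc)
  if (!is.null(mask_ranges) && nrow(mask_ranges)) {
    for (j in seq_len(nrow(mask_ranges))) {
      masked[max(1L, mask_ranges$start[j]):min(nc, mask_ranges$end[j])] <- TRUE
    }
  }
  isgap <- m == "-"
  events <- list()
  for (t in taxa) {
    g <- isgap[t, ] & !masked
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[j]; e <- ends[j]
      trunc <- (s > 1L && masked[s - 1L] && isgap[t, s - 1L]) ||
        (e < nc && masked[e + 1L] && isgap[t, e + 1L])
      kind <- if (is.null(outgroup) || t == outgroup) {
        "undetermined"
      } else if (all(!isgap[outgroup, s:e])) "deletion" else "undetermined"
      events[[length(events) + 1L]] <- data.frame(
        taxon = t, start = s, end = e, length = e - s + 1L, kind = kind,
        truncated = trunc, stringsAsFactors = FALSE)
    }
  }
  # insertions: exactly one taxon with sequence, all others gapped
  if (length(taxa) >= 2L) {
    nongap_count <- colSums(!isgap)
    single <- nongap_count == 1L & !masked
    if (any(single)) {
      owner <- apply(m[, single, drop = FALSE], 2L, function(col)
        taxa[col != "-"])
      pos <- which(single)
      brk <- cumsum(c(1L, (diff(pos) > 1L) | (owner[-1L] != owner[-length(owner)])))
      for (g in split(seq_along(pos), brk)) {
        s <- pos[g[1L]]; e <- pos[g[length(g)]]
        events[[length(events) + 1L]] <- data.frame(
          taxon = owner[g[1L]], start = s, end = e, length = e - s + 1L,
          kind = "insertion", truncated = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(events)) {
    ev <- data.frame(taxon = character(), start = integer(), end = integer(),
                     length = integer(), kind = character(),
                     truncated = logical(), stringsAsFactors = FALSE)
  } else {
    ev <- do.call(rbind, events)
  }
  attr(ev, "taxa") <- taxa
  attr(ev, "outgroup") <- outgroup
  class(ev) <- c("indel_events", "data.frame")
  ev
}

#' Count indels unique to a single taxon
#'
#' A deletion-type event of taxon `t` is unique when no gap event of any
#' other taxon overlaps its column interval (overlap on even a single
#' shared column disqualifies both). An insertion event of taxon `t`
#' (sequence present only in `t`) is unique when the corresponding gap
#' runs of every other taxon coincide exactly with the event columns --
#' i.e. no other taxon's gap extends beyond the inserted block.
#'
#' @param events an `indel_events` data frame from [call_indels()].
#' @param ingroup_taxa taxa whose unique indels are counted; defaults to
#'   all taxa in the alignment.
#' @return A list with `events` (the input plus a logical `unique`
#'   column), `per_taxon` (data frame `taxon, n_unique, total_bp`), and
#'   `size_distribution` (table of unique-event lengths).
#' @export
unique_indels <- function(events, ingroup_taxa = NULL) {
  taxa <- attr(events, "taxa")
  if (is.null(ingroup_taxa)) ingroup_taxa <- taxa
  gaps <- events[events$kind != "insertion", , drop = FALSE]
  uniq <- rep(FALSE, nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (!(e$taxon %in% ingroup_taxa)) next
    if (e$kind != "insertion") {
      other <- gaps[gaps$taxon != e$taxon, , drop = FALSE]
      uniq[i] <- !any(other$start <= e$end & other$end >= e$start)
    } else {
      ok <- TRUE
      for (t in setdiff(taxa, e$taxon)) {
        tg <- gaps[gaps$taxon == t, , drop = FALSE]
        ov <- tg[tg$start <= e$end & tg$end >= e$start, , drop = FALSE]
        if (nrow(ov) != 1L || ov$start != e$start || ov$end != e$end) {
          ok <- FALSE; break
        }
      }
      uniq[i] <- ok
    }
  }
  events$unique <- uniq
  ue <- events[uniq, , drop = FALSE]
  per <- data.frame(
    taxon = ingroup_taxa,
    n_unique = vapply(ingroup_taxa, function(t) sum(ue$taxon == t), integer(1)),
    total_bp = vapply(ingroup_taxa, function(t)
      sum(ue$length[ue$taxon == t]), integer(1)),
    stringsAsFactors = FALSE)
  list(events = events, per_taxon = per,
       size_distribution = table(ue$length))
}
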