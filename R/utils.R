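#' @import methods
#' @importFrom stats rnorm runif rbinom setNames aggregate median quantile
#' @importFrom utils head tail combn write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Reduce a 1-based position onto a circle of length L.
mod1 <- function(x, L) ((x - 1L) %% L) + 1L

#' Random DNA sequence with a target GC content
#'
#' @param n sequence length in bp.
#' @param gc target GC fraction in `[0, 1]`.
#' @return A single character string over `ACGT`.
#' @keywords internal
random_dna <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x character string over `ACGTN`.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Extend a circular sequence by `extra` bases past the origin.
circ_ext <- function(seq, extra) {
  L <- nchar(seq)
  if (extra <= 0L) return(seq)
  if (extra >= L) extra <- L - 1L
  paste0(seq, substr(seq, 1L, extra))
}

## Substring of a circular sequence starting at `start` (any integer),
## length `len`; wraps through the origin as needed.
circ_substr <- function(seq, start, len) {
  L <- nchar(seq)
  s <- mod1(start, L)
  if (s + len - 1L <= L) return(substr(seq, s, s + len - 1L))
  paste0(substr(seq, s, L), substr(seq, 1L, s + len - 1L - L))
}

## Hamming distance between two equal-length strings.
hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

## Forward arc length from position `from` to position `to` on a circle.
arc_fwd <- function(from, to, L) ((to - from) %% L)

## Does circular interval [s, s+len-1] (mod L) contain position p?
circ_contains <- function(s, len, p, L) arc_fwd(s, p, L) < len

## Split a possibly wrapping 1-based closed circular interval into
## non-wrapping pieces. Returns a matrix with columns start, end.
split_wrap <- function(start, end, L) {
  if (end >= start) return(cbind(start = start, end = end))
  cbind(start = c(start, 1L), end = c(L, end))
}

## Smallest gap (bp) between two non-overlapping intervals on a circle;
## 0 if they touch or overlap.
circ_gap <- function(s1, e1, s2, e2, L) {
  len1 <- (e1 - s1) %% L + 1L
  len2 <- (e2 - s2) %% L + 1L
  g1 <- (s2 - e1 - 1L) %% L # forward gap from interval 1 to 2
  g2 <- (s1 - e2 - 1L) %% L
  if (g1 + len2 + g2 + len1 != L) return(0L) # overlapping
  min(g1, g2)
}

## stopifnot with a custom message
fail_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' AT content of a DNA sequence
#'
#' Percentage of A+T among unambiguous bases; ambiguous characters are
#' excluded from both numerator and denominator.
#'
#' @param x character string (DNA).
#' @return AT percentage in `[0, 100]`; `NA` for an empty or all-ambiguous
#'   sequence.
#' @examples
#' at_content("ATAT") # 100
#' at_content("ACGT") # 50
#' @export
at_content <- function(x) {
  fail_if(nchar(x) == 0L, "at_content: empty sequence")
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(x), DNA_BASES)
  tot <- sum(cnt)
  if (tot == 0L) return(NA_real_)
  100 * (cnt[["A"]] + cnt[["T"]]) / tot
}

#' GC content of a DNA sequence
#'
#' @param x character string (DNA).
#' @return GC percentage in `[0, 100]` over unambiguous bases.
#' @export
gc_content <- function(x) {
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(x), DNA_BASES)
  tot <- sum(cnt)
  if (tot == 0L) return(NA_real_)
  100 * (cnt[["C"]] + cnt[["G"]]) / tot
}

#' Write a data frame as tab-separated values
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Are two circular sequences equal up to rotation (same orientation)?
is_rotation <- function(a, b) {
  nchar(a) == nchar(b) &&
    (nchar(a) == 0L || grepl(b, paste0(a, a), fixed = TRUE))
}

## Circular-equality up to rotation and strand.
same_circle <- function(a, b) is_rotation(a, b) || is_rotation(a, revcomp(b))
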