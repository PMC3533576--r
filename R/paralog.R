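# Pairwise similarity of tRNA paralogs, supporting the
# duplication/anticodon-mutation interpretation of remolded tRNA pairs.

#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch with match +1, mismatch -1 and an affine gap cost of
#' 2 for the first gapped position plus 1 per extension, end gaps penalized
#' (via [Biostrings::pairwiseAlignment]). Identity is counted over all
#' alignment columns, gaps included. Because co-optimal alignments can
#' differ in column count, the operands are aligned in a fixed canonical
#' order (shorter, then lexicographically smaller, first), which makes the
#' result symmetric and the tie-breaking deterministic.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return List with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length), `matches`, `columns` and `identity` (fraction in `[0, 1]`).
#' @export
align_pair <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  a <- toupper(a); b <- toupper(b)
  swapped <- nchar(a) > nchar(b) ||
    (nchar(a) == nchar(b) && .cmp_str(a, b) > 0L)
  x <- if (swapped) b else a
  y <- if (swapped) a else b
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    x, y, type = "global", substitutionMatrix = mat,
    gapOpening = 1, gapExtension = 1)
  px <- as.character(Biostrings::alignedPattern(aln))
  py <- as.character(Biostrings::alignedSubject(aln))
  cx <- strsplit(px, "")[[1]]; cy <- strsplit(py, "")[[1]]
  matches <- sum(cx == cy & cx != "-")
  list(aligned_a = if (swapped) py else px,
       aligned_b = if (swapped) px else py,
       matches = matches,
       columns = length(cx), identity = matches / length(cx))
}

# locale-independent string comparison: -1, 0, or 1
.cmp_str <- function(a, b) {
  if (a == b) return(0L)
  if (identical(sort(c(a, b), method = "radix")[1L], a)) -1L else 1L
}

#' Percent identity of two sequences
#'
#' Convenience wrapper around [align_pair()] reporting identity as a percent
#' rounded to the nearest integer, the convention used when quoting tRNA
#' paralog similarity.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Numeric percent in `[0, 100]`.
#' @export
#' @examples
#' similarity("AAAA", "AATA")  # 75
similarity <- function(a, b) {
  round(100 * align_pair(a, b)$identity)
}

#' Paralog similarity report for an annotated genome
#'
#' Extracts both genes in their coding sense (minus-strand genes are
#' reverse-complemented, since isoacceptor paralogs typically sit on
#' opposite strands) and aligns them.
#'
#' @param genome A [mito_genome()].
#' @param pair Character vector of two annotated gene names
#'   (default `c("trnL1", "trnL2")`).
#' @return List with `identity` (percent), `alignment` (see [align_pair()])
#'   and `spans` (the two annotation rows used).
#' @export
paralog_report <- function(genome, pair = c("trnL1", "trnL2")) {
  stopifnot(length(pair) == 2L)
  idx <- match(pair, genome$annotations$name)
  if (anyNA(idx))
    stop("gene(s) not annotated: ", paste(pair[is.na(idx)], collapse = ", "))
  seqs <- vapply(pair, function(nm) gene_sequence(genome, nm), character(1))
  aln <- align_pair(seqs[[1L]], seqs[[2L]])
  list(identity = round(100 * aln$identity), alignment = aln,
       spans = genome$annotations[idx, ])
}
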