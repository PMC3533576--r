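# Concatenated protein-coding supermatrices for external phylogenetic tools.

#' Extract the 13 protein-coding gene sequences of a genome
#'
#' Circular-safe, coding-sense extraction (minus-strand genes are
#' reverse-complemented).
#'
#' @param genome A [mito_genome()] with all 13 PCGs annotated.
#' @return Named list of 13 nucleotide strings keyed by gene token.
#' @export
extract_pcgs <- function(genome) {
  missing <- setdiff(.MT_PCG, genome$annotations$name)
  if (length(missing))
    stop("protein-coding gene(s) not annotated: ",
         paste(missing, collapse = ", "))
  stats::setNames(lapply(.MT_PCG, function(nm) gene_sequence(genome, nm)),
                  .MT_PCG)
}

.aln_matrix <- function(aln) {
  stopifnot(is.character(aln), !is.null(names(aln)))
  w <- unique(nchar(aln))
  if (length(w) != 1L) stop("alignment rows have unequal lengths")
  do.call(rbind, strsplit(aln, ""))
}

#' Remove third codon positions from an alignment
#'
#' Drops every third column in frame; gap characters in kept columns are
#' preserved. A column count not divisible by 3 (after the frame offset) is
#' an error, never a silent truncation.
#'
#' @param aligned_gene Named character vector of equal-length gapped
#'   nucleotide sequences.
#' @param frame Offset (0, 1 or 2): number of leading columns before the
#'   first complete codon; these leading columns are kept.
#' @return Named character vector with 2/3 of the in-frame coding columns.
#' @export
#' @examples
#' drop_third_positions(c(a = "ATGATGATG"))  # "ATATAT"
drop_third_positions <- function(aligned_gene, frame = 0L) {
  stopifnot(frame %in% 0:2)
  m <- .aln_matrix(aligned_gene)
  ncol_cod <- ncol(m) - frame
  if (ncol_cod %% 3L != 0L)
    stop("alignment length ", ncol(m), " minus frame ", frame,
         " is not divisible by 3")
  keep <- c(seq_len(frame),
            frame + which(seq_len(ncol_cod) %% 3L != 0L))
  apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in alphabetical token order (recorded in the
#' partition table). All gene alignments must cover the same taxon set
#' unless `permissive = TRUE`, in which case missing taxa are padded with
#' gap-only rows.
#'
#' @param alignments Named list (gene -> named character vector of
#'   equal-length sequences per taxon).
#' @param taxa Optional taxon subset/ordering; defaults to the taxa shared
#'   by all genes (all taxa seen anywhere when `permissive`).
#' @param alphabet `"nt"` or `"aa"`, recorded on the result.
#' @param permissive Pad missing taxa with gaps instead of erroring.
#' @return Object of class `supermatrix`: `taxa`, `alphabet`, `seqs` (named
#'   gapped sequences) and `partitions` (gene, start, end; 1-based inclusive
#'   column ranges tiling the matrix).
#' @export
concatenate_alignments <- function(alignments, taxa = NULL,
                                   alphabet = c("nt", "aa"),
                                   permissive = FALSE) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  genes <- sort(names(alignments))
  taxa_sets <- lapply(alignments, names)
  if (is.null(taxa)) taxa <- sort(unique(unlist(taxa_sets)))
  if (!length(taxa)) stop("empty taxon set")
  if (!permissive) {
    for (g in genes)
      if (!all(taxa %in% taxa_sets[[g]]))
        stop("gene ", g, " is missing taxa: ",
             paste(setdiff(taxa, taxa_sets[[g]]), collapse = ", "),
             " (set permissive = TRUE to pad with gaps)")
  }
  seqs <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- data.frame(gene = genes, start = NA_integer_, end = NA_integer_)
  col <- 0L
  for (gi in seq_along(genes)) {
    aln <- alignments[[genes[gi]]]
    w <- unique(nchar(aln))
    if (length(w) != 1L)
      stop("alignment rows of ", genes[gi], " have unequal lengths")
    block <- vapply(taxa, function(tx)
      if (tx %in% names(aln)) aln[[tx]]
      else strrep("-", w), character(1))
    seqs <- paste0(seqs, block)
    parts$start[gi] <- col + 1L
    parts$end[gi] <- col + w
    col <- col + w
  }
  structure(list(taxa = taxa, alphabet = alphabet,
                 seqs = stats::setNames(seqs, taxa), partitions = parts),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$taxa), " taxa x ",
      nchar(x$seqs[[1L]]), " ", x$alphabet, " columns, ",
      nrow(x$partitions), " partitions\n", sep = "")
  invisible(x)
}

#' Translate coding sequences with the invertebrate mitochondrial code
#'
#' Incomplete final codons are dropped with a warning; fuzzy codons
#' translate to `X`.
#'
#' @param seqs Named character vector/list of in-frame nucleotide sequences.
#' @return Named character vector of amino-acid sequences.
#' @export
translate_mt <- function(seqs) {
  seqs <- vapply(seqs, identity, character(1))
  trimmed <- nchar(seqs) %/% 3L * 3L
  if (any(trimmed < nchar(seqs)))
    warning("dropping incomplete final codon(s) in: ",
            paste(names(seqs)[trimmed < nchar(seqs)], collapse = ", "))
  dna <- Biostrings::DNAStringSet(substr(seqs, 1L, trimmed))
  aa <- Biostrings::translate(dna, genetic.code = Biostrings::getGeneticCode("5"),
                              if.fuzzy.codon = "X")
  stats::setNames(as.character(aa), names(seqs))
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' @param sm A `supermatrix`.
#' @param path Output file path.
#' @export
write_phylip <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$taxa), nchar(sm$seqs[[1L]])), con)
  writeLines(sprintf("%s  %s", names(sm$seqs), sm$seqs), con)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' @param path PHYLIP file written by [write_phylip()] (relaxed sequential
#'   format, one taxon per line).
#' @param alphabet `"nt"` or `"aa"`.
#' @return A `supermatrix` with a single unnamed partition spanning all
#'   columns.
#' @export
read_phylip <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1]])
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  seqs <- stats::setNames(vapply(parts, `[`, character(1), 2L),
                          vapply(parts, `[`, character(1), 1L))
  if (length(seqs) != hdr[1L] || any(nchar(seqs) != hdr[2L]))
    stop("PHYLIP dimensions do not match the header")
  structure(list(taxa = names(seqs), alphabet = alphabet, seqs = seqs,
                 partitions = data.frame(gene = "all", start = 1L,
                                         end = hdr[2L])),
            class = "supermatrix")
}

#' Write a supermatrix as FASTA
#'
#' @param sm A `supermatrix`.
#' @param path Output file path.
#' @export
write_supermatrix_fasta <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  write_fasta(sm$seqs, path)
}

#' Write a RAxML-style partition file
#'
#' One line per gene: `DNA, cox1 = 1-1534` (or `LG,` style datatype for
#' amino acids).
#'
#' @param sm A `supermatrix`.
#' @param path Output file path.
#' @export
write_partitions <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  dt <- if (sm$alphabet == "nt") "DNA" else "MTART"
  writeLines(sprintf("%s, %s = %d-%d", dt, sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end), path)
  invisible(path)
}
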