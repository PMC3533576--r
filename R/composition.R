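# Per-genome composition statistics: A+T content by partition, strand split,
# overlaps, and the noncoding-region inventory.

#' A+T content of a nucleotide segment
#'
#' Case-insensitive count of A and T over the full segment length; ambiguity
#' codes and N count in the denominator only.
#'
#' @param segment Non-empty nucleotide string.
#' @return Fraction in `[0, 1]` (full precision; the conventional report
#'   rounds to one decimal percent).
#' @export
#' @examples
#' at_content("ATAT")   # 1
#' at_content("GCGC")   # 0
at_content <- function(segment) {
  stopifnot(is.character(segment), length(segment) == 1L)
  n <- nchar(segment)
  if (n == 0L) stop("empty segment")
  at <- nchar(gsub("[^ATat]", "", segment))
  at / n
}

# circular intersection length of two 0-based half-open spans
.circ_overlap <- function(s1, e1, s2, e2, L) {
  ov <- 0L
  for (d in c(-L, 0L, L))
    ov <- ov + max(0L, min(e1, e2 + d) - max(s1, s2 + d))
  min(ov, e1 - s1, e2 - s2, L)
}

#' Find overlapping gene pairs on the circle
#'
#' All pairs of annotations whose spans intersect (computed circularly),
#' whether on the same strand or not.
#'
#' @param genome A [mito_genome()].
#' @return Data frame with columns `gene1`, `gene2`, `shared` (nt); `gene1`
#'   is the upstream partner by start position. Zero rows if no overlap.
#' @export
find_overlaps <- function(genome) {
  ann <- genome$annotations
  L <- nchar(genome$sequence)
  out <- list()
  n <- nrow(ann)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ov <- .circ_overlap(ann$start[i], ann$end[i], ann$start[j], ann$end[j], L)
    if (ov > 0L)
      out[[length(out) + 1L]] <- data.frame(
        gene1 = ann$name[i], gene2 = ann$name[j], shared = ov,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      shared = integer(0)))
  do.call(rbind, out)
}

#' Inventory of noncoding regions
#'
#' Maximal circular intervals not covered by any gene annotation. Control
#' region annotations are treated as noncoding (the CR is the leftover of the
#' coding map), so the CR span merges with any abutting spacers into one
#' region. The longest region is labeled `control_region`, all others
#' `spacer`; a length tie is broken by higher A+T, then by clockwise
#' proximity to rrnS.
#'
#' @param genome A [mito_genome()].
#' @return Data frame with columns `start`, `end` (internal circular
#'   convention), `length`, `at_content`, `role`; zero rows for a fully
#'   covered genome.
#' @export
noncoding_inventory <- function(genome) {
  L <- nchar(genome$sequence)
  ann <- genome$annotations[genome$annotations$kind != "CR", , drop = FALSE]
  covered <- logical(L)
  for (i in seq_len(nrow(ann))) {
    pos <- (ann$start[i]:(ann$end[i] - 1L)) %% L
    covered[pos + 1L] <- TRUE
  }
  if (all(covered))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), at_content = numeric(0),
                      role = character(0)))
  # runs of uncovered positions, circularly
  free <- which(!covered) - 1L
  breaks <- which(diff(free) > 1L)
  starts <- free[c(1L, breaks + 1L)]
  ends <- free[c(breaks, length(free))] + 1L
  if (length(starts) > 1L && starts[1L] == 0L && ends[length(ends)] == L) {
    # first and last run wrap into one circular region
    starts[1L] <- starts[length(starts)]
    ends[1L] <- ends[1L] + L
    starts <- starts[-length(starts)]; ends <- ends[-length(ends)]
  }
  reg <- data.frame(start = starts, end = ends, length = ends - starts)
  reg$at_content <- vapply(seq_len(nrow(reg)), function(i)
    at_content(extract_segment(genome, reg$start[i], reg$end[i])),
    numeric(1))
  reg$role <- "spacer"
  cand <- which(reg$length == max(reg$length))
  if (length(cand) > 1L)
    cand <- cand[reg$at_content[cand] == max(reg$at_content[cand])]
  if (length(cand) > 1L) {
    ri <- match("rrnS", genome$annotations$name)
    if (!is.na(ri)) {
      rs <- genome$annotations$end[ri] %% L
      cand <- cand[which.min((reg$start[cand] - rs) %% L)]
    } else cand <- cand[1L]
  }
  reg$role[cand[1L]] <- "control_region"
  reg[order(reg$start), , drop = FALSE]
}

#' Assemble the per-genome composition report
#'
#' @param genome A [mito_genome()].
#' @return A list of class `composition_report`: `genome_length`,
#'   `at_overall`, `at_pcg`, `at_rrna`, `at_trna`, `at_cr` (fractions, full
#'   precision), `pcg_strand_split` (named counts on `+`/`-`), `overlaps`
#'   (data frame, see [find_overlaps()]), `noncoding_total` (nt), `regions`
#'   (data frame, see [noncoding_inventory()]) and `trna_length_range`.
#' @export
composition_report <- function(genome) {
  ann <- genome$annotations
  part_at <- function(kind) {
    idx <- which(ann$kind == kind)
    if (!length(idx)) return(NA_real_)
    segs <- vapply(idx, function(i)
      extract_segment(genome, ann$start[i], ann$end[i]), character(1))
    at_content(paste(segs, collapse = ""))
  }
  regions <- noncoding_inventory(genome)
  cr <- regions[regions$role == "control_region", , drop = FALSE]
  pcg <- ann[ann$kind == "PCG", , drop = FALSE]
  trna_len <- ann$end[ann$kind == "tRNA"] - ann$start[ann$kind == "tRNA"]
  structure(list(
    genome_length = nchar(genome$sequence),
    at_overall = at_content(genome$sequence),
    at_pcg = part_at("PCG"),
    at_rrna = part_at("rRNA"),
    at_trna = part_at("tRNA"),
    at_cr = if (nrow(cr)) cr$at_content[1L] else NA_real_,
    pcg_strand_split = c(`+` = sum(pcg$strand == "+"),
                         `-` = sum(pcg$strand == "-")),
    overlaps = find_overlaps(genome),
    noncoding_total = sum(regions$length),
    regions = regions,
    trna_length_range = if (length(trna_len)) range(trna_len)
                        else c(NA_integer_, NA_integer_)),
    class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  pct <- function(f) sprintf("%.1f%%", 100 * f)
  cat("<composition_report>\n",
      "  length: ", x$genome_length, " bp; A+T overall ", pct(x$at_overall),
      " (PCG ", pct(x$at_pcg), ", rRNA ", pct(x$at_rrna),
      ", tRNA ", pct(x$at_trna), ", CR ", pct(x$at_cr), ")\n",
      "  PCG strand split: ", x$pcg_strand_split[["+"]], " (+) / ",
      x$pcg_strand_split[["-"]], " (-)\n",
      "  overlaps: ", nrow(x$overlaps), "; noncoding: ",
      x$noncoding_total, " bp in ", nrow(x$regions), " region(s)\n",
      sep = "")
  invisible(x)
}
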