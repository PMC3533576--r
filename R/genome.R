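# MitoGenome container and flat-file I/O.
#
# Coordinates are 0-based half-open internally; a feature spanning the origin
# is stored with end > genome length and reduced modulo length on sequence
# extraction. GenBank 1-based inclusive coordinates are converted on
# read/write.

#' Construct an annotated mitochondrial genome
#'
#' @param id Identifier (free text).
#' @param sequence Circular nucleotide string (IUPAC alphabet).
#' @param annotations Data frame with columns `name` (canonical token),
#'   `start` (0-based inclusive), `end` (0-based exclusive, may exceed the
#'   sequence length to encode a span across the origin), `strand`
#'   (`"+"`/`"-"`, where `+` is the strand carrying cox1).
#' @param complete If `TRUE` (default), require all 38 canonical tokens
#'   exactly once; set `FALSE` for partial genomes.
#' @return An object of class `mito_genome` (the `kind` column is derived
#'   from `name`).
#' @export
mito_genome <- function(id, sequence, annotations, complete = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end", "strand") %in% names(ann)))
  ann$start <- as.integer(ann$start); ann$end <- as.integer(ann$end)
  bad <- setdiff(ann$name, .MT_GENES)
  if (length(bad))
    stop("annotations with non-canonical names: ", paste(bad, collapse = ", "))
  if (any(ann$start < 0L) || any(ann$start >= L) || any(ann$end <= ann$start))
    stop("invalid annotation coordinates (need 0 <= start < length < end ... start < end)")
  if (any(ann$end - ann$start > L))
    stop("annotation span longer than the genome")
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (complete) {
    if (anyDuplicated(ann$name))
      stop("duplicate annotations: ",
           paste(unique(ann$name[duplicated(ann$name)]), collapse = ", "))
    missing <- setdiff(.MT_GENES, ann$name)
    if (length(missing))
      stop("complete genome is missing: ", paste(missing, collapse = ", "))
  }
  ann$kind <- gene_kind(ann$name)
  ann <- ann[order(ann$start), c("name", "start", "end", "strand", "kind")]
  rownames(ann) <- NULL
  structure(list(id = id, sequence = sequence, annotations = ann),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$id, ": ", nchar(x$sequence), " bp (circular), ",
      nrow(x$annotations), " annotations\n", sep = "")
  invisible(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a (possibly origin-spanning) segment of a circular genome
#'
#' @param genome A [mito_genome()].
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; `end > length` wraps across the origin.
#' @param strand `"+"` returns the genome strand, `"-"` its reverse
#'   complement (the coding sense of a minus-strand gene).
#' @return Nucleotide string of length `end - start`.
#' @export
extract_segment <- function(genome, start, end, strand = "+") {
  L <- nchar(genome$sequence)
  stopifnot(start >= 0L, start < L, end > start, end - start <= L)
  seg <- if (end <= L) substr(genome$sequence, start + 1L, end)
         else paste0(substr(genome$sequence, start + 1L, L),
                     substr(genome$sequence, 1L, end - L))
  if (strand == "-") .revcomp(seg) else seg
}

#' Coding-sense sequence of one annotated gene
#'
#' @param genome A [mito_genome()].
#' @param name Canonical gene token.
#' @return Nucleotide string (reverse-complemented for minus-strand genes).
#' @export
gene_sequence <- function(genome, name) {
  i <- match(name, genome$annotations$name)
  if (is.na(i)) stop("gene not annotated: ", name)
  a <- genome$annotations[i, ]
  extract_segment(genome, a$start, a$end, a$strand)
}

#' Flip a genome to the opposite strand convention
#'
#' Reverse-complements the sequence and remaps every annotation, so that
#' records annotated with cox1 on the minus strand are normalized to the
#' package convention (`+` = cox1 strand).
#'
#' @param genome A [mito_genome()].
#' @return The flipped [mito_genome()].
#' @export
flip_genome <- function(genome) {
  L <- nchar(genome$sequence)
  ann <- genome$annotations
  len <- ann$end - ann$start
  new_start <- (L - ann$end) %% L
  ann$start <- new_start
  ann$end <- new_start + len
  ann$strand <- ifelse(ann$strand == "+", "-", "+")
  ann$strand[ann$name == "CR"] <- "+"
  mito_genome(genome$id, .revcomp(genome$sequence), ann,
              complete = !isTRUE(attr(genome, "partial")))
}

## ---- GenBank flat files ----------------------------------------------

.parse_gb_location <- function(loc, L) {
  loc <- gsub("[<> ]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  rng <- t(vapply(parts, function(p) {
    xs <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(xs) == 1L) xs <- c(xs, xs)
    xs
  }, integer(2)))
  dimnames(rng) <- NULL
  start <- rng[1L, 1L]; end <- rng[nrow(rng), 2L]
  if (nrow(rng) > 1L && rng[nrow(rng), 1L] < rng[1L, 1L])
    end <- end + L  # join() across the origin
  c(start = start - 1L, end = end, strand = if (strand == "-") -1L else 1L)
}

#' Read one annotated mitogenome from a GenBank flat file
#'
#' Parses LOCUS, the FEATURES table (gene/CDS/tRNA/rRNA/misc_feature/D-loop
#' keys, `complement()` and origin-spanning `join()` locations, gene /
#' product / note / anticodon qualifiers) and ORIGIN, converts coordinates to
#' the internal 0-based half-open circular convention, and maps feature
#' labels onto the canonical vocabulary via [canonical_name()]. Features that
#' cannot be mapped are attached as the `"unmapped"` attribute and reported
#' with a warning, never silently dropped. If cox1 is annotated on the minus
#' strand the whole record is flipped to the package strand convention.
#'
#' @param path GenBank flat file containing one circular DNA record.
#' @param relax If `TRUE`, tolerate missing genes and conflicting duplicate
#'   features (first wins) instead of erroring.
#' @return A [mito_genome()].
#' @export
read_genbank <- function(path, relax = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1L]))
    stop("not a GenBank flat file: ", path)
  locus <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1]]
  id <- locus[2L]
  L <- as.integer(locus[which(locus == "bp") - 1L])

  fstart <- grep("^FEATURES", lines)[1L]
  ostart <- grep("^ORIGIN", lines)[1L]
  if (is.na(fstart) || is.na(ostart)) stop("missing FEATURES or ORIGIN block")

  seq <- paste(gsub("[^A-Za-z]", "", lines[(ostart + 1L):length(lines)]),
               collapse = "")
  seq <- toupper(seq)
  if (is.na(L)) L <- nchar(seq)
  if (nchar(seq) != L)
    stop("ORIGIN length ", nchar(seq), " does not match LOCUS length ", L)

  # split the feature table into (key, location, qualifiers) records
  flines <- lines[(fstart + 1L):(ostart - 1L)]
  keyline <- grepl("^ {5}\\S", flines)
  feat <- list()
  cur <- NULL
  for (i in seq_along(flines)) {
    ln <- flines[i]
    if (keyline[i]) {
      if (!is.null(cur)) feat[[length(feat) + 1L]] <- cur
      parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      cur <- list(key = parts[1L], loc = paste(parts[-1L], collapse = ""),
                  quals = character(0))
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
      else if (length(cur$quals) == 0L) cur$loc <- paste0(cur$loc, txt)
      else cur$quals[length(cur$quals)] <-
             paste0(cur$quals[length(cur$quals)], txt)
    }
  }
  if (!is.null(cur)) feat[[length(feat) + 1L]] <- cur

  qual_val <- function(f, name) {
    hit <- grep(paste0("^/", name, "="), f$quals, value = TRUE)
    if (!length(hit)) return(NULL)
    gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1L]))
  }

  rows <- list(); unmapped <- list()
  for (f in feat) {
    if (f$key %in% c("source", "ORIGIN")) next
    lc <- .parse_gb_location(f$loc, L)
    anticodon <- qual_val(f, "anticodon")
    if (!is.null(anticodon))
      anticodon <- sub(".*seq:([A-Za-z]{3}).*", "\\1", anticodon)
    name <- NULL
    if (f$key == "D-loop") name <- "CR"
    else {
      for (q in c("gene", "product", "note")) {
        lab <- qual_val(f, q)
        if (is.null(lab)) next
        name <- tryCatch(canonical_name(lab, anticodon), error = function(e) NULL)
        if (!is.null(name)) break
      }
    }
    if (is.null(name)) {
      unmapped[[length(unmapped) + 1L]] <-
        data.frame(key = f$key, location = f$loc, stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, start = lc[["start"]], end = lc[["end"]],
      strand = if (lc[["strand"]] < 0L) "-" else "+", key = f$key,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no mappable features in ", path)
  ann <- do.call(rbind, rows)

  # collapse gene/CDS/tRNA duplicates of the same gene
  keep <- logical(nrow(ann))
  for (nm in unique(ann$name)) {
    idx <- which(ann$name == nm)
    if (length(idx) == 1L) { keep[idx] <- TRUE; next }
    spans <- unique(ann[idx, c("start", "end", "strand")])
    if (nrow(spans) == 1L) { keep[idx[1L]] <- TRUE; next }
    spec <- idx[ann$key[idx] != "gene"]
    if (length(spec) == 1L) { keep[spec] <- TRUE; next }
    if (!relax)
      stop("two features with conflicting spans both map to ", nm,
           " (use relax = TRUE to keep the first)")
    keep[idx[1L]] <- TRUE
  }
  ann <- ann[keep, c("name", "start", "end", "strand")]

  g <- mito_genome(id, seq, ann, complete = !relax)
  if (relax) attr(g, "partial") <- TRUE
  ci <- match("cox1", g$annotations$name)
  if (!is.na(ci) && g$annotations$strand[ci] == "-") g <- flip_genome(g)
  if (length(unmapped)) {
    attr(g, "unmapped") <- do.call(rbind, unmapped)
    warning(length(unmapped), " feature(s) could not be mapped to the ",
            "canonical vocabulary; see attr(, 'unmapped')")
  }
  g
}

#' Write a genome as a GenBank flat file
#'
#' Emits a minimal flat file (LOCUS / FEATURES / ORIGIN) that [read_genbank()]
#' round-trips exactly: PCGs as CDS, tRNA/rRNA as their feature keys, the
#' control region as D-loop, origin-spanning features as `join()` locations.
#'
#' @param genome A [mito_genome()].
#' @param path Output file path.
#' @export
write_genbank <- function(genome, path) {
  L <- nchar(genome$sequence)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular     %s",
                     genome$id, L, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.",
                     genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  fmt_feat <- function(key, loc) sprintf("     %-16s%s", key, loc)
  writeLines(fmt_feat("source", sprintf("1..%d", L)), con)
  for (i in seq_len(nrow(genome$annotations))) {
    a <- genome$annotations[i, ]
    loc <- if (a$end <= L) sprintf("%d..%d", a$start + 1L, a$end)
           else sprintf("join(%d..%d,1..%d)", a$start + 1L, L, a$end - L)
    if (a$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- switch(a$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop")
    writeLines(fmt_feat(key, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", a$name), con)
  }
  writeLines("ORIGIN", con)
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substr(genome$sequence, off, min(off + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    writeLines(substring(s, seq(1L, nchar(s), 70L),
                         pmin(seq(70L, nchar(s) + 69L, 70L), nchar(s))), con)
  }
  invisible(path)
}
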