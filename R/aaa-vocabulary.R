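# Canonical 38-token gene vocabulary shared by every module.

.pkg_env <- new.env(parent = emptyenv())

.MT_PCG  <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
              "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
.MT_TRNA <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
              "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
              "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
              "trnY")
.MT_RRNA <- c("rrnL", "rrnS")
.MT_GENES <- c(.MT_PCG, .MT_TRNA, .MT_RRNA, "CR")

.MT_KIND <- stats::setNames(
  c(rep("PCG", length(.MT_PCG)), rep("tRNA", length(.MT_TRNA)),
    rep("rRNA", length(.MT_RRNA)), "CR"),
  .MT_GENES)

# single-letter amino-acid code -> tRNA token (L and S need a subscript or an
# anticodon to disambiguate the two isoacceptors)
.TRNA_LETTER <- c(A = "trnA", C = "trnC", D = "trnD", E = "trnE", F = "trnF",
                  G = "trnG", H = "trnH", I = "trnI", K = "trnK", M = "trnM",
                  N = "trnN", P = "trnP", Q = "trnQ", R = "trnR", T = "trnT",
                  V = "trnV", W = "trnW", Y = "trnY")

#' Canonical mitochondrial gene vocabulary
#'
#' The closed vocabulary of 38 tokens every mitorder gene order is written
#' over: the 13 protein-coding genes, 22 tRNA genes, 2 rRNA genes and the
#' control region (`CR`). `trnL1`/`trnL2` are tRNA-Leu(CUN)/tRNA-Leu(UUR) and
#' `trnS1`/`trnS2` are tRNA-Ser(AGN)/tRNA-Ser(UCN).
#'
#' @return Character vector of the 38 canonical tokens.
#' @export
#' @examples
#' mt_vocabulary()
mt_vocabulary <- function() .MT_GENES

#' Functional class of a canonical gene token
#'
#' @param name Character vector of canonical tokens.
#' @return Character vector over `"PCG"`, `"tRNA"`, `"rRNA"`, `"CR"`.
#' @export
#' @examples
#' gene_kind(c("cox1", "trnL1", "rrnS", "CR"))
gene_kind <- function(name) {
  bad <- setdiff(name, .MT_GENES)
  if (length(bad))
    stop("not canonical gene tokens: ", paste(bad, collapse = ", "))
  unname(.MT_KIND[name])
}

.norm_label <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.synonym_table <- function() {
  if (is.null(.pkg_env$synonyms)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "mitorder")
    if (path == "")  # during in-source testing before installation
      path <- file.path("inst", "extdata", "gene_synonyms.tsv")
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    .pkg_env$synonyms <- stats::setNames(tab$gene, .norm_label(tab$label))
  }
  .pkg_env$synonyms
}

# anticodon -> isoacceptor subscript for the two Leu / two Ser tRNAs
.resolve_anticodon <- function(base, anticodon) {
  ac <- chartr("u", "t", tolower(anticodon))
  if (base == "L") {
    if (ac == "tag") return("trnL1")   # decodes CUN codons
    if (ac == "taa") return("trnL2")   # decodes UUR codons
  } else if (base == "S") {
    if (ac %in% c("tct", "gct")) return("trnS1")  # AGN
    if (ac == "tga") return("trnS2")              # UCN
  }
  stop("cannot resolve tRNA-", base, " from anticodon '", anticodon, "'")
}

#' Map a raw annotation label to a canonical gene token
#'
#' Deterministic mapping from the many spellings found in GenBank records and
#' figure legends ("COI", "ND4L", "tRNA-Leu(CUN)", "16S ribosomal RNA",
#' "D-loop", "L1", ...) to the canonical vocabulary, driven by the synonym
#' table shipped in `extdata/gene_synonyms.tsv`. A bare "tRNA-Leu" or
#' "tRNA-Ser" is disambiguated by its anticodon (UAG -> trnL1, UAA -> trnL2,
#' UCU/GCU -> trnS1, UGA -> trnS2).
#'
#' @param raw_label Free-text label (gene/product/note qualifier, figure code).
#' @param anticodon Optional 3-mer (DNA or RNA alphabet) used only when the
#'   label alone cannot separate the Leu or Ser isoacceptors.
#' @return A single canonical token (see [mt_vocabulary()]).
#' @export
#' @examples
#' canonical_name("ND4L")
#' canonical_name("tRNA-Leu", anticodon = "UAG")
canonical_name <- function(raw_label, anticodon = NULL) {
  stopifnot(is.character(raw_label), length(raw_label) == 1L)
  raw <- trimws(raw_label)
  if (raw == "") stop("empty gene label")

  hit <- match(tolower(raw), tolower(.MT_GENES))
  if (!is.na(hit)) return(.MT_GENES[hit])          # idempotence on tokens

  # figure-legend single-letter codes (case-sensitive: one uppercase letter,
  # optionally subscripted 1/2 for the Leu/Ser pairs)
  if (grepl("^[A-Z][12]?$", raw)) {
    if (raw %in% c("L1", "L2", "S1", "S2")) return(paste0("trn", raw))
    letter <- substr(raw, 1, 1)
    if (letter %in% names(.TRNA_LETTER)) return(unname(.TRNA_LETTER[letter]))
    if (letter %in% c("L", "S")) {
      if (is.null(anticodon))
        stop("bare tRNA-", letter, " label '", raw,
             "' needs an anticodon to disambiguate")
      return(.resolve_anticodon(letter, anticodon))
    }
  }

  key <- .norm_label(raw)
  tab <- .synonym_table()
  if (!is.na(tab[key])) {
    tok <- unname(tab[key])
    if (tok %in% c("AMBIG_LEU", "AMBIG_SER")) {
      base <- if (tok == "AMBIG_LEU") "L" else "S"
      if (is.null(anticodon))
        stop("bare tRNA-", if (base == "L") "Leu" else "Ser",
             " label '", raw, "' needs an anticodon to disambiguate")
      return(.resolve_anticodon(base, anticodon))
    }
    return(tok)
  }
  stop("cannot map gene label '", raw_label, "' to the canonical vocabulary")
}
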