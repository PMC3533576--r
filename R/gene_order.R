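# Signed circular gene orders and their comparison.
#
# Internally an order is a pair of parallel vectors (gene, sign) read
# clockwise around the circle. Equality is invariant under rotation and under
# full reversal-with-sign-flip (the same molecule read from the other
# strand). The control region is strandless and keeps sign +1 under reversal.

#' Construct a signed circular gene order
#'
#' @param genes Character vector of canonical tokens (see [mt_vocabulary()]),
#'   no duplicates, read clockwise around the circle.
#' @param signs Integer/numeric vector of +1/-1 per gene (`CR` must be +1), or
#'   a character vector over `"+"`/`"-"`.
#' @return An object of class `gene_order`.
#' @export
#' @examples
#' gene_order(c("cox1", "trnL2", "cox2"), c(1, 1, -1))
gene_order <- function(genes, signs = rep(1L, length(genes))) {
  if (is.character(signs)) signs <- ifelse(signs == "-", -1L, 1L)
  signs <- as.integer(signs)
  stopifnot(length(genes) == length(signs), all(signs %in% c(-1L, 1L)))
  bad <- setdiff(genes, .MT_GENES)
  if (length(bad))
    stop("unknown gene tokens: ", paste(bad, collapse = ", "))
  if (anyDuplicated(genes))
    stop("duplicate genes in order: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  signs[genes == "CR"] <- 1L  # CR is strandless by convention
  structure(list(genes = genes, signs = signs), class = "gene_order")
}

#' @export
length.gene_order <- function(x) length(x$genes)

#' @export
format.gene_order <- function(x, ...) {
  paste(ifelse(x$genes == "CR", "CR",
               paste0(ifelse(x$signs < 0, "-", "+"), x$genes)),
        collapse = " ")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order> ", length(x), " genes (circular)\n  ",
      format(x), "\n", sep = "")
  invisible(x)
}

#' Parse a string of signed tokens into a gene order
#'
#' @param text Space-separated signed tokens, e.g. `"+cox1 +trnL2 ... -trnY"`.
#'   An unsigned token is taken as `+`.
#' @return A [gene_order()].
#' @export
parse_gene_order <- function(text) {
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks <- toks[toks != ""]
  sign <- ifelse(substr(toks, 1, 1) == "-", -1L, 1L)
  gene <- sub("^[+-]", "", toks)
  gene_order(gene, sign)
}

## ---- integer encoding -------------------------------------------------
## signed token t = 2 * gene_id + (sign < 0); CR always carries bit 0.
## Reading the circle from the other strand reverses the element sequence and
## toggles the bit of every token except CR.

.CR_TOK <- 2L * match("CR", .MT_GENES)

.ord_tok <- function(order) {
  2L * match(order$genes, .MT_GENES) + (order$signs < 0L)
}

.tok_flip <- function(t) ifelse(t == .CR_TOK, t, bitwXor(t, 1L))

.tok_to_order <- function(t) {
  gene_order(.MT_GENES[t %/% 2L], ifelse(t %% 2L == 1L, -1L, 1L))
}

# canonical integer code of the (unordered, strand-symmetric) adjacency u -> v
.adj_code <- function(u, v) {
  pmin(u * 256L + v, .tok_flip(v) * 256L + .tok_flip(u))
}

.gap_codes <- function(t) {
  n <- length(t)
  .adj_code(t, t[c(seq_len(n)[-1L], 1L)])
}

# is b (int tokens) a rotation of a, or of a's reversal-with-flip?
.tok_equal <- function(a, b) {
  n <- length(a)
  if (length(b) != n) return(FALSE)
  if (n == 0L) return(TRUE)
  for (cand in list(b, .tok_flip(rev(b)))) {
    for (j in which(cand == a[1L])) {
      idx <- ((j - 1L + seq_len(n) - 1L) %% n) + 1L
      if (all(cand[idx] == a)) return(TRUE)
    }
  }
  FALSE
}

# deterministic canonical key (lexicographically smallest rotation over both
# strand readings); used for visited-set hashing in the scenario search
.tok_canonical <- function(t) {
  n <- length(t)
  best <- NULL
  for (cand in list(t, .tok_flip(rev(t)))) {
    for (j in seq_len(n)) {
      rot <- cand[((j - 1L + seq_len(n) - 1L) %% n) + 1L]
      if (is.null(best)) best <- rot
      else {
        cmp <- which(rot != best)
        if (length(cmp) && rot[cmp[1L]] < best[cmp[1L]]) best <- rot
      }
    }
  }
  best
}

## ---- public operations ------------------------------------------------

#' Rotate a gene order into its canonical form
#'
#' Rotates so that `cox1` comes first; if `cox1` is on the minus strand the
#' whole circle is first read from the other strand (reversal with sign
#' flips), so that canonical forms can be compared literally.
#'
#' @param order A [gene_order()] containing `cox1`.
#' @return A [gene_order()] in canonical rotation.
#' @export
canonicalize <- function(order) {
  stopifnot(inherits(order, "gene_order"))
  i <- match("cox1", order$genes)
  if (is.na(i)) stop("cannot canonicalize: cox1 absent from order")
  g <- order$genes; s <- order$signs
  if (s[i] < 0L) {
    g <- rev(g); s <- -rev(s); s[g == "CR"] <- 1L
    i <- match("cox1", g)
  }
  n <- length(g)
  idx <- ((i - 1L + seq_len(n) - 1L) %% n) + 1L
  gene_order(g[idx], s[idx])
}

#' Test two signed circular gene orders for equality
#'
#' Equality is invariant under rotation and under reading the circle from the
#' opposite strand.
#'
#' @param a,b [gene_order()] objects.
#' @return Logical scalar.
#' @export
orders_equal <- function(a, b) {
  stopifnot(inherits(a, "gene_order"), inherits(b, "gene_order"))
  .tok_equal(.ord_tok(a), .ord_tok(b))
}

.check_same_genes <- function(a, b) {
  if (!setequal(a$genes, b$genes) || length(a) != length(b))
    stop("orders are over different gene sets")
}

#' Breakpoint distance between two signed circular gene orders
#'
#' Counts the adjacencies of `order` absent from `reference`, where an
#' adjacency `(a, b)` is matched orientation-symmetrically by `(-b, -a)`.
#'
#' @param order,reference [gene_order()] objects over the same gene set.
#' @return Integer count in `[0, n]`.
#' @export
breakpoint_distance <- function(order, reference) {
  .check_same_genes(order, reference)
  codes <- .gap_codes(.ord_tok(order))
  ref <- .gap_codes(.ord_tok(reference))
  sum(!(codes %in% ref))
}

# gene ids incident to a broken adjacency in either order of a reduced pair
.bp_incident_ids <- function(ta, tb) {
  n <- length(ta)
  nxt <- c(seq_len(n)[-1L], 1L)
  ga <- .gap_codes(ta); gb <- .gap_codes(tb)
  bp_a <- !(ga %in% gb)
  bp_b <- !(gb %in% ga)
  unique(c(ta[bp_a], ta[nxt][bp_a], tb[bp_b], tb[nxt][bp_b]) %/% 2L)
}

#' Minimum displaced-gene set between two circular signed orders
#'
#' The smallest set of genes whose deletion (with their signs) from both
#' orders leaves identical circular signed orders — the formalization of
#' "rearranged genes". Found exactly by iterative deepening on the set
#' size: at each partial deletion the search branches only over genes
#' incident to a broken adjacency of the current reduced pair (any valid
#' completion must delete one of them, so the restriction is exact).
#' Branching follows alphabetical gene order with the control region ranked
#' last (it marks a position on the circle rather than a gene), which makes
#' the returned set deterministic and prefers all-gene deletion sets when
#' several minima resolve the same junctions.
#'
#' @param order,reference [gene_order()] objects over the same gene set.
#' @param max_size Search cap on the set size (default 10); exceeding it is
#'   an error, never a silent truncation.
#' @return Character vector of gene names (empty if the orders are already
#'   equal).
#' @export
#' @examples
#' displaced_genes(fixture_order("gebiidea"), fixture_order("ground_pattern"))
displaced_genes <- function(order, reference, max_size = 10L) {
  .check_same_genes(order, reference)
  ta <- .ord_tok(order); tb <- .ord_tok(reference)
  if (.tok_equal(ta, tb)) return(character(0))

  rank_ids <- function(ids) {
    nm <- .MT_GENES[ids]
    ids[base::order(nm == "CR", nm, method = "radix")]
  }

  for (k in seq_len(max_size)) {
    visited <- new.env(parent = emptyenv())
    dfs <- function(del_ids, ra, rb) {
      if (.tok_equal(ra, rb)) return(del_ids)
      if (length(del_ids) == k) return(NULL)
      key <- paste0("s", paste(sort(del_ids), collapse = ","))
      if (!is.null(visited[[key]])) return(NULL)
      visited[[key]] <- TRUE
      for (g in rank_ids(.bp_incident_ids(ra, rb))) {
        if (g %in% del_ids) next
        hit <- dfs(c(del_ids, g), ra[ra %/% 2L != g], rb[rb %/% 2L != g])
        if (!is.null(hit)) return(hit)
      }
      NULL
    }
    hit <- dfs(integer(0), ta, tb)
    if (!is.null(hit)) return(.MT_GENES[sort(hit)])
  }
  stop("no deletion set of size <= ", max_size, " found")
}

#' Compare a gene order against a reference
#'
#' @param order,reference [gene_order()] objects over the same gene set.
#' @param max_size Passed to [displaced_genes()].
#' @return A list with `displaced` (character vector), `breakpoints` and
#'   `shared_adjacencies` (integers summing to the number of genes).
#' @export
compare_orders <- function(order, reference, max_size = 10L) {
  bp <- breakpoint_distance(order, reference)
  list(displaced = if (bp == 0L) character(0)
                   else displaced_genes(order, reference, max_size),
       breakpoints = bp,
       shared_adjacencies = length(order) - bp)
}

## ---- fixtures ---------------------------------------------------------

.FIXTURES <- list(
  ground_pattern = paste(
    "+cox1 +trnL2 +cox2 +trnK +trnD +atp8 +atp6 +cox3 +trnG +nad3 +trnA",
    "+trnR +trnN +trnS1 +trnE -trnF -nad5 -trnH -nad4 -nad4L +trnT -trnP",
    "+nad6 +cob +trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR +trnI -trnQ +trnM",
    "+nad2 +trnW -trnC -trnY"),
  gebiidea = paste(
    "+cox1 +trnL2 +trnL1 +cox2 +trnK +trnD +atp8 +atp6 +cox3 +trnG +nad3",
    "+trnA +trnR +trnN +trnS1 +trnE -trnF -nad5 -trnH -nad4 -nad4L +trnT",
    "-trnP +nad6 +cob +trnS2 +trnI -nad1 -rrnL -trnV -rrnS -trnQ CR -trnC",
    "-trnY +trnM +nad2 +trnW"),
  axiidea = paste(
    "+cox1 +trnL1 +trnL2 +cox2 +trnK +atp8 +atp6 +trnG +trnV +nad3 +cox3",
    "+trnA +trnR +trnN +trnS1 +trnE -trnF -nad5 -trnH -nad4 -nad4L +trnT",
    "-trnP +nad6 +cob +trnS2 -nad1 -rrnL -rrnS -trnI CR -trnQ +trnD +trnM",
    "+nad2 +trnW -trnC -trnY"))

#' Built-in gene-order fixtures
#'
#' The pancrustacean ground pattern and the two derived mud-shrimp orders,
#' frozen as signed circular constants of all 38 tokens.
#'
#' `"thalassina"` returns the ground pattern (the *T. kelanang* arrangement is
#' identical to it). `"gebiidea"` is the *A. edulis* / *U. major* order;
#' `"axiidea"` the *N. glyptocercus* / *N. thermophilus* order. In the axiidea
#' fixture trnL1 sits between cox1 and trnL2 (the published sentence labels
#' the downstream Leu gene "L1", read here as a slip for L2), and the segment
#' upstream of trnM is frozen as `-trnQ +trnD +trnM`; the relocated gebiidea
#' trnQ keeps its ancestral minus strand.
#'
#' @param key One of `"ground_pattern"`, `"gebiidea"`, `"axiidea"`,
#'   `"thalassina"`.
#' @return A [gene_order()] of 38 elements.
#' @export
#' @examples
#' fixture_order("ground_pattern")
fixture_order <- function(key = c("ground_pattern", "gebiidea", "axiidea",
                                  "thalassina")) {
  key <- match.arg(key)
  if (key == "thalassina") key <- "ground_pattern"
  parse_gene_order(.FIXTURES[[key]])
}

## ---- text format ------------------------------------------------------

#' Read gene orders from the plain-text format
#'
#' One genome per line: `identifier TAB space-separated signed tokens`;
#' `#` comment lines and blank lines are skipped.
#'
#' @param path File path.
#' @return Named list of [gene_order()] objects.
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("malformed gene-order line (need identifier TAB tokens): ", ln)
    out[[parts[1L]]] <- parse_gene_order(paste(parts[-1L], collapse = " "))
  }
  out
}

#' Write gene orders in the plain-text format
#'
#' @param orders Named list of [gene_order()] objects.
#' @param path File path.
#' @export
write_gene_orders <- function(orders, path) {
  stopifnot(is.list(orders), !is.null(names(orders)))
  writeLines(vapply(names(orders), function(id)
    paste0(id, "\t", format(orders[[id]])), character(1)), path)
  invisible(path)
}

#' Extract the signed gene order of an annotated genome
#'
#' Annotations are sorted by circular start position, signs are taken from
#' strands, and the result is canonicalized (cox1 first, plus strand).
#'
#' @param genome A [mito_genome()].
#' @return A [gene_order()].
#' @export
extract_order <- function(genome) {
  ann <- genome$annotations
  if (anyDuplicated(ann$name))
    stop("duplicate gene annotations: ",
         paste(unique(ann$name[duplicated(ann$name)]), collapse = ", "))
  ann <- ann[order(ann$start), , drop = FALSE]
  canonicalize(gene_order(ann$name, ifelse(ann$strand == "-", -1L, 1L)))
}
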