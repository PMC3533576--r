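# Mechanistic rearrangement events applicable to a gene order.
#
# Events are named by the genes they act on (not by positions), so the same
# event object is valid on any rotation of the order. Blocks are contiguous
# runs of genes read clockwise; the insertion target of a move is the
# adjacency immediately following a named gene (after block excision).

.new_event <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "mito_event")
}

#' Rearrangement event constructors
#'
#' * `ev_transposition(block, after)`: excise the contiguous `block` and
#'   reinsert it immediately after gene `after`.
#' * `ev_inversion(block)`: reverse the block in place, flipping every sign
#'   (the strandless `CR` keeps `+`).
#' * `ev_reverse_transposition(block, after)`: move plus inversion.
#' * `ev_tdrl(region, loss)`: tandem duplication of `region` followed by loss
#'   of one copy of each gene; `loss[i]` in `{1, 2}` is the copy in which
#'   gene `region[i]` survives. The region is replaced by the copy-1
#'   survivors (original relative order) followed by the copy-2 survivors.
#' * `ev_remold(donor, recipient, side)`: duplication / anticodon mutation /
#'   non-random loss — the recipient tRNA is deleted at its old position and
#'   a recipient-named copy is inserted `side` ("after"/"before") the donor
#'   with the donor's sign. Restricted to the (trnL1, trnL2) and
#'   (trnS1, trnS2) isoacceptor pairs.
#'
#' @param block,region Character vector of gene names forming a contiguous
#'   clockwise run in the order the event is applied to.
#' @param after Gene name (not in the block) after which the block is
#'   reinserted.
#' @param loss Integer vector over `{1, 2}`, one per region gene.
#' @param donor,recipient tRNA gene names from one isoacceptor pair.
#' @param side `"after"` (default) or `"before"` the donor.
#' @return A `mito_event` object.
#' @name events
#' @export
#' @examples
#' apply_event(fixture_order("ground_pattern"), ev_inversion("trnV"))
ev_transposition <- function(block, after) {
  stopifnot(is.character(block), length(block) >= 1L,
            is.character(after), length(after) == 1L, !(after %in% block))
  .new_event("transposition", block = block, after = after)
}

#' @rdname events
#' @export
ev_inversion <- function(block) {
  stopifnot(is.character(block), length(block) >= 1L)
  .new_event("inversion", block = block)
}

#' @rdname events
#' @export
ev_reverse_transposition <- function(block, after) {
  stopifnot(is.character(block), length(block) >= 1L,
            is.character(after), length(after) == 1L, !(after %in% block))
  .new_event("reverse_transposition", block = block, after = after)
}

#' @rdname events
#' @export
ev_tdrl <- function(region, loss) {
  stopifnot(is.character(region), length(region) >= 2L,
            length(loss) == length(region), all(loss %in% c(1L, 2L)))
  .new_event("tdrl", block = region, loss = as.integer(loss))
}

.REMOLD_PAIRS <- list(c("trnL1", "trnL2"), c("trnS1", "trnS2"))

#' @rdname events
#' @export
ev_remold <- function(donor, recipient, side = c("after", "before")) {
  side <- match.arg(side)
  ok <- any(vapply(.REMOLD_PAIRS, function(p)
    setequal(p, c(donor, recipient)), logical(1)))
  if (!ok || donor == recipient)
    stop("paralog remolding is restricted to the trnL1/trnL2 and ",
         "trnS1/trnS2 pairs")
  .new_event("paralog_remold", donor = donor, recipient = recipient,
             side = side)
}

#' @export
format.mito_event <- function(x, ...) {
  switch(x$kind,
    transposition = sprintf("transposition [%s] -> after %s",
                            paste(x$block, collapse = " "), x$after),
    inversion = sprintf("inversion [%s]", paste(x$block, collapse = " ")),
    reverse_transposition = sprintf("reverse_transposition [%s] -> after %s",
                                    paste(x$block, collapse = " "), x$after),
    tdrl = sprintf("tdrl [%s] keep copies (%s)",
                   paste(x$block, collapse = " "),
                   paste(x$loss, collapse = " ")),
    paralog_remold = sprintf("paralog_remold %s -> %s (%s donor)",
                             x$donor, x$recipient, x$side))
}

#' @export
print.mito_event <- function(x, ...) {
  cat("<mito_event> ", format(x), "\n", sep = "")
  invisible(x)
}

# locate `block` as a contiguous clockwise run; returns the start position
.find_block <- function(genes, block) {
  n <- length(genes)
  p <- match(block[1L], genes)
  if (is.na(p)) stop("block gene absent from order: ", block[1L])
  idx <- ((p - 1L + seq_along(block) - 1L) %% n) + 1L
  if (!identical(genes[idx], block))
    stop("block is not contiguous in the order: ",
         paste(block, collapse = " "))
  p
}

# rotate vectors so that positions [p .. p+len-1] are non-wrapping, then
# return a list(g, s, at) with the block at the front
.rotate_to <- function(g, s, p) {
  n <- length(g)
  idx <- ((p - 1L + seq_len(n) - 1L) %% n) + 1L
  list(g = g[idx], s = s[idx])
}

#' Apply a rearrangement event to a gene order
#'
#' Deterministic edited order; the result always satisfies the gene-order
#' invariants (same gene set, no duplicates, `CR` on `+`) and is rotated so
#' that the gene previously listed first stays first.
#'
#' @param order A [gene_order()].
#' @param event A `mito_event` (see [ev_transposition()] and friends).
#' @return The edited [gene_order()].
#' @export
apply_event <- function(order, event) {
  out <- .apply_event_raw(order, event)
  p <- match(order$genes[1L], out$genes)
  n <- length(out$genes)
  idx <- ((p - 1L + seq_len(n) - 1L) %% n) + 1L
  gene_order(out$genes[idx], out$signs[idx])
}

.apply_event_raw <- function(order, event) {
  stopifnot(inherits(order, "gene_order"), inherits(event, "mito_event"))
  g <- order$genes; s <- order$signs; n <- length(g)

  if (event$kind == "paralog_remold") {
    di <- match(event$donor, g); ri <- match(event$recipient, g)
    if (is.na(di) || is.na(ri))
      stop("remold needs both paralogs present in the order")
    keep <- seq_len(n)[-ri]
    g2 <- g[keep]; s2 <- s[keep]
    di2 <- match(event$donor, g2)
    at <- if (event$side == "after") di2 else di2 - 1L
    g2 <- append(g2, event$recipient, after = at)
    s2 <- append(s2, s[di], after = at)
    return(gene_order(g2, s2))
  }

  p <- .find_block(g, event$block)
  len <- length(event$block)
  if (len >= n) stop("block covers the whole circle")
  rot <- .rotate_to(g, s, p)
  g <- rot$g; s <- rot$s        # block now occupies positions 1..len
  bg <- g[seq_len(len)]; bs <- s[seq_len(len)]

  if (event$kind == "inversion") {
    bs <- -rev(bs); bg <- rev(bg)
    bs[bg == "CR"] <- 1L
    return(gene_order(c(bg, g[-seq_len(len)]), c(bs, s[-seq_len(len)])))
  }

  if (event$kind == "tdrl") {
    ord <- c(which(event$loss == 1L), which(event$loss == 2L))
    return(gene_order(c(bg[ord], g[-seq_len(len)]),
                      c(bs[ord], s[-seq_len(len)])))
  }

  # moves
  rg <- g[-seq_len(len)]; rs <- s[-seq_len(len)]
  ai <- match(event$after, rg)
  if (is.na(ai)) stop("insertion target absent from order: ", event$after)
  if (event$kind == "reverse_transposition") {
    bg <- rev(bg); bs <- -rev(bs); bs[bg == "CR"] <- 1L
  }
  gene_order(append(rg, bg, after = ai),
             append(rs, bs, after = ai))
}

#' Apply a sequence of events
#'
#' @param order Source [gene_order()].
#' @param events List of `mito_event` objects.
#' @return List with `order` (the final order) and `intermediates` (a list of
#'   the order after each event).
#' @export
apply_events <- function(order, events) {
  inter <- vector("list", length(events))
  cur <- order
  for (i in seq_along(events)) {
    cur <- apply_event(cur, events[[i]])
    inter[[i]] <- cur
  }
  list(order = cur, intermediates = inter)
}
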