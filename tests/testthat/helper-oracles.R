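# Independent brute-force oracles used to certify the fast implementations.
# These deliberately use naive string/position bookkeeping, not the package's
# integer encodings.

# signed-token strings of an order, e.g. "+cox1" "-trnY" ("CR" unsigned)
.o_toks <- function(ord) {
  ifelse(ord$genes == "CR", "CR",
         paste0(ifelse(ord$signs < 0, "-", "+"), ord$genes))
}

.o_flip <- function(tok) {
  ifelse(tok == "CR", tok,
         paste0(ifelse(substr(tok, 1, 1) == "+", "-", "+"),
                substring(tok, 2)))
}

# equality of signed circular orders by doubled-string search
oracle_equal <- function(a_toks, b_toks) {
  if (length(a_toks) != length(b_toks)) return(FALSE)
  if (length(a_toks) == 0) return(TRUE)
  hay <- paste(c(b_toks, b_toks), collapse = " ")
  rev_b <- rev(.o_flip(b_toks))
  hay2 <- paste(c(rev_b, rev_b), collapse = " ")
  needle <- paste(a_toks, collapse = " ")
  grepl(needle, hay, fixed = TRUE) || grepl(needle, hay2, fixed = TRUE)
}

# adjacency list of an order as "x y" strings (both orientations)
.o_adjacencies <- function(toks) {
  n <- length(toks)
  nxt <- c(seq_len(n)[-1], 1)
  paste(toks, toks[nxt])
}

# breakpoints of `ord` w.r.t. `ref` by scanning both orientations of ref
oracle_breakpoints <- function(ord, ref) {
  ta <- .o_toks(ord); tb <- .o_toks(ref)
  adj_a <- .o_adjacencies(ta)
  adj_b <- .o_adjacencies(tb)
  n <- length(tb)
  nxt <- c(seq_len(n)[-1], 1)
  adj_b_rev <- paste(.o_flip(tb[nxt]), .o_flip(tb))
  sum(!(adj_a %in% c(adj_b, adj_b_rev)))
}

# minimum deletion set by full subset enumeration over ALL genes
oracle_displaced <- function(ord, ref, max_size = length(ord)) {
  ta <- .o_toks(ord); tb <- .o_toks(ref)
  ga <- ord$genes; gb <- ref$genes
  if (oracle_equal(ta, tb)) return(character(0))
  genes <- sort(ga)
  for (k in seq_len(min(max_size, length(genes) - 1))) {
    for (S in utils::combn(genes, k, simplify = FALSE)) {
      if (oracle_equal(ta[!(ga %in% S)], tb[!(gb %in% S)])) return(S)
    }
  }
  stop("oracle found no deletion set of size <= ", max_size)
}

# random signed circular order over n canonical tokens (cox1 always included
# so canonicalize() is applicable)
rand_order <- function(n) {
  genes <- c("cox1", sample(setdiff(mt_vocabulary(), "cox1"), n - 1))
  genes <- sample(genes)
  gene_order(genes, sample(c(-1L, 1L), n, replace = TRUE))
}

# every unit move/inversion applicable to an order (naive enumeration)
.o_all_events <- function(ord) {
  g <- ord$genes; n <- length(g)
  evs <- list()
  for (p in seq_len(n)) for (len in seq_len(n - 2)) {
    block <- g[((p - 1 + seq_len(len) - 1) %% n) + 1]
    evs[[length(evs) + 1]] <- ev_inversion(block)
    for (after in setdiff(g, block)) {
      evs[[length(evs) + 1]] <- ev_transposition(block, after)
      evs[[length(evs) + 1]] <- ev_reverse_transposition(block, after)
    }
  }
  evs
}

.o_canon_str <- function(ord) {
  toks <- .o_toks(ord)
  n <- length(toks)
  best <- NULL
  for (cand in list(toks, rev(.o_flip(toks)))) {
    for (j in seq_len(n)) {
      s <- paste(cand[((j - 1 + seq_len(n) - 1) %% n) + 1], collapse = " ")
      if (is.null(best) || s < best) best <- s
    }
  }
  best
}

# minimum number of unit events (move/inversion vocabulary) by breadth-first
# enumeration with duplicate-state elimination; NA if beyond max_depth
oracle_min_events <- function(source, target, max_depth) {
  tgt <- .o_canon_str(target)
  frontier <- list(source)
  seen <- .o_canon_str(source)
  if (seen == tgt) return(0L)
  for (d in seq_len(max_depth)) {
    nxt <- list()
    for (ord in frontier) {
      for (ev in .o_all_events(ord)) {
        child <- apply_event(ord, ev)
        key <- .o_canon_str(child)
        if (key == tgt) return(d)
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          nxt[[length(nxt) + 1]] <- child
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  NA_integer_
}

# per-position membership overlap oracle for circular annotations
oracle_overlap <- function(s1, e1, s2, e2, L) {
  p1 <- (s1:(e1 - 1)) %% L
  p2 <- (s2:(e2 - 1)) %% L
  length(intersect(p1, p2))
}
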