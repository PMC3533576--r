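# Rearrangement scenarios: construction, the paper-narrative fixtures, and
# exact minimum-length scenario inference by iterative-deepening search.

#' Construct a rearrangement scenario
#'
#' Folds `events` over `source`, records every intermediate order, and
#' verifies that the fold reproduces `target` (when given).
#'
#' @param source Source [gene_order()].
#' @param events List of `mito_event` objects.
#' @param target Optional target [gene_order()]; defaults to the fold result.
#' @return An object of class `mito_scenario` with fields `source`, `events`,
#'   `intermediates`, `target`.
#' @export
scenario <- function(source, events, target = NULL) {
  stopifnot(inherits(source, "gene_order"))
  res <- apply_events(source, events)
  if (!is.null(target)) {
    stopifnot(inherits(target, "gene_order"))
    if (!orders_equal(res$order, target))
      stop("event fold does not reproduce the target order")
  } else target <- res$order
  structure(list(source = source, events = events,
                 intermediates = res$intermediates, target = target),
            class = "mito_scenario")
}

#' @export
length.mito_scenario <- function(x) length(x$events)

#' @export
print.mito_scenario <- function(x, ...) {
  cat("<mito_scenario> ", length(x$events), " event(s), ",
      max(grouped_steps(x), 0L), " grouped step(s)\n", sep = "")
  for (i in seq_along(x$events))
    cat(sprintf("  %d. %s\n", i, format(x$events[[i]])))
  invisible(x)
}

#' Grouped mechanistic phases of a scenario
#'
#' Heuristic view matching how rearrangement narratives count "steps":
#' consecutive transposition / reverse-transposition events whose blocks
#' consist only of tRNA genes are merged into one phase (simultaneous tRNA
#' shuffling around one junction); every other event opens a new phase. This
#' is a labeling heuristic, not part of the event algebra.
#'
#' @param scn A `mito_scenario`.
#' @return Integer vector of phase labels, one per event (empty for the
#'   empty scenario); `max()` of it is the grouped step count.
#' @export
grouped_steps <- function(scn) {
  stopifnot(inherits(scn, "mito_scenario"))
  ev <- scn$events
  if (!length(ev)) return(integer(0))
  trna_move <- vapply(ev, function(e)
    e$kind %in% c("transposition", "reverse_transposition") &&
      all(gene_kind(e$block) == "tRNA"), logical(1))
  ph <- integer(length(ev)); ph[1L] <- 1L
  for (i in seq_along(ev)[-1L])
    ph[i] <- if (trna_move[i] && trna_move[i - 1L]) ph[i - 1L]
             else ph[i - 1L] + 1L
  ph
}

#' The two published rearrangement scenarios
#'
#' Hard-coded regression fixtures for the mechanistic narratives leading from
#' the pancrustacean ground pattern to the two derived mud-shrimp orders.
#'
#' Gebiidea (3 phases): transpositions of trnI and of the trnC+trnY block;
#' a tandem-duplication/random-loss event relocating trnQ past the control
#' region; remolding of trnL1 from a duplicated trnL2. Axiidea (4 phases):
#' reverse transposition of trnI; a duplication/random-loss event moving cox3
#' past trnG and nad3; transposition of trnD and reverse transposition of
#' trnV; remolding of trnL1. Each phase is expanded into its unit events and
#' each scenario's fold reproduces the corresponding fixture order.
#'
#' @return Named list of two `mito_scenario` objects (`gebiidea`, `axiidea`).
#' @export
#' @examples
#' sc <- paper_scenarios()
#' max(grouped_steps(sc$gebiidea))  # 3
paper_scenarios <- function() {
  gp <- fixture_order("ground_pattern")
  geb <- scenario(gp, list(
    ev_transposition("trnI", after = "trnS2"),
    ev_transposition(c("trnC", "trnY"), after = "trnQ"),
    ev_tdrl(c("CR", "trnQ"), loss = c(2L, 1L)),
    ev_remold(donor = "trnL2", recipient = "trnL1", side = "after")),
    target = fixture_order("gebiidea"))
  axi <- scenario(gp, list(
    ev_reverse_transposition("trnI", after = "rrnS"),
    ev_tdrl(c("cox3", "trnG", "nad3"), loss = c(2L, 1L, 1L)),
    ev_transposition("trnD", after = "trnQ"),
    ev_reverse_transposition("trnV", after = "trnG"),
    ev_remold(donor = "trnL2", recipient = "trnL1", side = "before")),
    target = fixture_order("axiidea"))
  list(gebiidea = geb, axiidea = axi)
}

## ---- minimum-scenario search ------------------------------------------

# positional applications on integer token vectors (block never wraps after
# the caller rotates it to the front)
.tok_rotate <- function(t, p) {
  n <- length(t)
  t[((p - 1L + seq_len(n) - 1L) %% n) + 1L]
}

# block = circular positions (i+1 .. j); i == j is invalid
.tok_block_idx <- function(n, i, j) {
  size <- (j - i) %% n
  ((i + seq_len(size) - 1L) %% n) + 1L
}

.tok_move <- function(t, i, j, k, invert = FALSE) {
  n <- length(t)
  idx <- .tok_block_idx(n, i, j)
  block <- t[idx]
  if (invert) block <- .tok_flip(rev(block))
  rest <- t[-idx]
  # k indexes a gap of the original vector; find the element t[k] in rest
  pos <- match(t[k], rest)
  append(rest, block, after = pos)
}

.tok_invert <- function(t, i, j) {
  idx <- .tok_block_idx(length(t), i, j)
  t[idx] <- .tok_flip(rev(t[idx]))
  t
}

.tok_remold <- function(t, donor_id, recipient_id, side) {
  di <- which(t %/% 2L == donor_id)
  ri <- which(t %/% 2L == recipient_id)
  newtok <- 2L * recipient_id + t[di] %% 2L
  t2 <- t[-ri]
  di2 <- which(t2 %/% 2L == donor_id)
  append(t2, newtok, after = if (side == "after") di2 else di2 - 1L)
}

.VOCAB_DEFAULT <- c("transposition", "inversion", "reverse_transposition",
                    "paralog_remold")

# all (block, target) gap triples of an n-circle: ordered gap pair (I, J)
# delimits the circular block (I+1 .. J); K ranges over the gaps strictly
# outside. Memoized per n.
.move_triples <- function(n) {
  key <- paste0("triples", n)
  if (is.null(.pkg_env[[key]])) {
    g <- expand.grid(K = seq_len(n), J = seq_len(n), I = seq_len(n),
                     KEEP.OUT.ATTRS = FALSE)
    size <- (g$J - g$I) %% n
    m <- (g$K - g$J) %% n
    ok <- size >= 1L & size <= n - 2L & m >= 1L & m <= (n - size - 1L)
    .pkg_env[[key]] <- list(I = g$I[ok], J = g$J[ok], K = g$K[ok])
  }
  .pkg_env[[key]]
}

.gap_pairs <- function(n) {
  key <- paste0("pairs", n)
  if (is.null(.pkg_env[[key]])) {
    g <- expand.grid(J = seq_len(n), I = seq_len(n), KEEP.OUT.ATTRS = FALSE)
    ok <- g$I != g$J
    .pkg_env[[key]] <- list(I = g$I[ok], J = g$J[ok])
  }
  .pkg_env[[key]]
}

#' Infer minimum-length rearrangement scenarios
#'
#' Exact search for the shortest event sequences transforming `source` into
#' `target`, by iterative-deepening depth-first search over event
#' applications with the admissible lower bound `ceiling(breakpoints / 3)`
#' (no default-vocabulary event changes more than 3 adjacencies; with `tdrl`
#' enabled the divisor grows to the region cap + 1). At tight budgets only
#' moves cutting at breakpoint adjacencies can qualify and only those are
#' enumerated; at slack budgets the full move space is enumerated under a
#' node cap. Enumeration order is fixed (event kind, block start, target), so
#' results are deterministic.
#'
#' @param source,target [gene_order()] objects over the same gene set.
#' @param vocabulary Event kinds to search over; default excludes `tdrl`.
#' @param max_events Depth cap; an empty list is returned if no scenario of
#'   at most this many events exists.
#' @param max_scenarios Reporting cap on the number of minimum-length
#'   scenarios returned (default 10).
#' @param tdrl_cap Maximum tdrl region size when `"tdrl"` is in the
#'   vocabulary.
#' @param node_cap Guard on search-tree expansions; exceeding it is an error
#'   naming the cap.
#' @return List of `mito_scenario` objects, all of the same (minimal)
#'   length; empty if none exists within `max_events`. The attribute
#'   `"complete"` is `FALSE` when the list was truncated at `max_scenarios`.
#' @export
#' @examples
#' toy <- parse_gene_order("+cox1 +trnA +trnC +trnD +trnE")
#' tgt <- parse_gene_order("+cox1 +trnC +trnA +trnD +trnE")
#' length(infer_scenario(toy, tgt, max_events = 2)[[1]])  # 1
infer_scenario <- function(source, target,
                           vocabulary = .VOCAB_DEFAULT,
                           max_events = 6L, max_scenarios = 10L,
                           tdrl_cap = 6L, node_cap = 500000L) {
  stopifnot(inherits(source, "gene_order"), inherits(target, "gene_order"),
            max_events >= 0L)
  .check_same_genes(source, target)
  bad <- setdiff(vocabulary, c(.VOCAB_DEFAULT, "tdrl"))
  if (length(bad)) stop("unknown event kinds: ", paste(bad, collapse = ", "))

  t0 <- .ord_tok(source)
  ref <- sort(unique(.gap_codes(.ord_tok(target))))
  n <- length(t0)
  maxchange <- if ("tdrl" %in% vocabulary) max(3L, tdrl_cap + 1L) else 3L
  bp0 <- sum(!(.gap_codes(t0) %in% ref))
  if (bp0 == 0L)
    return(structure(list(scenario(source, list(), target)), complete = TRUE))

  remold_ids <- if ("paralog_remold" %in% vocabulary) {
    ids <- lapply(.REMOLD_PAIRS, match, .MT_GENES)
    ids[vapply(ids, function(p) all(p %in% (t0 %/% 2L)), logical(1))]
  } else list()

  env <- new.env(parent = emptyenv())
  env$nodes <- 0L

  # enumerate + score all qualifying child states of token vector `t`;
  # returns them in deterministic order as a list of (event, child) pairs
  children <- function(t, remaining) {
    gaps <- .gap_codes(t)
    isbp <- !(gaps %in% ref)
    bp <- sum(isbp)
    budget <- maxchange * (remaining - 1L)
    d_min <- bp - budget                # required breakpoint reduction
    nxt <- c(seq_len(n)[-1L], 1L)
    out <- list()

    # ordered gap pairs (i, j) delimit the circular block (i+1 .. j), so
    # wrapping blocks are enumerated too; targets k are the gaps strictly
    # outside the block
    add_move <- function(kind, invert) {
      g3 <- .move_triples(n)
      I <- g3$I; J <- g3$J; K <- g3$K
      if (d_min >= 1L) {
        ok <- (isbp[I] + isbp[J] + isbp[K]) >= d_min
        I <- I[ok]; J <- J[ok]; K <- K[ok]
      }
      if (!length(I)) return()
      first <- t[nxt[I]]; last <- t[J]
      c1 <- .adj_code(t[I], t[nxt[J]])
      if (!invert) {
        c2 <- .adj_code(t[K], first); c3 <- .adj_code(last, t[nxt[K]])
      } else {
        c2 <- .adj_code(t[K], .tok_flip(last))
        c3 <- .adj_code(.tok_flip(first), t[nxt[K]])
      }
      newbp <- (!(c1 %in% ref)) + (!(c2 %in% ref)) + (!(c3 %in% ref))
      bp2 <- bp - (isbp[I] + isbp[J] + isbp[K]) + newbp
      ok <- bp2 <= budget
      I <- I[ok]; J <- J[ok]; K <- K[ok]
      o <- order(I, J, K)
      for (q in o) {
        blk <- .MT_GENES[t[.tok_block_idx(n, I[q], J[q])] %/% 2L]
        after <- .MT_GENES[t[K[q]] %/% 2L]
        ev <- if (invert) ev_reverse_transposition(blk, after = after)
              else ev_transposition(blk, after = after)
        out[[length(out) + 1L]] <<-
          list(ev = ev, child = .tok_move(t, I[q], J[q], K[q], invert))
      }
    }

    add_inversions <- function() {
      if (d_min > 2L) return()
      pr <- .gap_pairs(n)
      pi <- pr$I; pj <- pr$J
      if (d_min >= 1L) {
        ok <- (isbp[pi] + isbp[pj]) >= d_min
        pi <- pi[ok]; pj <- pj[ok]
      }
      if (!length(pi)) return()
      c1 <- .adj_code(t[pi], .tok_flip(t[pj]))
      c2 <- .adj_code(.tok_flip(t[nxt[pi]]), t[nxt[pj]])
      bp2 <- bp - (isbp[pi] + isbp[pj]) + (!(c1 %in% ref)) + (!(c2 %in% ref))
      ok <- bp2 <= budget
      pi <- pi[ok]; pj <- pj[ok]
      o <- order(pi, pj)
      for (q in o) {
        ev <- ev_inversion(.MT_GENES[t[.tok_block_idx(n, pi[q], pj[q])] %/% 2L])
        out[[length(out) + 1L]] <<-
          list(ev = ev, child = .tok_invert(t, pi[q], pj[q]))
      }
    }

    add_remolds <- function() {
      for (pair in remold_ids) for (d in 1:2) for (side in c("after", "before")) {
        donor <- pair[d]; recip <- pair[3L - d]
        child <- .tok_remold(t, donor, recip, side)
        bp2 <- sum(!(.gap_codes(child) %in% ref))
        if (bp2 <= budget)
          out[[length(out) + 1L]] <<- list(
            ev = ev_remold(.MT_GENES[donor], .MT_GENES[recip], side),
            child = child)
      }
    }

    add_tdrl <- function() {
      for (size in 2L:min(tdrl_cap, n - 2L)) {
        assigns <- as.matrix(expand.grid(rep(list(1:2), size)))
        assigns <- assigns[rowSums(assigns == 1L) %in% seq_len(size - 1L), ,
                           drop = FALSE]
        for (p in seq_len(n)) {
          tr <- .tok_rotate(t, p)
          for (a in seq_len(nrow(assigns))) {
            loss <- assigns[a, ]
            ord2 <- c(which(loss == 1L), which(loss == 2L))
            if (identical(ord2, seq_len(size))) next
            child <- c(tr[seq_len(size)][ord2], tr[-seq_len(size)])
            bp2 <- sum(!(.gap_codes(child) %in% ref))
            if (bp2 <= budget)
              out[[length(out) + 1L]] <<- list(
                ev = ev_tdrl(.MT_GENES[tr[seq_len(size)] %/% 2L],
                             loss = as.integer(loss)),
                child = child)
          }
        }
      }
    }

    for (kind in sort(intersect(vocabulary,
                                c("inversion", "paralog_remold",
                                  "reverse_transposition", "tdrl",
                                  "transposition")))) {
      switch(kind,
             inversion = add_inversions(),
             paralog_remold = add_remolds(),
             reverse_transposition = add_move(kind, invert = TRUE),
             tdrl = add_tdrl(),
             transposition = add_move(kind, invert = FALSE))
    }
    out
  }

  results <- list()
  truncated <- FALSE
  dfs <- function(t, remaining, path) {
    if (length(results) >= max_scenarios) { truncated <<- TRUE; return() }
    bp <- sum(!(.gap_codes(t) %in% ref))
    if (bp == 0L) { results[[length(results) + 1L]] <<- path; return() }
    if (remaining == 0L || ceiling(bp / maxchange) > remaining) return()
    key <- paste(.tok_canonical(t), collapse = ",")
    seen <- env$visited[[key]]
    if (!is.null(seen) && seen >= remaining) return()
    env$visited[[key]] <- remaining
    env$nodes <- env$nodes + 1L
    if (env$nodes > node_cap)
      stop("scenario search exceeded the node cap (", node_cap, ")")
    for (ch in children(t, remaining)) {
      dfs(ch$child, remaining - 1L, c(path, list(ch$ev)))
      if (length(results) >= max_scenarios) return()
    }
  }

  lb <- ceiling(bp0 / maxchange)
  for (depth in seq.int(lb, length.out = max(0L, max_events - lb + 1L))) {
    env$visited <- new.env(parent = emptyenv())
    results <- list()
    truncated <- FALSE
    dfs(t0, depth, list())
    if (length(results)) {
      scns <- lapply(results, function(ev) scenario(source, ev, target))
      return(structure(scns, complete = !truncated))
    }
  }
  structure(list(), complete = TRUE)
}
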