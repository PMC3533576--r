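# Event algebra and minimum-scenario inference.

test_that("apply_event implements the documented edit semantics", {
  gp <- fixture_order("ground_pattern")
  # single-gene inversion flips the sign in place
  inv <- apply_event(gp, ev_inversion("trnV"))
  expect_equal(inv$signs[inv$genes == "trnV"], 1L)  # was -1 in gp
  i <- match("trnV", inv$genes)
  expect_equal(inv$genes[c(i - 1, i + 1)],
               gp$genes[c(i - 1, i + 1)])
  # transposition of trnD into the (-trnQ, +trnM) adjacency
  moved <- apply_event(gp, ev_transposition("trnD", after = "trnQ"))
  j <- match("trnD", moved$genes)
  expect_equal(moved$genes[j + 1], "trnM")
  expect_equal(moved$genes[j - 1], "trnQ")
  expect_equal(moved$signs[j], 1L)
  # remold: new trnL1 adjacent to trnL2 with the donor's sign, old copy gone
  rem <- apply_event(gp, ev_remold("trnL2", "trnL1", side = "after"))
  k <- match("trnL2", rem$genes)
  expect_equal(rem$genes[k + 1], "trnL1")
  expect_equal(rem$signs[k + 1], 1L)
  expect_equal(sum(rem$genes == "trnL1"), 1)
  expect_equal(rem$genes[match("nad1", rem$genes) + 1], "rrnL")
})

test_that("tdrl keeps copy-1 survivors before copy-2 survivors", {
  ord <- parse_gene_order("+cox1 +trnA +trnC +trnD +trnE +cox2")
  # duplicate [A C D], keep A and D in copy 1, C in copy 2 -> A D C
  out <- apply_event(ord, ev_tdrl(c("trnA", "trnC", "trnD"), c(1, 2, 1)))
  expect_equal(out$genes, c("cox1", "trnA", "trnD", "trnC", "trnE", "cox2"))
  # signs ride along unchanged
  ord2 <- parse_gene_order("+cox1 -trnA +trnC -trnD +trnE")
  out2 <- apply_event(ord2, ev_tdrl(c("trnA", "trnC", "trnD"), c(2, 1, 1)))
  expect_equal(format(out2), "+cox1 +trnC -trnD -trnA +trnE")
})

test_that("events reject malformed applications", {
  gp <- fixture_order("ground_pattern")
  expect_error(apply_event(gp, ev_transposition(c("trnD", "cox3"), "trnM")),
               "not contiguous")
  expect_error(ev_transposition("trnD", "trnD"))
  expect_error(ev_remold("trnL1", "trnS1"), "restricted")
  expect_error(apply_event(
    parse_gene_order("+cox1 +trnA"),
    ev_remold("trnL2", "trnL1")), "both paralogs")
})

test_that("random events preserve the gene-order invariants", {
  set.seed(77)
  for (rr in 1:40) {
    ord <- rand_order(sample(6:12, 1))
    cfg <- sim_config(seed = rr)
    ev <- mitorder:::.sample_event(ord, cfg)
    if (ev$kind == "paralog_remold" &&
        !all(c(ev$donor, ev$recipient) %in% ord$genes)) next
    out <- apply_event(ord, ev)
    expect_setequal(out$genes, ord$genes)
    expect_false(anyDuplicated(out$genes) > 0)
    expect_true(all(out$signs %in% c(-1L, 1L)))
    expect_true(all(out$signs[out$genes == "CR"] == 1L))
  }
})

test_that("identical source and target yield one empty scenario", {
  gp <- fixture_order("ground_pattern")
  res <- infer_scenario(gp, gp, max_events = 3)
  expect_length(res, 1)
  expect_length(res[[1]]$events, 0)
})

test_that("a one-transposition toy is solved in one event", {
  src <- parse_gene_order("+cox1 +trnA +trnC +trnD +trnE")
  tgt <- parse_gene_order("+cox1 +trnC +trnA +trnD +trnE")
  res <- infer_scenario(src, tgt, max_events = 3)
  expect_gt(length(res), 0)
  for (scn in res) {
    expect_length(scn$events, 1)
    expect_true(orders_equal(scn$intermediates[[1]], tgt))
  }
})

test_that("search minima match brute-force enumeration on small toys", {
  set.seed(19)
  for (rr in 1:6) {
    n <- sample(5:6, 1)
    src <- rand_order(n)
    k <- sample(1:2, 1)
    cur <- src
    cfg <- sim_config(seed = 100 + rr,
                      event_mix = c(transposition = 0.5, inversion = 0.25,
                                    reverse_transposition = 0.25,
                                    tdrl = 0, paralog_remold = 0))
    for (i in seq_len(k)) cur <- apply_event(cur, mitorder:::.sample_event(cur, cfg))
    truth_min <- oracle_min_events(src, cur, max_depth = 2)
    res <- infer_scenario(src, cur, max_events = 2,
                          vocabulary = c("transposition", "inversion",
                                         "reverse_transposition"))
    if (is.na(truth_min)) {
      expect_length(res, 0)
    } else {
      expect_gt(length(res), 0)
      expect_equal(length(res[[1]]$events), truth_min)
    }
  }
})

test_that("returned scenarios are sound and of equal minimal length", {
  gp <- fixture_order("ground_pattern")
  geb <- fixture_order("gebiidea")
  res <- infer_scenario(gp, geb, max_events = 5)
  expect_gt(length(res), 0)
  lens <- vapply(res, function(s) length(s$events), integer(1))
  expect_true(all(lens == lens[1]))
  for (scn in res) {
    fold <- apply_events(gp, scn$events)$order
    expect_true(orders_equal(fold, geb))
  }
})

test_that("depth limits below the minimum return an empty list", {
  gp <- fixture_order("ground_pattern")
  geb <- fixture_order("gebiidea")
  expect_length(infer_scenario(gp, geb, max_events = 3), 0)
})

test_that("paper scenarios fold onto the fixtures with 3 and 4 phases", {
  sc <- paper_scenarios()
  expect_true(orders_equal(apply_events(sc$gebiidea$source,
                                        sc$gebiidea$events)$order,
                           fixture_order("gebiidea")))
  expect_true(orders_equal(apply_events(sc$axiidea$source,
                                        sc$axiidea$events)$order,
                           fixture_order("axiidea")))
  expect_equal(max(grouped_steps(sc$gebiidea)), 3)
  expect_equal(max(grouped_steps(sc$axiidea)), 4)
  expect_length(sc$gebiidea$events, 4)
  expect_length(sc$axiidea$events, 5)
})

test_that("tdrl vocabulary can replace a transposition", {
  src <- parse_gene_order("+cox1 +trnA +trnC +trnD +trnE")
  tgt <- parse_gene_order("+cox1 +trnC +trnD +trnA +trnE")
  res <- infer_scenario(src, tgt, vocabulary = "tdrl", max_events = 2,
                        tdrl_cap = 3)
  expect_gt(length(res), 0)
  expect_length(res[[1]]$events, 1)
  expect_equal(res[[1]]$events[[1]]$kind, "tdrl")
})
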