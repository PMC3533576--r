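# Synthetic mitogenomes and rearrangement histories with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes: a
# mitogenome-scale circular molecule carrying the 37 canonical genes plus one control
# region, AT-biased i.i.d. sequence, typical per-kind gene lengths, small
# spacers, two forced 7-nt overlaps, and derived orders produced by sampled
# event histories.

#' Simulation configuration
#'
#' Defaults describe a typical decapod-like mitogenome: A+T target 0.70,
#' tRNAs 61-73 nt, PCGs 160-1800 nt, rRNAs 700-1400 nt, control region
#' 91-1200 nt, intergenic spacers of a few nucleotides, and the canonical
#' 7-nt atp8/atp6 and nad4L/nad4 reading-frame overlaps. Event histories
#' move small blocks (1-3 genes) and duplicate short tandem regions (2-3
#' genes); a remolded paralog is a copy of its donor carrying
#' `remold_mutations` point mutations.
#'
#' @param seed Integer seed driving the single pseudo-random stream.
#' @param at_target Genome-wide A+T fraction.
#' @param pcg_length,trna_length,rrna_length,cr_length Per-kind length
#'   sampling ranges (nt).
#' @param spacer_range Intergenic spacer length range (nt).
#' @param overlap_spec Data frame `gene1`, `gene2`, `shared`: forced
#'   overlaps applied when the two genes are adjacent in the layout.
#' @param n_events Number of rearrangement events for [simulate_history()].
#' @param event_mix Named sampling probabilities over event kinds (must sum
#'   to 1).
#' @param block_range Moved/inverted block size range (genes).
#' @param tdrl_region_range Duplicated region size range (genes).
#' @param remold_mutations Point mutations applied to a remolded paralog.
#' @param rotate_origin If `TRUE`, rotate the finished genome to a random
#'   origin so one annotation may span the sequence start.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       at_target = 0.70,
                       pcg_length = c(160L, 1800L),
                       trna_length = c(61L, 73L),
                       rrna_length = c(700L, 1400L),
                       cr_length = c(91L, 1200L),
                       spacer_range = c(0L, 10L),
                       overlap_spec = data.frame(
                         gene1 = c("atp8", "nad4L"),
                         gene2 = c("atp6", "nad4"),
                         shared = c(7L, 7L)),
                       n_events = 0L,
                       event_mix = c(transposition = 0.5,
                                     inversion = 0.15,
                                     reverse_transposition = 0.15,
                                     tdrl = 0.1,
                                     paralog_remold = 0.1),
                       block_range = c(1L, 3L),
                       tdrl_region_range = c(2L, 3L),
                       remold_mutations = 5L,
                       rotate_origin = FALSE) {
  ok_range <- function(r) length(r) == 2L && r[1L] <= r[2L] && r[1L] >= 0L
  stopifnot(at_target > 0, at_target < 1,
            abs(sum(event_mix) - 1) < 1e-8,
            ok_range(pcg_length), ok_range(trna_length),
            ok_range(rrna_length), ok_range(cr_length),
            ok_range(spacer_range), ok_range(block_range),
            ok_range(tdrl_region_range),
            n_events >= 0L, remold_mutations >= 0L)
  structure(list(seed = as.integer(seed), at_target = at_target,
                 pcg_length = pcg_length, trna_length = trna_length,
                 rrna_length = rrna_length, cr_length = cr_length,
                 spacer_range = spacer_range, overlap_spec = overlap_spec,
                 n_events = as.integer(n_events), event_mix = event_mix,
                 block_range = block_range,
                 tdrl_region_range = tdrl_region_range,
                 remold_mutations = as.integer(remold_mutations),
                 rotate_origin = isTRUE(rotate_origin)),
            class = "sim_config")
}

.sample_seq <- function(n, at) {
  if (n == 0L) return("")
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

.sample_gene_lengths <- function(cfg, genes) {
  rng <- list(PCG = cfg$pcg_length, tRNA = cfg$trna_length,
              rRNA = cfg$rrna_length, CR = cfg$cr_length)
  vapply(genes, function(g) {
    r <- rng[[gene_kind(g)]]
    as.integer(sample(r[1L]:r[2L], 1L))
  }, integer(1))
}

.mutate_seq <- function(seq, m) {
  if (m == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), min(m, length(chars)))
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

# lay a genome out along `order` from per-gene coding sequences
.realize_genome <- function(id, order, coding, cfg) {
  order <- canonicalize(order)
  g <- order$genes; s <- order$signs; n <- length(g)
  segs <- ifelse(s > 0L, unlist(coding[g]),
                 vapply(coding[g], .revcomp, character(1)))
  forced <- function(a, b) {
    os <- cfg$overlap_spec
    hit <- (os$gene1 == a & os$gene2 == b) | (os$gene1 == b & os$gene2 == a)
    if (any(hit)) os$shared[which(hit)[1L]] else 0L
  }
  seq_parts <- character(0)
  ann <- data.frame(name = g, start = NA_integer_, end = NA_integer_,
                    strand = ifelse(s > 0L, "+", "-"))
  cursor <- 0L
  for (i in seq_len(n)) {
    ov <- if (i > 1L) forced(g[i - 1L], g[i]) else 0L
    if (ov > 0L) {
      if (ov >= nchar(segs[i]) || ov >= nchar(segs[i - 1L]))
        stop("infeasible overlap_spec: ", ov, " nt between ",
             g[i - 1L], " and ", g[i])
      ann$start[i] <- cursor - ov
      seq_parts <- c(seq_parts, substr(segs[i], ov + 1L, nchar(segs[i])))
      cursor <- cursor + nchar(segs[i]) - ov
    } else {
      sp <- sample(cfg$spacer_range[1L]:cfg$spacer_range[2L], 1L)
      seq_parts <- c(seq_parts, .sample_seq(sp, cfg$at_target))
      cursor <- cursor + sp
      ann$start[i] <- cursor
      seq_parts <- c(seq_parts, segs[i])
      cursor <- cursor + nchar(segs[i])
    }
    ann$end[i] <- cursor
  }
  # spacer closing the circle between the last and the first gene
  sp <- sample(cfg$spacer_range[1L]:cfg$spacer_range[2L], 1L)
  seq_parts <- c(seq_parts, .sample_seq(sp, cfg$at_target))
  sequence <- paste(seq_parts, collapse = "")
  L <- nchar(sequence)
  if (cfg$rotate_origin) {
    shift <- sample(0:(L - 1L), 1L)
    if (shift > 0L) {
      len <- ann$end - ann$start
      sequence <- paste0(substr(sequence, shift + 1L, L),
                         substr(sequence, 1L, shift))
      ann$start <- (ann$start - shift) %% L
      ann$end <- ann$start + len
    }
  }
  mito_genome(id, sequence, ann)
}

#' Simulate an annotated mitogenome with known ground truth
#'
#' Builds a circular genome laid out along `order` (ground pattern by
#' default): per-kind gene lengths, i.i.d. AT-biased sequence
#' (P(A) = P(T) = at_target/2), forced overlaps sharing terminal
#' nucleotides, the control region as the largest noncoding region, small
#' spacers elsewhere. Fully reproducible from the configured seed.
#'
#' @param config A [sim_config()].
#' @param order Layout [gene_order()]; default [fixture_order("ground_pattern")].
#' @param id Genome identifier.
#' @return A list of class `sim_truth`: `genome` ([mito_genome()]), `order`
#'   (canonical), `history` (empty), `gene_seqs` (coding-sense truth,
#'   extracted from the realized genome) and `config`.
#' @export
#' @examples
#' truth <- simulate_genome(sim_config(seed = 1))
#' composition_report(truth$genome)$genome_length
simulate_genome <- function(config = sim_config(), order = NULL,
                            id = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(order)) order <- fixture_order("ground_pattern")
  .simulate_from_stream(config, order, id, history = list())
}

# shared tail of simulate_genome()/simulate_history(): assumes the RNG
# stream is already positioned
.simulate_from_stream <- function(config, order, id, history,
                                  remolds = list()) {
  lens <- .sample_gene_lengths(config, order$genes)
  coding <- stats::setNames(lapply(lens, .sample_seq, at = config$at_target),
                            order$genes)
  for (rm in remolds)
    coding[[rm$recipient]] <-
      .mutate_seq(coding[[rm$donor]], config$remold_mutations)
  genome <- .realize_genome(id, order, coding, config)
  truth <- stats::setNames(
    lapply(genome$annotations$name, function(nm) gene_sequence(genome, nm)),
    genome$annotations$name)
  structure(list(genome = genome, order = canonicalize(order),
                 history = history, gene_seqs = truth, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", x$genome$id, ": ", nchar(x$genome$sequence),
      " bp, ", length(x$history), " event(s) in history\n", sep = "")
  invisible(x)
}

.sample_event <- function(order, cfg) {
  g <- order$genes; n <- length(g)
  kind <- sample(names(cfg$event_mix), 1L, prob = cfg$event_mix)
  circ_block <- function(len) {
    p <- sample(n, 1L)
    g[((p - 1L + seq_len(len) - 1L) %% n) + 1L]
  }
  if (kind == "paralog_remold") {
    pair <- .REMOLD_PAIRS[[sample(length(.REMOLD_PAIRS), 1L)]]
    d <- sample(2L, 1L)
    return(ev_remold(pair[d], pair[3L - d],
                     side = sample(c("after", "before"), 1L)))
  }
  if (kind == "tdrl") {
    size <- sample(cfg$tdrl_region_range[1L]:cfg$tdrl_region_range[2L], 1L)
    region <- circ_block(size)
    repeat {
      loss <- sample(1:2, size, replace = TRUE)
      if (length(unique(loss)) > 1L) break
    }
    return(ev_tdrl(region, loss))
  }
  len <- sample(cfg$block_range[1L]:cfg$block_range[2L], 1L)
  len <- min(len, n - 2L)
  block <- circ_block(len)
  if (kind == "inversion") return(ev_inversion(block))
  after <- sample(setdiff(g, block), 1L)
  if (kind == "transposition") ev_transposition(block, after)
  else ev_reverse_transposition(block, after)
}

#' Simulate a rearrangement history and its realized genome
#'
#' Samples `config$n_events` events (uniform valid blocks and targets, tdrl
#' loss assignments uniform over the non-degenerate assignments, remolded
#' paralogs copying the donor sequence with `remold_mutations` point
#' mutations), applies them sequentially to `source`, and realizes a genome
#' from the final order. Replaying the returned history over `source` always
#' reproduces the returned order (asserted on generation).
#'
#' @param config A [sim_config()] (with `n_events`, `event_mix`, ...).
#' @param source Source [gene_order()]; default the ground pattern.
#' @param id Genome identifier.
#' @return A `sim_truth` whose `history` holds the sampled events and whose
#'   `order`/`genome` reflect the final arrangement.
#' @export
simulate_history <- function(config = sim_config(n_events = 2L),
                             source = NULL, id = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(source)) source <- fixture_order("ground_pattern")
  cur <- source
  history <- vector("list", config$n_events)
  remolds <- list()
  for (i in seq_len(config$n_events)) {
    ev <- .sample_event(cur, config)
    cur <- apply_event(cur, ev)
    history[[i]] <- ev
    if (ev$kind == "paralog_remold")
      remolds[[length(remolds) + 1L]] <-
        list(donor = ev$donor, recipient = ev$recipient)
  }
  replay <- apply_events(source, history)$order
  stopifnot(orders_equal(replay, cur))
  truth <- .simulate_from_stream(config, cur, id, history, remolds)
  truth$source <- source
  truth
}

#' Write a simulated truth bundle to disk
#'
#' Emits the genome as GenBank and FASTA, the gene order in the plain-text
#' format, and a JSON ground-truth file (order, history, per-gene spans).
#'
#' @param truth A `sim_truth`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- truth$genome$id
  write_genbank(truth$genome, file.path(dir, paste0(id, ".gb")))
  write_fasta(stats::setNames(truth$genome$sequence, id),
              file.path(dir, paste0(id, ".fasta")))
  write_gene_orders(stats::setNames(list(truth$order), id),
                    file.path(dir, paste0(id, "_order.txt")))
  hist <- lapply(truth$history, function(e) unclass(e))
  jsonlite::write_json(
    list(id = id, order = format(truth$order), history = hist,
         annotations = truth$genome$annotations),
    file.path(dir, paste0(id, "_truth.json")), auto_unbox = TRUE)
  invisible(dir)
}
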