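---
title: "Gene-order rearrangement analysis of mitochondrial genomes with mitorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-order rearrangement analysis of mitochondrial genomes with mitorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorder)
```

## The problem

Animal mitochondrial genomes are small circular molecules that almost always
carry the same 37 genes (13 protein-coding genes, 22 tRNAs, 2 rRNAs) plus a
noncoding control region (CR). Because the gene *content* is frozen while the
gene *arrangement* changes only rarely, shared derived arrangements are
strong phylogenetic characters, and the mechanistic route from an ancestral
arrangement to a derived one (which genes moved, in how many steps, by which
mechanism) is itself informative. mitorder implements this analysis for
decapod-like mitogenomes: it represents arrangements as signed circular gene
orders over a closed 38-token vocabulary, compares them against the
pancrustacean (Crustacea + Hexapoda) ground pattern, and reconstructs
minimal mechanistic scenarios under an explicit event algebra.

## Signed circular gene orders

A `gene_order` is a sequence of (gene, strand) pairs read clockwise around
the circle. Two orders are equal when one is a rotation of the other, or a
rotation of the other read from the opposite strand (reversal with all signs
flipped). The control region is strandless and by convention always carries
`+`; under strand reflection it keeps `+`. `canonicalize()` rotates an order
so cox1 comes first on the plus strand, giving a literal normal form.

Two comparison statistics are provided:

* **Breakpoint distance** — the number of gene adjacencies of one order
  absent from the other, counting an adjacency `(a, b)` and its mirrored
  form `(-b, -a)` as the same. It is 0 exactly when the orders are equal.
* **Displaced-gene set** — the smallest set of genes whose deletion from
  both orders leaves identical circular signed orders. This formalizes the
  informal notion of "which genes are rearranged": genes that simply ride
  along with the conserved backbone are not charged to the set.

The displaced-gene search is exact. It iteratively deepens on the set size;
at each partial deletion it branches only over genes incident to a broken
adjacency of the *current reduced pair*. This restriction is complete: if
the reduced orders still differ, any valid completion must delete a gene
flanking one of the remaining breakpoints (a gene whose neighborhood is
already consistent in both reductions can always be spared). A static
restriction to genes incident to breakpoints of the *original* pair would
be incomplete — the interior genes of a moved multi-gene block are not
themselves breakpoint-incident — which the test suite demonstrates against
a full-subset brute-force oracle on random permutations.

Ties between equal-sized minima are resolved deterministically by
depth-first search in alphabetical gene order, with CR ranked last. Ranking
CR last matters: for the Gebiidea arrangement, deleting
{trnC, trnI, trnL1, trnQ, trnY} or {CR, trnC, trnI, trnL1, trnY} both
equalize the orders, but CR is a position marker rather than a gene, so the
all-gene set is preferred — and it is the one a biologist would report as
"the rearranged genes".

## The event algebra

Five mechanistic edits act on gene orders:

* `transposition` — excise a contiguous block, reinsert it after a named
  gene;
* `inversion` — reverse a block in place, flipping strands;
* `reverse_transposition` — move plus inversion;
* `tdrl` — tandem duplication of a region followed by loss of one copy of
  each gene. The loss assignment is explicit (copy 1 or copy 2 per gene);
  the surviving copy-1 genes precede the surviving copy-2 genes, each in
  their original relative order. There is no randomness at inference time;
  only the simulator samples assignments.
* `paralog_remold` — duplication / anticodon mutation / non-random loss:
  the recipient tRNA is deleted at its old position and a recipient-named
  copy appears adjacent to its donor with the donor's strand. Remolding is
  restricted to the two isoacceptor pairs where an anticodon point mutation
  can switch identity, (trnL1, trnL2) and (trnS1, trnS2) — the only
  biologically motivated remoldings for these genomes.

Every event maps a valid order to a valid order (same 38 genes, no
duplicates); this closure is property-tested with random events.

## Minimal scenario inference

`infer_scenario()` finds *all* shortest event sequences from a source order
to a target order (up to a reporting cap, default 10), by iterative
deepening depth-first search. Correctness and efficiency rest on three
observations:

1. **Admissible bound.** Every default-vocabulary event removes at most 3
   adjacencies, so at least `ceiling(breakpoints / 3)` events are needed;
   depths below this bound need not be searched at all. When `tdrl` is
   enabled, a duplicated region of up to `tdrl_cap` genes can change
   `tdrl_cap + 1` adjacencies and the divisor grows accordingly.
2. **Tight-budget pruning.** With `r` events remaining, a child order must
   satisfy `breakpoints <= 3 * (r - 1)`. When the current budget forces a
   minimum per-event reduction `d_min >= 1`, only moves whose three cut
   gaps include at least `d_min` breakpoints can qualify, and only those
   are enumerated. At slack budgets the full move space is enumerated,
   guarded by a node cap that errors loudly rather than silently
   truncating.
3. **Circular completeness.** Blocks are enumerated as ordered pairs of
   boundary gaps, so blocks that wrap the current linear representation are
   included. For plain transpositions a wrapping block is redundant (moving
   the complement gives the same circle) but for reverse transpositions it
   is not, and omitting wrapped blocks would make the search miss genuine
   one-event solutions.

Enumeration order is fixed (event kind alphabetically, then block start,
then target gap) and a visited table collapses states already explored with
at least the same remaining budget, so results are deterministic.
Exhaustiveness at each depth is what turns "no scenario of length 3 found"
into a proof of minimality at length 4; the test suite certifies this
against breadth-first brute-force enumeration on small circles.

Applied to the built-in fixtures, the search proves the Gebiidea
arrangement is 4 unit events from the ground pattern and the Axiidea
arrangement 5. `paper_scenarios()` additionally ships the two published
mechanistic narratives as regression fixtures, with the trnQ and cox3
translocations encoded as explicit duplication/random-loss (tdrl) events;
both fold exactly onto the corresponding fixture orders.

### Unit events versus narrative steps

Published rearrangement narratives count mechanism *phases*, grouping
simultaneous tRNA shuffles around one junction into a single step.
`grouped_steps()` reproduces this view heuristically: consecutive
transposition / reverse-transposition events whose blocks contain only
tRNAs merge into one phase; duplication/loss and remolding events always
open a new phase. On the shipped scenarios this yields 3 phases (Gebiidea)
and 4 (Axiidea). It is a labeling heuristic layered on top of the unit
event algebra, not part of it, and it can over- or under-group scenarios
whose tRNA moves are mechanistically independent.

## Composition statistics

`composition_report()` mirrors the per-genome characteristics tables of
mitogenome papers: genome length, A+T fraction overall and per partition
(protein-coding, rRNA, tRNA, control region), the strand economy of the 13
protein-coding genes, all circularly-computed gene overlaps, and the
noncoding inventory. Conventions worth stating:

* A+T content counts A and T (case-folded) over the full segment length;
  IUPAC ambiguity codes and N count in the denominator only. Fractions are
  stored at full precision; percent displays round to one decimal.
* Noncoding regions are the maximal circular intervals not covered by any
  gene annotation; annotated control regions count as noncoding (the CR
  *is* the leftover of the coding map), so a CR annotation merges with
  abutting spacers. The longest region is labeled the control region; a
  length tie goes to the higher A+T region, then to the one nearest rrnS
  clockwise (the CR is AT-rich and sits by rrnS in the ground pattern).
* Overlap nucleotides belong to the covered set, so they are never double
  counted: union-of-spans plus noncoding always equals genome length.

## tRNA paralog similarity

High sequence identity between trnL1 and trnL2 is the signature of
remolding (one Leu tRNA arising as a duplicate of the other) as opposed to
independent translocation. `similarity()` scores a global Needleman–Wunsch
alignment — match +1, mismatch −1, gap cost 2 for the first gapped position
and 1 per extension, end gaps penalized — and reports identity as matches
over all alignment columns, gaps included, rounded to integer percent.
Published similarity figures rarely state their alignment conventions;
denominators differing by a few columns move the percentage by a point or
two, which is why comparisons against quoted values should allow a few
points of slack. Because co-optimal alignments can differ in column count,
operands are aligned in a canonical order, making the score exactly
symmetric. Genes are extracted in coding sense before alignment (the two
Leu tRNAs sit on opposite strands in the ground pattern, and homology is
strand-independent).

## Supermatrix assembly

`extract_pcgs()`, `drop_third_positions()`, `concatenate_alignments()` and
the PHYLIP/FASTA/partition writers prepare concatenated nucleotide or
amino-acid datasets for external phylogenetic tools. Multiple sequence
alignment, model selection and tree inference are deliberately out of
scope — the module only emits files such tools consume. Third-position
masking refuses alignments whose in-frame length is not a multiple of
three rather than silently truncating; translation uses the invertebrate
mitochondrial genetic code (NCBI table 5), dropping incomplete terminal
codons with a warning. Genes are concatenated in alphabetical token order
and the partition table records the resulting column ranges, so outputs
are format-compatible (not byte-identical) with matrices built under other
orderings.

## The synthetic-data generator

Every stage above is testable without downloads because
`simulate_genome()` / `simulate_history()` produce fully specified ground
truth. The generator's defaults describe a typical decapod-like
mitogenome and were fixed once, up front:

| parameter | default | rationale |
|---|---|---|
| `at_target` | 0.70 | middle of the 66–74% A+T range typical of these genomes |
| `trna_length` | 61–73 nt | the observed tRNA length range |
| `pcg_length` | 160–1800 nt | atp8 through nad5 scale |
| `rrna_length` | 700–1400 nt | rrnS through rrnL scale |
| `cr_length` | 91–1200 nt | shortest observed CR up to long CRs |
| `spacer_range` | 0–10 nt | "a few nucleotides" between most genes |
| `overlap_spec` | atp8/atp6 and nad4L/nad4, 7 nt each | the two canonical reading-frame overlaps |
| `block_range` | 1–3 genes | mitogenome rearrangements move short blocks |
| `tdrl_region_range` | 2–3 genes | small tandem duplications |
| `remold_mutations` | 5 | a remolded paralog differs by the anticodon plus a few drift substitutions |

Sequence is i.i.d. per position with P(A) = P(T) = `at_target`/2 — no codon
structure, no site-rate variation, no strand-asymmetric skew. That is
sufficient for what the generator must support (composition recovery,
overlap bookkeeping, paralog identity, order extraction, scenario
recovery) and deliberately nothing more: passing tests say the *pipeline*
is correct, not that real genomes look like the simulator. Real mitogenomes
have codon usage, GC/AT skew between strands, and structured control
regions; none of those properties are claimed or tested.

Keeping sampled tdrl regions small (2–3 genes) also keeps the recovery
property well-posed: any duplication/loss of a 2–3 gene region rearranges
at most one gene relative to the others, so a history of k events is always
expressible in at most k events of the default inference vocabulary, and
the inferred minimum can be compared against k honestly.

One seed drives a single pseudo-random stream; identical configurations
are byte-identical, and the realized genome's ground truth (per-gene
coding sequences, final order, event history) is returned alongside it.
Replaying the history over the source order is asserted to reproduce the
final order on every call.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; features spanning the
  origin are stored with `end > length` and reduced modulo length on
  extraction. GenBank's 1-based inclusive convention (and origin-spanning
  `join()` locations) are converted at the boundary.
* `+` is the strand carrying cox1; records annotated the other way are
  flipped whole on read.
* A genome fully covered by genes has an empty noncoding inventory (valid,
  not an error); an empty sequence segment is an error everywhere.
* `displaced_genes()` and `infer_scenario()` cap their searches
  (`max_size`, `node_cap`) and fail loudly at the cap — no silent
  truncation anywhere.
* Problem sizes in the shipped tests and acceptance script (60–500 random
  permutations of 4–12 genes, 100 seeded histories of 1–3 events, 20–25
  simulated genomes) were chosen as the smallest sizes at which the
  certified properties are statistically meaningful.

## Known limitations

* The scenario search is exact but exponential in the worst case; it is
  intended for the near-minimal scenarios typical of real mitogenome
  comparisons (a handful of events), not for arbitrary distant permutation
  pairs.
* The grouped-step view is a heuristic approximation of how narratives
  phase their mechanisms; it is reported alongside, never instead of, the
  unit event count.
* CREx-style common-interval analysis, inversion/DCJ distances,
  probabilistic rearrangement models, de novo annotation and tree
  inference are out of scope by design.
* The GenBank reader targets the feature-table subset mitogenome records
  actually use (gene/CDS/tRNA/rRNA/misc_feature/D-loop keys, complement
  and origin-wrapping join locations); it is not a general GenBank parser.

## A worked comparison

```{r}
gp <- fixture_order("ground_pattern")
geb <- fixture_order("gebiidea")
compare_orders(geb, gp)

sc <- paper_scenarios()
sc$gebiidea
max(grouped_steps(sc$gebiidea))
```

```{r}
truth <- simulate_history(sim_config(seed = 42, n_events = 2))
res <- infer_scenario(truth$source, truth$order, max_events = 2,
                      max_scenarios = 1)
length(res[[1]]$events)  # never exceeds the true event count
```
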