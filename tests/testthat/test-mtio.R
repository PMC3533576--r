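# Vocabulary mapping, fixtures, and flat-file round trips.

test_that("canonical_name maps synonyms, figure codes and anticodons", {
  expect_equal(canonical_name("ND4L"), "nad4L")
  expect_equal(canonical_name("COI"), "cox1")
  expect_equal(canonical_name("cytochrome b"), "cob")
  expect_equal(canonical_name("16S ribosomal RNA"), "rrnL")
  expect_equal(canonical_name("D-loop"), "CR")
  expect_equal(canonical_name("tRNA-Leu", anticodon = "UAG"), "trnL1")
  expect_equal(canonical_name("tRNA-Leu", anticodon = "taa"), "trnL2")
  expect_equal(canonical_name("tRNA-Ser(AGN)"), "trnS1")
  expect_equal(canonical_name("L1"), "trnL1")
  expect_equal(canonical_name("W"), "trnW")
  expect_error(canonical_name("tRNA-Xle"), "cannot map")
  expect_error(canonical_name("tRNA-Leu"), "anticodon")
})

test_that("canonical_name is idempotent on every canonical token", {
  for (tok in mt_vocabulary())
    expect_equal(canonical_name(tok), tok)
})

test_that("fixture orders are 38-token permutations of one vocabulary", {
  keys <- c("ground_pattern", "gebiidea", "axiidea", "thalassina")
  for (key in keys) {
    ord <- fixture_order(key)
    expect_length(ord$genes, 38)
    expect_setequal(ord$genes, mt_vocabulary())
  }
  expect_true(orders_equal(fixture_order("thalassina"),
                           fixture_order("ground_pattern")))
  expect_error(fixture_order("nonsense"))
})

test_that("rRNA placement differs between the two derived orders", {
  gap_between <- function(ord, a, b) {
    ia <- match(a, ord$genes); ib <- match(b, ord$genes)
    (ib - ia - 1) %% length(ord)
  }
  geb <- fixture_order("gebiidea")
  axi <- fixture_order("axiidea")
  # rrnL and rrnS separated by trnV in gebiidea, adjacent in axiidea
  expect_equal(gap_between(geb, "rrnL", "rrnS"), 1)
  expect_equal(geb$genes[match("rrnL", geb$genes) + 1], "trnV")
  expect_equal(gap_between(axi, "rrnL", "rrnS"), 0)
})

test_that("GenBank write/read round-trips a synthetic genome", {
  truth <- simulate_genome(sim_config(seed = 11))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(truth$genome, path)
  back <- read_genbank(path)
  expect_equal(back$sequence, truth$genome$sequence)
  expect_equal(back$annotations, truth$genome$annotations)
})

test_that("round trip survives an origin-spanning annotation", {
  truth <- simulate_genome(sim_config(seed = 5, rotate_origin = TRUE))
  L <- nchar(truth$genome$sequence)
  expect_true(any(truth$genome$annotations$end > L))  # wrap case exercised
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(truth$genome, path)
  back <- read_genbank(path)
  expect_equal(back$annotations, truth$genome$annotations)
  expect_equal(extract_order(back), truth$order)
})

.mini_gb <- function(lines, seq = "ATGCATGCATGCATGCATGC") {
  c(sprintf("LOCUS       toy %d bp    DNA     circular", nchar(seq)),
    "FEATURES             Location/Qualifiers",
    "     source          1..20",
    lines,
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(seq)),
    "//")
}

test_that("reader maps a COI feature and reports unmappables", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(.mini_gb(c(
    "     CDS             2..13",
    "                     /gene=\"COI\"",
    "     misc_feature    14..16",
    "                     /note=\"mystery ORF\"")), path)
  expect_warning(g <- read_genbank(path, relax = TRUE), "unmapped")
  expect_equal(g$annotations$name, "cox1")
  expect_equal(g$annotations$start, 1L)   # 1-based 2..13 -> 0-based [1,13)
  expect_equal(g$annotations$end, 13L)
  expect_equal(g$annotations$strand, "+")
  expect_equal(nrow(attr(g, "unmapped")), 1)
})

test_that("conflicting duplicate features error unless relaxed", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(.mini_gb(c(
    "     CDS             2..10",
    "                     /gene=\"COI\"",
    "     CDS             12..18",
    "                     /gene=\"CO1\"")), path)
  expect_error(read_genbank(path), "conflicting")
  g <- suppressWarnings(read_genbank(path, relax = TRUE))
  expect_equal(nrow(g$annotations), 1)
})

test_that("records annotated on the opposite strand are flipped to cox1-plus", {
  truth <- simulate_genome(sim_config(seed = 7))
  flipped <- flip_genome(truth$genome)
  expect_equal(flipped$annotations$strand[
    flipped$annotations$name == "cox1"], "-")
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(flipped, path)
  back <- read_genbank(path)  # reader must normalize back
  expect_equal(back$annotations$strand[back$annotations$name == "cox1"], "+")
  expect_true(orders_equal(extract_order(back), truth$order))
  expect_equal(back$sequence, truth$genome$sequence)
  expect_equal(back$annotations, truth$genome$annotations)
})

test_that("gene-order text format round-trips, with comments tolerated", {
  orders <- list(GP = fixture_order("ground_pattern"),
                 GEB = fixture_order("gebiidea"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_orders(orders, path)
  txt <- c("# comment line", readLines(path), "")
  writeLines(txt, path)
  back <- read_gene_orders(path)
  expect_named(back, c("GP", "GEB"))
  expect_true(orders_equal(back$GP, orders$GP))
  expect_true(orders_equal(back$GEB, orders$GEB))
})

test_that("fasta writer/reader round-trips sequences", {
  seqs <- c(a = strrep("ACGT", 30), b = "TTTTAAAACCCC")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})
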