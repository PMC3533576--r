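# PCG extraction, third-position masking, concatenation, format round trips.

test_that("extract_pcgs returns the generator's stored sequences", {
  truth <- simulate_genome(sim_config(seed = 14, rotate_origin = TRUE))
  pcgs <- extract_pcgs(truth$genome)
  expect_named(pcgs)
  expect_length(pcgs, 13)
  for (nm in names(pcgs))
    expect_equal(pcgs[[nm]], truth$gene_seqs[[nm]])
  # minus-strand genes really are reverse-complemented coding sense
  ann <- truth$genome$annotations
  minus <- ann$name[ann$strand == "-" & ann$kind == "PCG"]
  expect_setequal(minus, c("nad1", "nad4", "nad4L", "nad5"))
})

test_that("a missing PCG is reported by name", {
  toy <- mito_genome("t", strrep("ACGT", 25),
                     data.frame(name = "cox1", start = 0, end = 30,
                                strand = "+"), complete = FALSE)
  expect_error(extract_pcgs(toy), "nad6")
})

test_that("drop_third_positions keeps in-frame first and second positions", {
  out <- drop_third_positions(c(a = "123456789", b = "ABCDEFGHI"))
  expect_equal(out[["a"]], "124578")
  expect_equal(out[["b"]], "ABDEGH")
  # gaps in kept columns are preserved
  out2 <- drop_third_positions(c(a = "A-GT--XYZ"))
  expect_equal(out2[["a"]], "A-T-XY")
  # frame offset: leading columns kept, then every third dropped
  out3 <- drop_third_positions(c(a = "xxABCDEF"), frame = 2)
  expect_equal(out3[["a"]], "xxABDE")
  expect_error(drop_third_positions(c(a = "ACGTACG")), "divisible")
  set.seed(2)
  aln <- c(t1 = paste(sample(c("A", "-"), 300, TRUE), collapse = ""),
           t2 = paste(sample(c("C", "-"), 300, TRUE), collapse = ""))
  expect_equal(unique(nchar(drop_third_positions(aln))), 200)
})

test_that("concatenation tiles partitions and handles edge cases", {
  g1 <- c(t1 = "AAAAAA", t2 = "CCCCCC", t3 = "GGGGGG")
  g2 <- c(t1 = "TTTTTTTTT", t2 = "AAAAAAAAA", t3 = "CCCCCCCCC")
  sm <- concatenate_alignments(list(cox2 = g2, cox1 = g1))
  expect_equal(nchar(sm$seqs[["t1"]]), 15)
  expect_equal(sm$partitions$gene, c("cox1", "cox2"))  # alphabetical
  expect_equal(sm$partitions$start, c(1, 7))
  expect_equal(sm$partitions$end, c(6, 15))
  expect_equal(sm$seqs[["t1"]], "AAAAAATTTTTTTTT")
  # single gene: matrix equals input
  sm1 <- concatenate_alignments(list(cox1 = g1))
  expect_equal(unname(sm1$seqs), unname(g1))
  # taxon mismatch errors unless permissive, which pads with gaps
  g3 <- c(t1 = "GG", t2 = "TT")
  expect_error(concatenate_alignments(list(cox1 = g1, nad2 = g3)), "t3")
  smp <- concatenate_alignments(list(cox1 = g1, nad2 = g3),
                                permissive = TRUE)
  expect_equal(smp$seqs[["t3"]], "GGGGGG--")
  expect_error(concatenate_alignments(list(cox1 = g1),
                                      taxa = character(0)), "empty")
})

test_that("column counts are conserved through the pipeline", {
  truth <- simulate_genome(sim_config(seed = 15))
  pcgs <- extract_pcgs(truth$genome)
  trimmed <- lapply(pcgs, function(s)
    substr(s, 1, nchar(s) %/% 3 * 3))
  alns <- lapply(trimmed, function(s) c(tax1 = s, tax2 = s))
  sm <- concatenate_alignments(alns)
  expect_equal(nchar(sm$seqs[["tax1"]]),
               sum(vapply(trimmed, nchar, integer(1))))
  masked <- lapply(alns, drop_third_positions)
  sm2 <- concatenate_alignments(masked)
  expect_equal(nchar(sm2$seqs[["tax1"]]),
               nchar(sm$seqs[["tax1"]]) * 2 / 3)
})

test_that("PHYLIP and FASTA writes round-trip the matrix", {
  g1 <- c(taxon_one = "ACGTAC", taxon_two = "TGCATG")
  sm <- concatenate_alignments(list(cox1 = g1))
  pf <- withr::local_tempfile(fileext = ".phy")
  write_phylip(sm, pf)
  back <- read_phylip(pf)
  expect_equal(back$seqs, sm$seqs)
  ff <- withr::local_tempfile(fileext = ".fasta")
  write_supermatrix_fasta(sm, ff)
  expect_equal(read_fasta(ff), sm$seqs)
  parts <- withr::local_tempfile(fileext = ".txt")
  write_partitions(sm, parts)
  expect_equal(readLines(parts), "DNA, cox1 = 1-6")
})

test_that("translation uses the invertebrate mitochondrial code", {
  # ATA = Met and AGA = Ser in the invertebrate mitochondrial code
  expect_equal(unname(translate_mt(c(x = "ATAAGATGA"))), "MSW")
  expect_warning(out <- translate_mt(c(x = "ATGAA")), "incomplete")
  expect_equal(unname(out), "M")
})
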