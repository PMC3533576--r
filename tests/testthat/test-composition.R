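# Composition statistics: A+T content, overlaps, noncoding inventory.

test_that("at_content counts A and T over the full denominator", {
  expect_equal(at_content("ATAT"), 1)
  expect_equal(at_content("GCGC"), 0)
  expect_equal(at_content("atgc"), 0.5)       # case-folded
  expect_equal(at_content("ATNN"), 0.5)       # ambiguity in denominator only
  expect_error(at_content(""), "empty")
})

test_that("at_content of a concatenation is the length-weighted mean", {
  set.seed(9)
  for (rep in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:50, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:50, 1), TRUE),
               collapse = "")
    expect_equal(at_content(paste0(a, b)),
                 (at_content(a) * nchar(a) + at_content(b) * nchar(b)) /
                   (nchar(a) + nchar(b)))
  }
})

.toy_genome <- function(spans, L = 200, seed = 1) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  mito_genome("toy", seq, spans, complete = FALSE)
}

test_that("find_overlaps handles linear and origin-wrapping intersections", {
  g <- .toy_genome(data.frame(
    name = c("cox1", "cox2"), start = c(0, 7), end = c(10, 20),
    strand = "+"))
  ov <- find_overlaps(g)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$shared, 3)
  # span wrapping the origin: [196, 203) meets [0, 10) in 3 positions
  g2 <- .toy_genome(data.frame(
    name = c("cox1", "cox2"), start = c(196, 0), end = c(203, 10),
    strand = "+"))
  expect_equal(find_overlaps(g2)$shared,
               oracle_overlap(196, 203, 0, 10, 200))
  expect_equal(find_overlaps(g2)$shared, 3)
})

test_that("overlaps agree with the per-position membership oracle", {
  set.seed(31)
  for (rep in 1:40) {
    L <- sample(60:120, 1)
    k <- sample(2:4, 1)
    starts <- sample(0:(L - 1), k)
    lens <- sample(5:30, k, replace = TRUE)
    g <- .toy_genome(data.frame(
      name = mt_vocabulary()[seq_len(k)], start = starts,
      end = starts + lens, strand = "+"), L = L, seed = rep)
    ov <- find_overlaps(g)
    ann <- g$annotations
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      expected <- oracle_overlap(ann$start[i], ann$end[i],
                                 ann$start[j], ann$end[j], L)
      row <- ov[(ov$gene1 == ann$name[i] & ov$gene2 == ann$name[j]) |
                (ov$gene1 == ann$name[j] & ov$gene2 == ann$name[i]), ]
      got <- if (nrow(row)) row$shared[1] else 0L
      expect_equal(got, expected)
    }
  }
})

test_that("a single 91-nt gap is labeled control region", {
  g <- .toy_genome(data.frame(
    name = c("cox1", "cox2"), start = c(0, 191), end = c(100, 200),
    strand = "+"))
  reg <- noncoding_inventory(g)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$length, 91)
  expect_equal(reg$role, "control_region")
  expect_equal(reg$start, 100)
})

test_that("a fully covered genome yields an empty inventory", {
  g <- .toy_genome(data.frame(
    name = c("cox1", "cox2"), start = c(0, 100), end = c(100, 200),
    strand = "+"))
  expect_equal(nrow(noncoding_inventory(g)), 0)
})

test_that("noncoding regions merge across the origin", {
  g <- .toy_genome(data.frame(
    name = c("cox1", "cox2"), start = c(20, 120), end = c(100, 180),
    strand = "+"))
  reg <- noncoding_inventory(g)
  expect_equal(nrow(reg), 2)
  wrap <- reg[reg$length == max(reg$length), ]
  expect_equal(wrap$length, 40)   # [180, 220) across the origin
  expect_equal(wrap$start, 180)
  expect_equal(wrap$role, "control_region")
})

test_that("partition conservation holds on simulated genomes", {
  for (seed in c(2, 13)) {
    truth <- simulate_genome(sim_config(seed = seed))
    g <- truth$genome
    L <- nchar(g$sequence)
    ann <- g$annotations[g$annotations$kind != "CR", ]
    covered <- logical(L)
    for (i in seq_len(nrow(ann)))
      covered[((ann$start[i]:(ann$end[i] - 1)) %% L) + 1] <- TRUE
    rep <- composition_report(g)
    expect_equal(sum(covered) + rep$noncoding_total, L)
    expect_equal(rep$noncoding_total, sum(rep$regions$length))
    expect_true(all(rep$regions$at_content >= 0 &
                    rep$regions$at_content <= 1))
  }
})

test_that("composition report recovers the generator's ground truth", {
  truth <- simulate_genome(sim_config(seed = 8))
  rep <- composition_report(truth$genome)
  expect_equal(rep$genome_length, nchar(truth$genome$sequence))
  # ground-pattern strand economy: 9 PCGs on +, 4 on -
  expect_equal(unname(rep$pcg_strand_split), c(9, 4))
  expect_equal(sum(rep$pcg_strand_split), 13)
  # the two forced 7-nt overlaps, exactly
  ov <- rep$overlaps
  expect_equal(nrow(ov), 2)
  expect_setequal(paste(ov$gene1, ov$gene2),
                  c("atp8 atp6", "nad4 nad4L"))
  expect_true(all(ov$shared == 7))
  expect_lt(abs(rep$at_overall - 0.70), 0.02)
  expect_equal(unname(rep$trna_length_range[1] >= 61 &
                      rep$trna_length_range[2] <= 73), TRUE)
  # the CR-containing gap is the largest noncoding region
  cr <- rep$regions[rep$regions$role == "control_region", ]
  expect_equal(nrow(cr), 1)
  expect_equal(cr$length, max(rep$regions$length))
})
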