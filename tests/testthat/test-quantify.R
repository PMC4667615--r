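test_that("overlap counting follows the any-overlap rule", {
  intron <- GRanges("chr1", IRanges::IRanges(101, 200))
  # fragment [151,250] overlaps by 50 bp
  expect_equal(count_fragment_overlaps(
    intron, GRanges("chr1", IRanges::IRanges(151, 250))), 1L)
  # BED half-open abutment: fragment [201,300] does not overlap [101,200]
  expect_equal(count_fragment_overlaps(
    intron, GRanges("chr1", IRanges::IRanges(201, 300))), 0L)
  # missing chromosome -> 0
  expect_equal(suppressWarnings(count_fragment_overlaps(
    intron, GRanges("chr9", IRanges::IRanges(1, 500)))), 0L)
})

test_that("overlap counts equal the quadratic all-pairs oracle", {
  set.seed(42)
  for (rep in 1:10) {
    frags <- GRanges("chr1", IRanges::IRanges(
      sample.int(5000, 100, replace = TRUE), width = sample(50:400, 100,
                                                            replace = TRUE)))
    ivs <- GRanges("chr1", IRanges::IRanges(
      sample.int(5000, 10), width = sample(100:1000, 10, replace = TRUE)))
    expect_equal(as.numeric(count_fragment_overlaps(ivs, frags)),
                 oracle_count_overlaps(ivs, frags))
  }
})

test_that("strand-respecting mode counts only same-strand fragments", {
  iv <- GRanges("chr1", IRanges::IRanges(100, 200), strand = "+")
  frags <- GRanges("chr1", IRanges::IRanges(c(150, 150), c(250, 250)),
                   strand = c("+", "-"))
  expect_equal(count_fragment_overlaps(iv, frags), 2L)
  expect_equal(count_fragment_overlaps(iv, frags, respect_strand = TRUE), 1L)
})

test_that("FPKM formula and scale invariance", {
  expect_identical(fpkm(1000, 1000, 1e6), 1000)
  expect_identical(fpkm(0, 5000, 1e7), 0)
  # doubling count and total leaves the value unchanged
  expect_equal(fpkm(10, 2000, 1e6), 5)
  expect_equal(fpkm(20, 2000, 2e6), 5)
  expect_error(fpkm(10, 0, 1e6), "length")
  expect_error(fpkm(10, 100, 0), "total_mapped")
})

test_that("gene FPKM matrix equals per-gene brute force on a toy fixture", {
  models <- parse_gtf(write_toy_gtf())
  set.seed(7)
  frags <- GRanges("chr1", IRanges::IRanges(
    sample.int(1800, 500, replace = TRUE), width = 80))
  fs <- fragment_set(frags, "s1", total_mapped = 1e5)
  m <- gene_fpkm_matrix(models, list(fs))
  for (g in models$genes$gene_id) {
    union_ex <- GenomicRanges::reduce(models$exons[models$exons$gene_id == g])
    cnt <- sum(vapply(seq_along(frags), function(i)
      any(start(frags)[i] <= end(union_ex) &
            end(frags)[i] >= start(union_ex)), logical(1)))
    len <- models$genes$union_exonic_length[models$genes$gene_id == g]
    expect_equal(m[g, "s1"], cnt * 1e9 / (len * 1e5))
  }
})

test_that("intronic FPKM and IR values follow the definitions", {
  # intron of 2 kb with 20 overlapping fragments at 1e6 total -> FPKM 10
  expect_equal(fpkm(20, 2000, 1e6), 10)
  expect_equal(ir_value(10, 100), 0.1)
  expect_equal(ir_value(0, 50), 0)
  expect_true(is.na(ir_value(5, 0)))  # undefined when the gene is silent
  expect_error(ir_value(-1, 10), "non-negative")

  models <- parse_gtf(write_toy_gtf())
  introns <- collapse_introns(models)
  set.seed(8)
  frags <- GRanges("chr1", IRanges::IRanges(
    sample.int(1800, 300, replace = TRUE), width = 100))
  fs <- fragment_set(frags, "s1", total_mapped = 5e4)
  m <- gene_fpkm_matrix(models, list(fs))
  q <- intron_quant(introns, list(fs), m)
  expect_equal(as.numeric(q$counts[, 1]),
               oracle_count_overlaps(introns, frags))
  expect_equal(q$intronic_fpkm[, 1],
               q$counts[, 1] * 1e9 / (width(introns) * 5e4),
               ignore_attr = TRUE)
  # intronic_fpkm is 0 iff the count is 0
  expect_equal(q$intronic_fpkm[, 1] == 0, q$counts[, 1] == 0)
})

test_that("fragment_set validates its totals", {
  gr <- GRanges("chr1", IRanges::IRanges(1, 100))
  expect_error(fragment_set(gr, "s", total_mapped = 0), "total_mapped")
  expect_error(fragment_set(gr, "s", total_mapped = 0.5), "smaller")
  fs <- fragment_set(gr, "s")
  expect_equal(fs$total_mapped, 1)
})

test_that("FPKM is stable in expectation under uniform subsampling", {
  sm <- small_sim(seed = 303, depth = 2e5, n_genes = 10)
  fs <- sim_fragments(sm$sim)[[3]]
  m_full <- gene_fpkm_matrix(sm$sim$models, list(fs))
  set.seed(1)
  reps <- replicate(8, {
    keep <- runif(length(fs$fragments)) < 0.5
    half <- fragment_set(fs$fragments[keep], "half",
                         total_mapped = sum(keep))
    gene_fpkm_matrix(sm$sim$models, list(half))[, 1]
  })
  rel <- rowMeans(reps) / m_full[, 1]
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("BAM adapter merges proper pairs to outer fragment spans", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    paste("p1\t99\tchr1\t101\t60\t50M\t=\t401\t350",
          paste(rep("A", 50), collapse = ""), "*", sep = "\t"),
    paste("p1\t147\tchr1\t401\t60\t50M\t=\t101\t-350",
          paste(rep("A", 50), collapse = ""), "*", sep = "\t")), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  fs <- read_fragments_bam(bam, "s1")
  expect_length(fs$fragments, 1)  # one pair = one fragment
  expect_equal(start(fs$fragments), 101)
  expect_equal(end(fs$fragments), 450)
})
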