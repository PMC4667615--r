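test_that("weight table: consensus base strictly maximal everywhere", {
  mat <- acceptor_matrix()
  cons <- strsplit("TTTTTTTTTTTCAGG", "")[[1]]
  for (i in 1:15) {
    expect_equal(names(which.max(mat[i, ])), cons[i])
    expect_true(all(mat[i, setdiff(colnames(mat), cons[i])] < mat[i, cons[i]]))
  }
  bad <- mat; bad["-5", "C"] <- bad["-5", "T"]
  expect_error(score_acceptor("TTTTTTTTTTTCAGG", bad), "strictly maximal")
})

test_that("consensus scores 100 and every substitution lowers the score", {
  cons <- "TTTTTTTTTTTCAGG"
  expect_equal(score_acceptor(cons)$score, 100)
  bases <- c("A", "C", "G", "T")
  for (i in 1:15) {
    for (b in setdiff(bases, substr(cons, i, i))) {
      v <- cons
      substr(v, i, i) <- b
      res <- score_acceptor(v)
      if (i %in% c(13, 14)) {
        # breaking the AG invalidates the acceptor instead of scoring low
        expect_false(res$valid_ag)
        expect_true(is.na(res$score))
      } else {
        expect_lt(res$score, 100)
      }
    }
  }
})

test_that("GAG-type acceptor scores the value implied by the weight table", {
  mat <- acceptor_matrix()
  gag <- "TTTTTTTTGAGCAGG"
  # independent sum over the table
  b <- strsplit(gag, "")[[1]]
  s <- sum(vapply(1:15, function(i) mat[i, b[i]], numeric(1)))
  expected <- 100 * (s - sum(apply(mat, 1, min))) /
    (sum(apply(mat, 1, max)) - sum(apply(mat, 1, min)))
  res <- score_acceptor(gag)
  expect_equal(res$score, expected)
  expect_equal(res$score, 82.168, tolerance = 1e-4)
  expect_lt(res$score, 100)
})

test_that("invalid acceptors and ambiguous bases get no score", {
  ct <- score_acceptor("TTTTTTTTTTTCCTG")
  expect_false(ct$valid_ag)
  expect_equal(ct$reason, "no_ag")
  amb <- score_acceptor("TTTTTTNTTTTCAGG")
  expect_true(is.na(amb$score))
  expect_equal(amb$reason, "ambiguous_base")
  expect_error(score_acceptor("TTTCAGG"), "15 bases")
})

test_that("acceptor extraction slices the junction on both strands", {
  # toy chromosome: intron [101,200] on '+', context = bases [187,201]
  set.seed(5)
  seq_plus <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                    collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrP = seq_plus))
  intr <- GRanges("chrP", IRanges::IRanges(101, 200), strand = "+")
  ctx <- extract_acceptor(genome, intr)
  expect_equal(ctx$sequence, substr(seq_plus, 187, 201))

  # the same locus on the reverse-complemented chromosome, minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_plus)))
  genome_rc <- Biostrings::DNAStringSet(c(chrM = rc))
  intr_rc <- GRanges("chrM", IRanges::IRanges(300 - 200 + 1, 300 - 101 + 1),
                     strand = "-")
  ctx_rc <- extract_acceptor(genome_rc, intr_rc)
  expect_equal(ctx_rc$sequence, ctx$sequence)

  expect_error(extract_acceptor(
    genome, GRanges("chrP", IRanges::IRanges(101, 110), strand = "+")),
    "14")
})

test_that("strand invariance: flipping genome and annotation keeps all scores", {
  sm <- small_sim(seed = 77, depth = 1e3, n_genes = 6)
  introns <- collapse_introns(sm$sim$models)
  sc <- score_acceptors(sm$sim$genome, introns)

  flipped <- Biostrings::reverseComplement(sm$sim$genome)
  lens <- setNames(Biostrings::width(sm$sim$genome),
                   names(sm$sim$genome))
  L <- lens[as.character(seqnames(introns))]
  introns_f <- GRanges(seqnames(introns),
                       IRanges::IRanges(L - end(introns) + 1,
                                        L - start(introns) + 1),
                       strand = ifelse(strand(introns) == "+", "-", "+"))
  mcols(introns_f) <- mcols(introns)
  sc_f <- score_acceptors(flipped, introns_f)
  expect_equal(sc_f$sequence, sc$sequence)
  expect_equal(sc_f$score, sc$score)
})

test_that("batch scoring records invalid contexts and matches single calls", {
  sm <- small_sim(seed = 78, depth = 1e3, n_genes = 8)
  introns <- collapse_introns(sm$sim$models)
  sc <- score_acceptors(sm$sim$genome, introns)
  expect_equal(nrow(sc), length(introns))
  expect_true(all(sc$valid))
  for (i in sample(nrow(sc), 10))
    expect_equal(sc$score[i],
                 score_acceptor(sc$sequence[i])$score)

  # a short intron is flagged but the run continues
  short <- suppressWarnings(
    c(introns, GRanges(as.character(seqnames(introns))[1],
                              IRanges::IRanges(250, 259), strand = "+",
                              gene_id = "x", ordinal = 1L,
                              intron_id = "x:1")))
  sc2 <- score_acceptors(sm$sim$genome, short)
  expect_equal(nrow(sc2), length(short))
  expect_false(sc2$valid[nrow(sc2)])
  expect_match(sc2$reason[nrow(sc2)], "14")
})

test_that("planted acceptors reproduce their genomic context and class order", {
  sm <- small_sim(seed = 79, depth = 1e3, n_genes = 20, frac_weak = 0.3)
  introns <- collapse_introns(sm$sim$models)
  sc <- score_acceptors(sm$sim$genome, introns)
  ti <- sm$sim$truth_introns
  idx <- match(sc$intron_id, ti$intron_id)
  expect_equal(sc$sequence, ti$acceptor[idx])
  weak <- sc$score[ti$class[idx] == "weak"]
  strong <- sc$score[ti$class[idx] == "strong"]
  expect_gt(length(weak), 0)
  expect_lt(max(weak), min(strong))
})

test_that("rank-sum association is exact on the enumerable example", {
  scores <- data.frame(
    intron_id = paste0("i", 1:7),
    sequence = NA, valid = TRUE, reason = "ok",
    score = c(10, 20, 30, 70, 80, 90, 95), stringsAsFactors = FALSE)
  res <- retention_association(scores, c("i1", "i2", "i3"))
  expect_equal(res$p_value, 1 / 35)  # 1 / choose(7, 3)
  expect_equal(res$n_retained, 3)
  expect_equal(sum(res$bins$n), 7)
  expect_equal(res$bins$retained_fraction[res$bins$bin == "[10,20)"], 1)
  expect_error(retention_association(scores, character(0)), "retained")
  expect_error(retention_association(scores, paste0("i", 1:7)), "unretained")
})

test_that("label permutation gives a calibrated null", {
  set.seed(9)
  scores <- data.frame(intron_id = paste0("i", 1:60), sequence = NA,
                       valid = TRUE, reason = "ok",
                       score = runif(60, 0, 100), stringsAsFactors = FALSE)
  p <- replicate(1000, {
    lab <- sample(scores$intron_id, 10)
    retention_association(scores, lab)$p_value
  })
  expect_gt(median(p), 0.4)
  expect_lt(median(p), 0.6)
})

test_that("complete separation at scale is overwhelmingly significant", {
  scores <- data.frame(
    intron_id = paste0("i", 1:2200), sequence = NA, valid = TRUE,
    reason = "ok",
    score = c(runif(200, 0, 40), runif(2000, 60, 100)),
    stringsAsFactors = FALSE)
  res <- retention_association(scores, paste0("i", 1:200))
  expect_lt(res$p_value, 1e-6)
})

test_that("plain 15-mer scoring supports GAG vs TTT minigene comparisons", {
  df <- score_acceptor_seqs(c("TTTTTTTTGAGCAGG", "TTTTTTTTTTTCAGG",
                              "TTTTTTTTTTTCCTG"))
  expect_equal(df$valid, c(TRUE, TRUE, FALSE))
  expect_lt(df$score[1], df$score[2])
  f <- tempfile()
  writeLines(c("TTTTTTTTGAGCAGG", "TTTTTTTTTTTCAGG"), f)
  df2 <- score_acceptor_seqs(f)
  expect_equal(df2$score, df$score[1:2])
})
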