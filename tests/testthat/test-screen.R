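# independent Welch t oracle on log2(FPKM + 0.1)
welch_p <- function(x, y, pc = 0.1) {
  a <- log2(x + pc); b <- log2(y + pc)
  va <- var(a); vb <- var(b); na <- length(a); nb <- length(b)
  if (va == 0 && vb == 0) return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  t <- (mean(a) - mean(b)) / sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(-abs(t), df)
}

test_that("DE ratio filter uses pseudocounted max/min with strict inequality", {
  th <- screen_thresholds()
  m <- rbind(on_off = c(0, 0, 0, 0, 0, 30),    # 30.1/0.1 = 301 -> pass
             flat = rep(5, 6),                  # ratio 1 -> fail
             edge = c(0.9, 2.9, 2.9, 2.9, 2.9, 2.9))  # 3.0/1.0 = 3, not > 3
  colnames(m) <- design_default()$sample_id
  expect_equal(de_ratio_filter(m, th), "on_off")
})

test_that("condition association matches the Welch t reference", {
  design <- design_default()
  th <- screen_thresholds()
  # log2 values {5.0, 5.1, 4.9, 5.05} (RANKL) vs {1.0, 1.1} (none)
  v <- c(2^1.0, 2^1.1, 2^5.0, 2^5.1, 2^4.9, 2^5.05) - 0.1
  names(v) <- design$sample_id
  res <- condition_association(v, design, th)
  expect_equal(res$p_rankl,
               welch_p(v[design$stimulation == "RANKL"],
                       v[design$stimulation == "none"]))
  expect_lt(res$p_rankl, 0.05)
  expect_true(res$associated)

  # all six identical -> degenerate variance rule
  flat <- setNames(rep(4, 6), design$sample_id)
  res0 <- condition_association(flat, design, th)
  expect_equal(res0$p_rankl, 1)
  expect_equal(res0$p_genotype, 1)
  expect_false(res0$associated)

  # genotype-only association satisfies the "either" disjunction
  vg <- setNames(c(50, 1, 50.5, 49.5, 1.1, 0.9), design$sample_id)
  resg <- condition_association(vg, design, th)
  expect_lt(resg$p_genotype, 0.05)
  expect_gt(resg$p_rankl, 0.05)
  expect_true(resg$associated)

  expect_error(condition_association(flat, design[design$genotype == "WT", ],
                                     th), "both levels")
})

test_that("RANKL-induced partition matches hand enumeration", {
  design <- design_default()
  th <- screen_thresholds()
  set.seed(21)
  m <- matrix(rlnorm(60, 2, 2), nrow = 10,
              dimnames = list(paste0("g", 1:10), design$sample_id))
  # plant clear cases among the noise
  m["g1", ] <- c(2, 2, 40, 41, 39, 40)      # induced, genotype-flat
  m["g2", ] <- c(64, 8, 80, 80, 10, 10)     # induced, WT consistently higher
  m["g3", ] <- c(40, 41, 2, 2.1, 2, 2.2)    # repressed
  res <- rankl_induced_partition(m, design, rownames(m), th)

  stim <- design$stimulation == "RANKL"
  wt_stim <- stim & design$genotype == "WT"
  ko_stim <- stim & design$genotype == "KO"
  exp_induced <- character(0); exp_wt <- character(0)
  for (g in rownames(m)) {
    v <- m[g, ]
    pr <- welch_p(v[stim], v[!stim]); pg <- welch_p(
      v[design$genotype == "WT"], v[design$genotype == "KO"])
    if (!(pr < th$alpha || pg < th$alpha)) next
    if (mean(v[stim]) > mean(v[!stim])) {
      exp_induced <- c(exp_induced, g)
      if (mean(v[wt_stim]) > mean(v[ko_stim]) && pg < th$alpha)
        exp_wt <- c(exp_wt, g)
    }
  }
  expect_equal(res$induced, exp_induced)
  expect_equal(res$wt_higher, exp_wt)
  expect_true("g2" %in% res$wt_higher)
  expect_false("g3" %in% res$induced)
})

test_that("screen cascade selects exactly the hand-computed intron set", {
  fx <- cascade_fixture()
  s <- screen_retained_introns(fx$quant, fx$fpkm, fx$design)
  calls <- s$calls

  # hand-computed: i1 IR 4.1/40.1 vs 16.1/40.1 (ratio 3.93) selected;
  # i2 fails intronic max (8); i3's gene gB max FPKM 8 fails; i4 ratio 1;
  # i5 ratio 1.99; i6 ratio 151; i7 ratio 1.17; i8 ratio 2.18
  expect_equal(calls$intron_id[calls$selected], c("i1", "i5", "i6", "i8"))
  expect_equal(calls$passed_gene_fpkm,
               c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(calls$passed_intronic_fpkm,
               c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))

  # brute-force recomputation of every flag from the raw matrices
  th <- screen_thresholds()
  stim_wt <- c("WT_RANKL_1", "WT_RANKL_2")
  stim_ko <- c("KO_RANKL_1", "KO_RANKL_2")
  for (i in seq_len(nrow(calls))) {
    id <- calls$intron_id[i]
    g <- calls$gene_id[i]
    expect_equal(calls$passed_gene_fpkm[i], max(fx$fpkm[g, ]) > 10)
    expect_equal(calls$passed_intronic_fpkm[i],
                 max(fx$quant$intronic_fpkm[id, ]) > 10)
    irs <- (fx$quant$intronic_fpkm[id, ] + 0.1) / (fx$fpkm[g, ] + 0.1)
    ratio <- mean(irs[stim_ko]) / mean(irs[stim_wt])
    expect_equal(calls$ir_ratio[i], unname(ratio))
    expect_equal(calls$selected[i],
                 calls$passed_gene_fpkm[i] && calls$passed_intronic_fpkm[i] &&
                   ratio > 1.5)
  }
  expect_equal(unname(s$funnel),
               c(8L, 7L, 6L, 4L))
})

test_that("screen requires stimulated samples of both genotypes", {
  fx <- cascade_fixture()
  no_ko <- fx$design[!(fx$design$genotype == "KO" &
                         fx$design$stimulation == "RANKL"), ]
  expect_error(screen_retained_introns(fx$quant, fx$fpkm, no_ko),
               "RANKL-stimulated")
})

test_that("threshold monotonicity: stricter ratio shrinks, looser gene floor grows", {
  fx <- cascade_fixture()
  base <- screen_retained_introns(fx$quant, fx$fpkm, fx$design)
  sel_base <- base$calls$intron_id[base$calls$selected]
  for (r in c(2, 4, 10, 200)) {
    s <- screen_retained_introns(fx$quant, fx$fpkm, fx$design,
                                 screen_thresholds(ir_ratio_min = r))
    expect_true(all(s$calls$intron_id[s$calls$selected] %in% sel_base))
  }
  lo <- screen_retained_introns(fx$quant, fx$fpkm, fx$design,
                                screen_thresholds(gene_fpkm_min = 1))
  expect_true(all(sel_base %in% lo$calls$intron_id[lo$calls$selected]))
})

test_that("null simulation (KO retention = WT) selects fewer introns at depth", {
  counts <- vapply(c(2e4, 2e5), function(depth) {
    sel <- 0
    for (seed in 1:2) {
      cfg <- sim_config(n_genes = 12, depth = depth, frac_weak = 0.5,
                        rho_ko_weak = 0.05, seed = 400 + seed)
      sim <- sim_genome(cfg)
      fs <- sim_fragments(sim)
      introns <- collapse_introns(sim$models)
      m <- gene_fpkm_matrix(sim$models, fs)
      q <- intron_quant(introns, fs, m)
      s <- screen_retained_introns(q, m, design_default())
      sel <- sel + sum(s$calls$selected)
    }
    sel
  }, numeric(1))
  expect_lte(counts[2], counts[1])
})
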