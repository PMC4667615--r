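#' Screening thresholds
#'
#' Defaults follow the published screen: a 0.1 FPKM pseudocount against
#' division by zero, a max/min expression ratio above 3 to call a gene
#' differentially expressed, condition association at P < 0.05, gene and
#' intronic FPKM floors of 10, and a KO/WT IR ratio above 1.5 to call an
#' intron preferentially retained.
#'
#' @param pseudocount FPKM pseudocount (default 0.1).
#' @param de_ratio Max/min FPKM ratio for differential expression (default 3).
#' @param alpha Association significance level (default 0.05).
#' @param gene_fpkm_min Gene max-FPKM floor (default 10).
#' @param intronic_fpkm_min Intronic FPKM floor (default 10).
#' @param ir_ratio_min KO/WT IR ratio threshold (default 1.5).
#' @return A named list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(pseudocount = 0.1, de_ratio = 3, alpha = 0.05,
                              gene_fpkm_min = 10, intronic_fpkm_min = 10,
                              ir_ratio_min = 1.5) {
  th <- list(pseudocount = pseudocount, de_ratio = de_ratio, alpha = alpha,
             gene_fpkm_min = gene_fpkm_min,
             intronic_fpkm_min = intronic_fpkm_min,
             ir_ratio_min = ir_ratio_min)
  if (any(unlist(th) <= 0)) stop("all thresholds must be strictly positive")
  if (alpha >= 1) stop("alpha must be in (0, 1)")
  structure(th, class = "screen_thresholds")
}

#' Differential-expression ratio filter
#'
#' A gene passes when the ratio of its maximum to minimum FPKM across samples
#' (each plus the pseudocount) strictly exceeds `de_ratio`.
#'
#' @param fpkm_matrix Gene FPKM matrix (genes x samples, >= 2 samples).
#' @param th A [screen_thresholds()] object.
#' @return Character vector of passing gene ids.
#' @export
de_ratio_filter <- function(fpkm_matrix, th = screen_thresholds()) {
  stopifnot(ncol(fpkm_matrix) >= 2)
  mx <- apply(fpkm_matrix, 1, max)
  mn <- apply(fpkm_matrix, 1, min)
  ratio <- (mx + th$pseudocount) / (mn + th$pseudocount)
  rownames(fpkm_matrix)[ratio > th$de_ratio]
}

# Welch two-sample t on log2(FPKM + pseudocount); degenerate variance handled:
# both groups constant -> p = 1 if the means agree, else p = 0.
.welch_log2 <- function(x, grp1, grp2, pseudocount) {
  a <- log2(x[grp1] + pseudocount)
  b <- log2(x[grp2] + pseudocount)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Association of a gene's expression with stimulation and genotype
#'
#' Welch (unequal-variance) two-sample t-tests on `log2(FPKM + pseudocount)`:
#' RANKL-stimulated vs unstimulated samples, and WT vs KO samples. A gene is
#' associated when either test falls below `alpha`.
#'
#' @param values Per-sample FPKM values for one gene, named by sample id or
#'   ordered as `design`.
#' @param design Design data.frame (see [read_design()]).
#' @param th A [screen_thresholds()] object.
#' @return List with `p_rankl`, `p_genotype`, `associated`.
#' @export
condition_association <- function(values, design, th = screen_thresholds()) {
  if (!is.null(names(values))) values <- values[design$sample_id]
  for (fac in list(design$stimulation, design$genotype))
    if (length(unique(fac)) < 2)
      stop("both levels of stimulation and genotype must be present")
  p_rankl <- .welch_log2(values, design$stimulation == "RANKL",
                         design$stimulation == "none", th$pseudocount)
  p_geno <- .welch_log2(values, design$genotype == "WT",
                        design$genotype == "KO", th$pseudocount)
  list(p_rankl = p_rankl, p_genotype = p_geno,
       associated = (p_rankl < th$alpha) || (p_geno < th$alpha))
}

#' Partition differentially expressed genes by RANKL induction and genotype
#'
#' Among differentially expressed, condition-associated genes, the induced set
#' has higher mean FPKM under stimulation than without; the `wt_higher` subset
#' additionally has higher stimulated mean in WT than in KO with genotype
#' association below `alpha`.
#'
#' @param fpkm_matrix Gene FPKM matrix.
#' @param design Design data.frame.
#' @param de_genes Genes passing [de_ratio_filter()]; must be rows of the
#'   matrix.
#' @param th A [screen_thresholds()] object.
#' @return List with character vectors `induced` and `wt_higher`.
#' @export
rankl_induced_partition <- function(fpkm_matrix, design, de_genes,
                                    th = screen_thresholds()) {
  stopifnot(all(de_genes %in% rownames(fpkm_matrix)))
  stim <- design$sample_id[design$stimulation == "RANKL"]
  unstim <- design$sample_id[design$stimulation == "none"]
  wt_stim <- design$sample_id[design$stimulation == "RANKL" &
                                design$genotype == "WT"]
  ko_stim <- design$sample_id[design$stimulation == "RANKL" &
                                design$genotype == "KO"]
  induced <- character(0); wt_higher <- character(0)
  for (g in de_genes) {
    v <- fpkm_matrix[g, ]
    assoc <- condition_association(v, design, th)
    if (!assoc$associated) next
    if (mean(v[stim]) > mean(v[unstim])) {
      induced <- c(induced, g)
      if (mean(v[wt_stim]) > mean(v[ko_stim]) && assoc$p_genotype < th$alpha)
        wt_higher <- c(wt_higher, g)
    }
  }
  list(induced = induced, wt_higher = wt_higher)
}

#' Screen for introns preferentially retained in KO samples
#'
#' The three-step cascade: (1) keep introns whose host gene has maximum FPKM
#' above `gene_fpkm_min` in at least one sample; (2) keep introns with
#' intronic FPKM above `intronic_fpkm_min` in at least one sample; (3) compute
#' the mean IR over RANKL-stimulated replicates per genotype, with the
#' pseudocount added to both FPKM terms of each per-sample IR, and select
#' introns whose KO/WT mean-IR ratio strictly exceeds `ir_ratio_min`.
#' Unstimulated samples participate only in the gene-level filter.
#'
#' @param quant An [intron_quant()] object (all six samples).
#' @param fpkm_matrix Gene FPKM matrix covering all introns' genes.
#' @param design Design data.frame; must contain RANKL-stimulated samples of
#'   both genotypes.
#' @param th A [screen_thresholds()] object.
#' @return An object of class `retention_screen`: list with `calls` (one row
#'   per intron: pass flags, IR means, ratio, `selected`), `funnel` (counts
#'   surviving each step), and `thresholds`.
#' @export
screen_retained_introns <- function(quant, fpkm_matrix, design,
                                    th = screen_thresholds()) {
  wt_stim <- design$sample_id[design$genotype == "WT" &
                                design$stimulation == "RANKL"]
  ko_stim <- design$sample_id[design$genotype == "KO" &
                                design$stimulation == "RANKL"]
  if (length(wt_stim) == 0 || length(ko_stim) == 0)
    stop("retention_screen: design must contain RANKL-stimulated samples ",
         "of both genotypes")
  introns <- quant$introns
  if (!all(introns$gene_id %in% rownames(fpkm_matrix)))
    stop("intron with gene absent from the FPKM matrix")

  gene_max <- apply(fpkm_matrix[introns$gene_id, , drop = FALSE], 1, max)
  passed_gene <- gene_max > th$gene_fpkm_min
  passed_intronic <- apply(quant$intronic_fpkm, 1, max) > th$intronic_fpkm_min

  # per-sample IR with the pseudocount on both FPKM terms, so means and the
  # KO/WT ratio are always defined
  gf <- fpkm_matrix[introns$gene_id, colnames(quant$intronic_fpkm),
                    drop = FALSE]
  ir_pc <- (quant$intronic_fpkm + th$pseudocount) / (gf + th$pseudocount)
  ir_wt <- rowMeans(ir_pc[, wt_stim, drop = FALSE])
  ir_ko <- rowMeans(ir_pc[, ko_stim, drop = FALSE])
  ir_ratio <- ir_ko / ir_wt
  passed_ratio <- ir_ratio > th$ir_ratio_min

  calls <- data.frame(
    intron_id = introns$intron_id,
    gene_id = introns$gene_id,
    ir_wt_mean = ir_wt,
    ir_ko_mean = ir_ko,
    ir_ratio = ir_ratio,
    passed_gene_fpkm = passed_gene,
    passed_intronic_fpkm = passed_intronic,
    passed_ratio = passed_ratio,
    selected = passed_gene & passed_intronic & passed_ratio,
    row.names = NULL, stringsAsFactors = FALSE)
  funnel <- c(total = nrow(calls),
              gene_fpkm = sum(calls$passed_gene_fpkm),
              intronic_fpkm = sum(calls$passed_gene_fpkm &
                                    calls$passed_intronic_fpkm),
              selected = sum(calls$selected))
  structure(list(calls = calls, funnel = funnel, thresholds = th,
                 introns = introns),
            class = "retention_screen")
}

#' @export
print.retention_screen <- function(x, ...) {
  cat("Intron retention screen\n")
  cat(sprintf("  introns considered:            %d\n", x$funnel[["total"]]))
  cat(sprintf("  gene max FPKM > %-5s          %d\n",
              paste0(x$thresholds$gene_fpkm_min, ":"),
              x$funnel[["gene_fpkm"]]))
  cat(sprintf("  + intronic FPKM > %-5s        %d\n",
              paste0(x$thresholds$intronic_fpkm_min, ":"),
              x$funnel[["intronic_fpkm"]]))
  cat(sprintf("  + KO/WT IR ratio > %-5s       %d selected\n",
              paste0(x$thresholds$ir_ratio_min, ":"),
              x$funnel[["selected"]]))
  invisible(x)
}

#' @export
summary.retention_screen <- function(object, ...) {
  sel <- object$calls[object$calls$selected, , drop = FALSE]
  cat("Selected introns:", nrow(sel), "of", nrow(object$calls), "\n")
  if (nrow(sel)) {
    sel <- sel[order(-sel$ir_ratio), ]
    print(utils::head(sel[, c("intron_id", "ir_wt_mean", "ir_ko_mean",
                              "ir_ratio")], 10), row.names = FALSE)
  }
  invisible(object)
}

#' Selected introns of a retention screen
#'
#' @param screen A `retention_screen` object.
#' @return `GRanges` of the selected introns.
#' @export
selected_introns <- function(screen) {
  screen$introns[screen$calls$selected]
}

#' Write the retention-call table
#'
#' @param screen A `retention_screen` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_retention_calls <- function(screen, path) {
  utils::write.table(screen$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
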