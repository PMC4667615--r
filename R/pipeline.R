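`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run the full intron-retention analysis
#'
#' Chains the pipeline stages: gene FPKM over union exons, per-intron
#' quantification, the retention filter cascade, acceptor scoring, the
#' retention-vs-score association, and the PTC consequence of each selected
#' intron. Inputs may be file paths (GTF/FASTA/design TSV with
#' `fragment_path` columns) or in-memory objects.
#'
#' @param annotation A `gene_models` object or GTF path.
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param design Design data.frame or TSV path; when samples are loaded from
#'   disk, `fragment_path` is resolved relative to the design file.
#' @param samples Optional list of `fragment_set` objects; when omitted they
#'   are read from the design's `fragment_path` column.
#' @param out_dir Optional output directory; when given, all result tables
#'   are written there as TSV/BED.
#' @param thresholds A [screen_thresholds()] object.
#' @param mat Acceptor position weight matrix.
#' @param respect_strand Count fragments strand-specifically.
#' @return A list of class `ir_pipeline`: `fpkm`, `quant`, `screen`,
#'   `scores`, `association`, `consequence`, `design`.
#' @export
run_pipeline <- function(annotation, genome, design, samples = NULL,
                         out_dir = NULL, thresholds = screen_thresholds(),
                         mat = acceptor_matrix(), respect_strand = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  models <- stage("annotation_model",
                  if (is.character(annotation)) parse_gtf(annotation)
                  else annotation)
  genome <- stage("annotation_model", .as_genome(genome))
  design_dir <- if (is.character(design)) dirname(design) else "."
  design <- stage("quantify",
                  if (is.character(design)) read_design(design)
                  else validate_design(design))
  if (is.null(samples)) {
    samples <- stage("quantify", {
      if (is.null(design$fragment_path))
        stop("design lacks fragment_path and no samples were given")
      lapply(seq_len(nrow(design)), function(i) {
        tm <- design$total_mapped[i]
        read_fragments_bed(
          file.path(design_dir, design$fragment_path[i]),
          design$sample_id[i], design$genotype[i], design$stimulation[i],
          design$replicate[i],
          total_mapped = if (is.null(tm) || is.na(tm)) NULL else tm)
      })
    })
  }
  introns <- stage("annotation_model", collapse_introns(models))
  fpkm_m <- stage("quantify",
                  gene_fpkm_matrix(models, samples, respect_strand))
  quant <- stage("quantify",
                 intron_quant(introns, samples, fpkm_m, respect_strand))
  screen <- stage("retention_screen",
                  screen_retained_introns(quant, fpkm_m, design, thresholds))
  scores <- stage("splice_site", score_acceptors(genome, introns, mat))
  sel <- selected_introns(screen)
  assoc <- stage("splice_site", {
    if (length(sel) == 0 || length(sel) == length(introns)) NULL
    else retention_association(scores, sel$intron_id)
  })
  cons <- stage("consequence", {
    if (length(sel)) consequence_table(models, genome, sel) else NULL
  })
  message(sprintf(
    "retention funnel: %d introns -> %d gene-FPKM-filtered -> %d intronic-FPKM-filtered -> %d selected",
    screen$funnel[["total"]], screen$funnel[["gene_fpkm"]],
    screen$funnel[["intronic_fpkm"]], screen$funnel[["selected"]]))
  res <- structure(list(fpkm = fpkm_m, quant = quant, screen = screen,
                        scores = scores, association = assoc,
                        consequence = cons, design = design),
                   class = "ir_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.ir_pipeline <- function(x, ...) {
  print(x$screen)
  if (!is.null(x$association)) print(x$association)
  invisible(x)
}

#' Write all pipeline result tables
#'
#' @param res An `ir_pipeline` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  fp <- data.frame(gene_id = rownames(res$fpkm), res$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  tsv(fp, "gene_fpkm.tsv")
  write_intron_quant(res$quant, file.path(out_dir, "intron_quant.tsv"))
  write_retention_calls(res$screen, file.path(out_dir, "retention_calls.tsv"))
  sel <- selected_introns(res$screen)
  if (length(sel))
    write_intron_bed(sel, file.path(out_dir, "selected_introns.bed"))
  tsv(res$scores, "splice_scores.tsv")
  if (!is.null(res$association)) tsv(res$association$bins, "association.tsv")
  if (!is.null(res$consequence)) tsv(res$consequence, "consequence.tsv")
  invisible(out_dir)
}
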