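#' Read a sample design table
#'
#' The design is a TSV with columns `sample_id`, `genotype` (`WT`/`KO`),
#' `stimulation` (`none`/`RANKL`), `replicate` and optionally `fragment_path`
#' and `total_mapped`.
#'
#' @param path Path to the TSV file.
#' @return data.frame with validated columns.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_design(d)
  d
}

validate_design <- function(d) {
  req <- c("sample_id", "genotype", "stimulation", "replicate")
  if (!all(req %in% names(d)))
    stop("design table must have columns: ", paste(req, collapse = ", "))
  if (!all(d$genotype %in% c("WT", "KO")))
    stop("genotype must be WT or KO")
  if (!all(d$stimulation %in% c("none", "RANKL")))
    stop("stimulation must be none or RANKL")
  key <- paste(d$genotype, d$stimulation, d$replicate)
  if (anyDuplicated(key))
    stop("(genotype, stimulation, replicate) must be unique in the design")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in design")
  invisible(d)
}

#' Construct a fragment set for one sample
#'
#' A fragment set holds one sample's aligned fragments as genomic intervals
#' (one interval per sequenced fragment) together with the total
#' mapped-fragment count used as the FPKM denominator.
#'
#' @param fragments `GRanges`, one range per fragment.
#' @param sample_id Sample identifier.
#' @param genotype `"WT"` or `"KO"`.
#' @param stimulation `"none"` or `"RANKL"`.
#' @param replicate Positive integer replicate number.
#' @param total_mapped Total mapped fragments; defaults to
#'   `length(fragments)`. May exceed it (fragments outside loaded regions).
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, sample_id, genotype = "WT",
                         stimulation = "none", replicate = 1L,
                         total_mapped = NULL) {
  stopifnot(is(fragments, "GRanges"))
  if (is.null(total_mapped)) total_mapped <- length(fragments)
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  if (total_mapped < length(fragments))
    stop("total_mapped cannot be smaller than the number of fragments loaded")
  structure(list(
    sample = list(sample_id = sample_id, genotype = genotype,
                  stimulation = stimulation, replicate = as.integer(replicate)),
    fragments = fragments,
    total_mapped = as.numeric(total_mapped)), class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set", x$sample$sample_id, "(", x$sample$genotype,
      x$sample$stimulation, "rep", x$sample$replicate, "):",
      length(x$fragments), "fragments loaded,",
      format(x$total_mapped, big.mark = ","), "total mapped\n")
  invisible(x)
}

#' Read one sample's fragments from a BED6 file
#'
#' One BED record = one sequenced fragment (for paired-end data, the outer
#' genomic span of the pair, counted once).
#'
#' @inheritParams fragment_set
#' @param path Path to the BED file.
#' @return A `fragment_set`.
#' @export
read_fragments_bed <- function(path, sample_id, genotype = "WT",
                               stimulation = "none", replicate = 1L,
                               total_mapped = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  fragment_set(GenomicRanges::granges(gr), sample_id, genotype, stimulation,
               replicate, total_mapped)
}

#' Read one sample's fragments from a paired-end BAM file
#'
#' Optional adapter for alignment files: properly paired reads are merged to
#' the outer-coordinate span of the pair and each pair is counted once as a
#' fragment. Requires the Rsamtools and GenomicAlignments packages.
#'
#' @inheritParams fragment_set
#' @param path Path to a coordinate-sorted, indexed BAM file.
#' @return A `fragment_set`.
#' @export
read_fragments_bam <- function(path, sample_id, genotype = "WT",
                               stimulation = "none", replicate = 1L,
                               total_mapped = NULL) {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
      !requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading BAM requires the GenomicAlignments and Rsamtools packages")
  pairs <- GenomicAlignments::readGAlignmentPairs(
    path, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isProperPair = TRUE)))
  gr <- GenomicRanges::granges(pairs)
  fragment_set(gr, sample_id, genotype, stimulation, replicate, total_mapped)
}

#' Count fragments overlapping each interval
#'
#' A fragment counts for an interval when it overlaps it by at least 1 bp;
#' a fragment overlapping several intervals increments each of them
#' (the `intersectBed -c` convention). Strand is ignored unless
#' `respect_strand = TRUE`. Intervals on chromosomes absent from the
#' fragment set get count 0.
#'
#' @param intervals `GRanges` of target intervals.
#' @param frags A `fragment_set` or a `GRanges` of fragments.
#' @param respect_strand Count only same-strand fragments.
#' @return Integer vector of counts, parallel to `intervals`.
#' @export
count_fragment_overlaps <- function(intervals, frags, respect_strand = FALSE) {
  gr <- if (inherits(frags, "fragment_set")) frags$fragments else frags
  GenomicRanges::countOverlaps(intervals, gr, minoverlap = 1L,
                               ignore.strand = !respect_strand)
}

#' Fragments per kilobase per million mapped fragments
#'
#' `fpkm = count * 1e9 / (length * total_mapped)`.
#'
#' @param count Fragment count(s) over the feature.
#' @param length_bp Feature length(s) in bp; must be > 0.
#' @param total_mapped Total mapped fragments in the sample; must be > 0.
#' @return Numeric FPKM value(s).
#' @export
fpkm <- function(count, length_bp, total_mapped) {
  if (any(length_bp <= 0)) stop("length_bp must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count * 1e9 / (length_bp * total_mapped)
}

#' Gene FPKM matrix over union exons
#'
#' Gene expression is the FPKM of fragments overlapping the union of the
#' gene's exons, over the union-exonic length. This is a deterministic,
#' assembly-free surrogate for transcript-assembly FPKM and equals it in
#' expectation under uniform exonic coverage.
#'
#' @param models A `gene_models` object.
#' @param samples List of `fragment_set` objects.
#' @param respect_strand Passed to [count_fragment_overlaps()].
#' @return Numeric matrix, genes x samples.
#' @export
gene_fpkm_matrix <- function(models, samples, respect_strand = FALSE) {
  stopifnot(nrow(models$genes) > 0, length(samples) > 0)
  if (any(models$genes$union_exonic_length <= 0))
    stop("gene with union_exonic_length 0")
  gene_ids <- models$genes$gene_id
  per_gene <- lapply(gene_ids, function(g)
    GenomicRanges::reduce(models$exons[models$exons$gene_id == g]))
  union_exons <- unlist(GenomicRanges::GRangesList(per_gene))
  gene_idx_of_exon <- rep(seq_along(gene_ids), times = lengths(per_gene))
  # a fragment overlapping any exon of a gene's union counts once for the gene
  m <- vapply(samples, function(s) {
    hits <- GenomicRanges::findOverlaps(union_exons, s$fragments,
                                        ignore.strand = !respect_strand)
    gidx <- gene_idx_of_exon[S4Vectors::queryHits(hits)]
    key <- gidx * (length(s$fragments) + 1) + S4Vectors::subjectHits(hits)
    gidx <- gidx[!duplicated(key)]
    cnt <- tabulate(gidx, nbins = length(gene_ids))
    fpkm(cnt, models$genes$union_exonic_length, s$total_mapped)
  }, numeric(length(gene_ids)))
  matrix(m, nrow = length(gene_ids),
         dimnames = list(gene_ids,
                         vapply(samples, function(s) s$sample$sample_id,
                                character(1), USE.NAMES = FALSE)))
}

#' Per-intron fragment counts, intronic FPKM and IR values
#'
#' Counts fragments over each intron interval per sample, converts counts to
#' intronic FPKM, and divides by the host gene's FPKM to obtain the degree of
#' intron retention (IR value). IR is undefined (`NA`) in samples where the
#' gene's FPKM is 0.
#'
#' @param introns `GRanges` of introns with `gene_id` and `intron_id`
#'   metadata columns (see [collapse_introns()]).
#' @param samples List of `fragment_set` objects.
#' @param fpkm_matrix Gene FPKM matrix from [gene_fpkm_matrix()]; every
#'   intron's gene must be a row.
#' @param respect_strand Passed to [count_fragment_overlaps()].
#' @return An object of class `intron_quant`: list with `introns` and
#'   matrices `counts`, `intronic_fpkm`, `ir` (introns x samples).
#' @export
intron_quant <- function(introns, samples, fpkm_matrix,
                         respect_strand = FALSE) {
  stopifnot(length(introns) > 0, length(samples) > 0)
  if (!all(introns$gene_id %in% rownames(fpkm_matrix)))
    stop("intron with gene absent from the FPKM matrix")
  sample_ids <- vapply(samples, function(s) s$sample$sample_id, character(1),
                       USE.NAMES = FALSE)
  counts <- vapply(samples, function(s)
    count_fragment_overlaps(introns, s, respect_strand),
    numeric(length(introns)))
  counts <- matrix(counts, nrow = length(introns),
                   dimnames = list(introns$intron_id, sample_ids))
  totals <- vapply(samples, function(s) s$total_mapped, numeric(1))
  ifpkm <- sweep(counts, 2, totals, function(cnt, tot)
    cnt * 1e9 / tot) / GenomicRanges::width(introns)
  gene_fpkm <- fpkm_matrix[introns$gene_id, sample_ids, drop = FALSE]
  ir <- ir_value(ifpkm, gene_fpkm)
  structure(list(introns = introns, counts = counts, intronic_fpkm = ifpkm,
                 ir = ir), class = "intron_quant")
}

#' @export
print.intron_quant <- function(x, ...) {
  cat("intron_quant:", length(x$introns), "introns x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' Degree of intron retention
#'
#' IR = intronic FPKM / gene FPKM. Undefined (`NA`) where the gene FPKM is 0.
#'
#' @param intronic_fpkm Intronic FPKM value(s), >= 0.
#' @param gene_fpkm Gene FPKM value(s), >= 0.
#' @return IR value(s); `NA` where `gene_fpkm == 0`.
#' @export
ir_value <- function(intronic_fpkm, gene_fpkm) {
  if (any(intronic_fpkm < 0) || any(gene_fpkm < 0))
    stop("FPKM values must be non-negative")
  out <- intronic_fpkm / gene_fpkm
  out[gene_fpkm == 0] <- NA_real_
  out
}

#' Write the intron quantification table
#'
#' @param quant An `intron_quant` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_intron_quant <- function(quant, path) {
  df <- as.data.frame.intron_quant(quant)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.intron_quant <- function(x, ...) {
  base <- data.frame(
    intron_id = x$introns$intron_id,
    gene_id = x$introns$gene_id,
    chrom = as.character(GenomicRanges::seqnames(x$introns)),
    start = GenomicRanges::start(x$introns),
    end = GenomicRanges::end(x$introns),
    strand = as.character(GenomicRanges::strand(x$introns)),
    stringsAsFactors = FALSE)
  for (s in colnames(x$counts)) {
    base[[paste0("count.", s)]] <- x$counts[, s]
    base[[paste0("ifpkm.", s)]] <- x$intronic_fpkm[, s]
    base[[paste0("ir.", s)]] <- x$ir[, s]
  }
  base
}
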