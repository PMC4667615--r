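#' Parse a GTF annotation into a set of gene models
#'
#' Reads `exon` (and optional `CDS`) features from a GTF file and groups them
#' into transcripts and genes. Coordinates follow the usual R/Bioconductor
#' convention (1-based, closed) inside [GenomicRanges::GRanges-class] objects;
#' conversion from/to the file formats happens at the I/O boundary.
#'
#' @param path Path to a GTF file. Every `exon`/`CDS` feature must carry
#'   `gene_id` and `transcript_id` attributes.
#' @return An object of class `gene_models`: a list with components
#'   \describe{
#'     \item{exons}{`GRanges` of exons with `transcript_id` and `gene_id`
#'       metadata columns, sorted by start within each transcript.}
#'     \item{cds}{data.frame with `transcript_id`, `cds_start`, `cds_end`
#'       (genomic span of the coding region; `NA` if the transcript has no
#'       CDS features).}
#'     \item{transcripts}{data.frame with `transcript_id`, `gene_id`,
#'       `chrom`, `strand` in file order.}
#'     \item{genes}{data.frame with `gene_id` and `union_exonic_length`
#'       (bp covered by the union of all exons of the gene).}
#'   }
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nfield != 9)) {
    bad <- which(keep)[which(nfield != 9)[1]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields, got ",
         nfield[which(nfield != 9)[1]])
  }
  raw <- strsplit(lines[keep], "\t", fixed = TRUE)
  starts <- as.numeric(vapply(raw, `[[`, "", 4L))
  ends <- as.numeric(vapply(raw, `[[`, "", 5L))
  if (any(is.na(starts)) || any(is.na(ends)) || any(ends < starts)) {
    bad <- which(keep)[which(is.na(starts) | is.na(ends) | ends < starts)[1]]
    stop("malformed GTF line ", bad, ": invalid start/end coordinates")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("GTF contains no exon features: ", path)
  if (anyNA(gr$gene_id) || anyNA(gr$transcript_id))
    stop("exon/CDS feature missing gene_id or transcript_id attribute")

  exons <- gr[gr$type == "exon"]
  S4Vectors::mcols(exons) <-
    S4Vectors::DataFrame(transcript_id = exons$transcript_id,
                         gene_id = exons$gene_id)
  exons <- exons[order(match(exons$transcript_id, unique(exons$transcript_id)),
                       GenomicRanges::start(exons))]
  .validate_transcript_exons(exons)

  cdsg <- gr[gr$type == "CDS"]
  tx_ids <- unique(exons$transcript_id)
  cds <- data.frame(transcript_id = tx_ids,
                    cds_start = NA_real_, cds_end = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(cdsg)) {
    agg_min <- tapply(GenomicRanges::start(cdsg), cdsg$transcript_id, min)
    agg_max <- tapply(GenomicRanges::end(cdsg), cdsg$transcript_id, max)
    idx <- match(cds$transcript_id, names(agg_min))
    cds$cds_start <- as.numeric(agg_min[idx])
    cds$cds_end <- as.numeric(agg_max[idx])
  }

  first <- !duplicated(exons$transcript_id)
  transcripts <- data.frame(
    transcript_id = exons$transcript_id[first],
    gene_id = exons$gene_id[first],
    chrom = as.character(GenomicRanges::seqnames(exons))[first],
    strand = as.character(GenomicRanges::strand(exons))[first],
    stringsAsFactors = FALSE)

  gene_ids <- unique(exons$gene_id)
  union_len <- vapply(gene_ids, function(g) {
    sum(GenomicRanges::width(GenomicRanges::reduce(exons[exons$gene_id == g])))
  }, numeric(1))
  genes <- data.frame(gene_id = gene_ids, union_exonic_length = union_len,
                      stringsAsFactors = FALSE)

  structure(list(exons = exons, cds = cds, transcripts = transcripts,
                 genes = genes),
            class = "gene_models")
}

.validate_transcript_exons <- function(exons) {
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx]
    if (length(unique(as.character(GenomicRanges::strand(e)))) != 1L ||
        length(unique(as.character(GenomicRanges::seqnames(e)))) != 1L)
      stop("transcript ", tx, ": exons on multiple chromosomes/strands")
    if (length(e) > 1L) {
      s <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
      if (any(s[-1] <= en[-length(e)]))
        stop("transcript ", tx, ": overlapping or unsorted exons")
    }
  }
  invisible(TRUE)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      length(x$exons), "exons\n")
  invisible(x)
}

#' Exons of one transcript
#'
#' @param models A `gene_models` object.
#' @param transcript_id Transcript identifier.
#' @return `GRanges` of the transcript's exons, sorted by start.
#' @export
transcript_exons <- function(models, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id]
  if (length(e) == 0L) stop("unknown transcript: ", transcript_id)
  e
}

#' Derive the introns of a transcript
#'
#' Introns are the gaps between consecutive exons. Ordinals count introns in
#' transcript (5' to 3') orientation: on the minus strand, intron 1 is the
#' gap closest to the highest genomic coordinate.
#'
#' @param exons `GRanges` of one transcript's exons (sorted, non-overlapping,
#'   single chromosome and strand), e.g. from [transcript_exons()].
#' @return `GRanges` of introns with metadata columns `gene_id` (if present on
#'   the input) and `ordinal`. A single-exon transcript yields an empty result.
#' @export
derive_introns <- function(exons) {
  stopifnot(is(exons, "GRanges"))
  exons <- exons[order(GenomicRanges::start(exons))]
  n <- length(exons)
  str <- as.character(GenomicRanges::strand(exons))[1]
  if (n < 2L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$gene_id <- character(0)
    S4Vectors::mcols(out)$ordinal <- integer(0)
    return(out)
  }
  gap_start <- GenomicRanges::end(exons)[-n] + 1L
  gap_end <- GenomicRanges::start(exons)[-1] - 1L
  if (any(gap_end < gap_start))
    stop("zero-length intron: adjacent exons abut with no gap")
  introns <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(exons))[1],
    ranges = IRanges::IRanges(gap_start, gap_end),
    strand = str)
  ord <- seq_len(n - 1L)
  if (str == "-") ord <- rev(ord)
  S4Vectors::mcols(introns)$gene_id <-
    if (!is.null(exons$gene_id)) rep(exons$gene_id[1], n - 1L)
    else rep(NA_character_, n - 1L)
  S4Vectors::mcols(introns)$ordinal <- ord
  introns
}

#' Collapse the introns of all transcripts into a unique genomic set
#'
#' The intron universe is defined on unique genomic intervals
#' (chromosome, start, end, strand), not per-transcript copies; `gene_id` and
#' `ordinal` come from the first transcript (in annotation order) that
#' contributes each intron.
#'
#' @param models A `gene_models` object.
#' @return `GRanges` of unique introns with `gene_id`, `ordinal` and an
#'   `intron_id` (`gene_id:ordinal`) metadata column.
#' @export
collapse_introns <- function(models) {
  per_tx <- lapply(unique(models$exons$transcript_id), function(tx) {
    derive_introns(models$exons[models$exons$transcript_id == tx])
  })
  per_tx <- per_tx[lengths(per_tx) > 0L]
  if (length(per_tx) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      gene_id = character(0), ordinal = integer(0), intron_id = character(0))
    return(out)
  }
  all_introns <- GenomicRanges::GRanges(
    unlist(lapply(per_tx, function(x)
      as.character(GenomicRanges::seqnames(x)))),
    IRanges::IRanges(unlist(lapply(per_tx, GenomicRanges::start)),
                     unlist(lapply(per_tx, GenomicRanges::end))),
    strand = unlist(lapply(per_tx, function(x)
      as.character(GenomicRanges::strand(x)))))
  S4Vectors::mcols(all_introns) <- S4Vectors::DataFrame(
    gene_id = unlist(lapply(per_tx, function(x) x$gene_id)),
    ordinal = unlist(lapply(per_tx, function(x) x$ordinal)))
  key <- paste(GenomicRanges::seqnames(all_introns),
               GenomicRanges::start(all_introns),
               GenomicRanges::end(all_introns),
               GenomicRanges::strand(all_introns))
  out <- all_introns[!duplicated(key)]
  S4Vectors::mcols(out)$intron_id <- paste0(out$gene_id, ":", out$ordinal)
  out
}

#' Write gene models back to GTF
#'
#' Emits one `exon` feature per exon (and `CDS` features where annotated) with
#' `gene_id`/`transcript_id` attributes, suitable for re-parsing with
#' [parse_gtf()].
#'
#' @param models A `gene_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  e <- models$exons
  lines <- sprintf(
    '%s\tirscreen\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    as.character(GenomicRanges::seqnames(e)),
    GenomicRanges::start(e), GenomicRanges::end(e),
    as.character(GenomicRanges::strand(e)),
    e$gene_id, e$transcript_id)
  cds <- models$cds[!is.na(models$cds$cds_start), , drop = FALSE]
  if (nrow(cds)) {
    tx <- models$transcripts
    idx <- match(cds$transcript_id, tx$transcript_id)
    cds_lines <- sprintf(
      '%s\tirscreen\tCDS\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      tx$chrom[idx], as.integer(cds$cds_start), as.integer(cds$cds_end),
      tx$strand[idx], tx$gene_id[idx], cds$transcript_id)
    lines <- c(lines, cds_lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an intron set as BED6
#'
#' One record per intron, `name = gene_id:ordinal`, `score = 0`, strand kept.
#'
#' @param introns `GRanges` of introns, e.g. from [collapse_introns()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intron_bed <- function(introns, path) {
  out <- introns
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    name = paste0(introns$gene_id, ":", introns$ordinal),
    score = rep(0L, length(introns)))
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
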