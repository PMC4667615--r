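#' Build the mRNA of a transcript with selected introns retained
#'
#' Concatenates the transcript's exon sequences in transcript order, inserting
#' the sequences of the retained introns at their junctions; minus-strand
#' transcripts are reverse-complemented. The CDS start offset is recomputed
#' for the retained form.
#'
#' @param models A `gene_models` object.
#' @param transcript_id Transcript to build; must have an annotated CDS.
#' @param retained Integer vector of intron ordinals (transcript orientation)
#'   to retain; may be empty for the mature form.
#' @param genome Genome as in [extract_acceptor()].
#' @return List with `mrna` (character), `cds_offset` (1-based position of
#'   the first CDS base in `mrna`), and `origin` (integer vector parallel to
#'   `mrna`: 0 for exonic bases, the intron ordinal for retained-intron
#'   bases).
#' @export
build_retained_mrna <- function(models, transcript_id, retained = integer(0),
                                genome) {
  genome <- .as_genome(genome)
  exons <- transcript_exons(models, transcript_id)
  n <- length(exons)
  str <- as.character(GenomicRanges::strand(exons))[1]
  chrom <- as.character(GenomicRanges::seqnames(exons))[1]
  cds <- models$cds[models$cds$transcript_id == transcript_id, ]
  if (nrow(cds) == 0L || is.na(cds$cds_start))
    stop("transcript ", transcript_id, " has no annotated CDS")
  retained <- as.integer(retained)
  if (length(retained) && (any(retained < 1L) || any(retained > n - 1L)))
    stop("retained intron ordinal out of range for ", transcript_id)

  introns <- derive_introns(exons)
  # pieces in genomic order: exon_1, gap_1, exon_2, ..., exon_n
  pieces <- list(); origin <- integer(0)
  gaps <- introns[order(GenomicRanges::start(introns))]
  for (i in seq_len(n)) {
    pieces <- c(pieces, list(c(GenomicRanges::start(exons)[i],
                               GenomicRanges::end(exons)[i], 0L)))
    if (i < n && gaps$ordinal[i] %in% retained)
      pieces <- c(pieces, list(c(GenomicRanges::start(gaps)[i],
                                 GenomicRanges::end(gaps)[i],
                                 gaps$ordinal[i])))
  }
  if (str == "-") pieces <- rev(pieces)
  chrseq <- genome[[chrom]]
  seqs <- character(length(pieces)); origin <- vector("list", length(pieces))
  for (j in seq_along(pieces)) {
    p <- pieces[[j]]
    s <- Biostrings::subseq(chrseq, p[1], p[2])
    if (str == "-") s <- Biostrings::reverseComplement(s)
    seqs[j] <- as.character(s)
    origin[[j]] <- rep(p[3], p[2] - p[1] + 1L)
  }
  mrna <- toupper(paste(seqs, collapse = ""))
  origin <- unlist(origin)

  # transcript coordinate of the genomic CDS start (5' end in transcript
  # orientation): cds_start on '+', cds_end on '-'
  target <- if (str == "+") cds$cds_start else cds$cds_end
  cum <- 0L; cds_offset <- NA_integer_
  for (j in seq_along(pieces)) {
    p <- pieces[[j]]
    if (target >= p[1] && target <= p[2]) {
      within <- if (str == "+") target - p[1] + 1L else p[2] - target + 1L
      cds_offset <- cum + within
      break
    }
    cum <- cum + (p[2] - p[1] + 1L)
  }
  if (is.na(cds_offset))
    stop("CDS start does not fall in an exon of ", transcript_id)
  list(mrna = mrna, cds_offset = cds_offset, origin = origin)
}

#' Reference protein of a transcript
#'
#' Translation of the mature (no retention) mRNA from the CDS start to the
#' first stop, standard nuclear genetic code.
#'
#' @inheritParams build_retained_mrna
#' @return Character string of amino-acid residues (stop not included).
#' @export
reference_protein <- function(models, transcript_id, genome) {
  m <- build_retained_mrna(models, transcript_id, integer(0), genome)
  tr <- .translate_from(m$mrna, m$cds_offset)
  tr$peptide
}

# translate from offset to the first stop (or sequence end); returns the
# peptide, the number of residues, and whether/where a stop was hit
.translate_from <- function(mrna, cds_offset) {
  sub <- substr(mrna, cds_offset, nchar(mrna))
  nc <- floor(nchar(sub) / 3) * 3
  if (nc == 0L) return(list(peptide = "", n_aa = 0L, stop_codon_index = NA))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(sub, 1L, nc)), no.init.codon = TRUE))
  stop_pos <- as.integer(regexpr("*", aa, fixed = TRUE))
  if (stop_pos > 0L) {
    list(peptide = substr(aa, 1L, stop_pos - 1L),
         n_aa = stop_pos - 1L, stop_codon_index = stop_pos)
  } else {
    list(peptide = aa, n_aa = nchar(aa), stop_codon_index = NA)
  }
}

#' Premature-termination-codon consequence of a retained-intron mRNA
#'
#' Translates the (possibly intron-retaining) mRNA from the CDS start with
#' the standard genetic code until the first stop, and compares the product
#' with the reference protein. The intact prefix is the longest common prefix
#' with the reference; residues translated beyond it before the stop are
#' novel. The stop is premature when it occurs before the reference protein's
#' natural end, and is classified by the genomic origin of its first base.
#'
#' @param mrna mRNA sequence (character), e.g. from [build_retained_mrna()].
#' @param cds_offset 1-based position of the first CDS base in `mrna`.
#' @param ref_protein Reference protein sequence (character).
#' @param origin Optional integer vector parallel to `mrna` (0 = exon,
#'   k = retained intron ordinal k); enables `stop_source` classification.
#' @return List of class `ptc_consequence`: `ptc_found`, `intact_prefix_aa`,
#'   `novel_aa`, `stop_source` (`"retained_intron"`, `"downstream_exon"` or
#'   `"none"`), `peptide`.
#' @export
find_ptc <- function(mrna, cds_offset, ref_protein, origin = NULL) {
  if (cds_offset < 1L || cds_offset > nchar(mrna))
    stop("cds_offset out of range")
  if (substr(mrna, cds_offset, cds_offset + 2L) != "ATG")
    warning("mRNA does not start with ATG at cds_offset; translating anyway")
  tr <- .translate_from(mrna, cds_offset)
  lcp <- 0L
  max_cmp <- min(tr$n_aa, nchar(ref_protein))
  if (max_cmp > 0) {
    pep <- strsplit(substr(tr$peptide, 1, max_cmp), "")[[1]]
    ref <- strsplit(substr(ref_protein, 1, max_cmp), "")[[1]]
    mismatch <- which(pep != ref)
    lcp <- if (length(mismatch)) mismatch[1] - 1L else max_cmp
  }
  ptc_found <- !is.na(tr$stop_codon_index) && tr$n_aa < nchar(ref_protein)
  stop_source <- "none"
  if (ptc_found) {
    stop_source <- "downstream_exon"
    if (!is.null(origin)) {
      first_stop_base <- cds_offset + 3L * tr$n_aa
      if (origin[first_stop_base] > 0L) stop_source <- "retained_intron"
    }
  }
  structure(list(ptc_found = ptc_found, intact_prefix_aa = lcp,
                 novel_aa = tr$n_aa - lcp, stop_source = stop_source,
                 peptide = tr$peptide),
            class = "ptc_consequence")
}

#' @export
print.ptc_consequence <- function(x, ...) {
  cat("PTC consequence:",
      if (x$ptc_found) "premature stop" else "no premature stop", "\n")
  cat("  intact prefix:", x$intact_prefix_aa, "aa; novel:", x$novel_aa,
      "aa; stop source:", x$stop_source, "\n")
  invisible(x)
}

#' PTC consequences for a set of retained introns
#'
#' For each intron, finds a transcript of its gene that contains the intron,
#' builds the single-intron-retaining mRNA and computes the consequence
#' against that transcript's reference protein.
#'
#' @param models A `gene_models` object.
#' @param genome Genome as in [extract_acceptor()].
#' @param introns `GRanges` of introns with `intron_id`/`gene_id` columns
#'   (e.g. [selected_introns()] output).
#' @return data.frame with one row per intron: `intron_id`, `transcript_id`,
#'   `retained_ordinal`, `ptc_found`, `intact_prefix_aa`, `novel_aa`,
#'   `stop_source`.
#' @export
consequence_table <- function(models, genome, introns) {
  genome <- .as_genome(genome)
  rows <- lapply(seq_along(introns), function(i) {
    intr <- introns[i]
    res <- data.frame(intron_id = intr$intron_id,
                      transcript_id = NA_character_,
                      retained_ordinal = NA_integer_, ptc_found = NA,
                      intact_prefix_aa = NA_integer_, novel_aa = NA_integer_,
                      stop_source = NA_character_, stringsAsFactors = FALSE)
    txs <- models$transcripts$transcript_id[
      models$transcripts$gene_id == intr$gene_id]
    for (tx in txs) {
      if (is.na(models$cds$cds_start[models$cds$transcript_id == tx])) next
      tx_introns <- derive_introns(transcript_exons(models, tx))
      hit <- which(GenomicRanges::start(tx_introns) ==
                     GenomicRanges::start(intr) &
                   GenomicRanges::end(tx_introns) == GenomicRanges::end(intr))
      if (length(hit) != 1L) next
      ord <- tx_introns$ordinal[hit]
      m <- build_retained_mrna(models, tx, ord, genome)
      ref <- reference_protein(models, tx, genome)
      ptc <- find_ptc(m$mrna, m$cds_offset, ref, m$origin)
      res$transcript_id <- tx
      res$retained_ordinal <- ord
      res$ptc_found <- ptc$ptc_found
      res$intact_prefix_aa <- ptc$intact_prefix_aa
      res$novel_aa <- ptc$novel_aa
      res$stop_source <- ptc$stop_source
      break
    }
    res
  })
  do.call(rbind, rows)
}
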