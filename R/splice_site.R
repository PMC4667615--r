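#' Default acceptor-site position weight table
#'
#' Per-position base weights for the 15-base 3' splice-site (acceptor)
#' context: the last 14 intronic bases (positions -14..-1, the polypyrimidine
#' tract, then the invariant AG) followed by the first exonic base (+1).
#' The consensus is `TTTTTTTTTTTCAG/G` ("/" marks the intron/exon junction)
#' and at every position the consensus base carries the strictly maximal
#' weight, so only the consensus 15-mer reaches a score of 100.
#'
#' Values are percent-style base frequencies in the style of the classic
#' mammalian acceptor-site statistics (pyrimidine-dominated tract, C/T at -3,
#' near-invariant AG at -2/-1, G preferred at +1); they are a package-defined
#' table, editable via the `mat` argument of [score_acceptor()].
#'
#' @return 15 x 4 numeric matrix; rows are positions `-14..-1, +1`, columns
#'   `A`, `C`, `G`, `T`. Attribute `provenance` labels the table.
#' @export
acceptor_matrix <- function() {
  w <- matrix(c(
    10, 28, 14, 48,  # -14
     9, 30, 13, 48,  # -13
     9, 30, 12, 49,  # -12
     8, 31, 12, 49,  # -11
     8, 32, 11, 49,  # -10
     8, 33, 10, 49,  #  -9
     9, 33, 10, 48,  #  -8
     9, 34,  9, 48,  #  -7
     8, 35,  9, 48,  #  -6
     8, 34,  8, 50,  #  -5
    10, 30,  8, 52,  #  -4
    25, 40,  4, 31,  #  -3  branch-distal Y position: C > T
    96,  2,  1,  1,  #  -2  invariant A
     1,  1, 97,  1,  #  -1  invariant G
    25, 15, 45, 15   #  +1  first exonic base
  ), ncol = 4, byrow = TRUE,
  dimnames = list(c(paste0("-", 14:1), "+1"), c("A", "C", "G", "T")))
  attr(w, "provenance") <- "irscreen default mammalian acceptor weights v1"
  .validate_acceptor_matrix(w)
  w
}

acceptor_consensus <- function() "TTTTTTTTTTTCAGG"

.validate_acceptor_matrix <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != 15L ||
      !identical(colnames(mat), c("A", "C", "G", "T")))
    stop("acceptor matrix must be 15 x 4 with columns A, C, G, T")
  if (any(mat < 0)) stop("acceptor matrix weights must be non-negative")
  cons <- strsplit(acceptor_consensus(), "")[[1]]
  for (i in seq_len(15L)) {
    ci <- mat[i, cons[i]]
    if (any(mat[i, setdiff(colnames(mat), cons[i])] >= ci))
      stop("acceptor matrix: consensus base must be strictly maximal at ",
           "position ", rownames(mat)[i])
  }
  invisible(mat)
}

#' Extract the 3' splice-site context of an intron
#'
#' Returns the 15-base acceptor context in transcript orientation: the last
#' 14 intronic bases followed by the first base of the downstream exon. On
#' the minus strand, bases come from the genomic start side of the intron and
#' are reverse-complemented.
#'
#' @param genome A named [Biostrings::DNAStringSet] (names = chromosomes) or
#'   a FASTA file path.
#' @param intron A length-1 `GRanges` intron (width >= 14, with 1 bp of
#'   downstream exon available on the chromosome).
#' @return List with `sequence` (15-character string) and `valid_ag`
#'   (positions -2/-1 are `AG`).
#' @export
extract_acceptor <- function(genome, intron) {
  genome <- .as_genome(genome)
  stopifnot(is(intron, "GRanges"), length(intron) == 1L)
  if (GenomicRanges::width(intron) < 14L)
    stop("intron shorter than 14 bp: acceptor context undefined")
  chrom <- as.character(GenomicRanges::seqnames(intron))
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  chrlen <- Biostrings::width(genome[chrom])
  s <- GenomicRanges::start(intron); e <- GenomicRanges::end(intron)
  str <- as.character(GenomicRanges::strand(intron))
  if (str == "+") {
    if (e + 1L > chrlen) stop("no downstream exonic base within chromosome")
    seq <- Biostrings::subseq(genome[[chrom]], e - 13L, e + 1L)
  } else {
    if (s - 1L < 1L) stop("no downstream exonic base within chromosome")
    seq <- Biostrings::reverseComplement(
      Biostrings::subseq(genome[[chrom]], s - 1L, s + 13L))
  }
  sq <- toupper(as.character(seq))
  list(sequence = sq, valid_ag = substr(sq, 13L, 14L) == "AG")
}

.as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*", "", names(genome))
  genome
}

#' Score an acceptor context against the consensus
#'
#' The raw score is the sum of per-position weights of the observed bases;
#' it is rescaled to 0-100 between the per-position minimum and maximum
#' sums, so the consensus sequence scores exactly 100. Sequences without AG
#' at positions -2/-1 are not acceptors and get no score, as do sequences
#' containing `N`.
#'
#' @param sequence A 15-character acceptor context (see [extract_acceptor()]),
#'   or the list that function returns.
#' @param mat Position weight matrix (default [acceptor_matrix()]).
#' @return List with `score` (0-100, or `NA`), `valid_ag`, and `reason`
#'   (`"ok"`, `"no_ag"`, or `"ambiguous_base"`).
#' @export
score_acceptor <- function(sequence, mat = acceptor_matrix()) {
  .validate_acceptor_matrix(mat)
  if (is.list(sequence)) sequence <- sequence$sequence
  sequence <- toupper(sequence)
  if (nchar(sequence) != 15L)
    stop("acceptor context must be exactly 15 bases")
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T", "N")))
    stop("acceptor context contains a non-nucleotide character")
  valid_ag <- substr(sequence, 13L, 14L) == "AG"
  if (!valid_ag)
    return(list(score = NA_real_, valid_ag = FALSE, reason = "no_ag"))
  if (any(bases == "N"))
    return(list(score = NA_real_, valid_ag = TRUE, reason = "ambiguous_base"))
  s <- sum(mat[cbind(seq_len(15L), match(bases, colnames(mat)))])
  smin <- sum(apply(mat, 1, min)); smax <- sum(apply(mat, 1, max))
  list(score = 100 * (s - smin) / (smax - smin), valid_ag = TRUE,
       reason = "ok")
}

#' Score the acceptors of an intron set
#'
#' Applies [extract_acceptor()] and [score_acceptor()] to each intron;
#' invalid contexts (short intron, non-AG, ambiguous base) are recorded with
#' their reason and the run continues.
#'
#' @param genome Genome as in [extract_acceptor()].
#' @param introns `GRanges` of introns with an `intron_id` metadata column.
#' @param mat Position weight matrix.
#' @return data.frame with `intron_id`, `sequence`, `valid`, `reason`,
#'   `score`.
#' @export
score_acceptors <- function(genome, introns, mat = acceptor_matrix()) {
  genome <- .as_genome(genome)
  .validate_acceptor_matrix(mat)
  n <- length(introns)
  out <- data.frame(intron_id = introns$intron_id,
                    sequence = NA_character_, valid = FALSE,
                    reason = NA_character_, score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ctx <- tryCatch(extract_acceptor(genome, introns[i]),
                    error = function(e) conditionMessage(e))
    if (is.character(ctx)) {
      out$reason[i] <- ctx
      next
    }
    sc <- score_acceptor(ctx$sequence, mat)
    out$sequence[i] <- ctx$sequence
    out$valid[i] <- sc$reason == "ok"
    out$reason[i] <- sc$reason
    out$score[i] <- sc$score
  }
  out
}

#' Score plain 15-mer acceptor sequences
#'
#' Convenience for user-supplied contexts (e.g. GAG- vs TTT-type minigene
#' acceptors), one sequence per element or per line of a text file.
#'
#' @param seqs Character vector of 15-mers, or a path to a text file with one
#'   sequence per line.
#' @param mat Position weight matrix.
#' @return data.frame with `sequence`, `valid`, `reason`, `score`.
#' @export
score_acceptor_seqs <- function(seqs, mat = acceptor_matrix()) {
  if (length(seqs) == 1L && file.exists(seqs)) seqs <- readLines(seqs)
  seqs <- seqs[nzchar(seqs)]
  res <- lapply(seqs, function(s)
    tryCatch(score_acceptor(s, mat),
             error = function(e) list(score = NA_real_, valid_ag = FALSE,
                                      reason = conditionMessage(e))))
  data.frame(sequence = toupper(seqs),
             valid = vapply(res, function(r) r$reason == "ok", logical(1)),
             reason = vapply(res, function(r) r$reason, character(1)),
             score = vapply(res, function(r) r$score, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Association between intron retention and acceptor strength
#'
#' One-sided Wilcoxon rank-sum test of the hypothesis that retained introns
#' have lower acceptor scores than unretained introns, plus the retained
#' fraction per fixed-width score bin.
#'
#' @param scores data.frame from [score_acceptors()] (only rows with
#'   `valid = TRUE` are used).
#' @param retained Character vector of retained `intron_id`s; must be a
#'   non-empty strict subset of the scored introns.
#' @param bin_width Score bin width (default 10).
#' @return An object of class `acceptor_association`: list with `p_value`
#'   (one-sided, retained lower), `n_retained`, `n_unretained`, `bins`
#'   (data.frame: bin, n, n_retained, retained_fraction), and the two score
#'   vectors.
#' @export
retention_association <- function(scores, retained, bin_width = 10) {
  sc <- scores[scores$valid & !is.na(scores$score), , drop = FALSE]
  is_ret <- sc$intron_id %in% retained
  if (!any(is_ret)) stop("no retained intron among the scored introns")
  if (all(is_ret)) stop("no unretained intron among the scored introns")
  r <- sc$score[is_ret]; u <- sc$score[!is_ret]
  # ties at scale force the normal approximation; the warning is expected
  p <- suppressWarnings(
    stats::wilcox.test(r, u, alternative = "less")$p.value)
  breaks <- seq(0, 100, by = bin_width)
  bin <- cut(sc$score, breaks = breaks, include.lowest = TRUE, right = FALSE)
  bins <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    n_retained = as.integer(table(bin[is_ret])),
    stringsAsFactors = FALSE)
  bins$retained_fraction <- ifelse(bins$n > 0, bins$n_retained / bins$n, NA)
  structure(list(p_value = p, n_retained = length(r),
                 n_unretained = length(u), bins = bins,
                 retained_scores = r, unretained_scores = u),
            class = "acceptor_association")
}

#' @export
print.acceptor_association <- function(x, ...) {
  cat("Retention vs 3' splice-site score\n")
  cat(sprintf("  retained: %d (median score %.1f)\n",
              x$n_retained, stats::median(x$retained_scores)))
  cat(sprintf("  unretained: %d (median score %.1f)\n",
              x$n_unretained, stats::median(x$unretained_scores)))
  cat(sprintf("  one-sided rank-sum P = %.3g (retained lower)\n", x$p_value))
  invisible(x)
}

#' @export
plot.acceptor_association <- function(x, ...) {
  graphics::barplot(x$bins$retained_fraction, names.arg = x$bins$bin,
                    las = 2, ylab = "retained fraction",
                    xlab = "3' splice-site score bin", ...)
  invisible(x)
}
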