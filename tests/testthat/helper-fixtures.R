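# Shared fixtures and independent oracles for the test suite.

library(GenomicRanges)

# quadratic all-pairs overlap oracle (1-based closed intervals)
oracle_count_overlaps <- function(intervals, frags) {
  vapply(seq_along(intervals), function(i) {
    s <- start(intervals)[i]; e <- end(intervals)[i]
    sum(start(frags) <= e & end(frags) >= s)
  }, numeric(1))
}

# a tiny two-gene GTF on one chromosome; returns the file path
write_toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  lines <- c(
    'chr1\ttoy\texon\t101\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\ttoy\texon\t301\t400\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\ttoy\texon\t101\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
    'chr1\ttoy\texon\t301\t400\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
    'chr1\ttoy\texon\t501\t560\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
    'chr1\ttoy\texon\t1001\t1100\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";',
    'chr1\ttoy\texon\t1301\t1400\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";',
    'chr1\ttoy\texon\t1601\t1700\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";')
  writeLines(lines, path)
  path
}

# random small annotation built directly as a gene_models object, plus the
# per-transcript exon list for brute-force checks
random_models <- function(n_genes = 3, max_tx = 3, seed = 1) {
  set.seed(seed)
  exon_rows <- list()
  for (g in seq_len(n_genes)) {
    gid <- paste0("g", g)
    strand <- sample(c("+", "-"), 1)
    n_tx <- sample.int(max_tx, 1)
    # exon boundaries on a 10 kb gene body, shared pool so transcripts can
    # share introns
    starts_pool <- sort(sample(seq(1, 9000, by = 20), 6))
    for (t in seq_len(n_tx)) {
      n_ex <- sample(2:4, 1)
      st <- sort(sample(starts_pool, n_ex))
      en <- st + sample(10:15, n_ex, replace = TRUE)
      # enforce non-overlap
      ok <- c(TRUE, st[-1] > en[-n_ex])
      st <- st[ok]; en <- en[ok]
      if (length(st) < 1) next
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        chrom = paste0("chr", g), start = st + (g - 1) * 10000,
        end = en + (g - 1) * 10000, strand = strand,
        transcript_id = paste0(gid, ".t", t), gene_id = gid,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, exon_rows)
  exons <- GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                   strand = df$strand)
  mcols(exons) <- S4Vectors::DataFrame(transcript_id = df$transcript_id,
                                       gene_id = df$gene_id)
  exons <- exons[order(match(exons$transcript_id,
                             unique(exons$transcript_id)), start(exons))]
  first <- !duplicated(exons$transcript_id)
  gene_ids <- unique(exons$gene_id)
  structure(list(
    exons = exons,
    cds = data.frame(transcript_id = unique(exons$transcript_id),
                     cds_start = NA_real_, cds_end = NA_real_,
                     stringsAsFactors = FALSE),
    transcripts = data.frame(
      transcript_id = exons$transcript_id[first],
      gene_id = exons$gene_id[first],
      chrom = as.character(seqnames(exons))[first],
      strand = as.character(strand(exons))[first],
      stringsAsFactors = FALSE),
    genes = data.frame(
      gene_id = gene_ids,
      union_exonic_length = vapply(gene_ids, function(gi)
        sum(width(GenomicRanges::reduce(exons[exons$gene_id == gi]))),
        numeric(1)),
      stringsAsFactors = FALSE)), class = "gene_models")
}

# hand fixture for the screen cascade: intron_quant-shaped object and FPKM
# matrix with written-out values (see test-screen.R for the hand-computed
# expectations)
cascade_fixture <- function() {
  samples <- design_default()$sample_id
  gene_fpkm <- rbind(
    gA = rep(40, 6), gB = rep(8, 6), gC = rep(100, 6),
    gD = c(0, 0, 50, 50, 50, 50), gE = rep(20, 6))
  colnames(gene_fpkm) <- samples
  ifpkm <- rbind(
    i1 = c(0, 0, 4, 4, 16, 16),
    i2 = rep(8, 6),
    i3 = rep(12, 6),
    i4 = c(0, 0, 30, 30, 30, 30),
    i5 = c(0, 0, 10, 10, 20, 20),
    i6 = c(0, 0, 0, 0, 15, 15),
    i7 = c(0, 0, 12, 12, 14, 14),
    i8 = c(0, 0, 5, 5, 11, 11))
  colnames(ifpkm) <- samples
  intron_gene <- c(i1 = "gA", i2 = "gA", i3 = "gB", i4 = "gC", i5 = "gC",
                   i6 = "gD", i7 = "gD", i8 = "gE")
  introns <- GRanges("chr1",
                     IRanges::IRanges(seq(1000, by = 1000,
                                          length.out = 8), width = 200),
                     strand = "+")
  mcols(introns) <- S4Vectors::DataFrame(
    gene_id = unname(intron_gene), ordinal = rep(1L, 8),
    intron_id = names(intron_gene))
  counts <- round(ifpkm)  # counts only carried along, not used by the screen
  quant <- structure(list(introns = introns, counts = counts,
                          intronic_fpkm = ifpkm,
                          ir = ifpkm / gene_fpkm[unname(intron_gene), ]),
                     class = "intron_quant")
  list(quant = quant, fpkm = gene_fpkm, design = design_default())
}

# small simulation shared by several tests
small_sim <- function(seed = 101, depth = 1e5, n_genes = 15, ...) {
  cfg <- sim_config(n_genes = n_genes, depth = depth, seed = seed, ...)
  sim <- sim_genome(cfg)
  list(cfg = cfg, sim = sim)
}
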