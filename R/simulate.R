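#' Simulation configuration
#'
#' Parameters of the synthetic RNA-seq experiment the package uses for
#' end-to-end testing: a six-sample design (one unstimulated and two
#' RANKL-stimulated replicates per genotype), 101-bp paired-end sequencing
#' summarized as ~300-bp outer fragment spans, a subset of RANKL-induced
#' genes, and knockout-specific retention concentrated in weak-acceptor
#' (GAG-type) introns.
#'
#' @param n_genes Number of simulated genes.
#' @param exons_per_gene Range (min, max) of exons per gene.
#' @param exon_length Range of exon lengths (bp).
#' @param intron_length Range of intron lengths (bp); min must be >= 20 so
#'   the acceptor context is extractable.
#' @param frac_induced Fraction of genes induced by RANKL stimulation.
#' @param induction_fold Expression fold change of induced genes under
#'   stimulation.
#' @param frac_weak Fraction of introns carrying a weak (GAG-type) acceptor.
#' @param rho_wt Retention fraction of every intron in WT samples.
#' @param rho_ko_weak,rho_ko_strong Retention fraction of weak/strong
#'   acceptor introns in KO samples.
#' @param depth Expected mapped fragments per sample.
#' @param fragment_length Outer genomic span of one sequenced fragment (bp).
#' @param multi_intron If `TRUE`, introns are retained independently per
#'   molecule (multi-intron isoforms); default is single-intron retention
#'   isoforms.
#' @param seed Mandatory integer seed; all simulator randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100, exons_per_gene = c(4, 6),
                       exon_length = c(200, 400),
                       intron_length = c(1500, 5000),
                       frac_induced = 0.2, induction_fold = 5,
                       frac_weak = 0.1, rho_wt = 0.05, rho_ko_weak = 0.25,
                       rho_ko_strong = 0.05, depth = 1e6,
                       fragment_length = 300, multi_intron = FALSE, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  fracs <- c(frac_induced, frac_weak, rho_wt, rho_ko_weak, rho_ko_strong)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (any(c(exon_length, intron_length, fragment_length, depth) < 0) ||
      any(exon_length <= 0) || n_genes < 1)
    stop("lengths and depth must be positive")
  if (intron_length[1] < 20)
    stop("minimum intron length must be >= 20 bp")
  if (exon_length[1] < 10) stop("minimum exon length must be >= 10 bp")
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 frac_induced = frac_induced,
                 induction_fold = induction_fold, frac_weak = frac_weak,
                 rho_wt = rho_wt, rho_ko_weak = rho_ko_weak,
                 rho_ko_strong = rho_ko_strong, depth = depth,
                 fragment_length = as.integer(fragment_length),
                 multi_intron = isTRUE(multi_intron),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' The six-sample study design
#'
#' One unstimulated sample per genotype and two RANKL-stimulated replicates
#' per genotype.
#'
#' @return Design data.frame (see [read_design()]).
#' @export
design_default <- function() {
  data.frame(
    sample_id = c("WT_none_1", "KO_none_1", "WT_RANKL_1", "WT_RANKL_2",
                  "KO_RANKL_1", "KO_RANKL_2"),
    genotype = c("WT", "KO", "WT", "WT", "KO", "KO"),
    stimulation = c("none", "none", "RANKL", "RANKL", "RANKL", "RANKL"),
    replicate = c(1L, 1L, 1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE)
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

# sample() treats a length-1 vector as 1:x; guard degenerate ranges
.sample_range <- function(range, n) {
  v <- seq(range[1], range[2])
  if (length(v) == 1L) rep(v, n) else sample(v, n, replace = TRUE)
}

.random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# 14 intronic acceptor bases; weak acceptors carry GAG in place of the
# pyrimidine tract at -6..-4 (the Aire-intron-2-like configuration), strong
# ones the canonical T-rich tract. Only the four distal tract positions get
# mild C/T noise, so scores vary within a class but the weak class stays
# strictly below the strong class under the default weight table.
.plant_acceptor14 <- function(class) {
  tract <- c(sample(c("T", "C"), 4, replace = TRUE, prob = c(0.7, 0.3)),
             rep("T", 4))
  core <- if (class == "weak") c("G", "A", "G") else c("T", "T", "T")
  paste(c(tract, core, "C", "A", "G"), collapse = "")
}

#' Generate a synthetic genome, annotation and ground truth
#'
#' Each gene sits on its own chromosome with 200-bp flanks. The CDS spans all
#' exons (ATG ... single natural stop), every intron starts with `GT` and
#' ends with a planted 14-base acceptor, and the last exon base after each
#' intron completes the 15-base acceptor context. Deterministic for a seed.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `sim_genome`: `genome`
#'   ([Biostrings::DNAStringSet]), `models` (`gene_models`), `truth_genes`
#'   and `truth_introns` data.frames, and internal gene structures used by
#'   [sim_fragments()].
#' @export
sim_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  flank <- 200L
  chroms <- character(cfg$n_genes)
  seqs <- character(cfg$n_genes)
  exon_rows <- list(); cds_rows <- list(); tx_rows <- list()
  truth_genes <- list(); truth_introns <- list(); structures <- list()

  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("gene%03d", g)
    tx_id <- paste0(gene_id, ".t1")
    chrom <- sprintf("chr%03d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_ex <- .sample_range(cfg$exons_per_gene, 1L)
    ex_len <- .sample_range(cfg$exon_length, n_ex)
    ex_len[n_ex] <- ex_len[n_ex] + (3L - sum(ex_len) %% 3L) %% 3L
    in_len <- if (n_ex > 1L)
      .sample_range(cfg$intron_length, n_ex - 1L) else integer(0)

    total_cds <- sum(ex_len)
    n_codons <- total_cds / 3L - 2L
    codons <- paste0(sample(.BASES, n_codons, TRUE),
                     sample(.BASES, n_codons, TRUE),
                     sample(.BASES, n_codons, TRUE))
    bad <- codons %in% .STOPS
    while (any(bad)) {
      codons[bad] <- paste0(sample(.BASES, sum(bad), TRUE),
                            sample(.BASES, sum(bad), TRUE),
                            sample(.BASES, sum(bad), TRUE))
      bad <- codons %in% .STOPS
    }
    cds_seq <- paste0("ATG", paste(codons, collapse = ""), "TAA")
    ex_seq <- substring(cds_seq, cumsum(c(1L, ex_len[-n_ex])),
                        cumsum(ex_len))

    classes <- character(0); acc14 <- character(0); in_seq <- character(0)
    if (n_ex > 1L) {
      classes <- ifelse(stats::runif(n_ex - 1L) < cfg$frac_weak,
                        "weak", "strong")
      # single-intron isoforms need per-gene retention fractions summing to
      # <= 1; redraw the class vector when the draw is infeasible
      if (!cfg$multi_intron) {
        for (try in seq_len(100L)) {
          rho_ko_g <- ifelse(classes == "weak", cfg$rho_ko_weak,
                             cfg$rho_ko_strong)
          if (sum(rho_ko_g) <= 1) break
          classes <- ifelse(stats::runif(n_ex - 1L) < cfg$frac_weak,
                            "weak", "strong")
        }
      }
      acc14 <- vapply(classes, .plant_acceptor14, character(1))
      in_seq <- vapply(seq_len(n_ex - 1L), function(j)
        paste0("GT", .random_dna(in_len[j] - 16L), acc14[j]), character(1))
    }

    # pre-mRNA in transcript orientation: e1 i1 e2 i2 ... en
    pieces <- character(2L * n_ex - 1L)
    pieces[seq(1L, 2L * n_ex - 1L, by = 2L)] <- ex_seq
    if (n_ex > 1L) pieces[seq(2L, 2L * n_ex - 2L, by = 2L)] <- in_seq
    pre <- paste(pieces, collapse = "")
    L_pre <- nchar(pre)
    pre_len <- nchar(pieces)
    pre_off <- cumsum(c(1L, pre_len[-length(pre_len)]))  # 1-based starts

    chrom_seq <- paste0(.random_dna(flank),
                        if (strand == "+") pre else
                          as.character(Biostrings::reverseComplement(
                            Biostrings::DNAString(pre))),
                        .random_dna(flank))
    chroms[g] <- chrom; seqs[g] <- chrom_seq

    # genomic coordinates (1-based closed) of each transcript piece
    to_genomic <- function(a, b) {
      if (strand == "+") c(flank + a, flank + b)
      else c(flank + L_pre - b + 1L, flank + L_pre - a + 1L)
    }
    ex_idx <- seq(1L, 2L * n_ex - 1L, by = 2L)
    ex_g <- t(vapply(ex_idx, function(i)
      to_genomic(pre_off[i], pre_off[i] + pre_len[i] - 1L), numeric(2)))
    exon_rows[[g]] <- data.frame(chrom = chrom, start = ex_g[, 1],
                                 end = ex_g[, 2], strand = strand,
                                 transcript_id = tx_id, gene_id = gene_id,
                                 stringsAsFactors = FALSE)
    cds_rows[[g]] <- data.frame(transcript_id = tx_id,
                                cds_start = min(ex_g), cds_end = max(ex_g),
                                stringsAsFactors = FALSE)
    tx_rows[[g]] <- data.frame(transcript_id = tx_id, gene_id = gene_id,
                               chrom = chrom, strand = strand,
                               stringsAsFactors = FALSE)

    base_expr <- stats::rlnorm(1L, meanlog = 0, sdlog = 0.7)
    induced <- stats::runif(1L) < cfg$frac_induced
    truth_genes[[g]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                   strand = strand, base_expr = base_expr,
                                   induced = induced,
                                   stringsAsFactors = FALSE)
    if (n_ex > 1L) {
      in_idx <- seq(2L, 2L * n_ex - 2L, by = 2L)
      in_g <- t(vapply(in_idx, function(i)
        to_genomic(pre_off[i], pre_off[i] + pre_len[i] - 1L), numeric(2)))
      # acceptor 15-mer = planted 14 intronic bases + first base of next exon
      next_exon_first <- substring(ex_seq[-1L], 1L, 1L)
      rho_ko <- ifelse(classes == "weak", cfg$rho_ko_weak, cfg$rho_ko_strong)
      truth_introns[[g]] <- data.frame(
        intron_id = paste0(gene_id, ":", seq_len(n_ex - 1L)),
        gene_id = gene_id, ordinal = seq_len(n_ex - 1L), chrom = chrom,
        start = in_g[, 1], end = in_g[, 2], strand = strand,
        class = classes, acceptor = paste0(acc14, next_exon_first),
        rho_wt = cfg$rho_wt, rho_ko = rho_ko, stringsAsFactors = FALSE)
    }
    structures[[gene_id]] <- list(
      gene_id = gene_id, chrom = chrom, strand = strand, flank = flank,
      L_pre = L_pre, n_ex = n_ex, ex_len = ex_len, in_len = in_len,
      pre_off = pre_off, pre_len = pre_len)
  }

  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  exon_df <- do.call(rbind, exon_rows)
  exons <- GenomicRanges::GRanges(exon_df$chrom,
                                  IRanges::IRanges(exon_df$start,
                                                   exon_df$end),
                                  strand = exon_df$strand)
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
    transcript_id = exon_df$transcript_id, gene_id = exon_df$gene_id)
  exons <- exons[order(match(exons$transcript_id,
                             unique(exons$transcript_id)),
                       GenomicRanges::start(exons))]
  genes_df <- do.call(rbind, truth_genes)
  union_len <- vapply(genes_df$gene_id, function(gi)
    sum(GenomicRanges::width(GenomicRanges::reduce(
      exons[exons$gene_id == gi]))), numeric(1))
  models <- structure(list(
    exons = exons,
    cds = do.call(rbind, cds_rows),
    transcripts = do.call(rbind, tx_rows),
    genes = data.frame(gene_id = genes_df$gene_id,
                       union_exonic_length = union_len,
                       stringsAsFactors = FALSE)), class = "gene_models")

  structure(list(genome = genome, models = models,
                 truth_genes = genes_df,
                 truth_introns = do.call(rbind, truth_introns),
                 structures = structures, config = cfg),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", nrow(x$truth_genes), "genes,",
      nrow(x$truth_introns), "introns (",
      sum(x$truth_introns$class == "weak"), "weak acceptors ), seed",
      x$config$seed, "\n")
  invisible(x)
}

# transcript-orientation pieces of the isoform retaining intron ordinals
# `kept` (integer vector, possibly empty): matrix with columns iso_start,
# pre_start, len
.isoform_pieces <- function(st, kept) {
  idx <- seq(1L, 2L * st$n_ex - 1L, by = 2L)  # exon piece indices
  if (length(kept)) idx <- sort(c(idx, 2L * kept))
  len <- st$pre_len[idx]
  cbind(iso_start = cumsum(c(1L, len[-length(len)])),
        pre_start = st$pre_off[idx], len = len)
}

#' Simulate per-sample fragment alignments with known retention truth
#'
#' For each gene and sample, the fragment count is Poisson with mean
#' proportional to sequencing depth times relative expression (induced genes
#' get `induction_fold` under RANKL). Fragments are assigned to isoforms so
#' that a fraction rho of the gene's molecules retain each intron in the
#' sample's genotype (fragment sampling is isoform-length weighted, matching
#' uniform fragmentation of the molecule pool); fragment starts are uniform
#' along the chosen isoform and each fragment is written as its outer genomic
#' span (no split records).
#'
#' @param sim A [sim_genome()] object.
#' @param design Design data.frame; needs at least one RANKL-stimulated
#'   sample per genotype. Default [design_default()].
#' @return List of `fragment_set` objects, one per design row, with
#'   `total_mapped` equal to the realized fragment count.
#' @export
sim_fragments <- function(sim, design = design_default()) {
  stopifnot(inherits(sim, "sim_genome"))
  validate_design(design)
  for (geno in c("WT", "KO"))
    if (!any(design$genotype == geno & design$stimulation == "RANKL"))
      stop("design must include a RANKL-stimulated ", geno, " sample")
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  truth_in <- sim$truth_introns
  genes <- sim$truth_genes
  out <- vector("list", nrow(design))

  for (s in seq_len(nrow(design))) {
    stim <- design$stimulation[s] == "RANKL"
    geno <- design$genotype[s]
    w <- genes$base_expr * ifelse(genes$induced & stim,
                                  cfg$induction_fold, 1)
    mu <- cfg$depth * w / sum(w)
    n_g <- stats::rpois(nrow(genes), mu)
    acc_chrom <- list(); acc_start <- list(); acc_end <- list()
    acc_strand <- list()

    for (g in seq_len(nrow(genes))) {
      if (n_g[g] == 0L) next
      st <- sim$structures[[genes$gene_id[g]]]
      ti <- truth_in[truth_in$gene_id == genes$gene_id[g], , drop = FALSE]
      rho <- if (nrow(ti))
        (if (geno == "KO") ti$rho_ko else ti$rho_wt) else numeric(0)

      if (cfg$multi_intron && length(rho)) {
        # independent retention per intron per molecule
        kept_list <- lapply(seq_len(n_g[g]), function(i)
          which(stats::runif(length(rho)) < rho))
        key <- vapply(kept_list, paste, character(1), collapse = ",")
        groups <- split(seq_len(n_g[g]), key)
        iso_sets <- lapply(groups, function(ii) kept_list[[ii[1]]])
        iso_counts <- lengths(groups)
      } else {
        if (sum(rho) > 1)
          stop("per-gene retention fractions sum above 1; single-intron ",
               "isoforms are infeasible (use multi_intron = TRUE)")
        L_mat <- sum(st$ex_len)
        iso_len <- c(L_mat, L_mat + (if (length(rho)) st$in_len else NULL))
        mol_frac <- c(1 - sum(rho), rho)
        p <- mol_frac * iso_len
        cnt <- as.vector(stats::rmultinom(1L, n_g[g], p))
        iso_sets <- c(list(integer(0)),
                      lapply(seq_along(rho), function(k) k))
        iso_counts <- cnt
      }

      for (v in seq_along(iso_sets)) {
        nv <- iso_counts[v]
        if (nv == 0L) next
        pieces <- .isoform_pieces(st, iso_sets[[v]])
        L_iso <- sum(pieces[, "len"])
        f <- min(cfg$fragment_length, L_iso)
        a <- sample.int(L_iso - f + 1L, nv, replace = TRUE)
        b <- a + f - 1L
        ia <- findInterval(a, pieces[, "iso_start"])
        ib <- findInterval(b, pieces[, "iso_start"])
        pre_a <- pieces[ia, "pre_start"] + (a - pieces[ia, "iso_start"])
        pre_b <- pieces[ib, "pre_start"] + (b - pieces[ib, "iso_start"])
        if (st$strand == "+") {
          gs <- st$flank + pre_a; ge <- st$flank + pre_b
        } else {
          gs <- st$flank + st$L_pre - pre_b + 1L
          ge <- st$flank + st$L_pre - pre_a + 1L
        }
        k <- length(acc_chrom) + 1L
        acc_chrom[[k]] <- rep(st$chrom, nv)
        acc_start[[k]] <- gs; acc_end[[k]] <- ge
        acc_strand[[k]] <- rep(st$strand, nv)
      }
    }
    gr <- GenomicRanges::GRanges(
      unlist(acc_chrom, use.names = FALSE) %||% character(0),
      IRanges::IRanges(unlist(acc_start, use.names = FALSE) %||% integer(0),
                       unlist(acc_end, use.names = FALSE) %||% integer(0)),
      strand = unlist(acc_strand, use.names = FALSE) %||% character(0))
    out[[s]] <- fragment_set(gr, design$sample_id[s], design$genotype[s],
                             design$stimulation[s], design$replicate[s],
                             total_mapped = max(length(gr), 1))
  }
  names(out) <- design$sample_id
  out
}

#' Write a simulation to disk
#'
#' Writes `genome.fa`, `annotation.gtf`, `design.tsv`, one BED6 file per
#' sample and the two ground-truth tables (`truth_genes.tsv`,
#' `truth_introns.tsv`).
#'
#' @param sim A [sim_genome()] object.
#' @param frag_sets List of `fragment_set` objects from [sim_fragments()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
sim_write <- function(sim, frag_sets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"),
                              width = 70L)
  write_gtf(sim$models, file.path(dir, "annotation.gtf"))
  design <- do.call(rbind, lapply(frag_sets, function(fs)
    data.frame(sample_id = fs$sample$sample_id,
               genotype = fs$sample$genotype,
               stimulation = fs$sample$stimulation,
               replicate = fs$sample$replicate,
               fragment_path = paste0(fs$sample$sample_id, ".bed"),
               total_mapped = fs$total_mapped, stringsAsFactors = FALSE)))
  utils::write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (fs in frag_sets) {
    gr <- fs$fragments
    bed <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                      GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                      paste0("frag", seq_along(gr)), 0L,
                      as.character(GenomicRanges::strand(gr)))
    utils::write.table(bed,
                       file.path(dir, paste0(fs$sample$sample_id, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.table(sim$truth_genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth_introns, file.path(dir, "truth_introns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
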