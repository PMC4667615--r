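---
title: "Screening for genotype-dependent intron retention"
author: "irscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for genotype-dependent intron retention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irscreen)
```

## The problem

Loss of the dioxygenase Jmjd6 in thymic stroma leaves some transcripts with
unspliced introns. A retained intron typically shifts the reading frame or
carries an in-frame stop, so the affected allele produces a truncated
protein — for *Aire*, retention of intron 2 introduces a premature
termination codon (PTC) that removes everything downstream of the N-terminal
region. Introns that respond this way tend to have *weak acceptors*: instead
of the canonical pyrimidine-rich tract upstream of the 3' terminal AG, they
carry purines (a GAG in the *Aire* case), so they depend more strongly on
auxiliary splicing factors.

`irscreen` reimplements, as a reusable and fully testable pipeline, the
computational side of that analysis:

1. quantify per-intron retention from aligned RNA-seq fragment intervals,
2. screen for introns preferentially retained in knockout (KO) samples under
   stimulation,
3. score each intron's 3' splice site against the acceptor consensus and test
   whether retained introns have weaker acceptors,
4. predict the PTC consequence of retaining an intron,
5. simulate fragment data with known ground truth so that every stage can be
   validated end to end.

## The retention statistic

For a feature of length $L$ bp covered by $c$ fragments in a sample with $N$
mapped fragments,

$$\mathrm{FPKM} = \frac{c \cdot 10^9}{L \cdot N}.$$

Gene expression uses the union of the gene's exons (assembly-free; equal in
expectation to transcript-assembly FPKM under uniform exonic coverage).
Intronic FPKM uses the raw intron interval, counting any fragment that
overlaps it by at least 1 bp — the `intersectBed -c` convention; fragments
overlapping both exon and intron count for both, and introns are *not*
masked against exons of other isoforms. The degree of intron retention is

$$\mathrm{IR} = \frac{\text{intronic FPKM}}{\text{gene FPKM}},$$

undefined where the gene is silent. Under uniform coverage IR estimates the
fraction of the gene's transcripts that retain the intron.

## The screen

`screen_retained_introns()` applies three filters, each a strict inequality
("more than"), with defaults taken from the published screen:

| parameter | default | meaning |
|---|---|---|
| `pseudocount` | 0.1 FPKM | added to both FPKM terms to avoid division by 0 |
| `de_ratio` | 3 | max/min FPKM ratio calling a gene differentially expressed |
| `alpha` | 0.05 | significance level for condition association |
| `gene_fpkm_min` | 10 FPKM | gene must exceed this in at least one sample |
| `intronic_fpkm_min` | 10 FPKM | intron must exceed this in at least one sample |
| `ir_ratio_min` | 1.5 | KO/WT mean-IR ratio calling an intron retained |

The cascade: (1) keep introns of well-expressed genes; (2) keep introns with
appreciable intronic signal; (3) select introns whose KO/WT IR ratio, with
means taken over RANKL-stimulated replicates, exceeds 1.5. Unstimulated
samples inform only the gene-level filters — the selection itself is defined
under stimulation. Per-sample IR values inside the screen use the
pseudocount on both FPKM terms, which makes every mean and ratio defined;
this is the one place the screen deviates from the raw IR definition, and it
matters only for silent genes and empty introns. No multiple-testing
correction is applied, matching the original single-threshold design.

The gene-level differential-expression utilities (`de_ratio_filter()`,
`condition_association()`, `rankl_induced_partition()`) mirror the upstream
expression analysis. The association test is a Welch two-sample *t* on
$\log_2(\mathrm{FPKM} + 0.1)$, testing stimulation (4 vs 2) and genotype
(3 vs 3) separately and flagging a gene associated when either *P* falls
below `alpha`. The original work did not name its test; Welch's *t* is the
simplest location test valid for these unbalanced, heteroscedastic splits.
When both groups are constant with equal means the *P*-value is defined as
1 (and 0 when constant but different), which keeps all-zero genes out of the
associated set without special-casing.

## Acceptor strength

The 3' splice-site context is 15 bases: the last 14 intronic bases
(polypyrimidine tract, then the near-invariant AG) plus the first exonic
base, with consensus `TTTTTTTTTTTCAG/G`. `score_acceptor()` sums
per-position weights of the observed bases and rescales between the
per-position minimum and maximum sums:

$$S = 100 \cdot \frac{\sum_i w_i(b_i) - S_{\min}}{S_{\max} - S_{\min}},$$

so exactly the consensus scores 100 and every single-base departure scores
strictly less. The shipped weight table (`acceptor_matrix()`) is a
package-defined, percent-style frequency table in the style of the classic
mammalian acceptor statistics; the tool used in the original analysis does
not publish its matrix, so numeric equality with it is not claimed —
correctness here is defined by the invariants (consensus maximality,
monotonicity under substitution, the 0–100 range), all of which are tested.
Sequences without AG at positions −2/−1 are rejected as non-acceptors
rather than scored low, and any `N` in the window suppresses the score.

`retention_association()` compares retained vs unretained scores with a
one-sided Wilcoxon rank-sum test (retained lower) and reports the retained
fraction per fixed-width decile bin — the tabular form of the published
score-vs-retention figure.

## PTC consequence

`build_retained_mrna()` splices the transcript with a chosen set of introns
retained and recomputes the CDS offset; `find_ptc()` translates with the
standard nuclear code until the first stop. "Intact" residues are the
longest common prefix with the reference protein — a deliberate,
well-defined operationalization that sidesteps the question of whether a
junction-spanning codon that happens to agree with the reference counts.
The stop is classified by the genomic origin of its first base
(`retained_intron` vs `downstream_exon`). No NMD-efficiency prediction is
attempted.

## The simulator

`sim_genome()` + `sim_fragments()` emulate the study design: six samples —
one unstimulated and two RANKL-stimulated replicates per genotype — with
101-bp paired-end sequencing represented as one ~300-bp outer fragment span
per sequenced fragment. Defaults: 100 genes (each on its own chromosome),
4–6 exons of 200–400 bp, introns of 1,500–5,000 bp (the mouse genome's
typical intron scale), 20% RANKL-induced genes at fold 5, 10% weak-acceptor
introns, retention fractions $\rho_{\mathrm{WT}} = 0.05$ everywhere,
$\rho_{\mathrm{KO}} = 0.25$ for weak and $0.05$ for strong introns, and
$10^6$ fragments per sample.

Key modelling choices:

* **Acceptor planting.** Weak introns end in a GAG-at-tract acceptor
  (`...GAGCAG`), strong ones in the canonical `...TTTCAG`; only the four
  distal tract positions receive C/T noise, so scores vary within a class
  while the weak class stays strictly below the strong class under the
  default matrix — the class separation is guaranteed by construction, which
  the association tests rely on.
* **Single-intron isoforms.** By default a molecule retains at most one
  intron, so the per-gene retention fractions must sum to at most 1; the
  generator redraws a gene's acceptor classes when a draw violates this,
  and `multi_intron = TRUE` switches to independent per-intron retention
  (reaching double-retention molecules such as the *Aire* intron 2+9 forms).
* **Length-weighted fragment assignment.** $\rho$ is a *molecule* fraction;
  fragments are assigned to isoforms with probability proportional to
  $\rho \cdot L_{\text{isoform}}$, which is what uniform fragmentation of
  the molecule pool produces and what makes $E[\mathrm{IR}] \approx \rho$.
* **Poisson counts.** Fragment counts per gene are Poisson at mean
  depth × relative expression; the screen has no variance model to stress,
  so overdispersion is deliberately omitted.
* **Outer-span projection.** Fragments are written as their outer genomic
  span, never as split records, matching the interval-counting consumer.
  This is also the simulator's main deliberate artifact: a *mature*-isoform
  fragment whose ends fall in flanking exons projects across the intron and
  inflates the intronic count by roughly $(1-\rho)\,f/L_i$ for fragment
  span $f$ and intron length $L_i$. The KO/WT IR *ratio* is largely immune
  (the bias enters both terms), which is why the screen tolerates it; the
  absolute-IR recovery checks use long introns ($f \ll L_i$, 40–60 kb) where
  the artifact is negligible, exactly the regime in which IR is claimed to
  estimate $\rho$.

What the simulator does **not** model: sequencing error, mappability,
multi-mapping, positional coverage bias, library-strand effects, and
overdispersed biological replication. Passing tests therefore demonstrate
the pipeline's correctness and calibration under its own assumptions, not
robustness to alignment artifacts in real data.

## Problem sizes and numerical choices

The validation suite simulates at the study's per-sample depth ($10^6$
fragments) with 100-gene genomes — a deliberate desk-scale stand-in for a
transcriptome, sized so a full 20-seed screen scenario completes in a few
minutes. Sensitivity/specificity of the screen are aggregated over 20 seeds
(10 in the acceptance script); IR recovery uses two-exon genes so that
$\rho$ is a per-gene quantity and single-intron isoforms are always
feasible. All randomness flows from one seed per simulation; identical
seed and configuration give byte-identical FASTA/GTF/BED/TSV outputs.
Ties in the rank-sum test switch `wilcox.test` to its normal approximation,
which is the intended behaviour at genome scale; the exact distribution is
used automatically for small tie-free comparisons.

The published funnel (188,208 introns → 84,708 in expressed genes → 1,051
with intronic FPKM > 10 → 57 selected; *Aire* intron-2 ratio 1.9; 103
intact residues) depends on the deposited sequencing data and a specific
genome annotation, neither of which ships with this package, so those
numbers are not asserted anywhere; the pipeline reproduces the *shape* of
that analysis and reports its own funnel on any input.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 20, depth = 2e5, seed = 42)
sim <- sim_genome(cfg)
frags <- sim_fragments(sim)
res <- run_pipeline(sim$models, sim$genome, design_default(),
                    samples = frags)
print(res)
summary(res$screen)
plot(res$association)
```

## Known limitations

* Union-exon FPKM understates expression for genes whose dominant isoform
  is much shorter than the exon union.
* The IR ratio uses means over two stimulated replicates per genotype with
  no variance model; with real (overdispersed) replicates the 1.5 threshold
  has no controlled error rate, as in the original screen.
* Interval counting with outer-span fragments inflates absolute IR for
  short introns (see above); compare IR *ratios*, not absolute IR, when
  introns are short relative to the fragment span.
* The acceptor score is a position-weight sum; it does not model branch
  points, donor sites, or higher-order dependencies.
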