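# ohnoscope

Post-whole-genome-duplication (WGD) ohnolog analysis for haploid microbial
eukaryote genomes, built around the case of a facultative coral symbiont
assayed free-living and in hospite at ambient (28°C) and elevated (34°C)
temperature.

## What it does, and for whom

After a WGD every gene starts out in two copies ("ohnologs"). What natural
selection then does with those copies — purging, retention, expression
divergence, splicing divergence, pathway-level retention — is the central
question for anyone studying polyploidy in unicellular eukaryotes. This
package implements the full analysis chain a genome paper in that area
needs, against plain-text inputs (GFF3-like gene tables, FASTA, BLAST
tabular hits, TSV count matrices):

* **Collinear gene blocks** — dynamic-programming chaining of filtered
  homology anchors over gene-rank coordinates. A block is at least
  *k* = 5 genes conserved in order and orientation; blocks within one
  genome are the classical evidence for segmental duplication/WGD.
* **Duplicate classification** — every gene becomes `singleton`,
  `dispersed` (partner > 20 genes away), `proximal` (≤ 20 genes),
  `tandem` (adjacent) or `wgd_segmental` (block anchor), with the standard
  precedence.
* **Ka/Ks** — Nei–Gojobori (NG86) counting on codon alignments with
  Jukes–Cantor correction,
  `Ks = -3/4 · ln(1 - 4/3 · ps)`, a node-averaged Ks distribution
  (average-linkage consolidation within homologous clusters), and Gaussian
  mixture modelling of that distribution with AIC model selection
  (`AIC = 2(3k-1) - 2·logL`, k ≤ 4) — a low-Ks component is the WGD peak.
* **Expression divergence** — a self-contained negative-binomial GLM with
  Cox–Reid dispersion estimation and trend shrinkage tests four contrasts
  (symbiotic vs free-living at each temperature, L-28/L-34; 34 vs 28°C in
  each lifestyle, T-Fr/T-Sy; DE when FDR < 0.01 and |log2FC| > 1).
  Expressed ohnolog pairs (both copies ≥ 10 counts in ≥ 50% of samples)
  are classified into five groups: 1 neither DE, 2 one copy DE, 3 both DE
  same contrast and direction, 4 both DE in disjoint contrasts, 5 both DE
  in the same contrast with opposing direction.
* **Expression specificity** — the τ index over the four condition means
  on the log2(FPKM+1) scale, `τ = Σ(1 - x_i/x_max)/(N-1)`, 0 = broad,
  1 = single-condition; with Kruskal–Wallis/Wilcoxon class comparisons and
  chi-square + post-hoc residual preference tests.
* **Splicing** — exon counting bins (flattened at every exon boundary),
  a quasi-binomial score test of differential exon usage with gene-level
  Benjamini–Hochberg correction, 300-bp splice-junction flank extraction,
  junction conservation by dual-flank local alignment (E ≤ 1e-5), binary
  junction profiles, Kendall tau-b and an exact binomial divergence test.
* **Pathway retention** — enzymes uniquely retained as ohnologs vs
  singletons per pathway against the genome background (one-sided Fisher
  + BH), with the ≥ 5-enzyme and both-isolates reporting rules.
* **Synthetic data** — `simulate_wgd_genome()` and
  `simulate_expression()` generate a post-WGD genome and a
  lifestyle×temperature experiment with known ground truth (planted
  ohnolog pairs, Ks peak, group labels, τ-specific genes, exon-usage
  shifts, junction conservation), so every stage is testable end to end.

## Worked example

```r
library(ohnoscope)
report <- run_pipeline(list(seed = 3,
                            simulate = list(genome = list(n_ancestral_genes = 120))))
print(report)
```

```
ohnoscope pipeline report
  collinearity: 4 blocks, 208 genes in blocks (88.89%), 104 ohnolog pairs
  divergence: 104 pairs, median Ks = 0.194, GMM k = 2
  expression: 104 expressed pairs; groups 1-5: 48/39/5/11/1
  splicing: mean conserved junction fraction = 0.800
  pathways: 6 tested, 0 significant
```

Reading this: the simulated 120-gene genome was duplicated and 88.89% of
its genes fall in collinear blocks, yielding 104 detected ohnolog pairs
(the simulation retained 85% of duplicated copies). Their synonymous
divergence sits at the planted recent-WGD peak (median Ks 0.194; the
mixture model separates the WGD component, mean 0.197, from a minor older
background component near 1.0). Of the expressed pairs, 39 show DE in one
copy only (group 2) and 1 shows opposing DE (group 5), matching the
planted composition; 80% of splice junctions are conserved within pairs,
as planted.

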