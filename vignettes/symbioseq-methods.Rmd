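---
title: "Models and methods behind symbioseq"
author: "symbioseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind symbioseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbioseq)
```

# Scope

symbioseq implements the downstream statistics of a dual RNA-Seq study of
a protist host carrying an intracellular bacterial symbiont: host
differential expression and GO enrichment, symbiont expression
classification with COG and pangenome-partition enrichment,
rarefaction-based depth assessment, pangenome core/soft-core refinement,
Alien-Index screening for horizontal gene transfer (HGT), operon
colocation, and concatenated-supermatrix preparation. Everything upstream
of per-gene tables — read processing, quantification, genome annotation,
pangenome partition inference, homology searching, alignment and
trimming, tree inference — is deliberately out of scope; the package
consumes those tools' standard outputs.

# Host differential expression

## Model

Counts for gene $g$ in sample $j$ are modelled as negative binomial with
mean $s_j \mu_{g,c(j)}$ and dispersion $\alpha_g$, where $s_j$ is a
sample size factor and $c(j)$ the sample's condition. The size factors
are median-of-ratios: the reference profile is the geometric mean across
samples over genes positive in every sample, and $s_j$ is the median
ratio to it. When no gene is positive everywhere (heavily zero-inflated
input) the code falls back to total-count scaling with a warning.

The per-gene dispersion is a method-of-moments estimate from the pooled
within-group variance $s^2_g$ of normalized counts,
$\hat\alpha_g = \max\{(s^2_g - \bar\mu_g)/\bar\mu_g^2,\ 0.01\}$. The
floor of 0.01 prevents near-Poisson variance estimates from producing
overconfident tests at three replicates per group. No shrinkage towards a
mean-dispersion trend is attempted: with a planted-truth generator the
cost of the simpler estimator is measurable, and at the study's design
point (3 vs 3, moderate dispersion) it is small.

The log2 fold change contrasts the symbiont-positive condition against
the symbiont-negative reference with a pseudo-count,
$\mathrm{LFC}_g = \log_2\frac{\bar\mu_{g,+} + 0.5}{\bar\mu_{g,-} + 0.5}$.
The pseudo-count of 0.5 normalized counts keeps fold changes finite and
damped at very low expression; it slightly attenuates fold changes, which
is conservative with respect to the $|\mathrm{LFC}| > 1$ gate.

The Wald statistic uses the NB mean–variance relation on the log scale,
$\mathrm{SE}^2 = \sum_{c \in \{+,-\}} \frac{1/(\bar\mu_{g,c}+0.5) +
\hat\alpha_g}{n_c}$. The statistic is referred to a $t$ distribution with
$n_+ + n_- - 2$ degrees of freedom rather than the normal: with the
dispersion estimated from four residual degrees of freedom, the normal
reference visibly inflates the null rejection rate, while the $t$
reference keeps it close to nominal (about 0.04 at a nominal 0.05 in the
package's null simulations, comfortably inside the accepted
$[0.01, 0.10]$ band) without costing power at the planted effect sizes
(power 1.0 at $|\mathrm{LFC}| = 3$, mean 500, dispersion 0.05).

Genes with zero counts in every sample carry no information; they get
$p = 1$, $\mathrm{LFC} = 0$, and are excluded from the BH correction so
they do not dilute it.

## Calling

DEGs require FDR-adjusted $p < .05$ **and** $|\mathrm{LFC}| > 1$, both
strict inequalities as printed conventions go; `up` means higher in the
symbiont-positive strain. Note one deliberate interface decision: the
package accepts integer counts, the statistically canonical input for an
NB test, even though published workflows sometimes feed TPM values into
count-based tools. Supplying rounded TPMs works mechanically but mixes
two normalizations; raw counts are recommended.

# GO enrichment at fixed hierarchy levels

The ontology is restricted to `is_a` edges of a go-basic-style OBO file;
`part_of` and other relationships are ignored, and obsolete terms are
dropped at parse time. The *level* of a term is its shortest-path
distance from the namespace root (root = 0). This matches the common
tooling convention; a longest-path rule is available as a switch
(`rule = "longest"`) for users who prefer it, since flat "level"
language is genuinely ambiguous.

Annotations are flattened to a fixed level $L \in \{3, 4\}$: a term at
level $L$ represents itself, a deeper term is replaced by **all** of its
level-$L$ ancestors, and terms shallower than $L$ contribute nothing.
Mapping deeper terms up (rather than discarding everything not natively
at level $L$) retains the information carried by specific annotations; a
strict-native mode (`mode = "native"`) is provided because the
alternative reading is defensible. Genes left without a mapped term drop
out, and a gene with $k$ mapped terms is treated as $k$ separate counting
units — the expanded rows are the units in every 2×2 table.

Each regulation direction × namespace × level combination is one
independent enrichment call: a one-sided (greater) Fisher exact test per
term and one BH correction across the terms of that call. Only
over-representation is scored. Graph-aware decorrelation (elim/weight
algorithms) is intentionally not implemented: the classical method
treats terms independently, and that is what the flattened-level design
expects.

# Symbiont expression analysis

TPM is computed as $\mathrm{tpm}_i = 10^6 (c_i/\ell_i) / \sum_j
(c_j/\ell_j)$ from counts and effective lengths, so the vector sums to
$10^6$ and $\mathrm{tpm} = 0 \iff c = 0$. Replicates are merged by
summing counts, then TPM is recomputed on the merged vector — the
analysis design when no per-condition contrast exists for the symbiont.

Classification is two-tiered: *active* means strictly $\mathrm{tpm} >
0$; active genes are split at the 25th/75th percentiles of the active
genes' TPMs (linear interpolation between order statistics at
$h = (n-1)q + 1$). "Above"/"below" are strict, so values exactly at a
threshold fall to *moderate*. Percentiles are computed over active genes
only, because the stratification is a statement about the
transcriptionally active fraction.

Enrichment runs per classification: for activity the foregrounds are the
active and inactive sets against all annotated genes; for expression
level the foregrounds are the three strata against the **active**
annotated genes only — genes with $\mathrm{tpm} = 0$ are excluded from
that background, so a category carried only by silent genes can never
appear in an expression-level result. COG runs consider only genes with
at least one letter and expand multi-letter genes into one unit per
letter; pangenome runs use the single refined partition label per gene.
Each foreground × category-system pair is one Fisher/BH call.

## Rarefaction

The expected number of distinct genes at subsampled depth $m$ from
per-gene read counts $n_i$ (total $N$) is the exact hypergeometric
expectation $E[S(m)] = \sum_i \left(1 - \binom{N - n_i}{m} /
\binom{N}{m}\right)$, computed through `vegan::rarefy`; a Monte-Carlo
mode subsamples reads without replacement and reports mean ± SD. The
curve operates on gene-assigned read counts — if only TPMs are
available they are rounded back to counts with a warning, which is an
approximation.

Sequencing depth is judged *adequate* when the relative gain in expected
detected genes over the final depth step is below 1%. The 1% default is
the package's own choice of "the curve has flattened"; no numeric
criterion is standard, and the threshold is exposed (`relGain`). The
synthetic generator reproduces the qualitative decision pattern of
merging replicates: shallow replicates fail the check individually while
their merge passes.

# Pangenome refinement and genome quality

The upstream partition tool's labels (persistent/shell/cloud) are
consumed, not re-inferred — the only statistic added here is the
refinement: persistent families present in **all** genomes are `core`,
remaining persistent families `soft_core`; shell and cloud pass through.
Any annotated member counts as presence (fragmented genes are not
distinguished; the input matrix does not carry that information). A
non-persistent family present everywhere is passed through with a
warning, as it usually signals an upstream labelling oddity. Genomes
enter the analysis only if strictly above 80% complete single-copy and
strictly below 2% duplicated reference orthologs.

# Alien Index

From taxon-labelled homology hits (tabular format "6 std staxids"; a
semicolon-separated multi-taxid subject counts as ingroup if *any* of
its taxa is in the ingroup set), each query's best ingroup and best
outgroup E-values are extracted, a missing side defaulting to $E = 1$,
and

$$\mathrm{AI} = \ln(E_{\mathrm{in}} + 10^{-200}) -
               \ln(E_{\mathrm{out}} + 10^{-200}).$$

The natural log and the $10^{-200}$ pseudo-count are fixed constants of
the published index definition, bounding AI to roughly $\pm 460.5$.
Candidates are called strictly at $\mathrm{AI} > 45$. No taxa are
excluded by default (no excluded-genome pool), so recent transfers from
close relatives remain detectable; an optional exclusion set and an
optional self-hit filter exist but are off by default. Expanding the
ingroup taxid to its taxonomic descendants is the caller's
responsibility — the package takes an explicit id set and does not ship
a taxonomy database.

Colocation of candidates is summarized as maximal runs of set members
consecutive in the annotated gene order (no intervening annotated gene,
never spanning contigs), with per-block strand patterns — the signature
of an operon-like six-gene block being five genes on one strand and the
sixth adjacent on the other.

# Supermatrix preparation

Organisms occurring in fewer than three gene alignments are discarded
(exactly three is kept). Genes are concatenated in lexicographic order —
the one deterministic choice when no order is specified — with `-`
gap-fill for missing organism × gene cells and a 1-based inclusive
`GENE = start-end` partition table. Organism matching is exact-string;
naming variants should be reconciled upstream or via renamed FASTA
headers.

# The synthetic-data generator

The generator defines the study conditions under which the package is
validated, and its defaults mirror the emulated design:

* host: 5000 genes (desk-scale stand-in for a ciliate macronuclear
  genome an order of magnitude larger), 2 conditions × 3 replicates,
  log-normal baseline means (meanlog $\log 200$, sdlog 1), NB dispersion
  0.05, library-size multipliers in $[0.8, 1.25]$, 10% DEGs at planted
  $|\mathrm{LFC}| = 3$ split evenly up/down;
* ontology: a 42-term, three-namespace toy DAG with levels 0–4 and
  multi-parent terms, one level-3 biological-process term planted at 10×
  frequency among up-regulated genes;
* symbiont: 1755 genes of which 378 are planted inactive (so the active
  fraction is 1377/1755 ≈ 78.5%), log-normal TPM targets, three
  replicates of 150 000 multinomially sampled reads, one COG letter
  planted at 4× among active genes, and partitions leaning conserved for
  active genes and cloud for inactive ones, realized exactly in a
  13-genome presence/absence matrix (plus eight decoy genomes that fail
  the quality filter);
* HGT: six planted genes, consecutive on one contig with strand pattern
  `+++++-`, receiving only strong outgroup hits (best $E \le 10^{-60}$)
  and at most weak ingroup hits, which guarantees planted
  $\mathrm{AI} > 45$; vertical genes always have ingroup best $E \le$
  outgroup best $E$, hence $\mathrm{AI} \le 0$;
* alignments: six biotin-pathway-like protein alignments over twelve
  organisms, two of which carry fewer than three genes.

One global seed fans out to fixed per-stage substreams, so a stage can
be regenerated independently and every emitted file is byte-identical
across reruns. The generator writes every format the pipeline reads
(TSV, OBO, GFF3, FASTA, 13-column hit tables) plus a ground-truth JSON.

What the generator does **not** emulate: read-level sequencing noise and
mapping ambiguity, rRNA carry-over, correlated GO term structure beyond
the toy DAG, compositional coupling between host and symbiont libraries,
and realistic E-value distributions. Passing tests therefore demonstrate
correctness of the statistics under the stated generative model, not
robustness to every artefact of real libraries.

# Numerical conventions and degenerate inputs

* All threshold comparisons follow the printed conventions strictly:
  $p_{\mathrm{adj}} < .05$, $|\mathrm{LFC}| > 1$, TPM $> 0$, strictly
  above/below percentiles, $\mathrm{AI} > 45$, fewer than three genes
  discarded, $> 80\%$ / $< 2\%$ genome quality.
* One BH family per enrichment call; ties are handled by the step-up
  minimum, no extra tie-breaking.
* Degenerate odds ratios ($0 \cdot d$ and $b \cdot c$ both zero, e.g.
  foreground equal to background) are reported as 1.
* Empty foregrounds return empty results with a warning rather than
  erroring, so batch loops over classifications do not abort.
* Quantiles use type-7 interpolation; constant vectors place every value
  in the moderate stratum.
* All-zero genes: excluded from BH in the DEG stage; rejected outright
  in TPM computation (TPM undefined).

# Problem sizes used in the test suite

The suite validates oracle equivalences exhaustively at small $n$ (all
2×2 tables with total ≤ 12; all read subsets for totals ≤ 12) and runs
the seeded recovery checks at the design points stated above (2500-gene
power run, 2000-gene null run, full-size default pipeline for the
determinism check). The complete suite and the acceptance script each
run in a few minutes on one CPU.

# Known limitations

* The DEG test has no dispersion shrinkage, independent filtering or
  LFC moderation; at very low replication or very low counts it is
  conservative relative to fully moderated pipelines.
* GO enrichment treats flattened terms independently; correlated terms
  at one level can share signal.
* The rarefaction unit is the gene-assigned read count, not raw read
  identity.
* The Alien Index uses best-hit E-values only; it is a screen, not a
  phylogenetic verification, and downstream single-gene trees remain
  the confirmatory step.
* Exact-string organism matching in the concatenation stage is a
  deliberate simplicity; a mapping table handles naming variants.
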