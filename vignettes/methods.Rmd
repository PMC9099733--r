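---
title: "Methods: diversity and structure analysis of pooled DArTseq panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity and structure analysis of pooled DArTseq panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartpool)
```

`dartpool` analyses biallelic SNP panels genotyped on *pooled* cultivar
samples: each gene-bank accession is represented by DNA bulked from several
seedlings of a (largely self-pollinating, hence mostly inbred) cultivar. A
"heterozygous" call therefore usually signals *within-accession
heterogeneity* — a mixed seed lot — rather than an individual heterozygote.
This vignette documents the statistical methods, the synthetic-data model
used for testing, and the numerical choices.

## Input model and filtering

The reader `read_dartseq_tworow()` parses the two-row codominant dialect:
each locus occupies two consecutive CSV rows (presence of the reference and
of the alternate allele), so per accession

* (1, 0) → dosage 0 (reference homozygote),
* (0, 1) → dosage 2,
* (1, 1) → dosage 1 (both alleles in the pool),
* (0, 0) → missing.

`filter_loci()` applies three criteria in one pass and in a fixed order —
reproducibility (`RepAvg`), call rate, then minor allele frequency — so each
removed locus is attributed to the *first* criterion it fails. Removal uses
the strict inequality `metric < threshold`; boundary values are kept. The
defaults are 0.95, 0.95 and 0.01.

## Per-locus diversity statistics

With alternate-allele frequency $p$ estimated from $n$ non-missing
(diploid-coded) samples:

* PIC (biallelic form): $1 - p^2 - (1-p)^2$, maximal at 0.5;
* observed heterozygosity $H_o$: fraction of dosage-1 calls — for pooled
  inbred samples this is the *cultivar heterogeneity* rate;
* unbiased expected heterozygosity:
  $uH_e = \frac{2n}{2n-1}\left(1 - p^2 - (1-p)^2\right)$;
* fixation index $F = (uH_e - H_o)/uH_e$, defined as 0 when $uH_e = 0$.
  High $F$ is expected here: the material is inbred, so $H_o \ll uH_e$.

Allelic richness uses Hurlbert rarefaction to a common sample of $g$ allele
copies, $AR = \sum_a \left[1 - \binom{N-N_a}{g} / \binom{N}{g}\right]$,
evaluated in closed form via `lchoose` (and verified in the tests against
brute-force enumeration of all subsamples).

Transition/transversion accounting classifies the recorded substitution
(e.g. `A>G`) into the four transitions and eight transversions and reports
counts, percentages and the Ts/Tv ratio per chromosome and panel-wide.

## Genome scans

Window tracks use a fixed skeleton per chromosome: `n_positions` (default
250) evenly spaced centers from `width/2` to `length − width/2` with 500 kb
windows, half-open on the right (`[c − w/2, c + w/2)`), so adjacent windows
never double-count a locus even when they overlap. Reducers are `mean` and
`count`; empty windows yield `NA` (mean) or 0 (count).

Per-locus differentiation between two accession groups uses the
two-population Wright/Nei form $F_{ST} = (H_T - \bar{H}_S)/H_T$ with
$H_T = 2\bar p(1-\bar p)$, clipped to $[0, 1]$; the scan track plots the
contrast-enhancing transform $F_{ST}^{10}$. Unique alleles between
consecutive breeding periods are alleles at frequency ≥ a threshold (0.25
"common", 0.05 including rare) in one group and exactly absent in the
adjacent group, counted per chromosome as lost or gained.

## Distances, ordination, AMOVA

`jaccard_distance()` expands each call into two presence bits (reference,
alternate) and computes, per pair, one minus the ratio of shared to union
bits over jointly scored loci — so a 0 vs 1 call shares one allele and
contributes 1/2. The computation is a handful of matrix products over
validity masks, not a per-pair loop. PCoA double-centers $-\tfrac12 D^2$,
takes the eigendecomposition and drops negative eigenvalues (no Cailliez or
Lingoes correction); percentages of variance are relative to the positive
eigenvalue sum.

`amova()` is the distance-based analysis of molecular variance:
$SS_{total} = \sum_{i<j} d_{ij}^2 / N$ partitioned into among- and
within-group sums of squares, variance components via
$n_0 = (N - \sum_g n_g^2/N)/(k-1)$, $\Phi_{ST}$ as the among-group share,
and a permutation test of group labels with $p = (b+1)/(m+1)$.

## Relatedness and duplicates

`ibd_pihat()` is the method-of-moments estimator: observed identity-by-state
class counts (IBS 0/1/2) over jointly scored polymorphic loci are compared
with their expectations under panel allele frequencies assuming random union
of gametes, giving $P(IBD=0/1/2)$ (negatives truncated, renormalised) and
$\hat P = P(IBD{=}2) + P(IBD{=}1)/2$. Two caveats are inherent to applying
this estimator to inbred material and are deliberately reproduced, not
corrected: unrelated inbred pairs show an inflated baseline ($\hat P \sim
0.2$, because homozygous data violate the random-gamete IBS expectations),
and a single opposite-homozygote locus costs several percent of $\hat P$ on
small panels. Both sit far from the 0.95 duplicate cutoff.
`duplicate_clusters()` reports connected components (transitive closure) of
the $\hat P > 0.95$ graph, and `duplicate_verdict()` combines passport
flags, low Jaccard distance, identical dominant gene pool and IBD into one
verdict per candidate group.

## Admixture and the number of gene pools

`fit_admixture()` maximises the binomial admixture likelihood — dosage
$g_{il} \sim \mathrm{Binomial}(2, \sum_k q_{ik} p_{kl})$ — with
multiplicative EM updates from a seeded random start; this is the same
likelihood the Bayesian structure programs sample from, maximised instead of
integrated (a documented substitution: point estimates of $Q$ and $P$, no
posterior spread). $K = 1$ has the closed form $\hat p$ = panel frequencies.
Pool frequencies are clipped to $[10^{-6}, 1-10^{-6}]$; the log-likelihood
trace is monotone (a property the tests assert). Replicates are aligned
across label switching by the column permutation minimising the L1
difference to the first replicate — exhaustive for $K \le 8$, Hungarian
assignment above. The number of pools is chosen by the Evanno $\Delta K$:
$\mathrm{mean}\,|L(K{+}1) - 2L(K) + L(K{-}1)| / \mathrm{sd}\,L(K)$ over
replicates, maximised over interior $K$. Accessions with maximal membership
≥ 0.8 (inclusive) are assigned to that pool, otherwise labelled admixed.

## Core collection

`extract_core()` implements the M (maximisation) strategy exactly: the
smallest accession subset covering every observed allele class, where a
class is a (locus, allele) pair and a heterozygous call carries both
alleles. Search is best-first over partial selections with the admissible
bound $\lceil \text{uncovered}/\text{max per-accession gain} \rceil$, seeded
and pruned by a greedy cover, with forced inclusion of single-carrier
accessions; when the node budget is exceeded it degrades to the greedy
solution and records the search mode. The tests verify exactness against
exhaustive enumeration on small panels.

## Synthetic panel generator

`generate_panel()` emulates the survey design end to end so every module can
be tested against known truth:

* ancestral frequency $p_0 \sim U(0.05, 0.95)$ per locus (a small fraction
  drawn near 0 to exercise the MAF filter);
* pool frequencies from a Balding–Nichols beta around $p_0$ with spread
  `pool_divergence` (default 0.15, 11 pools);
* per-accession memberships $Q^*$ from a Dirichlet biased toward a sliding
  window of "home" pools per breeding period, so consecutive periods share
  ancestry;
* pooled calls: with the group's heterogeneity probability a locus is
  mixture-segregating, in which case each of `seedlings_per_pool` (default
  8) fully inbred seedlings draws an allele independently and the call is
  heterozygous when they disagree; otherwise all seedlings share one allele;
* duplicates are copies of a source accession with 0.5 % of calls *re-drawn
  from the same pooled-call model* — the same seed lot re-assayed — so
  redraws differ only where the lot segregates and planted pairs stay above
  $\hat P = 0.99$;
* sweeps fix the alternate allele within a genomic span for designated
  period groups; positions are denser toward chromosome ends;
* RepAvg/CallRate metadata and missing calls are drawn so configurable
  fractions of loci fail each filter. Everything is reproducible from one
  seed.

Default sizes (5 period groups of 13/14/18/26/12 accessions, 200 loci per
chromosome plus 50 unplaced) are a deliberately scaled-down stand-in chosen
so the full pipeline runs in well under ten minutes on one CPU; all sizes
are configuration, not constants.

## Pipeline and reproducibility

`run_pipeline()` chains filter → diversity → SNP types → scans → unique
alleles → distances/PCoA → AMOVA → IBD/duplicates → admixture/$\Delta K$ →
core collection, writing one CSV per stage plus a JSON manifest (package
version, seed, parameters, per-stage row counts). One global seed fans out
to per-stage seeds by fixed offsets, so stages are independently
reproducible; a stage failure aborts with a stage-named error after writing
the partial manifest. The desk-scale defaults fit admixture for $K = 1{:}6$
with 3 replicates (the full survey design, $K = 1{:}16$ with 6 replicates,
is a configuration change).

```{r example}
cfg <- pipeline_config(
  simulation = sim_config(
    loci_per_chromosome = c(`1H` = 80, `5H` = 80),
    group_sizes = c(7, 7, 7), heterogeneity_by_group = c(0.08, 0.05, 0.03),
    sweep_spec = list()),
  n_positions = 30, k_range = 1:3, n_replicates = 2, admix_max_iter = 100,
  amova_permutations = 99, seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
res$amova$table
res$core
```

## Limitations

* The admixture model returns maximum-likelihood point estimates, not
  posterior distributions; EM can reach local optima, mitigated by
  replicates and alignment.
* The IBD estimator assumes Hardy–Weinberg random mating when converting
  IBS counts to IBD probabilities; on inbred panels the absolute values are
  biased (see above) although duplicate detection at 0.95 is unaffected.
* $F_{ST}$ is the two-population Wright/Nei form, not Weir–Cockerham.
* PCoA does not correct negative eigenvalues; with Jaccard distances the
  leading axes are unaffected.
* No LD pruning is applied before IBD or admixture.
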