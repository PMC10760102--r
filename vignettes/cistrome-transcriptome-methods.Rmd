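---
title: "Methods: integrative cistrome-transcriptome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative cistrome-transcriptome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromeCT)
```

# The problem

Transcription-factor perturbation experiments produce two complementary
readouts: a *cistrome* (the genome-wide set of binding intervals, each with
a differential-enrichment significance) and a *transcriptome* (per-gene
differential-expression statistics). Neither alone says whether altered
binding *drives* altered expression. `cistromeCT` implements a family of
statistics that connect the two, plus a seeded simulator that plants known
effects so every statistic can be validated by parameter recovery.

# The wt-C-T score

The central statistic is the weighted cistrome-transcriptome (wt-C-T)
score, a regulatory-potential construction in the BETA tradition of
distance-decayed peak-to-gene summation. For gene $g$ with TSS $t_g$ and
differential-expression record with log2 fold change $f_g$, over peaks $i$
whose midpoint $m_i$ lies within $W$ bases of $t_g$
($|m_i - t_g| \le W$, boundary inclusive, $W = 100\,\mathrm{kb}$ by
default):

$$ S_g \;=\; \Big( \sum_{i \,:\, |m_i - t_g| \le W} w(d_i)\,
   \big(-\log_{10} q_i\big) \Big)\cdot |f_g|, \qquad d_i = |m_i - t_g| $$

where $q_i$ is the adjusted p-value of the peak's differential enrichment
(only regions with $q_i < 0.1$ enter the scoring) and $w$ is the distance
weight. Three weighting modes are exposed:

* **unweighted** — $w \equiv 1$;
* **weighted** (default) — exponential decay
  $w(d) = \exp\!\big(-(0.5 + 4d/W)\big)$, i.e. $\approx 0.607$ at the TSS
  and $\approx 0.011$ at the window edge. This is the regulatory-potential
  decay of the BETA family, reparameterised to the window;
* **binary** — proximal peaks ($d \le 10$ kb) weigh 1, distal 0.5.

The proximal-versus-distal weighting that best reflects any particular
dataset is an open modelling choice; both a smooth decay and a coarse
binary reading are defensible, so the package exposes both and defaults
to the decay, which uses the distance information fully. Score
distributions of a modified cell background and its control are compared
with a two-sided Wilcoxon rank-sum test (`compare_wtct()`): exact by
enumeration when $n_a + n_b \le 12$ and the pooled scores are tie-free,
otherwise the normal approximation with mid-rank tie correction and
continuity correction. Ties are expected (scores of exactly 0 are common),
which is why the tie-corrected approximation is the large-sample route.

Two decisions worth making explicit:

* genes carrying peaks but no differential-expression record are *skipped*,
  not scored with $f_g = 0$: the score is defined only for genes measured
  in the matching contrast;
* whether the summed per-peak significance is $-\log_{10}$ of the raw or
  the adjusted p is up to the upstream table; the readers default to the
  adjusted scale (consistent with the FDR < 0.1 entry rule) but accept
  either column.

# Interval statistics

All coordinates are 0-based half-open throughout; minimal GTF input is the
single 1-based conversion point. Two intervals overlap iff they share at
least 1 bp (`max(starts) < min(ends)` on the same chromosome). Set-level
overlap (`intersect_peak_sets()`) counts a peak as shared if it overlaps
any peak of the other set, so the two sides need not agree.

Co-occurrence of two cistromes is tested by tiling the genome into
fixed-width bins (1 kb default), labelling each bin covered/uncovered by
each set, and applying a 1-df chi-squared test without continuity
correction to the 2x2 table. The binning gives the contingency table
well-defined margins and a permutable null; counts, statistic and p are
all reported so the construction is auditable. A zero row or column margin
makes the test degenerate: p is reported as 1 with a warning rather than
NaN. The calibration test places two independent uniform cistromes (200
peaks of 500 bp on a 1 Mb chromosome) so expected cell counts are well
above the chi-squared validity threshold and bin-straddling dependence is
minor; the measured type-I error at $\alpha = 0.05$ sits inside its 95%
binomial interval.

Chromatin-state stratification assigns a peak to every state segment it
overlaps by $\ge$ 1 bp (a boundary-spanning peak legitimately appears
under both states); peaks touching no segment are collected under
`"unassigned"`. Overlapping segments within one segmentation are an error,
not a warning — a segmentation is a partition by construction.

# Concordance between paired contrasts

For two contrasts sharing a gene universe, a gene significant in both
(strict `logPV > 1` and `|log2FC| > 0.37`, the RNA-seq DEG rule; the
proteomics preset is `logPV > 1.3`) is *cooperative* when the fold-change
signs agree and *antagonistic* when they oppose; everything else is
*unclassified* rather than dropped, so the three counts always partition
the union. Because the natural denominator is ambiguous (all genes vs
regulated genes), the summary reports the antagonistic fraction both over
the union and over both-significant genes; a two-proportion chi-squared
(`compare_antagonism()`) compares fractions between backgrounds.

# Enrichment and delta-NES

Class enrichment in complex-membership lists uses the one-sided
hypergeometric upper tail $P(X \ge k)$ with BH adjustment across the sets
tested in one call. The universe is the caller's choice; the pipeline
default is the union of everything detected (member list plus all set
members), the least-assumption option, overridable by flag. Delta-NES is a
plain per-term difference between a variant background and its reference;
terms present on only one side are listed separately and never imputed.

# delta.corr

For a regulator $x$, target gene $y$ and coregulator $z$,
$\delta = \bar r_{xy} - \bar r_{xy\cdot z}$ with
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$,
means taken unweighted over the target set (per-gene values are also
emitted, since the aggregation level is a reporting choice). A large
$\delta$ means the coregulator accounts for much of the regulator-target
association. Correlations are Pearson on the values as given; collinearity
with the conditioning variable and zero-variance columns are errors, not
NaNs.

# Bootstrap Jaccard of ranked lists

Similarity of two ranked gene lists is the Jaccard index of their top-$k$
sets. Significance comes from a permutation null: the order of the second
list is permuted `n_boot` times (1000 by default) and
$p = (1 + \#\{J_{null} \ge J_{obs}\})/(n_{boot}+1)$ — the add-one
estimator, which can never return 0. The resampling unit (ranks of one
list) is the minimal null consistent with comparing rankings over a fixed
universe. Permutation p-values on a discrete statistic are only
*asymptotically* uniform: at small $k$ the overlap count takes few values
and the p distribution has visible atoms, which is a property of every
permutation test, not of this implementation. The null-uniformity test
therefore runs in the fine-grained regime (lists of 2000, $k = 1000$),
where a Kolmogorov-Smirnov check against U(0,1) is meaningful.

# The simulator

Every generator is a pure function of a `sim_config()`: one global seed,
with fixed per-generator offsets defining independent substreams, so a
composite pipeline is reproducible end-to-end and each generator is
independently reproducible. Truth labels are emitted next to every
dataset; recovery tests consume the data and compare against the labels
only.

The reference conditions (the defaults) are: two chromosomes of 10 Mb
(comfortably above twice the annotation window), 300 genes with distinct
uniform TSSs, 600 peaks of 500 bp, coupling 0.9, fold-change bonus 1.0,
half the genes designated as targets; a 200-gene both-significant set with
antagonism fraction 0.3; latent-factor loadings
$a = b = c = \lambda = 0.5$ with unit Gaussian noises and 293 samples (a
cohort-scale default); a 50% planted overlap of two top-100 lists over a
300-gene universe. Peak significance is drawn as
$-\log_{10} q = 1 + \mathrm{Exp}(1)$, so every simulated region passes the
FDR < 0.1 entry rule by construction. `log_pv` of the coupled-DE table is
a deterministic Gaussian-tail transform of `|log_fc|`, which keeps targets
and non-targets exchangeable when the coupling is zero — the property the
type-I-error test relies on.

What the simulator does *not* emulate: read-level noise, realistic peak
shapes or chromatin-state geometry, correlated gene expression beyond the
single latent factor, and heavy-tailed fold-change distributions. Passing
recovery tests therefore demonstrates correctness of the statistics, not
robustness to every pathology of real sequencing data.

```{r recovery}
cfg <- sim_config(seed = 1)
gg <- make_genome_and_genes(cfg)
cp <- make_coupled_peaks_and_de(gg$genes, cfg)
sc <- wtct_table(cp$peaks, gg$genes, cp$degs, mode = "weighted")
compare_wtct(sc[cp$truth$is_target, ], sc[!cp$truth$is_target, ])
```

# Numerical choices and degenerate inputs

* Adjusted p of exactly 0 is clamped to the smallest positive double with
  a warning (an infinite peak significance would otherwise dominate every
  sum).
* Reported p-values are clamped into $(0, 1]$.
* Unknown strand (`"."`/`"*"`) is treated as plus with a warning, never an
  error — peak-adjacent files carry it routinely.
* The peak anchor is the interval midpoint, `floor((start + end)/2)`; the
  window boundary is inclusive, and both facts are frozen in tests so the
  brute-force oracle and the interval-tree path cannot drift apart.
* Wilcoxon exactness switches at $n_a + n_b = 12$; the approximation is
  within 0.01 of enumeration at group sizes 10–12 (checked), while at
  very small sizes only the exact route is used.

# Problem sizes used by the test-suite

Oracle-equivalence checks run 50 random instances up to 500 genes x 500
peaks against an $O(\text{genes}\times\text{peaks})$ double loop;
calibration checks use 200 replicates (type-I error, null uniformity of
both the Wilcoxon and the bootstrap p), and power uses 50 replicates under
the reference conditions. These sizes make the whole suite run in about a
minute on a single core while keeping every Monte-Carlo interval tight
enough to be meaningful.

# Known limitations

* The chi-squared overlap test's bin construction is this package's
  definition; other reasonable constructions (peak-count or base-pair
  contingency) would give different statistics.
* `delta.corr` is first-order only: conditioning on one coregulator at a
  time, as the analysis it supports requires; it is not a graphical-model
  estimate.
* The concordance classification is sign-based and ignores effect
  magnitude beyond the significance filter.
* The simulator's uniform gene placement produces no gene clusters, so
  multi-gene peak assignment is rarer than in real genomes (the
  multi-assignment code path is exercised by dedicated fixtures instead).
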