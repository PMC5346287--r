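---
title: "Methods: bicodon usage bias between lowly and highly abundant proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bicodon usage bias between lowly and highly abundant proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicodonbias)
```

## The question

Synonymous codons are used unevenly, and so are adjacent codon *pairs*
(bicodons: the P-site codon followed by the A-site codon). If ribosomal
pauses are partly encoded at the bicodon level, bicodons that slow
translation should be depleted from coding sequences of highly abundant
proteins and tolerated (or enriched) in lowly abundant ones. This package
quantifies that contrast and — crucially — asks whether a bicodon's
differential usage can be explained by the usage of its two codons taken
singly, or whether the *pair itself* carries signal.

The bicodon universe is the 61 sense P-site codons times all 64 A-site
codons: 3,904 pairs. Pairs with a stop in the P-site cannot occur inside a
valid CDS and are excluded; sense:stop pairs (the last pair of every CDS)
are kept. The three stop codons are treated as one A-site symbol when
forming synonymous groups, so the group for an amino-acid pair `a1:a2` has
size `q_ap` = (codons of `a1`) x (codons of `a2`, or 3 for the stop signal),
and the 420 groups partition the universe.

## Sampling two length-matched sets

Protein abundance (PA) correlates negatively with coding-sequence length,
so naive low/high tails would differ in length and bicodon counts would be
confounded. The sampler therefore walks the abundance-ordered record list
from one extreme and accepts each candidate of length $l$ with probability

$$r_l = \exp\left[-\frac{(l - l_o)^2}{2\sigma}\right] > r,\qquad
r \sim \mathrm{Uniform}(0,1),$$

stopping once `n_select` (default 500, the reference sample size) records
are accepted; unaccepted records are revisited with fresh draws, up to
`max_passes` (default 100). The walk is deterministic given the seed, and
acceptance is maximal at $l = l_o$ and strictly decreasing away from it.

**Choice of the bandwidth.** The source description leaves the "target
distribution" supplying $l_o$ and $\sigma$ open, and $\sigma$ enters as a
variance-like quantity (the exponent divides by $2\sigma$, not $2\sigma^2$).
We fit $l_o$ to the pooled mean length and set $\sigma = (\mathrm{SD}/3)^2$,
i.e. an acceptance kernel whose SD is one third of the pooled length SD.
This was calibrated once by simulation at the default study conditions
(5,000 genes, log-length/log-abundance correlation $-0.3$):

* kernel SD = pooled SD leaves a residual mean-length mismatch of roughly
  $1.6\,|\rho|$ pooled SDs (about 0.47 SD at $\rho = -0.3$) — too weak;
* a literal bandwidth of $\sqrt{\mathrm{SD}}$ in length units is
  unit-dependent and so narrow that the walk consumes nearly the whole
  list, destroying the abundance contrast and sometimes failing to fill
  500;
* kernel SD = pooled SD/3 leaves the mean mismatch at $\le 0.13$ SD while
  the walk stays within the extreme ~30% of the abundance ordering.

Both parameters are overridable per run. Lengths are taken in nucleotides
(the unit of the abundance-table length column); since the rule is fitted
and applied in the same units, the choice is immaterial for the default
fit.

Isoform handling: when several records map to one gene, only the most
abundant is kept, ties broken by smallest identifier, so deduplication is
deterministic.

## The three statistics

For each sample $X \in \{L, H\}$ we count all overlapping adjacent codon
pairs in frame (each codon participates in up to two bicodons; the final
sense:stop pair is included), giving per-bicodon counts $o^X_{ij}$, codon
counts $f^X_i$, and totals $N_p$, $N_\mathrm{tot}$.

**1. Pause propensity.** Relative synonymous bicodon usage scales a
bicodon's count by its group size over the group total,
$\mathrm{RSBU}^X_{ij} = q_{ap}\, o^X_{ij} / N^X_{ap}$, and

$$\pi_{ij} = \mathrm{RSBU}^L_{ij} - \mathrm{RSBU}^H_{ij}.$$

Positive $\pi$ marks preference for lowly abundant proteins (a candidate
pause signal). The defining equation can be read with a single pooled
$N_{ap}$ for both samples; we default to the per-sample total, which makes
RSBU a proper relative-usage measure (it sums to $q_{ap}$ within every
represented group) and gives $\pi$ an exact sign interpretation, with
$\sum_{\mathrm{group}} \pi = 0$ for every doubly represented group. The
pooled variant is available via `normalization = "pooled"`.

**2. Fisher exact significance.** Each bicodon gets the 2x2 table
`[[o_L, N_ap_L - o_L], [o_H, N_ap_H - o_H]]` — the background is the other
bicodons of the same synonymous group (a whole-sample background is
available behind a flag). The two-sided p-value follows the
minimum-likelihood convention: the sum of hypergeometric probabilities of
all tables with the same margins whose probability is at most that of the
observed table, ties included, with relative tolerance $10^{-7}$ on the
comparison (the convention `stats::fisher.test` also uses; the source does
not state sidedness). Log-factorials are evaluated exactly via `lgamma` by
default; `factorial_mode = "stirling25"` reproduces the reference
evaluation — Stirling's $\sqrt{2\pi n}(n/e)^n$ for $n \ge 25$, exact
products below — and agrees with the exact mode to within 0.01 in
$\log_{10} p$ at the relevant margins. For display, significance is
sign-oriented as $-S \log_{10}(p)$ with $S = +1$ for low-PA preference, so
low-preferring bicodons plot positive.

**3. Residual scores against single-codon expectations.** The random
pairing expectation $e_{ij} = f_i f_j N_p / N_\mathrm{tot}^2$ (f over all 64
codons, since stops occupy A-sites) is rescaled within each synonymous
group to remove non-random amino-acid pairing,
$\hat e_{ij} = e_{ij}\sum^*o / \sum^*e$, which conserves the observed group
total exactly; then $\chi^2_{X,ij} = (o_{ij} - \hat e_{ij})^2 / \hat
e_{ij}$. Degenerate cases: $\hat e = 0 \wedge o = 0$ gives 0; $\hat e = 0
\wedge o > 0$ gives an `Inf` sentinel.

## Calibrating the residuals: the shuffle null

$\chi^2$ has no usable reference distribution here, so it is standardized
empirically: each replicate shuffles the codon order within every sequence
(terminal stop fixed), which preserves single-codon usage *exactly*
(the codon count vector is bit-identical) while destroying pair
correlations. Expectations and residuals are recomputed fully inside each
replicate, because the group rescaling depends on the shuffled counts. With
`n_reps = 200` (the reference setting) we obtain per-bicodon null means and
SDs, per sample independently, and report
$z = (\chi^2 - \langle\chi^2\rangle_\mathrm{ran}) /
\mathrm{SD}_\mathrm{ran}$. Where the null SD is 0 (bicodons whose counts
cannot vary under shuffling), $z$ is 0 if the observed residual equals the
null mean and an NA sentinel otherwise; sentinels are withheld from
classification and reported separately. One master seed spawns the
per-replicate streams, so the full replicate set is reproducible.

## Classification

With $\alpha = 0.01$ and a 3-SD residual threshold (two-sided normal tail
0.0027, i.e. the conventional 0.003 level):

* `unbiased` — $p \ge \alpha$;
* `explained_biased` — $p < \alpha$ but residuals below threshold;
* `low_unexplained` / `high_unexplained` — $p < \alpha$ and residual at or
  above threshold, split by the sign of $\pi$.

The threshold rule is `max(z_L, z_H) >= 3` by default: the quadrant
geometry of the residual scatter implies a per-axis rule. The summed
variant ($z_L + z_H \ge 3$), suggested by reading
$\chi^2 = \chi^2_L + \chi^2_H$ as one whole-residual score, is implemented
behind `rule = "sum"`; on our synthetic data the two differ only for
borderline bicodons.

Downstream reports reuse these thresholds: cross-organism tables intersect
bicodons passing all three filters with a consistent $\pi$ sign in every
organism (tightening a threshold can only remove rows); occupancy-filtered
candidate lists apply strict inequalities $\pi > 0.75$, $p < 0.01$,
occupancy $> 0.03$; and the synonymous-SNP report looks up $\pi$ for the
two flanking bicodons under the reference and variant codon and reports
$\Delta\pi = \pi_\mathrm{alt} - \pi_\mathrm{ref}$ per side (values absent
from the table are NA, never 0).

Heat maps are materialized as 64 x 64 matrices (P-site rows x A-site
columns) with the three stop P rows masked (192 cells); the axes are
ordered by average-linkage (UPGMA) clustering of Euclidean distances
between codon profile vectors, masked cells counting as 0. Because
dendrogram leaf order is otherwise implementation-defined, leaves are
extracted deterministically: ties resolve by input order and every subtree
is oriented smallest-leaf-first.

## The synthetic proteome

The generator provides study-condition data without any download. Per gene
it draws abundance lognormally (meanlog 2, sdlog 1.5, ppm-like), a
sense-codon count lognormally (meanlog log 400, sdlog 0.45, clamped at 30)
with log-length/log-abundance correlation $\rho = -0.3$ (a realistic
yeast-like negative correlation), an i.i.d. amino-acid sequence from a
typical eukaryotic composition with the first residue forced to Met, codons
from a per-class synonymous profile (moderate geometric bias, ratio 0.6,
identical in both classes by default), and a terminal stop from yeast-like
weights (TAA 0.47, TGA 0.30, TAG 0.23). Expression class is a median split
of the drawn abundance.

Codon-pair couplings are planted as first-order multipliers: when the
previous codon equals the coupling's P codon, the A codon's weight within
its synonymous family is multiplied by $m$ and the family renormalized.
This perturbs pair usage while leaving marginal amino-acid usage untouched
— exactly the signal the residual analysis is designed to isolate.
`expected_pair_frequency()` returns the renormalized conditional
distribution in closed form and is the analytic oracle for recovery tests.
Sampling is vectorized i.i.d. first, then affected genes are re-walked left
to right redrawing only positions where a coupling fires; untouched
positions already have the correct conditional, so the walk samples the
exact first-order chain.

What the generator does *not* emulate: GC/amino-acid composition gradients
along genes, organism-specific tRNA pools, secondary-structure effects,
isoform structure, transcript-level confounding of PA. Passing recovery
tests therefore demonstrates the statistics behave as designed on data
satisfying their assumptions — not that real proteomes satisfy them.

## Numerical choices and problem sizes

* Fisher probability comparisons use relative tolerance $10^{-7}$;
  group-total conservation of $\hat e$ is asserted to $10^{-9}$.
* All randomness flows through explicit integer seeds; the pipeline
  derives stage seeds from one master seed and writes a manifest with md5
  checksums, so reruns are byte-identical. Output TSVs carry no
  timestamps, and numeric values are written in shortest-faithful decimal
  so files round-trip bit-identically.
* Test and example problem sizes were chosen so the whole suite runs on a
  laptop-class single core: 5,000-gene proteomes with 500 + 500 samples
  and 200 shuffle replicates for calibration and recovery runs (5–10
  seeds), 2,000 genes for convergence checks, and exhaustive Fisher
  validation over every margin set with grand total up to 200 (about
  7 x 10^7 tables) against a direct hypergeometric enumeration.

## Known limitations

* The pause interpretation of positive $\pi$ is correlational; PA is also
  set by transcription and degradation, which the model ignores.
* Fisher p-values are reported raw, as in the reference analysis; a BH
  column is emitted for information but plays no role in classification.
* Stop codons are grouped as one A-site symbol; analyses that distinguish
  the three stops within aa:stop groups would need a finer grouping
  (flagged for sensitivity testing, not implemented).
* The sampler guarantees mean-length matching, not full distributional
  matching, and matches on length only (no GC or other covariates).
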