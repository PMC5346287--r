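# bicodonbias

Do adjacent codon pairs ("bicodons") carry information about translation
speed that single codons do not? Coding sequences of highly abundant
proteins are expected to be optimized for fast elongation, while sequences
of lowly abundant proteins can tolerate — or exploit — pause-prone codon
pairs. `bicodonbias` implements a complete statistical workflow for
contrasting bicodon usage between two sequence sets at the opposite ends of
the protein-abundance (PA) scale, and for deciding which biases the usage
of the individual codons cannot explain. It is aimed at researchers in
codon usage, translational regulation and heterologous expression design.

## The statistics

For the 3,904-pair universe (61 sense P-site codons x 64 A-site codons;
sense:stop pairs included, stop P-sites excluded), computed per sample
X ∈ {L, H} from counts o and codon counts f:

* **Pause propensity** — with RSBU the relative synonymous bicodon usage,
  `RSBU_ij^X = q_ap · o_ij^X / N_ap^X` over the bicodon's synonymous
  (dipeptide) group,

  `π_ij = RSBU_ij^L − RSBU_ij^H`.

  π > 0 marks preference for lowly abundant proteins, a candidate pause
  signal.

* **Fisher exact test** — per bicodon, on the 2x2 table
  `[[o_L, N_ap_L − o_L], [o_H, N_ap_H − o_H]]` (synonymous-group
  background), two-sided by the minimum-likelihood rule; factorials exact
  (`lgamma`) or by Stirling's formula for n ≥ 25. Displayed sign-oriented
  as `−S·log10(p)`, positive for low-PA preference.

* **Residual scores** — the random-pairing expectation
  `e_ij = f_i f_j N_p / N_tot²`, rescaled within each synonymous group to
  the observed group total (`ê`), gives
  `χ²_X,ij = (o_ij − ê_ij)² / ê_ij`, standardized against a 200-replicate
  codon-shuffling null (codon order permuted within each sequence, terminal
  stop fixed — codon usage preserved exactly, pair correlations destroyed).

Every bicodon is then classified: `low_unexplained` / `high_unexplained`
(p < 0.01 and ≥ 3 null SDs — differential usage the codon bias cannot
explain), `explained_biased`, or `unbiased`.

Because the original data sources require genome-scale downloads, the
package ships a synthetic proteome generator that reproduces the
statistical structure the method assumes (lognormal abundance, lognormal
length negatively correlated with abundance, synonymous codon bias) and can
plant first-order codon-pair couplings — ground truth for end-to-end
parameter recovery.

## Worked example

The `analysis/` directory is a five-stage narrative workflow; each stage is
a standalone script over the previous stage's TSVs in `results/`:

```sh
Rscript analysis/01_simulate.R            # 5,000-gene proteome, 3 planted couplings
Rscript analysis/02_sample.R              # 500 + 500 length-matched samples
Rscript analysis/03_bicodon_statistics.R  # RSBU, pi, Fisher, chi-squared
Rscript analysis/04_shuffle_null.R        # 200-replicate null, classification
Rscript analysis/05_reports.R             # heat maps, candidates, SNP report
```

Stage 2 prints the length matching achieved by the Gaussian-acceptance
rejection sampler:

```
low : 500 seqs, abundance median 1.61, mean length 1323 nt
high: 500 seqs, abundance median 32.3, mean length 1261 nt
|mean length difference| = 61.90 nt = 0.098 pooled SD
```

Stage 3 ranks bicodons by differential usage; the planted Val-Arg coupling
GTA→CGA (x6 in low-abundance genes) tops the list:

```
bicodons with p < 0.01: 44 of 3904 (1.13%)
 bicodon dipeptide o_L o_H         pi      p_value
  GTACGA        VR 166  67  3.5586904 1.098284e-13
  GCCAAA        AK 176  65  0.8805940 5.781108e-13
  GCCAAG        AK  96 164 -0.6547352 3.244118e-07
```

Stage 4 shows all three planted couplings landing in the "unexplained"
categories with the correct signs — e.g. GTACGA: π = +3.56, p ≈ 1e−13,
z_L = 214 null SDs, category `low_unexplained` — while ~99% of the
universe stays `unbiased`. Stage 5 ends with a synonymous-SNP report of the
kind used to interpret pathological silent variants: for a GTA→GTG variant
upstream of the planted pair,

```
Synonymous SNP in SYNG04823 at codon 103: GTA -> GTG (V)
  downstream GTACGA -> GTGCGA: pi 3.55869 -> -0.2548702 (delta -3.813561)
  RSCU: ref GTA = 1.818, alt GTG = 0.648
```

i.e. the variant abolishes a strong low-PA-preferring bicodon — a much
larger effect than the codon-usage change alone suggests.

`run_pipeline()` wraps the same stages as one call with a single master
seed and writes a manifest (config + md5 checksums); reruns are
byte-identical.

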