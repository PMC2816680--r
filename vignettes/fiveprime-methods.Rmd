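---
title: "Measuring reduced mRNA structure near the start codon: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring reduced mRNA structure near the start codon: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the statistic

Translation initiation is sensitive to how strongly the mRNA folds right
after the start codon: stable local secondary structure there can hinder
start-codon recognition and depress protein output. `fiveprime` asks, for
each gene of a genome, whether the observed coding sequence folds *less*
stably near its 5' end than expected given the protein it encodes and the
codons it uses — the signature of selection acting on synonymous sites.

The statistic is a sliding-window permutation Z-score. For a window $w$ of a
gene, let $\Delta G_{wt}(w)$ be the minimum-free-energy (MFE) of the
wild-type window (kcal/mol, $\le 0$), and let $\Delta G_i(w)$,
$i = 1,\dots,N$, be the MFE of the *same coordinates* in $N$ synonymously
permuted versions of the gene. Then

$$Z_{\Delta G}(w) \;=\; \frac{\Delta G_{wt}(w) - \overline{\Delta G}(w)}
        {s_{\Delta G}(w)},$$

with $\overline{\Delta G}$ the permutation mean and $s_{\Delta G}$ the
sample (N−1) standard deviation. A **positive** $Z_{\Delta G}$ means the
real sequence is *less* stable (less negative MFE) than its null. The same
construction applied to the window's G+C fraction gives $Z_{GC}$, which
separates composition effects from arrangement effects.

Because each permutation preserves the amino-acid sequence, the per-amino-
acid codon multiset, and therefore gene GC and codon-usage bias, any
systematic excess of $Z_{\Delta G}$ is attributable to the *arrangement* of
synonymous codons — the same conditioning that makes the design robust to
composition confounders.

Window defaults: width 30 nt, step 10 nt, up to 13 windows; window $i$
spans nucleotides $(i-1)\cdot 10 + 1$ to $(i-1)\cdot 10 + 30$ from the
first base of the start codon (1-based, inclusive). With the default length
filter (genes strictly longer than 50 codons, i.e. ≥ 153 nt) every accepted
gene covers all 13 windows, whose last ends at nt 150. Widths of 20 and 40
are supported for sensitivity checks; genes shorter than a full span simply
contribute the windows they cover.

## Permutation nulls

Two null generators are provided:

* **Codon shuffle** (default): within every amino acid's positions, a
  uniformly random permutation of the codons present. The terminal stop is
  fixed (it encodes no amino acid); the initiator ATG is a single-codon
  family and therefore fixed automatically. $N = 1000$ permutations per
  gene by default.
* **Dicodon shuffle** (control): a synonymous shuffle additionally required
  to preserve the gene's 16-entry dinucleotide count vector, including
  codon-junction dinucleotides, guarding against dinucleotide-stacking
  artifacts. When the synonymous arrangement space is enumerable (≤ 5000
  arrangements) the valid set is built exactly and sampled uniformly
  without rejection. Otherwise candidates are drawn from the uniform codon
  shuffle and accepted on exact count match; because the proposal is
  uniform over all arrangements, accepted draws are uniform over the valid
  subset. If no valid alternative appears within the attempt budget
  (default 2000) the input itself is returned — a conservative
  self-permutation. For genes of realistic length the exact-count
  constraint is extremely tight, so the control is most informative on
  short genes and as a distribution-level comparison; this trade-off is
  deliberate: an approximate sampler that silently relaxed the constraint
  would invalidate the contract the control exists to enforce.

Reproducibility is a contract, not an accident: each gene's permutation
stream is seeded by a hash of (master seed, gene id), so results are
byte-identical regardless of the order — or parallelism — in which genes
are processed.

## Folding backends

MFE values come from a pluggable backend (`fold_backend()`):

* **`rnafold`** — an adapter that batches windows through ViennaRNA's
  `RNAfold` in a single process. Settings mirror the analysis conventions:
  37 °C, GU wobble pairs allowed, dangling-end mode `-d1` (each unpaired
  base joins at most one dangling end), MFE structure only.
* **`nnfold`** — a compiled, dependency-free simplified nearest-neighbor
  folder used for the large permutation suites: Turner-style stacking free
  energies over the six pair types, hairpin/bulge/internal-loop initiation
  penalties with logarithmic extrapolation, an asymmetry penalty capped at
  3 kcal/mol, a linear multiloop cost (3.4 + 0.4/branch), minimum hairpin
  loop of 3 nt, loops capped at 12 unpaired bases (a standard fast-folding
  restriction with negligible effect on 30-nt windows), no dangling ends or
  terminal-mismatch bonuses, and parameters defined at 37 °C only.

Both backends are deterministic, report to 0.01 kcal/mol, and never return
a positive energy (the open chain, at 0, is always attainable). Energies
are *not* comparable across backends; every regression test compares a
backend only against its own frozen fixtures
(`inst/extdata/fold_fixtures.tsv`). The Z-score is a within-backend
standardization, which is what makes the headline statistic
backend-agnostic.

## Genome summaries and their tests

Per species and window, the genome summary reports the mean and standard
error of the per-gene $Z_{\Delta G}$, a two-sided one-sample t-test of the
mean against 0, the mean raw MFE, and the mean $Z_{GC}$. Degenerate nulls
(permutation sd of exactly 0, e.g. genes with no synonymous freedom) yield
an undefined Z; such gene-windows are excluded from the means — including
them as 0 would bias toward the null — and the exclusion count is reported.
No multiple-testing correction is applied across windows: the window
profile is interpreted as a shape, not as 13 independent discoveries.

## Comparative analyses

* **Cross-species**: Spearman correlations (average ranks on ties,
  two-sided asymptotic p, pairwise-complete) between per-genome summaries
  and genome covariates — genomic GC (pooled G+C over coding nucleotides,
  not a mean of per-gene fractions) against window-1 $Z_{\Delta G}$, the
  same per window, window-1 $Z_{GC}$, raw window-1 MFE and the window-1
  minus window-10 MFE difference; and, for prokaryotes with growth
  temperature data, temperature against window-1 Z and against genomic GC.
  Genome-level GC correlations exclude plants, birds and mammals by
  default: isochore structure makes gene GC within those genomes far more
  variable than between genomes, breaking the genome-level relation. The
  exclusion list is configuration, not hard-coded.
* **Within-genome stratification**: genes ranked by whole-CDS GC, by ENC,
  or by expression; the mean window-1 Z of the top 5 % is compared with the
  bottom 5 % (Welch t-test). Group size is `max(1, floor(0.05 n))`; ties at
  the cut are resolved by stable gene-id order so results cannot depend on
  input order. For ENC the *lowest* values (strongest bias) are the "top"
  group.
* **ENC** follows Wright's formula
  $ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$ with
  $F = (n\sum p^2 - 1)/(n-1)$ per amino acid, six-fold families (Leu, Ser,
  Arg) treated as single families, stops excluded, and the value capped at
  61. Amino acids seen fewer than twice (or with non-positive $F$, possible
  at small $n$) do not contribute. A degeneracy class with no usable amino
  acid is patched, by default, by neighbor interpolation
  ($\bar F_3 \approx (\bar F_2 + \bar F_4)/2$, otherwise the overall mean
  $F$); the alternative (`missing_class = "drop"`) removes the class's term
  and rescales to the 61-codon range so values stay comparable.
* **Principal component regression**: gene GC, ENC and log expression
  (pseudo-count: the smallest positive observed level) are standardized;
  window-1 Z is regressed on all principal components; the explained
  variance is allocated to the original predictors by the Pratt product
  measure — the back-transformed standardized coefficient times the
  marginal correlation. This convention was chosen over a squared-loading
  split because it reduces exactly to the classical squared-correlation
  decomposition when predictors are orthogonal (a squared-loading split
  does not: with near-equal eigenvalues the rotation is arbitrary and
  smears a single-predictor effect across all three), and it sums exactly
  to the model $R^2$. Its known cost is that under strong collinearity an
  individual share can be negative; shares are reported as-is.

## The synthetic-genome generator

The generator exists so that every stage of the pipeline can be validated
against data with *known* structure. One genome is defined by: number of
genes; a length range (default 60–300 codons, all passing the default
filter); a target pooled GC; a codon-usage bias strength; a 5'
destabilization strength `delta5`; the span of that signal (default 30 nt);
an expression–signal coupling; and a seed.

Mechanics and the reasoning behind them:

* Amino acids are i.i.d. uniform over the 20; genes start with ATG, end
  with a stop, and contain no internal stops. Because the Z statistic
  conditions on the amino-acid sequence, compositional realism of the
  proteins is not required for the validity of the validation — only the
  synonymous structure matters.
* Synonymous codons are drawn with weights $\exp(\gamma\,g_c)$, where
  $g_c$ is the codon's G+C count and $\gamma$ is solved numerically so the
  expected pooled GC matches the target. Under uniform amino-acid usage
  the attainable pooled GC tops out near 0.63 (many amino acids force A/T
  bases); targets beyond the attainable range are clamped with a warning.
  An optional bias strength adds a preferred codon per family, which
  lowers ENC.
* The 5' signal multiplies the weights of codons in the first 30 nt by
  $\exp(-\delta_g\,g_c)$ — an AT-shift of synonymous choice, the causal
  pathway under study (a GC-poor, weakly folding region right after the
  start), never a direct edit of folding energies. Per-gene strengths
  $\delta_g$ are gamma-distributed around `delta5` (CV 0.5) so that
  expression can be coupled to the realized signal. Separate derived RNG
  streams for proteins, codon choices, signal strengths and expression
  guarantee that changing `delta5` re-decides only the synonymous codons
  of the *same* proteins — the attribution argument in its strongest form.
* Species panels spread target GC over a range (default 0.30–0.62, the
  attainable span), couple `delta5` to GC linearly, and assign
  prokaryote-tagged species growth temperatures decreasing with signal
  strength (plus Gaussian noise, sd 4 °C), emulating the comparative
  setting in which GC correlates positively, and temperature negatively,
  with the 5' signal.

What the generator does *not* emulate: real amino-acid composition and its
5'-end peculiarities (signal peptides, N-end rules), operonic context and
UTRs, isochore heterogeneity within genomes, phylogenetic non-independence
among species, and any direct temperature dependence of folding (the
temperature coupling is purely statistical). Passing validation therefore
shows the *pipeline* recovers known synonymous-arrangement signals; it does
not certify any particular biological magnitude in real genomes.

## Validation suite: sizes and power

The package's property suite runs three stages on the built-in folder, at
sizes chosen by a power analysis and then frozen:

* **Null calibration** — 300 genes, 200 permutations, no signal: every
  per-window genome mean must lie within 3 SE of 0 and the pooled per-gene
  Z must be approximately standard normal (|mean| < 0.1, |sd − 1| < 0.15).
* **Signal recovery** — 300 genes, `delta5 = 1.5`, 100 permutations:
  window 1 significantly positive (p < 0.01), windows ≥ 6 showing no such
  excess. The folding-energy Z attenuates the injected composition signal
  roughly seven-fold ($Z_{GC} \approx -1.7$ maps to
  $Z_{\Delta G} \approx +0.25$) because MFE depends on pairing arrangement
  far more than on composition; the gene count is sized for that measured
  response, not for the raw GC effect.
* **Cross-species recovery** — 20 species × 120 genes, 50 permutations,
  signal slope 8 over GC 0.30–0.62 (signal strengths 0 to ≈ 2.6): the
  pipeline must recover a positive GC correlation and a negative
  temperature correlation (both p < 0.05). The slope comes from a measured
  response curve (~0.12 Z-units per unit of signal strength), giving a
  species-level signal-to-noise ratio near 3 and comfortable detection
  margins at 20 species.

`scripts/acceptance.R` re-runs the same three stages from scratch at a
caller-supplied seed and writes the resulting quantities as JSON, alongside
the structural contracts (13 windows on a minimum-length gene, 1000-element
null sets, the 50-codon filter boundary).

## Numerical conventions and degenerate inputs

* Energies to 0.01 kcal/mol; energy comparisons in tests use that
  tolerance.
* Sample (N−1) sd in every Z; at N = 1000 the difference from the
  population sd is negligible, but the choice is fixed.
* `zscore()` requires ≥ 2 permutation values and returns `NA` (undefined)
  on a degenerate null rather than ±Inf or 0.
* Windows are enumerated only where they fit entirely inside the sequence;
  a sequence shorter than one window yields an empty profile with a
  warning.
* Record validation rejects frame violations, non-ACGT characters
  (ambiguity codes included: folding and GC are undefined for them) and
  genes at or below the length threshold; internal stops and non-ATG
  starts are kept but flagged as warnings, since neither invalidates the
  statistic.
* The pipeline computes genome summaries from the persisted per-species
  tables, so cached reruns and fresh runs agree bit-for-bit.

## Known limitations

* The built-in folder is a deliberately simplified thermodynamic model —
  adequate for a standardized within-backend statistic, unsuitable for
  absolute energies or structure prediction.
* The dicodon control degenerates to self-permutations for long genes
  (exact dinucleotide preservation is a very tight constraint under
  rejection sampling); use it on short genes or as a qualitative check.
* Expression handling assumes a single non-negative level per gene
  (multi-tissue data should be reduced to a geometric mean upstream).
* Cross-species correlations are plain Spearman, as in the comparative
  tradition this follows; no phylogenetic correction is attempted.
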