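---
title: "Models and methods behind sybodykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sybodykit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sybodykit)
```

sybodykit implements the computational side of a synthetic single-domain
antibody (sybody) selection platform: library design arithmetic, in-silico
Golden-Gate-style assembly, selection analytics, and the four nonlinear
models used to characterize binders. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where the
underlying experimental description left the design open.

## Trinucleotide mixes and library diversity

Sybody libraries randomize 15 (concave), 16 (loop) or 18 (convex) codon
positions across the three CDRs. Randomization uses trimer-phosphoramidite
("trinucleotide") synthesis: whole codons are inserted at defined amino-acid
frequencies, so stop codons cannot occur and the amino-acid distribution is
controlled exactly. Three mixes are used, keyed to structural context:

* **mix 1** (loops): A, S, T, N, Y at 10.6% each; D, E, Q, R, K, H, W at 5%
  each; F, M, V, I, L, G at 2% each (18 amino acids; the percentages sum to
  exactly 1).
* **mix 2** (loop-to-sheet transitions): mix 1 without D and A (16 amino
  acids).
* **mix 3** (mid-sheet positions): mix 1 without D, N, Q, G, S, M (12 amino
  acids).

Cysteine and proline are excluded from every mix. Only the *exclusions* of
mixes 2 and 3 are specified by the design, not their resulting frequencies;
`mix_definition()` therefore redistributes the removed probability mass
proportionally over the remaining residues by default, with a `"uniform"`
alternative exposed. Diversity arithmetic is unaffected by this choice, as
it depends only on each mix's support size (18/16/12).

Primer strings encode randomized slots as the placeholder triplets `111`,
`222`, `333`. `parse_randomized_primer()` treats whitespace as cosmetic:
consecutive DNA tokens are merged and re-split into codons, aligning a fixed
run's right edge with a following placeholder so the placeholder frame is
preserved; leftover bases at run edges become partial slots that carry
sequence but no codon identity (in the built-in primers these occur only at
cassette ends, inside primer tails).

`theoretical_diversity()` multiplies per-slot support sizes. Because the
convex library's diversity (about 2.8 x 10^22) exceeds the exact range of
double-precision integers, the product is computed on an exact
decimal-digit representation and only rounded (to 2 significant figures, the
usual reporting convention) by `diversity_signif()`. For the built-in
primer sets this yields 8.3 x 10^17, 4.3 x 10^19 and 2.8 x 10^22.

`sample_library()` realizes members in silico: each randomized slot draws an
amino acid from its mix and is back-translated through a
one-codon-per-amino-acid table (most-used E. coli codons by default,
overridable via `default_codon_table(file=)`), mirroring the one-codon
nature of trimer synthesis. For the concave library, whose non-randomized
framework sequence is built in, sampled codons are spliced into the CDR
windows located by matching the primers' fixed anchors against the
framework; the loop and convex schemes, whose framework sequences are not
part of the package's built-in data, sample their CDR cassettes. Sampling is
seeded and reproducible; C/P can never appear at randomized positions
because their mix frequencies are zero.

## Type IIS assembly simulation

Libraries are assembled from three CDR cassettes in two
digestion-ligation steps (CDR1 cut with BsaI, CDR2 with BpiI, ligation;
then the pair re-cut with BsaI and joined to the BpiI-cut CDR3). The
simulator models linear double-stranded DNA as a top-strand string plus the
lengths of the 5'-protruding single-strand ends. Conventions:

* Enzyme geometry lives in a small editable registry (`restriction_enzyme()`):
  BsaI `GGTCTC(1/5)`, BpiI/BbsI `GAAGAC(2/6)` (4-base 5' overhangs), and
  SapI/BspQI `GCTCTTC(1/4)` (3-base 5' overhangs). The registry makes cut
  offsets auditable and overridable, since enzyme names alone do not fix the
  geometry.
* Both strands are scanned; digestion is complete (every site cut); partial
  digestion and circular substrates are not modeled (the workflow operates
  on linear PCR fragments).
* Overhangs are stored in top-strand representation, so two ends are
  ligatable exactly when their overhang strings are equal; the error message
  reports both overhangs as 5'->3' single strands. Digestion followed by
  ligation of the two pieces reconstructs the substrate exactly, and
  digesting a reverse complement mirrors the fragment list.
* A cut site closer to a sequence end than its bottom-strand offset raises
  an error naming the site, rather than producing a truncated fragment.
* After a complete digestion, `assemble_library()` carries the *largest*
  fragment forward; the discarded pieces are the ~14-nt primer stubs
  carrying the spent recognition sites.

`concave_assembly_fragments()` reconstructs the three non-randomized concave
cassettes from the built-in framework plus the printed primer tails; their
assembly reproduces the framework base-for-base and translates to a protein
with exactly one cysteine pair (the scaffold's single conserved disulfide).
`fx_overhang_check()` validates fragment-exchange (FX) subcloning inserts:
two SapI/BspQI sites in opposite orientations yielding the AGT (5') and GCA
(3') sticky ends.

## Selection analytics

**qPCR quantification.** A standard curve `Ct = intercept + slope *
log10(copies)` is inverted to absolute copy numbers; the amplification
efficiency `10^(-1/slope) - 1` is checked against an accepted band (the
platform's primer pairs run at 95-98%). Technical replicates are averaged
on the Ct scale by default (mean Ct, then transform) because Ct noise is
approximately Gaussian on that scale; averaging back-transformed copies is
available behind a flag. Replicate SD is propagated to the copy scale by
the delta method.

**Enrichment** is the fold excess of copies eluted against the target
versus a background protein. Relative errors add in quadrature for the
ratio. An undetectable background yields a flagged lower bound instead of a
ratio. Both raw copies and (via the standard curve) efficiency-corrected
copies feed the same ratio, so the reported fold is efficiency-corrected
whenever the curve is.

**Diversity arithmetic.** The expected number of distinct members among
`n` uniform draws from a pool of diversity `D` is `D(1 - (1 - 1/D)^n)`
(`expected_unique()`, computed with `log1p/expm1` so that `D >> n` does not
lose precision); `estimate_diversity()` inverts it, e.g. to turn "40 unique
of 48 sequenced hits" into a pool-diversity estimate. The selection
cascade model (`cascade_diversity()`) propagates this expectation through
the display, recovery, phage-library and infection steps. It is an
expectation-level model, not a stochastic simulator: the experimental
description provides endpoint diversities (10^12 displayed, 10^6-5 x 10^6
after the initial display round, 10^7 phage library, 2-5% phage infection),
which define the default step sizes; each step is treated as uniform
sampling from the surviving pool. Under these defaults the recovery of the
initial display round is the bottleneck, consistent with the observed
endpoint numbers.

**ELISA hit calling** uses a signal/background ratio threshold, default 3,
because the experimental readout ("strong and specific hits") does not
formalize a criterion; the threshold is exposed, and backgrounds below a
floor (default 0.01 absorbance units) are floored and flagged.

## Binding and stability models

All fitters use bounded Levenberg-Marquardt nonlinear least squares
(`minpack.lm::nlsLM`), pool replicate points by default, and always return
an explicit convergence flag; degenerate inputs (flat curves) are flagged,
never silently fitted.

**1:1 interaction kinetics.** Association
`R(t) = Rmax C/(C+KD) (1 - exp(-(kon C + koff) t))`, dissociation
`R_end exp(-koff t)`, continuous at the phase boundary; `KD = koff/kon`.
Mass-transport and drift terms are excluded (plain 1:1 fits). The global
fit across concentrations works on log-scale parameters (rates span orders
of magnitude and must stay positive); initialization takes `koff` from a
log-linear fit of the dissociation phase, `Rmax` from the largest observed
plateau, and `kon` from a log-spaced grid search. Parameter SEs come from
the log-scale covariance by the delta method.

**Schild allosteric competition.** The affinity ratio in the presence of a
competitor at concentration x is `(x/B + 1)/(alpha x/B + 1)`: 1 at x = 0,
saturating at `1/alpha`. With the characteristic parameters B = 1.0 uM and
alpha = 0.017 the saturation is 58.8; the package reports both `alpha` and
`1/alpha` and does not force either to match a rounded published value.
Initialization: `alpha` from the inverse of the largest observed ratio, B
from the concentration nearest the half-saturation ratio; `alpha` is
bounded to (0, 1].

**Hyperbolic inhibition.** Residual activity
`y = y0 + a IC50/(IC50 + x)`, with `y(0) = y0 + a` (normalized to 100%),
`y(Inf) = y0`, `y(IC50) = y0 + a/2`. Initialization from the data range and
the half-span crossing.

**Boltzmann melting.** `signal(T) = bottom + (top - bottom)/(1 +
exp((Tm - T)/slope))`; Tm is the inflection, where the curve passes through
`(bottom + top)/2`. The parameterization is fixed to this form since only
the function family is conventionally named. The slope's sign encodes the
transition direction (negative for a binding signal lost on melting, the
usual direction for the scintillation-proximity thermal-shift readout); Tm
initialization uses the temperature of steepest signal change. A fitted Tm
outside the measured temperature range flags the fit as unconverged.
`delta_tm()` returns `Tm(with binder) - Tm(without)`.

## Synthetic data

`sy_generate()` produces every dataset the analysis functions consume, with
a truth record of the generating parameters and full determinism per seed.
Default regimes follow the platform's assay designs: analyte series
0/1/3/9/27/81 nM, maltose series 0-100 uM, twelve-well temperature
gradients (30-60 degC), qPCR efficiencies in the 95-98% band, technical
triplicates. Default noise: SPR 1% of Rmax, melt 2% of the signal span,
qPCR Ct SD 0.15 cycles, all visible in `scenario_config()`.

The generators emulate the *statistical* structure of the assays (noise
level, replication, sampling design) under exactly the fitted models. They
do not emulate instrument artifacts: SPR bulk refractive-index jumps and
drift, qPCR melt-curve anomalies, plate edge effects, or sequence-dependent
synthesis bias. Passing parameter-recovery tests therefore demonstrates
correctness and statistical calibration of the estimators under the assumed
models, not robustness to model misspecification in real traces.

## Numerical choices and problem sizes

* Exact big-integer diversity; rounding only at reporting time.
* `expected_unique()` via `log1p`/`expm1`; diversity estimation by
  root-finding on the log scale.
* Monte-Carlo test sizes were chosen to give stable pass/fail behavior at
  small cost: 100 seeded runs per fitted model for noisy-recovery checks,
  1000 runs for enrichment error propagation, 10^4 replicates for
  distinct-count simulation, 10^5 draws for the mix frequency
  goodness-of-fit (chi-square at alpha = 0.01).
* Coordinates in the assembly simulator are 1-based with cuts "after base
  i"; overhangs are 5' extensions only (all supported enzymes leave 5'
  overhangs).

## Known limitations

* Loop and convex framework sequences are not built in, so full-length
  member realization and the non-randomized full-assembly check cover the
  concave library; loop/convex schemes operate on CDR cassettes (their slot
  counts and diversities are unaffected).
* Framework-internal substitutions outside the CDR primer windows (e.g. a
  V51L stabilization in the convex scaffold) are not modeled; positions are
  reconstructed solely from the CDR primers.
* The cascade model is expectation-level; it reports expected diversities,
  not their distributions.
* Single-cycle SPR kinetics and two-state binding models are out of scope;
  equilibrium-only affinity estimation is available through the isotherm
  plateau relation used for initialization.
* Experimental outcome figures (enrichment folds of 170/220/25, Tm shifts
  of 6.1-10 degC, an IC50 of 62 nM, 40/48 unique hits) depend on raw
  measurements that are not released; they serve here as regime anchors for
  the synthetic scenarios, and the package's tests verify model properties
  and parameter recovery in those regimes rather than reproducing the wet-lab
  numbers.
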