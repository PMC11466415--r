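---
title: "Evaluating fixed-backbone TCR interface designs with tcreval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating fixed-backbone TCR interface designs with tcreval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcreval)
```

## The problem

T cell receptors recognise peptides presented by MHC molecules through
their CDR loops; the hypervariable CDR3 loops of the α and β chains carry
most of the peptide contacts and most of the receptor's specificity. When
a design method (an inverse-folding network, or physics-based design)
proposes sequences for the interface positions of a fixed TCR backbone,
the natural yardstick is the native receptor solved in complex with its
pMHC: how often does the method recover the native amino acids, does it at
least stay within the right physicochemical class, and does it produce a
diverse set of candidates rather than one sequence m times?

`tcreval` implements that evaluation as a pipeline: structure in, designed
sequences in, metric tables and significance tests out.

## Position selection

Designable positions are selected from the bound complex:

1. **Interface detection.** Two residues are in contact when any pair of
   their atoms (all atoms, hydrogens included if present) lies within 5 Å.
   The boundary is *inclusive* (`d <= 5.0`); the underlying convention
   ("within 5 Å") does not state strictness, so the choice is explicit and
   configurable (`inclusive = FALSE` gives the strict rule). A TCR residue
   is "at the interface" if it contacts the peptide *or* the MHC.
2. **CDR delimitation.** Aho numbers are consumed as input (produced
   upstream by a numbering tool such as ANARCI; never inferred here).
   CDR1 = 27–40, CDR2 = 58–70, CDR3 = 106–139, all inclusive; everything
   else is framework.
3. **Scenario.** Five selection strategies: CDR3-at-interface,
   all-CDR-at-interface, all CDR3, all CDRs, full variable domain. They
   nest; positions are ordered α-chain first, then β, ascending residue
   number, so design strings are reproducible.

The pMHC-removal control (`strip_pmhc()`) drops the peptide and MHC chains
with coordinates untouched; positions selected on the bound complex remain
valid, so paired with/without-context design rounds can be compared on the
same positions (`compare_runs()`).

## Sequence metrics

Over $n$ designed positions with native $Y$ and design $X$:

* Sequence recovery $= 100\,\frac{1}{n}\sum_i \delta(x_i,y_i)$, computed
  as an integer match count over $n$ so that it is exact.
* Similarity recovery replaces $\delta$ with same-group membership in the
  fixed 6-group partition {A,G,S}, {C}, {D,E,P,T}, {Q,N,H,R,K},
  {I,L,M,V}, {F,Y,W}. The partition is **hard-coded**, not re-derived by
  clustering: the linkage and feature choices behind it are unspecified,
  while the partition itself is printed, so re-derivation could only
  introduce divergence.
* Uniqueness $= 100\,u/m$ over the **raw** generated set; so is the
  per-position Shannon entropy ($\log_2$, $0\log 0 = 0$, bounded by
  $\log_2 20 \approx 4.32$ bits) and its mean (MSE). These measure what
  the generator produced.
* Recovery-type statistics (per-design recovery/similarity, maximum
  recovery, per-position recovery, composition, substitution matrix,
  subset recovery) are computed on the **deduplicated** set (first
  occurrence kept): redundant designs would otherwise overweight a single
  solution.
* Per-position recovery is pooled across test cases by (chain role, Aho
  number); positions designed in fewer than `min_cases` (default 3) cases
  are flagged as sparse rather than silently dropped.
* The substitution matrix is normalised globally (all design × position
  cells sum to 100%) by default; per-native-amino-acid row normalisation
  is available via `normalize = "row"`. Composition pools positions
  uniformly across cases (not per-case weighted) — the simplest reading,
  documented here.
* Subset recovery over an all-false mask (e.g. a case with no buried
  designed position) is reported as missing (`NA`), never as 0.

## Solvent accessibility and burial

SASA is computed by the Shrake–Rupley rolling-probe algorithm with a
deterministic Fibonacci sphere lattice (default 960 points per atom,
probe 1.4 Å) and element-based van der Waals radii (C 1.7, N 1.55, O 1.52,
S 1.8, H 1.2, default 1.8 Å). The Fibonacci lattice makes results
reproducible and converges smoothly as the point count grows; quadrature
error at 960 points is well under the 2% band we verify against an
independent reference implementation. RSA divides per-residue SASA by the
theoretical maximum accessibility of the residue type (Tien et al.
reference table, replaceable via `max_asa_table`); a position is *buried*
iff RSA < 0.2, strictly. Burial is computed in the bound complex with all
chains present (including β2m when mapped); a TCR-only state can be
obtained by stripping the pMHC first — the bound state is the default
because burial feeds interface-focused subset recoveries.

Residues with unknown identity (`X`) have no reference maximum; their RSA
is `NA` and they are excluded from burial statistics and from designable
positions.

## Hotspots and statistics

Alanine-scan ΔΔG values are consumed from a TSV (the scan itself is run by
external software); a residue is a hotspot iff |ΔΔG| > 0.5 kcal/mol,
strictly.

**Group comparison.** To ask whether a small group of test cases (say 6
class-II cases) behaves like a reference panel (say 32 class-I cases), the
bootstrap test builds a null distribution of group means by subsampling
k = 6 cases from the reference panel 1000 times — without replacement
within each draw (the natural reading of "6 random test cases"; a
with-replacement mode is a flag) — and locates the observed test-group
mean with symmetric add-one empirical tails:
$p = 2\min(1 + \#\{\bar x^* \le \bar x_{obs}\},\;
1 + \#\{\bar x^* \ge \bar x_{obs}\})/(B+1)$, capped at 1. The add-one
form keeps $p \ge 2/(B+1) > 0$ on both sides. Reference values are sorted
internally before seeded subsampling, so the result is invariant to their
input order, not just in distribution.

**A calibration caveat.** This subsampling test is *anti-conservative for
small reference panels*. The null spread of a 6-subset mean of N
reference values around the reference mean is
$\frac{\sigma^2}{6}\cdot\frac{N-6}{N-1}$, while an independent 6-case mean
deviates from that same reference mean with variance
$\frac{\sigma^2}{6} + \frac{\sigma^2}{N}$. At N = 32 the ratio is ≈ 1.42,
and simulation puts the type-I error near 12% at nominal 5%; only for
large panels (N ≈ 1000) does the rejection rate approach 5% (verified in
the test suite, and independently cross-checked). The package implements
the procedure as defined — users comparing small panels should read its
p-values as optimistic, or prefer the rank-sum test below.

**Rank tests.** A self-contained two-sided Mann–Whitney test: exact
enumeration of the U distribution when the smaller group has ≤ 8
observations and there are no ties (it then matches the exhaustive
permutation distribution and `wilcox.test(exact = TRUE)`), otherwise the
normal approximation with tie and continuity corrections.

## The synthetic world

`generate_toy_complex()` builds a four-role pseudo-complex from idealised
5-atom residues (N, CA, C, O, CB): a 9-residue peptide (canonical MHC-I
epitope length), an MHC platform, and two TCR chains with framework, CDR1,
CDR2 and CDR3 residues carrying consistent Aho numbers. Defaults state the
world once: 10 CDR3 interface residues (matching the ~10 interface
positions typical of CDR3-interface design sets, and the 8–14 generator
band the tests check), 6 non-interface CDR3 residues, 2 buried residues, a
design budget of m = 10 per case. Interface residues are placed with
minimum atom distance ≤ 4.5 Å to the peptide and non-interface residues
≥ 7 Å from peptide and MHC, so the ground truth is robust on both sides of
the 5.0 Å boundary; buried residues are enclosed in a dense occluding
shell (an `other`-role chain) that drives their RSA near 0.

What the toys do **not** emulate: real loop conformations, packing,
chemistry, or the score distributions of any design method. A green
geometry test therefore establishes that contact detection, SASA, and
selection logic are correct on structures with known answers — not that
any particular design method is good.

`generate_design_set()` produces designs with controlled statistics: keep
the native with probability `p_match`, otherwise stay in the native's
group with probability `q_sim` (uniform over the group minus the native),
otherwise draw uniformly cross-group. Expected recovery is $100p$;
expected similarity is $100(p + (1-p)q)$ at non-cysteine positions —
cysteine's singleton group cannot host a same-group non-identity, so those
draws fall through to cross-group (the parameter-recovery checks use a
cysteine-free native for that reason). `random_dissimilar_baseline()`
substitutes every position cross-group excluding cysteine, so both
recovery and similarity are 0 by construction. All generators draw from
one seeded stream per call and never touch global RNG state.

## Numerical and interface choices

* Residue identity is (chain, residue number, insertion code)
  throughout; alternate locations resolve to blank/"A"; waters and
  non-polymer heteroatoms are excluded at parse time.
* Run configs are JSON (`load_run_config()`): same fields as the
  documented schema, validated programmatically; CSV outputs round
  percentages to 1 decimal, JSON keeps full precision. Runs are pure
  functions of (inputs, config, seeds) — two identical runs are
  byte-identical.
* Entropy uses base-2 logarithms; the plug-in estimator is biased low by
  at most $(K-1)/(2m\ln 2)$ bits for support size $K$, which the moment
  tests account for.
* The p-value floor, boundary strictness (RSA < 0.2, |ΔΔG| > 0.5,
  contact ≤ 5.0) and the deduplication conventions are fixed as documented
  above and exercised at their exact boundary values in the tests.

## Limitations

* PDB input only (no mmCIF), no structure repair or protonation.
* Aho numbering must be supplied; no numbering scheme conversion.
* The bootstrap group test inherits the small-panel anti-conservativeness
  described above; this is a property of the procedure, reported rather
  than silently corrected.
* ΔΔG tables, design sequences and numbering are consumed as inputs; the
  external tools that produce them are out of scope.
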