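---
title: "Conceptual-DFT reactivity descriptors: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conceptual-DFT reactivity descriptors: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdftkit)
```

## The problem this package addresses

Conceptual density-functional theory (CDFT) reads chemical reactivity off
quantities a standard Kohn–Sham calculation already produces: the chemical
potential, hardness and electrophilicity of the molecule as a whole, and the
Fukui and Parr functions that resolve reactivity atom by atom. For peptides —
here the motivating systems are marine cyclodepsipeptides such as the
theopapuamides — these descriptors connect electronic structure to expected
bioactivity, and a light chemoinformatic screen (drug-likeness rules, the
six-axis bioavailability radar) rounds out a first virtual-screening pass.

`cdftkit` implements everything downstream of the quantum chemistry. It never
runs an electronic-structure calculation: its input is a small JSON *record*
per molecule holding frontier-orbital energies, optionally the ground-state
total energies of the N−1, N and N+1 electron species, and optionally atomic
populations of the three species plus spin populations of the radical ions.

## Koopmans-in-DFT validation

The orbital route to reactivity descriptors is only trustworthy when the
functional behaves Koopmans-compliantly: −IP ≈ ε~HOMO~ and, through the
radical anion, −EA ≈ ε~LUMO~. `compute_kid()` quantifies the deviation with
four non-negative descriptors (eV),

$$J_I = |\epsilon_H + E(N{-}1) - E(N)|,\quad
  J_A = |\epsilon_L + E(N) - E(N{+}1)|,\quad
  J_{HL} = \sqrt{J_I^2 + J_A^2},$$

plus $\Delta S_L = |\epsilon_{SOMO}^{anion} - \epsilon_L|$. Values near zero
justify reading I and A from the orbitals. A record is called *compliant*
when every available descriptor is at or below a per-descriptor tolerance.
The literature only says compliant values are "very close to zero"; the
package pins the default tolerance at **0.10 eV**, exposed as an argument,
which comfortably accepts the benchmark peptides (all ≤ 0.043 eV) and
rejects clearly non-compliant functionals (deviations of several tenths of
an eV are typical for uncorrected GGAs on these systems). Partial records
produce partial reports rather than errors, because published benchmarks
routinely tabulate $\Delta S_L$ next to J-descriptors derived from different
inputs.

## Global descriptors

With $I$ and $A$ from either the orbital energies (default) or
total-energy finite differences:

$$\chi = \tfrac{1}{2}(I + A), \qquad \eta = I - A, \qquad S = 1/\eta,
  \qquad \omega = \chi^2 / 2\eta,$$
$$\omega^- = \frac{(3I + A)^2}{16\eta}, \qquad
  \omega^+ = \frac{(I + 3A)^2}{16\eta}, \qquad
  \Delta\omega^\pm = \omega^+ + \omega^-.$$

Two identities follow algebraically and are enforced by tests:
$\Delta\omega^\pm = \omega^+ + \omega^-$ exactly, and
$\omega^- - \omega^+ = \chi$ to floating-point precision. The two modes
coincide exactly on Koopmans-exact inputs, and their discrepancy on real
inputs is bounded by the KID descriptors — which is precisely why the KID
check comes first.

Design choices that were genuinely open:

* **Softness is pinned to S = 1/η.** One published benchmark softness cell
  (theopapuamide D, 0.2012 eV⁻¹) matches neither 1/η of its own hardness
  column (0.1733) nor any finite-difference hardness consistent with the
  rest of the row, while the other three rows agree with 1/η to ~10⁻³. The
  package does not guess at the provenance of that cell; it documents the
  mismatch (see `?theopapuamide_reference`) and keeps the textbook
  convention.
* **The nucleophilicity index** N = ε~HOMO~ − ε~HOMO~(TCE) needs a
  tetracyanoethylene reference at the same level of theory. The shipped
  default, −9.1212 eV (`tce_homo_default`), is *calibrated* from the
  benchmark (peptide A's published HOMO and N), not computed ab initio, and
  is documented as such. It reproduces the published N of peptides B and C
  to 4 decimals; peptide D's published N (3.2174 eV) is inconsistent with
  any single reference fitting A–C (which imply 2.4452 eV) and is flagged,
  not reproduced.
* **Nucleophile classes**: strong above 3.0 eV, moderate above 2.0 eV,
  marginal otherwise; the upper bound follows the benchmark's usage, the
  lower one the Domingo scale. Both are arguments.

## Local descriptors

Condensation uses population differences, with populations expressed through
partial charges ($p_k = -q_k$, so only differences matter):
$f^+_k = q^N_k - q^{N+1}_k$, $f^-_k = q^{N-1}_k - q^N_k$,
$f^0_k = (f^+_k + f^-_k)/2$, dual $= f^+_k - f^-_k$. The Parr functions are
the atomic spin populations of the radical ions ($P^-$: cation, $P^+$:
anion), and their difference $P^+ - P^-$ is carried as a dual-descriptor
analogue. Grid- or cube-based condensation is out of scope.

**Sign convention (stated prominently because the literature disagrees):**
dual > 0 marks sites favored for *nucleophilic* attack, dual < 0 for
*electrophilic* attack. `rank_sites()` ranks descending, ties broken by
ascending atom index; hydrogens are kept by default (`heavy_only = FALSE`)
since the appendix-style site tables this mirrors do not establish a
hydrogen-exclusion convention. The population-analysis scheme behind the
charges ("Hirshfeld", "MBS", ...) is carried as an opaque metadata tag and
never interpreted, because condensed values are only comparable within one
scheme and the upstream scheme is frequently unstated.

`compare_fukui_parr()` reports, per attack channel, the top-k overlap of
Fukui- and Parr-ranked sites and the concentration ratio
max(Parr)/max(Fukui); ratios above 1 reproduce the known observation that
Parr functions are the sharper site maps.

## The pKa model

For families of related peptides, pKa is modeled as affine in global
hardness, pKa = a + b·η, fitted by ordinary least squares (`stats::lm`).
The model form is pinned because the four packaged benchmark pairs are
collinear to a maximum residual of 0.003 pKa units — an affine model
reproduces every published pKa to 2 decimals — and because it follows the
methodology the benchmark itself cites. `pka_default_model()` refits the
coefficients from the packaged pairs at call time; they are re-derived
values (a ≈ 16.23, b ≈ −0.81 pKa/eV), and the originally published
coefficients, which are not printed alongside the benchmark, may differ in
later digits.

## Drug-likeness profiling

`compute_profile()` computes open, reproducible descriptors from SMILES via
OpenBabel: molecular weight, atom-contribution logP (recorded by name —
deliberately *not* the proprietary estimator behind some published logP
tables, which the package makes no attempt to match), Ertl fragment TPSA,
Lipinski H-bond donors and N+O acceptors, molar refractivity, and SMARTS
counts for rotatable bonds (classic Daylight/Veber pattern; amides count),
sp³ carbon fraction and aromatic proportion. Water solubility uses the ESOL
topological model, logS = 0.16 − 0.63·logP − 0.0062·MW + 0.066·RB −
0.74·AP, chosen because it needs no 3-D structure and its coefficients are
published. The six radar axes (LIPO, SIZE, POLAR, INSOLU, INSATU, FLEX) use
the widely published optimal ranges as closed intervals — a value exactly on
a bound is in range — and every bound is configurable, since radar charts
are typically published without their ranges.

## The synthetic-record generator

`generate_synthetic_record()` emulates what a well-behaved single-point
summary looks like, with every knob the tests need:

* frontier energies drawn with HOMO in (−9, −5) eV and a gap in (2, 7) eV —
  the range typical of mid-size organic molecules in implicit solvent;
* total energies constructed so the KID descriptors equal injected
  deviations drawn uniformly from ±0.05 eV by default, the magnitude a
  Koopmans-compliant functional actually shows; `delta_max = 0` gives the
  exact-functional limit;
* atomic charge sets built from normalized Fukui weights so every sum rule
  holds *exactly*, and spin populations as renormalized squares of those
  weights, reproducing the empirical "Parr maps are sharper but rank sites
  identically" behavior.

What it does **not** emulate: correlated noise between charge schemes,
basis-set or solvent sensitivity, open-shell parents, or any relation
between the molecular graph and the populations (elements are decorative).
Passing property tests therefore demonstrate the *arithmetic* contracts —
sum rules, identities, mode agreement — not agreement with any particular
population analysis on real molecules.

## Numerical choices

* Hartree→eV fixed at 27.211386 (`ev_per_hartree`) for bit-reproducibility;
  descriptors are computed in eV regardless of the record's unit, so unit
  conversion commutes with every computation to < 10⁻⁹ relative.
* Population sum rules are checked to 10⁻³ e by default (population
  analyses carry rounding); configurable.
* Report CSVs print eV quantities to 4 decimals, matching the conventional
  table shape; JSON sidecars keep full precision.
* Reproduction tests against the published benchmark use a tolerance of one
  unit in the last printed digit (1.1×10⁻⁴ eV): the printed inputs are
  themselves rounded to 4 decimals, and the benchmark carries two
  independent last-digit inconsistencies (peptide D's gap; peptide B's
  J~HL~, printed 0.043 where its printed components give 0.042).

## Problem sizes

The shipped test and acceptance workloads are deliberately desk-scale: the
four-record benchmark, 100 generated records for the sum-rule suite, 10⁴
random frontier-energy pairs for the algebraic identity, a 50-point noisy
refit for pKa parameter recovery, and a handful of small-molecule SMILES.
Everything completes in seconds.

## Known limitations

* No quantum-chemistry log parsing (`convert_qc_log()` is a documented
  stub) and no conformer search, geometry optimization or solvation free
  energies — records are consumed, not produced.
* No volumetric (cube-file) local descriptors or isosurface rendering;
  condensed per-atom values only.
* The logP and logS estimators are open approximations; published tables
  built on proprietary estimators will differ systematically.
* Trained ADME endpoint predictions (P-gp, CYP inhibition, GI absorption
  calls) are out of scope; only rule-based flags are computed.
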