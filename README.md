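# cdftkit

Conceptual-DFT reactivity descriptors and drug-likeness screening for
computational peptidology.

Given per-molecule electronic-structure summaries (frontier-orbital
energies, optionally total energies of the N−1/N/N+1 electron species and
atomic populations), `cdftkit` computes everything a CDFT-based virtual
screen needs downstream of the quantum chemistry:

- **KID validation** — Koopmans-in-DFT compliance descriptors
  `J_I = |ε_H + E(N−1) − E(N)|`, `J_A = |ε_L + E(N) − E(N+1)|`,
  `J_HL = √(J_I² + J_A²)` and `ΔS_L = |ε_SOMO(anion) − ε_L|`, with a
  per-descriptor tolerance verdict.
- **Global descriptors** — electronegativity `χ = (I+A)/2`, hardness
  `η = I − A`, softness `S = 1/η`, electrophilicity `ω = χ²/2η`,
  electrodonating/electroaccepting powers `ω⁻ = (3I+A)²/16η`,
  `ω⁺ = (I+3A)²/16η`, net electrophilicity `Δω± = ω⁺ + ω⁻`, and the
  nucleophilicity index `N = ε_H − ε_H(TCE)` with the Domingo
  strong/moderate/marginal classification.
- **Local descriptors** — condensed Fukui functions `f⁺, f⁻, f⁰`, the dual
  descriptor, Parr functions `P⁻, P⁺` (radical-ion spin populations) and
  their difference; site ranking and Fukui-vs-Parr agreement summaries.
- **pKa** — an affine-in-hardness model `pKa = a + b·η` fitted by ordinary
  least squares.
- **Drug-likeness** — SMILES-based physicochemical profiles (MW, open logP,
  TPSA, HBD/HBA, rotatable bonds, sp³ fraction, ESOL logS), the six-axis
  bioavailability radar (LIPO/SIZE/POLAR/INSOLU/INSATU/FLEX) and
  Lipinski/Veber rule flags, via OpenBabel.

Records are flat JSON documents with a schema version; a synthetic-record
generator with exact population sum rules supports testing and simulation.
The package ships the published theopapuamide A–D benchmark as fixtures
(`theopapuamide_records()`, `theopapuamide_reference()`).

## Worked example

```r
library(cdftkit)

recs <- theopapuamide_records()
global_table(recs)
#>       molecule_id     chi    eta    omega  softness nucleophilicity_n
#> 1 Theopapuamide A 3.56620 5.4904 1.158184 0.1821361            2.8098
#> 2 Theopapuamide B 3.68085 5.2197 1.297839 0.1915819            2.8305
#> 3 Theopapuamide C 3.60090 5.4232 1.195464 0.1843930            2.8087
#> 4 Theopapuamide D 3.79000 5.7720 1.244291 0.1732502            2.4452
#>   omega_minus omega_plus net_electrophilicity
#> 1    4.442617  0.8764172             5.319034
#> 2    4.762334  1.0814835             5.843817
#> 3    4.530328  0.9294280             5.459756
#> 4    4.744333  0.9543328             5.698666
```

Peptide B is the softest (smallest gap, η = 5.22 eV) and most
electrophilic of the family; all four are moderate-to-strong electron
donors (ω⁻ ≫ ω⁺). The hardness column feeds the pKa model:

```r
m <- pka_default_model()
m
#> <hardness-based pKa model>
#>   pKa = 16.2331 + (-0.8131) * eta  [fit on n = 4, max |resid| = 0.003219]
round(predict_pka(m, global_table(recs)$eta), 2)
#> [1] 11.77 11.99 11.82 11.54
```

KID compliance and a quick drug-likeness screen:

```r
compute_kid(recs$A)$delta_sl        # 0.0041 eV: Koopmans-compliant
p <- compute_profile("CCO")
radar_axes(p)                       # six radar axes with in-range flags
```

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "cdftkit.R", package = "cdftkit"))') \
    global inst/extdata/theopapuamide_*.json
```

See `vignettes/conceptual-dft-descriptors.Rmd` for the models, sign
conventions, calibration notes and known limitations.

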