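# hydroinfo

Information-theoretic evaluation of rigid three-site water models (TIP3P,
SPC, SPC/ε — written `SPCE` here) on a desktop: surrogate Gaussian-mixture
electron densities built from force-field geometries and charges, five
information descriptors in position and momentum space, Sevick
oxygen–oxygen cluster identification, and the statistical protocol
(Shapiro–Wilk, Filliben probability plots, Welch's t) that decides whether
two models are distinguishable. The package is aimed at force-field
developers and molecular-simulation practitioners who want electronic-level
comparisons of water models without running molecular dynamics or DFT.

## The descriptors

For a unit-normalized 3D probability density ρ(r) (all values in atomic
units, entropies in nats):

| measure | definition | meaning |
|---|---|---|
| Shannon entropy | S = −∫ ρ ln ρ dr | global delocalization |
| Fisher information | I = ∫ \|∇ρ\|²/ρ dr | local sharpness |
| disequilibrium | D = ∫ ρ² dr | distance from uniformity |
| LMC complexity | C_LMC = D·e^S | order–disorder balance, ≥ 1 |
| Fisher–Shannon complexity | C_FS = I·J, J = e^(2S/3)/(2πe) | local–global balance, ≥ 3 |

Each is computed in position space and, through the momentum conjugate of
the isotropic-Gaussian surrogate (σ_p = 1/(2σ_r), weights preserved), in
momentum space. For any single Gaussian the two entropies obey
S_r + S_p = 3(1 + ln π) ≈ 6.43388, and C_FS attains its lower bound of 3 —
both serve as standing numerical checks.

## Worked example

Descriptor set of the TIP3P surrogate monomer density:

```r
library(hydroinfo)
ff <- water_models()
print(descriptor_set(make_monomer_density(ff$TIP3P)))
#> <descriptor_set> (a.u. / nats)
#>         S        I         D   C_LMC    C_FS
#> r 2.61089 11.91540 0.1623110 2.20924 3.97707
#> p 4.40483  2.73714 0.0206787 1.69245 3.02101
#> quadrature error estimate: 6.34e-08
```

The position row says the three-atom mixture is much sharper than a unit
Gaussian (I ≈ 11.9 vs 3) and correspondingly far from uniform
(D ≈ 0.16); both complexities sit above their universal bounds (1 and 3),
as they must for any valid density. Can the descriptors tell TIP3P from
SPC from jittered 30-frame ensembles?

```r
tab_spc <- make_descriptor_samples(ff$SPC,   ensemble_spec(1, n_frames = 30, seed = 42))
tab_tip <- make_descriptor_samples(ff$TIP3P, ensemble_spec(1, n_frames = 30, seed = 43))
pick <- function(tab) subset(tab, space == "r" & measure == "S")$value
res <- welch_t(pick(tab_tip), pick(tab_spc))
#> Welch t = -16.70, df = 57.0, p = 1.24e-23, significant = TRUE
```

TIP3P's shorter O–H bond and tighter angle separate it decisively, while
the same test on SPC vs SPCE (identical geometry) stays non-significant —
the built-in null experiment. The `analysis/` scripts run these studies at
full size (`01` force fields, `02` monomer discrimination, `03` cluster
identification, `04` size scaling 1→11 molecules) and write their tables
under `results/`.

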