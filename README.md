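# dendripH

pH-dependent structural and energetic analysis of cationic peptide
dendrimers bound to siRNA duplexes.

Peptide dendrimers such as MH18 and its variants condense siRNA through
their protonatable amines, and the strength of that binding changes
between neutral and endosomal pH because the dendrimer N-termini
(intrinsic pKa ~7.5) titrate across exactly that range. Constant-pH
simulation studies of these carriers lean on a recurring set of
analyses; `dendripH` implements that analysis layer as a tested R
package for anyone who wants to run, check, or reuse the machinery:

* **Coupled-site titration Monte Carlo** with an exact 2^N Boltzmann
  enumeration oracle, for sampling protonation microstates
  $E(s) = \sum_i s_i[\ln 10\,RT(\mathrm{pH}-\mathrm{p}K_{a,i}) + \phi_i]
  + \sum_{i<j} W_{ij}s_i s_j$.
* **Hill-equation pKa fitting** of group titration curves,
  $f(\mathrm{pH}) = 1/(1+10^{n(\mathrm{pH}-\mathrm{p}K_a)})$, including
  apparent pKa values conditioned on phosphate contact (within 4 A) or
  groove burial (within 6 A).
* **Binding-mode geometry**: position along the duplex (0-100),
  helix bending angle, major/minor groove mapping with signed
  distances, amine-phosphate contact counts, Rg, RMSD, charge.
* **Surfaces**: Shrake-Rupley SASA, phosphate electrostatic shielding,
  buried interface area.
* **Conditional free-energy landscapes** over (signed groove distance,
  phosphate distance) via 2-D Gaussian KDE and
  $E(r) = -RT\ln(P(r)/P_{max})$.
* **Protonation-weighted MM/PBSA** (single-trajectory protocol) with a
  finite-difference Poisson-Boltzmann solver (dielectrics 4/80,
  Born-ion validated), Lennard-Jones and screened Coulomb terms, and a
  SASA-linear apolar term.
* **Wyman-Tanford proton linkage**:
  $\Delta\Delta G = \ln 10\,RT(\Delta Q_{\mathrm{pH}} -
  \Delta Q_{\mathrm{pH_{ref}}})$ between pH 5 and 7.
* A **synthetic-ensemble generator** (rigid idealized 21-bp duplex +
  branched dendrimer bead tree + titration MC) that produces bound and
  apo ensembles with the statistical structure the analyses assume, so
  everything runs self-contained.

See the methods vignette (`vignettes/dendripH-methods.Rmd`) for the
models, numerical choices and limitations.

## Worked example

```r
library(dendripH)

# a bound MH18-duplex ensemble at pH 7
ens <- sampleEnsemble(nFrames = 50, ph = 7, bound = TRUE, seed = 42)
ens
#> ComplexEnsemble: 50 frames, 162 atoms, 20 sites | pH 7.0 | bound | rep 1
#>   partners: DENDRIMER=38 RNA_A=62 RNA_B=62
#>   site groups: G2=4 G3_NTR=8 G3_SIDE=8

round(colMeans(geometryTable(ens, burnInFraction = 1/3)[,
  c("positionPct", "bendDeg", "nContacts", "rg", "charge")]), 2)
#> positionPct     bendDeg   nContacts          rg      charge
#>       50.35      179.52        2.68       10.09       17.50

# N-termini titration, apo vs bound
phGrid <- seq(4, 9.5, by = 0.5)
apo <- lapply(phGrid, function(p)
  sampleEnsemble(nFrames = 30, ph = p, bound = FALSE, seed = 42))
bnd <- lapply(phGrid, function(p)
  sampleEnsemble(nFrames = 30, ph = p, bound = TRUE, seed = 42))
hillFit(buildTitrationCurve(apo, "G3_NTR"))
#> HillFit: pKa = 6.817 +/- 0.010, n = 0.928 +/- 0.017
hillFit(buildTitrationCurve(bnd, "G3_NTR"))
#> HillFit: pKa = 7.442 +/- 0.028, n = 0.691 +/- 0.028

# proton-linkage free energy gain on acidification
wt <- wtLinkFromEnsembles(bnd[phGrid %in% c(5, 7)],
                          apo[phGrid %in% c(5, 7)], ph = 5, refPh = 7)
sprintf("ddG(pH5-pH7) = %.2f kcal/mol (dQ5 = %.2f, dQ7 = %.2f)",
        wt$ddG, wt$dqPh, wt$dqRef)
#> "ddG(pH5-pH7) = -3.33 kcal/mol (dQ5 = 0.05, dQ7 = 2.40)"
```

Read: the duplex stays straight (bend ~180 degrees), the dendrimer sits
near mid-duplex holding 2-3 amine-phosphate contacts, and binding
raises the N-termini apparent pKa (6.82 -> 7.44) while flattening the
Hill slope (0.93 -> 0.69) -- the anti-cooperative coupling signature.
Because binding increases proton uptake mostly at pH 7 (dQ7 = 2.4 e vs
dQ5 = 0.05 e), acidification strengthens binding by ~3 kcal/mol.

The full pipeline (geometry + surfaces + pKa table + MM/PBSA + linkage
+ landscape grids, deterministic under one seed) is one call:

```r
runPipeline(runConfig(seed = 42), "report/")
```

A thin command-line wrapper with `generate` / `analyze` / `report`
subcommands is installed at `inst/scripts/dendripH-cli.R`.

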