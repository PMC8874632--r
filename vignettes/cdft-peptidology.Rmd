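---
title: "Conceptual-DFT computational peptidology with cdftpept"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conceptual-DFT computational peptidology with cdftpept}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdftpept)
```

## The problem

Conceptual density functional theory (CDFT) reads chemical reactivity off
a handful of energy derivatives with respect to electron number. For
molecules the size of marine cyclohexadepsipeptides, no experimental
ionization energies or electron affinities exist, so every descriptor is
estimated from the frontier orbital energies of a single Kohn-Sham
calculation — which makes the *choice of density functional* the central
methodological risk. `cdftpept` post-processes per-species quantum-chemistry
energetics into

1. the global reactivity descriptor set and its strong/moderate/marginal
   scale bands,
2. a validation of the functional against the ionization energy theorem
   (the KID procedure and its aggregate, GKD),
3. grid-based local descriptors (Fukui functions, dual descriptor), and
4. a pharmacology layer: a hardness-based pKa QSAR plus classification of
   externally predicted bioactivity and ADMET panels.

The package never runs electronic-structure calculations; its inputs are a
documented energetics schema, Gaussian cube density files, and delimited
score/ADMET tables.

## Global descriptors

With $\epsilon_H$, $\epsilon_L$ the neutral molecule's frontier orbital
energies (eV) and $\eta = \epsilon_L - \epsilon_H$ the full gap:

$$\chi = -\tfrac{1}{2}(\epsilon_H+\epsilon_L), \qquad
S = 1/\eta, \qquad
\omega = \chi^2 / 2\eta,$$
$$\omega^- = (3\epsilon_H+\epsilon_L)^2/16\eta, \qquad
\omega^+ = (\epsilon_H+3\epsilon_L)^2/16\eta, \qquad
\Delta\omega^\pm = \omega^- + \omega^+,$$
$$N = \epsilon_H(\text{molecule}) - \epsilon_H(\text{TCE}).$$

Three conventions here were genuinely open and are fixed as follows:

* **Sign of $\chi$.** We report electronegativity as a positive magnitude,
  $\chi = -\mu$; the chemical potential is exposed separately as
  `chemical_potential()`. This is the convention reactivity tables print.
* **Denominator of $\omega$.** Both $\chi^2/\eta$ and $\chi^2/2\eta$
  circulate in the literature. The shipped Veraguamide reference table is
  consistent only with $\chi^2/2\eta$ (the $\chi^2/\eta$ variant is exactly
  double every entry), so that is the default;
  `electrophilicity(..., denominator = "4eta")` retains the other form for
  auditing.
* **Hardness without the 1/2.** $\eta$ is the full gap — under this choice
  the hardness column coincides with the printed HOMO-LUMO gap, and
  $S = 1/\eta$ reproduces the published softness while $1/2\eta$ does not.

The nucleophilicity origin (`tce_homo_reference`, default −8.793 eV) is a
derived constant: back-computed as $\epsilon_H - N$ from the shipped
tables, where it agrees to ±0.001 eV across all seven molecules. It is a
property of the model chemistry (functional, basis, solvent), so
`reactivity_config()` makes it overridable.

Scale bands use the published cutoffs — electrophiles: strong $\omega >
1.5$ eV, marginal $< 0.8$; nucleophiles: strong $N > 3.0$ eV, marginal
$\le 2.0$. The sources leave boundary behaviour unstated; we resolve exact
ties toward the middle band, documented in `classify_electrophile()` /
`classify_nucleophile()`.

```{r}
triads <- read_energetics_table(
  cdft_example("veraguamides_mn12sx_h2o_energetics.csv"))
head(global_descriptor_table(triads), 3)
```

## KID validation and the global KID descriptor

For the exact functional the frontier eigenvalues equal minus the vertical
ionization energy and electron affinity. The deviations

$$J_I = |\epsilon_H + E_{gs}(N{-}1) - E_{gs}(N)|, \quad
J_A = |\epsilon_L + E_{gs}(N) - E_{gs}(N{+}1)|, \quad
J_{HL} = \sqrt{J_I^2+J_A^2},$$

together with $\Delta_{SL} = |\epsilon_{SOMO}(\text{anion}) -
\epsilon_L(\text{neutral})|$, aggregate into

$$GKD = \sqrt{J_I^2 + J_A^2 + J_{HL}^2 + \Delta_{SL}^2}.$$

Two deliberate choices:

* All indices are stored as **magnitudes** (the signed one-sided deviations
  are not individually meaningful once aggregated, and reference tables
  print non-negative values).
* $GKD$ **double-counts** $J_I$ and $J_A$ through $J_{HL}$ — that is its
  definition, and we implement it as defined
  ($GKD^2 = 2J_{HL}^2 + \Delta_{SL}^2$ is asserted as an invariant). The
  non-redundant aggregate $\sqrt{J_I^2+J_A^2+\Delta_{SL}^2}$ is available
  as `gkd_nonredundant()` and is never silently substituted.
* $\Delta_{SL}$ uses the **anion's SOMO** (the HOMO of the N+1-electron
  doublet), the column reference tables tabulate; when it is near zero the
  derivative discontinuity is negligible and the LUMO is a trustworthy
  electron-affinity proxy.

Benchmark matrices average per-molecule GKD per (functional, solvent) cell
with an unweighted arithmetic mean, and `rank_functionals()` orders
functionals ascending in mean GKD with alphabetical tie-breaks for
determinism. On the shipped ten-functional matrix MN12SX leads in every
polar solvent, while in the gas phase the range-corrected wB97XD (mean GKD
0.28) edges out CAM-B3LYP (0.48) — the two gas-phase leaders.

### Known data inconsistencies

The shipped reference tables carry three internal discrepancies that the
package documents rather than hides:

* molecules A and F: $|\epsilon_{SOMO}-\epsilon_L|$ from the printed
  orbital columns (0.008, 0.044 eV) disagrees with the printed
  $\Delta_{SL}$ (0.003, 0.019 eV). `delta_sl()` computes from orbital
  energies; the consistency analysis excludes those two rows.
* the mean per-molecule GKD recomputed from the rounded printed indices
  (≈0.026 eV) differs from the benchmark matrix's H2O entry (0.01),
  presumably an unrounded-source effect; no assertion ties the two.
* the published pKa table is inconsistent with the published QSAR (below).

## Local descriptors

The nucleophilic and electrophilic Fukui functions are finite-difference
density differences on a voxel grid,
$f^+(\mathbf r) = \rho_{N+1}-\rho_N$ and
$f^-(\mathbf r) = \rho_N-\rho_{N-1}$, and the dual descriptor is their
difference (the two-parabola realization of the derivative of the Fukui
function with respect to electron number, the only form computable from
three species). $DD > 0$ marks sites prone to nucleophilic attack,
$DD < 0$ electrophilic ones.

Numerical choices: rectangle-rule quadrature (voxel sum × volume), the
standard for cube-file post-processing; grid compatibility is exact match
of shape with origin/axes agreement to $10^{-6}$ Bohr — mismatched grids
are refused, never resampled; cube text is written at six significant
figures, which bounds the round-trip error asserted in the tests.
Condensed per-atom variants use the charge-difference convention
($f^+_k = q_k(N)-q_k(N{+}1)$, etc.), signed so that both Fukui vectors sum
to +1.

## The pKa QSAR and the pharmacology layer

`predict_pka()` evaluates the published linear relationship
$\mathrm{p}K_a = 16.3088 - 0.8268\,\eta$ exactly as stated. Applied to the
shipped hardness values it yields 11.2–11.6, *not* the published 12.36–12.62
— and with the opposite ordering in $\eta$. Whether a different hardness
convention or geometry fed the published table is not recoverable from the
source; the package evaluates the formula as printed, ships the published
pKas as reference data with a discrepancy note, and asserts nothing that
forces agreement.

Bioactivity scores classify as active ($>0$), inactive ($<-5$), moderately
active between, with both boundaries assigned to the middle band (the
stated wording overlaps at 0; inclusive-middle is the documented
resolution). The ADMET layer is ingestion-only — the booleans come from
external predictors — and the summary partitions each of the 18 vocabulary
properties into uniformly positive / uniformly negative / mixed, exactly
one status each.

## The synthetic generator

`emulate_functional()` builds molecules whose KID ground truth is known by
construction: draw a vertical ionization energy $I \sim U(5, 8)$ eV and
affinity $A \sim U(0, 2)$ eV (ranges typical of mid-size closed-shell
organics in solvent), set total energies to $E_{gs}(N)=0$, $E_{gs}(N{-}1)=I$,
$E_{gs}(N{+}1)=-A$ (only differences enter any index), and perturb the exact
eigenvalues $-I$, $-A$, $\epsilon_{SOMO}=\epsilon_L$ with independent
$\mathcal N(0,\sigma)$ deviations. Additive Gaussian noise is the simplest
model that makes every expectation analytic: each one-sided deviation is
half-normal with mean $\sigma\sqrt{2/\pi}$, which the tests check at three
standard errors. What this does **not** emulate: the solvent dependence of
real functionals' Koopmans compliance (solvents are labels in the synthetic
suite), correlated HOMO/LUMO errors, or size-dependent trends — so passing
the synthetic suite validates the arithmetic and statistics of the KID
pipeline, not any claim about real functionals.

`gaussian_density_triad()` generates analytic density triads as sums of
isotropic normalized Gaussians evaluated at voxel centers (midpoint rule,
spectrally accurate for smooth Gaussians), with optional per-center
occupancies to localize the added electron. The box must cover every
center to $\pm5\sigma$, bounding truncated mass below $10^{-6}$.

Generators take an explicit `seed`, restore the caller's RNG state, and are
bitwise reproducible.

## Problem sizes and verification scope

The test-suite and analysis problem sizes are chosen where the statistics
stabilize: 1000 molecules for the exact-compliance check (pure arithmetic),
200 per noise level for half-normal recovery (3-standard-error band ≈ 5% of
the mean), 100 per cell for rank recovery (separation $\sigma = 0.005$ vs
$0.5$ is many times the sampling noise), and $64^3$ grids for Fukui
normalization (quadrature error well under the 1% assertion). The seven
shipped molecules are recomputed exactly as published.

## Limitations

* Only the frontier-orbital (vertical, single-point) descriptor forms are
  implemented; finite-difference global descriptors from total energies
  are out of scope by design.
* No native quantum-chemistry log parsing: the delimited energetics schema
  is the contract, and adapters belong upstream.
* Hirshfeld partitioning is not performed; condensed Fukui functions take
  externally computed charges.
* The pKa QSAR extrapolates far beyond the small peptides it was calibrated
  on; treat its output as a trend, and see the discrepancy note above.
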