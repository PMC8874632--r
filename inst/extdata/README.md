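# Shipped example data

Reference values for the Veraguamides A-G marine cyclohexadepsipeptides at
the MN12SX/Def2TZVP model chemistry with SMD water solvation, transcribed
from the published study this package's fixtures derive from, plus the
multi-functional GKD benchmark matrix.

- `veraguamides_mn12sx_h2o_energetics.csv` — the canonical energetics input
  schema (one row per electronic species). Ground-state total energies were
  not published and are left empty: KID operations that need them refuse
  these records, which is intended. HOMO/LUMO are on the neutral rows, the
  anion SOMO on the charge −1 rows; all energies in eV.
- `veraguamides_kid_published.csv` — published orbital energies, H-L gap
  and KID indices J(I), J(A), J(HL), ΔSL (eV). Note for molecules A and F
  the printed ΔSL (0.003, 0.019) is inconsistent with |SOMO − LUMO| from
  the printed orbital columns (0.008, 0.044); this package computes ΔSL
  from orbital energies and does not force agreement for those two rows.
- `veraguamides_global_published.csv` — published global reactivity
  descriptor table (χ, η, ω, S, N, ω⁻, ω⁺, Δω±).
- `gkd_benchmark_solvents.csv` — mean GKD over the seven molecules for ten
  density functionals in twelve solvents (rows carry 1/ε). ω is written
  `w` in functional labels (`wB97XD`, `LC-wHPBE`).
- `veraguamides_pka_published.csv` — published pKa predictions. These are
  NOT reproduced by the stated QSAR pKa = 16.3088 − 0.8268η with the
  published hardness values (which give ≈11.2–11.6 with the opposite
  η-ordering); the file documents the published numbers only and nothing
  in the package asserts agreement.
- `veraguamides_bioactivity_scores.csv` — externally predicted bioactivity
  scores for the six target classes.
- `veraguamides_admet.csv` — ADMET panel as a `+`/`-` matrix
  (18 properties × 7 molecules) from external predictors; this package
  only ingests, classifies and summarises it.
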