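---
title: "Geometric filtering of docked peptide poses for cleavage-site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric filtering of docked peptide poses for cleavage-site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavedock)
```

## The problem and the model

Proteolytic activation of the epithelial sodium channel (ENaC) requires
excision of an inhibitory tract from the γ-subunit: one cleavage proximal to
the tract (the furin-region polybasic site, R138 within 135-RKRR-138) and one
distal to it. TMPRSS2 is a trypsin-like serine protease — catalytic triad
His296/Asp345/Ser441, with an aspartate (D435) at the bottom of its S1 pocket
that selects for positively charged P1 side chains. Which of the several
arginines and lysines distal to the tract does it actually use?

`cleavedock` operationalises a docking-based answer. Candidate P1 residues
are enumerated from the sequence; a 6-mer peptide window around each
candidate region is docked into the catalytic domain (externally); and each
docked binding mode is kept or discarded by two geometric criteria:

* **Criterion i (S1 salt bridge).** The minimum heavy-atom distance between
  the P1 charged group (Arg NH1/NH2/NE, Lys NZ) and the S1 aspartate's
  carboxylate oxygens OD1/OD2 must be below `salt_bridge_max` (default
  4 Å). The charged-group/carboxylate minimum is the standard salt-bridge
  criterion; the exact atom pairs measured are configurable in
  `selection_criteria()` because different conventions exist.
* **Criterion ii (scissile presentation).** The distance from that residue's
  backbone carbonyl carbon to Ser441's hydroxyl oxygen OG must be below
  `scissile_max` (default 4 Å) — the geometry needed for nucleophilic
  attack on the scissile bond. Criterion ii is only evaluated for the S1
  occupant: the scissile bond is *defined* by whichever residue sits in S1.

Both bounds are strict inequalities by default ("less than"), with a
`strict_inequality = FALSE` switch for sensitivity analysis. When several
basic residues satisfy criterion i, the smallest salt-bridge distance wins,
with ties broken by the P1 preference order (Arg before Lys) and then the
lower residue number; this matches the empirical observation of exactly one
S1 occupant per productive mode. Hydrogens are ignored throughout (docked
structures rarely carry reliable ones), and poses are assumed to share the
receptor coordinate frame, as docking output does — no superposition is
performed anywhere.

## Specificity rules

`specificity_rules()` encodes the trypsin-like profile reported for TMPRSS2:
Arg or Lys required at P1, Arg strongly preferred over Lys, and Lys at P2
incompatible with cleavage. The P2 rule *excludes* a candidate (e.g. R180 in
177-GRKR-180, whose P2 is K179) but the candidate is retained in outputs
with its exclusion reason, so occupancy reports can still count every basic
residue. The P1 preference never excludes lysine sites — lysines do occupy
S1 in a minority of modes — it only annotates and breaks ranking ties.

Mutant construct names (`"RKRK178AAAA;K168A;K170A;R172A;K189A"`) are parsed
against the wild-type sequence. Published nomenclature anchors a
multi-residue run inconsistently — `RKRR138AAAA` names the *last* residue of
the 135–138 run while `RKRK178AAAA` names the *first* of 178–181 — so the
parser tries both anchorings and accepts the one consistent with the
wild-type sequence, erroring if both or neither match.

## Ensemble statistics

Per peptide window the reference campaign is 10 docking runs × 9 binding
modes = 90 poses (`plan_campaign()`, grid 40 × 25 × 25 Å centred on the
triad CA centroid — the centroid is this package's choice, since only
"close to the catalytic triad" is knowable; reproduction runs should check
sensitivity to ±2 Å shifts). `summarize_ensemble()` reports:

* the **pass fraction** (percent of modes selected, printed to one decimal);
* **S1 occupancy counts** per P1 position among selected modes;
* all-vs-all **pairwise backbone RMSD** (N, CA, C, O; all-heavy optional)
  within the selected and within the discarded group. Backbone scope is the
  default because the claim being tested concerns the backbone conformation
  of the whole peptide. "All-vs-all within group" is our reading of
  between-mode RMSD comparison; a reference-pose pairing would be an
  alternative, but all-vs-all is symmetric and parameter-free;
* a **group comparison** of the two RMSD lists. Default: two-sided
  Mann–Whitney. Because pairwise distances sharing a pose are not
  independent, a label-permutation alternative (difference of within-group
  mean RMSD, 1000 permutations) is provided; reports always name the method
  used. On clustered-vs-scattered ensembles the two agree in direction.

`site_ranking()` orders P1 positions by occupancy count (summed over
windows), tie-broken by P1 preference then position. `fragment_map()` turns
a proximal+distal event pair into N-terminal / released-tract / C-terminal
spans with lengths and unmodified average masses (residue-mass sum plus one
water per fragment, so masses conserve substrate mass + one water per cut).
Masses deliberately exclude glycosylation — apparent gel mobility of the
real fragments differs and is out of scope. `tract_release_check()` applies
`(proximal P1, distal P1]` tract semantics: full release needs bracketing
cuts; a proximal cut strictly inside the tract at or before the first
residue of the key inhibitory 11-mer (153-RFSHRIPLLIF-163) returns
`"retained-partial"` — most of the key sequence comes off, clipped at its
proximal end, which corresponds to partial rather than full channel
activation (the R153 case).

## The synthetic-data generator

Real pose ensembles require an external receptor model and docking engine,
so the package generates ensembles with known ground truth
(`make_ensemble()`):

* **productive modes** are rigid-body perturbations of a template pose whose
  occupant charged group sits `salt_bridge_target` (default 3.0 Å) from the
  carboxylate and whose carbonyl carbon sits `scissile_target` (default
  3.4 Å) from OG. Jitter is a small random rotation (σ of angle tied to
  `jitter_sd` at a 10 Å lever arm) plus a `jitter_sd` (default 0.3 Å)
  translation, resampled until the perturbed pose still satisfies both
  criteria — rigid transforms keep poses valid conformers, and resampling
  makes the labels true by construction;
* **decoys** are uniformly random rigid placements in a `decoy_box`
  (default 40 Å, the grid-box scale) around the pocket, resampled until
  every basic side chain is at least `margin` (default 1 Å) beyond the
  salt-bridge threshold; rejection sampling caps at 10,000 attempts and then
  errors rather than looping forever on infeasible settings.

Defaults mirror the reference campaign: 90 poses, productive fractions set
per window (0.45/0.35/0.08 in the three-window demo, reflecting the observed
>40% / >30% / <10% ordering for GKARDF / GRKRKV / IHKASN). Ensembles are a
pure function of their config seed, bit-identical across calls.

What the generator does *not* emulate: docking-engine energetics and score
distributions, partially-formed salt bridges near the threshold, receptor
flexibility, or peptide internal strain (peptides are idealised extended
backbones with side chains only on Arg/Lys — the criteria touch nothing
else). Passing tests therefore demonstrate that the *evaluation machinery*
is correct and discriminating under the assumed two-class structure, not
that any particular real peptide passes at the reported rate; the latter
needs the external docking route through `run_campaign()` /
`ingest_engine_output()`.

The bundled substrate fixture `mock_substrate()` assembles γ-ENaC 134–192
from its published segments (135-RKRR-138, 153-RFSHRIPLLIF-163, K168,
169-GKARDF-174, 175-FTGR-178, 177-GRKRKV-182, 187-IHKASN-192); unpublished
positions are alanine fill, which adds no spurious Arg/Lys candidates but
makes fixture masses outside the printed segments placeholders.

## Numerical and design notes

* Distances use exact Euclidean arithmetic; the min-distance primitive is
  the squared-norm expansion with a `max(0, ·)` guard against negative
  round-off before the square root.
* Pose windows at sequence termini are truncated with a warning rather than
  rejected — truncated windows are never docked in the reference workflow,
  but enumeration must behave at boundaries.
* The receptor is treated as rigid; insertion codes are rejected rather
  than guessed at; altlocs beyond the first are dropped with a warning.
* PDBQT ingest truncates ATOM records to the PDB columns and keeps
  MODEL/ENDMDL — the two dialects agree through column 66 — and attaches
  engine scores from `REMARK VINA RESULT` lines when present.
* Problem sizes in the test suite (ensembles of 12–90 poses, 20 recovery
  seeds, 100 oracle instances) were chosen as the smallest sizes at which
  each property is non-trivially exercised; the 90-pose ensembles match the
  reference campaign exactly.

## Worked demo

```{r demo}
receptor  <- make_mock_receptor()
substrate <- mock_substrate()
sources <- list(
  GKARDF = make_ensemble(synthetic_ensemble_config("GKARDF", 169, n_poses = 90,
                         productive_fraction = 0.45, seed = 101), receptor)$poses,
  GRKRKV = make_ensemble(synthetic_ensemble_config("GRKRKV", 177, n_poses = 90,
                         productive_fraction = 0.35, seed = 102), receptor)$poses,
  IHKASN = make_ensemble(synthetic_ensemble_config("IHKASN", 187, n_poses = 90,
                         productive_fraction = 0.08, seed = 103), receptor)$poses)
report <- run_full_pipeline(receptor, substrate, c(168, 192), sources,
                            proximal_site = 138, key_span = c(153, 163))
report
```

## Known limitations

* Geometry only: no rescoring, hydrogen-bond networks or solvent terms.
* The S1-occupant tie-break and the exact charged-atom sets are conventions;
  both are configurable and the defaults are stated above.
* Single- and dual-cut fragment maps only; no more than two events.
* No mmCIF or trajectory input; receptors and poses are PDB (or PDBQT via
  the adapter).
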