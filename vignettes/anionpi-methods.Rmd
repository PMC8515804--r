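---
title: "Measuring phosphate-guanine anion-pi contacts in RNA tetraloops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phosphate-guanine anion-pi contacts in RNA tetraloops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anionpi)
```

## The problem

GNRA-family tetraloops (GAAA, GGAG, ...) cap RNA hairpins and are among the
most common tertiary-structure building blocks. One of the interactions that
stabilizes the U-turn fold of these loops is an anion-pi contact: the
negatively charged, non-bridging oxygen of the phosphate that sits between
loop positions 2 and 3 stacks against the electron-poor face of the
six-membered ring of the first guanine. `anionpi` implements the geometric
descriptor used to monitor this contact, together with the ensemble-level
profiles (RMSD, RMSF, distance-angle distributions, native contacts,
occupancy grids) and a binned torsional-entropy statistic with which
wild-type and mutant loops are compared, and a synthetic-structure generator
that provides ground-truth inputs for validating all of it.

## The descriptor

For a phosphate/ring pair the package reports, per frame:

* **R** - the distance from the closest candidate oxygen (default the
  non-bridging `OP1`/`OP2`) to the ring centroid (Angstrom). The minimum
  over candidate oxygens is taken first; that oxygen defines everything
  else. Ties are broken by lexicographic atom name, so relabeling `OP1` and
  `OP2` can never change `R` and changes the reported oxygen only on exact
  ties.
* **A** - the angle at the centroid between the rays to that oxygen and to
  the ring C4 atom (degrees, in [0, 180]). Because the centroid-to-C4
  direction lies in the ring plane, a perpendicular contact over the ring
  face reads 90 degrees.
* **h_perp / d_offset** - the decomposition of `R` along and across the
  best-fit ring plane, satisfying `h_perp^2 + d_offset^2 = R^2`.

The ring frame is computed per model: the centroid is the plain mean of the
six ring heavy atoms (`weighting = "geometric"`, the convention used for
crystal-structure measurements) or their center of mass
(`weighting = "mass"`, the convention of trajectory monitors); for a
guanine ring (4 C + 2 N) the two differ by under 0.04 Angstrom. The plane
normal is the smallest principal direction of the centered (optionally
mass-weighted) coordinates; its sign follows the N1 -> C2 -> N3 circulation
so frames are comparable across models. Degenerate input - fewer than six
atoms, collinear atoms, an oxygen on the centroid - raises an error rather
than returning 0/0 artifacts.

Only heavy atoms enter any geometry; hydrogens are parsed and retained but
flagged and ignored. Bridging `O5'`/`O3'` oxygens can be added to the
candidate set with `o_names` when a survey beyond the anionic oxygens is
wanted.

## Classifying a contact

`classify_anion_pi()` calls a contact **canonical** when `R <= r_max` and
`A` falls in `a_window` (default 90 +/- 30 degrees), **weak** when
`R <= r_max + 1` regardless of angle, and **absent** otherwise. The default
`r_max` is 3.7 Angstrom, the distance at which the canonical face-on
contact is observed in these systems (roughly 3.7 Angstrom at 90 degrees);
it also sits between the close (~2.9 Angstrom) and far (~4.1 Angstrom)
populations of the two-state ensembles this package simulates, so the
canonical fraction of a mixed trajectory estimates the close-state
occupancy with only a small leakage term (about 0.006 under the default
generator). A looser survey cutoff can be requested explicitly via `r_max`.

## Tetraloop location

Author residue numbering from the input file is authoritative; the package
never renumbers. `find_tetraloops()` generalizes what is usually done by
eye or with known residue numbers: it scans each chain's nucleotide
sequence for `G[AUGC][AG][AG]` (overlapping matches allowed) and keeps
matches whose first residue carries the complete six-membered ring and
whose third residue carries `P`, `OP1`, `OP2`. Since a pyrimidine ring uses
the same six atom names, the sequence letter - not the atom roster - is
what restricts position 1 to G. When the loop position is known, an
explicit `override` bypasses the scan (the faithful path for published
loop positions); it is still validated against the atom roster. Alternate
locations resolve to altloc `A`/blank with highest occupancy on ties;
insertion codes are part of the residue key; legacy `O1P`/`O2P` names are
normalized on input.

## Ensemble profiles

* `rmsd_series()` superposes each frame on the reference with a
  least-squares rigid-body fit before measuring, so rigid motion
  contributes exactly zero. The default fit selection is the RNA backbone
  heavy atoms (P, O5', C5', C4', C3', O3').
* `sliding_window_stats()` advances one frame at a time and reports the
  pooled mean plus min/max across replicates - the summary used to draw
  replicate RMSD envelopes (a 500 ps window at a 1 ps/frame spacing is
  `window = 500`; time metadata is user-supplied since PDB ensembles carry
  no time units).
* `rmsf_per_residue()` fits first, then averages per-atom fluctuations over
  the residue's selected atoms. For nucleotides, "side chain" means the
  base heavy atoms - the nucleotide analog of a protein side chain - and
  "backbone" the sugar-phosphate atoms.
* `descriptor_distribution()` bins `(R, A)` with zero-anchored edges
  (defaults 0.1 Angstrom x 5 degrees), reports the maximal cell with
  deterministic tie-breaking (smaller R, then smaller A) and the Pearson
  correlation of R and A. `distance_modes()` ranks local maxima of the R
  histogram to recover multi-state ensembles.
* `select_snapshots()` interprets "structures close to the average" as the
  frames whose `R` is nearest the series mean, since the distance is the
  primary monitor; the 2-D mode can be targeted instead by filtering on the
  histogram. Tails are the n smallest/largest-R frames; ties break toward
  the earlier frame.
* `native_contacts()` uses heavy-atom pairs within 4.5 Angstrom in the
  reference frame, a common convention; the cutoff and the reference frame
  are arguments, since published contact analyses rarely state them.
* `occupancy_grid()` increments the voxel containing each selected atom per
  frame and normalizes by `n_frames * spacing^3`; grids export to OpenDX
  (`write_dx()`) for molecular viewers. The ensemble should be superposed
  first - the grid does not fit anything itself.

Frame indices are 1-based throughout, following R convention.

## Torsional entropy

`binned_entropy()` implements a deliberately simple, dimensionless measure:
bin the dihedral sample into 10-degree intervals anchored at -180, add one
pseudo-count to every bin so empty regions never produce `log(0)`, and
report `H = -sum(p log p)` with the natural logarithm. Choices worth
stating explicitly:

* **Sign.** The magnitude convention makes "entropy increase" a positive
  delta in `entropy_delta()`; `signed = TRUE` returns the raw
  `sum(p log p)` for anyone matching the opposite convention. Deltas are
  unaffected up to sign.
* **Base.** Natural log by default; `log_base` rescales (base 2 gives
  bits). The statistic is used comparatively, so the base is a display
  choice.
* **Bin anchoring.** Bins are `[-180, -170), ..., [170, 180)`, which makes
  exact 10-degree cyclic shifts a no-op - a property the tests exercise.
* **Bias.** The pseudo-count biases `H` upward for small n (an empty sample
  would spuriously report the maximum, and is therefore an error); on
  uniform samples the bias vanishes as O(1/n), and `H` is exactly `log(36)`
  whenever all bins hold equal counts.

Torsions come from the standard signed atan2 construction mapped to
`[-180, 180)` (so trans reads -180, not +180), with the usual nucleic-acid
definitions (alpha through zeta, and chi about the glycosidic bond:
O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines). Missing defining
atoms - e.g. alpha/beta on a 5'-terminal residue - omit that angle with a
warning instead of failing the whole report.

## What the synthetic generator does and does not emulate

The generator exists so that every pipeline stage can be tested against
known ground truth without downloading structures:

* `make_guanine_ring()` is a regular planar hexagon of side 1.39 Angstrom -
  the level of idealization at which ring-frame math has exact expected
  values. Real guanine rings are slightly irregular and slightly
  non-planar; nothing in the geometry code assumes otherwise.
* `place_phosphate()` inverts the descriptor: given (R, A, azimuth) it
  constructs coordinates that measure back to exactly those values, with
  the phosphorus and second oxygen placed at an idealized 1.48 Angstrom
  P-O bond and near-tetrahedral angle so that the designated oxygen is
  strictly the closest. This inverse-then-measure round trip is the
  package's sharpest self-test (recovery to 1e-6 over the whole parameter
  space).
* `simulate_two_state_ensemble()` draws per-frame states from a two-state
  Markov chain with stationary close-state occupancy `p_close`, then
  samples R (Gaussian) and A (von Mises, folded onto [0, 180], Best-Fisher
  sampler) within the state. The defaults - close 2.9 +/- 0.1 Angstrom,
  far 4.1 +/- 0.2 Angstrom, `p_close = 0.6`, tight angles (kappa 50) when
  close and broad angles (kappa 4) when far, both centered on 90 degrees -
  mirror the close/far snapshot geometries reported for these systems and
  the observation that short distances correlate with 90-degree angles;
  the 0.6 occupancy and the angular concentrations are this package's
  choices of a realistic mixed trajectory. Azimuths are uniform.
* `make_hairpin_fixture()` builds an 8-residue stem-loop with plausible
  bond geometry and then *constructs* the loop anion-pi contact at a
  requested (R, A). The stem is a pyrimidine placeholder and nothing is
  energy-minimized: passing tests demonstrate that the measurement,
  detection and carving code is correct on structures with the right
  topology and naming, not that the force-field behavior of real
  tetraloops is reproduced.

A consequence worth being explicit about: the validation suite checks the
measurement pipeline at the published crystal-structure descriptor values
(3.082 Angstrom / 75.1 degrees and 3.1 / 76.4 for the two GAAA systems,
3.472 / 86.5 for GGAG) using stand-in fixtures built at those geometries,
because the experimental coordinate files are not bundled with the package.
Running `anion_pi_series()` on the actual PDB entries (1HQ1, 1DUL, 1JID,
guanine at position 25, 25 and 13 respectively) reproduces those values
independently when the files are available locally; the stand-ins validate
the code path, not the crystallography.

## Problem sizes and numerical tolerances

The shipped validation suite uses 5000-frame two-state ensembles, 1000
placement round-trips, 100-instance oracle comparisons and 10^5-sample
entropy checks - sizes chosen so every statistical assertion has
comfortable margin (e.g. the canonical-fraction check at n = 5000 has a
standard error of 0.007 against a 0.03 tolerance) while the whole suite
runs in well under a minute of compute per file. Geometric identities are
asserted at 1e-9 Angstrom / 1e-7 degrees; statements at PDB precision use
5e-4 Angstrom (coordinates are written with 3 decimals).

## QM model export

`carve_fragment()` and `export_dimer()` prepare coordinate files for
external quantum-chemistry engines and nothing more: bases are cut at the
glycosidic bond, phosphates at the two ester bonds (giving the PO4 core
plus the bridging oxygens), and every severed bond is capped along the
original bond vector at a standard X-H length (N-H 1.01, C-H 1.09, O-H
0.96 Angstrom; methyl capping places a carbon at the corresponding X-C
length). Parent heavy atoms are never moved, every cap is listed in a
manifest, and dimer exports record per-fragment atom counts and the
closest inter-fragment approach for downstream counterpoise bookkeeping.
Interaction energies, density-topology and MEP analyses are out of scope.

## Known limitations

* No molecular dynamics and no energies: the package analyzes ensembles,
  it does not generate them.
* Only the six-membered ring is a descriptor target; the five-membered
  ring of purines is not measured.
* The synthetic hairpin is topologically, not energetically, realistic;
  base-pair geometry in the stem is not enforced.
* mmCIF support extends as far as the underlying bio3d reader.
* Occupancy grids assume a superposed ensemble; no wrapping or symmetry
  handling is performed.

## A worked example

```{r example}
pdb <- tempfile(fileext = ".pdb")
make_hairpin_fixture("GAAA", file = pdb, contact_r = 3.1, contact_a = 88)
s <- read_structure(pdb)
tl <- find_tetraloops(s)[[1]]
tl
anion_pi_series(s, tl)

ts <- simulate_two_state_ensemble(2000, seed = 1)
ser <- anion_pi_series(ts$structure, ts$assignment)
distance_modes(ser)
mean(classify_anion_pi(ser$R, ser$A) == "canonical")

h <- sample_dihedrals(5000, "von_mises", mu = 60, kappa = 8, seed = 2)
binned_entropy(h)
```
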