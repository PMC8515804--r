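# anionpi

Geometric and statistical analysis of phosphate–guanine **anion–π
contacts** in RNA GNRA-family tetraloops (GAAA, GGAG, ...), for structural
bioinformaticians working with crystal structures and conformational
ensembles (multi-model PDB).

In these loops the non-bridging phosphate oxygen between loop positions 2
and 3 stacks against the π-acidic face of the first guanine's six-membered
ring. `anionpi` measures that contact with the standard two-number
descriptor

* **R** — distance (Å) from the closest phosphate oxygen (OP1/OP2) to the
  centroid of the guanine six-ring,
* **A** — angle (degrees) O–centroid–C4, so a face-on contact reads 90°,

plus its ring-plane decomposition (`h_perp² + d_offset² = R²`), and builds
the surrounding analysis layer:

* tetraloop detection in PDB/mmCIF files (`find_tetraloops`, pattern
  `G[AUGC][AG][AG]`, explicit override for known loop positions);
* ensemble profiles: superposed RMSD with sliding-window mean/min/max
  across replicates, per-residue side-chain (base-atom) RMSF, 2-D
  distance–angle distributions with mode and Pearson correlation,
  representative snapshot selection, native-contact conservation, and
  ion/water occupancy grids with OpenDX export;
* a binned torsional-entropy statistic, `H = −Σ p log p` over 10° dihedral
  bins with +1 pseudo-counts, for wild-type vs mutant flexibility
  comparisons (`binned_entropy`, `entropy_report`, `entropy_delta`);
* a synthetic generator (idealized guanine ring, exact-inverse phosphate
  placement, two-state close/far Markov ensembles, hairpin fixtures,
  von Mises dihedral samples) providing ground truth for every stage;
* export of hydrogen-capped base/phosphate fragments and dimers as XYZ for
  external QM engines (coordinates and bookkeeping only — no energies).

## Worked example

```r
library(anionpi)

# a synthetic GAAA hairpin with its loop contact built at R = 3.1 A, A = 88 deg
pdb <- tempfile(fileext = ".pdb")
make_hairpin_fixture("GAAA", file = pdb, contact_r = 3.1, contact_a = 88)
s  <- read_structure(pdb)
tl <- find_tetraloops(s)[[1]]
tl
#> tetraloop GAAA (chain A, residues 3-4-5-6): ring G3, loop phosphate on residue 5

anion_pi_series(s, tl)
#>   frame        R        A   h_perp  d_offset o_atom
#> 1     1 3.100474 88.00663 3.098592 0.1080167    OP1
```

The measured `(R, A)` recover the construction to PDB coordinate
precision: the oxygen sits 3.10 Å from the ring centroid, 88° from the
in-plane C4 axis — i.e. almost directly over the ring face
(`h_perp` ≈ 3.10 Å, lateral offset 0.11 Å), a canonical anion–π geometry.

```r
# a mixed close/far trajectory with known 60% close-state occupancy
ts  <- simulate_two_state_ensemble(2000, seed = 1)
ser <- anion_pi_series(ts$structure, ts$assignment)
distance_modes(ser)
#> [1] 2.85 4.15
mean(classify_anion_pi(ser$R, ser$A) == "canonical")
#> [1] 0.621
```

The two histogram modes land within one 0.1 Å bin of the generating means
(2.9 and 4.1 Å), and the fraction of frames classified canonical estimates
the close-state occupancy (0.6) to within sampling error.

```r
h <- sample_dihedrals(5000, "von_mises", mu = 60, kappa = 8, seed = 2)
binned_entropy(h)
#> [1] 2.193964
```

A concentrated torsion (κ = 8) carries well under the uniform maximum
`log(36) ≈ 3.584`; wider distributions move `H` toward that ceiling, which
is how loop-disrupting mutations show up as positive entropy deltas.

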