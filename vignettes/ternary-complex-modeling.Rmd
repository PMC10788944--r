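---
title: "Linker-constrained modeling of PROTAC ternary complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linker-constrained modeling of PROTAC ternary complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modeling problem

PROTACs (degraders) are heterobifunctional molecules: a warhead that binds a
protein of interest (POI), an E3-ligase-recruiting ligand (L^E3), and a
linker joining the two. Degradation requires a productive three-body
assembly — the ternary complex (TC) — whose 3D structure is rarely available
experimentally. tcforge builds one predicted TC model per degrader using the
*linker as the geometric constraint*:

1. **Pose placement.** The warhead and L^E3 are kept in their native binding
   poses — taken from a co-crystal structure, supplied by the user, or
   transferred onto a co-crystallised reference ligand through their maximum
   common substructure (`transfer_pose()`). No docking is performed; pose
   provenance is co-crystal > user pose > MCS transfer.
2. **Linker construction and attachment.** The full-length linker is built
   de novo as a single low-energy conformer (`build_linker_3d()`) and
   attached separately to *both* half-complexes (`attach_linker()`), leaving
   the binding poses untouched.
3. **Separate restrained minimization.** Each half is minimized with the
   linker (and hydrogens) free and all protein/moiety heavy atoms under a
   harmonic positional restraint (`minimize_half()`), so the linker relaxes
   into a clash-free, solvent-facing orientation.
4. **Superposition and merging.** The two copies of the linker are
   rigidly superposed (`kabsch_fit()` over linker heavy atoms, equal
   weights); that superposition *defines the reciprocal orientation of the
   two proteins*. The E3-side linker copy is deleted, the L^E3–linker bond
   is formed to the surviving copy, and the fit RMSD is recorded as
   `assembly_rmsd` (`superpose_and_merge()`).
5. **Staged refinement.** Clash-driven local minimization rounds, a
   PROTAC-only minimization with the proteins fixed, and a final
   unrestrained minimization, followed by an independent residual-clash
   check (`refine_tc()`; `qc_pass` in the report).

Degraders are then ranked with an interaction-energy score summed over the
two protein-binding moieties only (`degrader_score()`):

$$E_\mathrm{score} \;=\; E^{\mathrm{warhead\ interactions}} \;+\;
E^{L^{E3}\ \mathrm{interactions}}$$

where each term is the sum of per-interaction energies (hydrogen bonds, salt
bridges, nonbonded contacts) that the moiety establishes in the TC. The more
negative the score, the more stable the predicted complex. Linker-mediated
contacts are deliberately excluded: the moieties' native interactions carry
the discriminating signal, while whole-complex energies accumulate larger
approximations. By default a moiety's contacts with *either* protein count
(a warhead touching the E3 ligase is a real interaction); `cognate_only =
TRUE` restricts each moiety to its own receptor.

## The energy engine

No molecular-mechanics engine is available in this R stack, so the package
ships a deliberately small one, used consistently for every minimization
stage and for the per-interaction energies (scores are therefore comparable
only within one run of one engine — the intended use is ranking degraders
within a series, not reproducing absolute kcal/mol values):

| term | form | parameters |
|---|---|---|
| bonds | harmonic | $r_0$ = covalent-radii sum, shortened 0.12 Å per bond order; $k$ = 300 kcal/mol/Å² |
| angles | harmonic | $\theta_0$ = 109.47°/120°/180° by coordination and bond order; $k$ = 60 kcal/mol/rad² |
| torsions | $\tfrac{V_3}{2}(1+\cos 3\phi)$, $V_3$ = 1 kcal/mol | saturated central bonds only |
| van der Waals | 12-6 Lennard-Jones | $r_\mathrm{min}$ = Bondi radii sum; polar hydrogens reduced to 0.4 Å |
| electrostatics | Coulomb, distance-dependent dielectric $\varepsilon = 4r$ | user-supplied partial charges |
| restraints | harmonic positional | 100 kcal/mol/Å² default |

1–2 and 1–3 pairs are excluded from the nonbonded sum. The three-fold
torsion term matters structurally: without torsional barriers a linker
minimized under dispersion alone curls away from its built conformer, and
the two half-complexes' linker copies diverge before superposition.
`assembly_rmsd` is the explicit diagnostic for that divergence.

Minimization is L-BFGS-B with analytic gradients. Two robustness measures
are built in: the optimizer is restarted (resetting its Hessian memory)
until the gradient criterion actually holds, and the nonbonded pair list
(10 Å cutoff) is rebuilt between restarts because a list built at the
starting coordinates goes stale once atoms move more than a few Ångström.
Convergence is an RMS-gradient tolerance of 0.1 kcal/mol/Å (configurable via
`min_config()`), with at most 2000 iterations per restart; stages never end
above their starting energy.

## Interaction typing

Contacts are enumerated over heavy-atom pairs within 4.0 Å and typed with
LigPlot-style criteria, each pair counted once at its highest-priority kind:

* **salt bridge** — oppositely formally charged N/O atoms within 4.0 Å;
* **hydrogen bond** — N/O donor bearing a hydrogen within 3.5 Å of an N/O
  acceptor, D–H···A angle ≥ 120°;
* **nonbonded contact** — any other heavy-atom pair within 4.0 Å.

For hydrogen bonds and salt bridges the per-interaction energy includes the
hydrogens bonded to the two polar atoms, so the polar group's electrostatics
are captured. `ppi_summary()` applies the same enumeration to the
protein–protein interface (PROTAC excluded) and measures the contact
surface as buried solvent-accessible area, $(\mathrm{SASA}_{POI} +
\mathrm{SASA}_{E3L} - \mathrm{SASA}_{both})/2$, with a Shrake–Rupley
sampler (probe 1.4 Å, 256 Fibonacci points per atom).

## Validation against a reference structure

`backbone_rmsd()` matches N/CA/C/O atoms by chain, residue number and atom
name, computes **one joint rigid superposition over both proteins**, and
reports the post-fit RMSD — one number per TC for the whole protein
component. `protac_rmsd()` then measures the degrader's heavy atoms *in
that same frame*, never re-fitting the ligand, so it reflects placement
error; symmetric degraders are scored under their best graph automorphism.
A model below 10 Å protein RMSD is classified crystal-like
(`classify_crystal_like()`, strict inequality).

## The synthetic fixture generator

`make_toy_tc()` builds fully synthetic, seeded toy systems so the entire
pipeline is testable without downloads:

* **Receptors** are polyalanine cages: eight alanine residues built from
  the force field's own ideal internal coordinates, arranged rigidly on a
  spherical cap with their C-beta atoms pointing at the pocket centre
  (`pocket_depth`, default 4.5 Å). Residues are not peptide-bonded to one
  another — a rigid cage of ideal residues sits exactly at the bonded
  terms' minimum, which is what makes exact ground-truth recovery a
  meaningful contract. A deterministic repair loop pushes residues outward
  until no inter-residue contact is tighter than 3.1 Å.
* **Guests** (warhead and L^E3) are branched four-carbon probes bound at
  the pocket centre, their junction atom pointing out of the pocket; the
  flanking atoms are placed in staggered torsional minima relative to the
  linker chain.
* **The linker** (default 6 heavy atoms, one ether oxygen for asymmetry) is
  an ideal zig-zag chain along the pocket axis.
* The assembled complex is relaxed to the engine's own local minimum, both
  halves are cut from the relaxed coordinates, and the recorded ground
  truth is the deterministic pipeline's own output on those unperturbed
  halves. The emitted E3 half is then displaced by a known, seeded rigid
  transform of magnitude `perturbation` — which a correct linker
  superposition removes exactly.
* Flavors seed specific defects: `CLASHED` (a cage residue pushed to 2.0 Å
  from the warhead), `STRAINED_JUNCTION` (L^E3 junction bond stretched to
  2.2 Å), `SYMMETRIC_LINKER` (all-carbon linker with the junction anchors
  left unset, exercising the mapping-ambiguity branch).

What passing on these fixtures shows — and what it does not. The fixtures
prove the geometric core: exact removal of rigid misplacement by linker
superposition, conservation and provenance bookkeeping, stage isolation,
clash resolution and energy monotonicity, score additivity and exclusion
rules. They do not emulate real protein folds, flexible loops, solvation,
crowded binding sites, or linkers with rotatable rings — so they say
nothing about pose-prediction accuracy on real PDB complexes, which should
be validated against experimental TC structures (see `validate_tc()`).

## Numerical and design choices

* **Which linker copy survives the merge:** the POI-side copy. This fixes
  the POI frame as the reference, so downstream RMSDs against a crystal
  structure are unaffected by the merge.
* **Anchored linker mapping:** the atom correspondence between the two
  linker copies is a graph isomorphism anchored at the junction atoms; when
  anchors are unavailable (symmetric linkers) every isomorphism is tried
  and the lowest-fit-RMSD mapping kept, ties broken canonically and logged.
* **Clash criterion:** heavy-atom pairs closer than 0.7 × the sum of their
  Bondi radii, excluding 1–2 and 1–3 neighbours. Local refinement frees a
  6 Å neighbourhood around each clash for at most 5 rounds.
* **Conformer builder:** acyclic linkers only, built by internal
  coordinates with anti-preferred, seeded staggered torsions and a steric
  audit (50 retries). Cyclic linkers are rejected with a clear error rather
  than embedded badly.
* **Manual inspection replaced by a metric:** instead of a visual check
  that the moieties kept their poses through refinement, the report carries
  `pose_rmsd_warhead` / `pose_rmsd_le3` against the pre-refinement poses.
* **Problem sizes in the shipped tests:** cages of 8 residues (~90 atoms
  per complex), 10 fixture seeds, 4 flavors; the superposition kernel is
  checked against a quaternion-grid search (9° coarse pass, 1° local
  refinement) on 50 seeded instances. These sizes exercise every branch
  while keeping the default suite fast.

## Known limitations

* Protein flexibility is limited to what unrestrained minimization can
  relax; large conformational changes and weakly cooperative interfaces
  are out of reach, as for any rigid-body-style method.
* One conformer per seed: flexible linkers are represented by a single
  built conformer (an ensemble mode — several seeds, keep the lowest
  `assembly_rmsd` — is available by looping over seeds).
* The shipped engine has no solvation term and element-level (not
  atom-type) parameters; absolute energies are not transferable across
  engines, orderings within a series are the deliverable.
* Covalent PROTACs, mmCIF input and NMR multi-model files are out of scope.
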