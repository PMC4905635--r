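---
title: "Discriminating alternative protein dimer models with dimerdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating alternative protein dimer models with dimerdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Transcription-factor dimerization domains (the motivating case is the
PAS-domain pairing of a bHLH-PAS receptor with its nuclear partner) can often
be modeled from several homologous template complexes, each suggesting a
*different* relative orientation of the same two protomers. Experimental
structures of the heterodimer may not exist, so the competing models must be
discriminated computationally, and the discrimination should come with
residue-level hypotheses that can be tested by mutagenesis. dimerdx
implements that workflow for any two-chain dimer given as PDB coordinates:

1. characterize each candidate interface (buried surface, interface
   residues, typed contacts);
2. estimate each model's binding free energy with a single-trajectory
   implicit-solvent model and decompose it into residue-pairwise
   contributions (the *interaction energy matrix*);
3. compare per-residue contributions between the two models with the Rank
   Products permutation statistic, yielding a *differential-contribution
   signature* for each model;
4. predict interface hot spots two ways (empirical burial/contact rule;
   computational alanine scanning);
5. propose point mutations expected to discriminate the two dimerization
   modes.

Because the original study's homology models are not redistributable, the
package ships a synthetic test bed (`build_toy_dimer()`, `make_decoy()`,
`simulate_replicates()`) that every stage is tested against.

## The energy model and its assumptions

The binding free energy is the end-point, single-trajectory estimate

$$\Delta G_{bind} = G_{complex} - G_{receptor} - G_{ligand},$$

with all three systems evaluated at the coordinates they hold in the
complex. Each $G$ is a sum of vacuum Coulomb and 12-6 Lennard-Jones terms
(no distance cutoff; intra-residue and 1-2/1-3 peptide-link pairs excluded),
a generalized Born polar solvation term, and a nonpolar term proportional to
the solvent accessible surface area. Because conformations are shared,
covalent and intramolecular mechanical terms cancel exactly: they are never
computed in the difference, which is what makes the intramolecular entries
of the interaction matrix identically zero.

The GB term uses HCT pairwise descreening integrals with OBC tanh rescaling
($\alpha, \beta, \gamma = 1.0, 0.8, 4.85$; intrinsic radii offset 0.09 A)
and the Still interpolation
$f_{GB} = \sqrt{r^2 + R_i R_j e^{-r^2/4R_iR_j}}$ with the salt-screened
prefactor $(1/\epsilon_{in} - e^{-\kappa f}/\epsilon_{out})$,
$\kappa = 0.316\sqrt{M}$ per Angstrom. Defaults:
$\epsilon_{in} = 1$, $\epsilon_{out} = 78.5$, salt 0.154 mol/L
(physiological), surface tension 0.0072 kcal/mol/A$^2$, Coulomb constant
332.06 kcal A/(mol e$^2$).

**A deliberate simplification, stated loudly:** the force field is an
embedded heavy-atom (united-atom-style) parameter table — stylized partial
charges that sum to each residue's formal charge, mbondi-like GB radii, and
element-typed Lennard-Jones parameters. Hydrogens are neither required nor
used. Absolute $\Delta G_{bind}$ values therefore cannot be compared with
all-atom results; everything downstream (decomposition identities, rankings,
signatures, hot-spot logic) is faithful, and the parameter table is
pluggable (`assign_parameters(table = ...)`) for anyone wanting to feed in
an all-atom set.

## The interaction matrix and its conventions

`pairwise_decomposition()` aggregates every atom-pairwise term to residue
pairs, storing half of each pair energy in each of the two symmetric
entries, so `sum(matrix)` equals $\Delta G_{bind}$ to numerical precision
(the conservation identity is asserted to 1e-6 kcal/mol in the tests).
Strict single-trajectory GB still produces nonzero *intramolecular*
desolvation differences (Born radii change on binding); these are folded
into the diagonal self terms so that off-diagonal intramolecular entries are
exactly zero while conservation holds. `intra_gb = "zero"` discards them
instead and reports the resulting conservation gap. Per-residue
contributions are row sums (self term plus half of each pair term), so they
too sum to $\Delta G_{bind}$.

## SASA

Shrake-Rupley quadrature on a deterministic golden-section sphere lattice
with element radii C 1.70, N 1.55, O 1.52, S 1.80 A and probe 1.4 A. Each
atom's lattice is oriented by a frame built from its own residue's
geometry, which (i) makes SASA exactly covariant under rigid motion, (ii)
makes complex and isolated-protomer SASA cancel exactly away from the
interface, and (iii) decorrelates quadrature error between atoms. The
default is 1920 points per atom: at 960 the worst per-residue change on
doubling the lattice was 3.2% on the toy fixtures, above the 2% the package
promises, while 1920 brings it to 1.6%. The energy model's nonpolar term
uses 960 points (configurable), where the residual ~1 A$^2$ error is 0.007
kcal/mol.

## Rank Products and the replicate ensemble

Replicates stand in for "multiple evaluations" of the decomposition. The
generator re-evaluates per-residue contributions over a seeded Gaussian
coordinate jitter (default sd 0.05 A per heavy-atom coordinate, 8
replicates); user-supplied matrices are accepted anywhere a generated one
is. Within each replicate, residues are ranked by contribution (most
stabilizing = rank 1, average ranks on ties) and

$$LOG(RP)_g = \frac{1}{n}\sum_r \log_2 \frac{R^A_{g,r}}{R^B_{g,r}},$$

negative when residue $g$ is relatively more stabilizing in model A. The
null permutes residue labels independently within each replicate of each
model; each permutation contributes all residues' $|LOG(RP)|$ values to the
null pool, and the e-value of residue $g$ is the *expected count* of null
values at least as extreme, i.e. count/n_perm (the convention of the Rank
Products method). Signatures are the sign-partitioned residues with e-value
at or below alpha (default 0.05, 10,000 permutations, seed mandatory).

Two consequences of this convention deserve emphasis:

* Under the null it is very conservative: the measured mean false-positive
  signature fraction at alpha 0.05 (20 residues, 8 replicates) is ~0.002.
* Its power is limited by replicate count, not effect size: ranks are
  scale-free, so once a planted effect dominates the ranking, increasing it
  further changes nothing. With three residues planted in the same model
  they compete for ranks 1-3, and the weakest sits near
  $\log_2(\bar R^B) - \log_2 3 \approx 1.5$, below the family-wise null
  quantile (~1.7 at 20 residues x 8 replicates). Recovery of all three at
  that size plateaus near 45/100 regardless of effect size; ~24-32
  replicates would be needed for reliable triple recovery. The same
  arithmetic limits the end-to-end toy comparison: the engineered
  salt-bridge pair is recovered decisively, the weaker hydrophobic motif
  members are not. The acceptance tests assert the stricter stated targets
  and are left failing rather than silently reinterpreted.

## Hot spots

Two predictors are implemented at the rule level; a trained-classifier
method is out of scope, so the consensus spans two methods:

* **Empirical rule:** a residue is a hot spot when complexation removes at
  least 20% of its isolated SASA *and* its contact-potential score is at
  least 18. The contact potential sums a knowledge-based residue-pair
  weight over partner residues with any heavy atom within a 7 A shell. The
  embedded weight table is class-based (hydrophobic-hydrophobic and
  opposite charges 4.0, mixed 2-2.5, like charges 0.5), normalized so that
  typical buried toy-interface residues score near the 18 threshold; a
  unit-weight table is provided for testing and the table is pluggable.
* **Alanine scanning:** every interface residue (Gly/Ala/Pro skipped) is
  truncated at CB and $\Delta\Delta G$ is computed as minus the sum of the
  removed atoms' intermolecular pairwise terms at frozen wild-type Born
  radii and SASA. This fixed-environment definition makes the scan exactly
  consistent with the interaction matrix, makes a residue with no
  intermolecular interactions score exactly zero, and matches the spirit of
  rotamer-based alanine-scan servers; a full-recompute mode
  (`mode = "recompute"`) exists for comparison. Hot spot when
  $\Delta\Delta G \ge 1$ kcal/mol.

Consensus ranks dual-method residues first, then single-method, ordered
within tiers by the mean z-score of (burial %, contact score, ddG), ties by
residue number.

## Mutation design

Candidates per targeted model are (signature $\cap$ hot spots) plus
intermolecular salt-bridge partners, restricted to interface residues.
Categories: hydrophobic residue in a hydrophobic partner environment (mean
Kyte-Doolittle hydropathy of partner residues within 6 A above 1.5) becomes
Arg — or Glu when a positive partner charge is within 6 A; a charged
residue in a salt bridge becomes Ala; a small/medium hydrophobic residue in
a tight pocket (>= 18 partner heavy atoms within 5 A of its side chain)
becomes Trp; a polar residue adjacent to a salt-bridge network gets the
complementary charge (the only *reinforcing* category). Priority is the
consensus tier plus |LOG(RP)|. The thresholds codify what was originally
expert visual inspection and are configurable; no claim is made of
reproducing any specific published panel row-for-row.

## The synthetic test bed, and what a green test does not establish

`build_toy_dimer()` builds ideal-geometry protomers (helix: phi/psi
-57/-47; strand: -119/113; standard peptide internal coordinates;
side-chain rotamers from embedded ideal-geometry templates with staggered
chi wells) and realizes requested interface motifs (Lys/Glu salt bridge,
Leu/Leu contact, Phe/Phe pair) by a greedy rotamer relaxation that
minimizes soft-sphere overlap under motif distance restraints. The default
world: 14-residue antiparallel helix pair, one salt bridge plus three
hydrophobic contacts, 10 A axis separation — chosen because it is the
smallest system in which the interface has distinct electrostatic and
hydrophobic character while a 180-degree decoy cleanly removes most of it.
`simulate_replicates()` draws per-residue contributions
Normal(baseline -0.2, sigma 0.3 kcal/mol) with planted shifts of -delta, a
replicate-noise scale typical of per-residue decompositions.

These toys emulate *structure* (chains, motifs, clashes, burial) and
*statistics* (replicate noise, planted signal); they do not emulate real
PAS-domain folds, conformational relaxation, or all-atom electrostatics. A
green suite establishes that the machinery is self-consistent and
calibrated, not that any particular biological dimer model is correct.

## Numerical choices and degenerate inputs

* Kabsch superposition via SVD with determinant correction; grafting
  rejects anchor fits worse than 2 A RMSD (configurable).
* Alternate locations resolve to highest occupancy; insertion codes are
  preserved verbatim; waters/ligands are parsed but excluded from
  energetics (flagged non-standard).
* Mutation keeps backbone and CB fixed; the first clash-free rotamer
  (heavy-atom contacts under 2 A against the environment) is chosen, else
  the least-clashing; mutation to Ala/Gly is pure truncation.
* Identical-coordinate atoms are a hard error in the Born-radius integral;
  nonbonded contacts under 0.5 A warn but still return energies; decoys
  with inter-chain contacts under 1.5 A are rejected.
* All randomness flows from explicit seeds; the pipeline derives stage
  seeds as master + 101/202/303 and stamps every artifact with a config
  hash.
* Global alignment uses Needleman-Wunsch with BLOSUM62, gap open 10, gap
  extend 0.5; identity counts matches over the full alignment length (gaps
  included), similarity counts positive-score pairs.

## Known limitations

Absolute binding free energies are not comparable to all-atom force fields;
entropy and conformational relaxation are ignored (single trajectory);
H-bond detection has no angular term (no hydrogens); the family-wise
e-value convention limits signature power at small replicate counts, as
quantified above; and the contact-potential weight table is a stylized
stand-in for an externally trained one.
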