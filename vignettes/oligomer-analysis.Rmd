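---
title: "Dissecting lipidated-peptide oligomerization with oligoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting lipidated-peptide oligomerization with oligoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoscope)
```

## The problem

Liraglutide is a 31-residue GLP-1 analogue with a palmitic acid conjugated
via a γ-glutamate spacer to its lysine (residue 20 of the analogue
sequence). The lipid tail makes the peptide amphiphilic: in solution it
self-associates into small oligomers (n = 2–8), which mature into stable
building-block oligomers (n = 12–18), and those building blocks associate
further — through hydrophilic surface contacts rather than the lipid
core — into high molecular weight assemblies (n = 25–62) that occupy four
disjoint bands on the oligomer-state axis. Tracking that process requires
several mass-spectrometric views at once: conventional native MS for the
low-mass states, single-ion (charge-detection) measurements for the
unresolvable high-mass tail, electron-capture dissociation for interfacial
structure, and a self-assembly simulation for mechanism. `oligoscope`
implements the analysis layer of each view, together with seeded
generators that emulate the corresponding raw data.

## Mass bookkeeping

All masses derive from one elemental table (C, H, N, O, S; monoisotopic
and average). The built-in analyte encodes the public monograph values:
sequence `HAEGTFTSDVSSYLEGQAAKEFIAWLVRGRG` with a net side-chain delta of
C21H37NO4 on the lysine (one γ-Glu residue, C5H7NO3, plus one
hexadecanoyl group, C16H30O). Summing residues reproduces the elemental
composition C172H265N43O51 to well under 0.01 Da in both mass modes —
the package's internal consistency check between the residue-sum and
formula-sum routes.

```{r masses}
lira <- liraglutide()
c(mono = monomer_mass(lira), avg = monomer_mass(lira, "average"))
round(c(mz_of(monomer_mass(lira), 3), mz_of(monomer_mass(lira), 3, k = 1)))
```

Charge reduction (electron capture without dissociation) keeps the
deposited protons and their mass: the product m/z uses the precursor mass
plus k electron masses over (z − k) charges — hence the 2+ species near
m/z 1876 from a 3+ precursor near m/z 1251.

Two conventions apply throughout and are worth stating once:

* **Mass mode by scale.** Monoisotopic masses for the monomer and for
  fragments (isotopically resolved), average masses for oligomer-scale
  work at n ≥ 9, where isotope envelopes are unresolved and the average
  is what a peak centroid estimates.
* **Polarity.** Residues are classed hydrophobic/hydrophilic by the sign
  of the Kyte–Doolittle hydropathy scale; a conjugated residue is
  hydrophobic regardless of its bare class, because the C16 tail dominates
  its interaction character. The table is overridable.

## The synthetic generators

The generators define the study conditions; every analysis test runs
against them.

**Kinetic time course.** A mass-action aggregation/fragmentation scheme
with three tiers: monomer addition (n = 1–7, slow addition also onto
building blocks so n = 17 can emerge late), fusion of small-oligomer
pairs into the 12–18 band, and irreversible pairing of building blocks
into HMW species. Concentrations are in monomer-equivalent units so
`sum(n * c_n)` is conserved exactly by construction; the ODE is integrated
with `deSolve::lsoda` at 1e-10 relative tolerance, and conservation is a
tested property. Rate presets were chosen once so the default pH 6.7 run
reproduces the qualitative order seen experimentally — small oligomers
dominant within minutes, the 13–17 band modal by a few hours, n = 17
appearing by 24 h — and the pH-jump preset (dissociation accelerated
40-fold, association throttled to 5%) roughly halves the 13–17 band
fraction within 10 min while small oligomers re-emerge.

**Native spectra.** One Gaussian per populated (state, charge) pair at
the closed-form m/z, optional additive baseline noise. The default charge
model is a discretized normal with mean 3.4·√n — native-spray charging
scales with the square root of mass, and this constant puts 3+ on the
monomer and 14+ on the 17-mer.

**Single-ion traces.** Cumulative intensity with expected slope
k_cal·z, per-trace multiplicative slope noise plus same-scale per-point
jitter, uniform durations with a 5% early-death fraction. The default
relative slope noise is 0.3%, the scale of sub-single-charge precision in
Orbitrap-based single-ion measurements (about 0.2 e at 75 charges). The
high-mass population presets place deterministic (rounded expected)
counts on the four regions — I (9–19), II (25–32), III (37–48),
IV (54–62) — with Region I bimodal at n = 12/16 at 25 °C and unimodal at
n = 16 at 37/50 °C, and charges following a discretized normal around a
linear state–charge trend bounded by 8 (smallest detectable) and 75
(Rayleigh-type ceiling of the largest species). Making the population
structure deterministic and leaving only trace noise stochastic keeps the
recovered endpoints and modal states stable across seeds.

**Fragment observations.** Bernoulli sampling of the theoretical c/z
ladder with class probabilities (ion type × conjugate content) and ppm-
scale Gaussian mass error. The monomer-like and oligomer-like presets
encode the observed contrast — oligomerization suppresses C-terminal
z-ion release and conjugate-containing fragments — with probabilities
chosen so the *expected* counts match the reported monomer/oligomer
totals (30/23 total, 18/4 conjugate-containing, 18/2 z-ions). The raw
experimental spectra are not deposited, so these counts parameterize the
generator rather than being reproduced from data.

## Native MS assignment

Peak picking thresholds local maxima at `min_snr` times a robust noise
estimate (1.4826 × MAD — robust against the peaks themselves) and
centroids by Gaussian (parabolic-in-log) apex interpolation, which is
exact for sampled Gaussian peaks; near-coincident maxima merge into the
taller.

State assignment enumerates all (n, z) within tolerance and scores each
candidate by the support of its charge-state series — the number of
distinct peaks consistent with the same n at any charge. Support below
`s_min = 2` is disqualifying unless it would leave a peak unexplained.
Exact degeneracies are intrinsic here: (n, z) and (2n, 2z) have
identical m/z, and every (n, n) species sits at M + m_proton. Ties are
broken by larger support, then smaller |ppm|, then smaller n
(parsimony). The default tolerance is 50 ppm at oligomer scale —
average-mass matching of unresolved envelopes is intrinsically coarser
than the 20 ppm used for isotopically resolved fragments. Because of the
exact coincidences, per-pair recovery is only well-posed on populations
without them; the test suite measures ≥95% (n, z) recovery on a
separable population (three-charge series per state, no doubled-state
aliases in the search window) and validates crowded spectra at the level
of band fractions, where degenerate intensity lands in the correct band.

## Single-ion charge and state inference

Per-ion charge is the OLS slope of cumulative intensity over time divided
by k_cal. Quality filtering (fit r² ≥ 0.995, duration ≥ half the maximum)
removes dying ions; surviving raw charges are histogrammed in 0.5-charge
bins and ions in bins holding fewer than 3 ions are discarded. This
bin-size / minimum-ion filter is what keeps the recovered charge range
honest: spurious tail estimates land in sparse bins and vanish, so the
extreme assigned charges coincide with the true population endpoints.
The specific defaults (bin 0.5, min 3 ions, r² 0.995) are declared
choices, not values inferred from any instrument.

Mass is z·(m/z − m_proton) — the electron mass is neglected, an error
below 0.01 Da per charge, irrelevant at 10⁵ Da scale. The state is the
nearest monomer multiple, accepted only within 25% of a monomer mass
(half the spacing would be 50%; the tighter default leaves a guard band
for charge misassignment, which displaces mass by a full m/z unit, not a
fraction). Regions are contiguous occupied runs on the state axis
separated by at least `min_gap = 3` empty states — the observed
inter-region gaps are ≥5 states wide, so the result is insensitive to
the exact choice.

Accuracy decays at the top of the charge range as relative noise grows:
at 1% slope noise a 75-charge ion has a 0.75-charge standard deviation
and mis-rounds often. At the 0.3% default, state round-trip recovery
stays above 99% across the full preset population.

## ECD fragment annotation

The c ladder is the cumulative residue sum (with modifications) plus
NH₃; the z• ladder is defined by complementarity,
z•_j = (M + H) − c_(L−j), which the tests verify across the whole ladder.
z ions are radical z• by default (the ECD/ETD convention); even-electron
z+1 masses are available behind a flag since annotation tools differ in
which species they count. Fragments count as unique (type, index) pairs —
charge states of the same fragment are one ion. Matching takes the
smallest |ppm| within 20 ppm (boundary inclusive); exact ties break
toward the c series, then the lower index. The differential report lists
sites lost between two coverage maps and the length of the lost-z suffix
run — the C-terminal contiguity that distinguishes a genuinely
restrained terminus from scattered losses. A minimal isotope-spacing
reader (z from the median spacing against 1.00235 Da, envelopes rejected
above 20% spacing spread) stands in for full isotope-fit deconvolution,
which is out of scope.

## The assembly surrogate

The simulator is explicitly a surrogate, not a production force field:
its purpose is to generate trajectories with the right phenomenology for
the analysis operators. Each chain is 8 backbone beads (majority polarity
and summed pH 6.7 charge of ~4-residue groups; His counted +0.5) plus a
hydrophobic tail bead anchored at the conjugation bead. Overdamped
Langevin dynamics with soft-core repulsion everywhere, short-range
Gaussian attraction between hydrophobic beads, and screened electrostatics
plus a weak short-range attraction between hydrophilic beads; periodic
cubic box, minimum-image convention, chains placed ≥2 nm apart initially.
Reduced units: kT = 0.3 at temperature factor 1, hydrophobic well depth
6 (deep enough that contacts persist), dt = 1e-3.

The experimental boxes (30 chains in a 26.22 nm cube, 45 in 29.20 nm —
both ≈3 mM, which is how the package reads those edge lengths, since a
volume reading would give an absurd molarity) are far too dilute for
association within desk-scale step budgets, so the demonstration runs use
smaller boxes (6–8 nm for 6–10 chains) where diffusion-limited encounters
happen within a few thousand steps. The analysis operators are
box-agnostic.

Cluster partitions are connected components over chains with any
inter-chain bead pair within 0.6 nm (a bead-scale contact distance,
independent of — and coarser than — the 0.45 nm pair-interaction cutoff,
which is kept at the literature value). Dense hydrophobic cores are
DBSCAN-style clusters over hydrophobic beads only (eps 0.8 nm, 5-bead
core threshold; declared defaults). Interaction pairs within 0.45 nm are
hydrophobic/hydrophilic/hybrid by bead classes, tallied separately for
intra-cluster and inter-cluster scopes; percentages are per scope and a
scope without pairs is reported absent rather than as 0/0. Radius of
gyration unwraps beads breadth-first along a proximity graph before
computing the mass-uniform Rg — exact for any connected cluster smaller
than half the box.

## What the tests do and do not show

Every analysis operator is checked against an independent brute-force
oracle (double-loop assignment, run-length segmentation, all-pairs
matching, O(N²·beads²) component search, triple-loop tallies, closed-form
OLS and Rg), and the generators against closed forms, binomial
frequencies and determinism-under-seed. Problem sizes are chosen for a
single CPU: ~10⁴ ion traces for the single-ion end-to-end checks, 10-odd
chains and a few thousand steps for assembly runs, hundreds of repeats
for frequency checks.

Passing these tests shows the pipeline's inference is correct *given the
generative assumptions* — Gaussian peaks, linear traces with
multiplicative noise, Bernoulli fragment detection, the surrogate force
field. It does not show robustness to what real instruments add: baseline
drift and chemical noise, ion-specific decay in the trap, overlapping
isotope envelopes, adducts, or the conformational detail a coarse-grained
surrogate cannot carry. The experimental fragment counts and the
interface-composition percentages depend on undeposited raw data and are
deliberately generator parameters, not reproduction targets.

## Known limitations

* Proton adducts only; no isotope fine structure; positive mode only.
* The n↔2n, z↔2z and (n, n) m/z degeneracies are resolved by the
  series-support heuristic and parsimony tie-break, which can misassign
  when a doubled series is genuinely present with matching support.
* Charge assignment rounds per-ion estimates; beyond ~0.7% relative slope
  noise the highest charges (≥70) begin to mis-round.
* The assembly engine makes no claim to physical time scales or
  energetics; temperature acts only through the noise term.
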