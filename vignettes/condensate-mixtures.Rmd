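---
title: "Simulating phase separation in PLCD mixtures on the lattice"
author: "latmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating phase separation in PLCD mixtures on the lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`latmix` simulates mixtures of disordered proteins — prion-like
low-complexity domains (PLCDs) and homopolymer stand-ins for them — as
self-avoiding chains on a periodic cubic lattice, one bead per residue.
Vacant sites play the role of solvent and carry no energy of their own. Two
beads are "in contact" when they occupy sites within each other's 26-site
neighbor shell (Chebyshev distance 1); consecutive beads of a chain are
bonded and must also sit within that shell, which is the bond convention
that makes the whole move set below usable without lattice artifacts. A
6-neighbor bond convention is not offered: every analysis in the package
assumes the 26-shell.

The energy of a contact between bead $i$ (on chain $a$) and bead $j$ (on
chain $b$) is

$$u_{ij} = \varepsilon(t_i, t_j) + w_{\mathrm{el}}\,\bar m_{ab}^2,
\qquad \bar m_{ab} = \tfrac{1}{2}\,(q_a + q_b),$$

where $\varepsilon$ is a symmetric contact-energy matrix over bead types
(negative = attractive, reduced units with $k_B = 1$), $q_a$ is the net
charge per residue (NCPR) of the chain the bead belongs to, and
$w_{\mathrm{el}} \ge 0$ couples a mean-field electrostatic penalty to the
*chain-pair-averaged* NCPR. Using the pair average rather than a
single-chain value is what lets charge complementarity act in mixtures: a
$+q$/$-q$ chain pair has $\bar m = 0$ and interacts at the full strength of
the contact matrix, while like-charged pairs are penalized.

The quadratic form of the penalty is this package's choice; only the use of
the chain-pair average is fixed by the physics we target. Two consequences
are worth knowing. First, because $\bar m^2$ is convex in the two NCPRs, the
cross-pair penalty never exceeds the mean of the two homotypic penalties:
purely electrostatic effects can make a mixture's dilute arm concave
(co-phase separation enhanced) or exactly additive, but never convex on
their own. In particular, a 1:1 mixture of two species with equal $|q|$ and
the same sign is *exactly* equivalent to a one-component system under this
form. Convex (antagonistic) dilute arms additionally require asymmetries in
the contact matrix, as real PLCD pairs have. The directional test battery
therefore asserts the concave-to-additive shift when one species' NCPR sign
is flipped, not a strict crossing into convexity. Second, the penalty also
applies to intra-chain (non-bonded) contacts, with $\bar m = q_a$.

Two default parameterizations ship with the package:

* `scenario_matrix()` — 2x2 generic matrices for the homopolymer batteries
  (all-equal, heterotypic-stronger, homotypic-stronger, asymmetric-weak-A),
  with `e_base = -1` setting the energy scale and `delta = 0.5` the
  modulation;
* `default_plcd_model()` — a 20-residue stickers-and-spacers default:
  aromatic-aromatic contacts strongly attractive (Tyr/Trp at $-3$, Phe at
  $-2.4$, His weak), Arg an auxiliary sticker toward aromatics, spacers
  weakly attractive ($-0.25$; Gly slightly stickier at $-0.45$), and
  $w_{\mathrm{el}} = 4$. These are package defaults on an arbitrary reduced
  scale — not a fitted parameter set — so absolute temperatures are not
  comparable to any published parameterization; only orderings and
  qualitative patterns are.

## Sampling

`run_mc()` samples the canonical ensemble with the Metropolis criterion
$p_{\mathrm{acc}} = \min[1, e^{-\Delta E/T}]$ at each of the configured
temperatures, with `n_replicates` independent repeats seeded from the base
seed. Seven move kinds are implemented, all with symmetric proposal
distributions so detailed balance holds without Hastings corrections:

* **local_bead** — relocate one bead to a site compatible with its bonded
  neighbors (the candidate set depends only on the neighbors' positions,
  hence symmetric);
* **slithering_snake** — reptation: remove a bead from one chain end and
  grow at the other;
* **chain_translation** — rigid displacement of one chain by up to `dmax`
  per axis;
* **pivot** / **double_pivot** — apply one of the 47 non-identity signed
  permutations of the cube to a chain tail (or an internal segment, with
  re-closure rejected if the closing bond breaks);
* **co_local** — displace a bead and one contacting foreign bead by the
  same shell vector, preserving their relative position;
* **cluster_translation** — rigid displacement of a whole connected
  cluster, rejected if it would merge clusters (this keeps the proposal
  symmetric and makes the move energy-neutral by construction).

Default weights in `run_config()` are equal across kinds; the scenario
presets override them with a production mix dominated by local moves (70)
with moderate reptation and pivots, and rare cluster translations (0.1),
which profiles showed to equilibrate condensed systems fastest per unit
CPU. For rotations on even boxes, segments with a minimal-image component
of exactly $L/2$ are rejected outright — the minimal image is ambiguous
there and both directions of the move are excluded, so no asymmetry is
introduced.

Energies are updated incrementally from the affected contacts only;
`run_mc(..., validate = TRUE)` recomputes the total from scratch after every
accepted move and checks every frame invariant (self-avoidance, bonds,
grid consistency). The test suite holds the accumulated drift to below
$10^{-9}$.

Runs are initialized by growing all chains as self-avoiding walks inside a
central subbox (`init_box`). The full-scale presets use the 35-site subbox
of the production protocol; the desk presets size the subbox so the seed
density is about 0.3, which removes the slow droplet-coarsening stage that
desk-length runs cannot afford. Frames are sampled from the second half of
the run by default (`analysis_fraction = 0.5`); an advisory sliding-window
slope test warns when the energy has not plateaued in the analysis window.

The compiled sampler uses its own `std::mt19937_64` stream with hand-rolled
bounded draws, so trajectories are reproducible bit-for-bit from
`(config, seed)` across platforms; every per-(temperature, replicate) seed
is derived deterministically from the base seed and recorded in trajectories
and manifests.

## From trajectories to coexistence data

The condensate in a frame is the largest connected component of the
chain-contact graph (chains linked when any inter-chain bead pair is in
contact). Its center of mass uses per-axis circular means, so droplets
straddling the periodic seam are handled exactly. Both constructions are
reconstructions — the underlying study does not state how cluster membership
or the center were computed.

`radial_profile()` bins beads in spherical shells of width 1 lattice unit
around the condensate center (per frame, then averaged within and across
replicates) and divides by the exact per-shell site counts, giving volume
fractions. `fit_logistic()` fits

$$\rho(r) = \rho_{\mathrm{dilute}} + \frac{\rho_{\mathrm{dense}} -
\rho_{\mathrm{dilute}}}{1 + e^{(r - r_{\mathrm{mid}})/w}}$$

by bounded Levenberg–Marquardt least squares (weights = shell site counts).
The interfacial interval is where the fitted curve passes 90% and 10% of
the way between the plateaus, i.e. $r_{\mathrm{mid}} \pm w\ln 9$; the
quantile is configurable (`interface_q`). The dilute-phase concentration is
read from the far-field plateau of the fit rather than from box-minus-cluster
counting — it is robust to stray small clusters and matches the fit-based
interfacial construction. A state point is declared single-phase when the
fit degenerates (no plateau contrast, non-convergence, or inverted
plateaus) or when the largest cluster holds less than half the chains
(`cluster_threshold`, configurable).

`build_binodal()` assembles phase points over temperatures;
`two_component_diagram()` recasts fixed-temperature campaigns over
stoichiometries into the $(c_A, c_B)$ plane. `tie_line()` joins
$c_{\mathrm{dilute}}$, $c_{\mathrm{tot}}$, $c_{\mathrm{dense}}$, reports the
dilute-to-total and total-to-dense slopes with errors propagated from the
replicate standard errors (total compositions carry no error), and
classifies: both slopes within 2 SE of unity means heterotypic interactions
dominate; below unity, homotypic interactions of the abscissa species;
above, of the ordinate species.

## The crosslinking statistic

The supplement defining the original $L_{i-j}$ formula is not available to
this package, so `crosslink_parameter()` implements an operational
definition pinned by the statistic's printed properties: for species $i$,
the observed fraction of its inter-chain bead contacts (inside the
condensate) made with species $j$, divided by the random-mixing expectation
given the cluster's composition,

$$\mathrm{exp}_{ij} = \frac{B_j - \delta_{ij} N_i}{B_{\mathrm{tot}} - N_i},$$

where $B_j$ is the cluster's bead count of species $j$ and $N_i$ the chain
length of species $i$. Subtracting the querying chain's own beads makes the
single-species null exactly one. Contacts are counted at the bead level,
self-chain contacts are excluded, and $L$ is deliberately not symmetrized:
$L_{A-B}$ answers "whom does A touch?", $L_{B-A}$ "whom does B touch?", and
the asymmetric-energy scenario genuinely separates them. One estimator
caveat: the expectation assumes a condensate of roughly stable composition.
When the largest cluster is small and its composition fluctuates
frame-to-frame (dispersed or near-critical states), contact-weighted
averaging inflates the self terms, so $L$ should only be read when the
cluster holds most chains — which is also when the underlying notion of "the
condensate" is meaningful.

`rg_profile()` measures each chain's radius of gyration about its own
center of mass after unwrapping the chain across the periodic seam (bond
minimal images are unambiguous because bonds live in the 26-shell),
normalizes by $\sqrt{N}$, and bins by the chain center's distance from the
condensate center.

## Synthetic data and study conditions

`scenario_config()` encodes the study conditions by name. All presets share
a total bead volume fraction of 0.016. Full scale reproduces the production
conditions — 150-bead chains, $150^3$ boxes ($120^3$ for the PLCD mixture),
$3\times10^{10}$ steps, five replicates, 35-site dense seed — and is meant
for cluster hardware. Desk scale is what the tests and the acceptance
script run:

* **fig8 battery** (`fig8_equal/hetero/homo/asym`): two 75-bead species
  (the interaction-battery claims are length-independent, so the desk
  variant shortens chains), 10 chains each, box $45^3$, $3\times10^6$
  steps, 3 replicates. With `e_base = -1` the two-phase window of this
  system extends to $T \approx 14$; the presets sample $T = 10$ and $12$,
  where the condensate holds essentially all chains. The random-mixing
  *null* checks are run at $T = 12.5$ and $13$ instead — still safely
  two-phase, but fluid enough that chains exchange neighbors many times
  within a desk-length run, which is what the tight $L = 1$ comparison
  needs — and with extra reptation weight for the same reason.
* **length battery** (`fig9_lengths`, `fig9_matched`,
  `fig9_three_lengths`): chain lengths are the object of study and are
  never shortened (150/300, optionally 200/300/400); desk scale reduces
  chain counts instead, with equal total beads per species (equal mass).
  Saturation-concentration comparisons run the pure species at $T = 15$,
  where the shorter polymer has a clearly measurable vapor; interface and
  chain-dimension profiling of the 1:1 mixture runs at $T = 13.5$ with
  3000 beads in a $57^3$ box.
* **electrostatic battery**: 30-bead homopolymers with $|q| = 0.25$,
  $w_{\mathrm{el}} = 8$ and an all-equal contact matrix, box $34^3$,
  $T = 5.25$ (the effective homotypic contact energy is $-0.5$, which
  halves the temperature scale). Pure runs give the additivity-null
  endpoints; 1:1 runs with opposite versus equal NCPR signs give the
  concave-versus-additive contrast discussed above.
* `make_random_plcd()` draws PLCD-like sequences (defaults: 55% polar, 10%
  aromatic, 4% charged, 16% Pro/Ala, remainder aliphatic) with the aromatic
  stickers placed near-uniformly along the chain, as in natural PLCDs.
* `study_fixture()` returns the three packaged 135/135/214-residue
  sequences. **These are synthetic stand-ins**: the real construct
  sequences live in supplementary material that is not redistributed here,
  so the package generates sequences with the documented lengths, charge
  signs (A1-LCD positive; the +12D variant with exactly twelve Gly/Ser
  positions replaced by Asp, net negative; FUS-LCD weakly negative) and a
  PLCD-like composition. Analyses that depend on the precise residue order
  of the real proteins cannot be reproduced from them, and the fixture file
  says so in its name (`plcd_sequences_synthetic.fasta`); a checksum guards
  against silent edits.

## What desk scale can and cannot show

The desk presets resolve, with replicate error bars, every *organizational*
claim: the random-mixing null, the enrichment/depletion patterns of
$L_{i-j}$ under heterotypic- or homotypic-dominant energies, internal
demixing, the temperature drift of the asymmetric scenario, tie-line slopes
of symmetric mixtures, the saturation-concentration ordering of H150 versus
H300, the longer species' preference for the dense phase and the cluster
exterior, and the electrostatic concave-to-additive shift.

They do *not* resolve the interfacial fine structure of the length
mixtures. A 3000-bead droplet has radius $\approx 10$ lattice units and
fitted interfacial widths $w \approx 1.5 \pm 0.4$ across replicates; the
inter-species width difference and the radial offset between the two
species' chain-expansion peaks are smaller than that droplet-to-droplet
scatter, and chain centers rarely visit the outer interface at these
counts. Those two orderings need the production droplet ($\sim 5\times10^4$
beads), where the interface is several widths away from the center and each
shell holds hundreds of chain centers. The corresponding acceptance checks
are therefore expected to fail at desk scale; they are kept in the suite
as written because they are the faithful statement of the full-scale
result, and the failure mode (scatter, not bias) is the informative part.
A related visibility limit: at desk scale the dilute arm of strongly
phase-separated states is often numerically zero (no chain evaporates
within the run), which is why the saturation-concentration comparisons are
done near the top of the two-phase window.

The homopolymer generators emulate the study conditions (volume fraction,
equal-mass mixing, dense seeding, replicate protocol) but not every feature
of real PLCD data: there is no sequence heterogeneity within a species, no
residue-specific sticker spacing, and the electrostatic term is mean-field
— passing batteries demonstrate the organizational physics of the model,
not sequence-specific predictions for particular proteins.

## Numerical choices, in one place

* Reduced units throughout, $k_B = 1$; energies on the arbitrary scale of
  the contact matrix.
* Contact and bond shell: 26 neighbors; bonded pairs excluded from energy
  (`bonded_excluded = TRUE`).
* Radial bins: 1 lattice unit (profiles), 1.5–2 (chain-dimension
  profiles, which need more chains per bin); profiles are truncated at
  half the box edge, where shells start wrapping.
* Logistic fits: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`),
  plateau seeds from the profile ends, width seeded at 1.5; degenerate
  contrast below $10^{-4}$ (or 10% of the dense plateau) is single-phase.
* Interfacial interval: 90%/10% crossings ($r_{\mathrm{mid}} \pm w\ln 9$).
* Single-phase cluster threshold: 0.5 of all chains.
* Tie-line and cooperativity classifications: 2 standard errors.
* Dense seed density: 0.3 (desk presets); 35-site subbox at full scale.
* Exact enumeration: translational reduction pins the first bead of the
  first chain; the guard refuses state spaces beyond $2\times10^7$
  configurations.
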