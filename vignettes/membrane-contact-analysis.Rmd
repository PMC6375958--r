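---
title: "Methods: residue-lipid contact, residence and distribution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue-lipid contact, residence and distribution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlipid)
```

This vignette documents the models, conventions and numerical choices
behind `memlipid`, in the order an analysis runs: trajectory model,
contact criterion, residence times, lipid distribution statistics,
geometric descriptors, motif scanning, and the synthetic generator that
makes all of it testable.

## Trajectory model and conventions

Coordinates are in Ångström, times in picoseconds, and residue numbering
follows the PDB author numbering, so cRaf kinase-domain residues are
addressed as 340–648 exactly as crystallographers write them. Boxes are
orthorhombic; the bilayer plane (x, y) is treated as periodic with the
minimum-image convention, while z — the membrane normal — is non-periodic,
which is the correct topology for leaflet logic (a lipid cannot wrap
through z into the other leaflet).

Topologies come from PDB files (parsed with bio3d); hydrogens are
identified from the element column when present, otherwise from a
leading-H atom-name heuristic with a logged warning, because headgroup
and contact definitions are heavy-atom definitions. Trajectories are read
from CHARMM/NAMD-dialect DCD (bio3d's reader) or from the MTRAJ plain-text
dialect (`#mtraj v1 natoms=<N> dt_ps=<dt>` header, one `box` line plus N
atom lines per frame), which exists so fixtures are human-readable and
diffable. A DCD writer is included so the two dialects can be checked
against each other; round trips agree to the float32 precision of the
binary format (~1e-6 Å relative).

Leaflets are assigned per frame from the sign of each lipid's phosphorus
z relative to the midplane (the mean z of all lipid P atoms); a lipid
exactly at the midplane goes to the upper leaflet, a documented
tie-break that matters only for pathological flat systems.

## The contact criterion

A residue-lipid contact exists in a frame when any protein heavy atom of
the residue lies within `d_cut` of any heavy atom of the lipid headgroup.
Defaults:

* `d_cut = 4.0` Å — the conventional heavy-atom contact distance for
  protein-lipid encounters;
* POPC headgroup = {N, C11–C15, P, O11–O14} (phosphate + choline),
  POPA headgroup = {P, O11–O14} (phosphate only). The headgroup sets are
  user-overridable per residue name because force-field nomenclature and
  the inclusion of glycerol carbons are genuinely conventions, not facts;
  we default to the solvent-exposed moiety, which is what a 4 Å criterion
  can actually reach from the aqueous side.

Distances are 3D with minimum image applied in x and y only. Contacts are
evaluated against both leaflets; in practice only the proximal leaflet is
reachable at 4 Å, so no leaflet filter is applied here. Correctness is
defined by an all-pairs brute-force scan, against which the vectorised
implementation is tested exactly on small instances; speed is an
implementation detail, not a semantic.

Contact probabilities are fractions of frames, computed over all frames
by default (a start-time window can be applied by subsetting the series).
When several identical peptide copies are present, probabilities are
averaged positionally — by sequence index within the chain, not by
residue number — so renumbered copies group correctly. Stable-contact
sets use a strict `>` at the threshold (a residue at exactly 50 % is not
"in contact for more than half the simulation").

The shipped region presets for the cRaf kinase domain are the N-terminal
acidic region (340–342), the polybasic cluster (391, 398–401) and the
activation segment (462, 463, 494–497).

## Residence times

A dwell event is a maximal run of consecutive contact frames for one
(residue, lipid) pair. Its residence time is the literal time difference

$$t_\mathrm{res} = t_f - t_i = (k - 1)\,\Delta t$$

for a k-frame run. This is deliberately not the occupancy time
$k\,\Delta t$: the two conventions differ by one frame spacing on every
event, which is material when events are short or Δt is coarse, so the
choice is stated prominently wherever events are documented. A
single-frame contact has $t_\mathrm{res} = 0$ and still counts as an
event.

By default no gap is tolerated inside an event — one non-contact frame
splits it. An optional `gap_frames` argument exists for robustness
studies only and is off by default. Events truncated by either trajectory
end are flagged `censored`; they are included in aggregate residence
times (the contact time existed) but excluded from mean-dwell estimates
(their true length is unknown). Event eligibility defaults to residues in
stable (> 50 %) membrane contact, mirroring how residence statistics are
normally restricted to the genuinely membrane-bound part of the protein.

Residence times are sensitive to the sampling interval: subsampling hides
short excursions, merges events and lengthens apparent dwells.
`stride_sensitivity()` makes this explicit by recomputing the statistics
at integer frame strides (effective spacing `stride * dt`). Whether a
coarse-Δt published number reflects subsampling or gap tolerance is often
ambiguous; both mechanisms are provided and neither is asserted as the
"right" reading.

## Lipid distribution statistics

The in-plane radial distribution function of lipid phosphorus around
reference protein atoms is

$$g_{2D}(r) = \frac{\langle n(r) \rangle}{2\pi r\,\Delta r\,\rho},$$

with xy-projected minimum-image distances, ρ the instantaneous
target-lipid surface density from the per-frame box area (NPT boxes
fluctuate), and averaging over reference atoms and frames (pooled
averaging over references is the default and is documented, since
per-reference normalisation is an equally defensible convention).
Defaults Δr = 0.2 Å and r_max = 12 Å resolve first/second/third
coordination-shell peaks (~4 / ~4.8 / ~5.7 Å apart for phosphate-
guanidinium contacts) without committing to figure-read values. The
leaflet scope defaults to the leaflet whose P plane is nearest the
reference atoms — cross-leaflet pairs are geometrically impossible below
~12 Å anyway. Reference atoms for the cRaf polybasic cluster default to
Lys NZ and Arg NE; guanidinium nomenclature has no "Nδ", so which
nitrogen a legacy analysis used is exposed as configuration (NH1/NH2
selectable) rather than silently resolved.

Convergence is assessed by recomputing the profile on time blocks and
reporting the largest absolute deviation from the full-window profile.
On a stationary field the blocks agree within Poisson counting noise; a
drifting field shows systematically larger early-versus-late deviations.

Enrichment: a lipid is "near" a residue set in a frame if it contacts at
least one member under the standard criterion; the local species
fraction is the ratio of frame-averaged counts, compared against the
global fraction from topology composition (50 POPA / 416 lipids = 12.0 %
for the default bilayer). When no lipid is ever near, the local fraction
is undefined and flagged rather than silently zero.

## Geometric descriptors

* **Salt bridges** use min(N···O) ≤ 4.0 Å between basic side-chain
  nitrogens (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2 — histidine counts as
  basic here) and lipid phosphate oxygens. No angle criterion is applied;
  this is an ionic-contact definition, not a hydrogen-bond definition.
  The 4 Å default matches the package's only other distance criterion
  and is overridable.
* **Multivalency** is interval algebra over a lipid's salt-bridge events:
  maximal windows in which ≥ 2 distinct residues are engaged
  simultaneously, reported with the partner set. Every multivalent
  interval is by construction a subset of each contributing event.
* **Shared-lipid episodes** collapse consecutive frames with an identical
  set of contacted regions into windows, per lipid; the windows partition
  the lipid's in-contact frames exactly, and lipids are ranked by total
  multi-region time. This is the statistic that identifies a single
  lipid bridging distant protein regions.
* **Helix orientation** fits a line through the helix C-alphas per frame
  (principal component) and reports θ = arccos |axis·ẑ| in [0°, 90°];
  the absolute value folds the axis sign ambiguity. A helix lying flat
  on the membrane reads θ ≈ 90°. At least four C-alphas are required;
  note that the principal axis of a short helical arc deviates from the
  true helical axis by up to a degree or two depending on how many
  residues cover whole turns — calibration fixtures therefore use
  20-residue helices (≈ 5.5 turns), where the bias is ≤ 0.4°. The
  default span 391–408 covers the αC-helix harbouring the polybasic
  cluster and is configurable, since helical boundaries are an
  assignment, not a fact.
* **Spine collinearity** reports the RMS perpendicular deviation of
  side-chain heavy-atom centroids (unweighted means, backbone excluded)
  from their best-fit line; 0 for perfect collinearity. Default spine
  F408, L397, F487, H466 with an `extended` flag adding W342. Glycine in
  a spine set is an error rather than a silent empty centroid.
* **Inter-chain independence** reports per-frame minimum heavy-atom
  distances between protein copies and flags frames below the contact
  cutoff — the check that peptide copies are genuinely independent
  replicas (copies placed ~60 Å apart should never flag).

## Motif scanning and composition groups

Patterns are fixed-length element lists: fixed residues, alternative
sets, and wildcard repeats. Two presets ship for the Raf-family
polybasic membrane-interaction consensus: strict
`R x E x{4} [RK] [KR] T R` (the default) and relaxed
`[RK] x E x{4} [RK] [KR] [TLQ] R`. Scanning reports all, possibly
overlapping, matches left to right, with positions in a caller-supplied
numbering (offset + 1-based index); on the printed cRaf segment numbered
from 390 the strict pattern spans 391–401. The scanner is tested for
exact agreement with an exhaustive window-checking oracle.

Membrane-binding residue sets are classified into three recurring
composition groups: (1) largely positively charged, (2) positive plus
aromatic/hydrophobic, (3) polar/aromatic/hydrophobic. The class
fractions use basic = {R, K, H}, aromatic = {F, W, Y}, hydrophobic =
{A, V, L, I, M, P}. The thresholds (group 1: basic ≥ 0.6 and
aromatic+hydrophobic < 0.25; group 2: basic ≥ 0.25 and
aromatic+hydrophobic ≥ 0.25; else group 3) are this package's own
calibration: the literature assigns groups by example rather than by
rule, so the thresholds are configuration values whose regression test
is that six classic examples (syntaxin-1A, MARK/PAR1, PKCα, SOS,
spectrin, PKCδ) land in their stated groups.

The compact interface code renders an ordered residue set with gaps of
one residue as `.` and gaps of two or more as `..`. Published codes of
this style sometimes encode secondary-structure membership in the dots
instead of numbering gaps; this implementation is strictly
numbering-based because that is the only definition computable from a
residue list alone.

## The synthetic generator

The generator emulates exactly the features of a bilayer trajectory the
analyses consume, and nothing else: single-bead lipid headgroups (atom
P) on two z planes at ±18 Å, peptide residues as a backbone bead plus an
interfacial side bead 2 Å above the proximal plane, in-plane Gaussian
random walks for free lipids, and scheduled binding. It does not emulate
energetics, z fluctuations, lipid flip-flop, headgroup internal
structure or protein conformational dynamics — so passing recovery tests
demonstrates the correctness of the analysis chain, not realism of the
physics; conclusions about real membranes still require real
trajectories.

Defaults mirror a symmetric 183 POPC + 25 POPA per leaflet patch
(12 % PA) in a 120 × 120 Å box at Δt = 10 ps. The default diffusion step
σ = 0.15 Å/frame corresponds to a POPC-like lateral diffusion
coefficient (~8 µm²/s via MSD = 4DΔt). Statistical calibration tests
pass a larger σ explicitly so that successive frames are effectively
independent samples; that is a property of those tests' inputs, not a
changed default.

Scheduling: scripted rules place a lipid within 0.8 × d_cut (3D) of its
partner's side bead for the scheduled frames — jittered uniformly in the
reachable disc so RDF peaks have finite width — and every lipid not
currently bound to a rule residue is kept outside 1.5 × d_cut of it
(pushed radially on violation). This exclusion zone is what makes
scripted schedules round-trip *exactly* through the geometric contact
criterion: without it, a diffusing lipid could graze a rule residue and
append spurious frames to a scheduled event. One lipid may be handed
between residues across non-overlapping intervals (how shared-lipid
fixtures are built); stochastic rules instead run a two-state
bind/unbind chain with per-frame probabilities, whose dwell lengths are
geometric with mean t_res = Δt(1 − p)/p — the closed form the recovery
tests check against.

All randomness comes from a 32-bit linear congruential generator
(multiplier 1664525, increment 1013904223, modulus 2³²) advanced in
exact double arithmetic, with per-lipid substreams derived by integer
mixing. The recurrence, substream derivation and per-frame draw schedule
are written into the fixture manifest so an oracle in any language can
replay lipid positions bit-for-bit; the test suite does exactly that for
the first ten frames of a free lipid. Identical spec + seed produces
byte-identical fixtures.

## Pipeline, configuration and outputs

`run_pipeline()` executes contacts → probabilities → events → RDF →
enrichment → salt bridges → shared episodes over one trajectory with a
single validated configuration (`run_config()`, or a YAML file via
`read_run_config()`; unknown keys are rejected so misspelled parameters
cannot silently fall back to defaults). YAML was chosen as the config
format because it satisfies the intended flat-keys-plus-sections shape
with a parser already in the dependency stack. Every resolved parameter
is logged; each stage failure aborts with the stage name and leaves a
`FAILED` marker beside any partial outputs; the summary JSON is a pure
function of inputs and configuration, which the test suite checks by
byte-comparing reruns.

## Problem sizes and limitations

The shipped tests run on desk-scale fixtures: systems of tens of lipids
and a handful of residues for oracle checks, ~50 000 frames for the
nanosecond-scale scripted round trip, 3 500 frames × 20 lipids for
stochastic dwell recovery, and ~10⁵ lipid samples for the uniform-field
RDF calibration — sizes chosen so the full suite completes in a few
minutes while leaving every statistical check with comfortable power.
Microsecond all-atom observables (e.g. maximum PA residence times of
order 100 ns on a specific arginine, or ~20 % local PA enrichment on a
real kinase surface) are properties of particular long trajectories that
are not redistributable; this package verifies the estimators, not those
numbers.

Known limitations: lipid identity is not corrected for periodic-image
swaps (a lipid leaving one box edge and re-entering is the same residue,
which is the desired bookkeeping for residence times, but true
neighbour-exchange kinetics are out of scope); no survival-curve or
Markov-state kinetic modelling is attempted on top of the dwell events;
salt bridges are distance-only; and the RDF is strictly two-dimensional.
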