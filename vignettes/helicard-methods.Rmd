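---
title: "helicard: models, synthetic data and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helicard: models, synthetic data and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helicard)
```

## The model

A one-start C1 helical filament is generated from a single subunit by the
screw operator $S(k)$: rotation by $k\,\theta$ about the $+z$ axis
followed by translation $(0, 0, k\,h)$, where $h$ is the axial **rise**
(Å/subunit) and $\theta$ the signed **twist** (deg/subunit). Negative
twist means a left-handed filament; the RIP2–CARD defaults are
$h = 4.936$ Å, $\theta = -101.4^\circ$ (`rip2_params()`). Derived lattice
quantities:

* pitch $P = (360/|\theta|)\,h$ — axial distance per full turn;
* protrusion spacing $(720/|\theta|)\,h = 2P$ — the repeat of the
  protruding features seen on a 2D projection. For this lattice
  ($360/|\theta| \approx 3.55$ subunits/turn) the projected outline
  quasi-repeats after 7 subunits $\approx$ 2 turns, which is why the
  visual repeat is two pitches, not one;
* subunits per turn $360/|\theta|$, and $\lfloor L/h \rfloor$ subunits in
  an axial span $L$ (a 60 Å segment holds 12).

The inverse problem — recovering $(h, \theta)$ from coordinates — is
solved by Kabsch superposition of each subunit onto its successor; the
rotation angle about the fitted screw axis (oriented so the axial
translation is positive) is the signed twist. Estimates from all
consecutive pairs are averaged. Noise-free round trips are exact to below
1e−9; with 0.2 Å coordinate jitter the recovery is within 0.05 Å / 0.5°.

### Interfaces and charge-reversal logic

Death-fold filaments are stabilised by three conserved interface types,
each pairing an "a" and a "b" half-surface: Ia:Ib, IIa:IIb, IIIa:IIIb.
`rip2_patches()` carries the published RIP2 residue sets; K471 and E472
each belong to two patches. Contacts are residue pairs in different
subunits with minimum heavy-atom distance ≤ 4.5 Å (the field's standard
contact criterion; the source study prints no cutoff, so it is
configurable). A subunit-pair interface is assigned the type whose patch
pairing explains at least half of its contacts; dual-membership residues
vote for whichever pairing matches the partner, half a vote each if both
match.

The mutation model is deliberately minimal: formal charges D/E = −1,
K/R = +1, all else 0 (histidine included — no printed interface pair
contains one), and a residue pair is attractive/repulsive/neutral by the
sign of the charge product. A mutant's category follows, in order: any
native pair turned repulsive → *loss*; a formerly neutral pair turned
attractive → *enhanced*; a formerly attractive pair preserved with
swapped signs → *rescue*; otherwise *ambiguous*.

Two editorial conflicts in the source figures had to be resolved:

* **Residue 458.** The interface figure lists "Q458" but the
  charge-reversal series names the mutant "R458E", and only an arginine
  at 458 makes the functional series internally consistent under a charge
  model: with Gln, E445R would be neutral→neutral (*ambiguous*, observed
  *loss*) and E445R+458E neutral→attractive (*enhanced*, observed
  *rescue*). With Arg, all eight printed single/double-mutant categories
  reproduce. `rip2_native_pairs()` therefore models 458 as Arg;
  substitutions are keyed by site number, so "Q458E" and "R458E" both
  denote 458→E.
* **"N495A".** The running text once names the top-silencing pair
  "N495A–K513E"; no N495 exists in any printed patch (D495 does) and the
  figure legend says N449A, which is adopted.

One printed outcome is knowingly not reproduced: the D495R single mutant
is reported as more active, but its partner N449 is neutral, so the
charge product cannot change — the model says *ambiguous*. This is left
as a documented mismatch rather than patched with an invented polar
bonus; the acceptance bar is ≥ 7 of 8 categories, and the model reaches
8/8 with the Arg458 reading.

## The synthetic world

`make_synthetic_monomer()` builds a pseudo-atom stand-in for a CARD: five
ideal α-helices (1.5 Å rise/residue, 2.3 Å helix radius) in an
antiparallel bundle filling ~40×25×25 Å, one bead per residue plus one
bead per charged side-chain terminus, with 0.15 Å seeded jitter.
Numbering starts at 432, mirroring the RIP2-CARD construct boundary. The
monomer is placed with its centroid 17 Å off the filament axis and its
long axis tilted 35° off radial, which makes screw propagation produce a
hollow-free tube ~64 Å across (the study's "~7 nm" core) whose subunits
touch at exactly three lattice offsets: Δk = 1 (the one-start lateral
neighbour), Δk = 3 and Δk = 4 (the two near-axial shells; Δk = 4 has the
smallest wrapped twist, −45.6°).

**Patch placement is geometry-driven.** The published Δk↔type mapping is
not printed anywhere, so the generator fixes its own convention —
Type I ↔ Δk = 3, Type II ↔ Δk = 4, Type III ↔ Δk = 1 — and labels the
contact epitopes of those shells: candidate residue pairs within 5.5 Å
are merged across the three shells, sorted by distance, and greedily
labelled (lower subunit side → "b" patch, upper side → "a" patch). A
residue may carry at most two same-side labels, mirroring the dual
membership of K471/E472 in the real patch set; epitope overlap between
shells makes this necessary. "a" residues get charge −1 (Glu-like
beads), "b" residues +1 (Lys-like), so every planned cross-interface
pair is a salt bridge, and the b-side patches end up on the top axial
face, a-side on the bottom, matching the published top = {Ib, IIb} /
bottom = {Ia, IIa} partition. Three bulky landmark residues (Trp/Tyr/Phe
at mid-H1/H3/H5, the aromatic registry used for model building) are
reserved before planning so they never collide with a patch.
`make_patch_decoy()` re-deals the labels among surface residues without
touching geometry — classification on decoy filaments must mostly fail,
and does (≥ 50% unclassified is the acceptance bar; in practice all
pairs fail).

What the generator does **not** emulate: sculpted molecular surfaces
(the ideal bundles interpenetrate slightly at the interfaces — harmless
for distance-based classification but unphysical), side-chain chemistry
beyond a single charged bead, CTF/dose/detector effects in images, and
filament flexibility or polymorphism. A green test therefore establishes
the correctness of the geometry, spectral analysis and classification
logic, not of any biological claim about RIP2.

## Projection images and the layer-line estimator

`render_micrograph()` projects heavy atoms along $+x$ onto the $(y, z)$
grid as isotropic Gaussians (default `blur_sigma` 1.5 Å, standing in for
~4 Å resolution), adds seeded white Gaussian noise scaled as a fraction
of the peak signal, and mean-subtracts. Defaults follow the study's
calibrations: 1.23 Å/px (cryo; 2.11 Å/px for the negative-stain case),
512-px box, 30-subunit default filament.

Two procedural points matter and are easy to get wrong:

* **Window in z, not in subunit count.** A free-floating 30-subunit
  filament has its furthest layer line measurably displaced from
  $1/h$ — the monomer form factor slopes across the finite-length
  Dirichlet peak, and the apparent rise comes out at 4.87–4.99 Å
  depending on the seed. Real analyses window segments out of filaments
  much longer than the box; windowing in $z$ turns the axial profile
  into (box window) × (exact comb), whose teeth sit exactly at $m/h$.
  `layerline_rise_experiment()` therefore renders a filament that
  overfills the field of view and lets the box do the windowing; with
  that procedure the noiseless estimate is 4.92 Å (one frequency bin
  from 4.936 at a 512×1.23 Å window) for every seed tested.
* **Read the meridian column only.** On the exact meridian only Bessel
  order 0 survives; the $n = \pm 1$ lines at $1/h \pm 1/P$ vanish there
  but leak into any wider lane, and for some rises they sit above the
  detection threshold and masquerade as "the furthest line" (rise-6
  filaments were misestimated at 4.66 Å with a ±3-px lane). The default
  `lane_halfwidth` is therefore 0; widen it only for off-centre images.

Peaks are local maxima above 5× the median lane amplitude (the source
prints neither its lane width nor threshold; both are flagged
engineering choices and are configurable), ties going to the higher
frequency, and the rise estimate is the reciprocal of the furthest peak
at bin-centre resolution (optional parabolic refinement behind a flag).

Single segments at a realistic per-segment SNR cannot show the furthest
line — at power SNR 2 it sits far below the noise floor. The study read
its profile from 2D class averages of hundreds of thousands of segments;
`class_average_micrograph()` emulates a class average of `n_segments`
(default 2000, conservative against the study's ~thousands per class),
using the exact identity that the mean of $K$ white-Gaussian-noise
renders equals one render with noise $\sigma/\sqrt{K}$. With that
pipeline the rise estimate lands in the 4.9–5.1 Å bracket in 20/20
seeded replicates at per-segment SNR 2.

A single projection cannot fix the hand of the filament: mirroring the
image leaves the amplitude spectrum unchanged, so only the twist
magnitude is determined (`twist_sign_ambiguity()` returns both signed
candidates with an explicit unresolved flag; resolving −101° required
the 3D map).

The protrusion-spacing measurement (`measure_protrusion_spacing_px()`)
emulates the manual pixel count: an edge lane at the filament rim is
collapsed to an axial profile, high-pass filtered (running median over
~50 Å) to remove the finite-length envelope, and the first
autocorrelation maximum above 0.15 beyond ~7.5 Å gives the repeat at
integer-pixel resolution. On default renders the three numbers of the
consistency argument — measured spacing, $(720/|\theta|)h$ and $2P$ —
agree pairwise within one pixel.

## Degenerate inputs and tie-breaks

* twist must lie in (−180, 180] and be nonzero; +180° is its own mirror
  (`twist_sign_ambiguity(180)` returns a single candidate).
* A monomer centred on the axis cannot be propagated (error), and a
  filament needs ≥ 2 congruent subunits for parameter recovery (post-fit
  RMSD ≤ 1.5 Å, else "not a filament").
* Equal-support interface types break toward the smaller summed contact
  distance; support below 0.5 is always `unclassified`.
* PDB altloc logic is first-wins; chains beyond 62 exhaust the chain-id
  alphabet (error); only ATOM/HETATM records are interpreted.

## Limitations

* No Bessel-order indexing, 3D reconstruction, CTF or FSC machinery —
  only the arithmetic actually needed for the reported numbers.
* The synthetic monomer's helix boundaries and patch residues are its
  own ground truth; the RIP2 helix table (`rip2_helix_table()`) is a
  package default chosen to place the published patch residues on their
  described secondary-structure elements, since no boundaries are
  printed — override it with structure-derived intervals when working
  with deposited coordinates.
* Real-data mode (deposited filament models) is exercised only through
  the PDB/mmCIF readers and the symmetry/contact machinery; no deposited
  files ship with the package.
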