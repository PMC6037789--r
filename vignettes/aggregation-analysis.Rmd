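---
title: "Order parameters for peptide aggregation: methods and design notes"
author: "aggscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order parameters for peptide aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggscape)
```

## The problem

Short amyloidogenic peptides — fragments of islet amyloid polypeptide
(hIAPP), Aβ, α-synuclein — self-assemble through a crowded zoo of
intermediates: disordered oligomers, open single- and double-layer
β-sheets, and closed β-barrels, before maturing into cross-β fibrils.
Simulation studies of this process produce multi-frame coordinate sets
of N identical short chains, and the scientific questions are asked of
*order parameters* computed per frame: how large is the biggest
aggregate, how much of it is β-sheet, is the sheet open or closed, which
residues drive pairing, and what does the free-energy surface over
aggregation coordinates look like. `aggscape` implements that analysis
stack, together with a geometric generator of labeled reference
structures that makes every stage testable without running microsecond
simulations.

## The analysis model

**Hydrogen bonds.** A backbone N–H···O=C bond is accepted when the N–O
distance is at most 3.5 Å and the N–H···O angle at the hydrogen is at
least 120°. This single geometric rule drives everything downstream;
bonds within a residue or between sequence-adjacent residues of one
chain are excluded, prolines and chain N-termini never donate. When
frames arrive without polar hydrogens, the amide H is reconstructed in
the C(prev)–N–CA plane at 1.0 Å along the bisector pointing away from
both neighbours — the standard planar-amide construction. Both input
conventions occur in practice, so both are supported; a reconstructed H
for ideal geometry lands within hundredths of an Ångström of a
generated one.

**Secondary structure.** Rather than mixing two bond definitions (an
energetic one for structure assignment and a geometric one for sheet
bookkeeping), one bond set feeds a Kabsch–Sander-pattern classifier:
β-bridges from the four ladder patterns (two antiparallel, two
parallel), helix from runs of two consecutive i→i+4 turns, turns from
isolated i→i+3/4/5 bonds, coil otherwise, with priority E > H > T > C.
The full eight-state alphabet is deliberately collapsed to the four
states the aggregation analysis consumes. A consequence worth noting:
an *isolated* bridge already carries two inter-strand hydrogen bonds, so
it is labeled E here rather than the single-bridge state of the full
dictionary — consistent with the two-bond chain-pairing rule below.

**Topology.** Per frame, two graphs over the peptides:

* the *contact graph* — an edge whenever any inter-molecular heavy-atom
  pair is within 5.5 Å (minimum image when a box is present); its
  connected components are the oligomers;
* the *pairing graph* — an edge whenever both chains contribute at least
  two consecutive E residues and at least two inter-chain backbone bonds
  link those residues, annotated with the bond count and the orientation
  (sign of the dot product of the chains' strand-segment direction
  vectors, first CA to last CA of the longest E run).

Sheets are pairing components of two or more chains; a sheet is a closed
**barrel** when every strand has degree ≥ 2 *and* the pairing subgraph is
2-edge-connected, with a minimum of four strands. Degree alone is not
enough — a path with one doubled edge region has all-degree-2 interior
but is not closed; 2-edge-connectivity ("no single pairing disconnects
the sheet") is the property that makes "every strand lies on a cycle"
precise. The four-strand floor excludes degenerate triangles while
admitting every barrel size observed in practice (hexamers through
octamers). β-sheet oligomers group sheets whose members are in *direct*
heavy-atom contact; a coil peptide bridging two sheets does not merge
them, and the group's size counts only the peptides in β conformation,
following the definition literally. One peptide is one strand node:
these are 7–11-residue chains that form single strands, and a chain with
two E segments still pairs via its longest segment.

**Ensemble statistics.** Object-size statistics are mass-weighted: the
mean is (Σnᵢ²)/(Σnᵢ) and P(s) ∝ s·c(s), i.e. the probability that a
random *peptide* sits in a size-s object, pooled over frames with equal
frame weight. The antiparallel/parallel ratio weights each pairing edge
by its hydrogen-bond count; a window without edges yields a missing
value, never zero. The per-frame traces are the largest oligomer, the
largest β-sheet oligomer, the mass-weighted mean sheet size (missing
when no sheet exists) and the total barrel size. Contact-frequency maps
count, per ordered chain pair and frame, whether any heavy-atom pair of
residues i and j is within the contact cutoff — backbone–backbone and
side-chain–side-chain separately, with CA standing in for glycine's
absent side chain so its rows are defined.

**Free-energy landscape.** Observations are per oligomer per frame:
(size, E residues per chain in the oligomer). The full trajectory is
used, not the equilibrium window, because the early assembly pathway is
exactly what the landscape should capture. The surface is
−k_B·T·ln P on a grid of exact integer oligomer sizes × 1-residue
β-content bins (left-closed), shifted so the global minimum is zero;
unsampled bins are reported as missing rather than infinite. Occurrence
weighting is per oligomer (the literal "probability of an oligomer");
per-peptide weighting is available as an option since the distinction
matters for asymmetric size distributions. k_B is the conventional
0.0019872 kcal/(mol·K); the two-bin sanity check at 300 K,
k_B·T·ln 2 = 0.4132 kcal/mol, is asserted to 10⁻⁶ in the tests.

## The synthetic generator

The generator's job is ground truth, not thermodynamics: frames whose
expected hydrogen bonds, pairings, sheets and barrels are known by
construction.

Helices, extended monomers and random coils are built from internal
coordinates (ideal bond lengths/angles, NeRF chain extension);
(−57, −47) yields a helix whose i→i+4 bonds sit at 3.09 Å / 165°,
(−120, 120) an extended strand, and coil mode draws per-residue
dihedrals from a uniform mixture over the β, polyproline-II and
right-handed-α basins with rejection of backbone self-clashes below
2.5 Å at sequence separation ≥ 2.

Sheets and barrels use an idealized strand template instead of
dihedral-built strands: residues rise 3.5 Å along the strand axis, and
the N–H/C=O groups of successive residues alternate between the two
lateral sides, offset toward the partner strand (N at 0.45 Å, H at
1.45 Å, O at 1.68 Å from the axis). With 4.85 Å between strand axes,
every intended ladder bond is then exactly 2.72 Å with a straight
180° N–H···O geometry — comfortably inside the 3.5 Å / 120° rule, with
the documented safety margin (≤ 3.3 Å, ≥ 150°) surviving the σ = 0.15 Å
noise floor used in the robustness tests. The price is that template
backbones are not at ideal covalent geometry; since every analysis stage
consumes only distances and angles between N, H, O and heavy atoms, that
trade is the right one for a test oracle. Registry is solved per seam:
antiparallel neighbours take the full-overlap registry (each residue
pairs its mirror), parallel neighbours a one-residue stagger, and each
strand carries a direction, axial offset and donor phase chosen so the
seam equations close. On a barrel the strands sit on a cylinder of
radius r = d/(2 sin(π/n)) (d = 4.85 Å) with bonding groups aimed along
the chord to the partner, which reproduces the flat-sheet bond geometry
on every seam exactly. Two consequences fall out of the closure
algebra rather than being imposed: an alternating-direction barrel with
an odd strand count necessarily contains one parallel seam (closed with
zero stagger), and a fully parallel barrel exists only for even strand
counts, because the per-seam ±1-residue staggers must cancel around the
cycle — odd counts raise a generation error. Double layers stack two
antiparallel sheets 10 Å apart with side-chain proxies (CB at 1.53 Å,
CG at 2.9 Å for residues larger than alanine) facing, giving the
inter-layer heavy-atom contact that merges the layers into one β-sheet
oligomer without any inter-layer hydrogen bond.

Scenes compose components on a wide lattice (80 Å spacing) so the
expected contact topology is the union of the components; scripted
trajectories emit scenes at a fixed stride with instantaneous
transitions, and the per-frame expected traces are the oracle for the
end-to-end tests. All generation is deterministic: a fixed seed yields
byte-identical files.

**What the generator does not emulate.** Real trajectories have
thermal backbone disorder, bent L-turn/U-turn sheets, partial
registries, transient bonds at the rule boundary, and continuous
transitions between states. Detection is topological, so bent sheets
reduce to the same pairing structure and are not geometrically modeled.
Passing the synthetic suite therefore demonstrates correctness of the
*definitions and their implementation* — not that any particular real
peptide aggregates one way or another, and no such empirical claim is
made by the tests.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `hbond_dist` | 3.5 | Å | max donor-N to acceptor-O distance |
| `hbond_angle` | 120 | deg | min N–H···O angle at H |
| `contact_cutoff` | 5.5 | Å | heavy-atom contact (0.55 nm) |
| `min_ladder_hbonds` | 2 | — | bonds required per chain pairing |
| `min_consecutive_E` | 2 | — | strand residues required per chain |
| `barrel_min_size` | 4 | strands | smallest closed sheet counted |
| `equilibrium_fraction` | 0.5 | — | trailing window for ensemble stats |
| `pmf_temperature` | 300 | K | free-energy transform temperature |
| `pmf_beta_bin` | 1.0 | residues | β-content bin width |

All thresholds live in `aggregation_control()` — there are no numeric
cutoffs buried in analysis code. The equilibrium window default mirrors
the common practice of discarding the first half of each run (for
300 ns runs, analyzing the final 150 ns); the landscape deliberately
ignores the window. Multiple runs are pooled with equal frame weight.

## Numerical choices and degenerate inputs

Distances use the minimum-image convention whenever a frame carries a
cubic box, otherwise open boundaries. Empty cases are defined, not
errors: a frame with no bonds is all-coil; a window with no pairing
edges has an undefined (missing) alignment ratio; a frame with no sheets
has a missing mass-weighted sheet size; an empty size list is a domain
error for the mass-weighted mean but an empty distribution for the
histogram. Orientation ties (a zero dot product between segment
directions) classify as antiparallel; they do not occur away from a
measure-zero geometry. The PDB writer emits standard fixed-width
records at 10⁻³ Å precision, and round-trips are exact to that
precision; frame times ride in a `REMARK 6 TIME_NS` line because the
PDB format has no native time field.

## Simulation bookkeeping

The bookkeeping module pins CODATA-2018 constants and reproduces the
published setup arithmetic: 20 peptides in a 10.8 nm cubic box are
26.4 mM (the "~26 mM" constant-concentration series), six million
discrete-dynamics time units of ~50 fs are 300 ns, and a 10 Å Debye
screening length at 300 K in water (ε_r = 78.5) corresponds to 93 mM
1:1 salt — the "~100 mM physiological" statement to one significant
figure. One published inconsistency is worth flagging rather than
silently correcting: a 2-peptide system in a 6.1 nm box evaluates to
≈ 15 mM, not ~26 mM — most plausibly a rounded or transcribed table
entry; `campaign_summary()` reports the computed value. The exact DMD
time-unit duration is a calibration ("~50 fs"); 50 fs is used and the
argument is exposed.

## Problem sizes in the test suite

The suite exercises systems of 2–20 chains of 7–11 residues: the full
noise-free sweep (sheets and barrels, 4–12 strands, both orientations,
plus 50 coil-only frames), brute-force oracle comparisons for hydrogen
bonds, contacts, components and barrel closure (exhaustive over all
labeled graphs on ≤ 5 nodes, sampled on 6–8 nodes — exhaustive
enumeration beyond that is combinatorially out of reach for any
budget), 1000-case property checks of the mass-weighting identities,
and a 15-frame scripted end-to-end trajectory. These sizes were chosen
to match the regime the definitions target (small oligomers) while
keeping the whole suite fast.

## Known limitations

* Detection is topological; no geometric barrel-shape fitting (radius,
  shear number) is attempted.
* The four-state secondary-structure alphabet cannot distinguish
  single-bridge β from extended ladders, by design.
* Whether a geometric bond rule and an energetic assignment would ever
  disagree on strand content in real frames cannot be settled here; the
  package commits to the single geometric definition throughout.
* The β-sheet-oligomer size counts β-conformation peptides only, and
  sheet grouping requires direct sheet–sheet contact; both readings are
  documented above and the second is a genuine interpretive choice.
* No reweighting or cross-run error estimation on landscapes; pooled
  surfaces only.
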