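---
title: "mdflow: methods, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mdflow: methods, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdflow)
```

This vignette is the package's own account of its models and the design
choices behind them: what the engine computes, which parameters matter and
why their defaults are what they are, what the synthetic fixtures do and do
not emulate, and where the numerical conventions come from.

## The execution model

An analysis is a graph of nodes with typed ports. A port type is a base
(`int`, `float`, `string`) plus an array rank; identical types connect,
`int` promotes to `float` at any rank, and rank mismatches are rejected at
validation time. Connections must form a DAG - cycles are only possible
through *attributes*, which are not connections.

Attributes are named per-atom float arrays in a mutable store. They are the
engine's only cross-frame state: values persist from one executed frame to
the next, so a graph in which a node reads an attribute and (directly or
downstream) writes the same attribute is a recurrence, unrolled implicitly
by the per-frame schedule. Reading a never-written attribute implicitly
declares it as all zeros rather than failing, because a recurrent graph
necessarily reads its state attribute on the first visited frame, before
anything has written it.

Two scheduling conventions make this well defined:

* **Immediate attribute semantics.** Reads and writes take effect the
  moment a node executes, in schedule order - not in an end-of-frame
  commit. With a deterministic schedule this gives feedback graphs exactly
  one meaning. The alternative (frame-atomic commits) was rejected because
  it silently turns a read-after-write within one frame into a
  read-of-last-frame, which is the kind of surprise a debugging-oriented
  tool should not produce.
* **Deterministic tie-break.** Nodes not ordered by connections run in
  lexicographic id order. Any two runs of the same graph on the same data
  are byte-identical (the suite asserts this on serialized run results).

Execution walks the configured frame range in ascending (`forward`) or
descending (`backward`) order. Every output port of every node is cached
per frame; recorded attributes are snapshotted after the last node of each
frame; re-executing a frame overwrites its snapshots. Visualization is
data, not rendering: per-atom colour as a single scalar in [0, 1] (a
consumer maps it blue to red; RGB triples are out of scope), a positive
radius scale, a visibility mask, deduplicated extra bonds and a camera
center, exportable as per-frame JSON or a PDB whose B-factor column carries
the colour.

Script nodes keep user code free of framework calls. A comment line of the
form `# @in xs : float[1]` or `# @out n : int[0]` immediately above a
statement exposes that variable; everything else stays private. The script
runs whole, top to bottom, in a fresh environment; inputs are copied in and
outputs copied out, so mutating an input inside a script can never corrupt
another node's cached output, and errors are reported with the original
file's line numbers. Only R scripts are supported: compiling and
dynamically loading C++ or Fortran is compiler plumbing, not method
content, and one language suffices to exercise the annotation contract.

## Cluster identification and tracking

`list_neighbors` builds neighbour lists with a spatial cell list under the
minimum-image convention and a **closed** cutoff (distance equal to the
cutoff counts as a neighbour; the tie rule is documented rather than left
to floating-point accident). On periodic axes the cutoff may not exceed
half the box length, the validity bound of the minimum image. The cell
list must - and in the tests does - reproduce the all-pairs search
exactly.

`group_list` labels connected components with consecutive ids ordered by
each component's smallest atom index; `mode_mask` selects the most
frequent id, ties to the smallest. All tie-breaks in the package go to the
smallest index or id, for determinism.

`track_cluster` is the recurrent step: for each current cluster, count the
members that carried a label on the previous visited frame; the cluster
with the largest count becomes the main cluster (label 1, ties to the
smallest group id); if every count is zero, the tracked cluster has
dissipated and all labels clear. A *cluster* here is a connected group of
at least `min_size = 2` atoms. The size floor matters: labels live on
atoms, so every previously labelled atom always sits in *some* component,
and if isolated atoms counted as clusters the dissipation branch could
never trigger - one stray gas atom would carry the label forever. Treating
singletons as gas rather than clusters is both the physically sensible
reading and the one that makes label clearing reachable; it is exercised
by the droplet fixture, where backward tracking clears the labels at the
nucleation frame. The tracked label is binary because a single main
cluster is tracked per pass.

`labels2colors` moves each atom's colour by `fade_rate` toward 1 while
labelled and toward 0 while not, clamped to [0, 1]. The default
`fade_rate = 0.05` reaches saturation in 20 frames - a visible gradient on
trajectories of tens to hundreds of frames; the rate is a presentation
parameter with no effect on any classification. Running the same colour
graph forward and backward and max-combining the two recorded histories
produces an envelope that grades atoms by how near in time they are to
membership; the suite checks the envelope dominates both passes pointwise.

These operations act per atom. For single-site particles "per atom" and
"per molecule" coincide; for multi-site molecules a one-site-per-molecule
reduction (e.g. molecule centroids) is the appropriate pre-step.

## MCG-1 hydrate recognition

The mutually coordinated guest order parameter proceeds in stages, each a
node so each intermediate is inspectable:

1. **Guest pairs** within `pair_cutoff = 9` Å (minimum image, closed).
2. **Coordinated waters**: a water oxygen O belongs to the pair (g1, g2)
   iff the angle between O−g1 and g2−g1 *and* the angle between O−g2 and
   g1−g2 are both ≤ `cone_angle = 45°` - the lens-shaped intersection of
   two cones whose apices sit on the guests and whose axes point at each
   other. The one-line phrase "waters 45° between each guest pair" does
   not pin down the vertex of the angle, so this symmetric double-cone
   reading is *this package's definition*, chosen because it is symmetric
   in the guests and contains the midplane where cage rings sit. The angle
   and an optional per-guest distance cap are configurable so stricter
   readings can be expressed. Degenerate pairs (zero separation) are
   skipped with a warning.
3. **Hydrogen bonds** among coordinated waters: donor and acceptor oxygens
   in different molecules, O-O ≤ `d_oo_max = 3.5` Å and H-O-O angle ≤
   `angle_max = 30°`. These are the standard geometric criteria for water;
   the source node list names none, so the conventional values are the
   defaults and both are parameters.
4. **Reconnection** of each accepted (O_d, H, O_a) to the undirected O-O
   edge, deduplicated - the hydrogen-bond *network* with hydrogens
   abstracted away. (The H→acceptor pair list is also exposed, so a
   visualization can switch between O-H and O-O bond drawings by rewiring
   one connection.)
5. **Ring perception**: all simple cycles of length exactly `n = 5` in the
   O-O graph, each in canonical form (smallest vertex first, direction
   with the smaller second vertex). The DFS enumerator prunes by root
   vertex and is required to match exhaustive subset/permutation
   enumeration - the pentagonal-dodecahedron cage, with its 30 edges, 12
   pentagonal faces and no hexagons, is the canonical check.
6. **Registration**: a pair is mutually coordinated iff at least
   `min_rings = 1` ring lies entirely within its coordinated set (the "-1"
   in MCG-1). Guests of qualifying pairs and the oxygens of their
   qualifying rings are labelled; label ids are connected components over
   pairs sharing a guest, numbered from the smallest guest index;
   `classified_count` reports how many *molecules* carry a label, the
   scalar whose accumulated time series locates the onset of hydrate
   formation.

Waters are found by residue-name selection (default
`resname=SOL|HOH|WAT`), guests by a caller-supplied selection string.

## Synthetic fixtures and what they show

The generators replace multi-gigabyte external simulations with small
configurations whose correct answers are known by construction, not by
running the pipeline:

* `gen_lj_droplet` builds two compact grid blobs (intra-blob spacing 0.9 ×
  cutoff, hence connected) in a dilute gas (all other separations > 2.2 ×
  cutoff, enforced by rejection sampling; failure to place advises a
  larger box). The larger blob assembles from dispersed positions at the
  nucleation frame, the blobs translate to first contact at the merge
  frame, and scripted gas atoms join or leave the main blob at recorded
  events. The emitted ground truth is the main-cluster membership per
  frame implied by that script; the acceptance suite demands the backward
  tracking graph reproduce it *exactly*, including the clear-out before
  nucleation. Defaults (60 atoms, 20 frames, merge at 12, cutoff 3 Å)
  keep one trajectory under a tenth of a second while containing every
  event the tracker must handle; seeds vary the gas and the event times.
* `gen_cage_pair` places two guests 8 Å apart (below the 9 Å pairing
  cutoff) and five waters on the midplane circle at radius 2.8 Å, chosen
  so the cone angles (atan(2.8/4) ≈ 35°) and ring O-O distances
  (2·2.8·sin 36° ≈ 3.29 Å) satisfy the criteria with margin; each water
  donates one hydrogen straight along the ring (a linear bond), the other
  out of plane. The generator validates these constraints and refuses
  infeasible parameters. Every stage's expected output is computed from
  the geometry.
* `gen_dodecahedral_cage` is the 5¹² cage from golden-ratio coordinates,
  hydrogens oriented along edges by an Eulerian-circuit orientation so
  every edge carries exactly one donor.
* `gen_bulk_water` is the negative control: random rigid waters (O-H
  0.9572 Å, H-O-H 104.52°, the common three-site geometry, fixed for
  determinism) with all O-O separations held above 3.7 Å so the
  hydrogen-bond graph is empty.

Fixture boxes are non-periodic (or several times the structure extent), so
structures never straddle a boundary; periodic correctness is tested
separately with random configurations against the all-pairs oracle.
Passing on these fixtures demonstrates the algorithms and the engine, not
robustness to thermal noise, fluctuating hydrogen-bond geometry or
finite-temperature cage defects - real trajectories exercise those, and
the thresholds above are exactly the knobs that absorb them.

## Numerical conventions and degenerate inputs

* Internal units: Å and Å/ps. GRO values (nm) are scaled by 10 at the
  reader boundary, where the cutoffs that define both case studies are
  stated in Å.
* Indices are 1-based throughout, the R convention; file formats keep
  their native numbering at I/O boundaries only. Group and hydrate labels
  run 1..k with 0 meaning unlabelled.
* Orthorhombic boxes only; triclinic input is rejected at read time. The
  minimum image wraps into [−L/2, L/2), with the exact-L/2 tie mapped to
  −L/2 (half-open, deterministic).
* A frame index must be unique; frames within a trajectory share one atom
  table. The centroid node does not unwrap across periodic boundaries -
  a documented limitation, acceptable because the fixtures keep clusters
  whole.
* Text parsing is strict: short lines, bad numbers, mismatched counts and
  malformed headers all error with the file name and line number.
  Debuggability beats leniency.
* SSV is written canonically (`%.6f`), so write → read → write is
  byte-identical and positions survive to better than 1e-4 Å; multi-frame
  SSV is blank-line-separated blocks under a single header, the simplest
  deterministic extension of the single-frame format, with reserved labels
  (`x y z vx vy vz name resname resid`) and every other column an
  attribute.
* Problem sizes in the acceptance checks (50 neighbour configurations up
  to 500 atoms, 100 random graphs up to 200 nodes, 50 ring graphs up to
  30 vertices, 5 droplet seeds, 100 recurrence cases) were chosen as the
  smallest sizes that still cover both periodic and open boxes, sparse and
  denser graphs, and every scripted droplet event; the whole suite runs in
  well under a minute on one core.

## Known limitations

* No triclinic cells, no binary trajectory formats (XTC/TRR/DCD), no
  remote file access; the reader registry is the extension point.
* Graph execution is serial; per-node vectorization is the only
  parallelism.
* One tracked cluster per pass; tracking several clusters simultaneously
  would need a label-per-cluster variant of `track_cluster`.
* The double-cone coordination criterion is this package's geometric
  definition of the "45°" rule; results depending sensitively on the
  criterion should be checked against the configurable strict variant
  (finite `max_dist`).
* Colour is a scalar ramp, not a colormap; consumers choose the mapping.
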