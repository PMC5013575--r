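---
title: "Maximum-clique common-substructure screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-clique common-substructure screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliquescreen)
```

## The screening model

Ligand-based virtual screening rests on the similarity principle: molecules
structurally similar to a known active ligand are more likely to share its
biochemical activity. cliquescreen quantifies similarity through the
*maximum common substructure* (MCS) of the reference and each library
molecule, detected as a maximum clique on a product graph.

Each molecule is first reduced to a molecular graph: the kept atoms
(heavy atoms by default, see below), their covalent adjacency, the
all-pairs topological distance matrix $D^{topo}$ (shortest-path lengths in
bond counts, from breadth-first traversal) and the Euclidean distance
matrix $D^{geo}$ in &Aring;ngstr&ouml;ms.

The *product graph* of a reference $A$ and target $B$ has one vertex per
type-compatible atom pair $(i, i')$, $i \in A$, $i' \in B$. Compatibility is
exact SYBYL-type string equality: `C.ar` matches only `C.ar`, never `C.3`.
This is the strictest reading of type-annotated matching; collapsing
subtypes (e.g. all carbons) would be a one-line change but would alter every
score, so the strict rule is fixed and documented as the package's single
most consequential matching assumption. Two vertices $(i,i')$, $(j,j')$ are
adjacent iff $i \neq j$, $i' \neq j'$ (the mapping stays injective) and
their internal relations agree:

* **2D (topological)**: $|D^{topo}_A(i,j) - D^{topo}_B(i',j')| \le t$,
  with $t$ the *maximum allowed shortest path difference* in bonds
  (default 1). Both entries must be finite: a comparison that touches a
  pair of atoms in different fragments fails, even against another
  infinite entry. This is deliberately conservative — the method never
  asserts topological consistency across disconnected fragments.
* **3D (geometric)**: $|D^{geo}_A(i,j) - D^{geo}_B(i',j')| \le t$, with
  $t$ the *maximum allowed spatial distance difference* in &Aring;
  (default 1.0).

Cliques of this graph are exactly the consistent atom-to-atom mappings, so
the maximum clique is the MCS under the chosen metric. Note the clique may
map a *disconnected* common substructure; no connectivity constraint is
imposed on the match itself. That is a modelling choice: requiring
connectivity would need a different search and typically discards useful
partial matches, but it means a reported "common substructure" can be a
union of fragments.

Similarity is the graph Tanimoto coefficient over kept atoms,

$$T_c = \frac{c}{n_A + n_B - c},$$

where $c$ is the clique size. $T_c = 1$ exactly when the mapping covers
both molecules entirely, and 0 when no atom pair is type-compatible.

## The exact clique solver

`max_clique()` is a compiled branch-and-bound of the MaxCliqueDyn family:
vertices enter the search in degree-descending order (ties by index); at
every node the candidate set is greedily sequentially coloured and
reordered by colour class, and a branch is cut when the current clique
plus the candidate's colour number cannot beat the incumbent. The bound
affects only speed — the search is exact.

Determinism matters as much as exactness here, because ranked lists and
aligned files must be byte-identical across runs and worker counts. The
solver therefore updates its incumbent only on *strict* improvement, so
the returned member set is the first maximum clique met in the fixed
search order — a cheaper canonicalisation than computing the
lexicographically least maximum clique (which would need one feasibility
solve per forced vertex) with the same reproducibility guarantee.

`brute_force_clique()` is the in-package oracle: plain recursive
enumeration with only the trivial size-remaining prune, no ordering, no
colouring, guarded to 24 vertices. The test suite cross-validates the two
solvers (and, as a third independent route, igraph's clique number) on
hundreds of random graphs per run.

## Screening, conformers, ranking

`screen_library()` scores every library record against the reference.
Records sharing a molecule name are treated as conformers of one
compound — the natural convention for multi-conformer MOL2 libraries,
where a rigid 3D comparison approximates flexibility by enumerating
geometries. In 2D the score is conformation-independent, so each compound
keeps one entry; in 3D a compound's score is the maximum over its
conformers and its best `conformers_per_molecule` geometries are retained.
The `top_k` best compounds (default 100, the scale at which hit lists are
visually inspected) survive to the report, sorted by decreasing $T_c$ with
ties broken by ascending record index — the tie rule is this package's own
convention and is stated here because any deterministic rule is equally
defensible.

Parallelism is a pure implementation detail: records are partitioned over
workers, partial results merged in record order *before* any ranking, so
the report is provably independent of the worker count and scheduling.

## Superposition and outputs

For 3D hits the target is rigidly superposed onto the reference over the
matched pairs (Kabsch: SVD of the paired covariance with a determinant
guard against reflections), and the matched-atom RMSD after the fit is
reported. With fewer than three pairs the rotation is underdetermined and
the fit degrades to a translation of centroids. The RMSD quoted is
post-fit; the whole target molecule (not only matched atoms) is
transformed, since a viewer needs every atom moved consistently. The test
suite checks the fitted RMSD against an independently implemented
closed-form quaternion solver.

A run directory contains `ranked_list.txt` (name, tab, $T_c$ to 4
decimals per line), one `<rank>_<name>.mol2` per hit holding the
reference and the aligned target plus a comment section with one
`# <ref_serial> <ref_type> <tgt_serial> <tgt_type>` line per matched pair,
and a flat key-value `manifest.txt`. The comment-line syntax is this
package's convention (the matched-pair list itself is standard plugin
fare, but no fixed syntax exists for it). `load_run()` rebuilds the
report from these files alone, recomputing each $T_c$ exactly from the
stored pair count and the re-derived kept-atom counts rather than parsing
the rounded 4-decimal text.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `dimension` | — | 2 | topological screening needs no conformers |
| `threshold_2d` | bonds | 1 | 0 demands identical path structure; 1 tolerates one-bond rearrangements, a practical scaffold-hopping setting |
| `threshold_3d` | &Aring; | 1.0 | of the order of typical bonded-geometry variation between conformers |
| `top_k` | molecules | 100 | the hit-list size commonly inspected visually |
| `conformers_per_molecule` | records | 1 | report the single best geometry per compound |
| `include_h` | flag | off | hydrogens roughly double atom counts and quadruple product-graph size while adding little discriminative signal |

No defaults are inherited from any external tool; the two thresholds in
particular are this package's own choices and should be tuned per
campaign.

## Hydrogens, dummies, degenerate inputs

Hydrogen detection uses the element prefix of the SYBYL type (`H`,
`H.spc`, `H.t3p`), the only information the format guarantees. `Du` and
`LP` pseudo-atoms are parsed and preserved in molecules but always
excluded from graphs — they carry no chemistry. A molecule reduced to
zero atoms by these rules is a degenerate input: an error from
`build_graph()`, a skip-with-warning inside `screen_library()`. An empty
product graph (no shared atom type) is not an error; it scores 0.

## The synthetic-molecule generator

`make_molecule()` / `make_library()` / `make_known_mcs_pair()` produce
chains, trees, rings and ring-plus-substituent topologies with SYBYL
types drawn from a configurable alphabet, unit bond lengths, Gaussian
coordinate jitter (default $\sigma = 0.05$ &Aring;, small distortion
around idealised geometry) and coordinates rounded to the MOL2 write
precision of 4 decimals so file round trips are exact. Generation is a
pure function of the spec seed and restores the session RNG state.

The planted-MCS pairs decorate a shared core (identical topology, types
*and coordinates*) with atoms whose types are absent from the partner
molecule (F/Cl on one side, Br/I on the other). Decoration atoms can
therefore never enter the product graph, which makes the planted truth
provable rather than probabilistic: at threshold 0 the maximum clique
size equals the core size by construction.

What the generator does *not* emulate: chemically valid valences,
realistic bond lengths and angles per element, aromatic ring planarity,
stereochemistry, and the type-frequency distribution of real compound
libraries (real drug-like molecules are mostly carbon, which makes
product graphs denser and cliques harder than the balanced alphabets used
here). Passing tests demonstrate algorithmic correctness — exactness,
invariances, determinism, format fidelity — not screening enrichment on
real actives, which requires benchmark databases outside this package's
scope.

## Problem sizes and numerical choices

The shipped test and acceptance runs use: 600 random graphs (up to 18
vertices, edge densities 0.3/0.5/0.7) plus 100 planted pairs for
solver/oracle equivalence; 50 molecules for identity screening; a
25-molecule library for invariance; 100 random rigid motions for
superposition recovery; 1000 generated molecules for format round trips.
These sizes exercise every code path while keeping a full run in the
tens of seconds; the solver itself has handled far larger product graphs
and scales with clique hardness, not library size.

Tolerances: orthonormality of rotations is enforced to 1e-9;
superposition recovery of exact rigid motions is asserted to 1e-9 &Aring;
(observed ~1e-15); identity-screen RMSD to 1e-6 &Aring;. Threshold
comparisons are plain floating-point `<=`; at threshold exactly equal to
a distance difference the edge is included. Coordinates are written with
4 decimals, so files quantise geometry at 1e-4 &Aring;.

## Known limitations

* Exact type-string matching means tautomer or protonation-state
  differences (e.g. `N.3` vs `N.4`) break matches; normalise the library
  typing upstream if that is not wanted.
* The MCS may be disconnected (see above).
* Exact maximum clique is NP-hard; adversarial near-symmetric molecules
  with a single dominant atom type can be slow, though typed vertices and
  the colouring bound keep drug-like inputs fast.
* Conformers are consumed, never generated: 3D screening is only as good
  as the conformer coverage of the input library.
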