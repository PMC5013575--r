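# cliquescreen

Ligand-based virtual screening for R: rank a small-molecule library by
similarity to a known active ligand, where similarity is the maximum
common substructure (MCS) between the two molecules, detected exactly as
a **maximum clique on a product graph**.

Ligand-based screening assumes that structurally similar molecules have
similar biochemical activity. Given one active reference ligand and a
library in Tripos MOL2 format, a screen reduces millions of candidates to
a ranked short list for visual inspection and purchase — including
*scaffold hops*, actives whose core framework differs from the
reference's. cliquescreen is written for computational chemists who want
that workflow scriptable end to end in R: MOL2 in, tidy tibbles and
aligned MOL2 files out.

## The method

For molecules $A$ (reference) and $B$ (target), build a product graph
whose vertices are atom pairs $(i, i')$ with identical SYBYL atom types,
and whose edges join pairs $(i,i'),(j,j')$ with $i \neq j$, $i' \neq j'$
and consistent internal relations:

- **2D screening** compares shortest-path lengths in covalent bonds:
  $|D^{topo}_A(i,j) - D^{topo}_B(i',j')| \le t$ bonds;
- **3D screening** compares interatomic distances:
  $|D^{geo}_A(i,j) - D^{geo}_B(i',j')| \le t$ &Aring;, with multiple
  conformers per compound grouped by molecule name.

Cliques of this graph are exactly the consistent atom-to-atom mappings,
so the maximum clique — found with an exact, deterministic
colouring-bounded branch-and-bound (compiled) — is the MCS. Hits are
ranked by the graph Tanimoto coefficient

$$T_c = \frac{c}{n_A + n_B - c}$$

over the kept (by default heavy) atom counts, where $c$ is the clique
size. For 3D hits the target is superposed onto the reference over the
matched atoms (Kabsch least squares) and the matched-atom RMSD is
reported. See `vignette("methods")` for the full model, parameter
guidance and limitations.

## Worked example

Benzene (6 aromatic carbons) against toluene (the same ring plus an sp3
methyl carbon), 2D, shortest-path difference 0:

```r
library(cliquescreen)

ref <- build_graph(benzene_molecule())
tgt <- build_graph(toluene_molecule())
score_pair(ref, tgt, screen_config(dimension = 2, threshold_2d = 0))
#> <match_result> c = 6 of (6, 7) atoms, Tanimoto 0.8571
```

The six ring carbons map one-to-one (the methyl `C.3` has no aromatic
partner), so $c = 6$ and $T_c = 6/(6+7-6) = 6/7 \approx 0.857$: the two
molecules share their entire ring but toluene carries one unmatched atom.

A library screen returns a ranked tibble (here a synthetic 10-molecule
library, screening its first member against all):

```r
lib <- make_library(fixture_spec(seed = 1, n_heavy = c(5, 9)), 10)
rep <- screen_library(lib[[1]], lib,
                      screen_config(dimension = 2, threshold_2d = 1,
                                    top_k = 5, workers = 1))
tidy(rep)
#> # A tibble: 5 × 8
#>    rank name     record_index tanimoto     c n_ref n_tgt  rmsd
#>   <int> <chr>           <int>    <dbl> <int> <int> <int> <dbl>
#> 1     1 SYN00001            0    1         7     7     7    NA
#> 2     2 SYN00010            9    0.556     5     7     7    NA
#> 3     3 SYN00008            7    0.364     4     7     8    NA
#> 4     4 SYN00009            8    0.273     3     7     7    NA
#> 5     5 SYN00006            5    0.25      3     7     8    NA
```

Rank 1 is the reference itself at $T_c = 1$ (its MCS with itself covers
all 7 heavy atoms); the rest score by how much of their structure maps
consistently onto it. `glance(rep)` gives the one-row run summary,
`autoplot(rep)` the rank-vs-score lollipop, `rep$hits$pairs` the matched
atom pairs per hit, and `save_run()`/`load_run()` round-trip a run
directory. From a shell:

```sh
Rscript inst/cli/cliquescreen.R -R ref.mol2 -T library.mol2 -d 2 --spd 1 \
    --top-k 100 --out-dir run1
```

writes `ranked_list.txt` (name, tab, Tanimoto to 4 decimals),
`<rank>_<name>.mol2` aligned structures whose comment sections list the
matched atom pairs, and a reloadable manifest.

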