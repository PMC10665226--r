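# tandemmap

Hierarchical sequence-conservation analysis for tandem repeat proteins,
built around the poly-FnIII super-repeats of titin's A-band.

Proteins like titin carry long tandems of ~100-residue domains organized
into super-repeats (D-zone: six `-AC-ABC` units; C-zone: eleven
`-AC-ABC-ABC` units, where A/B/C are FnIII sequence types and `-` an Ig
domain). Conservation in such a system is layered — residues conserved
across *all* domains, within one *type*, or only at one *position within
the super-repeat* — and the position-specific layer is where binding sites
for periodically docking partners (e.g. myosin-binding protein C) are
expected. `tandemmap` separates these layers and maps them onto structures.

## What it computes

1. **Pairwise-similarity vector maps.** Sequences are scored pairwise
   (BLOSUM62; Needleman–Wunsch with affine gaps 11/1, or "as-is" across MSA
   rows), normalized by self-scores, `cc_ij = raw_ij / sqrt(raw_ii raw_jj)`,
   and embedded as vectors `x_i` minimizing the off-diagonal Gram residual
   `sum_{i<j} (x_i . x_j - cc_ij)^2`. Dimensions are hierarchically ordered;
   the vector **angle** (D2/D3 plane) encodes which systematic features a
   sequence carries, the vector **length** how dominant they are
   ("prototypicality"). Angular k-medoids clustering recovers the sequence
   types.
2. **Sum-of-pairs conservation.** Per-column AL2CO-style SoP score
   (unweighted, pair probabilities without replacement, columns with >= 50%
   gaps zeroed).
3. **Differential consensus.** Columns are removed cumulatively in SoP
   order, each derivative alignment re-embedded, and the map perturbation
   measured as the RMSD after orthogonal superposition against the unedited
   map. With `delta(i) = RMSD(i) - RMSD(i-1)`, `w(i) = (i_max - i)/i_max`
   and `adjusted(i) = sum_{n<=i} w(n) delta(n)`, the consensus is the
   largest prefix whose adjusted increments beat a random-removal (sham)
   baseline — a data-driven conservation cutoff.
4. **Hierarchical tiers.** Global consensus columns are masked, type tiers
   rescored (SoP > 1), then position-specific conservation over C-zone
   repeats C2–C11 under three criteria (SoP >= 1, occupancy >= 90%,
   identity >= 70% with groups TIL / DEN / FY), plus linker classification
   (zero-length / `[N/Y]PF` / `DPI`).
5. **Structure utilities.** Kabsch Cα superposition, NCS-copy RMSD tables,
   conservation-to-B-factor PDB output, backbone dihedrals, and the
   extended-linker chain-length estimate.
6. **A synthetic generator** that plants all three conservation tiers and a
   V-shaped divergence gradient in study-scale families (118 domains x 95
   columns), with truth tables, so the whole pipeline is testable offline.

## Worked example

```r
library(tandemmap)

fam <- generate_family(synth_config(seed = 1))
fam$msa
#> msa: 118 sequences x 95 columns

map <- embed(build_similarity(fam$msa), d = 3)
map
#> vector_map: 118 sequences in 3 dimensions
#> eigenvalues: 17.559  2.964  2.331

cl <- angular_clusters(map)
table(cluster = cl$labels, type = fam$truth$domain_type[names(cl$labels)])
#>        type
#> cluster  A  B  C
#>       1 45  0  0
#>       2  0  0 45
#>       3  0 28  0
```

The eigenvalues show one dominant shared dimension and two finer ones (the
type structure); the angular clusters reproduce the planted types exactly.
The full pipeline, including the differential consensus and both further
tiers:

```r
run <- run_all(pipeline_config(synth = synth_config(seed = 1), seed = 42))
#> [tandemmap] inputs         118 sequences x 95 columns
#> [tandemmap] map            d = 3, k = 3 clusters
#> [tandemmap] diffmap        i_max = 39, cutoff = 3.455, 11 consensus cols
#> [tandemmap] type tier      A: 6 cols, B: 7 cols, C: 6 cols
#> [tandemmap] position tier  8 tokens, 62 conserved cols total

run$consensus
#> consensus_result: cutoff 3.455, 11 conserved columns (prefix 12)

head(run$report[, c("tandem_position", "column", "consensus", "sop", "identity")], 4)
#>   tandem_position column consensus      sop identity
#> 1              1'      4         Y 2.600000      0.7
#> 2              1'     15       D/N 1.488889      0.7
#> 3              1'     26       I/L 2.266667      0.8
#> 4              1'     68         N 2.688889      0.8
```

The removal of the 12 top-ranked columns (the planted global consensus)
perturbs the map faster than random removals, so the data-driven cutoff
lands just above the strongest non-global column; the manifest records
precision 1.0 / recall 0.92 against the planted truth for this seed. The
position tier reports per-token conserved residues with their consensus and
group identity. Finally, the linker arithmetic:

```r
unlist(linker_extension_estimate(n_res = 3, rise_per_res = 0.34, n_linkers = 10))
#> per_linker_nm      total_nm
#>          1.02         10.20
```

i.e. ~1 nm of extended chain per three-residue linker, ~10 nm summed over
the ten C-zone super-repeat copies.

A thin shell entry point is included for scripted runs:

```sh
Rscript inst/scripts/tandemmap.R run-all --out outdir --seed 1
```

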