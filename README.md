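# spatwin — 3D sliding-window analysis of sequence data on protein structures

Selection pressures often act on protein *structure*: an antibody binds a
conformational epitope, a surface patch whose residues are spatially
adjacent but can be far apart in the linear sequence. A sliding-window scan
along the gene dilutes any signal such a patch carries. **spatwin** slides
the window through space instead: every residue of a structure becomes the
center of a spherical window of radius *r* (15 Å by default — the typical
maximum dimension of an antibody–antigen interface), the sequence-aligned
data of all residues inside the window is pooled, and a scoring function
maps one number back to the central residue. Scores are exported as TSV,
JSON, and as a PDB file with the scores in the B-factor column, ready for
coloring in PyMOL or any structure viewer.

The default score is Tajima's *D*, computed from a population sample of
coding sequences mapped codon-wise onto the structure:

    D = (π − S/a₁) / √(e₁·S + e₂·S·(S−1)),   a₁ = Σ_{i<n} 1/i

where π is the mean number of pairwise differences and S the number of
segregating sites in the windowed sub-alignment. Positive *D* — an excess of
intermediate-frequency alleles — is the signature of balancing selection,
e.g. immune-driven diversity in malaria surface antigens. Also built in:
nucleotide diversity (π), Watterson's θ, segregating sites, per-column
Shannon entropy for protein alignments, and the mean of arbitrary
per-residue numeric tables; user-defined scoring functions plug in through
`scoring_function()`.

The machinery underneath: PDB/mmCIF parsing into a uniform residue model
(altloc resolution, first NMR model, author numbering throughout), exact
radius queries under three inter-residue metrics (min heavy atom, CA–CA,
centroid) backed by a grid index that is tested to agree with brute force,
chain-wise global alignment of the structure sequence to a reference
(BLOSUM62, affine gaps), six-frame codon mapping with reverse-sense
translation, per-window gap handling, and a deterministic synthetic-data
generator for structures and alignments with known statistical properties.

## Worked example

Generate a synthetic "antigen": a 60-residue helix, 24 sampled coding
sequences, and a balanced polymorphism planted on residues 28–32; then scan
Tajima's D over the structure with a 15 Å window:

```r
library(spatwin)

spec <- fixture_spec(n_residues = 60, n_sequences = 24,
                     mutation_model = "planted-balanced-cluster",
                     cluster_residues = 28:32, seed = 11)
st  <- make_structure(spec)$structure
fx  <- make_alignment(spec)

res <- run_window_analysis(st, fx$aln, fx$ref, "tajimas-d",
                           neighbor_config(radius = 15))
res
#> <window_result> tajimas-d, radius 15.0 A (min-atom)
#>   60 residues scored (60 defined, 0 null)
#>   window size: 11-21 residues

df <- as.data.frame(res)
head(df[order(-df$score), ], 5)
#>    chain resnum icode score window_size mapped_residues columns_used
#> 28     A     28        2.33          21              21           63
#> 29     A     29        2.33          21              21           63
#> 30     A     30        2.33          21              21           63
#> 31     A     31        2.33          21              21           63
#> 32     A     32        2.33          21              21           63

tajimas_d(fx$aln)   # the whole-gene value the spatial window unmasks
#> [1] 0.471

export_results(res, c("tsv", "json", "pdb"), prefix = "antigen_d")
```

The five top-scoring central residues are exactly the planted cluster, at
D ≈ 2.3 against a genome-wide-style background of 0.47: pooling spatially
linked codons concentrates a signal that the whole-gene statistic blurs.
`antigen_d.pdb` carries the scores in its B-factor column (null scores get
a configurable `missing_value`), so `spectrum b` in PyMOL paints the epitope
directly onto the structure.

The same pipeline runs from the shell via the `spatwin` script installed in
`exec/`:

```sh
spatwin fixtures --seed 11 --mutation-model planted-balanced-cluster --output-prefix toy
spatwin run --structure toy_structure.pdb --reference toy_reference.fasta \
            --data toy_alignment.fasta --radius 15 --output-prefix toy_d
```

Real inputs drop in the same way: `--structure` takes a PDB or mmCIF file,
`--data` a pre-aligned FASTA (nucleotide or protein) or a two-column
`position value` TSV, and `--reference` the reference protein FASTA the
alignment belongs to.

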