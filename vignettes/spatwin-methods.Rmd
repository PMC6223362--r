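---
title: "Methods: 3D sliding windows over protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D sliding windows over protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatwin)
```

## The model

Sliding-window analyses of genes usually group *sequence-adjacent* positions.
But many selective pressures act on protein *structure*: an antibody
recognizes a conformational (discontinuous) epitope — a surface patch whose
residues are spatially adjacent yet can be far apart in the linear sequence.
A linear window dilutes such a signal across the regions the patch borrows
its residues from.

spatwin therefore slides the window through space. For every residue $c$ of
a structure (the *central residue*), the window is the closed ball

$$W_r(c) = \{\, s : d(c, s) \le r \,\},$$

the set of residues whose distance to $c$ is at most the radius $r$. The
data attached to all residues in $W_r(c)$ — alignment columns of a
population sample, or arbitrary per-residue numbers — is pooled, a scoring
function maps the pool to one number (or an explicit null), and that number
is reported at $c$. Writing the scores into the B-factor column of a PDB
file turns any structure viewer into a results browser.

The default score is Tajima's $D$. With $n$ sequences, $S$ segregating
sites and mean pairwise difference $\pi$ (per alignment, *not* per site),

$$D = \frac{\pi - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}},
  \qquad a_1 = \sum_{i=1}^{n-1} \tfrac1i,$$

with the variance coefficients
$a_2 = \sum_{i<n} i^{-2}$,
$b_1 = \frac{n+1}{3(n-1)}$, $b_2 = \frac{2(n^2+n+3)}{9n(n-1)}$,
$c_1 = b_1 - 1/a_1$, $c_2 = b_2 - \frac{n+2}{a_1 n} + \frac{a_2}{a_1^2}$,
$e_1 = c_1/a_1$ and $e_2 = c_2/(a_1^2+a_2)$. Positive $D$ — an excess of
intermediate-frequency variants — is the classic signature of balancing
selection, e.g. immune-driven diversity in surface antigens of malaria
parasites; strongly negative $D$ suggests purifying selection or expansion.
Because spatial windows pool codons that linear windows cannot, a balanced
polymorphism spread over one epitope becomes visible as a patch of high $D$
on the structure.

### Where the statistics are defined

`tajimas_d()` returns `NA`, deliberately distinct from 0, whenever the
variance estimate degenerates: $S = 0$, $n < 3$, and also $n = 3$. The last
case is easy to miss: at $n = 3$, $b_1 = 2/3 = 1/a_1$ so $c_1 = 0$, and
$c_2 = 5/9 - 10/9 + 5/9 = 0$, so the estimated variance is identically zero
and $D$ is $0/0$. Downstream, a null score is exported as an empty TSV
field, a JSON `null`, and the user-chosen `missing_value` in PDB output —
never silently as 0, which is a meaningful value of $D$.

All diversity statistics operate on the per-alignment (total) scale that
Tajima's $D$ requires; per-site variants are obtained by dividing by the
column count. Mixing the two scales is the classic implementation bug in
this area, so the package never returns a per-site value from a function
whose name does not say so.

## Mapping sequence data onto the structure

Three coordinate systems must be reconciled: structure residues (author
chain/number/insertion code), reference protein positions (1-based), and
alignment columns (1-based). Two partial maps connect them:

1. **Structure to reference.** Each selected chain's polymer sequence (one
   letter per resolved residue, hetero groups and waters excluded, common
   modified residues such as MSE collapsed to their parent letter) is
   globally aligned to the reference with affine gaps (BLOSUM62, gap open
   11, gap extend 1 — the familiar protein-alignment defaults). Aligned
   *mismatches* still map: the reference drives the data while the structure
   drives space, and a polymorphic or engineered residue should not lose its
   window. Positions aligned to gaps are simply absent. An identity below a
   configurable floor (30% by default) aborts with a diagnostic, since it
   almost always means mismatched inputs. Chains are aligned independently;
   in a homo-oligomer every protomer therefore maps to the same reference
   positions, each protomer is scored at its own residues, and a window
   spanning protomers includes each residue's columns once per residue —
   the symmetric choice, recorded in the output metadata.

2. **Reference to columns.** For nucleotide alignments the coding frame is
   established from one designated *representative row* (the first row by
   default): the row is ungapped, translated in all six frame/strand
   combinations — reverse-sense translation handles genes deposited on the
   opposite strand — and each translation is aligned to the reference; the
   best score wins, ties resolving to the forward strand and lowest frame.
   Rows of one multiple sequence alignment share a frame by construction, so
   per-row frame detection would only invite inconsistency. Each mapped
   reference position then owns the three alignment columns carrying its
   codon in the representative row (gap columns skipped when counting
   bases; triplets stored in ascending column order with the strand
   recorded). Protein alignments map one column per position the same way.
   Inputs are assumed to be coding-sequence alignments; intron-containing
   genomic sequences are out of scope.

The composition of the two maps is defined exactly where both are — a
partial map, not an error. Residues without data still receive scores when
their window contains mapped residues (an unresolved-loop flank still sits
inside real windows); `min_data` sets how many mapped residues a window
needs before the scoring function is consulted.

### Gap policy

Within each window's sub-alignment, the default **complete deletion**
removes every column containing a gap or an ambiguous state (`N` for
nucleotide data, which cannot be scored as a segregating site, and `X` for
protein data). Deletion is per window, not global, to maximize usable
columns — the price is that windows have different effective lengths, so
the post-filter column count is exported alongside every score. A
**pairwise** mode is available, in which pairs are compared over the columns
where both are unambiguous; the population-genetics functions otherwise
treat any residual gap as a contract violation and say so. Equivalence of
either policy with other tools' gap handling is not claimed.

## Spatial windows

Three inter-residue distance metrics are provided, because "within a
radius" is underdetermined at atomic resolution:

* `min-atom` (default): minimum distance over heavy-atom pairs. The most
  inclusive reading, appropriate for surface epitopes.
* `c-alpha`: CA–CA distance; errors, naming the residue, where CA is
  missing.
* `centroid`: distance between unweighted atom centroids.

Distances compare with $\le$ (a closed ball), so boundary ties are included
deterministically. Hydrogens are excluded by default — most crystal
structures lack them, and including them would make neighborhoods differ
between X-ray and NMR inputs. Hetero residues are excluded by default since
they carry no alignment data. Windows may span chains (`chain_scope =
"all-chains"`), as conformational epitopes on oligomers do; a same-chain
scope is a flag away.

The default radius is **15 Å**, the typical maximum dimension of an
antibody–antigen interface — the natural window for questions about humoral
immune selection. The radius, metric and scope are recorded in every
result.

Neighbor queries run against a uniform-grid cell index (cell edge equal to
the build radius) holding each residue's metric-relevant points; queries
examine only neighboring cells, or fall back to a full scan when the query
radius spans the grid. The test suite requires exact agreement between
indexed queries and an index-free brute-force scan on every fixture, under
all three metrics, plus symmetry ($s \in W(c) \iff c \in W(s)$) and nesting
in the radius.

## Structure input and output

PDB files are parsed with bio3d; mmCIF files are read from the `atom_site`
category by a reader in this package. Only the first model of a multi-model
file is used. Alternate locations are resolved to a single conformer per
atom name — highest occupancy wins, ties keep the first record — before any
distance is computed. Author numbering plus insertion code addresses every
residue, never serial position, so output cross-references the deposited
structure.

B-factor output rewrites *only* columns 61–66 of the stored serialization
(the original text for PDB input, a canonical PDB v3.3 serialization for
mmCIF input): every other byte survives verbatim, which the tests assert by
field-wise diff. Scores are formatted to the fixed `%6.2f` convention;
values outside $(-100, 1000)$ cannot be represented there and raise an
error suggesting a rescale rather than writing a corrupt file.

## The synthetic-data generator

`fixture_spec()` + `make_structure()` / `make_alignment()` generate matched
toy inputs whose statistical structure is known by construction, so every
claim in the test suite is checkable without downloads.

* **Geometry.** An ideal helix (1.5 Å rise, 100° twist, 2.3 Å CA radius,
  five heavy atoms per residue), a 3.8 Å random coil, or two compact blobs
  ≥ 40 Å apart (for window-isolation tests). These are spatial substrates,
  not chemistry: side-chain atoms are placeholders at fixed offsets.
* **Sequences.** A random stop-free coding sequence of $3 \times$
  `n_residues` bases is the ancestor; its translation is both the reference
  and the structure's sequence. All mutations sit at codon third positions,
  keeping the frame and the protein-codon correspondence trivial to verify
  by eye, and never introduce stops.
* **Neutral model.** Each variable site is a new mutation (infinite sites)
  whose derived-allele count is drawn from the neutral site-frequency
  spectrum $P(i) \propto 1/i$, $i = 1..n-1$. Under this spectrum
  $E[\pi] = E[\theta_W]$ per site, so whole-alignment Tajima's $D$ is
  centred near zero — the calibration the test suite checks across 500
  replicates (empirical mean within $\pm 0.15$ of 0). Singletons remain the
  modal draw. The expected number of background sites is
  `snp_rate` × `n_residues` (Poisson), 0.25 per residue by default — about
  15 SNPs on a 60-residue fragment, a realistic density for a polymorphic
  antigen domain.
* **Planted balanced cluster.** On top of the neutral background, the
  codons of `cluster_residues` receive biallelic sites split across two
  fixed, equal haplotype groups — allele frequency ~50%, the configuration
  that maximizes $\pi$ relative to $\theta_W$ and hence $D$. Two equal
  haplotype groups, rather than a coalescent simulation, make $\pi$ and $S$
  per site exactly computable, which the tests exploit.

What the generator does **not** emulate: linkage and recombination
structure (sites are independent given the haplotype split), realistic
coalescent genealogies, indels and alignment error, side-chain packing,
crystallographic artifacts (altlocs and missing loops are exercised by
hand-written parser fixtures instead). Passing tests therefore demonstrate
correctness of the machinery and sensitivity under idealized conditions,
not performance on real data, where linked selection and demography can
move $D$ for reasons windows cannot distinguish.

## Problem sizes and default study conditions

The discovery experiment used in the tests and in `scripts/acceptance.R`
runs 20 replicates of a 60-residue helix antigen sampled in 24 coding
sequences with a 5-residue planted cluster, scored with Tajima's $D$ at the
15 Å default radius; the package's defaults (`fixture_spec()`, radius 15)
are exactly these conditions. In-cluster mean $D$ must exceed the
out-of-cluster mean in at least 19 of 20 replicates. The statistic oracle
corpus uses ≥ 100 alignments with $n \in [2,12]$ and $L \in [6,120]$; the
spatial oracle corpus uses 50 structures of 30–300 residues. These sizes
were chosen to make every oracle comparison exact and quick at a desk,
while still covering the regimes (tiny $n$, degenerate windows, multi-chain
geometry) where implementations typically disagree.

## Known limitations

* Mapping requires the reference to align to each scored chain; distantly
  homologous structures fail the identity floor by design.
* Intron-aware (spliced) mapping of genomic sequences is out of scope.
* No significance machinery for $D$ (no beta approximation, no
  permutations): scores are descriptive surfaces, not tests.
* mmCIF is input-only; annotated output is always PDB v3.3.
* Scores outside $(-100, 1000)$ cannot be written to the B-factor column.
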