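# s1census

Bacterial 30S ribosomal protein S1 is built from tandem copies of the
RNA-binding S1 domain (an OB-fold repeat of ~70 residues), and the number of
copies per chain varies in a narrow range — one to six — in a way that tracks
the bacterial phylum: six-domain proteins dominate Proteobacteria, four-domain
proteins Firmicutes and Actinobacteria, three-domain proteins Cyanobacteria,
and so on. `s1census` is an R toolkit for carrying out that kind of
domain-architecture census and for asking which of the repeats is the most
conserved one. It is aimed at computational biologists who have (or can
export) a table of annotated protein records — sequence, protein/gene name,
taxonomic lineage, and S1-domain boundaries — and want a tested, reproducible
pipeline from raw records to conservation statistics.

The package provides:

* **Record selection** — the five-rule funnel that defines the analysis set
  (protein-name keywords for S1; the *rpsA* gene or a numbered analog
  `rpsA_N`; removal of provisional "candidate"/"Candidatus" taxa; removal of
  records with zero annotated S1 domains; removal of records with extra
  non-S1 domains), with a per-rule attrition report.
* **Global alignment** — a from-first-principles Needleman–Wunsch aligner
  (Rcpp) with linear or affine gaps and deterministic traceback, plus percent
  identity with an explicitly named denominator.
* **Census** — phylum × domain-count occupancy tables with length statistics.
* **Conservation statistics** — inter-domain identity matrices per
  domain-count group, within-position identities, and reference scans against
  a one-domain sequence (e.g. the S1 domain of PNPase), combined by three
  independent "most conserved domain" locators.
* **A seeded simulator** of multi-domain families with known ground truth, so
  every stage is testable without database downloads.
* **A command line** (`simulate`, `filter`, `census`, `conserve`, `refscan`,
  `align`) via `s1_main()` / `inst/cli/s1census`.

## The statistics in brief

Global alignment maximizes the summed column scores over all end-to-end
alignments of two residue strings *a*, *b*:

```
M(i,j)  = s(a_i, b_j) + max{ M, Ix, Iy }(i-1, j-1)
Ix(i,j) = max{ M(i-1,j) + g_open,  Ix(i-1,j) + g_ext, Iy(i-1,j) + g_open }
Iy(i,j) = max{ M(i,j-1) + g_open,  Ix(i,j-1) + g_open, Iy(i,j-1) + g_ext }
```

with the single-matrix linear-gap special case when `g_open == g_ext`. The
default scheme is match = 1, mismatch = 0, free gaps — a globally optimal
match-count alignment. Percent identity is `100 × (identical non-gap, non-X
columns) / (alignment columns)` by default; `X` never counts as a match.

For the group of proteins with *k* domains, the inter-domain identity matrix
has off-diagonal cell *(i, j)* equal to the mean identity of domain *i* of one
record against domain *j* of another over all ordered record pairs (plus each
record's own internal *i*–*j* pair), and diagonal cell *(i, i)* equal to the
mean pairwise identity among domain-*i* instances of distinct records. The
most conserved repeat is located three independent ways — diagonal argmax,
off-diagonal argmax pair, and the modal best-hit position of a reference scan
— and the three locators are checked for agreement.

The simulator evolves every domain from one ancestral domain by independent
site substitution (probability *d* per site, uniform over the 19 other
residues), so the expected identity between two domains at divergences
*d₁*, *d₂* has the closed form `100 × [(1−d₁)(1−d₂) + d₁d₂/19]`, used as an
oracle in the tests.

## Worked example

Simulate a 300-record family under the default composition (the observed
phylum-linked domain-count shares) with one planted violation of each
selection rule, filter it, and locate the conserved domain:

```r
library(s1census)

cfg <- simulation_config(n_records = 300, seed = 42,
  contamination_counts = c(keyword = 1, gene = 1, candidate = 1,
                           zero_domain = 1, extra_domain = 1))
fam <- simulate_dataset(cfg)

res <- build_dataset(fam$dataset)   # the five-rule funnel
res$report
#>             rule n_in n_out n_dropped
#>          keyword  300   299         1
#>             gene  299   298         1
#>        candidate  298   297         1
#>  domain_presence  297   296         1
#>     extra_domain  296   295         1

count_shares(build_census(res$dataset))
#>    1    2    3    4    5    6
#>  0.3  0.7  1.4 31.5  1.4 64.7

length_summary(res$dataset, 6)      # six 70-residue domains + five linkers
#> mean  min  max
#>  470  470  470

mat <- interdomain_identity_matrix(res$dataset, 6)
mat
#> <identity_matrix> group k=6, 191 records
#>      [,1] [,2] [,3] [,4] [,5] [,6]
#> [1,] 38.9 41.7 51.5 49.0 43.8 39.3
#> [2,] 41.7 44.7 56.0 53.2 47.2 42.0
#> [3,] 51.5 56.0 71.5 67.7 59.6 52.2
#> [4,] 49.0 53.2 67.7 64.0 56.5 49.6
#> [5,] 43.8 47.2 59.6 56.5 50.1 44.3
#> [6,] 39.3 42.0 52.2 49.6 44.3 39.7

scan <- reference_scan(res$dataset, fam$truth$ancestor, "ancestor")
conserved_domain_summary(mat, scan)
#> <conservation_summary> group k=6
#>   within-position (diagonal) max at domain 3
#>   between-position max at pair {3, 4}
#>   reference-scan mode(s): ancestor=3
#>   locators agree: TRUE
```

Each rule dropped exactly its planted contaminant; the recovered domain-count
shares match the sampling profile (six-domain proteins ~62%, four-domain
~33%); and all three locators recover position 3, the argmin of the default
divergence vector `(0.40, 0.35, 0.15, 0.20, 0.30, 0.40)` — the planted
central-conservation signal, visible in the matrix as the 71.5% diagonal cell
at (3,3) and the 67.7% off-diagonal maximum at (3,4).

The same pipeline from a shell:

```sh
Rscript inst/cli/s1census simulate --out-dir sim --seed 42 --n 300
Rscript inst/cli/s1census filter   --fasta sim/family.fasta --meta sim/family.tsv --out-dir filt
Rscript inst/cli/s1census census   --fasta filt/filtered.fasta --meta filt/filtered.tsv --out-dir cen
Rscript inst/cli/s1census conserve --fasta filt/filtered.fasta --meta filt/filtered.tsv --group 6 --out-dir con
```

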