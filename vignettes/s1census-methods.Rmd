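---
title: "Methods: the S1 domain census and its conservation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the S1 domain census and its conservation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s1census)
```

## The problem

Bacterial 30S ribosomal protein S1 carries one to six tandem copies of the
RNA-binding S1 domain, an OB-fold repeat of roughly 70 residues, and the copy
number is strongly linked to the phylum: six-domain chains dominate
Proteobacteria, four-domain chains Firmicutes and Actinobacteria, three-domain
chains Cyanobacteria, five-domain chains Deinococcus-Thermus, while one- and
two-domain chains are rare (Tenericutes and scattered lineages). Two questions
drive the analysis this package implements: *how are domain counts distributed
across phyla?* and *which of the repeats is the most conserved one?* — the
latter asked both within the family (all repeats against all repeats) and
against external one-domain references such as the C-terminal S1 domain of
polynucleotide phosphorylase (PNPase).

This vignette documents the models, parameters, and numerical choices; every
empirical claim it makes is computed by the package's test suite or by
`scripts/acceptance.R`.

## Record model and selection rules

A record couples an amino-acid sequence (20-letter alphabet, `X` tolerated
but flagged) with a protein name, gene name, semicolon-separated lineage,
phylum, an ordered list of 1-based inclusive domain boundary pairs (the
UniProt convention; all internal slicing converts in one place,
`extract_domains()`), and a flag for annotated non-S1 domains. Boundaries
must be sorted, non-overlapping, and within the sequence.

`build_dataset()` applies five subset rules in a fixed order, each a pure
filter, and reports per-rule attrition:

1. **keyword** — the protein name must contain (case-insensitive substring)
   one of eight S1 protein-name keywords (`s1_keywords()`). Substring
   matching is deliberate: the keyword list is lowercase while database
   protein names are mixed case and often decorated.
2. **gene** — the gene name must match `rpsA` or a numbered analog
   (`rpsA_1`, `rpsA_2`, ...) as a full token, case-insensitively. Full-token
   matching excludes accidental substring hits such as `rpsAB`.
3. **candidate** — any lineage element or the phylum containing the stem
   `candidat` drops the record: provisional taxa ("candidate division ...",
   "*Candidatus* ...") cannot be assigned a phylum under bacterial
   nomenclature. The stem (rather than the literal word "candidate") is a
   deliberate widening so that *Candidatus* names are caught; `stem = FALSE`
   restores the literal behaviour.
4. **domain presence** — records with zero annotated S1 domains carry no
   boundary information and are removed.
5. **extra domains** — records with annotated non-S1 domains are removed, so
   the census counts pure S1 architectures.

A six-character-accession rule (a proxy for fully annotated database
records) exists behind `strict_accession = TRUE` but is off by default — it
is meaningless for synthetic accessions. Because every rule is a subset
operation, the funnel is idempotent and the report's chain invariant
(`n_in − n_dropped = n_out`, each rule feeding the next) always reconciles.

## Alignment and percent identity

The aligner is a from-first-principles global (Needleman–Wunsch) dynamic
program, written in C++ for speed. Gap runs cost `gap_open` for the first
column and `gap_extend` for each further column, both ≤ 0; when the two are
equal the model is linear and a single-matrix recurrence is used, otherwise
the three-state affine recurrence (M/Ix/Iy). The default scoring scheme is

* match = 1, mismatch = 0, gaps free —

i.e. the score is the maximal number of identical aligned residues (with
free gaps this equals the longest-common-subsequence length, which the tests
exploit as an independent cross-check). These are the "standard parameters"
of common pairwise-alignment routines for this kind of survey; since the
exact scoring behind published identity figures is rarely stated, the scheme
is configurable, and a BLOSUM62 table with affine penalties (−10/−0.5) is
available via `scoring_scheme_blosum62()` for sensitivity analysis.

**Percent identity** is `100 × matches / denominator`, where a match is a
column with the same non-gap, non-`X` residue in both rows. The default
denominator is the full alignment length (gap columns included) — the most
conservative choice and monotone under added gaps; `shorter` (the shorter
input length) and `aligned_columns` (residue–residue columns only) are
selectable, and every output header names the denominator used. `X` never
counts as a match, not even against `X`.

Two determinism choices matter:

* **Traceback tie-breaking** prefers the diagonal move, then a gap in the
  second row, then a gap in the first, making output byte-deterministic.
* **Canonical orientation.** Among equal-score alignments the column counts
  can differ, and a fixed tie-break order is not invariant under swapping
  the inputs — so naively `identity(a, b)` could differ from
  `identity(b, a)` by a fraction of a point. Each pair is therefore aligned
  with the lexicographically smaller sequence first (rows swapped back
  afterwards), which makes percent identity an exact function of the
  unordered pair; symmetry of the identity matrix is then structural, not
  approximate.

Empty inputs are legal (an empty-vs-nonempty alignment is all gaps, identity
0 by convention; empty-vs-empty scores 0).

## Census

`build_census()` groups records by domain count (the number of boundary
pairs; values above six are legal but flagged, since the family's observed
range is 1–6) and tabulates per-(phylum, count) occupancy with mean/min/max
sequence length. Phylum is taken from the explicit metadata column, not
re-parsed from the lineage, matching how taxonomy assignments are curated
upstream. Marginals must reconcile exactly; shares are reported to one
decimal place. Figures are deliberately out of scope: the census is the
computation, plotting is presentation.

## Conservation statistics

For the group with `k` domains (at least two records required, otherwise an
explicit insufficient-data error):

* **Off-diagonal cell (i, j)** of the identity matrix averages
  `identity(domain_i of a, domain_j of b)` over all ordered record pairs
  `a ≠ b` *plus* each record's internal `i`–`j` pair. Including the
  within-record pair is a deliberate reading of "identity between domains"
  of one architecture; `include_within_record = FALSE` gives
  cross-record-only averages.
* **Diagonal cell (i, i)** averages identity over all unordered pairs of
  domain-`i` instances from distinct records (`within_position_identity()`)
  — the repeat-wise conservation profile.
* **Reference scan**: per record, the best-identity domain position against
  a one-domain reference (ties to the lowest index); per group, the modal
  position, its representative count, and their mean identity.

`conserved_domain_summary()` reports the three locators side by side —
diagonal argmax, off-diagonal argmax pair, reference-scan mode — and flags
agreement and degeneracy (all cells equal, as with cloned records). All
argmax ties break toward the lower domain index, keeping output
deterministic.

Pair averages are unweighted (every record pair counts once, not every
protein). Groups larger than `max_records` (default 500) are reduced to a
seeded random subsample of records before the quadratic sweep — subsampling
records rather than individual pairs keeps the all-pairs structure within
the subsample and costs one seed, which is recorded in the result. The
published within-position figures this design echoes were computed from a
multiple alignment; this package uses mean pairwise global-alignment
identity instead, a documented substitution that avoids an external MSA
program and keeps the statistic self-contained.

## The simulator and what it does (not) emulate

The generator is first-class, tested code, and its defaults are the study
conditions:

* One **ancestral domain** of 70 residues (the canonical S1 repeat length),
  i.i.d. uniform over the 20 standard amino acids.
* Each record's **phylum and domain count** drawn from a profile whose
  default mirrors the observed family composition: shares 0.8 / 0.6 / 1.9 /
  33 / 1.1 / 62 % for one- to six-domain records, linked to Tenericutes,
  Actinobacteria, Cyanobacteria, Firmicutes+Actinobacteria (the 33% split
  evenly), Deinococcus-Thermus, and Proteobacteria respectively.
* Every domain evolved from the ancestor by **independent site
  substitution**: with probability `d(position)` a site is replaced by a
  uniformly chosen one of the other 19 residues, so the expected identity
  between two domains at divergences `d₁`, `d₂` is exactly
  `100[(1−d₁)(1−d₂) + d₁d₂/19]`. The default divergence vector
  `(0.40, 0.35, 0.15, 0.20, 0.30, 0.40)` plants position 3 as the most
  conserved repeat — the recoverable central-conservation signal.
* **Linkers** of 10 random residues join consecutive domains; boundaries
  never include linker positions, so extraction returns the generator's
  domain strings verbatim.
* **Contaminants** can be planted by rate or by exact count, each violating
  exactly one selection rule while passing all earlier ones, so the funnel's
  per-rule attrition is predictable.

Everything is reproducible under one integer seed (byte-identical FASTA/TSV
outputs), and the caller's RNG state is preserved.

The substitution-only model is chosen so expected identities have closed
forms; an optional indel mode (geometric lengths) exists for stress-testing
the aligner but is excluded from the quantitative oracles. The simulator
does *not* emulate tree-structured phylogeny, rate heterogeneity beyond the
per-position vector, compositional bias, or domain gain/loss — so passing
tests demonstrate that the statistics recover a planted signal under an
idealized divergence process, not that real families satisfy the model's
assumptions.

## Problem sizes and numerical choices

The validation workloads are sized for a single CPU: the exhaustive
alignment oracle uses 200 pairs of length ≤ 6 over a four-letter alphabet
plus 20 protein pairs of length ≤ 10 (enumeration is exponential; a memoized
variant covers the longer pairs); the closed-form check uses 200 replicate
pairs per divergence cell over `{0.1, 0.2, 0.3, 0.4}²` with a ±3-point
tolerance (the worst cell, (0.4, 0.4), sits ~2.7 points above the closed
form because free gaps let the optimal alignment harvest a few extra matches
at high divergence — the tolerance is chosen to cover exactly this regime);
planted-signal recovery uses 100 seeded runs of 50 six-domain records with a
≥95% recovery requirement per locator; the census recovery uses one seeded
2000-record simulation checked against 99% binomial confidence intervals.
With expected counts of 16 vs 12 for the two rarest classes, the strict
one->two ordering at n = 2000 is near the resolution limit of a single run —
a caveat worth remembering when reading that check.

Degenerate inputs are handled explicitly: empty datasets flow through
filters and I/O unchanged; groups with fewer than two records raise errors
rather than returning NaN; zero-length alignments have identity 0; cloned
datasets yield exactly-100 matrices and a degeneracy flag rather than a
spurious "most conserved" call.

## Known limitations

* Real annotation pipelines disagree about domain boundaries; the package
  stores one boundary set per record and leaves reconciliation upstream.
* Percent-identity conventions differ across published tools; all outputs
  name the denominator, but cross-study numeric comparisons should expect
  convention-sized differences.
* The reference scan assumes domain-vs-domain comparison against a
  one-domain reference sequence, and the census trusts the supplied phylum
  column.
* `fetch_uniprot_sequence()` requires network access and is intentionally
  kept out of every computational path; it exists for pinned-accession
  sanity checks only.
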