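---
title: "Methods: region-set colocalization, harmonic ranking, and the synthetic benchmark"
author: "snpcoloc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-set colocalization, harmonic ranking, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcoloc)
```

## The problem

Genome-wide association studies localize disease risk to thousands of
single-nucleotide variants, most of them non-coding. A recurring question in
regulatory genomics is whether such variants cluster inside particular
classes of regulatory DNA — enhancers and super-enhancers active in specific
cell types, regions transcribed into short-lived (transient) RNAs, or the
DNA binding regions (DBRs) of molecular transducers that couple non-genetic
risk factors to the genome (for example the vitamin D receptor VDR, the
B-cell mutator AID, and the Epstein–Barr virus nuclear antigens EBNA2 and
EBNA3C in the context of multiple sclerosis). `snpcoloc` implements the full
analysis chain for this question: region-set enrichment of variant positions
against region databases, a composite ranking score, multi-transducer
hotspot intersection, joining hotspots to precomputed Activity-By-Contact
(ABC) enhancer–gene predictions, and hypergeometric gene-set enrichment of
the resulting gene list.

## Enrichment model

Every enrichment question is reduced to a 2×2 contingency table over a
*universe* of background regions (all GWAS signals, or all transcription
factor binding sites — whatever population the region of interest was drawn
from):

|                | overlaps DB set | does not |
|----------------|-----------------|----------|
| ROI regions    | a ("support")   | b        |
| other universe | c               | d        |

with `a + b = |ROI|` and `a + b + c + d = |Universe|`. Overlap means at
least one shared base under 0-based half-open coordinates; abutting
intervals do not overlap, and no minimum-overlap fraction is applied.
Support counts ROI regions, never database regions or base pairs. The
p-value is the one-sided (enrichment) Fisher exact test, i.e. the exact
hypergeometric upper tail `P[X >= a]`, computed by direct summation of
point masses rather than a complemented CDF so the closed-form cases are
exact to machine precision. This one-sided convention matters: a two-sided
test would change every reported p-value, and depletion is deliberately not
scored. Benjamini–Hochberg q-values are computed across the sets of one
collection per run — the family is the analysis you would print as one
table; pooling families across runs is left to the caller.

Two deliberate conventions depart from naive formulas:

* **Extended variant windows are never merged.** Each variant, extended by
  ±50/100/200 kb, is tested independently; two nearby variants whose
  windows overlap still contribute 2 to the support. Merging would silently
  redefine support, and support counts can legitimately exceed the number
  of distinct loci at wide extensions.
* **Odds-ratio sentinels.** `OR = (a·d)/(b·c)` with no continuity
  correction. When every ROI region overlaps (`b = 0`, `a > 0`) the
  enrichment is saturated and the OR is `+Inf` regardless of `d`; when
  nothing overlaps anywhere it is undefined (`NaN`). An infinite OR
  contributes a zero reciprocal to the harmonic score (limit behaviour).

## The harmonic score

Ranking matches by p-value alone favours huge databases; by odds ratio
alone favours tiny ones. The three evidence channels are combined as a
scaled weighted harmonic mean:

$$ HS = k_p \cdot \frac{\sum_i w_i}{\frac{w_1}{-\log_{10} p} + \frac{w_2}{\mathrm{Supp}} + \frac{w_3}{\mathrm{OR}}} $$

with spacing parameter $k_p = 10$ and equal unit weights by default, so
$HS(x, x, x) = 10x$. The harmonic mean is dominated by the weakest
contributor: a match only ranks high when significance, support and effect
size all agree. Any zero contributor (including $p = 1$, whose
$-\log_{10} p$ is 0) gives $HS = 0$ rather than an error, keeping the
ranking total. The log is base 10 — recomputing published scores from
rounded printed triples reproduces them within ±0.05, the residual being
input rounding.

## ROI and universe construction

`build_roi()` reproduces the ingest semantics of a GWAS-catalog-style
table: trait filtering (exact code match with an optional substring
fallback), expansion of multi-mapped records to one region per position,
rejection of records without intelligible coordinates, and positional
deduplication — uniqueness is by `(chromosome, position)`, not rsID, since
the object of study is the set of unique single-nucleotide regions. The QC
report (kept / dropped-malformed / dropped-duplicate and the drop rate) is
always computed and logged, because a percent-level silent drop is exactly
the kind of thing a reader should be able to see. `build_universe()` applies
the same rules without the trait filter, which guarantees ROI ⊆ Universe —
a precondition `build_contingency()` enforces rather than assumes.

## Hotspots and ABC mapping

`transducer_membership()` flags each unique variant position for overlap
with each transducer's DBR set after window extension (default ±50 kb; a
vector of windows pools membership as a union across extensions).
`venn_counts()` reports exclusive Venn cells — a variant counts in exactly
the cell of the transducers it binds — so cells sum to the number of bound
variants, and `select_hotspots()` keeps variants bound by at least
`min_k` transducers (default 2). `map_hotspots_to_genes()` joins hotspots
to precomputed ABC enhancer–gene links (direct overlap by default; the join
window is configurable because different studies extend differently),
deduplicating genes per hotspot at the maximum score while retaining the
cell type of that best link; ties break lexicographically (gene symbol for
the top-gene call, cell-type label within a gene) so output is
deterministic. Computing ABC scores themselves is out of scope — the table
is consumed, not produced.

## Gene-set enrichment

`hypergeom_enrich()` is the accumulative (upper-tail) hypergeometric test
over a configurable integer background (default 20,000, whole-genome
semantics — a background gene *list* is deliberately not required, matching
how such web services define their default universe). It is exactly
`fisher_greater()` on the equivalent 2×2 table, and the test suite asserts
that cross-module identity. Gene symbols are uppercased on ingest.

## What the synthetic generator emulates — and what it does not

The generators in `sim_config()` / `simulate_*()` produce data with the
*statistical* structure the pipeline assumes, at sizes a laptop handles:

* genome of 5 × 10 Mb chromosomes; 20,000 uniform universe positions; an
  ROI of 600 of them (echoing the ~600 unique trait-associated variants of
  the motivating analysis);
* region sets of 2,000 regions with log-normal lengths (median 1 kb);
* a GWAS-like table with a planted 1.5% malformed-row rate and 0.5%
  duplicate rate, so ingest QC is exercised and its report can be checked
  against truth;
* transcript lists with exponential half-lives split at 60 minutes, the
  short fraction set to 0.5;
* an ABC table with Poisson(2) links per enhancer, Beta(1.5, 30) scores and
  a small cell-type label set;
* DBR panels with independent per-transducer binding probabilities
  (0.40/0.20/0.30/0.10 by default), giving membership counts a known
  Poisson-binomial expectation.

The planted enrichment is parameterized by the quantity the pipeline
estimates: the target odds ratio ρ. Background regions give every universe
point a hit probability `p0 = 1 − Π(1 − len_i/G)`; the planted set
additionally covers a Bernoulli(π) selection of ROI points with
`π = (p1 − p0)/(1 − p0)` where `odds(p1) = ρ · odds(p0)`. This additive
coverage scheme is feasible for ρ ≥ 1 (depletion would require removing
background coverage and is rejected with an error). At ρ = 1 the planted
set is exactly null.

What the generator does **not** emulate: linkage disequilibrium between
variants (real GWAS hits come in LD blocks; treating variants as
independent makes the synthetic test easier than reality), chromatin-domain
spatial clustering of regulatory regions, chromosome-specific density, or
any biological relationship between the gene sets and the ABC links. A
pipeline that passes the synthetic benchmark is arithmetically and
statistically correct; it is not thereby validated against the confounders
of real epigenomic data.

All generators are pure functions of `(config, seed)`: each uses a single
explicitly seeded stream (via seed offsets per generator so stages are
independently reproducible), and the CLI chain writes byte-identical
artifacts under a fixed seed.

## Numerical and design choices

* Fisher tail by point-mass summation; `a = 0` short-circuits to `p = 1`.
* BH q-values via the standard step-up; inputs validated to `[0, 1]`.
* Colocalization ties (equal HS) break by smaller p, larger support, then
  label, so ordering is total and stable.
* The universe "disjoining" option some enrichment tools apply is not
  used: universes are taken as provided, raw and unmerged.
* Calibration experiments in the test suite run the planted set alone
  (a one-set collection) for the type-I error check — the planted set's
  marginal p-value does not depend on how many null sets accompany it —
  with 500 seeds at the default sizes; detection/recovery experiments use
  the full 20-set collection over 100 seeds. The determinism check runs a
  reduced configuration (3,000 universe points) end to end, since
  byte-identity does not depend on size.

## Known limitations

* Enrichment treats ROI entries as exchangeable; LD-aware counting is not
  modelled.
* `build_contingency()` derives `c` by subtracting ROI hits from universe
  hits, which assumes each ROI point corresponds to one universe region;
  when the inputs disagree, `c` is clamped at 0 with a warning instead of
  failing.
* The HTML report is a static table export; interactive filtering belongs
  to a presentation layer outside this package.
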