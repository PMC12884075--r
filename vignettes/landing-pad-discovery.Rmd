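---
title: "Discovering native attB landing pads: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering native attB landing pads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attbscout)
```

## The problem

Site-specific integrases recombine a phage- or island-borne *attP* site
with a chromosomal *attB* site, integrating the mobile element and leaving
hybrid *attL*/*attR* sites at its ends.  Because most engineering hosts
lack the *attB* of any well-characterised integrase, integrase-mediated
cargo delivery usually requires first installing a synthetic landing pad —
an extra transformation step that is impractical in many non-model
prokaryotes.  The alternative implemented here is bioprospecting: genomic
islands have been mapped across hundreds of thousands of prokaryotic
genomes, and each mapped island supplies an (*attB*, integrase) pair that
is known to function in at least one relative of the target.  If an
unoccupied copy of such an *attB* exists in the target genome, the cognate
integrase can use it directly as a native landing pad.

`attbscout` takes a target genome plus a reference collection of
island-derived *attB*/integrase pairs and reports ranked, unoccupied,
high-quality candidate sites.

## Reference database construction

The reference inputs are a genomic-island (GI) table (coordinates, declared
island length, a support score from the upstream island predictor, the
*attB* sequence with its identity-block coordinates, and integrase ids),
the integrase proteins, their profile-HMM domain hits in HMMER `domtblout`
format, and a genome-to-species/genus taxonomy table.  Island prediction
itself, and running HMMER, are upstream concerns: their outputs are this
package's inputs.

### Integrase integrity

Integrases that are truncated or lack catalytic domains are removed before
their *attB*s can be offered as landing pads.  The truncation metric is

\[
\Delta\Delta HA \;=\; \Delta H - \Delta A ,
\]

where \(\Delta H\) counts HMM positions missing at the protein termini and
\(\Delta A\) counts protein residues extending beyond the HMM hit.  Large
positive values mean the protein is shorter than its domain model expects.
Tyrosine-family proteins are rejected when they have no hit to the
tyrosine HMM panel, when the best hit is to the Xer or Integron
subfamilies (which do not perform integrase chemistry), when they exceed
800 aa, or when \(\Delta\Delta HA > 100\).  Serine-family proteins pass
only with a Resolvase domain followed by a Recombinase domain, length at
most 800 aa and \(\Delta\Delta HA \le 0\), or with an S-Core_IS607
classification, length at most 300 aa and \(\Delta\Delta HA \le 0\).  All
cutoffs are configuration with these defaults.

Two places where the rules under-determine an implementation, and the
choices made here: when a protein has several domain hits, the single
best-scoring hit decides the subfamily call and \(\Delta\Delta HA\)
(standard HMMER practice, and deterministic); and "matched to Xer or
Integron" is read as *best* hit, so a weak secondary Xer hit does not
reject an otherwise sound integrase.

### attB deduplication

Identical *attB* sequences (uppercase, same strand) collapse to one record
whose GI and integrase references are the unions over contributors.
Reverse-complement-identical sequences are deliberately *not* merged: att
sites are orientation-bearing.  When contributing GIs disagree on
identity-block coordinates the highest-support GI wins (with a warning).
Sequences shorter than 22 nt are dropped — the floor below which random
matches become likely (see the discovery-rate model below).  An *attB*
whose every cognate integrase failed the integrity filter is excluded from
the queryable set.

## Taxonomic neighbour selection

In taxonomic mode, queries are drawn from the target's nearest relatives,
on the reasoning that an island that integrated in a close relative proves
its integrase works in that cellular background.  Genomes are compared by
bottom-\(s\) MinHash sketches of canonical \(k\)-mers (defaults
\(k = 21\), \(s = 1000\), MurmurHash3 with seed 42 — the conventions of
the delegated sketching tool; the hash seed is a protocol constant, not a
run seed).  The Jaccard estimate \(j\) over the merged bottom-\(s\) sketch
gives the distance \(d = -\tfrac{1}{k}\ln\frac{2j}{1+j}\), capped at 1
when \(j = 0\) since \(\ln 0\) is undefined.

Starting from the best-ranked species, whole species' *attB* sets are
added atomically — never a partial species, so results cannot depend on
within-species ordering — until at least \(n = 500\) sites are collected
(fewer are tolerated when the taxonomy is exhausted).  The fallback order
when ranked species run out is: remaining database species of
already-included genera, then remaining genera; the rules text names both
expansions without fixing their order, and species-then-genus is the
reading adopted here.  With `n_min = 0` the best species' block is still
returned: an empty query set is never useful.

## Matching

Each *attB* yields three queries: the full site, *attB^L* (left flank +
identity block) and *attB^R* (identity block + right flank), with flank
length 16 nt for serine-family sites and 10 nt for tyrosine-family sites.
Hits must span the whole query with at most 2 substitutions and at most 1
gap column (end gaps count); this is implemented as an exact internal
seed-and-extend scan — non-overlapping pigeonhole seeds, then banded
verification — rather than an external aligner call, because the queries
are short and the edit bounds tiny.  A brute-force per-offset scanner with
independently written evaluation code (`find_hits_brute()`) serves as the
oracle; the test suite asserts raw set equality between the two routes on
hundreds of randomized planted cases.  Requiring full-query coverage is a
design choice: the mismatch/gap caps and the "two or more hits" rule are
only well-defined on near-complete matches.  Hit support is scored
\(2\,\mathrm{id} - 3\,\mathrm{mm} - 5\,\mathrm{gap}\), the classic
nucleotide-search reward/penalty scheme.

## Occupancy inference

A site already containing an island shows its half sites separated by the
island: *attL* matches the left-half query and *attR* the right-half
query.  After per-hit rejection (identity < 95 %, > 1 gap column, > 2
mismatches), an *attB* whose surviving hits form two or more distinct loci
(loci = hits merged by coordinate overlap) is routed to the occupancy
pool.  A full-site hit with its own two half-site hits nested at the same
locus counts as one locus — the halves are substrings of the full query
and always co-hit.  An *attB* whose single locus lacks a full-site hit
(a lone half) also goes to the pool; with no pairable partner it ends as
questionable, which keeps the conservation invariant (every matched attB
lands in exactly one output bucket) intact.

For each pooled L/R pair the observed separation is compared with each
reference island length \(E\) via the normalized difference

\[
nd = \frac{E - A}{E + A}, \qquad |nd| < 0.05 \iff
\frac{A}{E} \in \left(\tfrac{19}{21}, \tfrac{21}{19}\right).
\]

The absolute value is used: the printed formula is signed, but without
\(|\cdot|\) any over-long observed span would pass, so the symmetric
tolerance is the only self-consistent reading.  The separation \(A\) is
the *outer* span (left-hit start to right-hit end) by default — upstream
island lengths include the att-bearing ends — with an inner-span option.
When the halves map to different contigs, the hit orientation chooses
which contig terminus would belong to the island, and \(A\) is the sum of
the two terminal distances; no further contig order or orientation is
guessed.  Per attB, the island minimising \(|nd|\) is reported.

## Refinement, binning and ranking

Candidates are demoted to questionable when they overlap an occupied
interval (any overlap, not strict containment — a partially overlapping
att is equally unusable), when their identity block occurs exactly at more
than one genomic locus on either strand, or when the identity block
contains a single-nucleotide run of 10 or more (no run-length threshold is
stated upstream; 10 is this package's configurable default, long enough
that polymerase-slippage artifacts are plausible and short enough to catch
the obvious cases).  Remaining candidates are binned by single-linkage
coordinate overlap; the per-bin winner has the best hit score, ties going
to the higher reference-island support, then leftmost start, then smallest
attB id.  Winners are ranked by reference-island support, descending.

## The discovery-rate model

The probability of finding a random \(k\)-mer in a genome of length
\(L\) (both strands) is \(p = 2L\cdot 4^{-k}\), and \(n\) queries give a
union-bound rate of \(np\).  This motivates the 22 nt database floor: at
\(p = 3.67\times10^{-7}\) per 22-mer, even 500 queries give only
\(1.84\times10^{-4}\) expected spurious discoveries.

```{r discovery}
discovery_rate(p = 3.67e-7, n_queries = 500)$any_of_n
```

## Synthetic data: what it emulates and what it does not

`synth_reference_db()` fabricates the four reference inputs plus
per-species reference genomes with the attBs embedded; domain hits are
fabricated coordinate sets realising any requested \(\Delta\Delta HA\),
domain order or length, because the filters read coordinates and scores,
never residues.  `standard_fixture()` builds the planted-truth world used
by the end-to-end tests: 3 species, 50 attBs, a target genome whose first
20 kb reproduce the top species' backbone (so sketching ranks it first)
followed by 5 planted unoccupied attBs, two occupied sites of 5 and 8 kb
with spans exactly matching their reference islands, a near-length decoy
(reference 40 kb, span 36 kb, \(|nd| = 0.0526\) — just outside the 0.05
acceptance), a duplicated-identity-block decoy and a 12-nt homopolymer
decoy.  Island filler is GC-matched random DNA rejection-sampled to
contain no exact identity-block copy, keeping truth tables exact.

What a green fixture run establishes: the geometry, thresholds and
bookkeeping of the pipeline are correct on sequences whose truth is known
by construction.  What it does not establish: performance on real genomes
— i.i.d. random DNA has no repeats, mobile elements, skews or assembly
artifacts, and the fixture database is orders of magnitude smaller than a
production island collection, so genome-scale candidate counts reported
elsewhere are not reproduced numerically here.

## Numerical and determinism notes

* All coordinates are 1-based inclusive on the forward strand, with a
  strand flag; descending published locus pairs are normalized to
  ascending.
* Sketch hashes are 64-bit values carried as fixed-width hexadecimal
  strings (base R has no exact 64-bit integer); lexicographic order equals
  numeric order, and the JSONL sketch cache stores them exactly.
* Every source of randomness is an explicit seed argument; regeneration is
  byte-identical, runs with identical configuration produce byte-identical
  reports, and the `threads` option cannot change output because results
  are order-normalized (the matcher core is serial; the option exists for
  interface compatibility).
* Per-offset alignment ties are broken by fewer gap columns, then fewer
  mismatches, then span preference (exact length first); neighbour-ranking
  ties by genome id; bin ties as described above.  Degenerate inputs
  (empty GI table, empty query set, no hits) produce empty outputs with
  warnings, not errors.

## Known limitations

* attB deduplication does not merge reverse complements; a site present in
  both orientations yields two records.
* The multi-copy identity-block refinement uses exact matches only;
  near-exact copies (one or two mismatches) do not trigger it.
* Cross-contig occupancy trusts hit orientation alone; it cannot detect a
  mis-assembled contig pair.
* Occupied loci are reported one per attB; overlapping occupied calls from
  different attBs are all listed rather than collapsed, so that every
  matched attB appears in exactly one report.
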