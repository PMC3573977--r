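---
title: "Rating reference proteins: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rating reference proteins: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refrank)
```

## The problem

Most protein sequences in public databases are annotated by automatic
transfer from homologs, and a substantial fraction of those annotations are
wrong or uninformatively vague. For real functional interpretation one
wants *reference proteins*: homologs that have been experimentally
characterized (PubMed literature), structurally solved (PDB), or manually
curated (Swiss-Prot). refrank finds such reference proteins for a query in
a local, annotated sequence collection and — the core of the method —
quantifies how much trust each homologous relationship deserves before any
annotation is transferred.

The danger cases are well known: paralogs (duplication rather than
speciation, often with diverged function) and remote homologs that share a
fold but not a substrate. The rating system is built to push both down the
ranking.

## The pipeline model

A run has two conceptual steps:

1. **Detection.** A local Smith–Waterman search (`search_all()`) finds
   homologs of the query; `identify_references()` keeps those with at least
   one evidence source. Publications linked to more than 100 protein
   records — typically genome papers — are dropped *per publication*: a
   protein keeps its specific literature even when a mega-study link is
   discarded, and it only leaves the candidate set when no source survives.
2. **Evaluation.** Each candidate is probed two ways and scored.
   *Reciprocal best hits* (`reciprocal_best_hit()`): the query is searched
   against the candidate's genome and the candidate against the query's
   genome; each direction is `true` when the top hit is the partner.
   *Multiple sequence comparison* (`msc_evaluate()`): the candidate is
   compared against the query's close sequence set and judged by the
   fraction of the set it detects — a many-alignment statistic that is far
   more robust than a single pairwise identity.

### Cluster-aware reciprocal best hits

Allelic variants (for instance SNP-bearing copies of the same gene) would
make naive reciprocal-best-hit tests fail: the top hit might be an allele
of the candidate rather than the candidate record itself. Each genome is
therefore preclustered by greedy incremental clustering
(`precluster_genome()`, longest sequence first, join the first
representative matched at ≥ 97% identity with ≥ 90% coverage of the
shorter sequence), and best-hit equality is tested at the level of cluster
representatives. The coverage denominator is the shorter sequence, the
convention of the greedy clustering tools this procedure mirrors.

The query's genome is detected automatically as the taxon of the first hit
with ≥ 97% identity and ≥ 90% query coverage (`detect_query_taxon()`), and
can always be overridden by the user. When the genome cannot be resolved a
reciprocal direction is scored `na`, worth +0.25 rather than 0: absence of
evidence is treated as mildly positive rather than as failure. The two
directions are assessed independently, so a candidate from an unplaceable
genome can still earn the hit-to-query-genome point. One further edge
case: if the stated query genome contains no ≥ 97%/≥ 90% counterpart of
the query, the hit-to-query direction is also `na` — the query cannot be
anchored there, which is the same epistemic situation as an unresolved
genome.

### Multiple sequence comparison

The close sequence set *N* is built from the query's hits with coverage
≥ 50% and e-value ≤ 10⁻³, capped at the best 250, excluding the query's own
record (so a reference cannot inflate its ratio through the query itself).
Each reference is then aligned against exactly the members of *N*; a member
counts as hit at cutoff *c* when identity ≥ *c*% and the reference-side
coverage is ≥ 50%. The filtered hit ratio is hits / |N|, and the reference
is *accepted* at cutoff *c* iff the ratio is strictly greater than 0.8.
Acceptance is assessed at 60%, 50% and 40% identity.

The close-set and per-hit filter values are design choices of this package
(the procedure itself only fixes the 0.8 threshold and the three cutoffs):
coverage ≥ 50% is permissive enough to populate *N* for multi-domain-free
queries while keeping fragment matches out, and the e-value filter matches
the default search cutoff. All five values are exposed via `msc_params()`.
With an empty close set all ratios are 0 and no points are awarded — the
scale has no `na` state for MSC.

### The plurality rating

`score_reference()` sums four features (maxima 2 / 1.5 / 1.5 / 1):

| feature | criterion | points |
|---|---|---|
| reciprocal search | query→hit-genome best hit | +1 true / 0 false / +0.25 na |
| | hit→query-genome best hit | +1 / 0 / +0.25 |
| MSC | accepted at 60% / 50% / 40% | +0.5 each |
| pairwise | identity >60% / >50% / >40% | +0.5 each |
| reference | candidate is a reference protein | +1 |

Pairwise bands are strict and cumulative: identity of exactly 60.0% earns
only the >50 and >40 rows; 65% earns all three. The pipeline rates only
reference proteins, so its totals run from 1 (both genomes resolved,
everything else failed) to 6; `score_reference()` itself accepts
non-references for library use and then bottoms out at 0. Points have 0.25
granularity and are summed exactly; reports format them with two decimals.

Candidates are ranked by score, then e-value, then subject ID (a
deterministic tie-break). Scores below 3 mark distant homologs whose
function may have diverged; the detailed display drops them by default
(`apply_display_filter()`, strictly-below-3 rule) while the summary table
keeps everything.

## The search backend

The built-in backend is exact Smith–Waterman (via Biostrings) under
BLOSUM62 with affine gaps (open 11, extend 1; a gap of length L costs
11 + L). Identity is counted over the alignment length including gaps;
coverage is the aligned span over the full sequence of the respective
side. E-values use Karlin–Altschul statistics, bit = (λS − ln K)/ln 2 and
E = m·n·2^(−bit), with the *ungapped* BLOSUM62 constants λ = 0.318,
K = 0.13 applied to gapped scores. That calibration is deliberately crude —
it overstates significance somewhat — but it is strictly monotone in the
raw score, and the pipeline uses e-values only for ordering and for the
close-set filter, where monotonicity is all that matters. Only the single
best local alignment per pair is considered; multi-domain proteins, which
can legitimately carry several distinct HSPs, are outside the model.
`external_search()` adapts a BLAST+ executable to the same hit contract
for large collections.

When no residue pair scores positively, the empty alignment is reported as
identity 0, coverage 0 and E = m·n, keeping every downstream filter
well-defined without special cases.

## What the synthetic fixtures emulate

`generate_fixture()` builds a deterministic toy study system; its defaults
are the conditions under which the package's claims are tested:

* 5 genomes × 3 families, ancestors of 200 residues drawn i.i.d. uniform
  over the 20 amino acids;
* orthologs mutated to 90% identity of the ancestor (so ortholog pairs land
  near 81%, comfortably above every rating band);
* one within-genome paralog per family at 55% — the classic confounder,
  close enough to be found, far enough to fail reciprocal tests;
* one cross-family decoy per family at 30%, flagged as a reference: a
  remote homolog whose literature should *not* be transferred;
* a 99%-identity allele of one ortholog, unannotated, to exercise
  cluster-aware reciprocity;
* one ortholog linked only to a publication with 150 protein records, to
  exercise the mega-study exclusion end to end;
* two unrelated random sequences that must not survive the e-value filter.

Mutations are point substitutions without replacement, drawn uniformly
from the 19 alternative residues; there are no indels, so realized
identities track the targets to within alignment wobble (±3 points on
length-200 sequences). This is deliberately *not* an evolutionary model:
no rate heterogeneity, no domain shuffling, no compositional bias, no
fragments. Passing tests on these fixtures demonstrates that the
machinery implements its contracts — that true orthologs rate ≥ 4 and
planted cross-family decoys < 3 under controlled identities — not that
those score bands are calibrated for any particular real superfamily.
Likewise the benchmark harness (`benchmark_evaluate()`) reproduces metric
definitions (coverage at an inclusive cutoff; accuracy averaged over
covered queries only; family truth implying subgroup truth) on labeled
data, but published accuracy numbers for real superfamilies depend on
databases this package does not ship.

## Numerical choices and degenerate inputs

* All boundary comparisons follow the stated rules exactly: >100 for
  publication exclusion, ≥ 97/≥ 90 for taxon detection and clustering,
  > 0.8 for MSC acceptance, strict > for pairwise bands, ≥ for the
  display filter and benchmark cutoffs.
* Hit ordering is ascending e-value, descending bit score, ascending
  subject ID (C-locale radix sort), which makes whole-pipeline reruns
  byte-identical.
* Zero homologs, zero candidates and empty close sets all produce valid
  empty results, not errors; an empty close set warns.
* Publication lists display newest first (the latest characterization is
  usually the most informative), ties broken by PubMed ID.
* Coverage is always computed relative to the query of the respective
  search; the displayed value for a candidate is therefore the original
  query's coverage, and MSC's per-hit filter uses the reference's own
  coverage as the querying side.
* Taxa may come from FASTA headers (`taxon=` key) or the genomes sidecar
  table; the explicit table wins on conflict.

## Problem sizes

The shipped tests and fixtures are sized for interactive use: 24-protein
collections, genomes of at most 10 sequences, close sets of at most 10
designed members, and exhaustive enumeration of all 1,152 rating-feature
combinations. The alignment engine and the pipeline have no intrinsic size
limits; for collections beyond a few thousand sequences the BLAST+ adapter
is the intended search path.

## Known limitations

* Single-HSP pairwise comparison: multi-domain architectures can inflate
  or deflate coverage and identity in ways the rating does not model.
* The e-value calibration is not comparable to BLAST e-values in absolute
  terms; only its ordering is meaningful.
* Reference identification is only as good as the sidecar tables; missing
  or wrong literature links propagate directly, and the rating does not
  judge the *content* of a publication, only its linkage.
* Orthology by reciprocal best hits is approximate; confident transfer of
  function still calls for gene-tree or synteny evidence.
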