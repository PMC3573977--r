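# refrank

Identify and rate **reference proteins** — experimentally characterized,
structurally solved, or manually curated homologs — for a query protein in
a local annotated sequence collection.

Annotation in sequence databases is overwhelmingly transferred from
homologs, and transfer from the *wrong* homolog (a paralog, or a remote
relative with a different substrate) is a major source of error. refrank
does not just find homologs with literature behind them; it quantifies, on
a 1–6 scale, how trustworthy each homologous relationship is, so that
annotation can be transferred from the best-supported reference first.

The package is aimed at computational biologists curating protein families
or building annotation pipelines: it works offline against FASTA
collections plus small TSV sidecar tables (literature links, publication
sizes, genome membership), uses an exact built-in Smith–Waterman backend
for small studies, and can delegate search to BLAST+ for large ones.

## The rating model

Each reference candidate *r* for query *q* receives

```
score(r) = RB(r) + MSC(r) + PW(r) + REF(r)        ∈ [1, 6] for references
```

| term | evidence | points |
|------|----------|--------|
| RB, max 2 | reciprocal best hits, one point per direction (q → r's genome, r → q's genome); cluster-aware so alleles don't break reciprocity; an unresolvable genome gives a neutral `na` | true +1, false 0, na +0.25 |
| MSC, max 1.5 | *r* is compared against the query's close sequence set (hits with coverage ≥ 50%, e ≤ 1e-3, best 250); accepted at an identity cutoff when it detects > 80% of the set | +0.5 at each of 60 / 50 / 40% |
| PW, max 1.5 | direct pairwise identity of *q* and *r*, cumulative strict bands | +0.5 for > 60 / > 50 / > 40% |
| REF, max 1 | *r* has at least one evidence source (PubMed / PDB / Swiss-Prot); publications linked to > 100 proteins are discounted | +1 |

Candidates are ranked by score, then e-value, then ID; scores below 3
(homologs too distant to trust functionally) are hidden from the detailed
report by default. See the vignette
(`vignettes/reference-rating.Rmd`) for the full method, parameter
rationale and limitations.

## Worked example

The package ships a deterministic study-system generator, so a complete
run needs nothing but a seed. Here query `F1_G1` is searched against a
generated 24-protein, 5-genome collection that plants true orthologs, a
within-genome paralog, a literature-bearing cross-family decoy, an allelic
variant and a mega-publication:

```r
library(refrank)
fx  <- generate_fixture(fixture_config(seed = 42), dir = "fx")
q   <- fx$seqs[fx$seqs$protein_id == "F1_G1", ]
res <- run_pipeline(q, fx$seqs, fx$annotations, fx$publications,
                    fx$genome_table, out_dir = "out")
#> step 1.1: homology search against 24 sequences
#> step 1.1: 8 homologs detected
#> step 1.2: identifying reference proteins
#> step 1.2: 5 reference-protein candidates
#> step 2.0: query taxon detected as G1
#> step 2.0: preclustered 4 genome(s)
#> step 2.1: close sequence set of 7 member(s)
#> step 2.2: 5 candidate(s) rated; 4 at or above display score 3
#> reports written to out
```

`out/report.tsv` (full ranking; `report.html` shows the displayed subset
with per-feature breakdowns):

| rank | subject_id | description | rating_score | e_value | percent_identity | sources |
|------|-----------|-------------|--------------|---------|------------------|---------|
| 1 | F1_G5 | F1 ortholog, characterized | 5.50 | 7.5e-118 | 80.8 | pubmed |
| 2 | F1_G3 | F1 ortholog, characterized | 5.50 | 2.7e-117 | 81.4 | pubmed |
| 3 | F1_G2 | F1 ortholog, characterized | 5.00 | 2.3e-119 | 81.5 | pubmed, swissprot |
| 4 | F1_G2_par | F1-related paralog | 3.00 | 7.7e-52 | 49.5 | swissprot |
| 5 | F1_X | remote homolog of F1, other family | 2.00 | 2.2e-15 | 29.1 | pubmed |

The ranking behaves as the model intends: true orthologs score ≥ 5, the
paralog — despite full coverage and curation — sits at the display
boundary because it fails both reciprocal tests, and the cross-family
decoy is pushed below 3 and hidden. The ortholog linked only to a
150-protein publication never becomes a candidate at all.

## Command-line use

`inst/cli/refrank.R` (installed under `system.file("cli", package =
"refrank")`) wraps the same workflow:

```sh
Rscript refrank.R simulate --seed 42 --out fx
Rscript refrank.R run --query q.fasta --collection fx/collection.fasta \
    --links fx/links.tsv --pubs fx/pubs.tsv --genomes fx/genomes.tsv --out out
Rscript refrank.R bench --results out/results.tsv --labels fx/labels.tsv \
    --out bench.tsv
```

Options may also come from a YAML config (`--config`); explicit flags win.
`bench` evaluates ranked results against family/subgroup labels, reporting
coverage and accuracy at score cutoffs.

## License

MIT (see `LICENSE`).
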