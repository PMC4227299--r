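---
title: "KO assignment by template voting: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KO assignment by template voting: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathvote)
```

## The model

`pathvote` annotates query proteins (or transcripts) with KEGG
Orthology terms by an election over reference species. Each annotated
reference species is a *template*: a protein set plus a table of KO
labels. For a query $q$ and template $s$, the search returns at most
one *best hit* — the highest-scoring subject under the E-value
threshold. Each best hit casts one vote per KO label of its subject.
The final assignment is

$$\mathrm{KO}(q) \;=\; \arg\max_k \bigl|\{\, s : k \in
\mathrm{labels}(\mathrm{besthit}_s(q)) \,\}\bigr|$$

accepted only when the winning frequency reaches `min_votes`. The
frequency counts **distinct species**: a species contributes one ballot
slot per KO regardless of how many strong subjects it contains, which
is what makes the election robust — a single mislabeled or
contaminated reference can cast at most one vote per KO.

Assumptions worth stating explicitly:

- orthology is approximated by best-hit homology per species
  (no bidirectional check);
- labels in the templates are mostly correct — voting tolerates a
  minority of bad electors, not a corrupted majority;
- one final KO per query (single-winner election). Genes with several
  true functions keep only the top-ranked term.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | `1e-5` | inclusive E-value ceiling on the best hit |
| `min_votes` | `2` | minimum winning frequency |
| substitution matrix | BLOSUM62 | protein scoring |
| gap open / extend | 11 / 1 | a gap of length $L$ costs $11 + L$ |
| $\lambda$, $K$ | 0.267, 0.041 | gapped Karlin–Altschul constants for BLOSUM62/11/1 |
| seed word size | 4 | two-hit exact-word filter (see below) |

The threshold and cutoff defaults are the standard operating point for
best-hit KO transfer; both are plain arguments everywhere they matter.
The E-value is the closed form $E = K m n e^{-\lambda S}$ with $m$ the
query length and $n$ the total residue count of the template — a
search-space rescaling of the raw score, not a compositional
adjustment. Bit scores are $(\lambda S - \ln K)/\ln 2$.

## The search backend

Production users can feed real BLASTP results in 12-column tabular
form (`read_blast_tabular()`); everything downstream is identical. The
internal backend exists so the whole pipeline runs and is testable
without external binaries. It is organised as *filter + exact DP*:

1. **Two-hit seed filter.** A query/subject pair is considered only if
   some diagonal carries two non-overlapping exact 4-mer matches
   (pairs shorter than two words pass on a single hit). This is the
   classic heuristic gate: cheap, and it can only *lose* a pair, never
   change a score.
2. **Exact affine Smith–Waterman** (C++, with traceback for identity
   and alignment length) on the survivors.

We deliberately run the full dynamic program rather than a banded one
after seeding: survivors are rare (unrelated random proteins almost
never produce two collinear exact words), so the full matrix costs
little and guarantees that every reported score is the true local
optimum. The failure mode of the heuristic is therefore binary — a
diverged pair either passes the gate and gets its exact score, or is
missed entirely — which keeps the "seeding may only lower, never
raise" invariant trivially true. The tests compare the exact DP
against an independent aligner (`Biostrings::pairwiseAlignment`) and
the seeded path against the exact DP on pairs across a 0–30%
substitution range.

Nucleotide queries are reduced to their longest stop-free six-frame
ORF of at least 30 residues before the protein search; transcripts
with no such ORF are dropped with a warning. Ties between equal-length
ORFs go to the first frame in a fixed enumeration order.

## Tie-breaking and determinism

Every potential tie has a documented, deterministic rule:

- best hit: higher bit score, then lower E-value, then smaller
  subject id;
- election: higher frequency, then smaller sum of supporting
  E-values (stronger aggregate homology), then smaller K number
  (`tie_broken` is flagged on the assignment);
- gene-set merge at equal lengths: the KEGG-side copy is kept, since
  it carries the KO annotation;
- subjects labeled with several KOs vote for each of them — a KEGG
  gene may genuinely map to several orthology groups, and abstaining
  would discard annotation.

Identical inputs and configuration therefore produce byte-identical
output files, which the test suite asserts via checksums.

## Precision and coverage

The validation harness holds one species out, re-annotates its
KO-labeled proteins from the remaining templates, and scores:

- **precision** — among truth-labeled queries that received an
  assignment, the fraction whose assigned KO is in their true KO set;
- **coverage** — the fraction of truth-labeled queries that received
  any assignment.

These are the only definitions under which both quantities are
well-posed for this experiment; queries without truth labels cannot be
scored and are excluded. When nothing is assigned, precision is
reported as `NaN` with a warning rather than silently as 0 or 1.
`compare_assigners()` contrasts voting with the single-best-hit
baseline (one designated template, the query adopting its best hit's
smallest K number) — the strategy voting is meant to improve on.

## The synthetic generator

`synth_config()` describes a miniature multi-species study: `n_kos`
ancestral protein families (roots drawn uniformly over the 20 amino
acids), dealt round-robin onto `n_pathways` synthetic pathways; each
of `n_species` templates carries one copy of every root with
independent per-site substitutions at `substitution_rate`; queries are
fresh mutated copies with truth = source family. Two noise knobs mimic
real annotation defects: `unlabeled_fraction` strips labels,
`mislabeled_species` permutes a template's labels wholesale (a
derangement), modelling a reference whose annotation pipeline went
wrong.

Defaults — 100 families, 10 pathways (10 KOs each), 10 species,
200-residue roots, rate 0.05, no noise, seed 42 — are the package's
standing study conditions: large enough that leave-one-out recovery is
a meaningful statement (100 scored queries, 9-member electorate),
small enough to run in seconds. The robustness experiment uses 40
families, 5 species, 150-residue roots with one mislabeled template,
across 10 seeds.

What the generator does **not** emulate, and hence what passing tests
do not show about real data:

- substitutions are uniform over the other 19 residues, not
  BLOSUM-biased, so percent identity maps to divergence slightly
  pessimistically;
- no indels, paralog families, domain shuffling, or phylogenetically
  correlated divergence — every species is an independent draw;
- truth labels are one KO per record; multi-KO genes appear in real
  KEGG data and are handled by the voting code, but not generated.

On such data the election is easier than in real annotation; the
synthetic leave-one-out result (precision ≥ 0.95, coverage ≥ 0.90 at
the defaults) validates the machinery, not the field performance of
the method.

## Numerical and degenerate-input choices

- Smith–Waterman scores floor at zero (empty alignment); percent
  identity of an empty alignment is reported as 0.
- The E-value filter is applied **after** best-hit selection: a query
  whose best hit fails the threshold yields no row, rather than
  falling back to a weaker subject.
- An empty ballot is a valid input to `assign_ko()` (unassigned, zero
  votes); an empty query set short-circuits to an empty assignment
  table.
- `U` (selenocysteine) is accepted on input and scored as `X`;
  `*` stop characters are stripped from protein input with a warning.
- KGML round trips are model-identities, not byte-identities:
  attribute order is normalized for comparison, unknown attributes and
  elements are carried verbatim. Projection keeps a multi-KO entry
  when *any* of its K numbers is present (KEGG boxes are alternative
  enzymes), always keeps map and compound entries, and drops
  relations/reactions with a dropped endpoint.

## Known limitations

- Single-winner assignment: frequency ties are resolved, never
  reported as multi-assignment.
- The Karlin–Altschul constants are the standard gapped BLOSUM62/11/1
  values, applied without edge-length or composition corrections; at
  very short query lengths the E-values are optimistic.
- The seed filter is tuned for the generator's divergence range
  (exact 4-mers, two-hit); at > ~40% substitution it will start losing
  genuinely homologous pairs that gapped BLAST would find. Use the
  BLAST tabular backend for sensitive production searches.
- The comparison baseline is a same-backend single-template best hit,
  not a reimplementation of any external annotation server.
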