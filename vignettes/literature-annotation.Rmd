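---
title: "Literature-based MeSH annotation of BLAST hits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-based MeSH annotation of BLAST hits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

De novo assembled transcriptomes of non-model organisms — commercially
important teleost fish are the motivating case — are hard to annotate with
ontology-transfer methods: pre-defined gene-to-tag databases are built from
model organisms, so species-specific genes (fish-specific Toll-like
receptors, for instance) either inherit misleading tags from distant
homologs or none at all. litmesh takes a reference-based route instead: it
does not transfer tags from the single best homolog but harvests the
published literature linked to a *deep* list of BLAST protein hits and
summarises it through MeSH, the controlled indexing vocabulary that the
National Library of Medicine assigns to every PubMed article.

## The procedure

For each query contig:

1. **Homology search.** The contig is searched with `blastx` (fast task
   mode) against a protein database, ideally taxon-restricted (see
   *Taxonomic restriction* below). Hits are read from the standard 12-column
   tabular output; the file order (BLAST's bitscore order) is trusted and
   never re-sorted, because depth truncation must mirror the behaviour of
   the `max_target_seqs` option.
2. **Hit filtering.** Hits with percent identity strictly below 40% are
   discarded as too diverged to contribute trustworthy literature; hits with
   E-value above 1e-6 are discarded. Both boundaries are inclusive on the
   keep side: identity exactly 40.0 and E-value exactly 1e-6 survive, the
   latter matching BLAST's own `-evalue` cut-off semantics. Within a query,
   subject accessions are deduplicated (first, i.e. highest-ranked,
   occurrence kept) so several HSPs to one protein cannot double-link its
   articles, and the list is capped at `max_hits_per_query` (default 500).
   The package applies the identity/E-value filters before the cap; the
   order is a package decision, made so that the cap counts only hits that
   can actually contribute literature.
3. **Literature resolution.** Each surviving accession is resolved to its
   linked PubMed IDs, either through a two-column offline link table or
   through the Entrez ELink service behind a pluggable client interface
   (batched, paced at ≤ 3 requests/second, bounded retries; the test suite
   only ever uses in-memory mocks). Whether links are fetched one accession
   at a time or in batches has no observable effect on results; batching is
   an engineering choice. Per query, the PMID sets of its accessions are
   unioned and deduplicated: one article cited by 50 hits of a query counts
   once for that query, but counts independently in every query that
   reaches it.
4. **Scoring.** For each query and each MeSH facet (major topics — headings
   flagged as a central subject of the article — and minor, the rest), the
   *correlation score* of a term is the number of the query's resolved
   articles carrying the term divided by the query's resolved article
   count. The normalization matters: popular genes accumulate articles, and
   without it every well-studied pathway term would dominate. Since a
   descriptor occurs at most once per article, scores live in (0, 1], and a
   score of 1 means the term occurs in every article of the query.
5. **Ranking.** Per-term scores are summed over queries and sorted
   descending; each term also reports how many queries support it, with the
   query IDs kept as evidence. The structural invariant
   `0 < total_score ≤ annotated_queries` holds for every emitted row. An
   immune-system-specific view restricts the ranked major-facet list to
   terms whose MeSH tree numbers fall under A15 (Hemic and Immune Systems)
   or G12 (Immune System Phenomena) — a restriction, not a re-normalization,
   so the restricted list is a subsequence of the full one. Scores are
   descriptive ranks for prioritising terms; they are not test statistics,
   and no p-values or multiple-testing machinery is attached.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `evalue_cutoff` | 1e-6 | conventional significance floor for cross-species blastx hits |
| `identity_floor_pct` | 40% | below this, hits are mostly unreliable across-species matches |
| `max_hits_per_query` | 500 | deep lists rescue queries whose best hits are poorly documented; the depth scan (below) quantifies the trade-off |
| `immune_categories` | A15, G12 | the MeSH branches covering hemic/immune systems and immune phenomena |
| `top_n_major/minor/immune` | 20 / 10 / 10 | report table lengths |

## The depth trade-off

Deeper hit lists annotate more queries (per-query article sets provably
nest as depth grows) but at falling mean identity, i.e. falling credibility
of the underlying homology. `depth_scan()` truncates a filtered table at a
grid of depths (default 1, 5, 10, 25, 50, 100, 200, 300, 400, 500) and
reports, per depth: percent of the query universe annotated, mean identity
of retained hits, mean distinct articles per annotated query, distinct
pooled articles, and distinct MeSH descriptors. Percent annotated and
article counts are non-decreasing in depth by construction; mean identity
is non-increasing whenever identities decay with rank, which holds for the
synthetic generator and typically (not necessarily) for real BLAST output
ordered by bitscore. The distinct-descriptor column counts unique terms;
the JSON output additionally carries the occurrence-token count, since both
readings of "term count" are defensible.

## Taxonomic restriction

`parse_nodes()` reads an NCBI `nodes.dmp` dump into a parent-pointer tree
(validated by pointer doubling, so multi-million-node dumps need no
recursion), and `subtree_taxids()` enumerates all taxids under a node —
including the node itself, since sequence records attached at the root rank
must not be dropped when the list is fed to `blastdbcmd`/`makeblastdb` to
carve a taxon-restricted database out of nr. Node 7898 (Actinopterygii,
the ray-finned fishes) is the intended root for teleost work. Merged or
deleted taxids are out of scope; users supply a consistent dump.

## Report artifacts

`render_report()` writes seven files: top major/minor/immune term tables
(scores displayed with two decimals; full precision retained in the JSON),
a best-hit taxonomic distribution, a journal distribution, the depth
profile, and a JSON evidence bundle that reloads losslessly via
`read_report_json()`. Two counting decisions were genuinely open and are
package choices: the taxonomic table counts one vote per query (its rank-1
hit's taxon), because hit-level counting would be dominated by whichever
species is deepest in the database; and the journal table counts distinct
pooled articles, not per-query citations, because it describes the evidence
corpus. Jobs are identified by the MD5 digest of the submitted file, so
duplicate uploads map to the same job.

## MEDLINE parsing choices

A heading's descriptor is filed as major iff the descriptor *or any of its
qualifiers* carries `MajorTopicYN="Y"` — NLM marks topical emphasis on
qualifiers, and a descriptor-only rule would systematically undercount
major topics. Qualifier names are never emitted as terms. Articles with no
MeSH headings are kept and count in the per-query article denominator (they
are retrieved evidence with zero terms), while PMIDs missing from the local
store are excluded from numerator and denominator alike — the denominator
is the count of articles actually parsed. A missing publication year falls
back to the first four-digit year in `MedlineDate`, else a 0 sentinel; the
year is stored but feeds no report. Descriptors are compared as exact
strings (MeSH is a controlled vocabulary) after whitespace trimming, and
category matching is dot-boundary aware, so prefix `A15` can never match a
hypothetical `A150` branch.

## Ties and determinism

Equal summed scores are ordered by supporting-query count descending, then
term name ascending — a package determinism rule, chosen so repeated runs
and platforms agree. Shuffling query or article order changes no score and
no output order.

## The synthetic corpus generator

Real inputs (nr-scale BLAST databases, the PubMed baseline, live ELink) are
far beyond desk scale, so the package ships a generator that emulates all
input files *jointly and consistently*: a hit table whose identities decay
linearly with rank (default 95% → 55%, all passing the filters), one
pseudo-accession per (query, rank) with optional cross-query accession
sharing to exercise deduplication, Poisson-distributed accession→PMID links
(default mean 1.2, with every query guaranteed at least one reachable
article), and an article store over a small journal set and a 14-term
background vocabulary whose terms appear per article with fixed
probabilities and are flagged major with fixed probabilities. Tree numbers
are synthetic stand-ins shaped like MeSH codes and include A15/G12 terms,
other-branch terms and unmapped terms, so the category filter always has
both outcomes to exercise. A planted enrichment gives ground truth: articles
linked to a chosen target subset of queries carry the planted term with
probability `p_hi`, all others with `p_lo`. The generator's default
conditions — 50 queries, 5 hits each, 20 target queries, `p_hi = 0.8`,
`p_lo = 0.05`, ≈ 6 articles per query — are the study conditions under which
the recovery property (planted term ranked first in ≥ 95 of 100 seeds) is
asserted. Everything is a deterministic function of the spec and seed, with
the RNG algorithm recorded in the spec, so byte-identical regeneration is a
supported promise.

What the generator does *not* emulate: real sequence content (the FASTA is
placeholder), realistic MeSH co-occurrence structure, ELink's patchy
coverage, journal-term correlations, or bitscore/identity discordance.
Passing tests therefore demonstrate algorithmic correctness — exact
agreement with an independently coded triple-loop scoring oracle, invariant
preservation, planted-signal recovery — not annotation quality on real
transcriptomes, which depends on database and literature coverage.

## Problem sizes and tolerances

Oracle-equivalence checks run on 100 seeded corpora of 10 queries × 4 hits
(≈ 40 articles each), with scores required to agree within 1e-12 and
supporting-query counts exactly; recovery checks run on 100 corpora at the
default 50-query conditions; taxonomy checks compare against a brute-force
ancestor-chain oracle on twenty random 10,000-node trees. These sizes keep
the whole suite comfortably interactive while leaving the properties
sharp — every check is exact or near machine precision, none is a loose
statistical band except the frozen ≥ 95/100 recovery threshold.

## Known limitations

- MeSH indexing itself is biased and lagging for non-model organisms; terms
  can only be as good as the linked literature.
- The method requires link and article stores; accessions with no
  literature leave queries unannotated rather than falling back to ontology
  transfer.
- Identity, not positional conservation, gates hits; paralog-dominated hit
  lists can import misleading literature.
- Scores rank terms within a run; they are not comparable across runs with
  different databases or depths.
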