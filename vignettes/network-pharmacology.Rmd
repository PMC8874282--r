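---
title: "Methods: offline network pharmacology for multi-compound extracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: offline network pharmacology for multi-compound extracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
library(dplyr)
```

## The problem

A medicinal plant extract is not one drug but a mixture of dozens to
hundreds of constituents, each potentially touching many protein targets.
Network pharmacology asks which constituents are plausibly bioavailable,
which targets they collectively engage, which diseases those targets are
over-represented in, and which constituents matter most once both network
connectivity and actual abundance in the extract are taken into account.
`herbnet` implements that chain of analyses as a fully offline pipeline:
every stage operates on local tables, and a synthetic-data generator with
planted ground truth stands in for the web services (descriptor
predictors, target-prediction servers, disease-gene databases) that such
studies normally query, so the whole pipeline is testable end to end.

## Drug-likeness and the candidate gate

Each compound carries nine gated descriptors. Six physicochemical windows
describe drug-likeness, inclusive at both ends:

| rule | descriptor | window | units |
|---|---|---|---|
| lipophilicity | XLOGP3 | −0.7 to 5.0 | — |
| size | MW | 150 to 500 | g/mol |
| polarity | TPSA | 20 to 130 | Å² |
| solubility | log S | ≥ −6 | — |
| flexibility | rotatable bonds | ≤ 9 | count |
| saturation | Fsp3 | ≥ 0.25 | fraction |

Three ADME rules are strict inequalities: HIA > 25 %, BBB log BB > −1,
bioavailability score > 0.15. The *candidate gate* — the filter that
decides which compounds proceed — is `HIA AND bioavailability` by
default. The physicochemical windows and BBB are computed and reported as
flags but do not gate; a configuration switch (`gate =
"hia_bioavailability_bbb"`) adds BBB for a stricter screen. We chose the
two-rule gate because it is the screen that defines the candidate set in
this kind of analysis (a 131-compound catalog passing 110 candidates);
whether BBB should additionally gate is genuinely ambiguous in practice,
so both variants are one switch apart.

The solubility rule deserves a note. log S is conventionally negative and
the insoluble edge of the standard bioavailability radar sits at −6, so
the default rule is `log_s ≥ −6`. A literal upper-bound reading
(`log_s ≤ 6`) is available via `log_s_literal_max`; the two readings
differ only for pathological inputs, and making both explicit keeps
boundary behaviour deterministic and documented.

Missing descriptor values are an error in strict mode. In permissive mode
the affected rule is treated as *failed* and a warning is raised: an
unevaluated rule must never silently pass.

```{r}
screen <- screen_candidates(gen_descriptor_table(131, 110, seed = 7)$profiles)
glance(screen)
```

## Target aggregation

Predictions from multiple sources (sequence-similarity, chemical-
similarity, interaction-database, and experimentally curated) are pooled
per compound as a set union after restricting to one species (exact
normalized-label match, `"Homo sapiens"` by default; no ortholog
mapping). Union rather than consensus is the default because
multi-source target prediction is a recall-oriented step here; a
`min_sources` parameter provides the stricter variant. Provenance (which
sources contributed each pair) is kept throughout. Class-level views —
per-class target pools, pairwise overlap matrices, and keyword-tagged
summaries such as "targets falling in brain-related disease terms" — are
set operations on this map.

## Enrichment: the accumulative hypergeometric test

For a hit list of $n$ genes from a universe of $N$, and a term annotating
$K$ of them, the probability of observing $k$ or more hits by chance is
the upper tail

$$p = \sum_{j=k}^{\min(n,K)} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}},$$

computed exactly as a log-space sum over the point masses. This matters:
the disease screen later needs $\log_{10} p$ thresholds near −70, far
below double-precision underflow, so the engine carries log-probabilities
alongside. The enrichment factor is $k/(nK/N)$, observed over expected.
Significance requires all of: $p$ (or the BH-adjusted $q$, for GO/KEGG
libraries) below the threshold (0.01 raw for disease libraries, 0.05
adjusted for GO/KEGG), $k \ge 3$, and EF > 1.5. $q$-values are computed
per library over **all** tested terms (a term the hit list never touches
contributes $p = 1$), never pooled across libraries.

The default universe is the library's annotated-gene union; a
genome-size override (`universe_size`, e.g. 20 000) is available because
a whole-genome background is often quoted without a number — the choice
changes EF and $p$ and is therefore explicit, not implicit.

## Kappa clustering of enriched terms

Enriched terms are redundant; clusters of near-duplicate terms are
summarised by a representative. Similarity between two significant terms
is Cohen's kappa of their hit-gene membership vectors over the union of
hit genes across significant terms:

$$\kappa = \frac{p_o - p_e}{1 - p_e}.$$

The kappa universe is deliberately the hit-gene union, not the genome: a
genome-sized universe makes the "neither" cell dominate and drives all
kappas toward degenerate agreement. Terms are agglomerated with average
linkage (configurable to complete/single; average is the conventional
choice when only "hierarchical clustering" is specified) on distance
$1-\kappa$, and every maximal sub-tree whose merges all occur at
similarity strictly above 0.3 becomes one cluster. Numerically the strict
cut is implemented by cutting the tree at height $1 - 0.3 - 10^{-9}$;
exact ties at the cut are broken toward *not* merging. Each cluster's
representative is its minimum-$p$ member, ties broken by larger hit
count and then lexicographic term id, so results are deterministic.

## Disease screen and the tripartite network

Disease terms enter the network stage when $\log_{10} p < -70$ and the
term matches more than 100 hit genes; survivors are ranked by $p$ and the
top 40 kept. The "logP" of the screen is read as $\log_{10}$ of the
enrichment p-value — the only reading under which a magnitude of 70
makes sense.

The network is tripartite and simple: compound–target edges from the
target map, target–disease edges where a target is among a selected
disease's hit genes; no within-layer or compound–disease edges, and
multi-source provenance never multiplies edges. Node importance is plain
degree (the measure this analysis style uses; no betweenness or
eigenvector centrality). Compound importance can additionally be
weighted by abundance: `weighted_score = degree × content_fraction`, for
the (typically ~10) constituents whose share of extract mass is known.
The induced subnetwork of those quantified compounds keeps targets
adjacent to at least one kept compound and diseases adjacent to at least
one kept target, with degrees recomputed.

```{r}
study <- synthetic_study(seed = 1, n_compounds = 50, n_pass = 35,
                         distinct_targets = 300, genome_size = 4000,
                         n_disease_terms = 50, n_strong_diseases = 15)
cand <- screen_candidates(study$profiles)$candidates
map <- aggregate_targets(study$predictions, cand)
enr <- enrich(unique(map$gene), study$libraries$disease)
net <- build_network(map, screen_diseases(enr, top_k = 12))
glance(net)
```

## What the synthetic generator emulates — and what it does not

The generator plants ground truth at every stage: exact gate-pass counts
in descriptor tables (gate-passing rows drawn inside the pass region,
failing rows violating at least one gate); class-structured target pools
with a controllable pairwise-overlap fraction and an exact distinct-gene
union; gene-set libraries with planted enriched terms (a configurable
fraction of each term drawn from a chosen gene pool) and planted term
families (a shared core of 32 genes plus 4 private genes per term, i.e.
within-family Jaccard ≈ 0.8, across-family ≈ 0); and hit lists with a
controllable signal fraction. Physicochemical descriptors are drawn
uniformly over windows extending 20 % beyond each rule window, so
individual flags fail independently of the candidate gate. All
randomness flows from one explicit integer seed per call; identical
seeds give byte-identical outputs. Gene symbols are synthetic
(`G000001`, …) so nothing accidentally matches a real annotation
resource.

The defaults mirror the scale of a flavone-rich extract study: 131
compounds (allocated across the nine classes by largest-remainder from
the proportions such catalogs report, about half flavones), 110 gate
passers, 25 targets per compound with a 0.25 shared-pool overlap and a
1,011-gene union, a genome-sized background of 20,000, and 48 disease
terms planted strongly enough (220–320 genes, 70 % from the target pool)
that the −70/100-gene screen retains a top 40. Ten flavones carry a
total content fraction of 0.7.

What the generator does **not** emulate: descriptor values are drawn from
distributions, not predicted from structure, so descriptor–descriptor
correlations of real chemistry are absent; target predictions carry no
confidence structure; gene-set libraries have no ontology hierarchy and
no realistic term-size or term-overlap distribution beyond what is
planted. Passing tests therefore demonstrate that the *computational
machinery* is correct and calibrated on known truth — not that any
biological conclusion about a particular extract is right.

## Numerical choices and degenerate inputs

* Hypergeometric tails are exact log-sum-exp accumulations; an
  exhaustive pmf-summation cross-check over every configuration with
  $N \le 60$ (1.23 million cases) agrees to ~2×10⁻¹⁴ relative error.
* Under the null the test is *discrete*: the achievable level just below
  0.01 averages ≈ 0.005 at term sizes 10–50 with 100 hits in a universe
  of 2,000. Null p-values are therefore superuniform (conservative) —
  $P(p \le t) \le t$ at every threshold — rather than exactly uniform.
  This is a property of any exact discrete test, not an implementation
  artefact, and the test suite asserts the superuniform direction.
* Cohen's kappa is undefined only when chance agreement is 1, which for
  subsets of a fixed universe forces the two sets to be identical (both
  empty or both the universe); that case returns 1.
* A single significant term yields one singleton cluster, not an error.
* Ranked outputs (`top_terms`, representatives, exports) carry total,
  documented tie-breaks so reruns are byte-identical.

## Problem sizes in the test suite

Module tests run on small instances (tens of compounds, hundreds of
genes). The calibration and recovery experiments use a 200-term library
over a 2,000-gene universe with 100-gene hit lists (200 null replicates;
100 recovery replicates at signal fraction 0.6; 50 clustering replicates
with 5 families of 4 terms), and the end-to-end arithmetic check runs at
the full study scale (131/110/1,011/40). These sizes were chosen so each
experiment's Monte-Carlo error is small relative to the property being
asserted while the whole suite stays quick to run.

## Known limitations

* Descriptors must be supplied (or generated); computing them from
  SMILES is intentionally out of scope.
* No GSEA-style ranked enrichment and no ontology-graph reasoning.
* No graph layout or figure reproduction; exports target Cytoscape.
* Species restriction is label matching, not orthology.
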