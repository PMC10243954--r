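---
title: "Methods: network pharmacology screening, diffusion and proximity"
author: "netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology screening, diffusion and proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# Scope

netpharm implements the computational core of a network-pharmacology
study of a multi-compound herbal formula against a disease: rule-based
ADMET screening of candidate compounds, assembly of drug and disease
target sets and their intersection, protein–protein interaction (PPI)
topology with a key-target screen, MCODE molecular complex detection,
random walk with restart (RWR) diffusion, the closest-distance network
proximity index with a random-group null, hypergeometric
over-representation analysis, correlation-based gene clustering, and
post-processing of molecular docking records. Everything that depends on
live databases or external software (target prediction servers, STRING
retrieval, GO/KEGG annotation services, docking engines) is out of
scope: those results enter as tables, and a synthetic-data generator
with planted ground truth replaces the downloads for testing and
demonstration.

# The screening model

A compound passes the oral-potential and drug-likeness screen when

* it has oral potential — oral bioavailability OB > 30% **or**
  Lipinski rule-of-five compliance, and
* Caco-2 permeability > 0.4, drug-likeness DL > 0.18, and half-life
  > 3 h.

All comparisons are strict, following the "greater than" convention of
the thresholds themselves. Rule-of-five compliance counts violations
among MW > 500 Da, AlogP > 5, H-bond donors > 5 and H-bond acceptors
> 10; the default tolerates at most one violation (Lipinski's original
convention), and `maxViolations = 0` gives the strict variant — both are
exposed because published screens are often ambiguous on this point.
Toxicity predictions (six endpoints plus LD50) are summarized but never
filtered on: they inform safety discussion, not compound selection.

`passesScreen()` is monotone in each continuous descriptor, and
screening an already-screened table is a no-op; both properties are
tested.

# Target assembly

Drug targets are genes with at least one compound association
probability strictly above 0.8, applied per association. Disease
targets union a score-ranked "top fraction" of GeneCards-style records
(stable sort by score descending, ties broken alphabetically, keeping
`ceiling(fraction * N)` — inclusive and deterministic where the
convention is unstated) with all DisGeNET-style records. The common
targets are the exact sorted intersection.

Compounds shared by two or more herbs receive single-letter display
aliases A, B, C, … in order of descending herb count then compound id;
herb-unique compounds get the herb abbreviation plus a 1-based index. A
user-supplied abbreviation map can reproduce any published label set.

# Network topology and key targets

Networks keep edges with confidence strictly above 0.4 (the
conventional medium-confidence STRING cutoff, rescaled from thousand
scale when needed). Degree and betweenness are exact and unnormalized,
computed on the unweighted graph — confidences decide which edges exist
but do not weight paths, since the key-target rule ("degree **and**
betweenness both strictly greater than twice the median over all
nodes") is scale-invariant to that choice anyway. Medians include
degree-zero nodes. Betweenness is cross-checked in the tests against a
from-scratch BFS path-counting oracle on random graphs.

# MCODE

Vertex weighting follows the k-core formulation: each node's closed
neighbourhood is reduced to its highest k-core, and the weight is that
core's density times k; nodes below the degree cutoff weigh zero.
Complexes grow greedily from the highest-weighted unassigned seed,
recruiting neighbours whose weight is at least
`seed weight × (1 − nodeScoreCutoff)`. The haircut step reduces each
complex to its 2-core; nodes the haircut removes stay consumed, which
keeps complexes disjoint and the seed loop finite. Fluff (off by
default) adds unassigned boundary nodes by closed-neighbourhood
density, still without overlap — the overlapping variant is deliberately
not implemented. Defaults (degree cutoff 2, node score cutoff 0.2,
k-core 2, haircut on) mirror the Cytoscape plugin's documented
defaults; seed ties break alphabetically for determinism. On a lone
clique $K_n$ the algorithm provably returns the single complex with
score $n$, which the tests assert.

# Random walk with restart

The diffusion score is the fixed point of

$$p \leftarrow (1 - r)\,W p + r\,e,$$

with $W$ the column-normalized adjacency, $e$ uniform over the seeds,
and mass at dangling nodes redirected to $e$ so that $\sum p = 1$
always. Power iteration stops when the L1 change falls below 1e-10
(cap 1000 iterations; non-convergence is an error, not a warning). The
restart probability defaults to 0.7, a common setting in
gene-prioritization work; the walk is unweighted by default with a
confidence-weighted option. Candidate ranking keeps seeds by default —
in practice the highest-scoring genes are often seeds, and excluding
them is a flag, not an assumption. The solver is validated against a
direct dense solve of $(I - (1-r)W)p = re$ on graphs up to 50 nodes and
against the closed-form 3-path example $(7/12,\ 1/3,\ 1/12)$ at
$r = 0.5$.

# Network proximity

The separation index between gene sets A and B is

$$s_{AB} = d_{AB} - \frac{d_{AA} + d_{BB}}{2},$$

where $d_{AB}$ averages each member's distance to the nearest member of
the other set and $d_{AA}$ averages each member's distance to its
nearest same-set neighbour. The formula by itself does not pin down a
distance convention; the closest-distance convention of the
separation-index literature (Menche et al.'s disease-module work) is
adopted — this is the single most consequential interpretation in the
package, hence stated here prominently. Consequences worth knowing: $s_{AB} \le 0$ whenever
A = B (it equals $-d_{AA}$), $d_{AA}$ is undefined for singletons
(an error), and unreachable members are an error by default because
silent infinities would corrupt the means (`onUnreachable = "drop"`
discards them with a warning instead).

The null control samples `nGroups` (default 50) gene groups uniformly
without replacement from the nodes outside A — uniform, not
degree-matched, matching the plain "randomly selected" description —
and reports the mean and SD of their index against A, reproducibly from
one seed.

# Enrichment and clustering

Over-representation uses the upper-tail hypergeometric probability
$P[X \ge k]$, computed from the log-space cumulative distribution, and
is cross-checked against exhaustive enumeration of all $\binom{N}{n}$
draws for $N \le 12$. The universe defaults to the union of term genes
and is overridable, since background sets are rarely stated in
published analyses. Terms with no query overlap are not reported;
Benjamini–Hochberg adjustment is computed over the tested terms and
always reported alongside the raw-p significance flag (default cutoff
0.005) so either convention is auditable. Correlation clustering is a
transparent stand-in for co-expression module services:
average-linkage hierarchical clustering on $1 - r$, cut to a requested
number of clusters.

# Docking records

Binding free energies convert to inhibition constants via
$K_i = e^{\Delta G / RT}$ with $R = 1.98720$ cal mol$^{-1}$ K$^{-1}$
and $T = 298.15$ K, the AutoDock reporting convention, returned on the
micromolar scale. Docking reports in the field sometimes label this
column "µmol/ml"; the numbers correspond to µmol/L under the standard
conversion, a labeling idiosyncrasy worth knowing when comparing
against published tables. Dockings with
$\Delta G < -5$ kcal/mol are flagged stable. Recomputed constants are
compared to recorded ones at the table's printed precision — a value
printed with one significant figure can differ from the exact
recomputation by more than 2% purely through rounding, so the
comparison tolerance is half a unit in the last printed decimal or 2%
relative, whichever is larger.

# The synthetic-data generator

Every input has a generator, all driven by one master seed from which
each generator derives a fixed child seed (the whole fixture is
reproducible from one integer, and generators are byte-identical across
repeated calls):

* **Compound tables** — a compound passes the full screen with
  probability `pass_fraction` (default 0.6); failing compounds violate
  a random non-empty subset of criteria, so limit cases 0 and 1 are
  exact. Compounds join 1–3 of 5 herbs with ~25% shared, toxicity
  labels are drawn per endpoint (active rates 0.05–0.25, hepatotoxicity
  rarest), LD50 is log-normal.
* **PPI networks** — preferential attachment (200 genes, m = 2) for the
  degree heterogeneity the 2×-median hub rule assumes, with a planted
  5-clique on low-degree nodes (MCODE ground truth), a planted set A,
  a near set inside A's 1-hop neighbourhood and a far set at distance
  ≥ 3 (proximity ground truth), and confidences Uniform(0.41, 1) so
  the 0.4 filter is a no-op on the fixture.
* **Gene sets** — 30 terms of 10–40 genes; exactly one term samples
  query genes with weight 8 (strength 1 degenerates to uniform).
* **Correlation matrices** — empirical correlations of latent-factor
  draws: 4 contiguous blocks at within-block correlation 0.8, ~0
  between, exactly symmetric with unit diagonal.
* **Disease genes, associations, regulations** — log-normal relevance
  scores, Uniform(0, 1) association probabilities (so ~20% clear the
  0.8 threshold), modes from activation/repression/unknown. The default
  association-table size (600) keeps drug targets a minority of the
  universe, as in real interactomes, leaving room to sample proximity
  null groups from the complement.

What the generator does **not** emulate: literature-scale gene counts
(published human interactomes carry on the order of 10,000 genes; the
fixture uses 200), correlated ADMET descriptors, herb-specific compound chemistry,
annotation-corpus structure in the gene sets, and assortativity or
community structure of real PPI networks beyond the scale-free degree
law. Passing the planted-recovery tests therefore demonstrates that the
algorithms recover known structure under realistic sparsity and noise —
not that any particular biological conclusion transfers.

# Numerical and degenerate-input choices

* All screen and filter thresholds are strict inequalities.
* RWR: L1 tolerance 1e-10, 1000-iteration cap, error on
  non-convergence.
* Proximity: unreachable members error by default; singleton sets are
  an error for $d_{AA}$.
* Ties: seed selection (MCODE), candidate ranking (RWR), disease-score
  ranking and alias assignment all break ties by identifier ascending;
  every ranking is therefore deterministic and permutation-invariant.
* Empty cases: empty compound tables screen to empty reports; an empty
  intersection of drug and disease targets warns and downstream stages
  refuse; an edgeless graph yields no complexes.
* Self-loops in edge lists are dropped with a warning (STRING exports
  occasionally contain them); duplicate undirected edges keep the
  maximum confidence; thousand-scale scores are auto-detected (any
  score > 1).

# Problem sizes

The test suite runs planted-recovery checks at 100 seeds for the
acceptance-level properties (clique recovery, proximity separation,
enrichment ranking) and 25-seed versions at module level, on the
200-gene default fixture; oracle equivalences use graphs of 10–50
nodes where exhaustive computation is exact. The full suite completes
in about 80 seconds on one CPU; the reproduction script in
`scripts/acceptance.R` takes about a minute.

# Known limitations

* Gene identifiers are matched at the symbol level (uppercased,
  trimmed); no alias resolution is attempted.
* The proximity null is uniform sampling; degree-matched controls —
  preferable when set degrees are extreme — are not yet implemented.
* MCODE omits the overlapping "fluff" variant by design.
* Enrichment ignores term ancestry/redundancy (no GO graph handling)
  and implements over-representation only, not rank-based enrichment.
* The pipeline's input mode expects tables in the package's own
  reader formats; it does not ingest raw database exports beyond
  STRING-style edge lists and GMT collections.
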