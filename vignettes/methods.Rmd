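---
title: "Evidence integration and resampling prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence integration and resampling prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onoprio)
```

This vignette is the package's own account of the statistics it
implements: what each stage assumes, which parameters matter and why
their defaults are what they are, what the synthetic benchmark does and
does not emulate, and where the design was genuinely open.

## 1. Evidence model and scoring

An evidence record ties a marker (SNP, SSR, QTL interval, transcript,
protein, metabolite pathway, or homolog) to the trait with one raw
statistic. Records are admitted when the treatment temperature is below
15 °C (missing temperatures — database and homolog evidence — pass) and,
for QTL evidence, when the marker–trait association interval is at most
5 cM; exact duplicates (same marker, layer, source, value) collapse to
one record.

Raw statistics are transformed onto a common bounded scale:

| kind | transform | rationale |
|---|---|---|
| p-value | `min(-log10 p, 10)` | evidence strength on the log scale |
| fold change | `min(|log2 FC|, 10)` | symmetric in up/down regulation |
| LOD | `min(floor(LOD), 10)` | integer linkage evidence |
| degree, clustering coef., reference count | step function, ≤ 10 | count-like, saturating |
| preset score | clipped to [0, 10] | curated input passed through |

The cap (default 10) is the data-heterogeneity control: a single platform
with extreme statistics cannot dominate a gene's profile. The step-bin
boundaries are package defaults (reference counts 1 / 2–3 / ≥4 → 1/2/3;
degrees 1/5/10/20/50 → 1–5; clustering coefficient quartiles → 1–4),
declared in `default_score_caps()` and fully configurable — the exact
bins any given curation effort used are a property of that curation, not
recoverable from first principles. Fold changes are assumed linear and
log2-transformed; inputs already on the log2 scale must set `is_log`.

Markers carrying coordinates map to every gene whose body extended by a
20 kb window (closed intervals, 1-based) intersects them; protein-pair
evidence is first converted to per-gene network degree.

Per treatment-duration class — short (<12 h), mid (12–48 h, inclusive),
long (>48 h) — the gene × layer matrix `S` aggregates multiple records of
one gene in one layer by the **maximum** (default). The maximum respects
the per-layer [0, 10] bound by construction and reads as "the strongest
independent report"; sum-then-clip is available (`aggregate = "sum"`)
for curation styles where repeated weak reports should accumulate.
Records without a treatment duration are duration-agnostic and
contribute to every class; a study reporting several time points
contributes each record to its own class. The combined score is
`W_j · Σ_l S_jl` with per-class duration weights defaulting to 1 (no
published weighting scheme exists to copy; weights are exposed per
class). Genes with combined score 0 carry no admissible evidence and are
removed.

## 2. Core genes and the cut-off bin

The number of genes to prioritize, `h`, is not a free parameter: it is
read off the separation between a small high-confidence **core** set and
the full test pool. Core genes enter by curated flag (scenario 1:
most-significantly reported; scenario 3: q-PCR-validated at p < 1e-4 —
both judgements are curation input, the package only consumes the flags)
or by predicate (scenario 2: reported on strictly more than 3 layers,
combined score in the top 0.5%, and above 3 on every reported non-homolog
layer).

"Optimal cut-off between a left-skewed core and right-skewed test
distribution" is operationalized as a dual-tail rule: integer scores `c`
with at least `tau_core = 0.9` of the core and at most `tau_test = 0.01`
of the test genes at or above `c` form the cut-off bin; the chosen
threshold is the bin's upper bound (the most conservative member — lower
cut-offs admit progressively more genes and, downstream, more enriched
pathways of diminishing specificity, which is exactly what
`compare_threshold_sensitivity()` tabulates). `h` counts test genes with
combined score ≥ the threshold, ties included (closed tail). Both taus
are configurable; 0.9/0.01 makes a 10-gene core tolerate one straggler
while keeping the admitted tail within 1% of the pool. Degenerate inputs
(no candidate `c`, or `h = 0`) raise explicit separation-failure errors
rather than guessing.

## 3. The resampling prioritization

The training set `D` is the per-class score matrix. Each iteration draws
a bootstrap sample of all `n` genes with replacement, takes the `h`
distinct genes with the highest combined scores (ties broken by higher
layer-score sum, then lexicographic gene id), and accepts this "decision
tree" only when its scores are significantly higher than a permutation
null — otherwise the tree is discarded and redrawn, until `r` trees are
accepted (guarded by `max_rejected_trees = 10 r`). Each accepted tree
casts one vote per member gene; counts divided by `r` are the gene
probabilities, and the final list is the top `h` by count, with the
largest consecutive probability drop reported as a consistency check on
`h`.

**The permutation null.** The null must "break the structure" of `D`.
Permuting the *combined* scores across gene labels conserves their
multiset, so every permutation has exactly the same top-`h` score values
as `D` itself — a bootstrap top set could then never test significantly
higher, and no tree would ever be accepted. The working null
(`perm_mode = "layers"`, the default) instead shuffles each layer's
scores independently across genes and recomputes the combined score:
what it destroys is precisely the within-gene concordance across layers
that distinguishes a replicated signal from scattered single-layer
noise. The literal combined-score shuffle is kept as
`perm_mode = "combined"` for the degenerate-null behavior it implies.
The permutation top sets are generated once per run (`q` sets, pooled
into one reference sample); regenerating them per tree is statistically
identical under this null and `O(q)` more expensive. A per-set variant
(`perm_pooling = "per_set"`: one test per permutation set, majority
rule) is provided.

**The acceptance test** is a one-sided Wilcoxon rank-sum test at
`alpha = 0.05` (no published value to copy; configurable). Because
scores are small and discrete, ties dominate, and the usual exact
algorithms assume tie-free data; the package computes the exact
permutation distribution of the midrank sum by dynamic programming over
doubled midranks whenever both samples have ≤ 12 observations, and a
tie-corrected normal approximation with continuity correction otherwise.
All-identical inputs give p = 1 (tree rejected) by convention.

**What vote probabilities can and cannot say.** A gene is absent from a
bootstrap sample with probability `(1 - 1/n)^n ≈ 1/e ≈ 0.368`, and an
absent gene cannot be voted. Under one-vote-per-gene-per-tree counting
the probability of even an infinitely strong gene is therefore bounded
near `1 - 1/e` (acceptance filtering nudges it upward, to ≈ 0.7–0.75 in
the package's benchmark, because trees containing more strong genes are
accepted more often). Two consequences are worth stating plainly: (i)
probabilities are relative ranking evidence, not absolute selection
frequencies — a flat plateau followed by a sharp drop is the signature
of a stable set; (ii) when `h` equals the number of genuinely strong
genes, the weakest strong gene (probability ≈ 0.63 × boost) and the
strongest background gene (voted when it fills a vacancy, probability ≈
0.63 × P(≥1 vacancy)) run a near-tie that sampling noise can resolve
either way. The acceptance test cannot break this tie: at `h = 10` a
single background gene among nine strong ones barely moves the rank-sum
statistic. Vote conservation, by contrast, is exact on every run:
`Σ counts = r · h`.

## 4. Validation statistics

Against an external per-gene differential-expression p-value table, the
prioritized set is compared with the remaining genes by a one-sided
rank-sum test (alternative: smaller p-values). The empirical p against
random sets draws `B` same-size sets without replacement from the
test-gene pool (the pool is a parameter); a random set "outperforms"
when its median `-log10 p` strictly exceeds the prioritized set's — the
median because it is robust and invariant under monotone transforms of
the statistic (the mean is available). A zero count is reported as the
bound `< 1/B`, never as 0. Competitor lists get both one-sided rank-sum
tests plus the upper-tail hypergeometric overlap probability in a stated
universe.

## 5. Enrichment and crosstalk

Terms outside 5–2500 genes (raw annotation size, as provided — the
filter guards against uninformatively small and uselessly broad
pathways) are excluded before testing; each surviving term gets the
upper-tail hypergeometric p of its query overlap, Bonferroni-adjusted by
the number of *tested* terms. Annotations are taken flat (no ontology
ancestor propagation). The crosstalk network joins significant terms
(adjusted p < 0.05) sharing at least one **query** gene — overlap among
the prioritized genes, since they are what the enrichment is about; a
term-wide overlap mode exists — with edge weight the shared-gene count
and node size `-log10` adjusted p. Degree means and medians are
summarized per duration class on the merged multi-class network, so a
class's nodes count their edges to other classes' nodes too.

## 6. Genotype classification

Monomorphic markers are removed (genes left without markers are dropped
from the marker–gene map). The identity-by-state dissimilarity between
two samples is the mean over pairwise non-missing loci of
`|g_i - g_j| / 2` on 0/1/2 dosages — the standard allele-sharing
distance; a pair sharing no genotyped locus is an error naming the pair,
not a silent NA. Neighbor joining follows the classical Q-criterion
agglomeration with the standard split branch lengths; two details are
pinned for determinism because no convention exists to copy: ties on Q
break by the lexicographically smallest label pair, and a negative
branch length is clamped to zero with the deficit moved to its sister
branch (pair total conserved, tree flagged). The two-group split is read
off the tree itself: every edge induces a bipartition, and the edge
maximizing label agreement (maximized over the two block-to-class
assignments, unknown labels excluded) is reported with its concordance
fraction.

## 7. The synthetic benchmark

The generators emulate the study's shape: ~2,000 test genes of which 10
planted signal genes carry one strong record on each of four omics
layers in every duration class plus a homolog record; background genes
carry 2 + Poisson(1) weak records; expression p-values are Beta(0.1, 10)
for signal and Uniform(0, 1) for null genes; genotypes form two 28-sample
clusters with allele-frequency gap 0.9 at signal-gene markers (plus one
deliberately monomorphic marker); annotations contain one planted term
holding ≥ 80% of the signal genes plus random decoys and deliberately
under- and over-sized terms. Signal per-layer scores are 4.2 ± 0.05: above
the core-gene per-layer threshold, tightly concordant across layers (the
defining property of replicated high-confidence genes), and placing the
combined score ≈ 19.8 mid-interval on the integer cut-off grid so the
dual-tail rule lands at `h = n_signal` rather than splitting the planted
set on a boundary.

What the benchmark does **not** emulate: realistic score distributions
of any actual curation (most real genes score 0–2 per layer with heavy
platform idiosyncrasy), linkage disequilibrium or population structure
beyond the two planted clusters, correlated evidence across layers of
noise genes, or annotation bias. Passing tests therefore demonstrate
that the machinery recovers a planted signal under clean conditions —
not that any particular real gene list is correct.

Default problem sizes (2,000 genes, `r = q = 1,000`, `B = 10,000` for
the single empirical p, `B = 200` × 500 replicates for the null
calibration, 100 additive trees ≤ 12 leaves) keep a full benchmark run
in tens of seconds on one CPU; `r = q = 10,000` (the full-scale setting)
is available behind the CLI's `--full` flag.

## 8. Numerical choices and limitations

* Exact rank-sum enumeration switches to the normal approximation above
  12 observations per side; the DP is exact under arbitrary ties.
* Cut-off candidates are scanned on the integer grid 0..max score;
  scores themselves are real-valued.
* `detect_probability_drop` breaks ties by the first index, with a 1e-9
  tolerance against floating-point noise.
* Neighbor joining is quadratic per merge (cubic overall) in pure R —
  comfortable to a few hundred samples, not for thousands.
* The pipeline seeds every stochastic stage deterministically from one
  seed; reruns with an identical configuration are byte-identical.
* Bonferroni is deliberately conservative (it is the correction the
  enrichment stage is defined with); no FDR alternative is exposed.
* The homolog layer consumes precomputed alignment tables (e-value
  < 1e-10, identity > 35%); the package performs no alignment, no
  literature retrieval, and no genome-version liftover (an id-mapping
  table can be applied upstream).
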