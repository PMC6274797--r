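---
title: "Path-weighted prediction of circRNA-disease associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-weighted prediction of circRNA-disease associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circpath)
```

## The problem and the model

Experimentally verified circRNA-disease associations are scarce, and wet-lab
confirmation is slow and expensive. Given a curated list of verified pairs,
the task is to rank all remaining (disease, circRNA) pairs by how likely they
are to be associated. `circpath` does this with a path-weighted score on a
heterogeneous network, built in five steps.

**1. Association matrix.** The verified pairs define a binary matrix $M$
(diseases $\times$ circRNAs), $M_{ij} = 1$ exactly when disease $i$ and
circRNA $j$ are a verified pair.

**2. Annotation similarity.** Each circRNA carries the set of GO terms of its
target genes; each disease carries the set of its gene annotations. For two
entities with term sets $A$ and $B$ the similarity is the Jaccard index
$|A \cap B| / |A \cup B|$. Two conventions matter for sparse, incomplete
annotation data:

* An entity with an *empty* term set has similarity 0 to everything,
  including itself. An absent annotation is absence of evidence, and a zero
  is exactly what routes the pair to the kernel fallback below.
* The diagonal is 1 for annotated entities. Self-similarity is never
  traversed by the path scorer (paths are node-simple and self-loops are
  masked at network assembly), so this choice cannot affect any score.

**3. GIP kernel similarity.** Annotation catalogs are sparse: many pairs have
no overlapping terms, or no terms at all. The Gaussian interaction profile
(GIP) kernel fills the gap using only the association matrix. An entity's
*profile* is its row (disease) or column (circRNA) of $M$, and

$$K(i, j) = \exp\left(-\gamma \, \lVert p_i - p_j \rVert^2\right), \qquad
\gamma = \gamma' \Big/ \tfrac{1}{n}\sum_{k=1}^{n} \lVert p_k \rVert^2,$$

with raw bandwidth $\gamma' = 1$ by default (the standard operating point for
interaction-profile kernels; exposed as `gamma_prime_circ` and
`gamma_prime_disease`). The normalization makes the bandwidth scale-free: it
divides by the mean squared profile norm over *all* entities, zero rows
included. If every profile is zero (possible on tiny cross-validation
training sets) the bandwidth is undefined; the package substitutes the
identity kernel with a warning, preserving "no evidence, no off-diagonal
similarity" instead of crashing.

**4. Integration and thresholding.** The fused similarity keeps the Jaccard
value where it is nonzero and falls back to the GIP kernel elsewhere. The
fused circRNA network, fused disease network and the bipartite association
network (weight 1 edges) form one undirected weighted heterogeneous graph,
and every edge of weight $< \gamma$ (default $\gamma = 0.5$; the comparator
is $\ge$, so ties survive) is removed as noise. The threshold applies
uniformly to all three blocks, but association edges weigh 1 and always
survive since $\gamma \le 1$ is enforced.

**5. Path scoring.** The score of a (disease $d$, circRNA $c$) pair sums over
all node-simple paths $p$ between them with at most $\eta$ edges:

$$\mathrm{score}(d, c) \;=\; \sum_{p}\;
\frac{\prod_{e \in p} w_e}{\alpha\, e^{\,\mathrm{len}(p)}}.$$

Defaults are $\eta = 3$ and $\alpha = 1$. Enumeration is a depth-first
search that marks nodes on entry and unmarks them on backtrack; neighbors
are visited in ascending node index, so path order (and every downstream
output) is deterministic. All node-type sequences are admitted — circRNA or
disease hops in any order — the only restriction is the edge budget $\eta$.

## Reading of the score formula

The combination of a path's weight product with the length penalty
$\alpha\,e^{\mathrm{len}}$ is implemented as *division* by the penalty. The
penalty grows with length, and the design intent is that longer paths
contribute less; multiplying by a growing factor would invert that. Division
makes a path's contribution decay exponentially with its length, which is
also what makes the $\eta$ cutoff innocuous (an admissible 3-edge path of
perfect weights contributes at most $e^{-3} \approx 0.05/\alpha$).

Two consequences are worth knowing:

* **$\alpha$ never changes a ranking.** It rescales every score by
  $1/\alpha$. The implementation factors $\alpha$ out of the path sum and
  applies it as one final division, so the scaling is *exactly* linear in
  floating point too: rank-based quantities (ROC, AUC, top-$k$ lists) are
  bitwise invariant to $\alpha$. The package asserts this; $\alpha$ is kept
  only as an interpretable scale knob.
* **$\eta$ is the real complexity dial.** Work grows roughly with the
  $\eta$-th power of node degree. At $\eta = 3$ exact enumeration is cheap at
  the scale of curated circRNA-disease data (hundreds of entities);
  approximate enumeration is deliberately out of scope.

## Cross-validation protocol

`pwcda_cv()` evaluates recovery of held-out associations.

* **LOOCV** holds out each verified pair in turn. The training matrix has
  that single entry zeroed; the GIP kernels, fused similarities and
  thresholded network are rebuilt *from the training matrix only* — a kernel
  computed on all data has seen the held-out label and would leak it. The
  annotation Jaccard matrices never touch $M$ and are computed once.
  Diseases with exactly one verified association are skipped (removing their
  only edge leaves no training signal for that disease) and reported.
* **k-fold** (default $k = 5$) partitions the pairs uniformly at random
  under a caller-supplied seed, zeroes each fold at once, and otherwise
  proceeds the same way.
* **Negatives** are all pairs absent from the full verified set, scored once
  under the all-data model. They are never held out, so this costs
  $|\text{positives}|$ model rebuilds rather than $|\text{pairs}|$. The
  convention is documented rather than switchable-by-accident: rescoring
  negatives per fold would change only the pairing of scores, not the labels.
* **ROC/AUC** sweeps thresholds over the distinct scores; a pair is called
  positive at threshold $t$ when its score is $\ge t$. The trapezoidal area
  equals the Mann-Whitney statistic with ties counted one half. Ties are
  real here — disconnected pairs score exactly 0 — so the tie convention is
  asserted against a brute-force concordant-pair oracle in the tests.

## The synthetic generator

Development and testing run entirely on seeded synthetic data from
`generate_synthetic()`, a planted block model:

* circRNAs and diseases are assigned round-robin to `n_blocks` balanced
  blocks (default 3);
* associations are independent Bernoulli draws: probability 0.35 for
  same-block pairs, 0.03 otherwise (defaults; 40 circRNAs by 12 diseases);
* each annotated entity draws 8 terms, 90% from a compact 10-term block pool
  and the rest uniformly from the 30-term vocabulary. Compact pools give
  block-mates an expected Jaccard overlap around 0.45, so a substantial
  share of within-block annotation edges survives the 0.5 edge threshold —
  the regime in which annotation fusion actually matters, as with
  gene-annotation sets of closely related diseases. Cross-block overlap
  stays near 0.04;
* 10% of entities per catalog get an empty term set, exercising the GIP
  fallback path.

The generator writes the same file formats the readers accept, so a
command-line run on synthetic data is file-for-file identical to a run on
real database extracts.

**What the planted model can and cannot show.** Within this model the
block structure is the *only* signal: given the blocks, association
indicators are independent coin flips, so a held-out positive and a
never-associated pair of the same block category are statistically
exchangeable no matter the method. The best achievable ranking is the
block-indicator oracle, whose expected AUC at the default sizes and
probabilities is

$$\mathrm{AUC}^\* = p_W (f_B + \tfrac{1}{2} f_W) + \tfrac{1}{2} p_B f_B
\approx 0.80,$$

where $p_W, p_B$ are the fractions of positives within/between blocks and
$f_W, f_B$ the corresponding fractions of negatives. Cross-validated AUC on
the default conditions should therefore be read against this ceiling of
about 0.80, not against 1.0 — the scorer is doing well when it lands within
a few points of the oracle, and `scripts/acceptance.R` reports exactly these
AUCs. Real curated datasets are not exchangeable within neighborhoods in
this way (degree structure, annotation detail and curation biases all carry
extra signal), which is why published evaluations on database extracts can
report substantially higher AUCs than any faithful synthetic rerun at desk
scale. Passing on planted data shows the machinery recovers the structure it
is designed for; it does not certify a particular AUC on real data.

## Numerical and degenerate-input choices

* Similarity matrices are symmetrized as $(K + K^\top)/2$ and GIP diagonals
  pinned to exactly 1; squared distances are clamped at 0 before
  exponentiation to absorb cross-product rounding.
* Score ties in ranked outputs break lexicographically by (disease id,
  circRNA id); identical inputs produce byte-identical outputs everywhere.
* Identifiers are trimmed and case-folded; each distinct normalized string
  is one entity. Alias resolution (merging database synonyms of one circRNA)
  is out of scope — it requires external alias tables.
* An all-zero association matrix yields the identity GIP kernel with a
  warning rather than an error; cross-validation on tiny fixtures hits this.
* Degenerate cross-validation inputs (no negatives at all) keep their fold
  bookkeeping but report `auc = NA` with a warning instead of failing.
* Seeded internals (`generate_synthetic()`, k-fold assignment) save and
  restore the caller's RNG state.

## Known limitations

* The score's reading of the length penalty (division, see above) is a
  documented interpretation; the penalty form $\alpha\,e^{\mathrm{len}}$
  itself is fixed rather than pluggable.
* Species filtering is the only curation step offered; reproducing any
  particular database's exact entity counts typically requires additional,
  dataset-specific curation.
* Path enumeration is exact; graphs whose degree explodes after a permissive
  threshold ($\gamma$ near 0) make $\eta > 3$ expensive.
* LOOCV rebuilds one model per held-out association. At the default
  synthetic scale (40 by 12, about 70 positives) this takes well under a
  minute; at the scale of a full curated database (hundreds of entities) it
  is minutes-to-hours work that users should plan for.

## A worked example

The five-circRNA, three-disease toy network below has exactly three
admissible paths between `c1` and `d2` at $\eta = 3$ — a two-edge route and
two three-edge routes — while the four-edge route through `c2` is excluded
by the length bound:

```{r worked-example}
circ <- paste0("c", 1:5); dis <- paste0("d", 1:3)
cc <- matrix(0, 5, 5, dimnames = list(circ, circ))
cc["c1", "c3"] <- cc["c3", "c1"] <- 0.9
cc["c1", "c4"] <- cc["c4", "c1"] <- 0.8
cc["c1", "c5"] <- cc["c5", "c1"] <- 0.7
cc["c1", "c2"] <- cc["c2", "c1"] <- 0.9
cc["c2", "c5"] <- cc["c5", "c2"] <- 0.8
dd <- matrix(0, 3, 3, dimnames = list(dis, dis))
dd["d1", "d2"] <- dd["d2", "d1"] <- 0.9
dd["d3", "d2"] <- dd["d2", "d3"] <- 0.7
cd <- matrix(0, 3, 5, dimnames = list(dis, circ))
cd["d1", "c3"] <- 0.9; cd["d2", "c4"] <- 0.6; cd["d3", "c5"] <- 0.8
net <- apply_threshold(hetnet(cc, dd, cd), 0.5)

vapply(enumerate_paths(net, "c1", "d2", eta = 3),
       function(p) paste(p$nodes, collapse = "-"), "")
association_score(net, "c1", "d2")
# by hand: 0.8*0.6/e^2 + 0.9^3/e^3 + 0.7*0.8*0.7/e^3
0.8 * 0.6 / exp(2) + 0.9^3 / exp(3) + 0.7 * 0.8 * 0.7 / exp(3)
```

And an end-to-end run on synthetic data:

```{r end-to-end}
dataset <- generate_synthetic(synthetic_spec(n_circ = 20, n_dis = 8, seed = 3))
fit <- pwcda(dataset$table, dataset$circ_catalog, dataset$disease_catalog)
fit
head(predict(fit), 5)
cv <- pwcda_cv(dataset$table, dataset$circ_catalog, dataset$disease_catalog,
               scheme = "kfold", k = 5, seed = 1)
cv
```
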