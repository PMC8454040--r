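---
title: "Latent-space pathway exploration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space pathway exploration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathlatent)
```

# The model

`pathlatent` treats chemistry as vector arithmetic in a fixed-dimension
latent space. An embedding backend maps a compound structure to two latent
vectors — a *tree* part capturing the coarse backbone and a *graph* part
capturing the full connectivity, mirroring the two encoders of junction-tree
generative models — and, when it can decode, maps latent vectors back to
structures. On top of that contract the package builds three layers:

1. **Representation.** An enzymatic reaction is its main substrate/product
   pair only (cofactors and co-substrates are deliberately ignored), and is
   represented by the difference vector `r = z_pro − z_sub`, stored with its
   EC number in a `ReactionFeatureDB`. The additive structure is the whole
   point: applying a reaction to any substrate is `z + r`, and a chain of
   reactions is a sum. The registered molecular-weight change
   `ΔMW = MW(pro) − MW(sub)` is stored alongside as a cheap physical
   invariant of the transformation.

2. **Design.** A query is the difference `p = z_target − z_start`. Candidate
   pathways are subsets of registered reaction vectors whose sum
   approximates `p` within `|e| ≤ Th`, with at most `K` reactions. The
   search repeats: draw a uniform random subset of `M` reaction features,
   select within it by binary differential evolution, enumerate all
   orderings of the selected set, reconstruct intermediates by cumulative
   sums and decoding, and prune orderings whose decoded per-segment ΔMW
   contradicts the registered ΔMW of the segment's reaction by more than a
   tolerance (±3 u). The subset indirection bounds the DE search space; its
   price is that a pathway can only be found when all of its reactions land
   in the same subset — which is why recovery degrades sharply with pathway
   length (the inclusion probability is hypergeometric in `M` and decreases
   geometrically with the number of required reactions).

3. **Scoring.** Latent arithmetic happily produces transformations no enzyme
   performs, so surviving candidates are scored by an ensemble of Q × R
   small binary classifiers. Each sees `[r ‖ z_sub,tree ‖ z_sub,graph]` —
   the reaction vector *and* the substrate, because plausibility depends on
   substrate specificity, not on the transformation alone. The voting
   average of hard 0/1 outputs is the per-segment possibility `v_r`; the
   pathway feasibility is `v_p = Π v_r` (never increasing with length); the
   final rank is by `s = |e| / v_p`, ascending.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `F`, `CR` | 0.5, 0.5 | DE mutation scale and crossover rate |
| `population` | 2000 | DE individuals per subset |
| `maxGenerations` | 50 | DE generation budget |
| `subsetSize` (M) | 500 | reactions drawn per repetition |
| `K` | 3 | maximum reaction steps per pathway |
| `Th` | 50 | residual threshold on `|e|` (latent units) |
| `C` | 1000 | over-length penalty constant |
| `repetitions` | 2000 | subset/DE repetitions per query |
| `mwTolerance` | 3 | allowed decoded-vs-registered ΔMW deviation (u) |
| ensemble `Q`, `R` | — | datasets × CV folds; models = Q·R |
| hidden widths | 64, 32, 8 | per-model architecture (ReLU, sigmoid out) |

The defaults above are the method's full-scale operating point. Desk-scale
analyses in the tests and the acceptance script shrink the *sizes*
(population 30–80, subsets of 8–40 from DBs of ~90–1000 reactions,
repetitions 10–30) but never the *rules*: thresholds, penalty, tolerance and
the algorithms themselves are identical at every scale. Problem sizes used
by each desk-scale study are stated where they run (test files, acceptance
script); they were chosen so each study reads clearly as a scaled instance
of the same design.

# The toy chemistry: what it emulates, what it does not

The shipped backend (`ToyChemistry`) replaces a trained molecular
autoencoder with an exactly linear one. A compound is a non-negative integer
vector of fragment counts; encoding multiplies by a fixed full-rank
orthonormal-column mixing matrix; molecular weight is the exact dot product
of counts with fragment masses; decoding maps a latent through the
pseudo-inverse and returns the nearest universe compound in count space,
ties broken by lowest compound id. Consequences worth knowing:

* **Exact arithmetic.** `decode(encode(c)) = c` on the whole universe, and a
  planted pathway's reaction vectors sum to its query vector with `|e| = 0`.
  This makes every algebraic claim in the pipeline testable to machine
  precision — which is precisely why the backend exists.
* **Sparse compositions.** `simulateUniverse()` draws compounds with only a
  few active fragment types. Valid compounds therefore occupy a thin region
  of latent space, and arithmetic over mismatched substrate/product pairs
  tends to leave it — the toy analogue of latent points that decode to
  chemically meaningless structures. The four-recipe possibility ordering
  (below) relies on this manifold structure, as it does in real chemical
  latent spaces.
* **Class-clustered reactions.** Each synthetic 3-digit EC class is a base
  fragment-count change plus small integer within-class noise, with classes
  paired under shared 2-digit prefixes. `classSeparation` scales the base
  changes; at 0 the classes coincide and EC classification drops to chance —
  a built-in negative control.
* **What it does not emulate.** Encoder noise and reconstruction failure
  (real decoders fail on a large fraction of inputs; the toy decoder never
  fails, so the decode-failure pruning path is exercised only by constructed
  tests), non-linearity of real embeddings (real reaction vectors are only
  approximately transferable between substrates), stereochemistry, and the
  sheer size of real compound space. Passing tests therefore demonstrate the
  *algorithms* are correct and the *statistical design* behaves as claimed —
  not that any particular real embedding is good enough.

# The four-recipe training scheme

The ensemble's negative data are constructed, not observed. Two binary
attributes define four recipes: is the substrate/product *pair* registered,
and is the attached *substrate* the one that formed the pair. Real
(pair registered, substrate in, label 1) is the positive class; Virtual-1
(real pair, substrate out), Virtual-2 (random pair, substrate in) and
Virtual-3 (random pair, substrate out) are negatives probing the two
attributes separately. Models trained against different negative types learn
different discriminators, and the voting ensemble therefore grades partial
realism instead of rejecting it: examples sharing one attribute with the
positives collect votes from the models blind to that attribute. The
expected signature is the strict ordering

    Real/in  >  Real/out  >  Virtual/in  >  Virtual/out

of mean possibility values, with Real/in near 1 and Virtual/out near 0. The
desk-scale replication (5 master seeds, 1,000 reactions, Q = 6, R = 5,
virtual datasets of 1,000) reproduces this ordering on every seed; the two
extreme means are recomputed by `scripts/acceptance.R`. The real:virtual
ratio per combined dataset is kept near 1:1, matching the full-scale
design's balance; training uses class-weighted cross-entropy and per-model
input standardization, which are training configuration, not method claims.
Possibility summaries can be computed both on the training examples
themselves and on freshly drawn held-out examples; the package reports
whichever the caller supplies, and the acceptance script labels its choices
(real-pair means are on the registered reactions themselves, virtual-pair
means on held-out draws).

# Numerical and algorithmic choices

* **Over-length penalty.** The printed form of the penalty is ambiguous
  between `C·(e^xlen)²` and `C·e^(xlen²)`. The package uses
  `C·e^(2·xlen)` (the left-to-right reading) as the default and isolates the
  choice in one function with the alternative behind
  `penaltyForm = "exp-of-square"`. Both grow fast enough that selections
  longer than `K` never win; nothing downstream depends on the choice.
* **Score direction.** The score combines `|e|` and `v_p`; the package uses
  `s = |e| / v_p` so that lower is better and feasibility is rewarded — a
  product would rank infeasible pathways best. The product reading is
  available behind `scoreForm = "product"`. `v_p = 0` gives `s = ∞`,
  ranked last; ties on `s` break by higher `v_p`.
* **Binary DE details.** Individuals are initialized with 1..K selected
  reactions; parents `a, b, c` are mutually distinct and distinct from the
  current individual; mutants binarize at exactly 0.5 (`v ≥ 0.5 → 1`);
  crossover is uniform at rate `CR` with one guaranteed mutant component
  (`guaranteedMutant = FALSE` restores the plain loop); replacement is
  strictly greedy, so the best-fitness trace never increases; runs may stop
  early once the best residual satisfies `|e| ≤ Th` within the step budget.
  On small instances (M ≤ 15, K ≤ 3) the selection is verified against
  exhaustive enumeration of all `Σ_{k≤K} C(M,k)` selections.
* **Integer selection.** The objective formally admits using a reaction
  several times (`x_i ∈ {0..K}`); the printed algorithm is binary, and the
  package implements the binary form only.
* **Decoding ties and failures.** Toy decoding breaks exact ties by lowest
  compound id (determinism for tests). An undecodable segment endpoint makes
  the MW rule unevaluable, so the pathway is removed with reason
  `decode-failure` rather than silently kept.
* **Distances.** Nearest-reaction queries use Euclidean distance, consistent
  with the squared-error design objective; ties keep DB order.
* **Seeds.** Every stochastic stage takes an explicit seed; master seeds
  derive per-repetition and per-model streams, and callers' RNG state is
  never disturbed. All derived seeds stay below 2³¹.
* **LDA evaluation.** The EC-classification evaluation uses stratified
  cross-validation (default 5-fold) since resubstitution flatters LDA;
  `folds = 1` gives resubstitution for comparison. Classes need more than
  one member to enter; constant latent coordinates are dropped before the
  fit; the LDA tolerance is lowered to 1e-10 because exactly-linear toy
  vectors are rank-deficient by construction. Default priors
  (class proportions) and no shrinkage are used.
* **Part defaults.** Pathway design uses tree-part vectors (the backbone
  signal is what EC classes share); ensemble inputs use combined-part
  reaction vectors plus both substrate parts. The toy backend exposes the
  same latent under both parts unless built with `splitParts = TRUE`;
  part-contrast tests construct DBs with signal confined to the tree block.

# Known limitations

* Recovery of pathways with three or more steps is structurally hard for
  the subset method (all reactions must co-occur in one random subset); the
  tests assert it is possible, not frequent. Clustering the reaction DB or
  multi-step search would be the natural extension.
* The ensemble judges single segments independently; feasibility multiplies
  them and cannot model inter-segment dependencies (e.g. an intermediate
  that inhibits the next enzyme).
* The toy universe's possibility ordering replicates the qualitative
  structure of the full-scale result, not its exact values; only the two
  extreme means are held to their reference magnitudes.
* No real-chemistry backend ships with the package; the `EmbeddingBackend`
  contract (encode, decode, dimensions, capability flags) is the seam where
  a trained encoder/decoder would plug in.

# A complete run at desk scale

```{r example, eval = FALSE}
sim <- simulateUniverse(nCompounds = 60, nReactions = 90, nEcClasses = 4,
                        nFragments = 6, latentDim = 6, seed = 401)
db  <- buildReactionDB(sim$records, sim$backend, part = "tree")

real <- buildVirtualDataset(db, sim$backend, "REAL", seed = 51)
virt <- lapply(1:3, function(q) buildVirtualDataset(db, sim$backend,
          c("VIRTUAL1", "VIRTUAL2", "VIRTUAL3")[q], nRecords = 60,
          seed = 51 + q))
model <- trainEnsemble(real, virt, R = 2, seed = 52, epochs = 20,
                       hidden = c(16L, 8L))

m   <- sim$manifest[[2]]     # planted 2-step query
cfg <- deConfig(population = 30, maxGenerations = 25, subsetSize = 40,
                K = 2, Th = 1e-6, repetitions = 10, seed = 17)
res <- explore(sim$backend, sim$records, m$startId, m$targetId, cfg,
               model = model, db = db)
res$report
```
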