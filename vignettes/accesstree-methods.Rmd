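---
title: "Phylogenetic analysis of binary chromatin accessibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic analysis of binary chromatin accessibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accesstree)
```

## The problem

During hematopoiesis, a stem cell (LSK) differentiates through progenitors
(CMP, then GMP and MEP) into terminal blood cell types. Chromatin
accessibility — whether a candidate cis-regulatory element (cCRE) is open
(1) or closed (0) to nuclease/transposase attack — changes along this
process and is somatically heritable, which makes it usable as a
phylogenetic character: each cCRE is one binary "site", each cell type one
"taxon". `accesstree` implements the full analysis this view enables:

1. classify each site's time course along each differentiation path
   (STABLE / UP / DOWN / OTHER);
2. infer cell-type trees from the binary matrix (NJ on raw pairwise
   character differences, exhaustive or heuristic maximum parsimony,
   maximum likelihood under two-state models with rate heterogeneity and
   AIC model choice, bootstrap supports);
3. reconstruct the open/closed states of internal nodes — the putative
   progenitors — by ACCTRAN/DELTRAN parsimony and by marginal likelihood
   on a fixed outgroup-rooted topology;
4. validate predictions against observed progenitor profiles
   (sensitivity/specificity with open as the positive class) and measure
   treelikeness with quartet delta scores.

Because the package is exercised on simulated data, a seeded generator
(`simulate_accessibility()`) produces matrices with known ancestral states
and site classes; every downstream stage can therefore be tested against
ground truth.

## Site classification

Along one stem-to-terminal path, a site is `STABLE` if its state never
changes, `UP` if it is monotone non-decreasing with at least one change,
`DOWN` for the mirror image, and `OTHER` otherwise. "Gradually open" is
formalised as monotone with a single 0→1 transition point — the only
reading consistent with binary data, and the reason a two-step path
(the lymphoid lineages, whose progenitor profiles are unobserved) can
never be OTHER. Across paths the summary label has precedence
OTHER > mixed direction > STABLE: a site OTHER on any path is OTHER
overall, one stable everywhere is STABLE, and anything else records the
set of directions seen (`UP`, `DOWN`, `UP+DOWN`; with a shared stem cell
a pure matrix can only show one direction per site, but custom paths may
mix them). The derived masks (`other_site_mask()`,
`stable_everywhere_mask()`) drive the two standard filters: dropping
OTHER sites before tree inference, and dropping stable-everywhere sites
before computing sensitivity/specificity, where they would otherwise
inflate specificity without carrying any signal.

## The two-state substitution model

Maximum-likelihood stages use a reversible two-state model with free
stationary frequencies $\pi = (\pi_0, \pi_1)$ and rate matrix

$$Q = \beta \begin{pmatrix} -\pi_1 & \pi_1 \\ \pi_0 & -\pi_0 \end{pmatrix},
\qquad \beta = \frac{1}{2\pi_0\pi_1},$$

normalised so one unit of branch length is one expected change per site.
The transition probability has the closed form
$P_{ij}(t) = \pi_j + (\delta_{ij} - \pi_j)e^{-\beta t}$. Among-site rate
variation is a finite mixture: an invariant class with proportion
$p_{inv}$ at rate 0, plus either a single rate (`BIN`, `BIN+I`), a
4-category discrete gamma with shape $\alpha$ (`BIN+I+G`, mean-rate
discretisation with equal category weights), or $n$ free rates with free
weights (`BIN+I+R4/R8/R12`). All categories are rescaled so
$(1-p_{inv})\sum_k w_k r_k = 1$, i.e. the expected rate over all classes
including the invariant one is 1; this keeps branch lengths comparable
across models. A per-site likelihood is

$$L_i = p_{inv}\,[\text{site constant}]\,\pi_{s_i} +
  (1-p_{inv})\sum_k w_k\, L(\text{pattern}_i \mid r_k t),$$

computed by Felsenstein pruning over compressed site patterns.

Fitting (`ml_fit()`) holds the topology fixed and alternates bounded
line searches on each branch length (bounds $[10^{-8}, 100]$, optimised
on the log scale) with joint Nelder–Mead optimisation of the model
parameters on unbounded transforms, accepting only improvements, until
the log-likelihood gains less than `tol` (default $10^{-6}$) in a sweep
or `max_iter` (default 100) sweeps elapse; non-convergence yields a
warning and the best-so-far fit, flagged in the result. $p_{inv}$ is
initialised at (slightly below) the constant-site fraction — its MLE
upper bound, and the value the estimate keeps in the degenerate
all-constant case where $p_{inv}$ is otherwise unidentifiable. Warm-start
branch lengths on an implausible scale (raw difference counts from an NJ
tree) are rescaled to per-site units. For a rooted topology the two root
branches are tied, since only their sum is identifiable under a
reversible model; the free branch-length count is $2n-3$ for every
topology and model, so AIC $= 2k - 2\ln L$ comparisons are valid, with
$k$ counting frequencies (1), $+I$ (1), $+G$ (1), $+R_n$ ($2n-2$) and
branch lengths. `select_model_aic()` fits all six families and returns
the lowest-AIC fit with the full table. The AIC values follow this
package's normalisation conventions and are internally comparable, though
not bit-identical to any external tool.

## Tree inference

`pairwise_differences()` counts raw character mismatches — deliberately
uncorrected, as the analysis treats the count itself as the distance.
`nj_tree()` wraps the Saitou–Nei agglomeration and clamps negative branch
estimates to zero, recording how many were clamped. `mp_exhaustive()`
enumerates every unrooted binary topology by stepwise leaf insertion
(each tree on $n+1$ taxa arises exactly once from one of the $2n-3$
branches of a tree on $n$), scores each with a vectorised Fitch pass over
compressed patterns, and returns the minimum with *all* co-optimal
topologies — ties are surfaced, not broken. The enumeration cap defaults
to 10 taxa ($(2n-5)!! \approx 2\times 10^6$); beyond it `mp_search()`
and `ml_search()` hill-climb with nearest-neighbor interchanges from the
NJ starting tree, accepting only score improvements, with an exhaustive
ML mode for up to 8 taxa. Bootstrap supports resample sites with
replacement from a single seeded stream, re-infer each replicate, and
report per-branch split frequencies on the point-estimate tree;
replicate trees are not retained.

## Ancestral reconstruction

On the fixed constraint topology — the known myeloid hierarchy joined to
the consistently inferred lymphoid topology (B,((TCD4,TCD8),NK)), rooted
on the LSK outgroup — ancestral states are estimated three ways.
ACCTRAN and DELTRAN both refine the Fitch downpass into a single
minimum-change labeling: ACCTRAN keeps the parent state whenever the
child's downpass set allows it, pulling changes toward the root (early
gain followed by loss); DELTRAN selects within the MPR (uppass) sets,
delaying changes toward the tips (parallel late gains). When the root
set is ambiguous it is resolved toward the outgroup-side state — the
outgroup is observed precisely to polarise changes. Both labelings
always realise the per-site Fitch score, which the tests verify against
brute-force enumeration of all optimal labelings.

ML marginals combine below-likelihoods (pruning) with above-likelihoods
in a preorder pass and mix rate categories — including the invariant
class — by their per-site posterior weights, yielding
$P(\text{open} \mid \text{leaves})$ for every internal node and site.
`call_states()` calls the larger marginal, treating exact ties
(within $10^{-9}$ of 0.5) as ambiguous; a threshold mode (ambiguous when
the winning marginal is below a cutoff) is available for sensitivity
analysis, since the external tool the analysis emulates does not document
its ambiguity rule. Branch lengths and model parameters for the
constraint tree are fitted from the terminal + stem profiles only; the
observed progenitor columns are held out for validation, mirroring the
design of predicting progenitors from differentiated cells.

## Validation and treelikeness

`sensitivity_specificity()` compares calls with the observed progenitor
profile, open = positive. Ambiguous calls and stable-everywhere sites are
removed first; a site qualifying for both is removed once and reported
separately, so `n_evaluated + n_removed_ambiguous + n_removed_stable`
always equals the site total. Empty denominators yield `NA`, never a
silent 0/0. Quartet delta is $(m_1-m_2)/(m_1-m_3)$ on the sorted pairwise
distance sums of a quartet, 0 for additive (treelike) distances and 1 for
maximal conflict; $m_1=m_3$ is defined as 0 for continuity with the
perfectly treelike case. `delta_scores()` returns the full per-quartet
distribution with the group mean as an attribute — no single scalar is
privileged, since distributions are what the comparison plots.

## The simulator

`simulate_accessibility()` is the package's study design. Sites are drawn
from five generating classes: constant open/closed; UP (root closed, one
0→1 gain on a branch chosen uniformly at random — no branch-length
information exists in the known hierarchy, so uniform is the neutral
choice — inherited by the whole clade, no reversals); DOWN (mirror); and
OTHER (random root state, independent per-branch flips with probability
`other_flip_rate`, rejection-sampled until the realised pattern is
genuinely non-monotone on at least one path). Single-event UP/DOWN sites
make ancestral states analytically recoverable, so recovery tests have an
exact oracle; rejection sampling guarantees OTHER sites carry real
homoplasy. The default class mix (7% stable open, 43% stable closed, 10%
UP, 10% DOWN, 30% OTHER) loosely follows the reported per-lineage ranges
for such data (UP roughly 5–14%, DOWN 8–22%, OTHER 27–34% in myeloid
lineages, with constant sites dominating the remainder); these are
figure-level approximations, not a calibration, and the flip rate default
of 0.15 per branch simply produces accepted OTHER sites at a practical
rate. Observed columns are the stem, the myeloid progenitors and the
terminals; lymphoid progenitors are simulated but unobserved, as in the
real panel, and appear only in the truth tables.

What the generator does *not* emulate: continuous accessibility signal
and peak-calling noise, linkage between neighbouring cCREs (sites are
independent), branch-length heterogeneity in event placement, and
population heterogeneity within a sorted cell type. Passing recovery
tests therefore demonstrates correctness of the algorithms under the
binary, site-independent model — not that real chromatin data meet those
assumptions.

The default hierarchy keeps the lymphoid node as a trifurcation
(B, (TCD4,TCD8), NK): the data cannot polarise that node, and
`generating_topology()` preserves the polytomy when building the
reference topology (stem attached as a leaf). A fully binary estimate
therefore has a Robinson–Foulds floor of 1 against the default truth —
recovery tests that demand RF 0 use a binary generating tree instead.

## Numerical choices and limitations

* Pattern compression makes all likelihood and parsimony passes scale
  with the number of distinct site patterns, not sites.
* Likelihoods are computed without log-scaling of partials; with at most
  a dozen taxa this stays far from underflow.
* Parameter transforms are clamped (frequencies to $[10^{-6},
  1-10^{-6}]$, $p_{inv} \le 0.999$, rates to $[10^{-6}, 10^3]$) so
  optimisers can roam the unbounded scale safely.
* Coordinate ascent is monotone but local; `ml_fit` reports sweep counts
  and a convergence flag, and `ml_search` refits candidates with a small
  sweep budget during the climb.
* MP ties are all returned; bootstrap and NNI searches take the first
  optimum in canonical order, so runs are deterministic given a seed.
* The problem sizes exercised by the test-suite and the acceptance script
  (thousands of sites, up to twelve taxa, hundreds of bootstrap
  replicates) were chosen as comfortably sufficient for the binary
  characters at hand: with at most $2^{12}$ possible patterns, more sites
  only sharpen frequencies that are already stable.

## A short tour

```{r tour, eval = FALSE}
sim <- simulate_accessibility(n_sites = 2000, seed = 1)
cls <- classify_sites(sim$matrix)
autoplot(cls)

x9 <- subset_cells(sim$matrix, constraint_tree()$tip.label)
nj <- nj_tree(pairwise_differences(x9))
rf_distance(nj, generating_topology(sim, taxa = constraint_tree()$tip.label))

fit <- ml_fit(constraint_tree(), x9, "BIN+I")
glance(fit)
pred <- progenitor_states(call_states(ml_marginals(fit, x9)), tree = fit$tree)
evaluate_progenitors(pred, sim$matrix,
                     exclude_stable = stable_everywhere_mask(cls))
```

Or run everything at once from one seeded configuration:

```{r pipeline, eval = FALSE}
report <- run_analysis(run_config(sim = list(n_sites = 2000),
                                  methods = c("nj", "mp", "ml"),
                                  seed = 1))
report
```
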