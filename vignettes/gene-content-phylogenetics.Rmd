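---
title: "Gene-content and morphological phylogenetics with ascertainment-corrected models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-content and morphological phylogenetics with ascertainment-corrected models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcphylo)
```

## The problem

Deep animal relationships are contested because different data types and
models favour different topologies. One line of evidence is *genome gene
content*: whether a gene family is present or absent in each genome. Two-level
clusterings of proteomes produce **homogroups** (whole homologous families)
and **orthogroups** (orthologous subfamilies); coding presence/absence of
either yields a binary taxa-by-characters matrix. Because families observed in
fewer than two or more than N−2 species cannot enter such a matrix (singletons
are removed, near-universal families carry no grouping signal and are filtered
the same way), the data are *ascertained*: the likelihood must condition on a
character being observable, or inference is biased.

`gcphylo` implements this pipeline end to end: cluster-file parsing and binary
coding, the observability filter, a reversible binary substitution model with
exact window conditioning, the Mk model family for discrete morphology with
two ascertainment corrections, a native MCMC sampler over topologies, branch
lengths and model parameters (with linked multi-partition "total evidence"
models), convergence diagnostics, majority-rule and Total Posterior Consensus
Trees (TPCT), and posterior-odds topology tests. A synthetic-data module
generates trees, gene-family clusterings and morphological matrices with the
statistical structure the inference assumes, so every stage is testable
without any external downloads.

## The binary substitution model and its ascertainment correction

Presence/absence evolves as a two-state reversible CTMC with stationary
frequencies $(\pi_0, \pi_1)$, normalised so one unit of branch length is one
expected change at stationarity, giving $\mu = 1/(2\pi_0\pi_1)$ and

$$P_{01}(t) = \pi_1(1 - e^{-\mu t}), \qquad P_{10}(t) = \pi_0(1 - e^{-\mu t}).$$

Pattern likelihoods use Felsenstein pruning from an arbitrary rooting
(reversibility makes the root placement irrelevant; this is tested). The
correction divides each character's likelihood by the probability that a
character falls inside the observability window $[m_\min, m_\max]$ (default
$[2, N-2]$). That probability comes from a pruning-style dynamic program over
(node state, number of 1-tips below the node), children combined by
convolution — exact in $O(N^2)$ per rate category, verified against full
$2^N$ enumeration. With discrete-gamma rate variation, the per-character
numerator and the window probability are each averaged over categories before
the division, i.e. the latent rate category is shared by the pattern and its
observability.

Two design points deserve emphasis:

* **The conditioning matches the data filter exactly.** We condition on the
  full $[2, N-2]$ window rather than a variable-sites-only (Mkv-style)
  approximation, because the filter removes both tails; consistent
  conditioning is required for unbiasedness.
* **Direction of the bias.** On data simulated under the model and filtered
  to the window, maximum-likelihood branch lengths under the *corrected*
  likelihood are unbiased within Monte-Carlo error, while the *uncorrected*
  fit is systematically inflated — window-conditioned data look more variable
  than any short tree predicts, and in extreme cases the uncorrected
  likelihood increases monotonically in tree length (iid-stationary tips fit
  the filtered patterns well). The acceptance suite reproduces both facts.

## The morphological model grid

Morphology uses the Mk family (equal exchangeabilities, $k$ states, unit
expected rate). The model grid crosses

* two **ascertainment corrections**: `variable_only` (constant characters
  unobservable — the Mkv assumption) and `parsimony_informative_only`
  (constants and autapomorphies unobservable). The second conditions on
  fewer than $N-1$ tips sharing a background state, computed per background
  state with a capped two-class count dynamic program; constant patterns are
  counted once. For $k \ge 3$ this autapomorphy rule is deliberately weaker
  than strict parsimony informativeness (a pattern like 0,0,0,1,2 counts as
  observable) — it is the natural generalisation of "autapomorphies were
  removed", and the matrix filter uses the same rule so data and conditioning
  agree.
* two **branch-length priors**: i.i.d. Exponential with fixed mean 0.1
  changes per character per branch, or a hierarchical prior
  $t_i \sim \text{Exp}(m)$, $m \sim \text{Exp}(0.1)$ — the simplest
  hyperprior consistent with a hyperprior-on-lengths design (a package
  choice).
* two **rate models**: equal rates, or four equal-weight discrete-gamma
  categories (bin means in closed form; shape $\alpha$ sampled with an
  Exponential(1) prior).
* three **frequency models** for binary characters: homogeneous (0.5, 0.5)
  or a symmetric Beta($\beta$, $\beta$) mixture with 4 or 5 categories at the
  equal-probability bin medians, weights $1/C$; $\beta$ is sampled with an
  Exponential(1) prior. Characters with $k \ge 3$ always use equal
  frequencies. The bin-median discretisation is a stated stand-in for the
  underlying continuous mixture; its two printed sanity points
  ($\beta = 1, C = 5 \Rightarrow \{0.1, 0.3, 0.5, 0.7, 0.9\}$; $\beta \to
  \infty \Rightarrow$ all 0.5) are tested.

That is $2 \times 2 \times 2 \times 3 = 24$ models per dataset;
`morph_model_grid()` enumerates them, and with the ten standard datasets the
grid has 240 analyses. Both `?` (missing) and `-` (inapplicable) are
marginalised in the likelihood; reductive-coding semantics live in the data,
not the model.

## The MCMC sampler

`run_mcmc()` is a single-chain Metropolis–Hastings sampler over unrooted
binary topologies, branch lengths and model parameters. One **generation** is
a weighted sweep of proposals (default: the sum of the move weights, so each
registered move fires about once per generation) — generation semantics are
engine-specific across phylogenetics software, and this is the package's
stated convention. Moves:

* **NNI** on a uniformly chosen internal edge (symmetric);
* **SPR**: a uniformly chosen (edge, orientation) pair with an internal
  attachment node is pruned and regrafted at a uniform position on a
  uniformly chosen remaining edge; the Hastings ratio reduces to
  `len(target)/len(merged)` because the candidate counts are equal in both
  directions;
* a single-branch **multiplier** with tuning constant $\lambda = 2$;
* parameter moves: reflected slide for $\pi_1$ (uniform prior), multipliers
  for $\alpha$, $\beta$, the hierarchical mean and partition rate scalers,
  each with the $\log f$ Hastings term.

Default mix NNI:SPR = 5:1; all weights are configurable. Proposal and
Hastings correctness is validated by prior-only sampling (branch-length mean
recovered within 2%) and by matching a four-taxon posterior against
exhaustive quadrature over a branch-length grid. Replicates (default four) are
reproducible from `derive_seed(seed, "replicate-r")`; burn-in defaults to 25%
(a configurable package choice recorded on every config). Metropolis coupling
is deliberately out of scope — replicate single chains with more generations
are used instead.

The binary-partition likelihood inside the sampler runs through a small C++
kernel (pruning over a compressed pattern bank plus the count dynamic
program); the reference R implementation of the identical algorithm is kept,
tested against enumeration, and the two are asserted to agree to $10^{-10}$.

For linked multi-partition ("total evidence") models, all partitions share
the topology and branch lengths; every partition after the first carries a
rate scaler with an Exponential(mean 1) prior (fixed to 1 on request). With
the scaler fixed and identical partitions, a two-partition run is
bit-identical to the concatenated single-partition run.

## Consensus, TPCT, and hypothesis tests

`bipartition_frequencies()` pools post-burn-in samples (each unrooted tree
contributes each internal bipartition once); `majority_consensus()` keeps the
strictly-greater-than-0.5 set — always mutually compatible — and collapses
the rest into polytomies, with clade posterior probabilities equal to pooled
frequencies exactly. `tpct()` applies the same pooling across *all* traces
sharing a taxon set, regardless of the dataset parameters that produced them
(E-value, inflation, coding level): the Total Posterior Consensus Tree.
Pooling weighs traces by their sample counts (plain concatenation), matching
a pool-all-samples design; provenance records per-trace counts, and passing
equally thinned traces gives an equal-weight-per-dataset summary. Convergence
screening before pooling is the caller's decision via the ESS (> 300) and
maxdiff (< 0.3) diagnostics — the package computes and flags both but does
not silently exclude runs.

Hypothesis tests classify each pooled sample against two topological
constraints after rooting on a declared outgroup (monophyly, sister group,
paraphyly), and report posterior fractions $p_0, p_1$, posterior odds
$p_0/p_1$, the natural-log odds, and the support category at the thresholds
lnPO > 1 / 3 / 5 (substantial / strong / very strong), under equal prior
odds. Samples matching neither hypothesis count toward neither fraction (the
renormalised fraction is also reported); a zero count yields infinite odds
plus a continuity-corrected bound $\ln((n_i + 0.5)/0.5)$. Classification on
pooled samples uses the cached bipartition sets; a property test asserts
exact agreement with the root-and-check-clades definition.

## The synthetic-data generators

The generators define the study conditions under which the machinery is
validated; their defaults are fixed once:

* **Trees**: uniform unrooted topologies, i.i.d. Exponential branch lengths
  with mean 0.1 changes per character — the same scale as the inference
  prior.
* **Binary matrices**: characters evolved independently under the binary
  CTMC (root at stationarity), then filtered with the observability window
  downstream, exactly as real matrices are built.
* **Gene families**: presence patterns either evolve from the root under the
  reversible model (`root_only`) or originate once on a uniformly chosen
  branch with reversible loss below it (`along_branches`, a Dollo-like
  surrogate that lets tests probe model misspecification). Each family splits
  into $1 + \text{Poisson}(g-1)$ orthogroups — so $g = 1$ degenerates to one
  orthogroup exactly — and each orthogroup thins the family pattern with
  independent per-species losses. The granularity knob $g$ emulates MCL
  inflation; per-species gene identifiers (`species|family.orthogroup`) are
  emitted for every presence, and families left unobserved are dropped, as
  in real clusterings. Ab-initio regeneration on a reduced taxon set re-draws
  the splitting under a seed derived from (seed, retained species), so the
  full-set regeneration is bit-identical to the original — this is what lets
  the pruning and ab-initio strategies be contrasted on one simulation.
* **Morphology**: Mk evolution with per-character state counts drawn from a
  configurable distribution, optional per-character binary frequencies from
  Beta($\beta$, $\beta$), missing-cell masking, and inapplicable blocks
  assigned to a random clade.

What the generators do *not* emulate: real proteome sizes, similarity-search
(E-value) behaviour, sequence evolution, correlated characters, and
gene-family birth rates estimated from data — the generative process of real
gene content is unknown, and the origination modes are surrogates, not claims
about any real dataset. Passing recovery tests therefore shows the inference
machinery is internally correct and well calibrated under its own model, not
that the model is adequate for real genomes.

## Numerical choices and degenerate inputs

* Likelihoods are computed in log space with per-node rescaling in the R
  reference implementation; the C++ kernel omits rescaling, which is safe at
  the moderate taxon counts of gene-content matrices and asserted against
  the R path. Oracle comparisons use a $10^{-10}$ relative tolerance.
* Zero-probability situations surface as errors, not silent `-Inf`:
  a window with zero probability, an ascertainment probability of zero
  (e.g. a zero-length tree under `variable_only`), characters that violate
  the ascertainment assumption (constants under Mkv; constants or
  autapomorphies under the parsimony-informative correction — drop them
  first with `filter_morph_characters()`).
* The observability filter warns and returns an explicitly empty matrix
  (class `gc_empty_matrix`) when nothing survives; pruning below four taxa
  is an error; ties at 0.5 are excluded from consensus trees (strict
  majority).
* Per-character state counts are `max(observed state) + 1` with a floor of
  two; `?` and `-` are both fully ambiguous in the likelihood.
* `fit_branch_lengths()` optimises log branch lengths with box constraints
  (lengths in `[1e-8, 100]`), which keeps the deliberately misspecified
  uncorrected fit finite when its likelihood increases monotonically in tree
  length.
* Exponential branch lengths occasionally draw internal edges of ~10⁻³
  expected changes that no realistic character count can resolve; the
  acceptance script therefore redraws its recovery tree until every internal
  edge is at least 0.01 expected changes, so the reported recovery summarises
  the estimator rather than one unresolvable draw. (The test suite's recovery
  experiment uses the plain generator draw.)

## Problem sizes used in the validation suites

The test and acceptance suites run, by choice, at sizes where the checks are
sharp but cheap: enumeration oracles up to $N = 8$ taxa ($2^N$ or $3^N$
patterns), the ascertainment-bias experiment at 8 taxa and 3,000 characters
over several replicates, topology recovery at 8 taxa with 5,000 filtered
characters and four replicate chains of 20,000 sweep-generations, and the
24-model morphology grid at 12 taxa and ~120 characters with short chains.
At these sizes the recovery run reports every true split at posterior
probability ≥ 0.95, replicate maxdiff < 0.3 and log-likelihood ESS > 300 —
the conventional convergence thresholds.

## Known limitations

* Single-chain kernels only; no Metropolis coupling or parallel tempering.
* The Dollo-like origination is simulation-only; there is no Dollo
  likelihood.
* The symmetric-mixture discretisation (bin medians) and the hierarchical
  branch-length hyperprior are stated package choices; other discretisations
  and hyperpriors exist.
* The posterior-odds machinery assumes equal prior odds and reports
  sample-fraction estimates; it is not a marginal-likelihood (Bayes factor)
  method.
* Consensus trees carry posterior probabilities but not branch lengths.
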