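---
title: "Modelling convergent gene loss and domain decay on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling convergent gene loss and domain decay on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genestream)
```

## The scientific problem

When two distantly related bacterial lineages converge on the same reduced
gene repertoire — as the two fructophilic Lactobacillaceae clades
(*Apilactobacillus*- and *Fructobacillus*-like lineages) do in fructose-rich
niches — two questions arise. Did they lose the *same* genes, and did they
lose them in the *same order*? A "stream" model of convergence predicts
similar loss orders (constrained paths); a "funnel" model predicts arbitrary
orders toward the same endpoint. A parallel question arises one level down:
when a two-domain gene such as the bifunctional
aldehyde/alcohol dehydrogenase (AdhE, an N-terminal ALDH domain fused to a
C-terminal ADH domain) decays, does the decay repeatedly pass through the
same single-domain intermediate, and do the surviving fragments accumulate
substitutions at predictable structural positions?

`genestream` implements the full analysis chain for these questions on a
fixed rooted species or gene phylogeny, together with a synthetic-data
module that generates every input with known ground truth, so the chain is
testable end to end without any external downloads.

## Ancestral gene content under the binary Mk model

Gene presence/absence of one ortholog group (OG) evolves as a two-state
continuous-time Markov chain with gain rate $q_{01}$ and loss rate $q_{10}$
(rates per unit branch length). The likelihood of a presence/absence profile
is computed by Felsenstein pruning (`mk_loglik()`), with the transition
probabilities in closed form,

$$P_{11}(t) = \pi_1 + \pi_0 e^{-(q_{01}+q_{10})t}, \qquad
  \pi_1 = \frac{q_{01}}{q_{01}+q_{10}},$$

and missing tips treated as uninformative partial vectors. `mk_fit()`
maximises the pooled likelihood on the log-rate scale (L-BFGS-B, box
constraint rate $\ge 10^{-10}$; near-flat profiles are snapped to the
boundary so uninformative data yield boundary MLEs explicitly flagged).

Because a single binary character carries little information, ancestral
states are not taken from one point estimate. `mk_mcmc()` samples rate pairs
by random-walk Metropolis on log rates — initialised at the MLE, with
independent exponential priors of mean twice the MLE, burn-in 500 and
thinning interval 10 by default — and `ancestral_replicates()` runs a
maximum-likelihood *joint* reconstruction (`mk_joint()`, Pupko-style dynamic
programming with back-pointers; ties broken toward the lower state index and
flagged) under every sampled rate pair. Downstream statements are therefore
supported by a replicate fraction rather than a single reconstruction.
The root prior defaults to the stationary distribution of the rates in use,
with a flat prior available; the proposal and prior are documented here
precisely because reproducibility of a sampler requires stating them.

The engines are k-state generic (`ctmc_loglik()`, `ctmc_joint()`,
`ctmc_marginal()`), which serves both the 7-state domain-repertoire model
and the 20-state amino-acid reconstruction below. All of them are verified
against exhaustive enumeration over internal-node assignments on small
trees; the matrix exponential uses a spectral decomposition with a Padé
fallback and row renormalisation.

## Scenarios, loss branches and the loss-order statistic

Three focal ancestors anchor the convergence analysis: the last common
ancestor of both convergent clades (`LCAfa`) and of each clade separately
(`LCAa`, `LCAf`). Each replicate reconstruction assigns an OG a triplet of
presence bits at these nodes; `classify_scenarios()` tabulates the support
for the 8 triplets and calls the majority (ties broken toward more
presences, i.e. conservatively against inferring loss). OGs with majority
scenario `100` were present in the joint ancestor and independently lost on
both paths — the commonly lost set (`select_commonly_lost()`).

For each commonly lost OG, `assign_loss_branch()` scans the node states
along each root-to-clade path and lets every replicate with *exactly one*
presence-to-absence transition and no regain vote for its loss branch;
the plurality branch wins, with the vote fraction as support. Replicates
with zero or multiple losses or any regain abstain, because a loss branch is
well defined only under a single-loss scenario.

Loss-order similarity between the two lineages is

$$S = \frac{\#\{\text{OG pairs lost in the same order}\}}
           {\#\{\text{OG pairs lost in both lineages}\}},$$

where a pair counts as concordant iff the sign of the branch-rank difference
agrees between lineages; two OGs lost on the *same* branch in both lineages
(sign 0 vs sign 0) count as concordant, treating "same branch" as a genuine
order statement (an exclude-ties variant is available by flag). The null
distribution shuffles the OG-to-branch correspondence within each lineage
independently, preserving each lineage's multiset of branch labels and hence
its tie structure; `permutation_pvalue()` reports the plain ratio
$p = \#\{S' \ge S\}/n_{\text{perm}}$ (which may be exactly 0) plus an
add-one smoothed value. Companion summaries are the 2x2 overlap contingency
with Pearson's chi-square (`overlap_contingency()`), the branch-by-branch
Jaccard matrix (`branch_jaccard()`), and per-category mean loss timing with
rank concordance (`category_loss_timing()`), where timing is the 1-based
branch index along the path (a length-weighted variant is a documented
alternative, not the default, because the branch order — not duration — is
the quantity compared between lineages).

## Fragment classification and repertoire states

AdhE-derived genes are classified by position rules on a multiple sequence
alignment whose left block is the ALDH domain and right block the ADH
domain. With the full-scale defaults: candidate complete genes are 800-1000
aa (inclusive); homology hits qualify with identity and target coverage
strictly greater than 0.45; each half-alignment (first/last 500 columns)
excludes rows with strictly more than 50% gaps; and a row is `complete` iff
its non-gap length exceeds 800 *and* its center column (midpoint of first
and last non-gap columns, rounded half down) lies in 400-900, `ALDH_only`
iff the center is left of 400, `ADH_only` iff right of 900, `incomplete`
otherwise. Where the borderline conventions (inclusive bounds, strict
inequalities, center definition) were genuinely open we fixed them as above
and exposed the alternatives as arguments. Paralogs are removed by rooting
the gene tree on a designated outgroup and keeping the clade descending from
the most recent common ancestor of the known complete genes
(`exclude_non_adhe()`); sequence similarity networks at strict identity
thresholds (`build_ssn()`) provide an independent view of the same split.
`assign_repertoire()` maps each species' fragment multiset onto a 7-state
catalog (`none`, `1_complete`, `2_complete`, `1_ALDH`, `1_ADH`,
`1_incomplete`, `complete_plus_ALDH`), with explicit overrides for species
whose tandem fragments are known assembly artifacts; `mk_fit(k = 7)`
estimates all 42 transition rates of the repertoire chain by multi-start ML
(uniform 1/42 start plus a count heuristic and random restarts, because
42-parameter Mk likelihoods are multimodal).

## Fragment-specific substitutions and structural context

`marginal_asr_aa()` reconstructs ancestral amino acids of the domain
alignment on a fixed gene tree by up/down message passing under an
equal-exchangeability model with empirical stationary frequencies (an
F81-type closed form; a user exchangeability matrix upgrades it to GTR-type).
The gene tree's branch lengths are expected in substitutions per site, as
trees inferred from the alignment are. A residue is *called* at a node/site
iff its posterior exceeds 0.5 strictly — at most one residue can qualify —
otherwise the site is uncertain. `map_substitutions()` emits one event per
branch-site where both endpoints are known and differ (tips use observed
residues; gaps are missing data, not a 21st state; uncertain endpoints are
skipped and tallied, never imputed). A branch belongs to the fragment class
iff all its descendant tips carry fragments, stems included
(`fragment_branch_set()`). Sites substituted at least 5 times are scored by
the fraction of their events on fragment branches (`site_fragment_ratio()`),
the top 15 by ratio (ties: higher fragment count, then lower site index) are
reported (`top_sites()`), and site groups defined from structure —
inter-chain interface residues and ligand contacts by an inclusive 5
angstrom any-atom rule (`chain_interface()`, `ligand_contacts()`), mapped to
alignment columns through the reference row's non-gap positions
(`map_residues_to_msa()`) — are compared by two-sided Mann-Whitney tests on
ratios and counts (`group_enrichment()`).

## Statistical utilities

`chi_square()` is Pearson's test without continuity correction by default
(Yates by flag); `mann_whitney()` is exact for small tie-free samples and
tie-corrected normal otherwise; `phylogenetic_anova()` compares the observed
one-way ANOVA F against F statistics of traits simulated under Brownian
motion on the tree (groups fixed), the classical simulation-null
formulation, with the BM rate estimated by the mean squared independent
contrast. p is the plain fraction of null F at or above the observed value.

## What the synthetic data emulate — and what they do not

The generators are the package's study conditions, fixed once:

* `simulate_convergent_tree()` — an ultrametric depth-1 species tree: a
  6-tip outgroup clade, `LCAfa` at depth 0.15, ladders of 6 and 8 equal
  branches to `LCAa`/`LCAf` (each carrying 8-tip focal clades from depth
  0.7), and a 3-tip clade hanging off every intermediate path node. The
  side clades matter: they are the retaining witnesses that date each loss.
  A gene lost on the *first* branch of both paths leaves no ingroup witness
  of presence at `LCAfa`, and its two losses cannot be distinguished from a
  single loss on the `LCAfa` stem — such plantings are avoided by
  `sample_planted_orders()` and discussed wherever headline recovery
  numbers are reported.
* `simulate_binary_ogs()` — independent forward Mk simulations recording
  every node's state; `plant_convergent_losses()` deterministically
  overwrites planted OGs (present everywhere except below the two loss
  branches) so order-recovery tests are exact, not stochastic.
* `simulate_fragment_tree()` / `simulate_domain_msa()` — a gene family of
  21 clades of 12 tips (5 fragment clades, about a quarter of the tips,
  dispersed as in the real family), alignment of 100 ALDH + 80 ADH columns,
  background clock 0.2 substitutions/site/unit under a Poisson jump model,
  fragment tips gapped across the ADH block, and designated interface sites
  accelerated 10-fold on fragment-clade branches. These sizes keep per-site
  event counts high enough that the ratio statistic is informative at the
  "at least 5 events" filter while a 25-minute desk-scale budget holds.
* `write_toy_structure()` — CA-only two-chain structures with declared
  contact pairs at exactly 4.0 angstrom and all other inter-chain pairs
  beyond 6.0, so a 5 angstrom rule recovers the declared set exactly.

What passing tests on these data do *not* show: robustness to tree
estimation error (all trees are known), to annotation error in the
presence/absence table, to alignment error, to rate heterogeneity beyond
the planted interface acceleration, or to model misspecification of the
amino-acid process (the generator and the reconstruction share the
equal-exchangeability family, though not the frequencies). Conclusions
about real data rest on the method, not on these fixtures.

## Numerical choices and limitations

Likelihood passes rescale partial vectors per node and accumulate log
scales, so deep trees do not underflow. Zero-length branches are identity
transitions; negative lengths are rejected. Transition matrices are
renormalised to row sum 1 after the spectral reconstruction. MCMC output is
deterministic given a seed; chains with zero acceptance raise an error
rather than returning a frozen chain. The permutation p value of 0 is
reported as 0 (with the smoothed companion), matching its definition as a
plain ratio. Problem sizes used by the test suite and the acceptance script
(trees of 30-130 tips, 137 planted OGs, 50 replicate reconstructions, 200
or 10,000 permutations, 20-seed recovery experiments) were chosen as the
smallest sizes at which the statistical properties under test are stable.

Known limitations: no rate heterogeneity across branches or sites in the
binary model; joint amino-acid reconstruction is out of scope (marginal
only); the 7-state repertoire fit is only weakly identified on a few
hundred tips, so rate *contrasts* (which transitions are fast), not
absolute rates, are the quantity to interpret; and the loss-order statistic
conditions on the assigned branches, ignoring assignment uncertainty below
the replicate-vote level.
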