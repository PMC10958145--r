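---
title: "Detecting convergent adaptation after selenocysteine loss: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent adaptation after selenocysteine loss: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selconv)
```

## The scientific question

Selenoproteins carry the 21st amino acid, selenocysteine (Sec, encoded by
UGA), at their catalytic site. In mammalian GPX6 this Sec was independently
exchanged for cysteine (Cys) in several lineages over the last ~64 million
years. `selconv` implements the comparative-genomics side of asking what
happened next: did the branches on which Sec was lost evolve faster than
their neighbours, did the same amino-acid replacements recur across the
independent Sec-loss lineages more often than chance allows, and do those
recurrent (convergent) sites carry signatures of positive selection?

The package treats the Sec-to-Cys exchange itself as the *conditioning
event*: the catalytic column is excluded from every rate estimate and every
convergence count, and is carried along only as metadata (its ancestral
Sec/Cys states are assigned by Fitch parsimony, which also places and counts
the independent losses).

## Codon model and branch-partitioned dN/dS

Rates are modelled with the GY94 codon substitution model on the 61 sense
codons: a substitution rate proportional to the target codon's equilibrium
frequency, multiplied by κ for transitions and by ω = dN/dS for
nonsynonymous changes; multi-nucleotide changes have rate zero. Codon
frequencies are F3x4 — products of position-specific nucleotide frequencies
tabulated from the analysed region — and are never re-estimated by maximum
likelihood. Each rate matrix is scaled to one expected substitution per
codon, so branch lengths are in substitutions per codon.

Three branch schemes are fitted by maximum likelihood with Felsenstein
pruning:

* **one-ratio** — a single ω for the whole tree (the null of all LRTs);
* **partition** — one ω per branch class: `SEC` (Sec retained), `EXCHANGE`
  (the branch on which Sec was exchanged for Cys) and `INHERITED`
  (descendants that inherited Cys);
* **free-ratio** — an independent ω per branch, used mainly to export
  per-branch dN values.

The partition-vs-one-ratio LRT uses `2(ℓ1 − ℓ0)` against χ² with df equal
to the difference in ω counts (df = 2 for three classes against one); no
boundary-mixture correction is applied for branch models.

**dN and dS per branch.** A branch of length *t* substitutions per codon is
decomposed using the expected nonsynonymous/synonymous flux under its
fitted matrix; "sites" are counted at ω = 1 with the same κ and
frequencies, so that dN/dS equals ω exactly. The free-ratio dN values are
the amino-acid-scale branch lengths handed to the simulation null.

### Optimisation

The likelihood is maximised by alternating two moves until the
log-likelihood changes by less than a tolerance (default 1e-6): a
Nelder–Mead step on the logs of the global parameters (κ and the ω values),
and a monotone coordinate-ascent pass over branch lengths. The branch pass
walks the tree depth-first with cached inside/outside partial likelihoods,
Brent-optimising each length against an exact one-dimensional profile (the
profile is evaluated in the spectral basis of the rate matrix, so each
candidate length costs a vector operation rather than a matrix
exponential), and refreshes the cached partials as it returns — a
Gauss–Seidel scheme that can only increase the joint likelihood. A joint
quasi-Newton optimiser over all branch lengths was implemented as a
reference; the coordinate scheme reaches the same optimum (the test suite
verifies local optimality against L-BFGS-B) roughly an order of magnitude
faster, which is what makes the calibration simulations below affordable.
Fits start from up to three deterministic perturbed starts (`restarts`);
LRT pairs warm-start the alternative from the null so the likelihood
ordering of nested models is preserved.

Degenerate branch lengths are floored at 1e-8 to keep the likelihood
differentiable; ω is optimised on a log scale within [1e-6, 50].

## Ancestral sequence reconstruction

Ancestral states are reconstructed at the protein level under the JTT
empirical replacement model (exchangeabilities and stationary frequencies
taken from phangorn, rescaled to one expected replacement per site).
Reconstruction is *marginal* empirical Bayes: for every internal node and
site, inside (subtree) and outside (rest-of-tree) partial likelihoods are
combined into a posterior over the 20 amino acids; the MAP state breaks
ties toward the alphabetically earlier residue so results are
deterministic. Branch lengths can be refit by ML under the amino-acid model
before reconstruction (the observed-data pipeline does this). Per-node
accuracy is summarised as the mean MAP posterior across sites — the
expected fraction of correctly inferred residues under the model.

Columns that are all gaps get a uniform posterior and a warning. The Sec
column is excluded; codon-level ancestral reconstruction is intentionally
out of scope (a codon-level reconstruction would weight silent changes,
which carry no information about protein convergence).

## Convergence detection

Substitution events are read off the reconstruction: one event per
(branch, site) where the MAP states at the branch's two ends differ, with
observed residues used at the tips. For each pair of phylogenetically
independent branches (neither ancestral to the other — enforced), sites
with events on both branches and the same derived residue are classified

* **parallel** — same ancestral residue on both branches;
* **convergent** — different ancestral residues.

Headline "convergent sites" are the union of the two classes, matching the
umbrella usage of classical convergence counting; the classes stay separate
in all outputs. Changes toward merely *similar* residues (same
physicochemical group; groups configurable) are reported as a third class
and never merged into headline counts.

**Expected counts.** For each branch pair, the probability that both
branches substitute at a site and end in the same residue is computed by
summing the marginal ancestral posteriors at the two parent nodes against
the JTT transition probabilities over each branch (an exact 20×20×20 sum,
verified against brute-force enumeration in the tests). Summing over sites
gives expected parallel and convergent counts; a Poisson tail
`P(X ≥ observed)` with mean equal to the expectation gives a per-pair
p-value. Observed counts use MAP states while expectations integrate over
the posterior — deliberately so: the observed count is the classical
estimator, the expectation its model-based reference.

**Trees from convergent sites.** Convergence strong enough to mimic shared
ancestry distorts phylogeny. `convergence_tree()` rebuilds a tree from a
designated site subset using maximum-likelihood JTT distances,
neighbour-joining and midpoint rooting, and reports the minimum number of
clades covering a designated taxon set (e.g. the Cys-bearing species). An
ML topology search was deliberately replaced by NJ on ML distances: the
scientific readout is clade membership, not the exact topology, and NJ is
deterministic and fast.

## The simulation null

Chance convergence is calibrated by simulating protein evolution along the
fixed species tree under JTT, with branch lengths set to the per-branch
amino-acid rate (the free-ratio dN values) and the root fixed at the
inferred ancestral sequence. Each replicate is then pushed through the same
reconstruction-plus-counting pipeline as the observed data, so ancestral
reconstruction error is part of the null. The empirical p-value is
`(1 + #{replicates ≥ observed}) / (R + 1)`; the default replicate count is
1000. One economy is taken by default: replicate reconstructions keep the
(true, generating) branch lengths rather than refitting them per replicate
— reconstruction error stays in the null while the per-replicate cost drops
by an order of magnitude; `null_optimize_lengths = TRUE` restores the full
re-analysis. Both per-pair and total counts are recorded; the headline test
uses the total convergent-site count.

## Branch-site positive selection and enrichment

The branch-site model (model A) is fitted on a designated foreground branch
set (by default the `EXCHANGE` branches): four site classes with
proportions p0, p1, p2a, p2b, where class 0 evolves at ω0 < 1 everywhere,
class 1 neutrally, and classes 2a/2b at ω2 on the foreground. The null
fixes ω2 = 1; the LRT uses χ² with df = 1 (the conservative convention,
not the 50:50 boundary mixture). Branch lengths and κ starting values come
from a one-ratio fit; branch lengths are then held fixed during the mixture
fits — a standard practical approximation that removes the dominant cost
without touching the parameters under test. The alternative is
warm-started from the fitted null over a small grid of ω2 values, which
both guarantees `ℓ_alt ≥ ℓ_null` and protects against the boundary local
optimum (everything in class 0) that cold starts can fall into.

Per-site posteriors of the selected classes (2a + 2b) are naive empirical
Bayes at the MLEs; the output records `kind = "NEB"` because the BEB
variant (integrating over parameter uncertainty) is intentionally out of
scope. "Signatures of positive selection" for reporting are sites above
the 90th percentile of posteriors within a reference region, with the
percentile computed by midpoint interpolation.

Enrichment of selection signal at convergent sites uses a Mann–Whitney U
test (one-sided "greater" by default): exact enumeration when the smaller
site set has at most 8 members and there are no ties, the tie-corrected
normal approximation otherwise.

A note on power: at desk scale the model-A LRT operates in a weak-signal
regime. Direct maximisation on data with ω2 = 3 at 10% of 300 codons
yields LR statistics of roughly 0–3 for any foreground of realistic total
length, and even ω2 = 8 yields LR ≈ 2–5 — consistent with the marginal
significance such tests achieve on real single-gene datasets. The test
suite therefore checks calibration under the null and that LRs under
strong foreground selection clearly dominate their null behaviour, rather
than asserting a high single-replicate rejection rate that the statistic
cannot deliver at this problem size.

## The synthetic-data generator

Because the original 22-species sequence set is not redistributable, the
package ships a generator that emulates its statistical structure, with
full ground truth. The packaged preset (`gpx6_scenario()`) fixes the study
conditions:

* 22 taxa on a mammal-like topology with five independent Sec-loss
  (`EXCHANGE`) branches — the stem of a four-species muroid-rodent clade
  (the focal branch), rabbit, guinea pig, a New-World-monkey pair and a
  bat — nine Cys-bearing species in total;
* tag-specific dN/dS of 0.217 (SEC), 0.370 (EXCHANGE) and 0.279
  (INHERITED), with κ = 2.5 (a typical mammalian transition bias);
* domains of 39 (N-terminus), 113 (GPX) and 65 (C-terminus) amino acids,
  with the catalytic site at position 73 (0-based) inside the GPX domain:
  TGA (Sec) ancestrally, TGT/TGC below every `EXCHANGE` branch;
* a burst of exactly 25 amino-acid changes on the focal branch, of which
  14 are convergent across all five Sec-loss branches.

Branch lengths (~0.02–0.15 substitutions per codon, rodent terminals
longest) and the slightly GC-skewed position-specific nucleotide
frequencies are fixed choices representative of mammalian single-copy
coding genes. Codon states evolve by sampling from GY94 transition
matrices, so internal stop codons cannot arise. Convergence is injected
*post hoc* on the simulated history: at each chosen site every `EXCHANGE`
branch is forced to the same derived amino acid (via a single-nucleotide
codon step where one exists; multi-step substitutions are recorded in the
truth), and the subtree below each modified branch is re-simulated so
descendants stay coherent. The focal branch is then topped up (or trimmed,
never touching injected sites) to exactly 25 changes. Injection on
simulated histories rather than a convergence-favouring process is a
deliberate trade: the ground truth is exact, at the price of convergent
sites whose surrounding history is ordinary.

What the generator does *not* emulate: alignment error and indels
(masking consumes an externally supplied confidence track), rate
heterogeneity across sites, codon usage biases beyond F3x4, GC-biased gene
conversion, and selection regimes more nuanced than branch-class ω. A test
passing on this generator therefore shows the statistical machinery is
correct and calibrated under the stated model — not that real GPX6 data
would give the same numbers.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_codon_dataset(gpx6_scenario(seed = 1))
res <- run_pipeline(ds, pipeline_config(n_rep = 200, focal_branch = "EUM",
                                        seed = 2))
res$table1          # per-region omega by branch class, LRT p, convergent counts
res$focal           # the 25-change focal branch, 14+ convergent sites
empirical_p(res$null)
res$branch_site$lrt # positive selection on the Sec-loss branches
res$enrichment      # selection signal concentrated at convergent sites
autoplot(res$null)
```

## Numerical choices and problem sizes

* Likelihood tolerance 1e-6 (fits), Brent tolerance 1e-4 on log branch
  lengths; per-site scaling by column sums guards against underflow.
* Transition matrices come from the symmetrised eigen-decomposition of the
  reversible rate matrix; tiny negative entries from round-off are clamped
  to zero.
* MAP ties break lexicographically; Fitch parsimony ties are reported as
  ambiguous, never resolved silently.
* Masking operates on whole codon columns (one amino-acid confidence value
  per codon); it is idempotent at a fixed threshold, and coordinates are
  0-based half-open everywhere.
* The test suite runs its simulations at reduced problem sizes chosen for a
  single CPU: 200 null simulations of 10 taxa × 100 codons for LRT
  calibration, 20 replicates for recovery checks, a 39-replicate null per
  negative-control run (20 runs), 15 replicates for branch-site
  calibration and 4 for the selection-response check. The acceptance
  script runs the full preset with the complete 1000-replicate null.

## Known limitations

* NEB (not BEB) site posteriors; branch-site branch lengths fixed at
  one-ratio MLEs.
* No site-heterogeneous ω outside the branch-site model; no F61
  frequencies; no Γ rate variation in the protein simulation.
* Convergence detection uses MAP ancestral states, so reconstruction
  uncertainty enters the observed counts only through the simulation null
  (which reconstructs ancestors the same way), not through per-site
  weighting.
* The branch partition must be supplied by the user; the package checks it
  against the catalytic column but never infers it.
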