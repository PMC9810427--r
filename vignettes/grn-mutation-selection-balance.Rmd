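---
title: "Gene regulatory networks at mutation-selection balance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene regulatory networks at mutation-selection balance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnmsb)
```

## The model

`grnmsb` studies the long-run composition of an infinitely large, asexually
reproducing population of gene regulatory networks (GRNs) evolving under
viability selection, reproduction and mutation with non-overlapping
generations — a quasi-species model, i.e. multi-locus mutation-selection
balance.

**Genotypes.** Under the pathway framework a genotype is an ordered
assignment of one allele per gene, where an allele is an ordered pair
(activator protein, product protein): the gene is expressed when its
activator is present and then turns its product present. The protein
universe is fixed and partitioned into *input* proteins (externally
stimulable, never a product), *output* proteins (physiological effects only,
never an activator) and *internal* proteins. With $|\alpha(\Omega)|$
admissible pairs and $|\Gamma|$ genes there are
$|G| = |\alpha(\Omega)|^{|\Gamma|}$ genotypes; genes are distinguishable
labels, so two genes carrying the same pair are a different genotype from
any rearrangement. Genotypes are indexed by a mixed-radix encoding (gene A
is the least-significant digit), which is the stable join key in every
output format.

**Phenotypes.** The environment stimulates a set of input proteins; the
phenotype is the least fixed point of propagating presence along allele
edges — equivalently, the set of proteins reachable from the stimuli, union
the stimuli. Protein states are binary, so the cascade is monotone and
needs no cycle handling.

**Selection.** A genotype's viability $\nu_g \in [0,1]$ is its survival
probability and its reproductivity $\rho_g \ge 0$ the chance that a random
member of the next (infinite) generation descends from a viable parent with
that genotype. The package supports arbitrary $\nu$ and $\rho$; the binary
case — $\nu_g = 1$ iff all *essential* proteins are present in the
phenotype and no *fatal* protein is, with uniform $\rho$ — is a
configuration preset (`selection_model()` defaults), not a hard-coded
assumption.

**Mutation.** Each gene mutates independently per generation with
probability $\mu$, and a mutation replaces the allele by one of the other
$|\alpha(\Omega)| - 1$ pairs uniformly. The genotype-to-genotype kernel is
therefore
$\left(\tfrac{\mu}{|\alpha(\Omega)|-1}\right)^{d}(1-\mu)^{|\Gamma|-d}$
with $d$ the number of genes whose alleles differ; it factorizes exactly
into a per-locus matrix with diagonal $1-\mu$ and constant off-diagonal,
applied along each gene axis of the $K^{|\Gamma|}$ tensor.

**Dynamics.** Writing $T[g,g'] = \rho_{g'}\mu_{g'g}\nu_g$ over viable
genotypes with positive reproductivity (and $R$ for the transitions into
viable zero-reproductivity "sinks"), one generation maps the conditional
genotype distribution $p$ to $Tp / (\mathbf{1}^\top Tp + \mathbf{1}^\top
Rp)$. For $\mu > 0$ the neutral network of any phenotypic constraint is
connected, so $T$ is strictly positive and Perron-Frobenius gives a unique
attracting fixed point: the stationary distribution is the sum-normalized
leading eigenvector $v_1$ of $T$, with sink masses $R v_1 / \lambda_1$
under the common normalizer. As $\mu \to 0$ (binary viability, uniform
reproductivity), $T$ reduces to a constant diagonal plus a term
proportional to the neutral network's adjacency matrix, so the stationary
distribution converges to the network's **eigenvector centrality** — the
package's `centrality_distribution()`.

## Numerical choices

- **Power iteration with a diagonal shift.** `stationary_distribution()`
  iterates the matrix-free operator, subtracting the common no-mutation
  diagonal term $\sigma = \min_g \rho_g \nu_g (1-\mu)^{|\Gamma|}$ first.
  The shift leaves every eigenvector unchanged while removing the shared
  diagonal mass, so the convergence rate is governed by the mutation part's
  spectral gap and does not degrade as $\mu \to 0$ (the unshifted ratio
  approaches $1 - O(\mu)$, which would make the $\mu = 10^{-4}$ limit
  computation infeasibly slow). With the shift, the 45 389-node case-study
  problems converge in under a hundred iterations.
- **Stopping rule.** Successive sum-normalized iterates must differ by less
  than `tol` in total variation (default $10^{-12}$), with `max_iter`
  defaulting to $10^5$. The fixed-point residual
  $\|Tv - \lambda v\|_1/\lambda$ is reported so convergence can be audited.
  The stationary output is invariant to the starting vector (checked to
  $10^{-10}$ TV in the tests).
- **Matrix-free application.** $T$ is never materialized: a vector is
  lifted to the full genotype space, scaled by $\rho$ at the source, swept
  by the per-locus factor along each gene axis, scaled by $\nu$ at the
  destination and restricted. A dense entry-by-entry assembly
  (`dense_transition_matrix()`) exists for diagnostics on spaces up to a
  few thousand genotypes; the test suite verifies the two agree to
  floating-point accuracy on the 81-genotype reduced universe.
- **Centrality.** Power iteration on $A + I$; the unit shift removes any
  bipartite oscillation without changing eigenvectors. Connectivity is
  checked first and a disconnected input is an error naming the component
  sizes.
- **Enumeration cap.** Full enumeration (phenotypes, adjacency) is refused
  above $2^{20}$ genotypes with a pointer to the matrix-free routines, so
  larger universes fail loudly rather than exhausting memory.
- **Ties.** `most_prevalent()` treats centralities within $10^{-9}$
  relative as tied and reports the whole argmax set; the deterministic
  representative is the gene-relabelling canonical form (sorted allele
  ranks) with the smallest genotype index, so outputs are reproducible
  rather than randomly sampled.

## The study systems

Three built-in systems (`grn_fixture()`) define the conditions under which
all results and tests are computed:

- **case-study**: 6 proteins (2 input / 2 internal / 2 output), 4 genes —
  16 alleles, 65 536 genotypes, and 45 389 viable genotypes under the
  environment with one stimulated input and one fatal output. Seven
  reference environments (`reference_environments()`) combine single and
  multiple stimulated, essential and fatal proteins.
- **reduced**: 4 proteins (1 input / 2 internal / 1 output), 2 genes — 81
  genotypes. Small enough that every oracle (dense eigensolvers, exhaustive
  predicate scans, brute-force viability via graph reachability) runs
  exhaustively; this is the scale at which the rare-mutation limit and the
  Wright-Fisher validation are exercised.
- **micro**: 2 proteins, 1 gene, a single genotype — degenerate-path
  checks.

These systems emulate the combinatorics of real regulatory evolution (a
fixed protein repertoire, labelled genes, single-activator/single-product
expression) but not continuous dosage, multi-input logic, expression noise,
recombination, duplication, changing environments or demographic structure.
Passing tests therefore validate the mathematics of the model at these
scales, not the biology of any particular organism.

## Wright-Fisher validation

`wf_simulate()` evolves finite populations ($N$ individuals; the reference
protocol uses $N = 16$, $\mu = 0.1$) with non-overlapping generations:
every offspring picks a parent uniformly with replacement among the viable
members of the current population, then mutates per locus. Each lineage
starts from individuals drawn uniformly from *all* genotypes, and after the
horizon one viable individual per lineage is sampled to form the empirical
distribution.

- **Horizon.** `convergence_horizon()` returns the first generation at
  which the deterministic master-equation distribution (from uniform over
  viable genotypes) is within a tolerance of the stationary distribution.
  The auto-horizon used by `wf_simulate()` is *twice* that first crossing:
  a bare first crossing leaves deterministic bias of the same order as the
  sampling tolerance, which would confound the comparison, and the doubling
  is the standard safety margin where an analytic mixing-time bound is
  unavailable. The default tolerance is the mean total-variation distance
  of multinomial resamples of the stationary distribution at the simulated
  lineage count (`resampling_band()`), i.e. the finite-sampling noise
  floor.
- **Extinction policy.** A lineage whose generation contains no viable
  individual is reinitialized from a fresh uniform population; events are
  counted and reported. This keeps the lineage count fixed without biasing
  toward any particular viable genotype.
- **Random numbers.** All lineages are advanced in lock-step through a
  single seeded Mersenne-Twister stream (the whole population array is
  vectorized per generation), so a given seed reproduces results exactly;
  results are tied to the lineage count rather than to per-lineage
  substreams.
- **Scale.** The default protocol runs $10^5$ lineages on the reduced
  universe, where the empirical distribution typically sits at total
  variation $\approx 0.013$–$0.016$ from the analytic stationary against a
  sampling floor of $\approx 0.010$. The residual is finite-population
  bias: the sampled-genotype marginal of a 16-individual population
  deviates from the infinite-population prediction by a few parts per
  thousand of total variation (rerunning with $N = 256$ brings the distance
  down to the sampling floor), so per-genotype agreement with a 99%
  multinomial band hovers around 90–98% coverage depending on the seed.

## Prevalence analysis

For each environment and structural constraint group (combinations of
excluding spare genes, excluding redundant genes, requiring all genes
functionally activated, and excluding stimulus-to-essential direct
selection), `most_prevalent()` reports the viable genotypes with the
greatest eigenvector centrality. The default `"filter"` mode computes
centrality on the environment's full neutral network and restricts the
argmax to group-satisfying genotypes: the structural groups are not
phenotypic constraints, so their induced subgraphs carry no connectedness
guarantee, whereas the filter reading is always well defined. An
`"induced"` mode (centrality on the largest component of the group-induced
subgraph) is provided for sensitivity analysis; which reading underlies
published figures of this kind is generally not stated, so the package
documents its default rather than asserting equivalence.

Two open modelling points are resolved as follows: stimuli are restricted
to input proteins by default with a permissive mode for any non-output
protein, and environments in which a stimulated protein is also essential
or fatal are accepted with a warning, since no reference environment
exercises that corner.

## Known limitations

- Full enumeration limits exact analysis to modest universes; beyond the
  cap only the matrix-free operator path is available and connectivity
  must be argued rather than verified.
- The rare-mutation limit is validated on the reduced universe; at the
  case-study scale the stationary distribution at $\mu = 0.1$ sits at
  total variation $\approx 0.005$ from the centrality limit, consistent
  with the reduced-universe trend, but the $\mu$-sweep is not repeated at
  that scale for runtime reasons.
- Finite-population agreement is qualitative at $N = 16$ (see above); the
  package quantifies the bias rather than modelling genetic drift
  explicitly.
- Reproductivity enters the Wright-Fisher simulator only through the
  viable/inviable distinction (uniform parent choice among viable
  members); graded $\rho$ affects the analytic operator but not the
  forward simulator, which implements the binary/uniform reference
  protocol.
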