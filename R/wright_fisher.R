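#' Configuration for Wright-Fisher lineage simulation
#'
#' @param pop_size individuals per population (N); the reference protocol
#'   uses 16.
#' @param mu per-locus per-generation mutation probability.
#' @param generations evolution horizon, or `NULL` to auto-select as twice
#'   the [convergence_horizon()] at `tolerance` (the doubling is a safety
#'   margin standing in for an analytic mixing-time bound).
#' @param lineages number of independent populations.
#' @param seed RNG seed recorded in all outputs.
#' @param tolerance total-variation tolerance used when `generations` is
#'   auto-selected (default: the mean resampling TV of a multinomial sample
#'   of `lineages` draws from the analytic stationary).
#' @param initial `NULL` for individuals chosen uniformly at random from all
#'   genotypes (the reference protocol), or explicit genotype indices
#'   recycled across each initial population.
#' @return An object of class `wf_config`.
#' @export
wf_config <- function(pop_size = 16L, mu = 0.1, generations = NULL,
                      lineages = 10000L, seed = 1L, tolerance = NULL,
                      initial = NULL) {
  stopifnot(pop_size >= 1, lineages >= 1, mu >= 0, mu < 1)
  structure(list(pop_size = as.integer(pop_size), mu = mu,
                 generations = generations, lineages = as.integer(lineages),
                 seed = as.integer(seed), tolerance = tolerance,
                 initial = initial),
            class = "wf_config")
}

# mutate a vector of genotype indices in place: each gene independently with
# probability mu jumps to a uniformly random *different* allele
# ((digit + r) mod K with r uniform in 1..K-1).
wf_mutate <- function(idx, system, mu) {
  K <- system$n_alleles
  if (mu == 0 || K == 1L) return(idx)
  for (j in seq_len(system$n_genes)) {
    w <- gene_radix(system, j)
    hit <- which(stats::runif(length(idx)) < mu)
    if (!length(hit)) next
    dig <- (idx[hit] %/% w) %% K
    r <- floor(stats::runif(length(hit)) * (K - 1)) + 1
    idx[hit] <- idx[hit] + (((dig + r) %% K) - dig) * w
  }
  idx
}

#' One Wright-Fisher generation
#'
#' Each of the N offspring picks a parent uniformly with replacement from
#' the *viable* members of the current population, then every gene mutates
#' independently with probability `mu` to a uniformly random different
#' allele. Uses the current RNG state.
#'
#' @param pop numeric vector of genotype indices (0-based).
#' @param system a [grn_system()].
#' @param env a [grn_env()] (binary viability).
#' @param mu per-locus mutation probability.
#' @param nu optional precomputed viability vector over the full genotype
#'   space.
#' @return The next-generation population, or `NULL` if no member of `pop`
#'   is viable (lineage extinct).
#' @export
step_generation <- function(pop, system, env, mu, nu = NULL) {
  if (is.null(nu)) nu <- viability_vector(system, env)
  viable <- pop[nu[pop + 1] > 0]
  if (!length(viable)) return(NULL)
  parents <- viable[floor(stats::runif(length(pop)) * length(viable)) + 1]
  wf_mutate(parents, system, mu)
}

# Resample parents for all lineages at once. pop is an L x N matrix of
# genotype indices; rows with no viable member are reinitialized uniformly
# at random (the extinction policy) and the count of such events returned.
wf_select <- function(pop, viable01, n_out, n_genotypes) {
  L <- nrow(pop)
  V <- matrix(viable01[pop + 1] > 0, L, ncol(pop))
  ext <- 0L
  repeat {
    k <- rowSums(V)
    dead <- which(k == 0)
    if (!length(dead)) break
    ext <- ext + length(dead)
    pop[dead, ] <- matrix(
      floor(stats::runif(length(dead) * ncol(pop)) * n_genotypes),
      length(dead), ncol(pop))
    V[dead, ] <- matrix(viable01[pop[dead, ] + 1] > 0, length(dead), ncol(pop))
  }
  vals <- t(pop)[which(t(V))]          # viable entries in row-major order
  off <- cumsum(k) - k
  U <- matrix(stats::runif(L * n_out), L, n_out)
  pick <- off + pmin(floor(U * k) + 1, k)   # k, off recycle down columns
  list(parents = matrix(vals[pick], L, n_out), extinctions = ext, pop = pop)
}

#' Simulate parallel Wright-Fisher lineages
#'
#' Every lineage starts from a population whose individuals are chosen
#' uniformly at random from all genotypes, evolves for a fixed number of
#' generations (reproduction from viable parents with replacement, then
#' per-locus mutation), and finally contributes one uniformly sampled viable
#' individual to the empirical distribution. Lineages that lose all viable
#' individuals are reinitialized from a fresh random population; these
#' events are counted and reported.
#'
#' @param system a [grn_system()].
#' @param env a [grn_env()] (binary viability).
#' @param config a [wf_config()].
#' @param operator optional [build_transition_operator()] reused for the
#'   auto-horizon computation.
#' @return An object of class `wf_sim`: `ids` and `counts` of the sampled
#'   viable genotypes, `total`, `generations`, `extinctions`, `seed`,
#'   `config`.
#' @export
wf_simulate <- function(system, env, config, operator = NULL) {
  set.seed(config$seed)
  nu <- viability_vector(system, env)
  gens <- config$generations
  if (is.null(gens)) {
    if (is.null(operator))
      operator <- build_transition_operator(system, selection_model(system, env),
                                            config$mu)
    st <- stationary_distribution(operator)
    tol <- config$tolerance
    if (is.null(tol)) {
      band <- resampling_band(st$distribution, n_samples = config$lineages,
                              repeats = 200L)
      tol <- band$mean_tv
    }
    # run twice the first-crossing horizon: the safety factor keeps the
    # residual deterministic bias negligible against sampling noise, which a
    # bare first crossing does not (it leaves bias of order the tolerance)
    gens <- 2L * convergence_horizon(operator, stationary = st, tolerance = tol)
  }
  L <- config$lineages
  N <- config$pop_size
  nG <- system$n_genotypes
  pop <- if (is.null(config$initial))
    matrix(floor(stats::runif(L * N) * nG), L, N)
  else matrix(rep_len(config$initial, N), L, N, byrow = TRUE)
  ext <- 0L
  for (t in seq_len(gens)) {
    sel <- wf_select(pop, nu, N, nG)
    ext <- ext + sel$extinctions
    pop <- wf_mutate(as.numeric(sel$parents), system, config$mu)
    dim(pop) <- c(L, N)
  }
  fin <- wf_select(pop, nu, 1L, nG)   # one viable sample per lineage
  ext <- ext + fin$extinctions
  draw <- as.numeric(fin$parents)
  tab <- table(draw)
  structure(list(ids = as.numeric(names(tab)), counts = as.integer(tab),
                 total = L, generations = gens, extinctions = ext,
                 seed = config$seed, config = config),
            class = "wf_sim")
}

#' @export
print.wf_sim <- function(x, ...) {
  cat("Wright-Fisher simulation: ", x$total, " lineages x ", x$config$pop_size,
      " individuals, ", x$generations, " generations (seed ", x$seed, ")\n",
      sep = "")
  cat("  distinct sampled genotypes: ", length(x$ids),
      "; extinction-reinitializations: ", x$extinctions, "\n", sep = "")
  invisible(x)
}

#' Empirical distribution of a simulation
#'
#' @param sim a [wf_simulate()] result.
#' @param support optional genotype ids to zero-fill onto (e.g. all viable
#'   genotypes).
#' @return A [grn_distribution()].
#' @export
empirical_distribution <- function(sim, support = NULL) {
  if (is.null(support)) return(grn_distribution(sim$ids, sim$counts / sim$total))
  probs <- numeric(length(support))
  m <- match(sim$ids, support)
  if (anyNA(m)) stop("simulation sampled genotypes outside the given support")
  probs[m] <- sim$counts / sim$total
  grn_distribution(support, probs)
}

#' Total-variation distance between two distributions
#'
#' Half the L1 distance; distributions with different supports are compared
#' over the union with zero fill.
#'
#' @param p,q [grn_distribution()] objects (or plain probability vectors of
#'   equal length).
#' @return A number in [0, 1].
#' @export
total_variation <- function(p, q) {
  if (!inherits(p, "grn_distribution") && !inherits(q, "grn_distribution"))
    return(0.5 * sum(abs(p - q)))
  ids <- sort(union(p$ids, q$ids))
  pv <- qv <- numeric(length(ids))
  pv[match(p$ids, ids)] <- p$probs
  qv[match(q$ids, ids)] <- q$probs
  0.5 * sum(abs(pv - qv))
}

#' Multinomial resampling band around a predicted distribution
#'
#' Draws repeated multinomial samples of a given size from the predicted
#' distribution and summarizes, per genotype, the central quantile band of
#' the sampled frequencies, plus the mean total-variation distance of the
#' samples from the prediction (the finite-sampling error tolerance).
#'
#' @param pred a [grn_distribution()].
#' @param n_samples draws per replicate.
#' @param repeats number of replicates (reference protocol: 1000).
#' @param level central band coverage (default 0.99).
#' @return List with `band` (data frame: genotype, lower, upper), `mean_tv`,
#'   `level`, `n_samples`, `repeats`.
#' @export
resampling_band <- function(pred, n_samples, repeats = 1000L, level = 0.99) {
  X <- stats::rmultinom(repeats, n_samples, pred$probs) / n_samples
  a <- (1 - level) / 2
  qs <- apply(X, 1L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  list(band = data.frame(genotype = pred$ids, lower = qs[1, ], upper = qs[2, ]),
       mean_tv = mean(0.5 * colSums(abs(X - pred$probs))),
       level = level, n_samples = n_samples, repeats = repeats)
}

#' Generations needed to approach the stationary distribution
#'
#' Iterates the deterministic master equation from `p0` (default uniform
#' over the core genotypes, the infinite-population analogue of uniform
#' random initial populations after one round of selection) and returns the
#' first generation at which the distribution is within `tolerance` total
#' variation of the stationary distribution.
#'
#' @param op a [build_transition_operator()] result.
#' @param tolerance target total-variation distance.
#' @param p0 optional start vector over the core set.
#' @param stationary optional precomputed [stationary_distribution()]
#'   result for `op`.
#' @param max_iter generation cap.
#' @return Integer horizon (0 if `p0` is already within tolerance).
#' @export
convergence_horizon <- function(op, tolerance, p0 = NULL, stationary = NULL,
                                max_iter = 1e5) {
  if (is.null(stationary)) stationary <- stationary_distribution(op)
  target <- stationary$distribution
  n <- length(op$core_ids)
  p <- if (is.null(p0)) rep(1 / n, n) else p0 / sum(p0)
  tv_now <- function(p, sink) total_variation(
    grn_distribution(c(op$core_ids, op$sink_ids), c(p, sink), normalize = TRUE),
    target)
  sink <- numeric(length(op$sink_ids))
  t <- 0L
  repeat {
    if (tv_now(p, sink) < tolerance) return(t)
    if (t >= max_iter)
      stop("stationary distribution not approached within ", max_iter,
           " generations (TV still ", signif(tv_now(p, sink), 3), ")")
    st <- iterate_master_equation(p, op, 1L)
    p <- st$p
    sink <- st$sink
    t <- t + 1L
  }
}
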