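#' Per-locus mutation model
#'
#' Mutation hits each gene independently per generation with probability
#' `mu`; when it hits, the allele is replaced by one of the other
#' `n_alleles - 1` alleles uniformly at random.
#'
#' @param mu per-locus per-generation mutation probability in [0, 1).
#' @param n_alleles number of alleles |alpha(Omega)|.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(mu, n_alleles) {
  if (mu < 0 || mu >= 1) stop("mu must lie in [0, 1)")
  if (mu > 0 && n_alleles < 2) stop("mutation requires at least two alleles")
  structure(list(mu = mu, n_alleles = as.integer(n_alleles)),
            class = "mutation_model")
}

#' Mutation probability between two genotypes
#'
#' The per-generation probability that genotype `from` mutates into `to`:
#' `(mu / (n_alleles - 1))^d * (1 - mu)^(n_genes - d)` where `d` counts the
#' genes whose alleles differ. The kernel factorizes over loci, which the
#' transition operator exploits.
#'
#' @param from,to allele-rank vectors.
#' @param system a [grn_system()].
#' @param mu per-locus mutation probability.
#' @export
mutation_probability <- function(from, to, system, mu) {
  d <- sum(from != to)
  if (mu == 0) return(as.numeric(d == 0))
  (mu / (system$n_alleles - 1))^d * (1 - mu)^(system$n_genes - d)
}

#' Single-locus mutation matrix
#'
#' The `n_alleles` x `n_alleles` matrix with diagonal `1 - mu` and
#' off-diagonal `mu / (n_alleles - 1)`; rows sum to one, and its
#' `n_genes`-fold per-locus application reproduces the full mutation kernel
#' exactly.
#'
#' @param model a [mutation_model()].
#' @export
single_locus_factor <- function(model) {
  K <- model$n_alleles
  if (K == 1L) return(matrix(1, 1, 1))
  M <- matrix(model$mu / (K - 1), K, K)
  diag(M) <- 1 - model$mu
  M
}

# Apply the mutation kernel to a vector over the full genotype space by
# sweeping the single-locus factor along each gene axis of the K^G tensor.
# M = (1-mu-b) I + b J with b = mu/(K-1), so each sweep is
# x <- (1-mu-b) x + b * (axis marginal).
apply_mutation_kernel <- function(x, K, G, mu) {
  if (mu == 0 || K == 1L) return(x)
  b <- mu / (K - 1)
  a <- 1 - mu - b
  for (j in seq_len(G)) {
    lo <- K^(j - 1)
    hi <- K^(G - j)
    arr <- array(x, c(lo, K, hi))
    marg <- colSums(aperm(arr, c(2L, 1L, 3L)), dims = 1L)  # lo x hi
    x <- as.vector(a * arr +
                     b * aperm(array(marg, c(lo, hi, K)), c(1L, 3L, 2L)))
  }
  x
}

#' Build the matrix-free transition operator
#'
#' The transition matrix T among viable genotypes with non-zero
#' reproductivity has entries `T[g, g'] = rho_{g'} * mu_{g'g} * nu_g`; the
#' companion matrix R carries the same weights into the viable
#' zero-reproductivity genotypes (sinks). Neither matrix is materialized:
#' `apply` lifts a probability vector to the full genotype space, scales by
#' reproductivity at the source, applies the per-locus mutation factor along
#' each gene axis, scales by viability at the destination, and restricts to
#' the target set.
#'
#' @param system a [grn_system()].
#' @param selection a [selection_model()].
#' @param mu per-locus mutation probability.
#' @return An object of class `transition_operator` with elements
#'   `core_ids` (viable, rho > 0), `sink_ids` (viable, rho = 0), `apply`,
#'   `apply_R`, `factor` (the single-locus matrix), `shift` (the common
#'   no-mutation diagonal term usable for shifted power iteration), `mu`,
#'   `system`, `selection`.
#' @export
build_transition_operator <- function(system, selection, mu) {
  model <- mutation_model(mu, system$n_alleles)
  if (!length(selection$viable)) stop("all genotypes are inviable")
  if (!length(selection$core)) stop("every viable genotype has zero reproductivity")
  K <- system$n_alleles
  G <- system$n_genes
  nu <- selection$nu
  rho <- selection$rho
  core <- selection$core
  sink <- selection$sinks
  nfull <- system$n_genotypes
  propagate <- function(p) {
    x <- numeric(nfull)
    x[core + 1] <- p * rho[core + 1]
    apply_mutation_kernel(x, K, G, mu) * nu
  }
  op <- list(
    core_ids = core, sink_ids = sink,
    apply = function(p) propagate(p)[core + 1],
    apply_R = function(p) if (length(sink)) propagate(p)[sink + 1] else numeric(0),
    factor = single_locus_factor(model),
    # common no-mutation diagonal term; only useful as a spectral shift when
    # the off-diagonal part is irreducible, i.e. when mu > 0
    shift = if (mu > 0) min(rho[core + 1] * nu[core + 1]) * (1 - mu)^G else 0,
    mu = mu, system = system, selection = selection)
  class(op) <- "transition_operator"
  op
}

#' @export
print.transition_operator <- function(x, ...) {
  cat("Transition operator: ", length(x$core_ids), " core genotypes, ",
      length(x$sink_ids), " sinks, mu = ", x$mu, "\n", sep = "")
  invisible(x)
}

#' A probability distribution over genotypes
#'
#' @param ids genotype indices (0-based), ascending.
#' @param probs non-negative vector summing to 1 (within 1e-12).
#' @param normalize divide by the sum instead of insisting on it.
#' @export
grn_distribution <- function(ids, probs, normalize = FALSE) {
  if (length(ids) != length(probs)) stop("ids and probs must have equal length")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  s <- sum(probs)
  if (normalize) probs <- probs / s
  else if (abs(s - 1) > 1e-12) stop("probabilities must sum to 1 (got ", s, ")")
  o <- order(ids)
  structure(list(ids = ids[o], probs = probs[o]), class = "grn_distribution")
}

#' @export
print.grn_distribution <- function(x, ...) {
  cat("Distribution over", length(x$ids), "genotypes; top entries:\n")
  top <- utils::head(order(x$probs, decreasing = TRUE), 5L)
  print(data.frame(genotype = x$ids[top], probability = signif(x$probs[top], 4)))
  invisible(x)
}

#' Iterate the quasi-species master equation
#'
#' One generation maps p to `T p / (1' T p + 1' R p)`; the same normalizer
#' scales the companion sink masses `R p`.
#'
#' @param p0 numeric vector over `op$core_ids` (or a [grn_distribution()]
#'   supported on them).
#' @param op a [build_transition_operator()] result.
#' @param steps number of generations.
#' @return List with `p` (vector over core ids after `steps` generations)
#'   and `sink` (vector over sink ids from the final step; zeros if
#'   `steps = 0`).
#' @export
iterate_master_equation <- function(p0, op, steps) {
  p <- if (inherits(p0, "grn_distribution")) {
    if (!all(p0$ids %in% op$core_ids)) stop("p0 must be supported on the core set")
    v <- numeric(length(op$core_ids))
    v[match(p0$ids, op$core_ids)] <- p0$probs
    v
  } else p0
  sink <- numeric(length(op$sink_ids))
  for (t in seq_len(steps)) {
    tp <- op$apply(p)
    rp <- op$apply_R(p)
    z <- sum(tp) + sum(rp)
    if (z <= 0) stop("population extinct: master-equation normalizer underflowed to 0")
    p <- tp / z
    sink <- rp / z
  }
  list(p = p, sink = sink)
}

#' Stationary distribution at mutation-selection balance
#'
#' Power iteration on the transition operator (with the constant no-mutation
#' diagonal term subtracted as a spectral shift, which leaves the
#' eigenvectors unchanged and keeps convergence fast as mu shrinks) yields
#' the leading eigenvector v1 of T; the stationary distribution over the
#' viable genotypes is `v1 / (1'v1 + 1'R v1 / lambda1)` on the core set and
#' `R v1 / lambda1` with the same normalizer on the sinks. Inviable
#' genotypes have stationary probability zero. Uniqueness follows from the
#' Perron-Frobenius theorem, since T is strictly positive for mu > 0.
#'
#' @param op a [build_transition_operator()] result.
#' @param tol stop when successive normalized iterates differ by less than
#'   this total-variation distance (default 1e-12).
#' @param max_iter iteration cap (default 1e5).
#' @param p0 optional start vector over the core set (default uniform).
#' @return List with `distribution` (a [grn_distribution()] over all viable
#'   genotypes) and `spectral` (leading value `lambda1`, sum-normalized
#'   `leading_vector` over the core set, `gap_ratio` estimate, `iterations`,
#'   and the fixed-point `residual` |T v - lambda v|_1 / lambda).
#' @export
stationary_distribution <- function(op, tol = 1e-12, max_iter = 1e5, p0 = NULL) {
  n <- length(op$core_ids)
  v <- if (is.null(p0)) rep(1 / n, n) else p0 / sum(p0)
  if (n == 1L) {
    lambda <- op$apply(1)
    rv <- op$apply_R(1)
    sm <- if (length(rv)) rv / lambda else numeric(0)
    return(list(
      distribution = grn_distribution(c(op$core_ids, op$sink_ids), c(1, sm),
                                      normalize = TRUE),
      spectral = list(leading_value = lambda, leading_vector = 1,
                      gap_ratio = NA_real_, iterations = 0L, residual = 0)))
  }
  sigma <- op$shift
  diff_prev <- NA_real_
  ratio <- NA_real_
  it <- 0L
  repeat {
    it <- it + 1L
    w <- op$apply(v) - sigma * v
    s <- sum(w)
    if (s <= 0) stop("shifted operator annihilated the iterate; is mu = 0 with ties?")
    w <- w / s
    d <- 0.5 * sum(abs(w - v))
    if (!is.na(diff_prev) && diff_prev > 0) ratio <- d / diff_prev
    diff_prev <- d
    v <- w
    if (d < tol) break
    if (it >= max_iter)
      stop("power iteration did not converge in ", max_iter,
           " iterations (last TV gap ", signif(d, 3), ")")
  }
  tv <- op$apply(v)
  lambda <- sum(tv)
  rv <- op$apply_R(v)
  sink_mass <- if (length(rv)) rv / lambda else numeric(0)
  denom <- 1 + sum(sink_mass)
  ids <- c(op$core_ids, op$sink_ids)
  probs <- c(v, sink_mass) / denom
  gap <- if (is.na(ratio)) NA_real_ else (sigma + ratio * (lambda - sigma)) / lambda
  list(distribution = grn_distribution(ids, probs, normalize = TRUE),
       spectral = list(leading_value = lambda, leading_vector = v,
                       gap_ratio = gap, iterations = it,
                       residual = sum(abs(tv - lambda * v)) / lambda))
}

#' Eigenvector-centrality distribution on a neutral network
#'
#' In the rare-mutation limit the stationary distribution of viable
#' genotypes converges to the sum-normalized leading eigenvector of the
#' neutral network's adjacency matrix, i.e. the eigenvector centrality of
#' the mega-nodes. Computed by power iteration on A + I (the unit shift
#' removes any bipartite oscillation without changing eigenvectors);
#' requires a connected network so that Perron-Frobenius applies.
#'
#' @param net a [build_neutral_network()] result.
#' @param tol,max_iter power-iteration controls as in
#'   [stationary_distribution()].
#' @param check verify connectivity first (default TRUE).
#' @return A [grn_distribution()] over the network's nodes with attribute
#'   `"leading_value"` (the adjacency spectral radius) and `"iterations"`.
#' @export
centrality_distribution <- function(net, tol = 1e-12, max_iter = 1e5,
                                    check = TRUE) {
  if (check) {
    cc <- is_connected(net)
    if (!cc$connected)
      stop("neutral network is disconnected (component sizes: ",
           paste(cc$component_sizes, collapse = ", "), ")")
  }
  A <- net$adjacency
  n <- length(net$node_ids)
  if (n == 1L) {
    out <- grn_distribution(net$node_ids, 1)
    attr(out, "leading_value") <- 0
    attr(out, "iterations") <- 0L
    return(out)
  }
  v <- rep(1 / n, n)
  it <- 0L
  repeat {
    it <- it + 1L
    w <- as.numeric(A %*% v) + v
    w <- w / sum(w)
    d <- 0.5 * sum(abs(w - v))
    v <- w
    if (d < tol) break
    if (it >= max_iter)
      stop("centrality power iteration did not converge in ", max_iter,
           " iterations (last TV gap ", signif(d, 3), ")")
  }
  out <- grn_distribution(net$node_ids, v)
  attr(out, "leading_value") <- sum(as.numeric(A %*% v))
  attr(out, "iterations") <- it
  out
}

#' Dense transition matrix for small genotype spaces
#'
#' Assembles T (and R) entry by entry from the explicit formula
#' `rho_{g'} mu_{g'g} nu_g`. Intended for diagnostics and cross-checks on
#' spaces of at most a few thousand genotypes; the matrix-free operator is
#' the production path.
#'
#' @param system a [grn_system()].
#' @param selection a [selection_model()].
#' @param mu per-locus mutation probability.
#' @param max_size refuse assembly beyond this core-set size.
#' @return List with dense matrices `T` (core x core) and `R`
#'   (sink x core), plus the id vectors.
#' @export
dense_transition_matrix <- function(system, selection, mu, max_size = 4096) {
  core <- selection$core
  sink <- selection$sinks
  if (length(core) > max_size)
    stop("core set larger than max_size; use the matrix-free operator")
  Rk <- genotype_ranks(core, system)
  d_of <- function(tgt_ids) {
    Rt <- genotype_ranks(tgt_ids, system)
    D <- matrix(0L, length(tgt_ids), length(core))
    for (j in seq_len(system$n_genes))
      D <- D + outer(Rt[, j], Rk[, j], "!=")
    D
  }
  K <- system$n_alleles
  G <- system$n_genes
  kern <- function(D) if (mu == 0) (D == 0) + 0 else
    (mu / (K - 1))^D * (1 - mu)^(G - D)
  rho_src <- selection$rho[core + 1]
  TT <- kern(d_of(core)) * rep(rho_src, each = length(core)) *
    selection$nu[core + 1]
  RR <- if (length(sink))
    kern(d_of(sink)) * rep(rho_src, each = length(sink)) *
      selection$nu[sink + 1]
  else matrix(0, 0, length(core))
  list(T = TT, R = RR, core_ids = core, sink_ids = sink)
}
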