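#' Fit the mutation-selection balance of a GRN system
#'
#' The central estimator of the package: given a GRN system, a selective
#' environment (or an explicit selection model) and a per-locus mutation
#' probability, computes the exact stationary distribution of genotypes at
#' mutation-selection balance as the normalized leading eigenvector of the
#' reproduction-mutation-viability transition operator.
#'
#' @param system a [grn_system()].
#' @param env a [grn_env()] (ignored if `selection` is supplied).
#' @param mu per-locus per-generation mutation probability.
#' @param selection optional [selection_model()]; default binary viability
#'   under `env` with uniform reproductivity.
#' @param tol,max_iter power-iteration controls, see
#'   [stationary_distribution()].
#' @return An object of class `msb` with components `distribution` (the
#'   stationary [grn_distribution()] over viable genotypes), `spectral`
#'   (leading eigenvalue, iterations, residual), `operator`, `system`,
#'   `env`, `mu`.
#' @examples
#' sys <- grn_fixture("reduced")
#' env <- grn_env(1L, fatals = 4L, universe = sys$universe)
#' fit <- msb(sys, env, mu = 0.1)
#' head(coef(fit))
#' @export
msb <- function(system, env = NULL, mu, selection = NULL,
                tol = 1e-12, max_iter = 1e5) {
  if (is.null(selection)) selection <- selection_model(system, env)
  op <- build_transition_operator(system, selection, mu)
  st <- stationary_distribution(op, tol = tol, max_iter = max_iter)
  structure(
    list(distribution = st$distribution, spectral = st$spectral,
         operator = op, system = system,
         env = if (is.null(env)) selection$env else env, mu = mu),
    class = "msb")
}

#' @export
print.msb <- function(x, ...) {
  cat("Mutation-selection balance fit\n")
  cat("  genotypes: ", x$system$n_genotypes, " total, ",
      length(x$distribution$ids), " viable\n", sep = "")
  cat("  mu = ", x$mu, ", lambda1 = ", signif(x$spectral$leading_value, 8),
      " (", x$spectral$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' @export
summary.msb <- function(object, ...) {
  d <- object$distribution
  top <- order(d$probs, decreasing = TRUE)[seq_len(min(5L, length(d$ids)))]
  out <- list(
    n_genotypes = object$system$n_genotypes,
    n_viable = length(d$ids),
    mu = object$mu,
    leading_value = object$spectral$leading_value,
    residual = object$spectral$residual,
    iterations = object$spectral$iterations,
    entropy = -sum(d$probs * log(d$probs)),
    top = data.frame(genotype = d$ids[top], probability = d$probs[top]))
  class(out) <- "summary.msb"
  out
}

#' @export
print.summary.msb <- function(x, ...) {
  cat("Mutation-selection balance over", x$n_viable, "viable of",
      x$n_genotypes, "genotypes (mu =", x$mu, ")\n")
  cat("  lambda1 =", signif(x$leading_value, 8),
      "| fixed-point residual =", signif(x$residual, 3),
      "| iterations =", x$iterations, "\n")
  cat("  Shannon entropy of the stationary distribution:",
      signif(x$entropy, 6), "nats\n")
  cat("  most probable genotypes:\n")
  print(transform(x$top, probability = signif(probability, 4)))
  invisible(x)
}

#' @export
coef.msb <- function(object, ...) {
  stats::setNames(object$distribution$probs, object$distribution$ids)
}

#' Stationary probabilities for specific genotypes
#'
#' @param object an [msb()] fit.
#' @param newdata genotype indices (0-based), or a matrix/list of
#'   allele-rank vectors; default all viable genotypes.
#' @param ... unused.
#' @return Numeric vector of stationary probabilities (0 for inviable
#'   genotypes).
#' @export
predict.msb <- function(object, newdata = NULL, ...) {
  d <- object$distribution
  if (is.null(newdata)) return(stats::setNames(d$probs, d$ids))
  ids <- if (is.matrix(newdata))
    apply(newdata, 1L, encode_grn, system = object$system)
  else if (is.list(newdata))
    vapply(newdata, encode_grn, numeric(1), system = object$system)
  else as.numeric(newdata)
  p <- numeric(length(ids))
  m <- match(ids, d$ids)
  p[!is.na(m)] <- d$probs[m[!is.na(m)]]
  stats::setNames(p, ids)
}

#' Draw genotype samples from a fitted stationary distribution
#'
#' @param object an [msb()] fit.
#' @param nsim number of independent genotype draws.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return Data frame with column `genotype` of sampled indices.
#' @export
simulate.msb <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$distribution
  data.frame(genotype = sample(d$ids, nsim, replace = TRUE, prob = d$probs))
}

#' Rank plot of the stationary distribution
#'
#' Viable genotypes ordered by increasing stationary probability, on a log
#' scale; optionally overlays the rare-mutation (eigenvector-centrality)
#' limit in grey for comparison.
#'
#' @param x an [msb()] fit.
#' @param centrality optional [centrality_distribution()] over the same
#'   genotypes.
#' @param ... passed to [graphics::plot()].
#' @export
plot.msb <- function(x, centrality = NULL, ...) {
  d <- x$distribution
  o <- order(d$probs)
  graphics::plot(seq_along(o), d$probs[o], log = "y", type = "l",
                 xlab = "viable GRNs (ordered by stationary probability)",
                 ylab = "probability", ...)
  if (!is.null(centrality)) {
    m <- match(d$ids[o], centrality$ids)
    graphics::lines(seq_along(o), centrality$probs[m], col = "grey50", lty = 2)
    graphics::legend("topleft", bty = "n", lty = c(1, 2),
                     col = c("black", "grey50"),
                     legend = c(paste0("stationary (mu = ", x$mu, ")"),
                                "rare-mutation limit"))
  }
  invisible(x)
}
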