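test_that("the mutation kernel follows its closed form and normalizes", {
  sys <- grn_fixture("case-study")
  g <- c(1L, 2L, 3L, 4L)
  expect_equal(mutation_probability(g, g, sys, 0.1), 0.9^4)
  g1 <- g; g1[2] <- 9L
  expect_equal(mutation_probability(g, g1, sys, 0.1), (0.1 / 15) * 0.9^3)
  # kernel rows sum to one over the full genotype space
  for (mu in c(0, 0.05, 0.3)) {
    M <- oracle_kernel(reduced_sys, mu)
    expect_equal(rowSums(M), rep(1, nrow(M)), tolerance = 1e-12)
  }
})

test_that("the single-locus factor reproduces the kernel by tensor application", {
  expect_equal(single_locus_factor(mutation_model(0, 5)), diag(5))
  expect_equal(single_locus_factor(mutation_model(0.1, 2)),
               matrix(c(0.9, 0.1, 0.1, 0.9), 2))
  expect_error(mutation_model(0.1, 1), "two alleles")
  # per-locus application of the factor equals the explicit kernel column
  sys <- reduced_sys
  M <- oracle_kernel(sys, 0.1)
  sel_all <- selection_model(sys, viability = function(ids, s) rep(1, length(ids)))
  op <- build_transition_operator(sys, sel_all, 0.1)
  for (src in c(0, 40, 80)) {
    point <- numeric(sys$n_genotypes)
    point[src + 1] <- 1
    expect_equal(op$apply(point), M[, src + 1], tolerance = 1e-14)
  }
})

test_that("the matrix-free operator agrees with dense entrywise assembly", {
  sys <- reduced_sys
  sel <- selection_model(sys, reduced_env)
  op <- build_transition_operator(sys, sel, 0.1)
  expect_length(op$sink_ids, 0L)
  dn <- oracle_dense_T(sys, sel, 0.1)
  set.seed(41)
  for (i in 1:100) {
    p <- runif(length(op$core_ids))
    p <- p / sum(p)
    expect_equal(op$apply(p), as.numeric(dn$T %*% p), tolerance = 1e-13)
  }
  # with sinks: reproductivity zero on part of the viable set
  sel2 <- selection_model(sys, viability = function(ids, s)
    viability_vector(s, reduced_env),
    reproductivity = function(ids, s) as.numeric(ids %% 3 != 0))
  op2 <- build_transition_operator(sys, sel2, 0.1)
  dn2 <- oracle_dense_T(sys, sel2, 0.1)
  p <- rep(1 / length(op2$core_ids), length(op2$core_ids))
  expect_equal(op2$apply(p), as.numeric(dn2$T %*% p), tolerance = 1e-14)
  expect_equal(op2$apply_R(p), as.numeric(dn2$R %*% p), tolerance = 1e-14)
})

test_that("degenerate operators are rejected or collapse as expected", {
  sys <- reduced_sys
  expect_error(
    build_transition_operator(
      sys, selection_model(sys, viability = function(ids, s) rep(0, length(ids))), 0.1),
    "inviable")
  expect_error(
    build_transition_operator(
      sys, selection_model(sys, reduced_env,
                           reproductivity = function(ids, s) rep(0, length(ids))), 0.1),
    "zero reproductivity")
  # mu = 0 keeps only the identity term: T p = rho p on the viable support
  sel <- selection_model(sys, reduced_env)
  op0 <- build_transition_operator(sys, sel, 0)
  p <- runif(length(op0$core_ids))
  expect_equal(op0$apply(p), p, tolerance = 1e-15)
})

test_that("master-equation iteration matches explicit dense-matrix steps", {
  sys <- reduced_sys
  sel <- selection_model(sys, reduced_env)
  op <- build_transition_operator(sys, sel, 0.1)
  dn <- oracle_dense_T(sys, sel, 0.1)
  n <- length(op$core_ids)
  p <- rep(1 / n, n)
  expect_equal(iterate_master_equation(p, op, 0)$p, p)
  q <- p
  for (t in 1:3) {
    tq <- as.numeric(dn$T %*% q)
    q <- tq / sum(tq)
  }
  expect_equal(iterate_master_equation(p, op, 3)$p, q, tolerance = 1e-12)
})

test_that("a symmetric no-selection system keeps the uniform distribution fixed", {
  sys <- reduced_sys
  env_free <- grn_env(1L, universe = sys$universe)  # nothing essential or fatal
  sel <- selection_model(sys, env_free)
  op <- build_transition_operator(sys, sel, 0.2)
  n <- length(op$core_ids)
  expect_equal(n, sys$n_genotypes)
  it <- iterate_master_equation(rep(1 / n, n), op, 5)
  expect_equal(it$p, rep(1 / n, n), tolerance = 1e-14)
  st <- stationary_distribution(op)
  expect_lt(total_variation(st$distribution$probs, rep(1 / n, n)), 1e-12)
})

test_that("power iteration reproduces the dense leading eigenvector", {
  sys <- reduced_sys
  sel <- selection_model(sys, reduced_env)
  op <- build_transition_operator(sys, sel, 0.1)
  st <- stationary_distribution(op)
  dn <- oracle_dense_T(sys, sel, 0.1)
  expect_lt(total_variation(st$distribution$probs, oracle_leading_vector(dn$T)), 1e-10)
  expect_equal(st$spectral$leading_value, max(Re(eigen(dn$T)$values)),
               tolerance = 1e-10)
  expect_lt(st$spectral$residual, 1e-10)
  # invariance to the starting vector
  set.seed(42)
  st2 <- stationary_distribution(op, p0 = runif(length(op$core_ids)))
  expect_lt(total_variation(st$distribution, st2$distribution), 1e-10)
  # eigenvalue bound: dominated by reproduction x viability caps
  expect_lte(st$spectral$leading_value,
             max(sel$rho) * max(sel$nu) + 1e-12)
})

test_that("sink genotypes receive their stationary mass R v / lambda", {
  sys <- reduced_sys
  sel <- selection_model(sys, viability = function(ids, s)
    viability_vector(s, reduced_env),
    reproductivity = function(ids, s) as.numeric(ids %% 3 != 0))
  op <- build_transition_operator(sys, sel, 0.1)
  st <- stationary_distribution(op)
  dn <- oracle_dense_T(sys, sel, 0.1)
  v <- oracle_leading_vector(dn$T)
  lam <- max(Re(eigen(dn$T)$values))
  sink <- as.numeric(dn$R %*% v) / lam
  expected <- c(v, sink) / (sum(v) + sum(sink))
  got <- st$distribution$probs[match(c(sel$core, sel$sinks), st$distribution$ids)]
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("eigenvector centrality matches dense solutions on known graphs", {
  # complete graph: uniform centrality
  sys <- grn_fixture("micro")
  k4 <- structure(list(
    node_ids = 0:3,
    adjacency = Matrix::Matrix(1, 4, 4, sparse = TRUE) - Matrix::Diagonal(4),
    system = sys, env = NULL), class = "neutral_network")
  expect_equal(centrality_distribution(k4, check = FALSE)$probs, rep(0.25, 4))
  # star on 4 nodes: centre sqrt(3)/(sqrt(3)+3), leaves 1/(sqrt(3)+3)
  A <- Matrix::sparseMatrix(i = c(1, 1, 1, 2, 3, 4), j = c(2, 3, 4, 1, 1, 1),
                            x = 1, dims = c(4, 4))
  star <- structure(list(node_ids = 0:3, adjacency = A, system = sys,
                         env = NULL), class = "neutral_network")
  cen <- centrality_distribution(star, check = FALSE)
  expect_equal(cen$probs, c(sqrt(3), 1, 1, 1) / (sqrt(3) + 3), tolerance = 1e-10)
  expect_equal(attr(cen, "leading_value"), sqrt(3), tolerance = 1e-10)
  # a disconnected network is refused with component sizes named
  two <- build_neutral_network(reduced_sys, nodes = c(0, 80))
  expect_error(centrality_distribution(two), "disconnected")
})

test_that("neutral-network centrality agrees with a dense eigensolver", {
  net <- build_neutral_network(reduced_sys, reduced_env)
  cen <- centrality_distribution(net)
  expect_lt(total_variation(cen$probs,
                            oracle_leading_vector(as.matrix(net$adjacency))),
            1e-10)
  expect_true(all(cen$probs > 0))
})

test_that("the stationary distribution approaches centrality as mutation becomes rare", {
  sys <- reduced_sys
  sel <- selection_model(sys, reduced_env)
  cen <- centrality_distribution(build_neutral_network(sys, reduced_env))
  tvs <- vapply(c(0.1, 0.03, 0.01, 0.003, 0.001, 1e-4), function(mu) {
    st <- stationary_distribution(build_transition_operator(sys, sel, mu),
                                  max_iter = 1e6)
    total_variation(st$distribution, cen)
  }, numeric(1))
  expect_true(all(diff(tvs) < 0))
  expect_lt(tvs[6], 1e-3)
})

test_that("relabelling symmetries permute the stationary distribution", {
  sys <- reduced_sys
  sel <- selection_model(sys, reduced_env)
  st <- stationary_distribution(build_transition_operator(sys, sel, 0.1))
  p <- numeric(sys$n_genotypes)
  p[st$distribution$ids + 1] <- st$distribution$probs
  # gene swap: digit transposition of the genotype index
  K <- sys$n_alleles
  swapped <- (seq_len(sys$n_genotypes) - 1) %% K * K +
    (seq_len(sys$n_genotypes) - 1) %/% K
  expect_equal(p, p[swapped + 1], tolerance = 1e-10)
  # internal-protein swap 2 <-> 3 fixes the environment, permutes alleles
  perm_prot <- c(1L, 3L, 2L, 4L)
  al <- sys$alleles
  perm_allele <- vapply(seq_len(nrow(al)), function(r)
    allele_rank(sys, perm_prot[al[r, 1]], perm_prot[al[r, 2]]), integer(1))
  R <- decode_grn(seq_len(sys$n_genotypes) - 1, sys)
  permuted_ids <- apply(matrix(perm_allele[R], ncol = 2), 1L, encode_grn,
                        system = sys)
  expect_equal(p, p[permuted_ids + 1], tolerance = 1e-10)
})
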