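# Independent oracles for exhaustive checks on small genotype spaces.
# These deliberately avoid the package's production code paths: mutation
# kernels are evaluated from the closed form genotype pair by genotype pair,
# eigenvectors come from dense base::eigen or igraph's ARPACK, reachability
# for the brute-force viability oracle is done with igraph.

reduced_sys <- grn_fixture("reduced")
reduced_env <- grn_env(1L, fatals = 4L, universe = reduced_sys$universe)

# pairwise allele-difference counts between two id sets
oracle_distance <- function(ids_to, ids_from, system) {
  Rt <- decode_grn(ids_to, system)
  Rf <- decode_grn(ids_from, system)
  D <- matrix(0L, length(ids_to), length(ids_from))
  for (j in seq_len(system$n_genes)) D <- D + outer(Rt[, j], Rf[, j], "!=")
  D
}

# dense mutation kernel over the full genotype space from the closed form
oracle_kernel <- function(system, mu) {
  ids <- seq_len(system$n_genotypes) - 1
  D <- oracle_distance(ids, ids, system)
  K <- system$n_alleles
  if (mu == 0) return((D == 0) + 0)
  (mu / (K - 1))^D * (1 - mu)^(system$n_genes - D)
}

# dense T (and R) restricted from the full-space entry formula
# T[g, g'] = rho_{g'} mu_{g'g} nu_g
oracle_dense_T <- function(system, selection, mu) {
  M <- oracle_kernel(system, mu)
  full <- sweep(sweep(M, 2, selection$rho, "*"), 1, selection$nu, "*")
  core <- selection$core + 1
  sink <- selection$sinks + 1
  list(T = full[core, core, drop = FALSE],
       R = full[sink, core, drop = FALSE])
}

# normalized leading eigenvector of a dense symmetric-or-not matrix
oracle_leading_vector <- function(M) {
  e <- eigen(M)
  v <- abs(Re(e$vectors[, 1]))
  v / sum(v)
}

# brute-force viability of one genotype via igraph reachability
oracle_viable <- function(id, system, env) {
  ranks <- drop(decode_grn(id, system))
  g <- igraph::make_empty_graph(n = system$universe$n)
  g <- igraph::add_edges(g, rbind(system$alleles[ranks, 1L],
                                  system$alleles[ranks, 2L]))
  if (!length(env$stimuli)) present <- integer()
  else {
    d <- igraph::distances(g, v = env$stimuli, mode = "out")
    present <- which(apply(is.finite(d), 2, any))
  }
  all(env$essentials %in% present) && !any(env$fatals %in% present)
}

# scalar structural predicate evaluation for the prevalence oracle
oracle_group_ok <- function(id, system, env, group) {
  ranks <- drop(decode_grn(id, system))
  act <- system$alleles[ranks, 1L]
  prod <- system$alleles[ranks, 2L]
  roles <- system$universe$roles
  ph <- express_cascade(ranks, system, env$stimuli)
  spare <- (act == prod) |
    (roles[act] == "input" & !(act %in% env$stimuli)) |
    (roles[prod] == "output" & !(prod %in% c(env$essentials, env$fatals)))
  ok <- TRUE
  if (group$no_spare) ok <- ok && !any(spare)
  if (group$no_redundant) ok <- ok && !anyDuplicated(ranks)
  if (group$all_activated) ok <- ok && all(act %in% ph)
  if (group$no_direct_selection)
    ok <- ok && !any(act %in% env$stimuli & prod %in% env$essentials)
  ok
}

# a small pool of randomized reduced-universe environments with a nonempty
# viable set (stimuli from inputs; essentials/fatals disjoint)
random_reduced_envs <- function(n, seed) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    ess <- if (stats::runif(1) < 0.5) sample(2:4, 1) else integer()
    fat <- setdiff(sample(2:4, sample(0:2, 1)), ess)
    env <- try(grn_env(1L, ess, fat, universe = reduced_sys$universe),
               silent = TRUE)
    if (inherits(env, "try-error")) next
    if (sum(viability_vector(reduced_sys, env)) == 0) next
    out[[length(out) + 1L]] <- env
  }
  out
}

allele_rank <- function(system, a, p)
  which(system$alleles[, 1L] == a & system$alleles[, 2L] == p)
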