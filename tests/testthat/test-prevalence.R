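test_that("the seven reference environments are exactly specified", {
  envs <- reference_environments()
  expect_named(envs, paste0("env", 1:7))
  expect_equal(envs$env1, grn_env(1L, integer(), 6L))
  expect_equal(envs$env2$fatals, c(5L, 6L))
  expect_equal(envs$env3$stimuli, c(1L, 2L))
  expect_equal(envs$env4$essentials, 6L)
  expect_equal(envs$env5$essentials, c(5L, 6L))
  expect_equal(envs$env6, grn_env(c(1L, 2L), 6L, integer()))
  expect_equal(envs$env7$essentials, 5L)
  expect_equal(envs$env7$fatals, 6L)
  for (e in envs) expect_length(intersect(e$essentials, e$fatals), 0L)
})

test_that("the eight constraint groups map labels to flags exactly", {
  g <- constraint_groups()
  expect_equal(g$label, c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii"))
  flags <- as.matrix(g[, -1]) + 0
  expected <- rbind(c(0,0,0,0), c(1,0,0,0), c(1,1,0,0), c(1,0,1,0),
                    c(1,1,1,0), c(0,1,0,0), c(0,0,0,1), c(0,1,0,1))
  expect_equal(unname(flags), expected)
})

test_that("gene spareness covers its three clauses", {
  sys <- grn_fixture("case-study")
  envs <- reference_environments()
  g33 <- allele_rank(sys, 3, 3)
  g25 <- allele_rank(sys, 2, 5)
  g16 <- allele_rank(sys, 1, 6)
  grn <- c(g33, g25, g16, allele_rank(sys, 1, 5))
  expect_true(is_spare_gene(1, grn, sys, envs$env1))   # self-pair
  expect_true(is_spare_gene(2, grn, sys, envs$env1))   # unstimulated input 2, effect-free 5
  expect_false(is_spare_gene(3, grn, sys, envs$env1))  # stimulus to fatal output
  expect_true(is_spare_gene(4, grn, sys, envs$env1))   # product 5 effect-free in env1
  expect_false(is_spare_gene(4, grn, sys, envs$env5))  # 5 essential under env5
})

test_that("redundancy, activation and direct selection predicates", {
  sys <- grn_fixture("case-study")
  envs <- reference_environments()
  expect_true(has_redundant_genes(c(3L, 3L, 1L, 2L)))
  expect_false(has_redundant_genes(c(1L, 2L, 3L, 4L)))
  expect_false(has_redundant_genes(7L))  # single gene
  g <- c(allele_rank(sys, 1, 3), allele_rank(sys, 3, 5),
         allele_rank(sys, 3, 4), allele_rank(sys, 4, 4))
  expect_true(all_genes_activated(g, sys, envs$env1))
  g2 <- g; g2[3] <- allele_rank(sys, 2, 4)  # input 2 unstimulated in env1
  expect_false(all_genes_activated(g2, sys, envs$env1))
  expect_true(all_genes_activated(g2, sys, envs$env3))
  expect_true(has_direct_selection(c(allele_rank(sys, 1, 6), g[-1]), sys, envs$env4))
  expect_false(has_direct_selection(c(allele_rank(sys, 3, 6), g[-1]), sys, envs$env4))
  expect_false(has_direct_selection(g, sys, envs$env1))  # empty essentials
})

test_that("vectorized group membership equals the scalar predicate oracle", {
  sys <- reduced_sys
  groups <- constraint_groups()
  for (env in random_reduced_envs(2, seed = 61)) {
    ids <- seq_len(sys$n_genotypes) - 1
    for (k in seq_len(nrow(groups))) {
      got <- satisfies_group(ids, sys, env, groups[k, ])
      want <- vapply(ids, oracle_group_ok, logical(1),
                     system = sys, env = env, group = groups[k, ])
      expect_equal(got, want)
    }
  }
})

test_that("gene relabelling canonicalization sorts allele ranks", {
  sys <- grn_fixture("reduced")
  r13 <- allele_rank(sys, 1, 3)
  r35 <- allele_rank(sys, 3, 4)
  stopifnot(r13 < r35)
  can <- gene_relabel_canonicalize(c(r35, r13), sys)
  expect_equal(as.integer(can), c(r13, r35))
  expect_equal(as.integer(gene_relabel_canonicalize(can, sys)), as.integer(can))
  # orbit identity: orbit sizes sum to the number of genotypes
  ids <- seq_len(sys$n_genotypes) - 1
  canon <- vapply(ids, function(id)
    attr(gene_relabel_canonicalize(system = sys, index = id), "index"), numeric(1))
  orbit_sizes <- table(canon)
  expect_equal(sum(orbit_sizes), sys$n_genotypes)
  # a 2-gene orbit has size 1 (equal ranks) or 2 (distinct ranks)
  expect_true(all(orbit_sizes %in% c(1L, 2L)))
  expect_equal(sum(orbit_sizes == 1L), sys$n_alleles)
})

test_that("centrality is constant on gene-relabelling orbits", {
  net <- build_neutral_network(reduced_sys, reduced_env)
  cen <- centrality_distribution(net)
  canon <- vapply(cen$ids, function(id)
    attr(gene_relabel_canonicalize(system = reduced_sys, index = id), "index"),
    numeric(1))
  spread <- tapply(cen$probs, canon, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-12)
})

test_that("most_prevalent equals the exhaustive argmax oracle on the reduced universe", {
  sys <- reduced_sys
  groups <- constraint_groups()
  for (env in list(reduced_env, grn_env(1L, essentials = 4L, universe = sys$universe))) {
    net <- build_neutral_network(sys, env)
    cen <- centrality_distribution(net)
    oracle_cen <- oracle_leading_vector(as.matrix(net$adjacency))
    for (k in seq_len(nrow(groups))) {
      ok <- vapply(net$node_ids, oracle_group_ok, logical(1),
                   system = sys, env = env, group = groups[k, ])
      if (!any(ok)) {
        expect_error(most_prevalent(sys, env, groups[k, ], net = net,
                                    centrality = cen), "constraints")
        next
      }
      rep <- most_prevalent(sys, env, groups[k, ], net = net, centrality = cen)
      mx <- max(oracle_cen[ok])
      arg <- net$node_ids[ok][oracle_cen[ok] >= mx * (1 - 1e-9)]
      expect_equal(sort(rep$argmax_ids), sort(arg))
      expect_equal(rep$max_centrality, mx, tolerance = 1e-9)
      # every reported maximizer is viable and satisfies the group
      expect_true(all(rep$argmax_ids %in% net$node_ids))
      expect_true(all(vapply(rep$argmax_ids, oracle_group_ok, logical(1),
                             system = sys, env = env, group = groups[k, ])))
      # the canonical representative belongs to an argmax orbit
      rep_id <- attr(rep$representative, "index")
      expect_true(attr(gene_relabel_canonicalize(system = sys, index = rep$argmax_ids[1]),
                       "index") %in%
                    vapply(rep$argmax_ids, function(i)
                      attr(gene_relabel_canonicalize(system = sys, index = i), "index"),
                      numeric(1)))
      expect_true(rep_id %in% vapply(rep$argmax_ids, function(i)
        attr(gene_relabel_canonicalize(system = sys, index = i), "index"), numeric(1)))
    }
  }
})

test_that("induced-mode centrality is computed on the largest component", {
  sys <- reduced_sys
  env <- reduced_env
  rep_f <- most_prevalent(sys, env, "ii", mode = "filter")
  rep_i <- most_prevalent(sys, env, "ii", mode = "induced")
  expect_s3_class(rep_i, "prevalence_report")
  # induced maximizers still satisfy the group and viability
  gr <- constraint_groups(); g2 <- gr[gr$label == "ii", ]
  expect_true(all(vapply(rep_i$argmax_ids, oracle_group_ok, logical(1),
                         system = sys, env = env, group = g2)))
  expect_true(all(rep_i$argmax_ids %in%
                    build_neutral_network(sys, env)$node_ids))
  expect_false(identical(rep_f$mode, rep_i$mode))
})

test_that("genotypes render in pathway and conventional representations", {
  sys <- grn_fixture("case-study")
  g <- c(allele_rank(sys, 1, 3), allele_rank(sys, 3, 5),
         allele_rank(sys, 3, 4), allele_rank(sys, 4, 4))
  gp <- grn_as_igraph(g, sys, "pathway")
  expect_equal(igraph::gorder(gp), 6L)
  expect_equal(igraph::gsize(gp), 4L)
  gc <- grn_as_igraph(g, sys, "conventional")
  expect_equal(igraph::gorder(gc), 4L)
  # regulation edges: A(1,3) regulates B(3,5) and C(3,4); C regulates D(4,4); D self
  expect_equal(igraph::gsize(gc), 4L)
})
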