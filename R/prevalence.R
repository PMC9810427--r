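#' Structural constraint groups
#'
#' The eight groups of genotypes obtained by combining four structural
#' constraints: excluding spare genes, excluding redundant genes, requiring
#' all genes to be functionally activated, and excluding direct selection
#' (a stimulus-activated gene producing an essential protein).
#'
#' @return Data frame with columns `label` (i .. viii) and the four logical
#'   flags `no_spare`, `no_redundant`, `all_activated`,
#'   `no_direct_selection`.
#' @export
constraint_groups <- function() {
  data.frame(
    label = c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii"),
    no_spare             = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    no_redundant         = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    all_activated        = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    no_direct_selection  = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# ---- structural predicates -------------------------------------------------

# logical n x n_genes matrix of gene spareness for genotypes given as a rank
# matrix R (rows: genotypes).
spare_gene_matrix <- function(R, system, env) {
  act <- matrix(system$alleles[R, 1L], nrow(R), ncol(R))
  prod <- matrix(system$alleles[R, 2L], nrow(R), ncol(R))
  roles <- system$universe$roles
  effect <- c(env$essentials, env$fatals)
  (act == prod) |
    (matrix(roles[act] == "input", nrow(R)) & !(act %in% env$stimuli)) |
    (matrix(roles[prod] == "output", nrow(R)) & !(prod %in% effect))
}

#' Is a gene spare in a genotype?
#'
#' A gene is spare when it has negligible phenotypic consequence: it is
#' self-regulating (activator = product), its activator is an input protein
#' that is not externally stimulated, or its product is an output protein
#' with no essential or fatal effect under the environment.
#'
#' @param gene gene position (1-based).
#' @param ranks allele-rank vector of the genotype.
#' @param system a [grn_system()].
#' @param env a [grn_env()].
#' @export
is_spare_gene <- function(gene, ranks, system, env) {
  spare_gene_matrix(matrix(ranks, nrow = 1), system, env)[1, gene]
}

#' Does a genotype carry redundant genes?
#'
#' TRUE iff at least two genes carry the identical (activator, product)
#' allele.
#'
#' @param ranks allele-rank vector.
#' @export
has_redundant_genes <- function(ranks) anyDuplicated(ranks) > 0L

#' Are all genes functionally activated?
#'
#' TRUE iff every gene's activator protein is present in the genotype's
#' phenotype under the environment's stimuli.
#'
#' @param ranks allele-rank vector.
#' @param system a [grn_system()].
#' @param env a [grn_env()].
#' @export
all_genes_activated <- function(ranks, system, env) {
  ph <- express_cascade(ranks, system, env$stimuli)
  all(system$alleles[ranks, 1L] %in% ph)
}

#' Is any gene under direct selection?
#'
#' TRUE iff some gene is activated by a stimulated protein and produces an
#' essential protein.
#'
#' @param ranks allele-rank vector.
#' @param system a [grn_system()].
#' @param env a [grn_env()].
#' @export
has_direct_selection <- function(ranks, system, env) {
  any(system$alleles[ranks, 1L] %in% env$stimuli &
        system$alleles[ranks, 2L] %in% env$essentials)
}

#' Which genotypes satisfy a constraint group?
#'
#' Vectorized evaluation of the four structural constraints over a set of
#' genotype indices.
#'
#' @param ids genotype indices (0-based).
#' @param system a [grn_system()].
#' @param env a [grn_env()].
#' @param group one row of [constraint_groups()], or a group label.
#' @return Logical vector along `ids`.
#' @export
satisfies_group <- function(ids, system, env, group) {
  if (is.character(group)) {
    gr <- constraint_groups()
    group <- gr[gr$label == group, ]
    if (!nrow(group)) stop("unknown constraint group label")
  }
  R <- genotype_ranks(ids, system)
  ok <- rep(TRUE, length(ids))
  if (group$no_spare)
    ok <- ok & rowSums(spare_gene_matrix(R, system, env)) == 0
  if (group$no_redundant) {
    dup <- rep(FALSE, length(ids))
    for (j1 in seq_len(ncol(R) - 1L)) for (j2 in (j1 + 1L):ncol(R))
      dup <- dup | (R[, j1] == R[, j2])
    ok <- ok & !dup
  }
  if (group$all_activated) {
    P <- phenotype_matrix(system, env$stimuli, ids)
    act_ok <- rep(TRUE, length(ids))
    for (j in seq_len(ncol(R)))
      act_ok <- act_ok & P[cbind(seq_along(ids), system$alleles[R[, j], 1L])]
    ok <- ok & act_ok
  }
  if (group$no_direct_selection) {
    direct <- rep(FALSE, length(ids))
    for (j in seq_len(ncol(R)))
      direct <- direct | (system$alleles[R[, j], 1L] %in% env$stimuli &
                            system$alleles[R[, j], 2L] %in% env$essentials)
    ok <- ok & !direct
  }
  ok
}

#' Canonical genotype under gene relabelling
#'
#' Genes are distinguishable labels, so permuting which gene carries which
#' allele yields a different genotype with the same role in the neutral
#' network. The canonical representative of that orbit is the
#' lexicographically minimal genotype, i.e. the one with sorted allele
#' ranks.
#'
#' @param ranks allele-rank vector (or use `index`).
#' @param system a [grn_system()].
#' @param index genotype index alternative to `ranks`.
#' @return The canonical allele-rank vector, with the canonical genotype
#'   index in attribute `"index"`.
#' @export
gene_relabel_canonicalize <- function(ranks = NULL, system, index = NULL) {
  if (is.null(ranks)) ranks <- drop(decode_grn(index, system))
  can <- sort(ranks)
  attr(can, "index") <- encode_grn(can, system)
  can
}

#' Most prevalent genotypes of an environment and constraint group
#'
#' Identifies the genotypes with the greatest eigenvector centrality in the
#' environment's neutral network among those satisfying the constraint
#' group, i.e. the genotypes with the largest predicted probability under
#' mutation-selection balance in the rare-mutation limit. In `"filter"`
#' mode (default) centrality is computed on the full neutral network and
#' the argmax is restricted to group-satisfying nodes; in `"induced"` mode
#' centrality is recomputed on the largest connected component of the
#' group-induced subgraph (structural groups carry no connectedness
#' guarantee, hence the component restriction).
#'
#' @param system a [grn_system()].
#' @param env a [grn_env()].
#' @param group a label (`"i"` .. `"viii"`) or a row of
#'   [constraint_groups()].
#' @param mode `"filter"` or `"induced"`.
#' @param tie_tol relative tolerance within which centralities count as
#'   tied (default 1e-9).
#' @param net,centrality optional precomputed neutral network and
#'   centrality for the environment (reused across groups).
#' @return An object of class `prevalence_report`: `group`, `mode`,
#'   `max_centrality`, `argmax_ids` (all tied maximizers),
#'   `representative` (canonical allele-rank vector of the minimal orbit
#'   representative), `n_candidates`.
#' @export
most_prevalent <- function(system, env, group, mode = c("filter", "induced"),
                           tie_tol = 1e-9, net = NULL, centrality = NULL) {
  mode <- match.arg(mode)
  if (is.character(group)) {
    gr <- constraint_groups()
    group <- gr[gr$label == group, ]
    if (!nrow(group)) stop("unknown constraint group label")
  }
  if (is.null(net)) net <- build_neutral_network(system, env)
  sat <- satisfies_group(net$node_ids, system, env, group)
  if (!any(sat)) {
    on <- names(group)[-1][unlist(group[-1])]
    stop("no viable genotype satisfies the group's constraints (",
         paste(on, collapse = " + "), ")")
  }
  if (mode == "filter") {
    if (is.null(centrality)) centrality <- centrality_distribution(net)
    cent_ids <- centrality$ids
    cent <- centrality$probs
    cand <- which(sat)
  } else {
    sub_ids <- net$node_ids[sat]
    sub <- build_neutral_network(system, nodes = sub_ids)
    comp <- is_connected(sub)
    if (!comp$connected) {
      g <- igraph::graph_from_adjacency_matrix(sub$adjacency, mode = "undirected")
      mem <- igraph::components(g)$membership
      big <- which.max(tabulate(mem))
      sub <- build_neutral_network(system, nodes = sub_ids[mem == big])
    }
    centrality <- centrality_distribution(sub, check = FALSE)
    cent_ids <- centrality$ids
    cent <- centrality$probs
    cand <- seq_along(cent_ids)
  }
  mx <- max(cent[cand])
  arg <- cand[cent[cand] >= mx * (1 - tie_tol)]
  arg_ids <- cent_ids[arg]
  canon <- vapply(arg_ids, function(id)
    attr(gene_relabel_canonicalize(system = system, index = id), "index"),
    numeric(1))
  rep_ranks <- gene_relabel_canonicalize(system = system, index = min(canon))
  structure(list(group = group, mode = mode, env = env,
                 max_centrality = mx, argmax_ids = arg_ids,
                 representative = rep_ranks,
                 n_candidates = length(cand)),
            class = "prevalence_report")
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat("Prevalence report (group ", x$group$label, ", mode ", x$mode, ")\n",
      sep = "")
  cat("  max centrality ", signif(x$max_centrality, 6), " attained by ",
      length(x$argmax_ids), " genotype(s) of ", x$n_candidates,
      " candidates\n", sep = "")
  cat("  canonical representative: index ", attr(x$representative, "index"),
      "\n", sep = "")
  invisible(x)
}

#' Render a genotype as a graph
#'
#' Two representations of the same genotype: the pathway representation has
#' protein nodes and one gene-labelled directed edge per gene (activator to
#' product); the conventional representation has gene nodes with an edge
#' from gene x to gene y when x's product is y's activator.
#'
#' @param ranks allele-rank vector.
#' @param system a [grn_system()].
#' @param representation `"pathway"` or `"conventional"`.
#' @return An igraph graph.
#' @export
grn_as_igraph <- function(ranks, system,
                          representation = c("pathway", "conventional")) {
  representation <- match.arg(representation)
  act <- system$alleles[ranks, 1L]
  prod <- system$alleles[ranks, 2L]
  if (representation == "pathway") {
    g <- igraph::make_empty_graph(n = system$universe$n)
    igraph::V(g)$name <- system$universe$labels
    g <- igraph::add_edges(g, rbind(act, prod))
    igraph::E(g)$gene <- system$gene_labels[seq_along(ranks)]
  } else {
    g <- igraph::make_empty_graph(n = length(ranks))
    igraph::V(g)$name <- system$gene_labels[seq_along(ranks)]
    e <- which(outer(prod, act, "=="), arr.ind = TRUE)
    if (nrow(e)) g <- igraph::add_edges(g, rbind(e[, 1], e[, 2]))
  }
  g
}
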