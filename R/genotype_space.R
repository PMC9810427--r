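# radix weight of gene j in the mixed-radix genotype index
gene_radix <- function(system, j) system$n_alleles^(j - 1)

#' Single-locus mutational neighbours of a genotype
#'
#' Two genotypes are mutational neighbours when they differ by the allele of
#' exactly one gene; every genotype therefore has
#' `n_genes * (n_alleles - 1)` neighbours, which makes the full genotype
#' network a regular graph.
#'
#' @param ranks allele-rank vector of the genotype.
#' @param system a [grn_system()].
#' @return Integer matrix of neighbour genotypes (one row each, columns =
#'   genes), with the neighbour indices in attribute `"index"`.
#' @export
mutational_neighbors <- function(ranks, system) {
  K <- system$n_alleles
  G <- system$n_genes
  out <- matrix(0L, nrow = G * (K - 1L), ncol = G,
                dimnames = list(NULL, system$gene_labels))
  idx <- numeric(G * (K - 1L))
  base <- encode_grn(ranks, system)
  r <- 0L
  for (j in seq_len(G)) for (a in seq_len(K)) {
    if (a == ranks[j]) next
    r <- r + 1L
    nb <- ranks
    nb[j] <- a
    out[r, ] <- nb
    idx[r] <- base + (a - ranks[j]) * gene_radix(system, j)
  }
  attr(out, "index") <- idx
  out
}

# Edge list (upper triangle) of single-locus mutations within a node set.
# ids must be sorted ascending; returns positions into ids.
mutation_edges <- function(ids, system) {
  K <- system$n_alleles
  pos <- rep(NA_integer_, system$n_genotypes)
  pos[ids + 1] <- seq_along(ids)
  R <- genotype_ranks(ids, system)
  ei <- ek <- vector("list", system$n_genes * (K - 1L))
  n <- 0L
  for (j in seq_len(system$n_genes)) {
    w <- gene_radix(system, j)
    for (a in seq_len(K)) {
      nb <- ids + (a - R[, j]) * w
      sel <- (R[, j] != a) & nb > ids
      if (!any(sel)) next
      nbp <- pos[nb[sel] + 1]
      keep <- !is.na(nbp)
      if (!any(keep)) next
      n <- n + 1L
      ei[[n]] <- pos[ids[sel][keep] + 1]
      ek[[n]] <- nbp[keep]
    }
  }
  cbind(from = unlist(ei[seq_len(n)]), to = unlist(ek[seq_len(n)]))
}

#' Build the neutral network (or the full genotype network)
#'
#' Mega-nodes are genotypes, edges are single-locus mutations. The neutral
#' network is the induced subgraph over the viable genotypes (more generally
#' over any node set of equal viability and reproductivity); with no
#' environment and no node set, the full genotype network is returned.
#'
#' @param system a [grn_system()].
#' @param env optional [grn_env()]; nodes default to the binary-viable set.
#' @param nodes optional explicit genotype indices (0-based) overriding the
#'   environment-derived node set.
#' @param size_cap refuse enumeration beyond this many genotypes; beyond it,
#'   use the matrix-free operator routines instead.
#' @return An object of class `neutral_network`: `node_ids` (ascending
#'   genotype indices), `adjacency` (symmetric sparse 0/1 matrix), `system`,
#'   `env`.
#' @examples
#' sys <- grn_fixture("reduced")
#' net <- build_neutral_network(sys, grn_env(1L, fatals = 4L, universe = sys$universe))
#' @export
build_neutral_network <- function(system, env = NULL, nodes = NULL,
                                  size_cap = 2^20) {
  if (system$n_genotypes > size_cap)
    stop("genotype space larger than size_cap (", size_cap,
         "); adjacency cannot be materialized — use the matrix-free ",
         "transition operator instead", call. = FALSE)
  ids <- if (!is.null(nodes)) sort(unique(as.numeric(nodes)))
         else if (!is.null(env)) {
           nu <- viability_vector(system, env, size_cap = size_cap)
           (seq_len(system$n_genotypes) - 1)[nu > 0]
         } else seq_len(system$n_genotypes) - 1
  if (!length(ids)) stop("empty node set: no viable genotype under this environment")
  ed <- mutation_edges(ids, system)
  adj <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                              x = 1, dims = c(length(ids), length(ids)))
  structure(list(node_ids = ids, adjacency = adj, system = system, env = env),
            class = "neutral_network")
}

#' @export
print.neutral_network <- function(x, ...) {
  cat("Neutral network:", length(x$node_ids), "nodes,",
      Matrix::nnzero(x$adjacency) / 2, "edges\n")
  invisible(x)
}

#' Connectivity of a neutral network
#'
#' Graph search over the mega-nodes; the induced subgraph of the genotype
#' network under any phenotypic constraint is expected to be connected.
#'
#' @param net a [build_neutral_network()] result.
#' @return List with `connected` (logical), `n_components` and
#'   `component_sizes` (descending).
#' @export
is_connected <- function(net) {
  if (!length(net$node_ids)) stop("empty network")
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                           weighted = NULL)
  comp <- igraph::components(g)
  list(connected = comp$no == 1L, n_components = comp$no,
       component_sizes = sort(comp$csize, decreasing = TRUE))
}

#' Shortest neutral path between two genotypes
#'
#' Breadth-first search through genotypes satisfying a predicate: returns a
#' shortest sequence of single-locus mutations from `from` to `to` in which
#' every intermediate genotype also satisfies the predicate.
#'
#' @param from,to genotype indices (0-based).
#' @param system a [grn_system()].
#' @param predicate logical vector over the full genotype space (TRUE =
#'   admissible), or a function `(ids, system) -> logical`.
#' @return Numeric vector of genotype indices from `from` to `to` inclusive.
#' @export
neutral_path <- function(from, to, system, predicate) {
  ok <- if (is.function(predicate))
    predicate(seq_len(system$n_genotypes) - 1, system) else predicate
  if (!ok[from + 1] || !ok[to + 1])
    stop("both endpoints must satisfy the predicate")
  if (from == to) return(from)
  K <- system$n_alleles
  parent <- rep(NA_real_, system$n_genotypes)
  seen <- logical(system$n_genotypes)
  seen[from + 1] <- TRUE
  frontier <- from
  repeat {
    R <- genotype_ranks(frontier, system)
    nxt <- numeric(0)
    for (j in seq_len(system$n_genes)) {
      w <- gene_radix(system, j)
      for (a in seq_len(K)) {
        nb <- frontier + (a - R[, j]) * w
        sel <- (R[, j] != a) & ok[nb + 1] & !seen[nb + 1]
        if (!any(sel)) next
        nbs <- nb[sel]
        first <- !duplicated(nbs)
        nbs <- nbs[first]
        parent[nbs + 1] <- frontier[sel][first]
        seen[nbs + 1] <- TRUE
        nxt <- c(nxt, nbs)
      }
    }
    if (seen[to + 1]) break
    if (!length(nxt))
      stop("no neutral path found: predicate-satisfying set is disconnected ",
           "(non-phenotypic predicate, or a bug)")
    frontier <- nxt
  }
  path <- to
  while (path[1] != from) path <- c(parent[path[1] + 1], path)
  path
}

#' Construct a naive viable genotype for an environment
#'
#' The naive construction assigns, for each essential protein, one gene with
#' a stimulated activator producing that protein, and fills the remaining
#' genes with phenotype-redundant alleles (duplicates of an essential gene,
#' self-pairs, or otherwise spare pairs) that do not open a path to a fatal
#' protein.
#'
#' @param env a [grn_env()].
#' @param system a [grn_system()].
#' @return Allele-rank vector of a genotype that is viable under `env`.
#' @export
construct_naive_grn <- function(env, system) {
  al <- system$alleles
  roles <- system$universe$roles
  required <- setdiff(env$essentials, env$stimuli)
  if (length(required) > system$n_genes)
    stop("insufficient genes: ", length(required), " essential proteins but only ",
         system$n_genes, " genes")
  if (any(roles[required] == "input"))
    stop("an unstimulated input protein can never be produced, so it cannot be essential")
  if (length(required) && !length(env$stimuli))
    stop("essential proteins require at least one stimulated protein")
  ranks <- integer(0)
  for (p in required) {
    r <- which(al[, 1L] == env$stimuli[1] & al[, 2L] == p)
    if (!length(r)) stop("no allele from stimulus to essential protein ", p)
    ranks <- c(ranks, r)
  }
  fill_pool <- unique(c(
    ranks,
    which(al[, 1L] == al[, 2L]),
    which(roles[al[, 1L]] == "input" & !(al[, 1L] %in% env$stimuli)),
    which(roles[al[, 2L]] == "output" &
            !(al[, 2L] %in% c(env$essentials, env$fatals))),
    seq_len(nrow(al))))
  n_fill <- system$n_genes - length(ranks)
  for (f in fill_pool) {
    cand <- c(ranks, rep(f, n_fill))
    if (binary_viability(cand, system, env) == 1) return(cand)
  }
  stop("no viable naive genotype exists under this environment")
}

#' Export a network and its node attributes to plain-text formats
#'
#' @param net a [build_neutral_network()] result.
#' @param edges_tsv path for a two-column genotype-index edge list (optional).
#' @param graphml path for a GraphML export (optional).
#' @param nodes_tsv path for a node attribute table: genotype index,
#'   viability, phenotype bitmask, and centrality when supplied (optional).
#' @param centrality optional numeric vector aligned with `net$node_ids`.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, edges_tsv = NULL, graphml = NULL,
                           nodes_tsv = NULL, centrality = NULL) {
  written <- character()
  adj <- methods::as(methods::as(net$adjacency, "generalMatrix"), "TsparseMatrix")
  up <- adj@i < adj@j
  if (!is.null(edges_tsv)) {
    utils::write.table(
      data.frame(from = net$node_ids[adj@i[up] + 1],
                 to = net$node_ids[adj@j[up] + 1]),
      edges_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, edges_tsv)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
    igraph::V(g)$genotype <- net$node_ids
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(nodes_tsv)) {
    stim <- if (!is.null(net$env)) net$env$stimuli else integer()
    P <- phenotype_matrix(net$system, stim, net$node_ids)
    bitmask <- as.numeric(P %*% 2^(seq_len(ncol(P)) - 1))
    tab <- data.frame(genotype = net$node_ids, viability = 1,
                      phenotype_bitmask = bitmask)
    if (!is.null(centrality)) tab$centrality <- centrality
    utils::write.table(tab, nodes_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, nodes_tsv)
  }
  invisible(written)
}
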