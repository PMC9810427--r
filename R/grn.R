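#' Encode and decode genotypes
#'
#' A genotype is an ordered assignment of one allele per gene, stored as a
#' vector of allele ranks (1 .. n_alleles, row numbers of `system$alleles`).
#' Genotypes are indexed by a mixed-radix bijection with radix `n_alleles`
#' per gene; gene A is the least-significant digit, so the all-rank-1
#' genotype has index 0 and indices run to `n_genotypes - 1`.
#'
#' @param ranks integer vector of allele ranks, one per gene.
#' @param index genotype index (0-based); vectorized.
#' @param system a [grn_system()].
#' @return `encode_grn` returns the numeric index; `decode_grn` returns an
#'   integer matrix of ranks with one row per index and one column per gene.
#' @examples
#' sys <- grn_fixture("reduced")
#' encode_grn(c(1, 1), sys) # 0
#' decode_grn(80, sys)      # both genes at rank 9
#' @export
encode_grn <- function(ranks, system) {
  K <- system$n_alleles
  if (length(ranks) != system$n_genes) stop("one allele rank per gene required")
  if (any(ranks < 1L | ranks > K)) stop("allele rank out of range")
  sum((as.numeric(ranks) - 1) * K^(seq_len(system$n_genes) - 1))
}

#' @rdname encode_grn
#' @export
decode_grn <- function(index, system) {
  K <- system$n_alleles
  G <- system$n_genes
  if (any(index < 0 | index >= system$n_genotypes))
    stop("genotype index out of range [0, ", system$n_genotypes, ")")
  out <- matrix(0L, nrow = length(index), ncol = G,
                dimnames = list(NULL, system$gene_labels))
  rest <- as.numeric(index)
  for (j in seq_len(G)) {
    out[, j] <- as.integer(rest %% K) + 1L
    rest <- rest %/% K
  }
  out
}

# Rank matrix for a set of genotype indices (rows: genotypes, cols: genes).
genotype_ranks <- function(ids, system) decode_grn(ids, system)

#' Run the expression cascade of one genotype
#'
#' Starting from the externally stimulated proteins, repeatedly expresses
#' every gene whose activator protein is present, turning its product
#' present, until no state changes. The resulting present-protein set (the
#' least fixed point, equivalently the set of proteins reachable from the
#' stimuli along allele edges, union the stimuli) is the genotype's
#' phenotype.
#'
#' @param ranks allele-rank vector of the genotype (one entry per gene).
#' @param system a [grn_system()].
#' @param stimuli integer ids of stimulated proteins.
#' @return Sorted integer vector of present proteins.
#' @examples
#' sys <- grn_fixture("case-study")
#' al <- function(a, p) which(sys$alleles[, 1] == a & sys$alleles[, 2] == p)
#' g <- c(al(1, 3), al(3, 5), al(2, 4), al(4, 4))
#' express_cascade(g, sys, stimuli = 1L) # 1 3 5
#' @export
express_cascade <- function(ranks, system, stimuli) {
  if (length(stimuli) == 0L) return(integer())
  present <- logical(system$universe$n)
  present[stimuli] <- TRUE
  act <- system$alleles[ranks, 1L]
  prod <- system$alleles[ranks, 2L]
  repeat {
    new <- present
    new[prod[new[act]]] <- TRUE
    if (identical(new, present)) break
    present <- new
  }
  which(present)
}

#' Phenotypes of many genotypes at once
#'
#' Vectorized expression cascade over a set of genotype indices: the
#' propagation step is applied to all genotypes simultaneously until every
#' row is stable.
#'
#' @param system a [grn_system()].
#' @param stimuli integer ids of stimulated proteins.
#' @param ids genotype indices (0-based); default all genotypes (guarded by
#'   `size_cap`).
#' @param size_cap refuse full enumeration beyond this many genotypes.
#' @return Logical matrix, one row per genotype, one column per protein.
#' @export
phenotype_matrix <- function(system, stimuli, ids = NULL,
                             size_cap = 2^20) {
  if (is.null(ids)) {
    if (system$n_genotypes > size_cap)
      stop("genotype space larger than size_cap (", size_cap,
           "); pass explicit ids or use matrix-free routines", call. = FALSE)
    ids <- seq_len(system$n_genotypes) - 1
  }
  n <- length(ids)
  P <- matrix(FALSE, nrow = n, ncol = system$universe$n)
  if (length(stimuli)) P[, stimuli] <- TRUE else return(P)
  R <- genotype_ranks(ids, system)
  rows <- seq_len(n)
  repeat {
    changed <- FALSE
    for (j in seq_len(system$n_genes)) {
      act <- system$alleles[R[, j], 1L]
      prod <- system$alleles[R[, j], 2L]
      src <- P[cbind(rows, act)]
      dst <- cbind(rows, prod)
      upd <- src & !P[dst]
      if (any(upd)) {
        P[dst[upd, , drop = FALSE]] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  P
}

#' Binary viability of genotypes under an environment
#'
#' A genotype is viable (viability 1) iff every essential protein is present
#' in its phenotype and no fatal protein is; otherwise viability is 0.
#' Viability depends on the genotype only through its phenotype.
#'
#' @param ranks allele-rank vector of a single genotype.
#' @param system a [grn_system()].
#' @param env a [grn_env()].
#' @return 0 or 1.
#' @seealso [viability_vector()] for the vectorized version over indices.
#' @export
binary_viability <- function(ranks, system, env) {
  ph <- express_cascade(ranks, system, env$stimuli)
  as.numeric(all(env$essentials %in% ph) && !any(env$fatals %in% ph))
}

#' @rdname binary_viability
#' @param ids genotype indices (0-based); default all genotypes.
#' @param size_cap see [phenotype_matrix()].
#' @export
viability_vector <- function(system, env, ids = NULL, size_cap = 2^20) {
  P <- phenotype_matrix(system, env$stimuli, ids, size_cap)
  ok <- rep(TRUE, nrow(P))
  for (e in env$essentials) ok <- ok & P[, e]
  for (f in env$fatals) ok <- ok & !P[, f]
  as.numeric(ok)
}

#' Specify viability and reproductivity
#'
#' The selection model assigns every genotype a viability nu in [0, 1] (its
#' survival probability) and a reproductivity rho >= 0 (the chance that a
#' random member of the next generation descends from a viable parent of
#' that genotype). The default is the binary-viability, uniform-
#' reproductivity case: nu from [binary_viability()] under `env`, rho = 1
#' for every genotype.
#'
#' @param system a [grn_system()].
#' @param env a [grn_env()] (used by the default binary viability).
#' @param viability optional function `(ids, system) -> numeric in [0,1]`.
#' @param reproductivity optional function `(ids, system) -> numeric >= 0`.
#' @param size_cap see [phenotype_matrix()].
#' @return An object of class `selection_model` with materialized vectors
#'   `nu` and `rho` over the full genotype space, plus the index sets
#'   `viable` (nu > 0), `sinks` (viable with rho = 0) and `core`
#'   (viable with rho > 0).
#' @export
selection_model <- function(system, env = NULL, viability = NULL,
                            reproductivity = NULL, size_cap = 2^20) {
  ids <- seq_len(system$n_genotypes) - 1
  nu <- if (is.null(viability)) {
    if (is.null(env)) stop("either env or a viability function is required")
    viability_vector(system, env, ids, size_cap)
  } else viability(ids, system)
  rho <- if (is.null(reproductivity)) rep(1, length(ids))
         else reproductivity(ids, system)
  if (any(nu < 0 | nu > 1)) stop("viability must lie in [0, 1]")
  if (any(rho < 0)) stop("reproductivity must be non-negative")
  viable <- ids[nu > 0]
  structure(
    list(nu = nu, rho = rho, env = env,
         viable = viable,
         sinks = viable[rho[nu > 0] == 0],
         core = viable[rho[nu > 0] > 0],
         binary = all(nu %in% c(0, 1)),
         uniform = length(unique(rho[nu > 0])) == 1L),
    class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat("Selection model over", length(x$nu), "genotypes:",
      length(x$viable), "viable,", length(x$sinks), "zero-reproductivity\n")
  cat("  viability:", if (x$binary) "binary" else "graded",
      "| reproductivity:", if (x$uniform) "uniform" else "graded", "\n")
  invisible(x)
}

#' Serialize a genotype to and from JSON
#'
#' The JSON record maps each gene label to its `[activator, product]`
#' protein pair, e.g. `{"A":[1,3],"B":[3,5]}`.
#'
#' @param ranks allele-rank vector, or a genotype index via `index`.
#' @param index genotype index (alternative to `ranks`).
#' @param system a [grn_system()].
#' @export
grn_to_json <- function(ranks = NULL, system, index = NULL) {
  if (is.null(ranks)) ranks <- drop(decode_grn(index, system))
  pairs <- lapply(seq_len(system$n_genes),
                  function(j) as.integer(system$alleles[ranks[j], ]))
  names(pairs) <- system$gene_labels
  jsonlite::toJSON(pairs)
}

#' @rdname grn_to_json
#' @param json a JSON string as produced by `grn_to_json`.
#' @return `grn_from_json` returns the allele-rank vector.
#' @export
grn_from_json <- function(json, system) {
  pairs <- jsonlite::fromJSON(json)
  ranks <- vapply(system$gene_labels, function(lb) {
    pr <- pairs[[lb]]
    if (is.null(pr)) stop("missing gene ", lb, " in JSON record")
    r <- which(system$alleles[, 1L] == pr[1] & system$alleles[, 2L] == pr[2])
    if (!length(r)) stop("pair (", pr[1], ",", pr[2], ") is not a valid allele")
    r
  }, integer(1))
  unname(ranks)
}
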