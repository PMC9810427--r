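#' Define a protein universe
#'
#' A protein universe is the fixed collection of proteins that can appear in
#' an organism, each with one of three roles: `input` proteins are provided
#' externally and cannot be the product of any gene; `output` proteins have
#' direct physiological effects and cannot activate any gene; `internal`
#' proteins may do both.
#'
#' @param roles character vector, one of `"input"`, `"internal"`, `"output"`
#'   per protein; proteins are identified by position (1-based ids).
#' @param labels optional character labels, default the numerals `"1"`, ...
#' @return An object of class `protein_universe` with elements `n`, `roles`,
#'   `labels` and the role index vectors `inputs`, `internals`, `outputs`.
#' @examples
#' protein_universe(c("input", "input", "internal", "internal", "output", "output"))
#' @export
protein_universe <- function(roles, labels = as.character(seq_along(roles))) {
  if (length(roles) < 2L)
    stop("a protein universe needs at least two proteins", call. = FALSE)
  roles <- match.arg(roles, c("input", "internal", "output"), several.ok = TRUE)
  if (!any(roles == "input") || !any(roles == "output"))
    stop("invalid universe: at least one input and one output protein are required",
         call. = FALSE)
  if (length(labels) != length(roles)) stop("labels must match roles in length")
  structure(
    list(n = length(roles), roles = roles, labels = labels,
         inputs = which(roles == "input"),
         internals = which(roles == "internal"),
         outputs = which(roles == "output")),
    class = "protein_universe")
}

#' @export
print.protein_universe <- function(x, ...) {
  cat("Protein universe:", x$n, "proteins\n")
  cat("  inputs   :", paste(x$labels[x$inputs], collapse = ", "), "\n")
  cat("  internal :", if (length(x$internals)) paste(x$labels[x$internals], collapse = ", ") else "(none)", "\n")
  cat("  outputs  :", paste(x$labels[x$outputs], collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all alleles of a protein universe
#'
#' An allele is an ordered (activator, product) pair of proteins: the gene is
#' expressed when its activator protein is present and then turns its product
#' protein present. Activators cannot be output proteins and products cannot
#' be input proteins; any remaining pair is admissible, including self-pairs
#' on internal proteins.
#'
#' @param universe a [protein_universe()].
#' @return Integer matrix with one row per allele and columns `activator`,
#'   `product`, in canonical order (activator-major, then product).
#' @examples
#' u <- protein_universe(c("input", "internal", "output"))
#' enumerate_alleles(u)
#' @export
enumerate_alleles <- function(universe) {
  stopifnot(inherits(universe, "protein_universe"))
  activators <- which(universe$roles != "output")
  products <- which(universe$roles != "input")
  al <- cbind(activator = rep(activators, each = length(products)),
              product = rep(products, times = length(activators)))
  storage.mode(al) <- "integer"
  al
}

#' Specify a selective environment
#'
#' An environment is given by three protein sets: `stimuli` are externally
#' provided and start the expression cascade; `essentials` must be present in
#' the phenotype for the organism to be viable; `fatals` must be absent.
#'
#' @param stimuli,essentials,fatals integer protein ids (possibly empty).
#' @param universe optional [protein_universe()] used to validate roles.
#' @param permissive if `FALSE` (default) stimuli must be input-role proteins;
#'   if `TRUE` any non-output protein may be stimulated.
#' @return An object of class `grn_env`.
#' @export
grn_env <- function(stimuli, essentials = integer(), fatals = integer(),
                    universe = NULL, permissive = FALSE) {
  stimuli <- as.integer(sort(unique(stimuli)))
  essentials <- as.integer(sort(unique(essentials)))
  fatals <- as.integer(sort(unique(fatals)))
  if (length(intersect(essentials, fatals)))
    stop("a protein cannot be both essential and fatal", call. = FALSE)
  if (!is.null(universe)) {
    ids <- c(stimuli, essentials, fatals)
    if (length(ids) && (min(ids) < 1L || max(ids) > universe$n))
      stop("environment refers to proteins outside the universe", call. = FALSE)
    bad <- if (permissive) stimuli[universe$roles[stimuli] == "output"]
           else stimuli[universe$roles[stimuli] != "input"]
    if (length(bad))
      stop("stimulated proteins must be input proteins (or non-output in permissive mode): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (length(intersect(stimuli, union(essentials, fatals))))
      warning("a stimulated protein is also essential or fatal; no reference environment exercises this")
  }
  structure(list(stimuli = stimuli, essentials = essentials, fatals = fatals),
            class = "grn_env")
}

#' @export
print.grn_env <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste0("{", paste(s, collapse = ","), "}") else "{}"
  cat("Environment: stimuli ", fmt(x$stimuli),
      ", essentials ", fmt(x$essentials),
      ", fatals ", fmt(x$fatals), "\n", sep = "")
  invisible(x)
}

#' Bundle a protein universe and a gene set into a GRN system
#'
#' A system fixes the combinatorics of the genotype space: the allele set
#' alpha(Omega) and the gene collection Gamma. A genotype (GRN) is then an
#' ordered assignment of one allele per gene, so there are
#' `n_alleles^n_genes` genotypes, indexed 0 .. n_alleles^n_genes - 1 by a
#' mixed-radix encoding (gene A is the least-significant digit).
#'
#' @param universe a [protein_universe()].
#' @param n_genes number of genes (labelled `A`, `B`, ... by default).
#' @param gene_labels optional gene labels.
#' @return An object of class `grn_system` with the allele table and counts.
#' @examples
#' sys <- grn_system(protein_universe(rep(c("input", "internal", "output"), each = 2)), 4)
#' sys$n_alleles # 16
#' @export
grn_system <- function(universe, n_genes,
                       gene_labels = make.unique(rep(LETTERS, length.out = n_genes))) {
  stopifnot(inherits(universe, "protein_universe"), n_genes >= 1L)
  alleles <- enumerate_alleles(universe)
  structure(
    list(universe = universe, n_genes = as.integer(n_genes),
         gene_labels = gene_labels, alleles = alleles,
         n_alleles = nrow(alleles),
         n_genotypes = nrow(alleles)^n_genes),
    class = "grn_system")
}

#' @export
print.grn_system <- function(x, ...) {
  cat("GRN system: ", x$universe$n, " proteins, ", x$n_genes, " genes (",
      paste(x$gene_labels, collapse = ""), ")\n", sep = "")
  cat("  alleles   |alpha(Omega)| =", x$n_alleles, "\n")
  cat("  genotypes |G| =", format(x$n_genotypes, big.mark = " "), "\n")
  invisible(x)
}

#' Built-in study systems
#'
#' Three fixed configurations used throughout the package:
#' \describe{
#'   \item{`case-study`}{6 proteins (inputs 1-2, internal 3-4, outputs 5-6),
#'     4 genes: 16 alleles and 65 536 genotypes.}
#'   \item{`reduced`}{4 proteins (input 1, internal 2-3, output 4), 2 genes:
#'     9 alleles and 81 genotypes; small enough for exhaustive oracles.}
#'   \item{`micro`}{2 proteins (1 input, 1 output), 1 gene: a single allele
#'     and a single genotype, for degenerate-path checks.}
#' }
#'
#' @param name one of `"case-study"`, `"reduced"`, `"micro"`.
#' @return A [grn_system()].
#' @export
grn_fixture <- function(name = c("case-study", "reduced", "micro")) {
  name <- match.arg(name)
  switch(name,
    "case-study" = grn_system(
      protein_universe(c("input", "input", "internal", "internal", "output", "output")), 4L),
    "reduced" = grn_system(
      protein_universe(c("input", "internal", "internal", "output")), 2L),
    "micro" = grn_system(protein_universe(c("input", "output")), 1L))
}

#' The seven reference environments
#'
#' The selective environments of the six-protein case study, combining single
#' and multiple stimulated, essential and fatal proteins:
#' env1 ({1}, {}, {6}); env2 ({1}, {}, {5,6}); env3 ({1,2}, {}, {6});
#' env4 ({1}, {6}, {}); env5 ({1}, {5,6}, {}); env6 ({1,2}, {6}, {});
#' env7 ({1}, {5}, {6}).
#'
#' @param universe universe used for validation; default the case-study one.
#' @return Named list of [grn_env()] objects, `env1` .. `env7`.
#' @export
reference_environments <- function(universe = grn_fixture("case-study")$universe) {
  list(
    env1 = grn_env(1L, integer(), 6L, universe),
    env2 = grn_env(1L, integer(), c(5L, 6L), universe),
    env3 = grn_env(c(1L, 2L), integer(), 6L, universe),
    env4 = grn_env(1L, 6L, integer(), universe),
    env5 = grn_env(1L, c(5L, 6L), integer(), universe),
    env6 = grn_env(c(1L, 2L), 6L, integer(), universe),
    env7 = grn_env(1L, 5L, 6L, universe))
}
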