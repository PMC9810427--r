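#' Read a system and environment from a configuration file
#'
#' The YAML layout has three sections: `proteins` (a role string per
#' protein, in id order), `genes` (a count or a list of labels) and
#' `environment` (the `stimuli` / `essentials` / `fatals` id sets).
#'
#' @param path path to a YAML file.
#' @return List with `system` (a [grn_system()]) and `env` (a [grn_env()],
#'   or NULL if the file has no environment section).
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$proteins) || is.null(cfg$genes))
    stop("config must define 'proteins' (roles) and 'genes'")
  u <- protein_universe(unlist(cfg$proteins))
  n_genes <- if (is.numeric(cfg$genes)) cfg$genes else length(unlist(cfg$genes))
  labels <- if (is.numeric(cfg$genes)) make.unique(rep(LETTERS, length.out = n_genes))
            else unlist(cfg$genes)
  system <- grn_system(u, n_genes, labels)
  env <- if (!is.null(cfg$environment)) {
    e <- cfg$environment
    grn_env(unlist(e$stimuli) %||0% integer(),
            unlist(e$essentials) %||0% integer(),
            unlist(e$fatals) %||0% integer(),
            universe = u)
  }
  list(system = system, env = env)
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

#' Write a genotype distribution to TSV with a JSON manifest
#'
#' The TSV has columns genotype_index, probability, viability and rank
#' (1 = most probable); the manifest records the parameters needed to
#' reproduce the run.
#'
#' @param dist a [grn_distribution()].
#' @param path output TSV path.
#' @param manifest optional path for a JSON manifest.
#' @param meta named list merged into the manifest (mu, environment,
#'   leading eigenvalue, iterations, seed, ...).
#' @return Invisibly, `path`.
#' @export
write_distribution <- function(dist, path, manifest = NULL, meta = list()) {
  tab <- data.frame(genotype_index = dist$ids,
                    probability = dist$probs,
                    viability = 1,
                    rank = rank(-dist$probs, ties.method = "min"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest)) {
    meta$n_genotypes <- length(dist$ids)
    meta$written <- path
    jsonlite::write_json(meta, manifest, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}
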