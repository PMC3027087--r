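# Stage-based pipeline runner: pool -> fit -> score -> diagnose, with a run
# directory of plain-text artifacts and a manifest. Stages are resumable
# from the artifacts of a previous run.

#' Build a validated pipeline configuration
#'
#' @param expression path to the training expression matrix (TSV).
#' @param labels path to the training label file.
#' @param ppi character vector of interaction file paths.
#' @param out_dir run directory for all artifacts.
#' @param ppi_dialect dialect per interaction file (recycled); see
#'   [read_interactions()].
#' @param query_expression,query_labels optional query cohort for the
#'   diagnose stage (z-scored within its own cohort).
#' @param mapping optional gene-to-protein mapping file (two-column TSV).
#' @param pool_file optional file with one protein symbol per line,
#'   bypassing differential pool selection.
#' @param de_alpha,neighbor_threshold,t_alpha,crv_p thresholds (all in
#'   `(0, 1]`, except `neighbor_threshold` a positive integer).
#' @param n_permutations permutation-null replicates.
#' @param seed global integer seed, fanned out per stage by fixed offsets.
#' @return a `RunConfig` list.
#' @export
run_config <- function(expression, labels, ppi, out_dir,
                       ppi_dialect = "edgelist",
                       query_expression = NULL, query_labels = NULL,
                       mapping = NULL, pool_file = NULL,
                       de_alpha = 0.05, neighbor_threshold = 3L,
                       t_alpha = 0.05, crv_p = 0.05,
                       n_permutations = 100000L, seed = 1L) {
  for (nm in c("de_alpha", "t_alpha", "crv_p")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v > 1)
      abort_contract("%s must be in (0, 1]", nm)
  }
  if (neighbor_threshold < 1L) abort_contract("neighbor_threshold must be >= 1")
  if (n_permutations < 1L) abort_contract("n_permutations must be >= 1")
  structure(list(expression = expression, labels = labels, ppi = ppi,
                 out_dir = out_dir, ppi_dialect = ppi_dialect,
                 query_expression = query_expression,
                 query_labels = query_labels, mapping = mapping,
                 pool_file = pool_file, de_alpha = de_alpha,
                 neighbor_threshold = as.integer(neighbor_threshold),
                 t_alpha = t_alpha, crv_p = crv_p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

# Load and normalize the training cohort described by a config.
load_training <- function(config) {
  x <- read_expression(config$expression, config$labels)
  mapping <- if (!is.null(config$mapping)) read_tsv_(config$mapping, header = FALSE)
  x <- overlay_genes_on_proteins(x, mapping)
  suppressWarnings(znormalize(x))
}

load_ppi <- function(config) {
  read_interactions(config$ppi, config$ppi_dialect)
}

require_artifact <- function(out_dir, name, stage) {
  path <- file.path(out_dir, name)
  if (!file.exists(path))
    abort_pipeline("missing artifact %s: run the '%s' stage first", name, stage)
  path
}

read_rough_artifacts <- function(out_dir) {
  proteins <- readLines(require_artifact(out_dir, "rough_proteins.txt", "pool"))
  edges <- read_tsv_(require_artifact(out_dir, "rough_edges.tsv", "pool"))
  meta <- readLines(require_artifact(out_dir, "rough_meta.txt", "pool"))
  cap <- as.integer(sub("^degree_cap=", "",
                        grep("^degree_cap=", meta, value = TRUE)))
  K <- length(proteins)
  adj <- matrix(FALSE, K, K, dimnames = list(proteins, proteins))
  adj[cbind(edges$protein_a, edges$protein_b)] <- TRUE
  adj[cbind(edges$protein_b, edges$protein_a)] <- TRUE
  rough_network(proteins, adj, cap)
}

read_association_artifact <- function(out_dir, phenotype) {
  name <- sprintf("%s_edges.tsv", if (phenotype == "cancer") "cpan" else "npan")
  edges <- read_tsv_(require_artifact(out_dir, name, "fit"))
  proteins <- readLines(require_artifact(out_dir, "rough_proteins.txt", "pool"))
  K <- length(proteins)
  M <- matrix(0, K, K, dimnames = list(proteins, proteins))
  if (nrow(edges)) {
    M[cbind(edges$protein_a, edges$protein_b)] <- edges$alpha
    M[cbind(edges$protein_b, edges$protein_a)] <- edges$alpha
  }
  association_network(proteins, M, phenotype)
}

#' Run the pipeline stages
#'
#' Executes the requested stages in dependency order, writing every
#' intermediate table under `config$out_dir`:
#' \describe{
#'   \item{pool}{`differential.tsv`, `pool.txt`, `rough_edges.tsv`,
#'     `rough_proteins.txt`, `rough_meta.txt`}
#'   \item{fit}{`cpan_edges.tsv`/`npan_edges.tsv` (+ `.sif`),
#'     `fit_audit.tsv`}
#'   \item{score}{`difference_edges.tsv`, `difference.sif`,
#'     `crv_table.tsv`, `significant_proteins.tsv`}
#'   \item{diagnose}{`diagnosis.tsv`, `metrics.json` (when the query has
#'     labels)}
#' }
#' plus `manifest.txt` echoing the configuration. A stage whose inputs were
#' produced by an earlier run is resumed from the artifacts on disk.
#'
#' @param config a [run_config()].
#' @param stages subset of `c("pool", "fit", "score", "diagnose")`.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("pool", "fit", "score", "diagnose")) {
  stages <- match.arg(stages, c("pool", "fit", "score", "diagnose"),
                      several.ok = TRUE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(out_dir, name)
  res <- list()
  x <- NULL
  ensure_training <- function() {
    if (is.null(x)) x <<- load_training(config)
    x
  }
  if ("pool" %in% stages) {
    x <- ensure_training()
    ppi <- load_ppi(config)
    dt <- differential_test(x, alpha = config$de_alpha)
    write_tsv_(dt, f("differential.tsv"))
    pool <- if (!is.null(config$pool_file)) {
      toupper(readLines(config$pool_file))
    } else {
      select_pool(dt, ppi, alpha = config$de_alpha,
                  neighbor_threshold = config$neighbor_threshold)
    }
    writeLines(pool, f("pool.txt"))
    net <- build_rough_network(pool, ppi, x)
    idx <- rn_edges(net)
    write_tsv_(data.frame(protein_a = net$proteins[idx[, 1]],
                          protein_b = net$proteins[idx[, 2]],
                          stringsAsFactors = FALSE),
               f("rough_edges.tsv"))
    writeLines(net$proteins, f("rough_proteins.txt"))
    writeLines(c(sprintf("degree_cap=%d", net$degree_cap),
                 sprintf("n_pruned_edges=%d",
                         length(attr(net, "pruning_log")))),
               f("rough_meta.txt"))
    res$pool <- list(differential = dt, pool = pool, rough = net)
  }
  if ("fit" %in% stages) {
    x <- ensure_training()
    net <- res$pool$rough %||% read_rough_artifacts(out_dir)
    cpan <- build_association_network(net, x, "cancer", config$t_alpha)
    npan <- build_association_network(net, x, "noncancer", config$t_alpha)
    write_association_network(cpan, f("cpan_edges.tsv"), f("cpan.sif"))
    write_association_network(npan, f("npan_edges.tsv"), f("npan.sif"))
    audit <- rbind(cbind(attr(cpan, "audit"), phenotype = "cancer"),
                   cbind(attr(npan, "audit"), phenotype = "noncancer"))
    write_tsv_(audit, f("fit_audit.tsv"))
    res$fit <- list(cpan = cpan, npan = npan)
  }
  if ("score" %in% stages) {
    net <- res$pool$rough %||% read_rough_artifacts(out_dir)
    cpan <- res$fit$cpan %||% read_association_artifact(out_dir, "cancer")
    npan <- res$fit$npan %||% read_association_artifact(out_dir, "noncancer")
    d <- difference_matrix(cpan, npan)
    dn_edges <- an_edges(d)  # only needs $matrix/$proteins
    names(dn_edges)[3] <- "d"
    dn_out <- dn_edges
    dn_out$d <- sprintf("%.17g", dn_out$d)
    write_tsv_(dn_out, f("difference_edges.tsv"))
    writeLines(paste(dn_edges$protein_a, "pp", dn_edges$protein_b),
               f("difference.sif"))
    crv <- permutation_null(net, d, n_permutations = config$n_permutations,
                            seed = config$seed + 1L)
    write_tsv_(crv, f("crv_table.tsv"))
    write_tsv_(significant_proteins(crv, config$crv_p),
               f("significant_proteins.tsv"))
    res$score <- list(difference = d, crv = crv)
  }
  if ("diagnose" %in% stages) {
    if (is.null(config$query_expression))
      abort_pipeline("diagnose stage needs query_expression in the config")
    cpan <- res$fit$cpan %||% read_association_artifact(out_dir, "cancer")
    npan <- res$fit$npan %||% read_association_artifact(out_dir, "noncancer")
    q <- read_expression(config$query_expression, config$query_labels)
    q <- suppressWarnings(znormalize(q))
    rec <- classify_samples(q, cpan, npan)
    write_tsv_(rec, f("diagnosis.tsv"))
    res$diagnose <- list(records = rec)
    if (!anyNA(rec$truth)) {
      perf <- evaluate_diagnoses(rec)
      jsonlite::write_json(unclass(perf), f("metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      res$diagnose$summary <- perf
    }
  }
  manifest <- c(sprintf("package_version=%s",
                        as.character(utils::packageVersion("crvnet"))),
                sprintf("stages=%s", paste(stages, collapse = ",")),
                vapply(names(config), function(nm) {
                  v <- config[[nm]]
                  sprintf("%s=%s", nm,
                          if (is.null(v)) "" else paste(v, collapse = ","))
                }, character(1)))
  writeLines(manifest, f("manifest.txt"))
  invisible(res)
}
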