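# Ground-truth network pairs and model-consistent expression cohorts.
# Generative law: Y = A Y + E with spectral radius(A) < 1, hence
# Y = (I - A)^-1 E with E i.i.d. Gaussian noise.

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

# Deterministic symbol set P001..PK.
protein_symbols <- function(K) sprintf("P%03d", seq_len(K))

#' Generate a ground-truth pair of association networks
#'
#' Samples `n_edges` distinct protein pairs with weights uniform in
#' `+/-[weight_low, weight_high]` for the first (cancer) network; a
#' `shared_fraction` subset of those edges is copied with identical position
#' and weight into the second (non-cancer) network, and the remainder is
#' resampled (fresh positions and weights). Both matrices are divided by a
#' common factor so each spectral radius is at most 0.8 (a shared factor so
#' the shared edges keep identical weights).
#'
#' @param K number of proteins.
#' @param n_edges number of edges per network (at most `K (K-1)/2`).
#' @param shared_fraction fraction of edges identical between the networks.
#' @param weight_low,weight_high absolute-weight range, `0 < low <= high`.
#' @param seed integer seed.
#' @param n_cancer,n_noncancer,noise_sd cohort parameters recorded in
#'   `params` (and used for the rough network's degree cap).
#' @return a `GroundTruth` list: `cpan_true`, `npan_true`
#'   ([association_network()]s), `rough_true` (a [rough_network()] over the
#'   union of true edges), and `params`.
#' @export
generate_network_pair <- function(K, n_edges, shared_fraction,
                                  weight_low = 0.2, weight_high = 0.8,
                                  seed = 1L, n_cancer = 150L,
                                  n_noncancer = 150L, noise_sd = 0.1) {
  n_pairs <- K * (K - 1L) / 2L
  if (n_edges > n_pairs)
    abort_contract("n_edges %d exceeds the %d available pairs", n_edges, n_pairs)
  if (shared_fraction < 0 || shared_fraction > 1)
    abort_contract("shared_fraction must be in [0, 1]")
  if (weight_low <= 0 || weight_low > weight_high)
    abort_contract("need 0 < weight_low <= weight_high")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  proteins <- protein_symbols(K)
  ut <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  draw_weights <- function(m)
    stats::runif(m, weight_low, weight_high) * sample(c(-1, 1), m, replace = TRUE)
  e1 <- sample.int(n_pairs, n_edges)
  w1 <- draw_weights(n_edges)
  n_shared <- round(shared_fraction * n_edges)
  shared_idx <- if (n_shared > 0) sample.int(n_edges, n_shared) else integer(0)
  n_new <- n_edges - n_shared
  pool2 <- setdiff(seq_len(n_pairs), e1[shared_idx])
  e2_new <- if (n_new > 0) sample(pool2, n_new) else integer(0)
  e2 <- c(e1[shared_idx], e2_new)
  w2 <- c(w1[shared_idx], draw_weights(n_new))
  fill <- function(edges, weights) {
    A <- matrix(0, K, K, dimnames = list(proteins, proteins))
    A[ut[edges, , drop = FALSE]] <- weights
    A[ut[edges, 2:1, drop = FALSE]] <- weights
    A
  }
  C <- fill(e1, w1)
  N <- fill(e2, w2)
  s <- max(1, spectral_radius(C) / 0.8, spectral_radius(N) / 0.8)
  C <- C / s
  N <- N / s
  union_adj <- (C != 0) | (N != 0)
  # a protein can be missed by every sampled edge; the rough network type
  # forbids isolated nodes, so rough_true covers the connected ones
  keep <- rowSums(union_adj) > 0
  truth <- list(
    cpan_true = association_network(proteins, C, "cancer"),
    npan_true = association_network(proteins, N, "noncancer"),
    rough_true = rough_network(proteins[keep],
                               union_adj[keep, keep, drop = FALSE],
                               min(n_cancer, n_noncancer)),
    params = list(K = K, n_edges = n_edges, shared_fraction = shared_fraction,
                  weight_low = weight_low, weight_high = weight_high,
                  noise_sd = noise_sd, n_cancer = n_cancer,
                  n_noncancer = n_noncancer, seed = seed,
                  rescale = s))
  class(truth) <- "GroundTruth"
  truth
}

#' @export
print.GroundTruth <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("GroundTruth: K=%d, %d edges/network, shared_fraction=%g,",
                     " noise_sd=%g, seed=%d\n"),
              p$K, p$n_edges, p$shared_fraction, p$noise_sd, p$seed))
  invisible(x)
}

#' Simulate an expression cohort from a ground-truth network
#'
#' Each sample is `(I - A)^-1 e` with `e` i.i.d. mean-zero Gaussian of
#' standard deviation `noise_sd`, where A is the group's true association
#' matrix. Returned un-normalized (the pipeline z-scores it).
#'
#' @param truth a `GroundTruth` from [generate_network_pair()].
#' @param group `"cancer"` or `"noncancer"`.
#' @param n number of samples (>= 2).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param prefix sample-id prefix (defaults to `C`/`N` by group).
#' @return a raw labeled [expression_matrix()].
#' @export
simulate_expression <- function(truth, group, n,
                                noise_sd = truth$params$noise_sd, seed = 1L,
                                prefix = NULL) {
  group <- match.arg(group, PHENOTYPES)
  if (n < 2L) abort_contract("n must be >= 2")
  A <- if (group == "cancer") truth$cpan_true$matrix else truth$npan_true$matrix
  if (spectral_radius(A) >= 1)
    abort_contract("spectral radius of the group matrix must be < 1")
  K <- nrow(A)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  E <- matrix(stats::rnorm(K * n, 0, noise_sd), K, n)
  Y <- solve(diag(K) - A, E)
  prefix <- prefix %||% if (group == "cancer") "C" else "N"
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  dimnames(Y) <- list(rownames(A), ids)
  expression_matrix(Y, labels = stats::setNames(rep(group, n), ids),
                    normalized = FALSE)
}

#' Simulate a full two-phenotype study
#'
#' Convenience wrapper drawing both cohorts (at the sizes recorded in the
#' ground truth's `params` by default) and binding them into one labeled
#' matrix. Per-group seeds are derived from `seed` by fixed offsets.
#'
#' @param truth a `GroundTruth`.
#' @param n_cancer,n_noncancer cohort sizes.
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @return a raw labeled [expression_matrix()].
#' @export
simulate_study <- function(truth, n_cancer = truth$params$n_cancer,
                           n_noncancer = truth$params$n_noncancer,
                           noise_sd = truth$params$noise_sd, seed = 1L) {
  xc <- simulate_expression(truth, "cancer", n_cancer, noise_sd, seed = seed)
  xn <- simulate_expression(truth, "noncancer", n_noncancer, noise_sd,
                            seed = seed + 1000L)
  expression_matrix(cbind(xc$values, xn$values),
                    labels = c(xc$labels, xn$labels), normalized = FALSE)
}

#' Write a fixture bundle to disk
#'
#' Writes `expression.tsv`, `labels.tsv`, `ppi_edges.tsv` (the union of true
#' edges plus a configurable fraction of decoy non-edges), the true-network
#' edge lists `truth_cpan.tsv` / `truth_npan.tsv`, and a key-value
#' `manifest.txt` recording every parameter and seed — exactly the formats
#' the ingest functions read.
#'
#' @param truth a `GroundTruth`.
#' @param cohorts a labeled [expression_matrix()] (e.g. [simulate_study()]).
#' @param out_dir output directory (created if needed).
#' @param decoy_fraction decoy edges as a fraction of the true edge count.
#' @param decoy_seed seed for decoy sampling (default derived from the
#'   truth's seed).
#' @return invisible character vector of the files written.
#' @export
write_fixture <- function(truth, cohorts, out_dir, decoy_fraction = 0.3,
                          decoy_seed = truth$params$seed + 2000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(out_dir, name)
  expr <- data.frame(protein = em_entities(cohorts),
                     cohorts$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv_(expr, f("expression.tsv"))
  utils::write.table(data.frame(sample = names(cohorts$labels),
                                label = unname(cohorts$labels)),
                     f("labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  union_edges <- an_edges_union(truth)
  n_decoy <- round(decoy_fraction * nrow(union_edges))
  decoys <- sample_decoy_edges(truth, n_decoy, decoy_seed)
  ppi <- rbind(union_edges[, c("protein_a", "protein_b")], decoys)
  ppi <- ppi[order(ppi$protein_a, ppi$protein_b, method = "radix"), ]
  utils::write.table(ppi, f("ppi_edges.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv_(an_edges(truth$cpan_true), f("truth_cpan.tsv"))
  write_tsv_(an_edges(truth$npan_true), f("truth_npan.tsv"))
  p <- truth$params
  manifest <- c(sprintf("K=%d", p$K),
                sprintf("n_edges=%d", p$n_edges),
                sprintf("shared_fraction=%.17g", p$shared_fraction),
                sprintf("weight_low=%.17g", p$weight_low),
                sprintf("weight_high=%.17g", p$weight_high),
                sprintf("noise_sd=%.17g", p$noise_sd),
                sprintf("n_cancer=%d", sum(cohorts$labels == "cancer")),
                sprintf("n_noncancer=%d", sum(cohorts$labels == "noncancer")),
                sprintf("seed=%d", p$seed),
                sprintf("decoy_fraction=%.17g", decoy_fraction),
                sprintf("decoy_seed=%d", decoy_seed))
  writeLines(manifest, f("manifest.txt"))
  invisible(vapply(c("expression.tsv", "labels.tsv", "ppi_edges.tsv",
                     "truth_cpan.tsv", "truth_npan.tsv", "manifest.txt"),
                   f, character(1)))
}

an_edges_union <- function(truth) {
  adj <- truth$rough_true$adjacency
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(protein_a = truth$rough_true$proteins[idx[, 1]],
             protein_b = truth$rough_true$proteins[idx[, 2]],
             stringsAsFactors = FALSE)
}

sample_decoy_edges <- function(truth, n_decoy, seed) {
  if (n_decoy < 1L)
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE))
  proteins <- truth$rough_true$proteins
  K <- length(proteins)
  adj <- truth$rough_true$adjacency
  free <- which(!adj & upper.tri(adj))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  sel <- sample(free, min(n_decoy, length(free)))
  ut <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  pos <- match(sel, which(upper.tri(matrix(0, K, K))))
  data.frame(protein_a = proteins[ut[pos, 1]],
             protein_b = proteins[ut[pos, 2]],
             stringsAsFactors = FALSE)
}
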