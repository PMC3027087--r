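# In-code fixtures shared across test files. Everything is generated at
# test time; nothing binary is stored.

# Small deterministic expression matrix.
toy_em <- function(normalized = FALSE) {
  v <- matrix(c(1, 2, 3,
                4, 6, 8,
                2, 2, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC"), c("s1", "s2", "s3")))
  expression_matrix(v, normalized = normalized)
}

# Labeled Gaussian matrix with a mean shift on `de` rows for the cancer
# group; entities E001..EK.
toy_labeled_em <- function(K = 20, n_per_group = 10, de = integer(0),
                           shift = 2, seed = 1, sd = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  ids <- sprintf("s%02d", seq_len(n))
  labels <- stats::setNames(rep(c("cancer", "noncancer"), each = n_per_group), ids)
  v <- matrix(rnorm(K * n, sd = sd), K, n,
              dimnames = list(sprintf("E%03d", seq_len(K)), ids))
  if (length(de)) v[de, labels == "cancer"] <- v[de, labels == "cancer"] + shift
  expression_matrix(v, labels = labels)
}

# Write an ExpressionMatrix (plus optional labels) to tab-delimited files.
write_em_files <- function(x, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  expr_path <- file.path(dir, "expression.tsv")
  df <- data.frame(protein = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  labels_path <- NULL
  if (!is.null(x$labels)) {
    labels_path <- file.path(dir, "labels.tsv")
    utils::write.table(data.frame(names(x$labels), unname(x$labels)),
                       labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  list(expression = expr_path, labels = labels_path, dir = dir)
}

write_edgelist <- function(pairs, dir = withr::local_tempdir(.local_envir = parent.frame()),
                           name = "edges.tsv") {
  path <- file.path(dir, name)
  writeLines(paste(pairs[, 1], pairs[, 2], sep = "\t"), path)
  path
}

# Default-scale synthetic study used by several modules (kept smaller than
# the acceptance-scale fixture for speed).
small_truth <- function(K = 30, n_edges = 60, shared_fraction = 0.7, seed = 1) {
  generate_network_pair(K, n_edges, shared_fraction, seed = seed,
                        n_cancer = 80, n_noncancer = 80)
}

# Fit both association networks on a normalized study.
fit_pair <- function(truth, xz, t_alpha = 0.05) {
  net <- truth$rough_true
  list(net = net,
       cpan = build_association_network(net, xz, "cancer", t_alpha),
       npan = build_association_network(net, xz, "noncancer", t_alpha))
}

# Row-wise z-scoring for hand-built matrices (no flag guard).
scale_rows <- function(v) {
  t(scale(t(v)))[, , drop = FALSE]
}

rn_edges_for_test <- function(net) crvnet:::rn_edges(net)
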