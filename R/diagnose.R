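# Mapping-error classification against the two association networks, and
# the evaluation baselines (random networks, cross-validation, cohort
# similarity).

#' Mapping errors of a sample against both networks
#'
#' For a z-scored sample vector Z indexed like the networks' protein order,
#' the mapping error against a coefficient matrix A is the Euclidean norm
#' `||Z - A Z||_2`: how well the sample's expression is self-explained by
#' the network's association structure.
#'
#' @param z numeric vector of length K in the networks' protein order.
#' @param cpan,npan [association_network()]s sharing a protein list.
#' @return named numeric vector `c(me_c = , me_n = )`.
#' @export
mapping_errors <- function(z, cpan, npan) {
  if (!identical(cpan$proteins, npan$proteins))
    abort_contract("networks have different protein lists")
  if (length(z) != length(cpan$proteins))
    abort_contract("sample vector length %d != network size %d",
                   length(z), length(cpan$proteins))
  c(me_c = sqrt(sum((z - cpan$matrix %*% z)^2)),
    me_n = sqrt(sum((z - npan$matrix %*% z)^2)))
}

#' Classify samples by mapping-error comparison
#'
#' Aligns a z-scored query cohort to the networks' proteins (network
#' proteins absent from the cohort are imputed as 0, the z-score mean, with
#' a logged count; query entities outside the networks are ignored), computes
#' both mapping errors per sample, and predicts `cancer` when
#' `me_c < me_n`. An exact tie predicts `noncancer` with a warning.
#'
#' @param x a normalized [expression_matrix()] (labels, if present, are
#'   carried through as `truth`).
#' @param cpan,npan [association_network()]s.
#' @return a `DiagnosisRecord` data frame: `sample_id`, `me_c`, `me_n`,
#'   `predicted`, `truth`.
#' @export
classify_samples <- function(x, cpan, npan) {
  if (!inherits(x, "ExpressionMatrix")) abort_contract("x must be an ExpressionMatrix")
  if (!ncol(x$values)) abort_contract("empty query cohort")
  if (!x$normalized) abort_contract("query cohort must be z-scored")
  proteins <- cpan$proteins
  if (!identical(proteins, npan$proteins))
    abort_contract("networks have different protein lists")
  Z <- matrix(0, length(proteins), ncol(x$values),
              dimnames = list(proteins, em_samples(x)))
  shared <- intersect(proteins, em_entities(x))
  n_missing <- length(proteins) - length(shared)
  if (n_missing)
    crv_log("%d network protein(s) absent from the query cohort imputed as 0",
            n_missing)
  Z[shared, ] <- x$values[shared, , drop = FALSE]
  res_c <- Z - cpan$matrix %*% Z
  res_n <- Z - npan$matrix %*% Z
  me_c <- sqrt(colSums(res_c^2))
  me_n <- sqrt(colSums(res_n^2))
  ties <- me_c == me_n
  if (any(ties))
    warning(sprintf("%d sample(s) with exactly equal mapping errors classified noncancer",
                    sum(ties)))
  out <- data.frame(sample_id = em_samples(x),
                    me_c = unname(me_c), me_n = unname(me_n),
                    predicted = ifelse(me_c < me_n, "cancer", "noncancer"),
                    truth = if (is.null(x$labels)) NA_character_
                            else unname(x$labels),
                    stringsAsFactors = FALSE)
  class(out) <- c("DiagnosisRecord", "data.frame")
  out
}

#' Summarize diagnostic performance
#'
#' Confusion counts and percentage metrics with cancer as the positive
#' class: accuracy = (tp+tn)/n, sensitivity = tp/(tp+fn),
#' specificity = tn/(tn+fp), all in percent.
#'
#' @param records a `DiagnosisRecord` data frame whose `truth` is complete.
#' @return a `PerformanceSummary` list: `n`, `tp`, `tn`, `fp`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_diagnoses <- function(records) {
  if (!nrow(records)) abort_contract("no diagnosis records to evaluate")
  if (anyNA(records$truth)) abort_contract("every record needs a truth label")
  tp <- sum(records$predicted == "cancer" & records$truth == "cancer")
  tn <- sum(records$predicted == "noncancer" & records$truth == "noncancer")
  fp <- sum(records$predicted == "cancer" & records$truth == "noncancer")
  fn <- sum(records$predicted == "noncancer" & records$truth == "cancer")
  n <- nrow(records)
  structure(list(n = n, tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = 100 * (tp + tn) / n,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp)),
            class = "PerformanceSummary")
}

#' @export
print.PerformanceSummary <- function(x, ...) {
  cat(sprintf(paste0("PerformanceSummary: n=%d (tp=%d tn=%d fp=%d fn=%d)\n",
                     "  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n"),
              x$n, x$tp, x$tn, x$fp, x$fn,
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

# Fit both networks for a pool on a training cohort and classify a test
# cohort; empty/unbuildable networks fall back to all-noncancer (zero
# matrices give equal mapping errors).
fit_and_classify <- function(pool, ppi, train, test, t_alpha = 0.05) {
  net <- tryCatch(build_rough_network(pool, ppi, train),
                  crvnet_pipeline_error = function(e) NULL)
  if (is.null(net)) {
    return(data.frame(sample_id = em_samples(test),
                      me_c = 0, me_n = 0, predicted = "noncancer",
                      truth = if (is.null(test$labels)) NA_character_
                              else unname(test$labels),
                      stringsAsFactors = FALSE))
  }
  cpan <- build_association_network(net, train, "cancer", t_alpha)
  npan <- build_association_network(net, train, "noncancer", t_alpha)
  suppressWarnings(classify_samples(test, cpan, npan))
}

#' Mean accuracy of randomly selected protein networks
#'
#' Chance baseline for the diagnostic evaluation: per replicate, a pool of
#' `pool_size` proteins is drawn uniformly from the universe, the full
#' network construction is rerun on the training cohort, the test cohort is
#' classified, and the accuracies are averaged.
#'
#' @param pool_size number of proteins per random network.
#' @param universe character vector of candidate protein symbols (must have
#'   expression rows and appear in `ppi`).
#' @param ppi an [interaction_set()].
#' @param train normalized labeled training [expression_matrix()].
#' @param test normalized labeled test [expression_matrix()].
#' @param reps number of random networks.
#' @param seed integer seed.
#' @return mean accuracy in percent, with the per-replicate accuracies as
#'   attribute `"accuracies"`.
#' @export
random_network_baseline <- function(pool_size, universe, ppi, train, test,
                                    reps = 100L, seed = 1L) {
  if (reps < 1L) abort_contract("reps must be >= 1")
  if (pool_size > length(universe))
    abort_contract("pool_size %d exceeds universe size %d",
                   pool_size, length(universe))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  accs <- vapply(seq_len(reps), function(r) {
    pool <- sample(universe, pool_size)
    rec <- fit_and_classify(pool, ppi, train, test)
    100 * mean(rec$predicted == rec$truth)
  }, numeric(1))
  structure(mean(accs), accuracies = accs)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the cohort into phenotype-stratified folds; for each fold the
#' training samples are z-scored, the pool selected (ANOVA + neighbor
#' augmentation, unless an explicit `pool` is supplied), both networks
#' fitted, and the held-out fold (z-scored within itself, mirroring
#' per-cohort normalization) classified.
#'
#' @param x a raw (un-normalized) labeled [expression_matrix()].
#' @param ppi an [interaction_set()].
#' @param folds number of folds (>= 2 and <= the smaller group size).
#' @param seed integer seed for the fold assignment.
#' @param pool optional explicit pool of protein symbols, bypassing
#'   differential selection (needed e.g. for mean-zero synthetic cohorts,
#'   where no protein is differentially expressed).
#' @param de_alpha,neighbor_threshold,t_alpha pipeline thresholds.
#' @return list with `fold_summaries` (per-fold `PerformanceSummary`),
#'   `summary` (pooled confusion over folds), `records` (all held-out
#'   diagnoses), and `assignment` (named fold index per sample).
#' @export
cross_validate <- function(x, ppi, folds = 5L, seed = 1L, pool = NULL,
                           de_alpha = 0.05, neighbor_threshold = 3L,
                           t_alpha = 0.05) {
  if (is.null(x$labels)) abort_contract("x must be labeled")
  if (x$normalized)
    abort_contract("pass the raw cohort; folds are z-scored internally")
  n <- ncol(x$values)
  if (folds < 2L || folds > n) abort_contract("folds must be in [2, n]")
  sizes <- table(factor(x$labels, levels = PHENOTYPES))
  if (folds > min(sizes))
    abort_contract("folds (%d) exceeds the smaller group size (%d)",
                   folds, min(sizes))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  assignment <- integer(n)
  names(assignment) <- em_samples(x)
  for (g in PHENOTYPES) {
    idx <- which(x$labels == g)
    assignment[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  all_records <- list()
  fold_summaries <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_ids <- em_samples(x)[assignment == f]
    train_ids <- em_samples(x)[assignment != f]
    train <- znormalize(em_subset(x, train_ids))
    test <- znormalize(em_subset(x, test_ids))
    fold_pool <- pool
    if (is.null(fold_pool)) {
      dt <- differential_test(train, alpha = de_alpha)
      fold_pool <- select_pool(dt, ppi, alpha = de_alpha,
                               neighbor_threshold = neighbor_threshold)
    }
    rec <- fit_and_classify(fold_pool, ppi, train, test, t_alpha)
    rec$fold <- f
    all_records[[f]] <- rec
    fold_summaries[[f]] <- evaluate_diagnoses(rec)
  }
  records <- do.call(rbind, all_records)
  class(records) <- c("DiagnosisRecord", "data.frame")
  list(fold_summaries = fold_summaries,
       summary = evaluate_diagnoses(records),
       records = records,
       assignment = assignment)
}

#' Within-group and pooled cohort similarity
#'
#' Mean pairwise Pearson correlation of sample expression profiles: over
#' unordered sample pairs within the cancer group, within the non-cancer
#' group, and over all pairs pooled. High values indicate the phenotypes
#' share a molecular pattern (a driver of moderate specificity).
#'
#' @param x a labeled [expression_matrix()] (raw or normalized; correlations
#'   are computed on the matrix as given).
#' @return named numeric vector `c(mean_r_cancer, mean_r_noncancer,
#'   mean_r_pooled)`.
#' @export
cohort_similarity <- function(x) {
  if (is.null(x$labels)) abort_contract("x must be labeled")
  sizes <- table(factor(x$labels, levels = PHENOTYPES))
  if (any(sizes < 2L))
    abort_contract("each group needs >= 2 samples for pairwise correlations")
  mean_upper <- function(m) {
    r <- stats::cor(m)
    mean(r[upper.tri(r)])
  }
  c(mean_r_cancer = mean_upper(x$values[, x$labels == "cancer", drop = FALSE]),
    mean_r_noncancer = mean_upper(x$values[, x$labels == "noncancer", drop = FALSE]),
    mean_r_pooled = mean_upper(x$values))
}
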