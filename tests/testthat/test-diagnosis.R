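an_zero <- function(proteins, phenotype) {
  association_network(proteins,
                      matrix(0, length(proteins), length(proteins)),
                      phenotype)
}

test_that("mapping_errors matches hand evaluations", {
  prots <- c("A", "B")
  C <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(prots, prots))
  cpan <- association_network(prots, C, "cancer")
  npan <- an_zero(prots, "noncancer")
  expect_equal(unname(mapping_errors(c(0, 0), cpan, npan)), c(0, 0))
  z <- c(1, 1)
  me <- mapping_errors(z, cpan, npan)
  # C z = (0.5, 0.5); ||z - Cz|| = sqrt(0.5); zero matrix gives ||z||
  expect_equal(unname(me["me_c"]), sqrt(0.5))
  expect_equal(unname(me["me_n"]), sqrt(2))
  expect_error(mapping_errors(c(1, 2, 3), cpan, npan), "length",
               class = "crvnet_contract_error")
})

test_that("mapping errors are 1-homogeneous, so classification is scale-free", {
  truth <- small_truth(K = 15, n_edges = 25, seed = 71)
  xz <- znormalize(simulate_study(truth, 40, 40, seed = 72))
  nets <- fit_pair(truth, xz)
  z <- xz$values[nets$net$proteins, 1]
  me1 <- mapping_errors(z, nets$cpan, nets$npan)
  me2 <- mapping_errors(2 * z, nets$cpan, nets$npan)
  expect_identical(unname(me2), unname(2 * me1))
})

test_that("classify_samples applies the mapping-error rule with tie policy", {
  prots <- c("A", "B")
  C <- matrix(c(0, 0.9, 0.9, 0), 2, 2, dimnames = list(prots, prots))
  cpan <- association_network(prots, C, "cancer")
  npan <- an_zero(prots, "noncancer")
  v <- cbind(s1 = c(1, 1), s2 = c(1, -1))
  rownames(v) <- prots
  x <- expression_matrix(v, normalized = TRUE)
  rec <- classify_samples(x, cpan, npan)
  # s1: me_c = 0.1*sqrt(2) < me_n = sqrt(2) -> cancer
  # s2: me_c = 1.9*sqrt(2) > me_n = sqrt(2) -> noncancer
  expect_identical(rec$predicted, c("cancer", "noncancer"))
  expect_true(all(is.na(rec$truth)))
  # exact tie -> noncancer with a warning
  expect_warning(rec0 <- classify_samples(x, npan, npan), "equal mapping")
  expect_true(all(rec0$predicted == "noncancer"))
  empty <- x
  empty$values <- empty$values[, 0, drop = FALSE]
  expect_error(classify_samples(empty, cpan, npan), "empty",
               class = "crvnet_contract_error")
})

test_that("network proteins missing from the query are imputed as zero", {
  prots <- c("A", "B", "C")
  M <- matrix(0, 3, 3, dimnames = list(prots, prots))
  M["A", "B"] <- M["B", "A"] <- 0.5
  cpan <- association_network(prots, M, "cancer")
  npan <- an_zero(prots, "noncancer")
  v <- cbind(s1 = c(1, 1))  # only A and B measured
  rownames(v) <- c("A", "B")
  x <- expression_matrix(v, normalized = TRUE)
  expect_message(rec <- classify_samples(x, cpan, npan), "imputed")
  expect_equal(rec$me_c, sqrt(0.5))
})

test_that("evaluate_diagnoses computes the confusion metrics", {
  rec <- data.frame(sample_id = paste0("s", 1:4),
                    me_c = 1, me_n = 2,
                    predicted = c("cancer", "cancer", "noncancer", "noncancer"),
                    truth = c("cancer", "cancer", "noncancer", "noncancer"))
  perf <- evaluate_diagnoses(rec)
  expect_equal(perf$accuracy, 100)
  expect_equal(perf$sensitivity, 100)
  expect_equal(perf$specificity, 100)
  expect_identical(perf$tp + perf$tn + perf$fp + perf$fn, perf$n)
  expect_error(evaluate_diagnoses(rec[0, ]), class = "crvnet_contract_error")
  rec$truth[2] <- NA
  expect_error(evaluate_diagnoses(rec), "truth",
               class = "crvnet_contract_error")
})

test_that("counts always add to n on randomized records", {
  set.seed(73)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    rec <- data.frame(sample_id = seq_len(n), me_c = 0, me_n = 0,
                      predicted = sample(c("cancer", "noncancer"), n, TRUE),
                      truth = sample(c("cancer", "noncancer"), n, TRUE))
    perf <- evaluate_diagnoses(rec)
    expect_identical(perf$tp + perf$tn + perf$fp + perf$fn, n)
    expect_equal(perf$accuracy,
                 100 * mean(rec$predicted == rec$truth))
  }
})

test_that("random_network_baseline is seeded and near chance on null fixtures", {
  truth <- generate_network_pair(30, 60, 1, seed = 74,
                                 n_cancer = 60, n_noncancer = 60)
  train <- znormalize(simulate_study(truth, 60, 60, seed = 75))
  test <- znormalize(simulate_study(truth, 15, 15, seed = 76))
  edges <- rn_edges_for_test(truth$rough_true)
  ppi <- interaction_set(truth$rough_true$proteins[edges[, 1]],
                         truth$rough_true$proteins[edges[, 2]])
  universe <- truth$rough_true$proteins
  b1 <- random_network_baseline(15, universe, ppi, train, test,
                                reps = 6, seed = 5)
  b2 <- random_network_baseline(15, universe, ppi, train, test,
                                reps = 6, seed = 5)
  expect_identical(b1, b2)
  accs <- attr(b1, "accuracies")
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(as.numeric(b1) - 50), 3 * se + 15)
  expect_error(random_network_baseline(999, universe, ppi, train, test),
               class = "crvnet_contract_error")
})

test_that("the true network outperforms random baselines on a signal fixture", {
  truth <- generate_network_pair(30, 60, 0.3, seed = 77,
                                 n_cancer = 80, n_noncancer = 80)
  train <- znormalize(simulate_study(truth, 80, 80, seed = 78))
  test <- znormalize(simulate_study(truth, 20, 20, seed = 79))
  nets <- fit_pair(truth, train)
  rec <- classify_samples(test, nets$cpan, nets$npan)
  acc_true <- 100 * mean(rec$predicted == rec$truth)
  edges <- rn_edges_for_test(truth$rough_true)
  ppi <- interaction_set(truth$rough_true$proteins[edges[, 1]],
                         truth$rough_true$proteins[edges[, 2]])
  base <- random_network_baseline(10, truth$rough_true$proteins, ppi,
                                  train, test, reps = 8, seed = 6)
  expect_gt(acc_true, as.numeric(base))
})

test_that("cross_validate is stratified, seeded, and tracks fixture signal", {
  truth <- generate_network_pair(25, 50, 0.2, seed = 80,
                                 n_cancer = 50, n_noncancer = 50)
  x <- simulate_study(truth, 50, 50, seed = 81)
  edges <- rn_edges_for_test(truth$rough_true)
  ppi <- interaction_set(truth$rough_true$proteins[edges[, 1]],
                         truth$rough_true$proteins[edges[, 2]])
  cv1 <- cross_validate(x, ppi, folds = 5, seed = 7,
                        pool = truth$rough_true$proteins)
  cv2 <- cross_validate(x, ppi, folds = 5, seed = 7,
                        pool = truth$rough_true$proteins)
  expect_identical(cv1$assignment, cv2$assignment)
  expect_identical(cv1$summary$accuracy, cv2$summary$accuracy)
  # stratification: every fold holds samples of both phenotypes
  for (f in 1:5) {
    held <- names(cv1$assignment)[cv1$assignment == f]
    expect_identical(sort(unique(unname(x$labels[held]))),
                     c("cancer", "noncancer"))
  }
  expect_gte(cv1$summary$accuracy, 90)
  expect_error(cross_validate(x, ppi, folds = 1, seed = 1),
               class = "crvnet_contract_error")
  expect_error(cross_validate(x, ppi, folds = 60, seed = 1),
               class = "crvnet_contract_error")
})

test_that("cross-validation is at chance under identical generating networks", {
  truth <- generate_network_pair(25, 50, 1, seed = 82,
                                 n_cancer = 50, n_noncancer = 50)
  x <- simulate_study(truth, 50, 50, seed = 83)
  edges <- rn_edges_for_test(truth$rough_true)
  ppi <- interaction_set(truth$rough_true$proteins[edges[, 1]],
                         truth$rough_true$proteins[edges[, 2]])
  cv <- cross_validate(x, ppi, folds = 5, seed = 8,
                       pool = truth$rough_true$proteins)
  # binomial 99% band around 50% for n = 100 held-out classifications
  band <- 100 * (0.5 + c(-1, 1) * 2.576 * sqrt(0.25 / cv$summary$n))
  expect_gt(cv$summary$accuracy, band[1])
  expect_lt(cv$summary$accuracy, band[2])
})

test_that("cohort_similarity matches hand-computed correlation structure", {
  ids <- paste0("s", 1:4)
  labels <- stats::setNames(c("cancer", "cancer", "noncancer", "noncancer"), ids)
  base <- c(1, 2, 3, 4, 5)
  v <- cbind(base, base, -base, -base)
  dimnames(v) <- list(paste0("G", 1:5), ids)
  x <- expression_matrix(v, labels = labels)
  sim <- cohort_similarity(x)
  expect_equal(unname(sim["mean_r_cancer"]), 1)
  expect_equal(unname(sim["mean_r_noncancer"]), 1)
  # pooled: pairs (1,1,-1,-1,-1,1) averaged = -1/3
  expect_equal(unname(sim["mean_r_pooled"]), -1 / 3)
  expect_error(cohort_similarity(expression_matrix(v[, 1:3],
                                                   labels = labels[1:3])),
               class = "crvnet_contract_error")
  # identical samples: all means are 1
  v1 <- cbind(base, base, base, base)
  dimnames(v1) <- list(paste0("G", 1:5), ids)
  expect_equal(unname(cohort_similarity(expression_matrix(v1, labels = labels))),
               c(1, 1, 1))
})

test_that("independent Gaussian cohorts have near-zero mean correlation", {
  set.seed(84)
  n_genes <- 1000
  ids <- paste0("s", 1:10)
  labels <- stats::setNames(rep(c("cancer", "noncancer"), each = 5), ids)
  v <- matrix(rnorm(n_genes * 10), n_genes, 10,
              dimnames = list(paste0("G", seq_len(n_genes)), ids))
  sim <- cohort_similarity(expression_matrix(v, labels = labels))
  expect_true(all(abs(sim) < 3 / sqrt(n_genes)))
})
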