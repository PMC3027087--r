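# Helper: expression matrix + rough network with named proteins and a given
# adjacency over them.
net_from_edges <- function(proteins, edges, degree_cap) {
  K <- length(proteins)
  adj <- matrix(FALSE, K, K, dimnames = list(proteins, proteins))
  for (e in edges) {
    adj[e[1], e[2]] <- TRUE
    adj[e[2], e[1]] <- TRUE
  }
  rough_network(proteins, adj, degree_cap)
}

labeled_zem <- function(v, group = "cancer") {
  ids <- colnames(v)
  expression_matrix(v, labels = stats::setNames(rep(group, ncol(v)), ids),
                    normalized = TRUE)
}

test_that("fit_target_model recovers an exact linear relation", {
  set.seed(41)
  n <- 30
  yb <- rnorm(n)
  v <- rbind(A = 0.7 * yb, B = yb)
  colnames(v) <- paste0("s", seq_len(n))
  x <- labeled_zem(v)
  net <- net_from_edges(c("A", "B"), list(c("A", "B")), n)
  fit <- fit_target_model("A", net, x, "cancer")
  expect_equal(unname(fit$alpha_hat["B"]), 0.7, tolerance = 1e-9)
  expect_lt(fit$residual_variance, 1e-18)
  expect_identical(fit$n_samples, 30L)
})

test_that("fit coefficients equal the generic least-squares oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 50
    k <- sample(2:6, 1)
    prots <- c("T", paste0("N", seq_len(k)))
    v <- matrix(rnorm((k + 1) * n), k + 1, n,
                dimnames = list(prots, paste0("s", seq_len(n))))
    x <- labeled_zem(v)
    net <- net_from_edges(prots, lapply(prots[-1], function(p) c("T", p)), n)
    fit <- fit_target_model("T", net, x, "cancer")
    X <- t(v[prots[-1], , drop = FALSE])
    oracle <- lm(v["T", ] ~ 0 + X)
    expect_lt(max(abs(unname(fit$alpha_hat) - unname(coef(oracle)))), 1e-9)
    sm <- summary(oracle)$coefficients
    expect_lt(max(abs(unname(fit$se) - sm[, 2])), 1e-9)
    expect_lt(max(abs(unname(fit$t_stat) - sm[, 3])), 1e-9)
  }
})

test_that("independent-noise neighbors give small t statistics", {
  set.seed(43)
  n <- 200
  prots <- c("T", paste0("N", 1:4))
  v <- matrix(rnorm(5 * n), 5, n, dimnames = list(prots, paste0("s", 1:n)))
  x <- labeled_zem(v)
  net <- net_from_edges(prots, lapply(prots[-1], function(p) c("T", p)), n)
  fit <- fit_target_model("T", net, x, "cancer")
  # all |t| below the 0.9999 two-sided quantile at this seed
  expect_lt(max(abs(fit$t_stat)), qt(1 - 1e-4 / 2, n - 4))
  expect_lt(max(abs(fit$alpha_hat)), 0.25)
})

test_that("degree >= group size is a contract error", {
  set.seed(44)
  n <- 4
  prots <- c("T", paste0("N", 1:4))
  v <- matrix(rnorm(5 * n), 5, n, dimnames = list(prots, paste0("s", 1:n)))
  x <- labeled_zem(v)
  net <- net_from_edges(prots, lapply(prots[-1], function(p) c("T", p)), 99)
  expect_error(fit_target_model("T", net, x, "cancer"), "degree",
               class = "crvnet_contract_error")
})

test_that("refine_model keeps true neighbors and discards spurious ones", {
  set.seed(45)
  n <- 150
  yb <- rnorm(n)
  yc <- rnorm(n)  # independent, spurious
  y <- 0.8 * yb + rnorm(n, sd = 0.2)
  v <- rbind(T = y, B = yb, C = yc)
  colnames(v) <- paste0("s", seq_len(n))
  x <- labeled_zem(v)
  net <- net_from_edges(c("T", "B", "C"), list(c("T", "B"), c("T", "C")), n)
  refined <- refine_model(fit_target_model("T", net, x, "cancer"))
  expect_identical(refined$neighbors, "B")
  aud <- attr(refined, "audit")
  expect_identical(aud$decision[aud$neighbor == "C"], "dropped_aic")
})

test_that("pure-noise targets end empty in at least 90% of replicates", {
  # with the coefficient screen at t_alpha = 0.05 the empty-model chance is
  # about 0.95^k; asserted at k = 2 neighbors over 100 seeded replicates
  empty <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    n <- 100
    v <- matrix(rnorm(3 * n), 3, n,
                dimnames = list(c("T", "N1", "N2"), paste0("s", 1:n)))
    x <- labeled_zem(v)
    net <- net_from_edges(c("T", "N1", "N2"),
                          list(c("T", "N1"), c("T", "N2")), n)
    refined <- refine_model(fit_target_model("T", net, x, "cancer"))
    if (length(refined$neighbors) == 0L) empty <- empty + 1
  }
  expect_gte(empty, 90)
})

test_that("an exact single-neighbor relation is retained with lower AIC", {
  set.seed(46)
  n <- 25
  yb <- rnorm(n)
  v <- rbind(T = 0.5 * yb, B = yb)
  colnames(v) <- paste0("s", seq_len(n))
  x <- labeled_zem(v)
  net <- net_from_edges(c("T", "B"), list(c("T", "B")), n)
  fit <- fit_target_model("T", net, x, "cancer")
  refined <- refine_model(fit)
  expect_identical(refined$neighbors, "B")
  aic_empty <- n * log(max(sum(v["T", ]^2), 1e-12) / n)
  expect_lt(refined$aic, aic_empty)
})

test_that("the AIC-gated elimination phase never increases AIC", {
  # the AIC phase is monotone by construction; the terminal coefficient
  # screen trades AIC for parsimony, so the guarantee applies with the
  # screen disabled (t_alpha = 1) and the screened model must keep only
  # significant coefficients
  for (s in 1:20) {
    set.seed(2000 + s)
    n <- 60
    k <- 6
    prots <- c("T", paste0("N", seq_len(k)))
    B <- rnorm(k) * rbinom(k, 1, 0.4)
    Xn <- matrix(rnorm(k * n), k, n)
    y <- as.vector(t(Xn) %*% B) + rnorm(n, sd = 0.5)
    v <- rbind(T = y, Xn)
    rownames(v) <- prots
    colnames(v) <- paste0("s", seq_len(n))
    x <- labeled_zem(v)
    net <- net_from_edges(prots, lapply(prots[-1], function(p) c("T", p)), n)
    fit <- fit_target_model("T", net, x, "cancer")
    aic_phase <- refine_model(fit, t_alpha = 1)
    expect_lte(aic_phase$aic, fit$aic)
    refined <- refine_model(fit)
    # the terminal screen only ever removes neighbors (single refit pass)
    expect_true(all(refined$neighbors %in% aic_phase$neighbors))
  }
})

test_that("backward elimination tracks the all-subsets AIC optimum", {
  # logged diagnostic: final AIC within 2 units of the exhaustive optimum on
  # at least 95% of seeded random instances
  n_instances <- 40
  hits <- 0
  for (s in seq_len(n_instances)) {
    set.seed(3000 + s)
    n <- 60
    k <- 7
    B <- rnorm(k) * rbinom(k, 1, 0.5) * 0.6
    Xn <- matrix(rnorm(k * n), n, k)
    y <- as.vector(Xn %*% B) + rnorm(n)
    prots <- c("T", paste0("N", seq_len(k)))
    v <- rbind(T = y, t(Xn))
    rownames(v) <- prots
    colnames(v) <- paste0("s", seq_len(n))
    x <- labeled_zem(v)
    net <- net_from_edges(prots, lapply(prots[-1], function(p) c("T", p)), n)
    refined <- refine_model(fit_target_model("T", net, x, "cancer"),
                            t_alpha = 1)  # isolate the AIC search
    # exhaustive oracle over all 2^k subsets
    best <- Inf
    for (m in 0:(2^k - 1)) {
      sel <- which(bitwAnd(m, 2^(0:(k - 1))) > 0)
      rss <- if (length(sel)) sum(lm.fit(Xn[, sel, drop = FALSE], y)$residuals^2)
             else sum(y^2)
      best <- min(best, n * log(max(rss, 1e-12) / n) + 2 * length(sel))
    }
    if (refined$aic <= best + 2) hits <- hits + 1
  }
  expect_gte(hits / n_instances, 0.95)
})

test_that("symmetrize_pairs picks the larger magnitude with declared ties", {
  expect_identical(symmetrize_pairs(0.5, -0.8), -0.8)
  expect_identical(symmetrize_pairs(0.3, 0.3), 0.3)
  expect_identical(symmetrize_pairs(0, 0.4), 0.4)
  expect_identical(symmetrize_pairs(-0.2, 0.2), -0.2)  # tie -> first fit
})

test_that("association networks are symmetric, zero-diagonal, on-support", {
  truth <- small_truth(seed = 51)
  xz <- znormalize(simulate_study(truth, 60, 60, seed = 52))
  nets <- fit_pair(truth, xz)
  M <- nets$cpan$matrix
  expect_identical(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_true(all(M[!nets$net$adjacency] == 0))
})

test_that("a vanishing t_alpha forces the empty (zero) network", {
  truth <- small_truth(K = 10, n_edges = 15, seed = 53)
  xz <- znormalize(simulate_study(truth, 30, 30, seed = 54))
  cpan <- build_association_network(truth$rough_true, xz, "cancer",
                                    t_alpha = 1e-300)
  expect_true(all(cpan$matrix == 0))
})

test_that("fitted networks are invariant to pre-normalization rescaling", {
  truth <- small_truth(K = 12, n_edges = 20, seed = 55)
  x <- simulate_study(truth, 40, 40, seed = 56)
  x4 <- expression_matrix(x$values * 4, labels = x$labels)
  n1 <- fit_pair(truth, znormalize(x))
  n2 <- fit_pair(truth, znormalize(x4))
  expect_identical(n1$cpan$matrix, n2$cpan$matrix)
  expect_identical(n1$npan$matrix, n2$npan$matrix)
})
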