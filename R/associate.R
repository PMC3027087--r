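# Per-target linear association model: Gaussian ML (= OLS without intercept
# on z-scored rows), AIC-gated backward elimination, t-test pruning, and
# assembly of the symmetric association-ability matrices.

# AIC for a no-intercept Gaussian linear model; RSS floored to avoid -Inf on
# perfect fits.
aic_gaussian <- function(rss, n, k) {
  n * log(max(rss, 1e-12) / n) + 2 * k
}

# Least squares without intercept. Falls back to the smallest-norm (pseudo-
# inverse) solution on rank deficiency.
ols_fit <- function(y, X) {
  n <- length(y)
  k <- ncol(X)
  if (k == 0L) {
    rss <- sum(y^2)
    return(list(coef = numeric(0), se = numeric(0), t = numeric(0),
                rss = rss, rank = 0L, df = n,
                residual_variance = rss / n, degenerate = FALSE))
  }
  qrx <- qr(X)
  degenerate <- qrx$rank < k
  if (!degenerate) {
    coef <- qr.coef(qrx, y)
    res <- y - X %*% coef
    rss <- sum(res^2)
    df <- n - k
    s2 <- if (df > 0) rss / df else NA_real_
    xtx_inv <- chol2inv(qr.R(qrx))
    se <- sqrt(pmax(s2 * diag(xtx_inv), 0))
  } else {
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    coef <- as.vector(coef)
    res <- y - X %*% coef
    rss <- sum(res^2)
    df <- n - sum(pos)
    s2 <- if (df > 0) rss / df else NA_real_
    # covariance of the pseudo-inverse estimator
    pinv <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    se <- sqrt(pmax(s2 * rowSums(pinv^2), 0))
  }
  tstat <- as.vector(coef) / se
  tstat[se == 0] <- ifelse(coef[se == 0] == 0, 0, sign(coef[se == 0]) * Inf)
  list(coef = as.vector(coef), se = se, t = tstat, rss = rss,
       rank = if (degenerate) sum(qrx$rank) else k, df = df,
       residual_variance = if (df > 0) rss / df else 0,
       degenerate = degenerate)
}

make_target_fit <- function(target, phenotype, neighbors, y, X, fit) {
  structure(list(target = target, phenotype = phenotype,
                 neighbors = neighbors,
                 alpha_hat = stats::setNames(fit$coef, neighbors),
                 se = stats::setNames(fit$se, neighbors),
                 t_stat = stats::setNames(fit$t, neighbors),
                 residual_variance = fit$residual_variance,
                 rss = fit$rss,
                 aic = aic_gaussian(fit$rss, length(y), length(neighbors)),
                 n_samples = length(y),
                 degenerate = fit$degenerate,
                 y = y, X = X),
            class = "TargetFit")
}

#' Fit the linear association model for one target protein
#'
#' Regresses the target's z-scored expression on its rough-network neighbors
#' within one phenotype group, by Gaussian maximum likelihood (ordinary least
#' squares without intercept, since rows are z-scored). Standard errors and
#' t statistics use the standard linear-model covariance with `n - k`
#' degrees of freedom. A rank-deficient neighbor design yields the
#' smallest-norm solution with a degeneracy warning.
#'
#' @param target protein symbol present in `net`.
#' @param net a [rough_network()].
#' @param x a normalized labeled [expression_matrix()] covering the network.
#' @param phenotype `"cancer"` or `"noncancer"`.
#' @return a `TargetFit` (coefficients, se, t, residual variance, AIC, and
#'   the design it was fitted on, for refitting).
#' @export
fit_target_model <- function(target, net, x, phenotype) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  if (!x$normalized) abort_contract("x must be normalized")
  if (!target %in% net$proteins) abort_contract("target %s not in network", target)
  samples <- group_samples(x, phenotype)
  neighbors <- net$proteins[net$adjacency[target, ]]
  n <- length(samples)
  if (length(neighbors) >= n)
    abort_contract("target %s: degree %d >= group size %d",
                   target, length(neighbors), n)
  y <- x$values[target, samples]
  X <- t(x$values[neighbors, samples, drop = FALSE])
  colnames(X) <- neighbors
  fit <- ols_fit(y, X)
  if (fit$degenerate)
    warning(sprintf("rank-deficient design for target %s: smallest-norm solution used",
                    target))
  make_target_fit(target, phenotype, neighbors, y, X, fit)
}

#' @export
print.TargetFit <- function(x, ...) {
  cat(sprintf("TargetFit %s (%s): %d neighbor(s), AIC %.3f, sigma^2 %.4g\n",
              x$target, x$phenotype, length(x$neighbors), x$aic,
              x$residual_variance))
  invisible(x)
}

refit_subset <- function(fit, keep) {
  X <- fit$X[, keep, drop = FALSE]
  make_target_fit(fit$target, fit$phenotype, fit$neighbors[keep],
                  fit$y, X, ols_fit(fit$y, X))
}

#' Refine a target fit by AIC and coefficient t-tests
#'
#' Backward stepwise elimination: repeatedly drop the neighbor with the
#' smallest absolute t statistic and refit, as long as the AIC
#' (`n log(RSS/n) + 2k`) decreases. Then drop every remaining coefficient
#' whose two-sided t-test p-value is at or above `t_alpha` and refit once.
#' An empty model is a valid outcome. The elimination trail is attached as
#' attribute `"audit"`.
#'
#' @param fit a `TargetFit` from [fit_target_model()].
#' @param t_alpha significance level of the final coefficient screen.
#' @return the refined `TargetFit`.
#' @export
refine_model <- function(fit, t_alpha = 0.05) {
  if (!inherits(fit, "TargetFit")) abort_contract("fit must be a TargetFit")
  audit <- data.frame(neighbor = fit$neighbors,
                      alpha = unname(fit$alpha_hat),
                      se = unname(fit$se), t = unname(fit$t_stat),
                      stage = "full", decision = "kept",
                      stringsAsFactors = FALSE)
  current <- fit
  while (length(current$neighbors) > 0L) {
    abst <- abs(current$t_stat)
    abst[!is.finite(abst)] <- Inf
    ord <- order(abst, current$neighbors, method = "radix")
    drop_idx <- ord[1L]
    candidate <- refit_subset(current, -drop_idx)
    if (candidate$aic < current$aic) {
      audit$decision[audit$neighbor == current$neighbors[drop_idx]] <- "dropped_aic"
      current <- candidate
    } else break
  }
  if (length(current$neighbors) > 0L) {
    df <- current$n_samples - length(current$neighbors)
    pvals <- 2 * stats::pt(abs(current$t_stat), df, lower.tail = FALSE)
    keep <- is.finite(pvals) & pvals < t_alpha
    if (!all(keep)) {
      audit$decision[audit$neighbor %in% current$neighbors[!keep]] <- "dropped_t"
      current <- refit_subset(current, which(keep))
    }
  }
  attr(current, "audit") <- audit
  current
}

#' Resolve the two directional association estimates for a pair
#'
#' The association ability between two proteins is whichever directional
#' regression coefficient has the larger absolute value; a pruned direction
#' contributes 0. An exact tie on absolute value returns the first argument,
#' which callers supply from the lexicographically smaller (target, neighbor)
#' ordered fit.
#'
#' @param a_ij coefficient from the fit of the lexicographically smaller
#'   target on the larger.
#' @param a_ji coefficient from the reverse fit.
#' @return the resolved association ability.
#' @export
symmetrize_pairs <- function(a_ij, a_ji) {
  if (abs(a_ji) > abs(a_ij)) a_ji else a_ij
}

#' Build a phenotype's protein association network
#'
#' Fits and refines the linear association model for every protein in the
#' rough network on the given phenotype's samples, places each retained
#' coefficient alpha_ik in row i, symmetrizes every pair with
#' [symmetrize_pairs()], and forces a zero diagonal. The concatenated fit
#' audit is attached as attribute `"audit"`.
#'
#' @inheritParams fit_target_model
#' @param t_alpha passed to [refine_model()].
#' @return an [association_network()].
#' @export
build_association_network <- function(net, x, phenotype, t_alpha = 0.05) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  K <- length(net$proteins)
  A <- matrix(0, K, K, dimnames = list(net$proteins, net$proteins))
  audits <- vector("list", K)
  for (i in seq_len(K)) {
    target <- net$proteins[i]
    refined <- refine_model(fit_target_model(target, net, x, phenotype), t_alpha)
    if (length(refined$neighbors))
      A[target, refined$neighbors] <- unname(refined$alpha_hat)
    aud <- attr(refined, "audit")
    if (nrow(aud)) aud$target <- target
    audits[[i]] <- aud
  }
  M <- matrix(0, K, K, dimnames = dimnames(A))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (j <= i) next
      pi_ <- net$proteins[i]; pj <- net$proteins[j]
      # proteins are kept sorted, so (pi_, pj) is the lexicographically
      # smaller ordered fit
      val <- if (pi_ < pj) symmetrize_pairs(A[pi_, pj], A[pj, pi_])
             else symmetrize_pairs(A[pj, pi_], A[pi_, pj])
      M[i, j] <- val
      M[j, i] <- val
    }
  }
  out <- association_network(net$proteins, M, phenotype)
  attr(out, "audit") <- do.call(rbind, audits)
  out
}

#' Write an association network as weighted edge list and SIF
#'
#' @param net an [association_network()].
#' @param edge_path path for the tab-delimited weighted edge list
#'   (`protein_a`, `protein_b`, `alpha`).
#' @param sif_path optional path for a SIF file (`a pp b`) for network
#'   viewers.
#' @return the edge data frame, invisibly.
#' @export
write_association_network <- function(net, edge_path, sif_path = NULL) {
  edges <- an_edges(net)
  out <- edges
  # full 17-digit precision so artifacts round-trip bit-exactly on resume
  out$alpha <- sprintf("%.17g", out$alpha)
  write_tsv_(out, edge_path)
  if (!is.null(sif_path))
    writeLines(paste(edges$protein_a, "pp", edges$protein_b), sif_path)
  invisible(edges)
}
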