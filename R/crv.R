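# Network comparison: difference matrix, carcinogenesis relevance values,
# and the structure-permutation null.

#' Difference between the two association networks
#'
#' Elementwise `C - N` over identically ordered protein lists; symmetry and
#' the zero diagonal are inherited.
#'
#' @param cpan,npan [association_network()]s with identical protein lists.
#' @return an object of class `DifferenceMatrix` (`proteins`, `matrix`).
#' @export
difference_matrix <- function(cpan, npan) {
  if (!identical(cpan$proteins, npan$proteins)) {
    delta <- c(setdiff(cpan$proteins, npan$proteins),
               setdiff(npan$proteins, cpan$proteins))
    abort_contract("protein lists differ between networks: %s",
                   paste(unique(delta), collapse = ", "))
  }
  structure(list(proteins = cpan$proteins,
                 matrix = cpan$matrix - npan$matrix),
            class = "DifferenceMatrix")
}

#' @export
print.DifferenceMatrix <- function(x, ...) {
  cat(sprintf("DifferenceMatrix: %d proteins, %d differing associations\n",
              length(x$proteins), sum(x$matrix[upper.tri(x$matrix)] != 0)))
  invisible(x)
}

#' Carcinogenesis relevance values
#'
#' The CRV of protein i is the sum of absolute association-ability
#' differences over its row of the difference matrix: `crv_i = sum_j |d_ij|`.
#'
#' @param d a [difference_matrix()].
#' @return named nonnegative numeric vector, one value per protein.
#' @export
compute_crv <- function(d) {
  if (!inherits(d, "DifferenceMatrix")) abort_contract("d must be a DifferenceMatrix")
  M <- abs(d$matrix)
  K <- nrow(M)
  out <- numeric(K)
  # sequential double-precision accumulation: bit-identical to the
  # elementwise definition (rowSums would accumulate in extended precision)
  for (i in seq_len(K)) {
    acc <- 0
    for (j in seq_len(K)) acc <- acc + M[i, j]
    out[i] <- acc
  }
  stats::setNames(out, d$proteins)
}

#' Empirical CRV p-values by network-structure permutation
#'
#' Builds a null CRV distribution by repeatedly reassigning the observed
#' multiset of absolute edge differences (the `|d_e|` on the rough network's
#' edges) uniformly at random to distinct protein pairs, keeping the edge
#' count and forbidding self-pairs. Each replicate contributes the K
#' per-protein null CRVs to one pooled null distribution; the p-value of an
#' observed CRV is the fraction of pooled null CRVs at least as large. An
#' observed CRV exceeding every null value is reported as below the null's
#' resolution (displayed `"< 1/(K R)"`, stored as half the resolution).
#'
#' @param net the [rough_network()] whose edges carry the differences.
#' @param d a [difference_matrix()] whose nonzero support lies on `net`'s
#'   edges.
#' @param n_permutations number of random structures.
#' @param seed integer seed; identical seeds give identical p-values.
#' @return a `CRVTable` data frame (`protein`, `crv`, `p_value`,
#'   `p_display`, `significant`) sorted by descending CRV, with attributes
#'   `n_permutations` and `seed`.
#' @export
permutation_null <- function(net, d, n_permutations = 100000L, seed = 1L) {
  if (n_permutations < 1L) abort_contract("n_permutations must be >= 1")
  if (!identical(net$proteins, d$proteins))
    abort_contract("network and difference matrix protein lists differ")
  off_support <- d$matrix != 0 & !net$adjacency
  if (any(off_support))
    abort_contract("difference matrix has support off the rough network edges")
  K <- length(net$proteins)
  edges <- rn_edges(net)
  vals <- abs(d$matrix[edges])
  E <- length(vals)
  n_pairs <- K * (K - 1L) / 2L
  ut <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  ipair <- ut[, 1L]; jpair <- ut[, 2L]
  crv_obs <- compute_crv(d)
  null_pool <- numeric(K * n_permutations)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  for (r in seq_len(n_permutations)) {
    sel <- sample.int(n_pairs, E)
    null_crv <- numeric(K)
    acc_i <- c(ipair[sel], jpair[sel])
    acc_v <- c(vals, vals)
    sums <- rowsum(acc_v, acc_i)
    null_crv[as.integer(rownames(sums))] <- sums
    null_pool[((r - 1L) * K + 1L):(r * K)] <- null_crv
  }
  total <- length(null_pool)
  sorted <- sort(null_pool)
  # count of null values >= crv via position in the sorted pool; the small
  # relative epsilon makes exact float ties count as "at least as large"
  eps <- pmax(abs(crv_obs) * 1e-12, 1e-15)
  counts <- total - findInterval(crv_obs - eps, sorted)
  p <- counts / total
  p_display <- formatC(p, format = "g", digits = 6)
  zero <- counts == 0L
  p[zero] <- 0.5 / total
  p_display[zero] <- sprintf("< %g", 1 / total)
  out <- data.frame(protein = net$proteins,
                    crv = unname(crv_obs),
                    p_value = unname(p),
                    p_display = unname(p_display),
                    significant = unname(p <= 0.05),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$crv, out$protein, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("CRVTable", "data.frame")
  attr(out, "n_permutations") <- as.integer(n_permutations)
  attr(out, "seed") <- as.integer(seed)
  out
}

# Save/restore the global RNG state so seeded operations do not perturb the
# caller's stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Filter a CRV table to significant proteins
#'
#' Keeps rows with `p_value <= threshold` (boundary included), preserving
#' the descending-CRV order.
#'
#' @param t a `CRVTable` from [permutation_null()].
#' @param threshold p-value cutoff.
#' @return the subset `CRVTable`.
#' @export
significant_proteins <- function(t, threshold = 0.05) {
  if (!inherits(t, "CRVTable")) abort_contract("t must be a CRVTable")
  out <- t[t$p_value <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
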