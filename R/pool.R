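# Differential protein pool selection and rough PPI network construction.

#' One-way ANOVA differential test per protein
#'
#' Tests each row of a labeled, normalized expression matrix for a mean
#' difference between the phenotype groups with the one-way F test (the
#' two-group case equals the pooled two-sample t statistic squared).
#' P-values are Bonferroni-adjusted over all tested proteins.
#'
#' The `selected` column reports the Bonferroni criterion
#' (`p_bonferroni < alpha`) only; the additional requirement that a selected
#' protein has at least one interaction is applied by [select_pool()], which
#' sees the interaction set.
#'
#' @param x a normalized labeled [expression_matrix()] with at least two
#'   samples per phenotype.
#' @param alpha significance level for the `selected` flag.
#' @return a `DifferentialTable` data frame with columns `protein`,
#'   `f_statistic`, `p_raw`, `p_bonferroni`, `selected`, `degenerate`.
#' @export
differential_test <- function(x, alpha = 0.05) {
  if (!inherits(x, "ExpressionMatrix")) abort_contract("x must be an ExpressionMatrix")
  if (is.null(x$labels)) abort_contract("x must be labeled")
  if (!x$normalized) abort_contract("x must be normalized")
  groups <- factor(x$labels, levels = PHENOTYPES)
  sizes <- table(groups)
  if (any(sizes < 2L))
    abort_contract("each phenotype group needs >= 2 samples (got %s)",
                   paste(sizes, collapse = "/"))
  v <- x$values
  n <- ncol(v)
  G <- nlevels(groups)
  grand <- rowMeans(v)
  ssb <- 0
  ssw <- 0
  for (g in levels(groups)) {
    vg <- v[, groups == g, drop = FALSE]
    mg <- rowMeans(vg)
    ssb <- ssb + ncol(vg) * (mg - grand)^2
    ssw <- ssw + rowSums((vg - mg)^2)
  }
  f <- (ssb / (G - 1)) / (ssw / (n - G))
  degenerate <- ssw == 0 & ssb > 0
  p <- stats::pf(f, G - 1, n - G, lower.tail = FALSE)
  # perfect separation: F is infinite, p underflows; report the smallest
  # representable positive value and flag it
  p[degenerate] <- .Machine$double.xmin
  p[ssw == 0 & ssb == 0] <- 1
  f[ssw == 0 & ssb == 0] <- 0
  m <- nrow(v)
  out <- data.frame(protein = rownames(v),
                    f_statistic = unname(f),
                    p_raw = unname(p),
                    p_bonferroni = unname(pmin(1, p * m)),
                    stringsAsFactors = FALSE)
  out$selected <- out$p_bonferroni < alpha
  out$degenerate <- unname(degenerate)
  class(out) <- c("DifferentialTable", "data.frame")
  out
}

#' Select the protein pool
#'
#' The pool is the union of (a) differentially expressed proteins
#' (Bonferroni p below `alpha`) that have at least one interaction record,
#' and (b) tested non-DE proteins interacting with at least
#' `neighbor_threshold` proteins of set (a). DE proteins without any PPI
#' record are excluded.
#'
#' @param dt a `DifferentialTable` from [differential_test()].
#' @param ppi an [interaction_set()] on the same (case-folded) symbol universe.
#' @param alpha Bonferroni significance cutoff.
#' @param neighbor_threshold minimum number of distinct DE pool partners for
#'   a non-DE protein to be pulled in.
#' @return sorted character vector of pool protein symbols.
#' @export
select_pool <- function(dt, ppi, alpha = 0.05, neighbor_threshold = 3L) {
  if (!inherits(dt, "DifferentialTable")) abort_contract("dt must be a DifferentialTable")
  nm <- neighbor_map(ppi)
  de <- dt$protein[dt$p_bonferroni < alpha]
  de_pool <- de[de %in% names(nm)]
  dropped <- setdiff(de, de_pool)
  if (length(dropped))
    crv_log("excluded %d DE protein(s) without PPI records", length(dropped))
  candidates <- setdiff(intersect(dt$protein, names(nm)), de_pool)
  n_links <- vapply(candidates, function(p)
    length(intersect(unique(nm[[p]]), de_pool)), integer(1))
  augmented <- candidates[n_links >= neighbor_threshold]
  pool <- sort(unique(c(de_pool, augmented)), method = "radix")
  if (!length(pool))
    abort_pipeline(paste("empty protein pool: relax alpha (%g) or",
                         "neighbor_threshold (%d)"), alpha, neighbor_threshold)
  pool
}

#' Build the degree-bounded rough PPI network
#'
#' Links pool proteins that share an interaction, then enforces the
#' overfitting guard: every protein's degree must stay strictly below the
#' smaller phenotype group's sample size. Proteins exceeding the cap lose
#' incident edges one at a time, weakest absolute Pearson correlation of the
#' endpoint expression rows first (ties broken lexicographically by partner
#' symbol), until their degree is `degree_cap - 1`. Isolated proteins are
#' removed. The pruning log is attached as attribute `"pruning_log"`.
#'
#' @param pool character vector of pool protein symbols.
#' @param ppi an [interaction_set()].
#' @param x a labeled [expression_matrix()] covering the pool (proteins
#'   absent from `x` are dropped with a message).
#' @return a [rough_network()].
#' @export
build_rough_network <- function(pool, ppi, x) {
  if (!length(pool)) abort_contract("pool is empty")
  if (is.null(x$labels)) abort_contract("x must be labeled")
  missing <- setdiff(pool, em_entities(x))
  if (length(missing)) {
    crv_log("dropped %d pool protein(s) without expression rows", length(missing))
    pool <- setdiff(pool, missing)
  }
  pool <- sort(unique(pool), method = "radix")
  K <- length(pool)
  adj <- matrix(FALSE, K, K, dimnames = list(pool, pool))
  inpool <- ppi$a %in% pool & ppi$b %in% pool
  ea <- ppi$a[inpool]; eb <- ppi$b[inpool]
  adj[cbind(ea, eb)] <- TRUE
  adj[cbind(eb, ea)] <- TRUE
  n_c <- sum(x$labels == "cancer")
  n_n <- sum(x$labels == "noncancer")
  cap <- min(n_c, n_n)
  v <- x$values[pool, , drop = FALSE]
  pruning_log <- character()
  repeat {
    deg <- rowSums(adj)
    over <- which(deg >= cap)
    if (!length(over)) break
    p <- pool[min(over)]  # pool is sorted: lexicographically first violator
    partners <- pool[adj[p, ]]
    cors <- abs(as.vector(stats::cor(v[p, ], t(v[partners, , drop = FALSE]))))
    ord <- order(cors, partners, method = "radix")
    weakest <- partners[ord[1L]]
    adj[p, weakest] <- FALSE
    adj[weakest, p] <- FALSE
    pruning_log <- c(pruning_log,
                     sprintf("pruned %s -- %s (|r| = %.6f)", p, weakest, cors[ord[1L]]))
  }
  iso <- rowSums(adj) == 0
  if (all(iso))
    abort_pipeline("all pool proteins are isolated in the interaction data")
  if (any(iso))
    crv_log("removed %d isolated protein(s) from the rough network", sum(iso))
  keep <- !iso
  if (length(pruning_log))
    crv_log("degree cap %d enforced: %d edge(s) pruned", cap, length(pruning_log))
  net <- rough_network(pool[keep], adj[keep, keep, drop = FALSE], cap)
  attr(net, "pruning_log") <- pruning_log
  net
}
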