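# Core S3 containers shared by the pipeline stages.

PHENOTYPES <- c("cancer", "noncancer")

#' Construct an expression matrix container
#'
#' Holds an entities-by-samples real matrix together with optional per-sample
#' phenotype labels and a normalization flag. Entity identifiers (gene or
#' protein symbols) are stored upper-cased and must be unique; sample
#' identifiers must be unique. This is the carrier every pipeline stage
#' consumes: ingest returns it raw, [znormalize()] row-standardizes it, and
#' the fitting and diagnosis stages require the normalized form.
#'
#' @param values numeric matrix with unique rownames (entity symbols) and
#'   unique colnames (sample ids); no missing values.
#' @param labels optional named character vector mapping every sample id to
#'   `"cancer"` or `"noncancer"`.
#' @param normalized logical; `TRUE` once each row has mean 0 and sd 1.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, labels = NULL, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_contract("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_contract("values must carry entity rownames and sample colnames")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    abort_contract("entity ids must be unique after case folding")
  if (anyDuplicated(colnames(values)))
    abort_input("duplicate sample ids: %s",
                paste(unique(colnames(values)[duplicated(colnames(values))]),
                      collapse = ", "))
  if (anyNA(values))
    abort_contract("ExpressionMatrix must contain no missing values")
  if (!is.null(labels)) {
    labels <- structure(tolower(as.character(labels)), names = names(labels))
    if (is.null(names(labels)))
      abort_contract("labels must be named by sample id")
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
      abort_input("samples without labels: %s", paste(missing, collapse = ", "))
    unknown <- setdiff(names(labels), colnames(values))
    if (length(unknown))
      abort_input("label for unknown sample: %s", paste(unknown, collapse = ", "))
    bad <- setdiff(unique(labels), PHENOTYPES)
    if (length(bad))
      abort_input("labels must be in {cancer, noncancer}; got: %s",
                  paste(bad, collapse = ", "))
    labels <- labels[colnames(values)]
  }
  structure(list(values = values, labels = labels,
                 normalized = isTRUE(normalized)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d entities x %d samples (%s%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "z-normalized" else "raw",
              if (is.null(x$labels)) ", unlabeled"
              else sprintf(", %d cancer / %d noncancer",
                           sum(x$labels == "cancer"),
                           sum(x$labels == "noncancer"))))
  invisible(x)
}

em_entities <- function(x) rownames(x$values)
em_samples  <- function(x) colnames(x$values)

# Sample ids of one phenotype group.
group_samples <- function(x, phenotype) {
  if (is.null(x$labels)) abort_contract("ExpressionMatrix is unlabeled")
  phenotype <- match.arg(phenotype, PHENOTYPES)
  em_samples(x)[x$labels == phenotype]
}

# Column subset keeping labels; used by cross-validation.
em_subset <- function(x, samples) {
  expression_matrix(x$values[, samples, drop = FALSE],
                    labels = if (is.null(x$labels)) NULL else x$labels[samples],
                    normalized = x$normalized)
}

#' Construct an interaction set
#'
#' Canonical container for undirected protein-protein interactions. Pairs are
#' stored upper-cased with the lexicographically smaller symbol first;
#' self-pairs are dropped and duplicate pairs merged, with per-pair provenance
#' accumulated across sources.
#'
#' @param a,b character vectors of interacting protein symbols.
#' @param provenance character vector (recycled) tagging each pair with its
#'   source: `"biogrid"`, `"hprd"` or `"generic"`.
#' @return an object of class `InteractionSet`: a data frame with columns
#'   `a`, `b`, `provenance` (sources joined by `";"`).
#' @export
interaction_set <- function(a, b, provenance = "generic") {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (length(a) != length(b)) abort_contract("a and b lengths differ")
  provenance <- rep_len(as.character(provenance), length(a))
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  prov <- provenance[keep]
  key <- paste(a2, b2, sep = "\r")
  merged <- vapply(split(prov, key), function(p)
    paste(sort(unique(p)), collapse = ";"), character(1))
  ord <- sort(names(merged), method = "radix")
  parts <- strsplit(ord, "\r", fixed = TRUE)
  out <- data.frame(a = vapply(parts, `[`, "", 1L),
                    b = vapply(parts, `[`, "", 2L),
                    provenance = unname(merged[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("InteractionSet", "data.frame")
  out
}

#' @export
print.InteractionSet <- function(x, ...) {
  cat(sprintf("InteractionSet: %d pairs over %d proteins\n",
              nrow(x), length(unique(c(x$a, x$b)))))
  invisible(x)
}

# All proteins appearing in the interaction set.
is_universe <- function(ppi) sort(unique(c(ppi$a, ppi$b)), method = "radix")

# Named list: protein -> character vector of interaction partners.
neighbor_map <- function(ppi) {
  syms <- c(ppi$a, ppi$b)
  partners <- c(ppi$b, ppi$a)
  split(partners, syms)
}

#' Construct a rough PPI network
#'
#' @param proteins ordered character vector of K protein symbols.
#' @param adjacency symmetric logical K x K matrix, zero diagonal.
#' @param degree_cap positive integer; every degree must be strictly below it.
#' @return an object of class `RoughNetwork`.
#' @export
rough_network <- function(proteins, adjacency, degree_cap) {
  if (!identical(dim(adjacency), c(length(proteins), length(proteins))))
    abort_contract("adjacency dimension mismatch")
  if (any(diag(adjacency))) abort_contract("self-edges are not allowed")
  if (!isTRUE(all(adjacency == t(adjacency))))
    abort_contract("adjacency must be symmetric")
  deg <- rowSums(adjacency)
  if (any(deg >= degree_cap))
    abort_contract("maximum degree (%d) must be below the degree cap (%d)",
                   max(deg), degree_cap)
  if (any(deg < 1))
    abort_contract("isolated proteins are not allowed in a RoughNetwork")
  dimnames(adjacency) <- list(proteins, proteins)
  structure(list(proteins = proteins, adjacency = adjacency,
                 degree_cap = as.integer(degree_cap)),
            class = "RoughNetwork")
}

#' @export
print.RoughNetwork <- function(x, ...) {
  cat(sprintf("RoughNetwork: %d proteins, %d edges, degree cap %d (max degree %d)\n",
              length(x$proteins), sum(x$adjacency) / 2, x$degree_cap,
              max(rowSums(x$adjacency))))
  invisible(x)
}

# Edge list (i < j indices into proteins) of a rough network.
rn_edges <- function(net) {
  idx <- which(net$adjacency & upper.tri(net$adjacency), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Construct a protein association network
#'
#' A symmetric K x K matrix of association abilities (regression
#' coefficients) for one phenotype, zero diagonal.
#'
#' @param proteins ordered character vector of K symbols.
#' @param matrix symmetric numeric K x K matrix, zero diagonal.
#' @param phenotype `"cancer"` or `"noncancer"`.
#' @return an object of class `AssociationNetwork`.
#' @export
association_network <- function(proteins, matrix, phenotype) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  if (!identical(dim(matrix), c(length(proteins), length(proteins))))
    abort_contract("matrix dimension mismatch")
  if (any(diag(matrix) != 0)) abort_contract("diagonal must be zero")
  if (!identical(matrix, t(matrix)))
    abort_contract("association matrix must be exactly symmetric")
  dimnames(matrix) <- list(proteins, proteins)
  structure(list(proteins = proteins, matrix = matrix, phenotype = phenotype),
            class = "AssociationNetwork")
}

#' @export
print.AssociationNetwork <- function(x, ...) {
  nz <- sum(x$matrix[upper.tri(x$matrix)] != 0)
  cat(sprintf("AssociationNetwork (%s): %d proteins, %d associations\n",
              x$phenotype, length(x$proteins), nz))
  invisible(x)
}

# Weighted edge data frame of an association network.
an_edges <- function(net) {
  idx <- which(net$matrix != 0 & upper.tri(net$matrix), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(protein_a = net$proteins[idx[, 1]],
             protein_b = net$proteins[idx[, 2]],
             alpha = net$matrix[idx],
             stringsAsFactors = FALSE)
}
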