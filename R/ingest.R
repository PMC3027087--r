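# Readers and normalization: expression matrices, interaction tables,
# gene-to-protein overlay.

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids (with or without a leading cell naming
#' the entity column) and one row per entity, first field the gene/protein
#' symbol. Rows containing non-numeric or missing cells are dropped with a
#' warning; duplicate symbols are collapsed by the row mean of their raw
#' values. Gzip-compressed files are read transparently.
#'
#' @param matrix_path path to the expression matrix file.
#' @param labels_path optional path to a two-column tab-delimited file
#'   (sample id, `cancer`/`noncancer`). When given, every sample must be
#'   labeled.
#' @return an un-normalized [expression_matrix()].
#' @export
read_expression <- function(matrix_path, labels_path = NULL) {
  lines <- read_lines_(matrix_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    abort_input("expression file %s has no data rows", matrix_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  width <- length(fields[[2L]])
  if (length(header) == width) {
    sample_ids <- header[-1L]
  } else if (length(header) == width - 1L) {
    sample_ids <- header
  } else {
    abort_input("malformed header in %s: %d header fields vs %d data fields",
                matrix_path, length(header), width)
  }
  if (anyDuplicated(sample_ids))
    abort_input("duplicate sample ids in %s: %s", matrix_path,
                paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- fields[-1L]
  badlen <- which(lengths(body) != width)
  if (length(badlen))
    abort_input("row %d of %s has %d fields, expected %d",
                badlen[1L] + 1L, matrix_path, lengths(body)[badlen[1L]], width)
  syms <- toupper(vapply(body, `[`, "", 1L))
  vals <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(body, `[`, -1L), use.names = FALSE))),
    nrow = length(body), byrow = TRUE)
  bad <- which(rowSums(is.na(vals)) > 0L)
  if (length(bad)) {
    warning(sprintf("dropped %d row(s) with non-numeric or missing cells: %s",
                    length(bad), paste(utils::head(syms[bad], 5L), collapse = ", ")))
    vals <- vals[-bad, , drop = FALSE]
    syms <- syms[-bad]
  }
  if (!nrow(vals)) abort_input("no usable expression rows in %s", matrix_path)
  vals <- collapse_rows_mean(vals, syms)
  colnames(vals) <- sample_ids
  labels <- if (!is.null(labels_path)) read_labels(labels_path) else NULL
  expression_matrix(vals, labels = labels, normalized = FALSE)
}

# Collapse duplicate symbols by arithmetic mean of raw rows; preserves the
# order of first appearance.
collapse_rows_mean <- function(vals, syms) {
  if (anyDuplicated(syms)) {
    dup <- unique(syms[duplicated(syms)])
    crv_log("collapsed %d duplicate symbol(s) by row mean: %s",
            length(dup), paste(utils::head(dup, 5L), collapse = ", "))
    keys <- factor(syms, levels = unique(syms))
    vals <- rowsum(vals, keys) / as.vector(table(keys))
    rownames(vals) <- levels(keys)
  } else {
    rownames(vals) <- syms
  }
  vals
}

read_labels <- function(labels_path) {
  lines <- read_lines_(labels_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L))
    abort_input("label file %s: every line must have 2 tab-separated fields",
                labels_path)
  ids <- vapply(fields, `[`, "", 1L)
  # tolerate a header line
  labs <- tolower(vapply(fields, `[`, "", 2L))
  if (labs[1L] %in% c("label", "phenotype", "group")) {
    ids <- ids[-1L]; labs <- labs[-1L]
  }
  structure(labs, names = ids)
}

#' Z-transform each expression row
#'
#' Standardizes every row to mean 0 and standard deviation 1 over all samples
#' (sample sd, denominator n-1). Zero-variance rows are removed with a
#' warning before transforming.
#'
#' @param x an un-normalized [expression_matrix()].
#' @return the normalized `ExpressionMatrix`.
#' @export
znormalize <- function(x) {
  if (!inherits(x, "ExpressionMatrix")) abort_contract("x must be an ExpressionMatrix")
  if (x$normalized) abort_contract("ExpressionMatrix is already normalized")
  v <- x$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  drop <- which(!is.finite(sdv) | sdv == 0)
  if (length(drop)) {
    warning(sprintf("removed %d zero-variance row(s): %s", length(drop),
                    paste(utils::head(rownames(v)[drop], 5L), collapse = ", ")))
    v <- v[-drop, , drop = FALSE]
    mu <- mu[-drop]; sdv <- sdv[-drop]
  }
  if (!nrow(v)) abort_input("no rows left after zero-variance filtering")
  z <- (v - mu) / sdv
  expression_matrix(z, labels = x$labels, normalized = TRUE)
}

#' Read protein-protein interaction files
#'
#' Supported dialects: `biogrid_tab2` (official-symbol columns of the BioGRID
#' TAB2 format), `hprd` (tab-delimited flat file with gene symbols in columns
#' 1 and 4), and `edgelist` (two tab-separated symbol columns, optional
#' header). Files are unioned: self-interactions are removed and duplicate
#' pairs merged with multi-source provenance. Gzip transparent.
#'
#' @param paths character vector of file paths.
#' @param dialect one dialect for all files, or a vector matched to `paths`.
#' @return an [interaction_set()].
#' @export
read_interactions <- function(paths, dialect = "edgelist") {
  dialect <- rep_len(dialect, length(paths))
  ok <- dialect %in% c("biogrid_tab2", "hprd", "edgelist")
  if (!all(ok))
    abort_input("unknown interaction dialect: %s",
                paste(unique(dialect[!ok]), collapse = ", "))
  a <- character(); b <- character(); prov <- character()
  for (i in seq_along(paths)) {
    pr <- switch(dialect[i],
                 biogrid_tab2 = parse_biogrid_tab2(paths[i]),
                 hprd = parse_hprd(paths[i]),
                 edgelist = parse_edgelist(paths[i]))
    if (!nrow(pr))
      abort_input("no parseable interaction pairs in %s", paths[i])
    a <- c(a, pr$a); b <- c(b, pr$b)
    prov <- c(prov, rep(switch(dialect[i], biogrid_tab2 = "biogrid",
                               hprd = "hprd", edgelist = "generic"), nrow(pr)))
  }
  interaction_set(a, b, prov)
}

parse_biogrid_tab2 <- function(path) {
  lines <- read_lines_(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort_input("empty interaction file %s", path)
  header <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  ia <- match("Official Symbol Interactor A", header)
  ib <- match("Official Symbol Interactor B", header)
  if (is.na(ia) || is.na(ib))
    abort_input("%s lacks BioGRID TAB2 official-symbol columns", path)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  body <- body[lengths(body) >= max(ia, ib)]
  data.frame(a = vapply(body, `[`, "", ia),
             b = vapply(body, `[`, "", ib), stringsAsFactors = FALSE)
}

parse_hprd <- function(path) {
  body <- strsplit(read_lines_(path), "\t", fixed = TRUE)
  body <- body[lengths(body) >= 4L]
  df <- data.frame(a = vapply(body, `[`, "", 1L),
                   b = vapply(body, `[`, "", 4L), stringsAsFactors = FALSE)
  df[df$a != "" & df$b != "" & df$a != "-" & df$b != "-", , drop = FALSE]
}

parse_edgelist <- function(path) {
  body <- strsplit(read_lines_(path), "\t", fixed = TRUE)
  body <- body[lengths(body) >= 2L]
  df <- data.frame(a = vapply(body, `[`, "", 1L),
                   b = vapply(body, `[`, "", 2L), stringsAsFactors = FALSE)
  # tolerate an explicit header line
  hdr <- tolower(df$a[1L]) %in% c("protein_a", "source", "from", "protein1",
                                  "node1", "interactor_a")
  if (nrow(df) && hdr) df <- df[-1L, , drop = FALSE]
  df[df$a != "" & df$b != "", , drop = FALSE]
}

#' Overlay gene expression onto proteins
#'
#' Maps gene symbols to protein symbols (identity by default) and collapses
#' genes sharing a protein by the arithmetic mean of their raw rows. Must be
#' applied before [znormalize()] so collapsing acts on raw values.
#'
#' @param x an un-normalized [expression_matrix()].
#' @param mapping optional two-column data frame (gene, protein) or named
#'   character vector `gene -> protein`. Unmapped genes are kept under their
#'   own symbol.
#' @return an `ExpressionMatrix` with protein entity ids.
#' @export
overlay_genes_on_proteins <- function(x, mapping = NULL) {
  if (!inherits(x, "ExpressionMatrix")) abort_contract("x must be an ExpressionMatrix")
  if (x$normalized)
    abort_contract("overlay must run on raw values, before znormalize")
  if (is.null(mapping)) return(x)
  if (is.data.frame(mapping)) {
    map <- structure(toupper(mapping[[2L]]), names = toupper(mapping[[1L]]))
  } else {
    map <- structure(toupper(as.character(mapping)), names = toupper(names(mapping)))
  }
  if (anyDuplicated(names(map))) {
    dups <- unique(names(map)[duplicated(names(map))])
    conflict <- dups[vapply(dups, function(k)
      length(unique(map[names(map) == k])) > 1L, logical(1))]
    if (length(conflict))
      abort_input("conflicting mapping for key(s): %s",
                  paste(conflict, collapse = ", "))
    map <- map[!duplicated(names(map))]
  }
  genes <- em_entities(x)
  target <- ifelse(genes %in% names(map), unname(map[genes]), genes)
  unmapped <- sum(!genes %in% names(map))
  if (unmapped && length(map))
    crv_log("%d gene(s) without protein mapping retained under their own symbol",
            unmapped)
  vals <- collapse_rows_mean(x$values, target)
  expression_matrix(vals, labels = x$labels, normalized = FALSE)
}

#' Read a GEO series-matrix file as an expression matrix
#'
#' Minimal reader for the `!series_matrix_table_begin` /
#' `!series_matrix_table_end` block of a GEO series matrix; probe ids become
#' entity ids and no labels are attached. Provided as an optional convenience
#' behind the same contract as [read_expression()].
#'
#' @param path path to a (optionally gzipped) series-matrix file.
#' @return an un-normalized unlabeled [expression_matrix()].
#' @export
read_geo_series_matrix <- function(path) {
  lines <- read_lines_(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    abort_input("%s has no series-matrix table block", path)
  block <- lines[(beg + 1L):(end - 1L)]
  block <- gsub('"', "", block, fixed = TRUE)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(block, tmp)
  read_expression(tmp)
}
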