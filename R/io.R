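# Readers, writers, and input alignment.

.validate_abundance <- function(x, normalized = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance table must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (ncol(x) < 2L) stop("need at least 2 OTUs", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance table must carry sample and OTU identifiers", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop("duplicate sample identifiers", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate OTU identifiers", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("abundances must be finite and nonnegative", call. = FALSE)
  if (normalized && any(abs(rowSums(x) - 1) > 1e-8))
    stop("rows are not compositions (sums differ from 1)", call. = FALSE)
  invisible(x)
}

#' Normalize an abundance matrix to row compositions
#'
#' Divides each row (sample) by its total so rows sum to one. Input may be
#' counts or already-relative abundances.
#'
#' @param x numeric matrix, samples in rows, with dimnames.
#' @return row-normalized matrix.
#' @export
normalize_abundance <- function(x) {
  .validate_abundance(x)
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("degenerate sample(s) with zero total abundance: ",
         paste(rownames(x)[rs == 0], collapse = ", "), call. = FALSE)
  x / rs
}

#' Read an OTU abundance table from TSV
#'
#' Reads a tab-separated table with one header row and a first column of
#' identifiers, then normalizes each sample to a composition (each row
#' divided by its sum). Counts and relative abundances are both accepted;
#' analysis always proceeds on compositions.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples-as-rows"` (default) or `"samples-as-cols"`;
#'   the latter transposes after reading.
#' @return numeric matrix of relative abundances, samples in rows, with
#'   sample and OTU identifiers as dimnames.
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples-as-rows",
                                                 "samples-as-cols")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1L)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in abundance table", call. = FALSE)
  if (orientation == "samples-as-cols") m <- t(m)
  normalize_abundance(m)
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance_table()] (samples as rows); values round-trip
#' to full double precision.
#'
#' @param x abundance matrix with dimnames.
#' @param path output path.
#' @export
write_abundance_table <- function(x, path) {
  .validate_abundance(x)
  df <- data.frame(sample_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Wraps [ape::read.tree()] with the checks the UniFrac computations need:
#' unique leaf labels, finite nonnegative branch lengths, positive total tree
#' length. Missing branch lengths are set to 0 with a warning. Trees stored
#' with a basal multifurcation (unrooted Newick) are accepted; the basal
#' node acts as the root.
#'
#' @param path path to a Newick file.
#' @return an [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick file: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("unparseable Newick file", call. = FALSE)
  .validate_tree(tree)
}

.validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("leaf labels are not unique", call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths treated as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and nonnegative", call. = FALSE)
  tree
}

#' Align an abundance table, sample metadata, and tree
#'
#' Restricts table and metadata to their common samples (warning with a count
#' when samples are dropped), reorders metadata to the table's sample order,
#' dummy-encodes categorical columns (one-hot minus reference level), and
#' mean-centers every design column. The design matrices the test consumes
#' are therefore always numeric and centered.
#'
#' @param table abundance matrix (samples in rows, with sample ids).
#' @param meta data.frame of sample metadata with sample ids as row names.
#' @param x1_cols character vector: metadata columns of interest.
#' @param x2_cols character vector of confounder columns, or NULL.
#' @param tree optional `phylo` tree passed through after leaf checks.
#' @return list with `table`, `x1`, `x2` (NULL if no confounders), `tree`,
#'   and `n_dropped`.
#' @export
align_inputs <- function(table, meta, x1_cols, x2_cols = NULL, tree = NULL) {
  .validate_abundance(table)
  if (is.null(rownames(meta))) stop("metadata must have sample ids as row names")
  common <- intersect(rownames(table), rownames(meta))
  if (length(common) == 0L)
    stop("no samples shared between table and metadata", call. = FALSE)
  n_dropped <- (nrow(table) - length(common)) + (nrow(meta) - length(common))
  if (n_dropped > 0L)
    warning(sprintf("dropped %d unmatched sample(s) during alignment", n_dropped))
  table <- table[rownames(table) %in% common, , drop = FALSE]
  meta <- meta[rownames(table), , drop = FALSE]
  missing_cols <- setdiff(c(x1_cols, x2_cols), colnames(meta))
  if (length(missing_cols))
    stop("metadata columns not found: ", paste(missing_cols, collapse = ", "))
  sel <- meta[, c(x1_cols, x2_cols), drop = FALSE]
  if (anyNA(sel)) stop("missing values in selected metadata columns", call. = FALSE)
  x1 <- encode_design(meta[, x1_cols, drop = FALSE])
  x2 <- if (length(x2_cols)) encode_design(meta[, x2_cols, drop = FALSE]) else NULL
  if (!is.null(tree)) tree <- .validate_tree(tree)
  list(table = table, x1 = x1, x2 = x2, tree = tree, n_dropped = n_dropped)
}

#' Encode and center a design matrix
#'
#' One-hot encodes factors/characters (dropping the reference level) and
#' mean-centers every column. Constant columns trigger a rank warning.
#'
#' @param df data.frame or matrix of covariates.
#' @return centered numeric matrix.
#' @export
encode_design <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) if (is.character(df[[j]]) || is.logical(df[[j]]))
    df[[j]] <- factor(df[[j]])
  mm <- model.matrix(~ ., data = df)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  ctr <- scale(mm, center = TRUE, scale = FALSE)
  const <- apply(ctr, 2L, function(z) all(abs(z) < 1e-12))
  if (any(const))
    warning("constant design column(s) after centering: ",
            paste(colnames(ctr)[const], collapse = ", "))
  attr(ctr, "scaled:center") <- NULL
  ctr
}

.format_num <- function(x) sprintf("%.17g", x)

#' Write ensemble test results to disk
#'
#' Writes a TSV with one row per base test (distance, exponent, statistic,
#' permutation moments, skewness, p-value) and a JSON summary holding the
#' ensemble statistic and p-value. Output is byte-identical across repeated
#' runs on identical input because the whole analysis path is deterministic.
#'
#' @param result an object of class `emanova`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, dir) {
  if (!inherits(result, "emanova")) stop("result must be an 'emanova' object")
  if (nrow(result$base) == 0L) stop("empty base-test result list", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- result$base
  tsv <- file.path(dir, "base_tests.tsv")
  out <- data.frame(distance = base$distance, d = base$d,
                    r = .format_num(base$r),
                    statistic = .format_num(base$statistic),
                    e_perm = .format_num(base$e1),
                    var_perm = .format_num(base$var),
                    e3_perm = .format_num(base$e3),
                    skewness = .format_num(base$skewness),
                    p_value = .format_num(base$p_value),
                    stringsAsFactors = FALSE)
  write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(n = result$n,
         distances = result$distances,
         r_set = result$r_set,
         n_base_tests = nrow(base),
         statistic = result$statistic,
         p_value = result$p_value),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}

#' Export a distance matrix as a labeled square TSV
#'
#' @param D square distance matrix with dimnames.
#' @param path output path.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(sample_id = rownames(D),
                   format(D, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
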