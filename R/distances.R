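# Pairwise distances: weighted/unweighted UniFrac and Bray-Curtis.

#' Per-branch descendant abundance profile
#'
#' For each sample and each branch of the tree, computes the total relative
#' abundance of the OTUs descending from that branch, by postorder
#' accumulation of leaf proportions. Branches are enumerated in the tree's
#' edge order (root stem excluded); the same fixed order is used for the
#' branch lengths, so UniFrac computations are deterministic.
#'
#' Every OTU with nonzero abundance in some sample must map to exactly one
#' leaf. OTUs present in the tree but absent from the table contribute zero.
#' The tree's stored basal node is taken as the root: a basal multifurcation
#' (how unrooted Newick trees are stored) is accepted as-is, since branch
#' direction is all the computation needs.
#'
#' @param table relative-abundance matrix (samples in rows, OTU ids as
#'   column names; rows must be compositions).
#' @param tree a `phylo` tree whose tip labels cover the table's OTUs.
#' @return list with `proportions` (n x L matrix of per-branch descendant
#'   abundances), `lengths` (branch lengths, length L), and `tree`.
#' @export
branch_profile <- function(table, tree) {
  .validate_abundance(table, normalized = TRUE)
  tree <- .validate_tree(tree)
  used <- colnames(table)[colSums(table) > 0]
  unmapped <- setdiff(used, tree$tip.label)
  if (length(unmapped))
    stop("OTUs with nonzero abundance missing from the tree: ",
         paste(utils::head(unmapped, 5L), collapse = ", "),
         if (length(unmapped) > 5L) ", ...", call. = FALSE)
  n <- nrow(table)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # node proportions: tips first, then internal nodes, accumulated postorder
  node_prop <- matrix(0, n, ntip + nnode)
  idx <- match(tree$tip.label, colnames(table))
  hit <- !is.na(idx)
  node_prop[, which(hit)] <- table[, idx[hit], drop = FALSE]
  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    node_prop[, po[e, 1L]] <- node_prop[, po[e, 1L]] + node_prop[, po[e, 2L]]
  }
  P <- node_prop[, edge[, 2L], drop = FALSE]
  rownames(P) <- rownames(table)
  list(proportions = P, lengths = tree$edge.length, tree = tree)
}

.as_distmatrix <- function(D, ids) {
  dimnames(D) <- list(ids, ids)
  D
}

#' Weighted UniFrac distance matrix
#'
#' Abundance-weighted phylogenetic distance
#' \deqn{d_{ij} = \frac{\sum_l b_l (p_{il}+p_{jl})^\alpha |p_{il}-p_{jl}|}
#'                     {\sum_l b_l (p_{il}+p_{jl})^\alpha},}
#' where \eqn{p_{il}} is the descendant abundance of branch \eqn{l} in sample
#' \eqn{i} and \eqn{b_l} its length. The generalized exponent `alpha` in
#' \[0, 1\] moderates the weight given to abundant lineages; `alpha = 0.5`
#' is the robust default. Branches with \eqn{p_{il}+p_{jl}=0} contribute to
#' neither sum (at `alpha = 0` this makes the denominator the total length of
#' branches present in either sample). A pair with an all-zero denominator is
#' assigned distance 0 with a warning.
#'
#' @param profile a branch profile from [branch_profile()].
#' @param alpha abundance-weighting exponent in \[0, 1\].
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
weighted_unifrac <- function(profile, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  P <- profile$proportions
  b <- profile$lengths
  n <- nrow(P)
  D <- matrix(0, n, n)
  degenerate <- FALSE
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    Pj <- P[js, , drop = FALSE]
    sumP <- sweep(Pj, 2L, P[i, ], "+")
    diffP <- abs(sweep(Pj, 2L, P[i, ], "-"))
    W <- if (alpha == 0) {
      (sumP > 0) + 0
    } else if (alpha == 0.5) {
      sqrt(sumP)
    } else {
      sumP^alpha
    }
    Wb <- sweep(W, 2L, b, "*")
    num <- rowSums(Wb * diffP)
    den <- rowSums(Wb)
    bad <- den == 0
    if (any(bad)) degenerate <- TRUE
    d <- ifelse(bad, 0, num / pmax(den, .Machine$double.xmin))
    D[i, js] <- d
    D[js, i] <- d
  }
  if (degenerate)
    warning("pair(s) with no shared nonzero branches; distance set to 0")
  .as_distmatrix(D, rownames(P))
}

#' Unweighted UniFrac distance matrix
#'
#' Presence/absence phylogenetic distance
#' \deqn{d_{ij} = \sum_l b_l |I(p_{il}>0) - I(p_{jl}>0)| / \sum_l b_l.}
#' Presence means descendant abundance strictly greater than zero; the
#' denominator is the total tree length.
#'
#' @inheritParams weighted_unifrac
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
unweighted_unifrac <- function(profile) {
  P <- profile$proportions
  b <- profile$lengths
  total <- sum(b)
  if (total <= 0) stop("total tree length is zero", call. = FALSE)
  Z <- (P > 0) + 0
  M <- (Z * rep(b, each = nrow(Z))) %*% t(1 - Z)
  D <- (M + t(M)) / total
  diag(D) <- 0
  .as_distmatrix(D, rownames(P))
}

#' Bray-Curtis distance matrix
#'
#' \deqn{d_{ij} = \sum_k |p_{ik}-p_{jk}| / \sum_k (p_{ik}+p_{jk}).}
#' On compositions the denominator equals 2, so this is half the L1 distance
#' between rows. Computed with [vegan::vegdist()].
#'
#' @param table relative-abundance matrix (rows are compositions).
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  .validate_abundance(table, normalized = TRUE)
  D <- as.matrix(vegan::vegdist(table, method = "bray"))
  .as_distmatrix(D, rownames(table))
}

#' Compute one of the supported distance matrices
#'
#' @param table relative-abundance matrix.
#' @param metric `"wuf"` (weighted UniFrac, d = 1), `"uuf"` (unweighted
#'   UniFrac, d = 2), or `"bc"` (Bray-Curtis, d = 3).
#' @param tree tree required for the UniFrac metrics.
#' @param alpha_unifrac weighting exponent for weighted UniFrac.
#' @param profile optional precomputed [branch_profile()] (avoids
#'   recomputation when several metrics share a tree).
#' @return symmetric n x n distance matrix.
#' @export
compute_distance <- function(table, metric = c("wuf", "uuf", "bc"),
                             tree = NULL, alpha_unifrac = 0.5,
                             profile = NULL) {
  metric <- match.arg(metric)
  if (metric == "bc") return(bray_curtis(table))
  if (is.null(profile)) {
    if (is.null(tree))
      stop("UniFrac distances require a phylogenetic tree", call. = FALSE)
    profile <- branch_profile(table, tree)
  }
  switch(metric,
         wuf = weighted_unifrac(profile, alpha = alpha_unifrac),
         uuf = unweighted_unifrac(profile))
}

.metric_id <- c(wuf = 1L, uuf = 2L, bc = 3L)
.metric_label <- c(wuf = "weighted UniFrac", uuf = "unweighted UniFrac",
                   bc = "Bray-Curtis")
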