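# Cauchy combination and the main ensemble test.

#' Cauchy combination of p-values
#'
#' Combines p-values with equal weights via
#' \deqn{T = \frac{1}{m}\sum_i \tan\{(0.5 - p_i)\pi\}, \quad
#'       P = 0.5 - \arctan(T)/\pi.}
#' Under the null T is standard Cauchy regardless of the dependence among
#' the inputs, so P is a valid p-value without any resampling. Tangents for
#' extreme p are evaluated through the stable identities
#' \eqn{\tan\{(0.5-p)\pi\} = 1/\tan(p\pi)} (small p) and
#' \eqn{-1/\tan((1-p)\pi)} (p near 1), and the arctangent is folded
#' symmetrically so tiny combined p-values keep full relative precision.
#'
#' @param pvals numeric vector of p-values, all strictly in (0, 1).
#' @return list with `statistic` (T) and `p_value` (P).
#' @export
cauchy_combine <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value list", call. = FALSE)
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals >= 1))
    stop("p-values must lie strictly in (0, 1)", call. = FALSE)
  tanvals <- ifelse(pvals < 0.5, 1 / tanpi(pvals),
             ifelse(pvals > 0.5, -1 / tanpi(1 - pvals), 0))
  T <- mean(tanvals)
  P <- if (T > 1) {
    atan(1 / T) / pi
  } else if (T < -1) {
    1 - atan(-1 / T) / pi
  } else {
    0.5 - atan(T) / pi
  }
  list(statistic = T, p_value = P)
}

#' Ensemble distance-based association test
#'
#' Tests the association between microbial community composition and the
#' variables of interest `x1`, adjusting for confounders `x2`. For every
#' combination of distance metric d and kernel exponent r, a base statistic
#' \eqn{T_{d,r} = \mathrm{tr}((H_X - H_{X_2})(K^*)^r)} is computed, its
#' permutation null is approximated analytically by matching the exact first
#' three permutation moments to a Pearson type III distribution, and the
#' resulting p-values are aggregated with the Cauchy combination method.
#' One eigendecomposition per distance is shared by all exponents. The
#' whole path is deterministic: repeated runs give identical results.
#'
#' Base tests whose permutation null is degenerate (zero variance, e.g. a
#' permutation-invariant kernel) are dropped from the combination with a
#' warning, and the equal weights are renormalized over the remaining tests.
#'
#' @param table relative-abundance matrix, samples in rows; rows must be
#'   compositions (see [normalize_abundance()] / [read_abundance_table()]).
#' @param x1 variables of interest: vector, matrix, or data.frame
#'   (categoricals are dummy-encoded); centered internally.
#' @param x2 confounders, same conventions, or NULL.
#' @param tree phylogenetic tree (`phylo`); required for the UniFrac
#'   metrics, may be NULL when `distances` is restricted to `"bc"`.
#' @param distances subset of `c("wuf", "uuf", "bc")` (weighted UniFrac,
#'   unweighted UniFrac, Bray-Curtis); duplicates are an error.
#' @param r positive kernel exponents; default is the recommended geometric
#'   grid `c(0.125, 0.25, 0.5, 1, 2)`. Values outside \[0.125, 2\] trigger a
#'   warning because the moment approximation degrades there. Duplicates are
#'   an error.
#' @param alpha_unifrac weighted-UniFrac abundance exponent, default 0.5.
#' @return an object of class `"emanova"`: a list with `statistic` (the
#'   Cauchy-combined ensemble statistic), `p_value`, `base` (a data.frame
#'   with one row per base test: distance, d, r, statistic, e1, var, e3,
#'   skewness, bhat, p_value, degenerate), `n`, `distances`, `r_set`,
#'   `n_dropped` (degenerate base tests removed), and `call`.
#' @examples
#' sim <- simulate_dataset(sim_config(n = 30, K = 40, beta = 1, seed = 1))
#' fit <- emanova(sim$table, x1 = sim$y, x2 = cbind(sim$x1, sim$x2),
#'                tree = sim$tree)
#' fit
#' @export
emanova <- function(table, x1, x2 = NULL, tree = NULL,
                    distances = if (is.null(tree)) "bc" else c("wuf", "uuf", "bc"),
                    r = c(0.125, 0.25, 0.5, 1, 2),
                    alpha_unifrac = 0.5) {
  cl <- match.call()
  .validate_abundance(table, normalized = TRUE)
  distances <- match.arg(distances, c("wuf", "uuf", "bc"), several.ok = TRUE)
  if (anyDuplicated(distances)) stop("duplicate distance metrics", call. = FALSE)
  if (anyDuplicated(r)) stop("duplicate kernel exponents", call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0)) stop("exponents must be positive")
  if (any(r < 0.125 | r > 2))
    warning("exponent(s) outside [0.125, 2] may cause approximation inaccuracy")
  if (any(distances %in% c("wuf", "uuf")) && is.null(tree))
    stop("UniFrac distances require a phylogenetic tree", call. = FALSE)

  x1m <- encode_design(as.data.frame(x1))
  x2m <- if (!is.null(x2)) encode_design(as.data.frame(x2)) else NULL
  if (nrow(x1m) != nrow(table))
    stop("x1 and table disagree on the number of samples")
  proj <- projection_matrices(x1m, x2m)
  if (proj$v == 0L)
    stop("degenerate design: x1 lies entirely in the span of x2", call. = FALSE)
  primG <- .moment_primitives(proj$G)

  profile <- if (any(distances %in% c("wuf", "uuf")))
    branch_profile(table, tree) else NULL

  rows <- vector("list", length(distances) * length(r))
  k <- 0L
  for (metric in distances) {
    D <- compute_distance(table, metric, tree = tree,
                          alpha_unifrac = alpha_unifrac, profile = profile)
    ck <- centered_kernel(D)
    for (rr in r) {
      k <- k + 1L
      rows[[k]] <- .base_test_row(proj$G, ck, metric, rr, primG = primG)
    }
  }
  base <- do.call(rbind, rows)
  usable <- !base$degenerate
  if (!all(usable))
    warning(sprintf("dropped %d degenerate base test(s) from the combination",
                    sum(!usable)))
  if (!any(usable))
    stop("all base tests are degenerate; no combination possible", call. = FALSE)
  comb <- cauchy_combine(base$p_value[usable])
  structure(list(statistic = comb$statistic, p_value = comb$p_value,
                 base = base, n = nrow(table), v = proj$v,
                 distances = distances, r_set = r,
                 alpha_unifrac = alpha_unifrac,
                 n_dropped = sum(!usable), call = cl),
            class = "emanova")
}

#' @export
print.emanova <- function(x, digits = 4, ...) {
  cat("Ensemble distance-based association test\n\n")
  cat(sprintf("  samples: %d | rank of tested contrast: %d\n", x$n, x$v))
  cat(sprintf("  distances: %s\n",
              paste(.metric_label[x$distances], collapse = ", ")))
  cat(sprintf("  kernel exponents: %s\n",
              paste(format(x$r_set, trim = TRUE), collapse = ", ")))
  if (x$n_dropped > 0L)
    cat(sprintf("  (%d degenerate base test(s) dropped)\n", x$n_dropped))
  cat(sprintf("\n  ensemble statistic: %s\n  ensemble p-value:  %s\n",
              format(x$statistic, digits = digits),
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}

#' @export
summary.emanova <- function(object, ...) {
  structure(object, class = c("summary.emanova", "emanova"))
}

#' @export
print.summary.emanova <- function(x, digits = 4, ...) {
  print.emanova(x, digits = digits)
  cat("\nBase tests:\n")
  b <- x$base
  out <- data.frame(distance = b$distance, r = b$r,
                    statistic = signif(b$statistic, digits),
                    skewness = signif(b$skewness, digits),
                    p_value = format.pval(b$p_value, digits = digits))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Plot base-test p-values of an ensemble fit
#'
#' Draws -log10 base-test p-values against the kernel exponent, one line per
#' distance metric, with the ensemble p-value as a horizontal reference.
#' Shows which spectral scale and which distance carry the association
#' signal.
#'
#' @param x an `emanova` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.emanova <- function(x, ...) {
  b <- x$base[!x$base$degenerate, ]
  rs <- sort(unique(b$r))
  mets <- unique(b$distance)
  M <- sapply(mets, function(m) {
    -log10(b$p_value[b$distance == m][order(b$r[b$distance == m])])
  })
  graphics::matplot(rs, M, type = "b", log = "x", pch = 19, lty = 1,
                    xlab = "kernel exponent r",
                    ylab = expression(-log[10](p)), ...)
  graphics::abline(h = -log10(x$p_value), lty = 2, col = "grey40")
  graphics::legend("topleft", legend = c(mets, "ensemble"),
                   col = c(seq_along(mets), "grey40"),
                   lty = c(rep(1, length(mets)), 2), pch = c(rep(19, length(mets)), NA),
                   bty = "n")
  invisible(x)
}
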