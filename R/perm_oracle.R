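# Permutation oracles: exhaustive enumeration and Monte Carlo references
# against which the analytic moments and Pearson type III p-values are
# validated.

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- cbind(i, sub + (sub >= i))
  do.call(rbind, out)
}

#' Exhaustive permutation moments of a trace statistic
#'
#' Averages \eqn{T(\pi) = \mathrm{tr}(G \Pi K \Pi^\top)}, its square, and
#' its cube over all n! simultaneous row/column permutations of the kernel.
#' Exact up to floating point; the normative reference for
#' [permutation_moments()]. Refuses n > 8.
#'
#' @param G,Kr symmetric matrices.
#' @return list with `e1`, `var`, `e3` (raw third moment).
#' @export
exhaustive_moments <- function(G, Kr) {
  n <- nrow(G)
  if (n > 8L) stop("exhaustive enumeration is limited to n <= 8", call. = FALSE)
  perms <- .all_permutations(n)
  Tv <- apply(perms, 1L, function(p) sum(G * Kr[p, p]))
  list(e1 = mean(Tv), var = mean(Tv^2) - mean(Tv)^2, e3 = mean(Tv^3))
}

#' Monte Carlo permutation p-value of a trace statistic
#'
#' Estimates the upper-tail permutation p-value of the observed statistic
#' \eqn{T = \mathrm{tr}(G K)} by sampling B random simultaneous row/column
#' permutations of the kernel while holding G fixed (the same scheme whose
#' moments the analytic path computes), using the add-one convention
#' \eqn{\hat p = (1 + \#\{T(\pi_b) \ge T\}) / (B + 1)}, which can never
#' return 0 and is bounded below by 1/(B+1).
#'
#' @param G,Kr symmetric matrices.
#' @param B number of permutations (at least 100).
#' @param seed integer seed.
#' @return list with `p` (the estimate), `B`, and `se` (binomial standard
#'   error).
#' @export
mc_permutation_pvalue <- function(G, Kr, B = 10000L, seed = 1L) {
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  n <- nrow(G)
  Tobs <- sum(G * Kr)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    p <- sample.int(n)
    if (sum(G * Kr[p, p]) >= Tobs) hits <- hits + 1L
  }
  phat <- (1 + hits) / (B + 1)
  list(p = phat, B = B, se = sqrt(phat * (1 - phat) / B))
}

#' Validation report: analytic path versus permutation references
#'
#' On a seeded synthetic dataset, compares for every (distance, exponent)
#' pair the analytic moments against Monte Carlo moment estimates and the
#' Pearson type III p-value against the add-one Monte Carlo permutation
#' p-value.
#'
#' @param n samples in the synthetic dataset.
#' @param K OTUs.
#' @param B Monte Carlo permutations.
#' @param seed integer seed.
#' @param distances,r grids passed to the analysis.
#' @return data.frame with one row per base test: analytic and Monte Carlo
#'   p-values, their deviation, and the Monte Carlo standard error.
#' @export
oracle_report <- function(n = 50, K = 80, B = 20000L, seed = 1L,
                          distances = c("wuf", "uuf", "bc"),
                          r = c(0.125, 0.25, 0.5, 1, 2)) {
  cfg <- sim_config(n = n, K = K, scenario = "S2", beta = 0, seed = seed)
  ds <- simulate_dataset(cfg)
  x1m <- encode_design(data.frame(y = ds$y))
  x2m <- encode_design(data.frame(X1 = ds$x1, X2 = ds$x2))
  proj <- projection_matrices(x1m, x2m)
  profile <- branch_profile(ds$table, ds$tree)
  rows <- list()
  for (metric in distances) {
    D <- compute_distance(ds$table, metric, tree = ds$tree, profile = profile)
    ck <- centered_kernel(D)
    for (rr in r) {
      row <- .base_test_row(proj$G, ck, metric, rr)
      Kr <- kernel_power(ck, rr)
      mc <- mc_permutation_pvalue(proj$G, Kr, B = B,
                                  seed = seed + 1000L * length(rows))
      rows[[length(rows) + 1L]] <-
        data.frame(distance = row$distance, r = rr,
                   p_analytic = row$p_value, p_mc = mc$p, se_mc = mc$se,
                   deviation = abs(row$p_value - mc$p),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
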