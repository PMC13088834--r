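# Synthetic microbiome data: sparse compositional tables on random
# phylogenies, outcome models, and replicate runners.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic benchmark. The
#' scenario fixes the link between the aggregate abundance of the associated
#' OTUs and the outcome, and how the associated set is chosen:
#' * S1 (linear, f(x) = x) and S3 (diminishing, f(x) = cube root of x):
#'   associated OTUs form phylogenetically coherent clusters;
#' * S2 (linear) and S4 (periodic, f(x) = sin x): associated OTUs are the
#'   most abundant ones, ignoring the tree.
#' `beta = 0` is the null of no association.
#'
#' @param n samples (default 100).
#' @param K OTUs (default 330).
#' @param scenario `"S1"`, `"S2"`, `"S3"`, or `"S4"`.
#' @param beta nonnegative effect size.
#' @param covariate_mode `"independent"` or `"correlated"`: whether the
#'   continuous confounder is generated independently of the community or
#'   correlated (rho) with the aggregate associated abundance.
#' @param outcome `"continuous"` or `"binary"`.
#' @param n_clusters phylogenetic clusters for S1/S3 (default 20).
#' @param assoc_frac target fraction of OTUs in the associated set
#'   (default 0.1).
#' @param rho correlation used in `covariate_mode = "correlated"`
#'   (default 0.5).
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth parameters
#'   (defaults log(5000) and 0.4).
#' @param theta total Dirichlet concentration controlling compositional
#'   overdispersion (default 50).
#' @param base_sdlog log-normal spread of the baseline rank-abundance
#'   profile (default 1.25).
#' @param zero_target calibration target for the fraction of zero entries
#'   (default 0.7).
#' @param seed integer seed; every randomness in the generator derives
#'   from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n = 100, K = 330, scenario = c("S1", "S2", "S3", "S4"),
                       beta = 0, covariate_mode = c("independent", "correlated"),
                       outcome = c("continuous", "binary"),
                       n_clusters = 20, assoc_frac = 0.1, rho = 0.5,
                       depth_meanlog = log(5000), depth_sdlog = 0.4,
                       theta = 50, base_sdlog = 1.25, zero_target = 0.7,
                       seed = 1) {
  scenario <- match.arg(scenario)
  covariate_mode <- match.arg(covariate_mode)
  outcome <- match.arg(outcome)
  if (n < 3 || K < 2) stop("need n >= 3 and K >= 2", call. = FALSE)
  if (beta < 0) stop("beta must be nonnegative", call. = FALSE)
  if (scenario %in% c("S1", "S3") && K < n_clusters)
    stop("K must be at least n_clusters for tree-based scenarios", call. = FALSE)
  link <- switch(scenario, S1 = "identity", S2 = "identity",
                 S3 = "cbrt", S4 = "sin")
  structure(list(n = n, K = K, scenario = scenario, beta = beta,
                 covariate_mode = covariate_mode, outcome = outcome,
                 link = link, n_clusters = n_clusters,
                 assoc_frac = assoc_frac, rho = rho,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 theta = theta, base_sdlog = base_sdlog,
                 zero_target = zero_target,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.link_fun <- function(link) {
  switch(link,
         identity = function(x) x,
         cbrt = function(x) sign(x) * abs(x)^(1 / 3),
         sin = function(x) sin(x))
}

#' Simulate a sparse compositional OTU table and a random phylogeny
#'
#' Draws a random coalescent tree on K leaves and generates counts from a
#' zero-inflated Dirichlet-multinomial: baseline OTU proportions are
#' log-normal (strongly skewed rank-abundance), per-sample compositions are
#' Dirichlet perturbations of the baseline, library sizes are log-normal,
#' and entry-level dropout is calibrated analytically so the expected
#' fraction of zero entries matches `zero_target` (each sample's dominant
#' entry is protected so no sample degenerates to all zeros). Rows of the
#' returned table are compositions. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `table` (n x K relative abundances) and `tree`
#'   (`phylo`, leaf labels matching the table's OTU ids).
#' @export
simulate_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n; K <- config$K
  tree <- ape::rcoal(K, tip.label = sprintf("OTU%03d", seq_len(K)))
  base <- exp(rnorm(K, 0, config$base_sdlog))
  base <- base / sum(base)
  depths <- pmax(100, round(rlnorm(n, config$depth_meanlog, config$depth_sdlog)))
  counts <- matrix(0L, n, K,
                   dimnames = list(sprintf("S%03d", seq_len(n)),
                                   tree$tip.label))
  alpha <- config$theta * base
  for (i in seq_len(n)) {
    g <- rgamma(K, shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(base)] <- 1
    counts[i, ] <- rmultinom(1L, depths[i], g / sum(g))[, 1L]
  }
  z0 <- mean(counts == 0)
  if (z0 < config$zero_target) {
    q <- (config$zero_target - z0) / (1 - z0)
    drop <- matrix(runif(n * K) < q, n, K)
    # never drop a sample's largest count: rows stay valid compositions
    drop[cbind(seq_len(n), max.col(counts, ties.method = "first"))] <- FALSE
    counts[drop] <- 0L
  }
  list(table = normalize_abundance(counts), tree = tree)
}

#' Select the outcome-associated OTU set
#'
#' For the tree-based scenarios (S1/S3) the OTUs are partitioned into
#' `n_clusters` groups by average-linkage hierarchical clustering of the
#' patristic (cophenetic) distance matrix, and randomly chosen clusters are
#' accumulated until the union covers at least `assoc_frac` of the OTUs.
#' For the abundance-based scenarios (S2/S4) the top `assoc_frac` fraction
#' of OTUs by mean relative abundance is selected.
#'
#' @param table relative-abundance matrix.
#' @param tree `phylo` tree (required for S1/S3).
#' @param scenario scenario string.
#' @param n_clusters number of phylogenetic clusters.
#' @param assoc_frac target fraction of associated OTUs.
#' @return integer vector of column indices (the set A).
#' @export
select_associated_otus <- function(table, tree, scenario,
                                   n_clusters = 20, assoc_frac = 0.1) {
  K <- ncol(table)
  target <- max(1L, ceiling(assoc_frac * K))
  if (scenario %in% c("S1", "S3")) {
    if (is.null(tree)) stop("tree required for scenarios S1/S3", call. = FALSE)
    pd <- as.dist(ape::cophenetic.phylo(tree))
    cl <- cutree(hclust(pd, method = "average"), k = n_clusters)
    cl <- cl[match(colnames(table), names(cl))]
    order_cl <- sample(n_clusters)
    A <- integer(0)
    for (cc in order_cl) {
      A <- c(A, which(cl == cc))
      if (length(A) >= target) break
    }
    if (length(A) == 0L) stop("empty cluster selection", call. = FALSE)
    sort(A)
  } else {
    mu <- colMeans(table)
    sort(order(mu, decreasing = TRUE)[seq_len(target)])
  }
}

.aggregate_signal <- function(table, A) {
  s <- rowSums(table[, A, drop = FALSE])
  sdv <- sd(s)
  if (sdv == 0) return(rep(0, length(s)))
  (s - mean(s)) / sdv
}

#' Simulate covariates and a continuous outcome
#'
#' \deqn{y_i = 0.5 X_{1i} + 0.5 X_{2i} + \beta f(\mathrm{scale}(\sum_{k \in A}
#' Z_{ik})) + \epsilon_i,} with standard normal noise, Bernoulli(0.5)
#' \eqn{X_1}, and \eqn{X_2} either standard normal (independent mode) or
#' correlated (rho) with the standardized aggregate abundance. The cube-root
#' link uses the real signed root.
#'
#' @param signal standardized aggregate abundance of the associated set.
#' @param config a [sim_config()].
#' @return list with `x1`, `x2`, `y`.
#' @export
simulate_outcome_continuous <- function(signal, config) {
  n <- length(signal)
  f <- .link_fun(config$link)
  x1 <- rbinom(n, 1L, 0.5)
  x2 <- if (config$covariate_mode == "correlated") {
    config$rho * signal + sqrt(1 - config$rho^2) * rnorm(n)
  } else {
    rnorm(n)
  }
  y <- 0.5 * x1 + 0.5 * x2 + config$beta * f(signal) + rnorm(n)
  list(x1 = x1, x2 = x2, y = y)
}

#' Simulate covariates and a binary outcome
#'
#' Logistic analogue of [simulate_outcome_continuous()]:
#' \eqn{\mathrm{logit}(p_i) = 0.5X_{1i} + 0.5X_{2i} + \beta f(\cdot)},
#' \eqn{y_i \sim \mathrm{Bernoulli}(p_i)}.
#'
#' @inheritParams simulate_outcome_continuous
#' @return list with `x1`, `x2`, `p` (success probabilities), `y`.
#' @export
simulate_outcome_binary <- function(signal, config) {
  n <- length(signal)
  f <- .link_fun(config$link)
  x1 <- rbinom(n, 1L, 0.5)
  x2 <- if (config$covariate_mode == "correlated") {
    config$rho * signal + sqrt(1 - config$rho^2) * rnorm(n)
  } else {
    rnorm(n)
  }
  eta <- 0.5 * x1 + 0.5 * x2 + config$beta * f(signal)
  p <- 1 / (1 + exp(-eta))
  list(x1 = x1, x2 = x2, p = p, y = rbinom(n, 1L, p))
}

#' Simulate one complete benchmark dataset
#'
#' Table and tree from [simulate_table()], associated set from
#' [select_associated_otus()], covariates and outcome from the scenario's
#' outcome model. Everything derives from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `table`, `tree`, `A`, `x1`, `x2`, `y` (and `p` for
#'   binary outcomes), plus the `config`.
#' @export
simulate_dataset <- function(config) {
  tt <- simulate_table(config)
  A <- select_associated_otus(tt$table, tt$tree, config$scenario,
                              config$n_clusters, config$assoc_frac)
  signal <- .aggregate_signal(tt$table, A)
  out <- if (config$outcome == "binary") {
    simulate_outcome_binary(signal, config)
  } else {
    simulate_outcome_continuous(signal, config)
  }
  c(list(table = tt$table, tree = tt$tree, A = A, signal = signal,
         config = config), out)
}

#' Replicate runner: type I error and power
#'
#' Runs the full ensemble test on `n_reps` independently simulated datasets
#' (per-replicate seeds derived from `config$seed`) and reports the
#' rejection rate at level `alpha` with its binomial standard error, plus
#' the per-replicate p-values. The variable of interest handed to the test
#' is the simulated outcome; the simulated covariates are adjusted for as
#' confounders.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicates.
#' @param alpha significance level (default 0.05).
#' @param distances,r passed to [emanova()].
#' @return list with `rejection_rate`, `se`, `alpha`, `n_reps`, `pvalues`.
#' @export
replicate_study <- function(config, n_reps, alpha = 0.05,
                            distances = c("wuf", "uuf", "bc"),
                            r = c(0.125, 0.25, 0.5, 1, 2)) {
  stopifnot(n_reps >= 1)
  pvals <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- (config$seed + 104729L * i) %% 2147483647L
    ds <- simulate_dataset(cfg)
    fit <- emanova(ds$table, x1 = ds$y, x2 = cbind(X1 = ds$x1, X2 = ds$x2),
                   tree = ds$tree, distances = distances, r = r)
    pvals[i] <- fit$p_value
  }
  rate <- mean(pvals <= alpha)
  list(rejection_rate = rate,
       se = sqrt(rate * (1 - rate) / n_reps),
       alpha = alpha, n_reps = n_reps, pvalues = pvals)
}
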