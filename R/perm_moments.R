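# Exact moments of the permutation null of trace statistics.
#
# For symmetric, double-centered n x n matrices A and B, the statistic
#   T(pi) = tr(A Pi B Pi^T) = sum_{i,j} A_{ij} B_{pi(i), pi(j)}
# has permutation moments E[T^m] that are finite linear combinations of
# joint "contraction" sums of A and B. Writing each m-fold product of matrix
# entries as a multigraph on index slots, the moment decomposes over the
# partition lattice of the 2m slots:
#
#   E[T^m] = sum_P  D_A(P) * D_B(P) / n_(b(P)),
#
# where D_X(P) is the sum of the entry products over index assignments that
# are constant on the blocks of P and *distinct* across blocks, b(P) is the
# number of blocks, and n_(k) is the falling factorial. D_X is recovered from
# the unconstrained block-sums M_X by Moebius inversion on the partition
# lattice. Double centering (zero row sums) makes every unconstrained
# contraction containing a degree-one vertex vanish, so each surviving M_X(P)
# is a product of a handful of cheap matrix invariants. The result is exact
# up to floating point; it is validated against exhaustive enumeration in the
# test suite (and see exhaustive_moments()).

# all set partitions of 1..k as canonical block-label vectors
.set_partitions <- function(k) {
  parts <- list(integer(0))
  for (i in seq_len(k)) {
    new <- vector("list", 0L)
    for (p in parts) {
      nb <- if (length(p)) max(p) else 0L
      for (b in seq_len(nb + 1L)) new[[length(new) + 1L]] <- c(p, b)
    }
    parts <- new
  }
  parts
}

.canon_partition <- function(p) match(p, unique(p))

# Decompose the contraction multigraph of a slot partition into connected
# components and name the invariant each contributes. NA marks a contraction
# that vanishes for double-centered input (some index appears only once).
.contraction_recipe <- function(p) {
  edges <- matrix(p, ncol = 2L, byrow = TRUE)
  nv <- max(p)
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (t in seq_len(nrow(edges))) {
    a <- find(edges[t, 1L]); b <- find(edges[t, 2L])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(nv), find, 1L)
  deg <- tabulate(c(edges), nbins = nv)
  if (any(deg == 1L)) return(NA_character_)
  prims <- character(0)
  for (cc in unique(comp)) {
    vs <- which(comp == cc)
    es <- edges[edges[, 1L] %in% vs | edges[, 2L] %in% vs, , drop = FALSE]
    nl <- sum(es[, 1L] == es[, 2L])
    ne <- nrow(es) - nl
    nvv <- length(vs)
    prim <-
      if (nl == 1L && ne == 0L) "tr1"        # sum_i X_ii
      else if (nl == 2L && ne == 0L) "d2"    # sum_i X_ii^2
      else if (nl == 3L && ne == 0L) "d3"    # sum_i X_ii^3
      else if (nl == 0L && ne == 2L) "f2"    # sum_ij X_ij^2
      else if (nl == 0L && ne == 3L && nvv == 2L) "f3"   # sum_ij X_ij^3
      else if (nl == 0L && ne == 3L && nvv == 3L) "tr3"  # tr(X^3)
      else if (nl == 1L && ne == 2L) "df"    # sum_ij X_ii X_ij^2
      else if (nl == 2L && ne == 1L) "dxd"   # sum_ij X_ii X_ij X_jj
      else stop("unclassified contraction component", call. = FALSE)
    prims <- c(prims, prim)
  }
  prims
}

# invariants consumed by the recipes above
.moment_primitives <- function(X) {
  d <- diag(X)
  X2 <- X * X
  c(tr1 = sum(d),
    d2 = sum(d^2),
    d3 = sum(d^3),
    f2 = sum(X2),
    f3 = sum(X2 * X),
    df = sum(d * rowSums(X2)),
    dxd = drop(crossprod(d, X %*% d)),
    tr3 = sum((X %*% X) * X))
}

# combinatorial structure for the m-th moment; independent of n and data
.moment_structure <- function(m) {
  key <- paste0("mstruct", m)
  if (!is.null(.emanova_env[[key]])) return(.emanova_env[[key]])
  parts <- lapply(.set_partitions(2L * m), .canon_partition)
  keys <- vapply(parts, paste, "", collapse = ".")
  recipes <- lapply(parts, .contraction_recipe)
  nblocks <- vapply(parts, max, 1L)
  coars <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    sigmas <- .set_partitions(nblocks[i])
    rows <- vapply(sigmas, function(sg) {
      q <- .canon_partition(sg[parts[[i]]])
      mu <- 1
      for (blk in unique(sg)) {
        sz <- sum(sg == blk)
        mu <- mu * (-1)^(sz - 1) * factorial(sz - 1)
      }
      c(match(paste(q, collapse = "."), keys), mu)
    }, c(idx = 0, mu = 0))
    coars[[i]] <- t(rows)
  }
  st <- list(recipes = recipes, nblocks = nblocks, coars = coars)
  .emanova_env[[key]] <- st
  st
}

.contraction_M <- function(struct, prim) {
  vapply(struct$recipes, function(r) {
    if (length(r) == 1L && is.na(r[1L])) 0 else prod(prim[r])
  }, 0)
}

.distinct_D <- function(struct, Mv) {
  vapply(struct$coars, function(co) sum(co[, "mu"] * Mv[co[, "idx"]]), 0)
}

.falling_factorial <- function(n, k) prod(n - seq_len(k) + 1)

.check_centered <- function(X, name) {
  if (!is.matrix(X) || nrow(X) != ncol(X))
    stop(name, " must be a square matrix", call. = FALSE)
  if (max(abs(X - t(X))) > 1e-8 * max(abs(X), 1e-300))
    stop(name, " must be symmetric", call. = FALSE)
  rs <- abs(rowSums(X))
  if (max(rs) > 1e-6 * max(abs(X), 1e-300))
    stop(name, " must be double-centered (zero row sums); ",
         "apply gower_center() first", call. = FALSE)
  invisible(TRUE)
}

# m-th raw permutation moment; expects primitives precomputed
.perm_raw_moment <- function(primA, primB, n, m) {
  st <- .moment_structure(m)
  keep <- st$nblocks <= n
  Da <- .distinct_D(st, .contraction_M(st, primA))
  Db <- .distinct_D(st, .contraction_M(st, primB))
  ffs <- vapply(st$nblocks, .falling_factorial, 0, n = n)
  sum((Da * Db / ffs)[keep])
}

#' Exact first three permutation moments of a trace statistic
#'
#' Computes, in closed form and without sampling, the mean, variance, and raw
#' third moment of \eqn{T(\pi) = \mathrm{tr}(G \Pi K \Pi^\top)} when the
#' permutation matrix \eqn{\Pi} is uniform over all \eqn{n!} simultaneous
#' row/column permutations of the kernel. Both inputs must be symmetric and
#' double-centered (zero row and column sums): the projection contrast `G`
#' from [projection_matrices()] and a centered kernel power from
#' [kernel_power()] satisfy this by construction.
#'
#' The computation is exact up to floating point; it agrees with exhaustive
#' enumeration over all permutations (see [exhaustive_moments()]) to relative
#' error below 1e-10 for any n.
#'
#' @param G symmetric double-centered matrix (projection contrast).
#' @param Kr symmetric double-centered matrix (powered kernel).
#' @return list with components `e1` (mean), `var` (variance), and `e3`
#'   (raw third moment \eqn{E[T^3]}).
#' @examples
#' n <- 6
#' H <- diag(n) - 1 / n
#' G <- H %*% tcrossprod(rnorm(n)) %*% H
#' K <- H %*% tcrossprod(matrix(rnorm(n * n), n)) %*% H
#' permutation_moments(G, K)
#' @export
permutation_moments <- function(G, Kr) {
  .check_centered(G, "G")
  .check_centered(Kr, "Kr")
  if (nrow(G) != nrow(Kr)) stop("G and Kr must have the same dimension")
  n <- nrow(G)
  pg <- .moment_primitives(G)
  pk <- .moment_primitives(Kr)
  e1 <- .perm_raw_moment(pg, pk, n, 1L)
  e2 <- .perm_raw_moment(pg, pk, n, 2L)
  e3 <- .perm_raw_moment(pg, pk, n, 3L)
  list(e1 = e1, var = max(e2 - e1^2, 0), e3 = e3)
}
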