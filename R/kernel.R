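# Distance -> similarity -> centered kernel -> PSD repair -> powers.

#' Similarity matrix from a distance matrix
#'
#' Applies the transformation \eqn{s_{ij} = -d_{ij}^2 / 2}, the standard
#' step turning squared dissimilarities into (un-centered) inner-product-like
#' similarities.
#'
#' @param D symmetric distance matrix.
#' @return symmetric similarity matrix with zero diagonal.
#' @export
similarity_from_distance <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  -0.5 * D * D
}

#' Gower double centering
#'
#' Computes \eqn{K = H S H} with \eqn{H = I_n - n^{-1} 1 1^\top}, so that K
#' has zero row and column sums. Idempotent: re-centering K returns K.
#'
#' @param S symmetric matrix.
#' @return centered matrix K.
#' @export
gower_center <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be square")
  n <- nrow(S)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  cm <- colMeans(S)
  K <- S - rep(cm, each = n)
  rm <- rowMeans(S) - mean(S)
  K <- K - rm
  # exact symmetrization guards against tiny asymmetric round-off
  (K + t(K)) / 2
}

#' Positive semi-definite repair of a centered kernel
#'
#' Eigendecomposes \eqn{K = U \Lambda U^\top} and reconstructs
#' \eqn{K^* = U |\Lambda| U^\top}, replacing every eigenvalue by its absolute
#' value. Microbiome distances (UniFrac, Bray-Curtis) routinely produce
#' indefinite centered kernels, and a PSD kernel is required before matrix
#' powering. Eigenvalues with \eqn{|\lambda| < 10^{-12} \max|\lambda|} are
#' zeroed so that fractional powers do not amplify numerical noise. Since
#' \eqn{|0| = 0}, the all-ones null vector of K is preserved: K* stays
#' double-centered.
#'
#' @param K symmetric centered matrix.
#' @return object of class `centered_kernel`: list with `values` (the
#'   repaired spectrum, descending), `vectors` (orthonormal U), `Kstar`
#'   (the repaired matrix), and `n`.
#' @export
psd_fix <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("K must be square")
  if (max(abs(K - t(K))) > 1e-8 * max(abs(K), 1e-300))
    stop("K must be symmetric", call. = FALSE)
  eig <- eigen(K, symmetric = TRUE)
  lam <- abs(eig$values)
  lam[lam < 1e-12 * max(lam, .Machine$double.xmin)] <- 0
  Kstar <- eig$vectors %*% (lam * t(eig$vectors))
  Kstar <- (Kstar + t(Kstar)) / 2
  structure(list(values = lam, vectors = eig$vectors, Kstar = Kstar,
                 n = nrow(K)),
            class = "centered_kernel")
}

#' Power of a PSD-repaired kernel
#'
#' Computes \eqn{(K^*)^r = U\, \mathrm{diag}(\lambda_i^r)\, U^\top} from the
#' stored spectrum, with \eqn{0^r} defined as 0. All powers reuse the single
#' eigendecomposition performed by [psd_fix()], so they are mutually
#' consistent. Raising the kernel to a power reweights its spectrum: r < 1
#' flattens the eigenvalue profile (up-weighting minor axes of variation),
#' r > 1 sharpens it (concentrating on the dominant axes).
#'
#' @param kernel a `centered_kernel` from [psd_fix()], or a symmetric PSD
#'   matrix (eigendecomposed on the fly).
#' @param r positive exponent.
#' @return symmetric PSD matrix \eqn{(K^*)^r} with zero row sums.
#' @export
kernel_power <- function(kernel, r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("r must be a single positive number", call. = FALSE)
  if (!inherits(kernel, "centered_kernel")) {
    if (!is.matrix(kernel)) stop("kernel must be a matrix or centered_kernel")
    kernel <- psd_fix(kernel)
  }
  lam <- kernel$values
  lr <- numeric(length(lam))
  pos <- lam > 0
  lr[pos] <- lam[pos]^r
  M <- kernel$vectors %*% (lr * t(kernel$vectors))
  (M + t(M)) / 2
}

#' Centered, PSD-repaired kernel from a distance matrix
#'
#' Convenience chain: distance -> similarity (\eqn{-d^2/2}) -> Gower
#' centering -> PSD repair.
#'
#' @param D symmetric distance matrix.
#' @return a `centered_kernel` (see [psd_fix()]).
#' @export
centered_kernel <- function(D) {
  psd_fix(gower_center(similarity_from_distance(D)))
}

#' @export
print.centered_kernel <- function(x, ...) {
  cat("Centered PSD-repaired kernel\n")
  cat("  n:", x$n, "\n")
  cat("  spectrum: max", format(max(x$values), digits = 4),
      "| nonzero", sum(x$values > 0), "of", x$n, "\n")
  invisible(x)
}
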