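# shared test utilities; all fixtures are generated in code

# random symmetric double-centered matrix
random_centered <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(rnorm(n * n), n)
  S <- S + t(S)
  H <- diag(n) - 1 / n
  K <- H %*% S %*% H
  (K + t(K)) / 2
}

# small labeled compositional table
random_table <- function(n, K, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n * K), n, K,
              dimnames = list(paste0("S", seq_len(n)), paste0("OTU", seq_len(K))))
  m / rowSums(m)
}

# tiny star tree over the given OTU names, unit branches
star_tree <- function(otus) {
  ape::read.tree(text = paste0("(", paste0(otus, ":1", collapse = ","), ");"))
}

centering_mat <- function(n) diag(n) - 1 / n
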