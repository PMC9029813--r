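# Independent brute-force oracles and small fixture builders shared by
# the test files. Oracles are deliberately written as literal loops,
# independent of the vectorized package code they check.

# Literal binary Tanimoto: shared on-bits / union of on-bits.
bf_binary_tanimoto <- function(a, b) {
  shared <- 0; on_a <- 0; on_b <- 0
  for (i in seq_along(a)) {
    if (a[i] > 0 && b[i] > 0) shared <- shared + 1
    if (a[i] > 0) on_a <- on_a + 1
    if (b[i] > 0) on_b <- on_b + 1
  }
  shared / (on_a + on_b - shared)
}

# Literal continuous Tanimoto, standard (minus) denominator.
bf_continuous_tanimoto <- function(a, b) {
  num <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    sa <- sa + a[i]^2
    sb <- sb + b[i]^2
  }
  num / (sa + sb - num)
}

# Literal evaluation of the concordance formulas: column rank totals,
# their mean, the squared-deviation sum, W = 12S / (m^2 (n^3 - n)).
bf_kendall_w <- function(recalls, offset = 0) {
  m <- nrow(recalls); n <- ncol(recalls)
  rk <- matrix(0, m, n)
  for (j in seq_len(m)) rk[j, ] <- rank(recalls[j, ]) + offset - 1
  R <- numeric(n)
  for (i in seq_len(n)) R[i] <- sum(rk[, i])
  R_bar <- sum(R) / n
  S <- 0
  for (i in seq_len(n)) S <- S + (R[i] - R_bar)^2
  12 * S / (m^2 * (n^3 - n))
}

# Random integer-count fingerprint dataset.
make_toy_dataset <- function(n = 8, f = 12, labels = NULL, seed = 1,
                             max_count = 5) {
  set.seed(seed)
  counts <- matrix(rpois(n * f, 1.2), n, f)
  counts[sample(length(counts), length(counts) %/% 3)] <- 0
  counts[rowSums(counts) == 0, 1] <- 1  # no all-zero molecules
  fingerprint_dataset(sprintf("m%02d", seq_len(n)),
                      labels %||% rep("A", n), counts)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Relative error between analytic and central finite-difference
# gradients, over every parameter of a model, on a fixed batch.
gradient_check <- function(model, X, eps = 1e-4) {
  loss_of <- function(m) aescreen:::ae_forward(m, X)$loss
  g <- ae_gradients(model, X)
  worst <- 0
  poke <- function(getter, setter, grad) {
    for (k in seq_along(grad)) {
      m1 <- setter(model, k, +eps); m2 <- setter(model, k, -eps)
      fd <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      an <- grad[k]
      rel <- abs(an - fd) / max(1e-8, abs(an) + abs(fd))
      worst <<- max(worst, rel)
    }
  }
  for (i in seq_along(model$W)) {
    poke(NULL, function(m, k, d) { m$W[[i]][k] <- m$W[[i]][k] + d; m },
         g$gW[[i]])
    poke(NULL, function(m, k, d) { m$b[[i]][k] <- m$b[[i]][k] + d; m },
         g$gb[[i]])
  }
  for (j in seq_along(model$b_dec)) {
    poke(NULL, function(m, k, d) { m$b_dec[[j]][k] <- m$b_dec[[j]][k] + d; m },
         g$gb_dec[[j]])
    if (!model$architecture$tied) {
      poke(NULL,
           function(m, k, d) { m$W_dec[[j]][k] <- m$W_dec[[j]][k] + d; m },
           g$gW_dec[[j]])
    }
  }
  worst
}

# Sampled variant for wider nets: checks a random subset of weights.
gradient_check_sampled <- function(model, X, n_sample = 25, seed = 1,
                                   eps = 1e-4) {
  loss_of <- function(m) aescreen:::ae_forward(m, X)$loss
  g <- ae_gradients(model, X)
  set.seed(seed)
  worst <- 0
  for (i in seq_along(model$W)) {
    ks <- sample(length(model$W[[i]]), min(n_sample, length(model$W[[i]])))
    for (k in ks) {
      m1 <- model; m1$W[[i]][k] <- m1$W[[i]][k] + eps
      m2 <- model; m2$W[[i]][k] <- m2$W[[i]][k] - eps
      fd <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      an <- g$gW[[i]][k]
      worst <- max(worst, abs(an - fd) / max(1e-8, abs(an) + abs(fd)))
    }
  }
  worst
}
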