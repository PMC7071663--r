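## random positive reciprocal matrix: consistent ratio structure from
## random weights, optionally perturbed multiplicatively on the upper
## triangle (reciprocity enforced by construction)
random_reciprocal <- function(n, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- rlnorm(n)
  a <- outer(w, w, "/")
  if (noise_sd > 0) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        a[i, j] <- a[i, j] * exp(rnorm(1, 0, noise_sd))
        a[j, i] <- 1 / a[i, j]
      }
    }
  }
  a
}

## independent dense-eigensolver oracle for AHP weights and lambda_max
eigen_oracle <- function(a) {
  e <- eigen(a)
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  list(weights = v, lambda_max = Re(e$values[k]))
}

## random nonnegative criteria matrix with coded rows/columns
random_criteria <- function(n, k = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rlnorm(n * k), nrow = n,
              dimnames = list(sprintf("i%02d", seq_len(n)),
                              sprintf("c%d", seq_len(k))))
  m
}
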