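# Brute-force reference implementations, independent of the package's
# vectorized code paths, plus small fixture builders.

oracle_range <- function(design, responses, direction = "benefit") {
  km <- matrix(NA_real_, ncol(design), 3L)
  for (j in seq_len(ncol(design))) {
    for (l in 1:3) {
      acc <- c()
      for (r in seq_len(nrow(design)))
        if (design[r, j] == l) acc <- c(acc, responses[r])
      km[j, l] <- sum(acc) / length(acc)
    }
  }
  R <- numeric(ncol(design))
  opt <- integer(ncol(design))
  for (j in seq_len(ncol(design))) {
    R[j] <- max(km[j, ]) - min(km[j, ])
    opt[j] <- if (direction == "benefit") which.max(km[j, ]) else which.min(km[j, ])
  }
  list(level_means = km, range = R, optimal = opt)
}

oracle_wdist <- function(row, ref, w) {
  s <- 0
  for (j in seq_along(row)) s <- s + w[j] * (ref[j] - row[j])^2
  sqrt(s)
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)  # average ranks for ties
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oracle_composite <- function(Z, H) {
  out <- numeric(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    s <- 0
    for (j in seq_len(ncol(Z))) s <- s + H[j] * Z[i, j]
    out[i] <- s
  }
  out
}

# Plain TOPSIS (no virtual ideals) on an already benefit-oriented raw matrix.
oracle_classical_topsis <- function(X, w) {
  Z <- sweep(X, 2L, sqrt(colSums(X^2)), "/")
  zp <- apply(Z, 2L, max); zm <- apply(Z, 2L, min)
  dp <- apply(Z, 1L, function(r) sqrt(sum(w * (zp - r)^2)))
  dm <- apply(Z, 1L, function(r) sqrt(sum(w * (zm - r)^2)))
  dm / (dp + dm)
}

random_matrix <- function(n, m, min = 1, max = 10) {
  matrix(runif(n * m, min, max), n, m,
         dimnames = list(paste0("T", seq_len(n)), paste0("I", seq_len(m))))
}

# Random entropy vector with entries strictly inside [0, 1].
random_entropies <- function(m) runif(m, 0.01, 0.99)

write_treatment_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "treatments.csv")
  writeLines(lines, path)
  path
}
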