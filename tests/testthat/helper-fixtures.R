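# Shared fixtures: small grids and random spectrum sets built in code.

small_grid <- function(n_bands = 11) wavelength_grid(450, 450 + n_bands - 1, 1)

random_set <- function(n = 5, n_bands = 11, seed = 1, labels = NULL) {
  set.seed(seed)
  vals <- matrix(runif(n * n_bands, 0.2, 0.9), n, n_bands)
  spectrum_set(vals, small_grid(n_bands), labels = labels)
}

# Brute-force Savitzky-Golay: least-squares polynomial over each window,
# terminal windows evaluated at the edge positions.
sg_oracle_matrix <- function(len, window, polyorder) {
  half <- (window - 1) / 2
  S <- matrix(0, len, len)
  fit_row <- function(idx, at) {
    V <- outer(idx - mean(idx), 0:polyorder, `^`)
    a <- outer(at - mean(idx), 0:polyorder, `^`)
    as.numeric(a %*% solve(crossprod(V), t(V)))
  }
  for (i in seq_len(len)) {
    idx <- if (i <= half) 1:window
    else if (i > len - half) (len - window + 1):len
    else (i - half):(i + half)
    S[i, idx] <- fit_row(idx, i)
  }
  S
}

# Exhaustive projection recursion: at each step regress every remaining
# column on the span of the selected ones and take the largest residual.
spa_oracle_chain <- function(Xc, start, size) {
  chain <- start
  for (m in seq_len(size - 1)) {
    sel <- Xc[, chain, drop = FALSE]
    Q <- qr.Q(qr(sel))
    norms <- vapply(seq_len(ncol(Xc)), function(j) {
      r <- Xc[, j] - Q %*% crossprod(Q, Xc[, j])
      sum(r^2)
    }, numeric(1))
    norms[chain] <- -Inf
    norms[norms < 1e-20] <- -Inf
    if (all(!is.finite(norms))) break
    chain <- c(chain, which.max(norms))
  }
  chain
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
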