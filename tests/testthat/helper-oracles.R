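# Naive O(N^2) reference implementations of the three entropies, kept as
# the arbiter for the compiled fast paths. Direct enumeration of every
# template pair, written independently of the package internals.

cheb_dist <- function(a, b) max(abs(a - b))

apen_oracle <- function(x, m, r_abs) {
  N <- length(x)
  phi <- numeric(2)
  for (s in 0:1) {
    mm <- m + s
    nt <- N - mm + 1L
    templ <- t(vapply(seq_len(nt), function(i) x[i:(i + mm - 1L)],
                      numeric(mm)))
    logs <- numeric(nt)
    for (i in seq_len(nt)) {
      d <- apply(abs(sweep(templ, 2L, templ[i, ])), 1L, max)
      cnt <- if (r_abs > 0) sum(d <= r_abs) else sum(d == 0)
      logs[i] <- log(cnt / nt)
    }
    phi[s + 1L] <- mean(logs)
  }
  phi[1L] - phi[2L]
}

sampen_oracle_counts <- function(x, m, r_abs) {
  N <- length(x)
  nt <- N - m # same template count at both dimensions
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dm <- cheb_dist(x[i:(i + m - 1L)], x[j:(j + m - 1L)])
      ok_m <- if (r_abs > 0) dm <= r_abs else dm == 0
      if (ok_m) {
        B <- B + 1L
        dm1 <- max(dm, abs(x[i + m] - x[j + m]))
        ok_m1 <- if (r_abs > 0) dm1 <= r_abs else dm1 == 0
        if (ok_m1) A <- A + 1L
      }
    }
  }
  c(B = B, A = A)
}

sampen_oracle <- function(x, m, r_abs) {
  cnt <- sampen_oracle_counts(x, m, r_abs)
  -log(cnt[["A"]] / cnt[["B"]])
}

fuzzyen_oracle <- function(x, m, r_abs, n_exp) {
  N <- length(x)
  nt <- N - m
  phi <- numeric(2)
  for (s in 0:1) {
    mm <- m + s
    templ <- t(vapply(seq_len(nt), function(i) {
      v <- x[i:(i + mm - 1L)]
      v - mean(v)
    }, numeric(mm)))
    acc <- 0
    for (i in seq_len(nt - 1L)) {
      for (j in (i + 1L):nt) {
        d <- cheb_dist(templ[i, ], templ[j, ])
        acc <- acc + if (r_abs > 0) exp(-(d / r_abs)^n_exp) else (d == 0)
      }
    }
    phi[s + 1L] <- 2 * acc / (nt * (nt - 1))
  }
  log(phi[1L]) - log(phi[2L])
}

# naive first-layer convolution: cross-correlation + bias, explicit loops
conv1_oracle <- function(X, W1, b1) {
  B <- nrow(X); K <- nrow(W1); F1 <- ncol(W1)
  L1 <- ncol(X) - K + 1L
  Z <- array(0, c(B, L1, F1))
  for (b in seq_len(B)) {
    for (i in seq_len(L1)) {
      for (f in seq_len(F1)) {
        acc <- 0
        for (d in seq_len(K)) acc <- acc + X[b, i + d - 1L] * W1[d, f]
        Z[b, i, f] <- acc + b1[f]
      }
    }
  }
  Z
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
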