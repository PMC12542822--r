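# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they validate.

# Benjamini-Hochberg step-up, written directly from the definition:
# sort ascending, q_(i) = min_{j >= i} min(1, p_(j) * m / j).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  q <- pmin(1, po * m / seq_len(m))
  for (i in seq(m - 1L, 1L, length.out = max(0L, m - 1L)))
    q[i] <- min(q[i], q[i + 1L])
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper-tail hypergeometric P(X >= k) by combinatorial enumeration.
hyper_oracle <- function(k, K, N, n) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Greedy minimum-variance (Ward) agglomeration using the closed-form
# merge cost sqrt(2 nA nB / (nA + nB) * ||centroid_A - centroid_B||^2),
# independent of the Lance-Williams recurrence.
ward_oracle_heights <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  cost <- function(a, b) {
    ca <- colMeans(x[a, , drop = FALSE])
    cb <- colMeans(x[b, , drop = FALSE])
    sqrt(2 * length(a) * length(b) / (length(a) + length(b)) *
           sum((ca - cb)^2))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in seq.int(i + 1L, length(clusters))) {
        h <- cost(clusters[[i]], clusters[[j]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# Direct frequency / KL computation of the scaled enrichment logo.
motif_oracle <- function(fg, bg, pseudocount) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  width <- nchar(fg[1])
  ic <- matrix(0, width, 20, dimnames = list(NULL, aa))
  for (pos in seq_len(width)) {
    fgc <- substring(fg, pos, pos)
    bgc <- substring(bg, pos, pos)
    fgc <- fgc[fgc %in% aa]
    bgc <- bgc[bgc %in% aa]
    for (a in aa) {
      f <- (sum(fgc == a) + pseudocount) / (length(fgc) + 20 * pseudocount)
      b <- (sum(bgc == a) + pseudocount) / (length(bgc) + 20 * pseudocount)
      if (f > 0 && b == 0) b <- 1 / (length(bgc) + 20)
      v <- if (f > 0) f * log2(f / b) else 0
      ic[pos, a] <- min(max(v, 0) / log2(20), 1)
    }
  }
  ic
}

# Prior hyperparameters by direct evaluation of the two moment equations,
# inverting the trigamma equation with uniroot instead of Newton.
prior_oracle <- function(s2, d) {
  if (length(d) == 1L) d <- rep(d, length(s2))
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  rhs <- var(e) - mean(trigamma(d / 2))
  if (rhs <= 0) return(list(d0 = Inf, s0_sq = exp(mean(e))))
  half_d0 <- uniroot(function(x) trigamma(x) - rhs,
                     lower = 1e-6, upper = 1e8, tol = 1e-12)$root
  list(d0 = 2 * half_d0,
       s0_sq = exp(mean(e) + digamma(half_d0) - log(half_d0)))
}
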