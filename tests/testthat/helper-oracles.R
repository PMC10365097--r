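# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: normal equations instead of gradient
# descent, direct formula evaluation instead of chow_test, raw combinatorics
# instead of the distribution functions.

# closed-form OLS via the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  w <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% w
  list(coefficients = as.numeric(w), rss = sum(r^2))
}

# generalized Chow F and p from separately refit models, straight from the
# definition
oracle_chow <- function(x, y, groups) {
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  G <- length(labs)
  k <- 2
  S_g <- 0; N <- 0
  for (g in labs) {
    idx <- groups == g
    S_g <- S_g + oracle_ols(x[idx], y[idx])$rss
    N <- N + sum(idx)
  }
  S_c <- oracle_ols(x, y)$rss
  f <- ((S_c - S_g) / ((G - 1) * k)) / (S_g / (N - G * k))
  list(f = f, p = pf(f, (G - 1) * k, N - G * k, lower.tail = FALSE),
       df = c((G - 1) * k, N - G * k))
}

# hypergeometric PMF by raw combinatorics (exact choose(), no dhyper)
oracle_hyper_pmf <- function(M, n, N) {
  ks <- max(0, N - (M - n)):min(n, N)
  p <- choose(n, ks) * choose(M - n, N - ks) / choose(M, N)
  list(k = ks, p = p)
}

# centralized least-squares gradient
oracle_gradient <- function(w, x, y) {
  X <- cbind(1, x)
  as.numeric(crossprod(X, X %*% w - y))
}

# HWE conditional distribution by direct enumeration and normalization
# (choose products; no lfactorial trick, no allele-count closed form)
oracle_hwe <- function(aa, ab, bb) {
  n <- aa + ab + bb
  nA <- 2 * aa + ab
  hets <- 0:n
  weight <- vapply(hets, function(h) {
    homA <- (nA - h) / 2
    homB <- n - h - homA
    if (homA < 0 || homB < 0 || homA != round(homA)) return(0)
    choose(n, h) * choose(n - h, homA) * 2^h
  }, 0)
  pr <- weight / sum(weight)
  obs <- pr[ab + 1]
  sum(pr[pr <= obs + 1e-12])
}

# Benjamini-Hochberg step-up by the definitional min over tail ratios
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)  # rank of p[i]
    q[i] <- min(1, min(p[o][j:m] * m / (j:m)))
  }
  q
}
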