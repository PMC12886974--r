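# independent oracles, kept free of the implementation paths they check

# colocalization by explicit configuration enumeration: every placement of
# the causal variant(s), weighted by per-variant priors
coloc_enumerate <- function(bf1, bf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  n <- length(bf1)
  w <- c(h0 = 1,
         h1 = sum(p1 * bf1),
         h2 = sum(p2 * bf2),
         h3 = { s <- 0
           for (i in seq_len(n)) for (j in seq_len(n))
             if (i != j) s <- s + p1 * p2 * bf1[i] * bf2[j]
           s },
         h4 = sum(p12 * bf1 * bf2))
  w / sum(w)
}

# Firth penalized log-likelihood, evaluated directly
firth_pll_oracle <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  pr <- plogis(eta)
  info <- crossprod(X * sqrt(pr * (1 - pr)))
  sum(y * eta - log1p(exp(eta))) +
    0.5 * determinant(info, logarithm = TRUE)$modulus[1]
}

# numeric maximizer of the Firth penalized likelihood
firth_optim_oracle <- function(X, y) {
  p <- ncol(X)
  optim(rep(0, p), function(b) -firth_pll_oracle(b, X, y),
        method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))$par
}

# greedy LD pruning reference: priority order given explicitly
prune_oracle <- function(ids, r2, order_idx, r2_max) {
  kept <- integer(0)
  for (i in order_idx) {
    if (all(r2[i, kept] < r2_max)) kept <- c(kept, i)
  }
  ids[sort(kept)]
}
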