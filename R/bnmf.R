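# Bayesian NMF with automatic relevance determination (ARD).
#
# Gaussian likelihood, half-normal column priors on both factors sharing a
# per-component relevance lambda_k with an inverse-gamma hyperprior.
# MAP estimation by multiplicative updates; components whose relevance
# collapses are pruned, giving an automatic effective rank.

ard_nmf_once <- function(A, k_max, max_iter = 3000, tol = 1e-10,
                         a_hyper = 2, seed = 1) {
  set.seed(seed)
  M <- nrow(A); N <- ncol(A)
  scale0 <- sqrt(mean(A) / k_max)
  W <- matrix(stats::runif(M * k_max, 0.5, 1.5) * scale0, M, k_max)
  H <- matrix(stats::runif(k_max * N, 0.5, 1.5) * scale0, k_max, N)
  # b chosen so the prior relevance scale matches the data scale
  b_hyper <- mean(A^2) / k_max
  c_hyper <- (M + N) / 2 + a_hyper + 1
  eps <- .Machine$double.eps
  # the noise variance is floored during the ARD phase: otherwise a
  # superfluous-rank exact fit drives it to zero, the penalty vanishes and
  # no component is ever pruned
  sigma2_floor <- 1e-2 * mean(A^2)
  obj_old <- Inf
  for (iter in seq_len(max_iter)) {
    R <- W %*% H
    sigma2 <- max(mean((A - R)^2), sigma2_floor)
    lambda <- (0.5 * colSums(W^2) + 0.5 * rowSums(H^2) + b_hyper) / c_hyper
    W <- W * (A %*% t(H)) /
      (R %*% t(H) + sigma2 * sweep(W, 2, lambda, "/") + eps)
    R <- W %*% H
    H <- H * (t(W) %*% A) /
      (t(W) %*% R + sigma2 * H / lambda + eps)
    obj <- sum((A - W %*% H)^2) +
      sigma2 * sum((0.5 * colSums(W^2) + 0.5 * rowSums(H^2)) / lambda)
    if (abs(obj_old - obj) < tol * (obj + eps)) break
    obj_old <- obj
  }
  relevance <- colSums(W^2) + rowSums(H^2)
  keep <- relevance > 1e-3 * max(relevance)
  W <- W[, keep, drop = FALSE]
  H <- H[keep, , drop = FALSE]
  # polish: unpenalized multiplicative updates on the retained components
  for (iter in seq_len(500)) {
    W <- W * (A %*% t(H)) / (W %*% H %*% t(H) + eps)
    H <- H * (t(W) %*% A) / (t(W) %*% W %*% H + eps)
  }
  list(W = W, H = H,
       relevance = relevance[keep], effective_rank = sum(keep),
       rss = sum((A - W %*% H)^2))
}

#' Soft clustering by Bayesian non-negative matrix factorization
#'
#' Embeds the signed z-score matrix in a nonnegative space by column
#' doubling (each trait column t becomes a positive part max(z, 0) and a
#' negative part max(-z, 0)), then factorizes it with ARD Bayesian NMF from
#' `n_restarts` seeded initializations. The number of components K is the
#' modal effective rank across restarts; the returned factors come from the
#' best-fitting restart attaining that rank. Variant weights are
#' row-normalized for assignment under the weight > 0.75 rule (see
#' [soft_assignment()]).
#'
#' @param matrix `zmatrix` or numeric matrix (variants x traits).
#' @param k_max maximum number of components offered to the model.
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @return list with `k`, `variant_weights` (variants x K, row-normalized),
#'   `variant_weights_raw`, `trait_weights` (traits x K, positive and
#'   negative halves summed), `trait_weights_signed` (2T x K), `ranks`
#'   (per-restart effective ranks), `rss`.
#' @export
bnmf_soft_cluster <- function(matrix, k_max = 8L, n_restarts = 10L,
                              seed = 1L) {
  if (k_max < 1) stop("k_max must be >= 1")
  z <- if (inherits(matrix, "zmatrix")) matrix$z else as.matrix(matrix)
  if (any(!is.finite(z))) stop("matrix must be finite")
  A <- cbind(pmax(z, 0), pmax(-z, 0))
  colnames(A) <- c(paste0(colnames(z), "_pos"), paste0(colnames(z), "_neg"))
  fits <- lapply(seq_len(n_restarts), function(r) {
    ard_nmf_once(A, k_max, seed = seed + r)
  })
  ranks <- vapply(fits, `[[`, integer(1), "effective_rank")
  k <- as.integer(names(which.max(table(ranks))))
  cand <- fits[ranks == k]
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "rss"))]]
  W <- best$W
  rownames(W) <- rownames(z)
  colnames(W) <- paste0("k", seq_len(ncol(W)))
  H <- best$H
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(A)
  Tn <- ncol(z)
  trait_w <- t(H[, seq_len(Tn), drop = FALSE] +
                 H[, Tn + seq_len(Tn), drop = FALSE])
  rownames(trait_w) <- colnames(z)
  rs <- rowSums(W)
  Wn <- W / ifelse(rs == 0, 1, rs)
  list(k = k, variant_weights = Wn, variant_weights_raw = W,
       trait_weights = trait_w, trait_weights_signed = t(H),
       ranks = ranks, rss = best$rss)
}
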