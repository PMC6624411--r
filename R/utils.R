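# Shared internal numerics: companion-form algebra, lagged design
# matrices, seeded RNG helpers, and permutation matching of state labels.

#' Companion matrix of a lagged coefficient array
#'
#' Stacks an `order x D x D` coefficient array into the `(order*D) x
#' (order*D)` companion form whose spectral radius decides stability of
#' the AR process.
#'
#' @param A numeric array `order x D x D`.
#' @return the companion matrix.
#' @export
companionMatrix <- function(A) {
  P <- dim(A)[1L]; D <- dim(A)[2L]
  C <- matrix(0, P * D, P * D)
  for (tau in seq_len(P))
    C[seq_len(D), (tau - 1L) * D + seq_len(D)] <- matrix(A[tau, , ], D, D)
  if (P > 1L)
    C[D + seq_len((P - 1L) * D), seq_len((P - 1L) * D)] <-
      diag((P - 1L) * D)
  C
}

#' Spectral radius of the companion matrix of an AR coefficient array
#'
#' @param A numeric array `order x D x D`.
#' @return largest eigenvalue modulus; `< 1` means the process is stable.
#' @export
spectralRadius <- function(A) {
  max(Mod(eigen(companionMatrix(A), only.values = TRUE)$values))
}

# Stationary covariance of the companion-form state s_t = C s_{t-1} + w,
# w ~ N(0, S) with S = blockdiag(Q, 0, ...). Solves the discrete
# Lyapunov equation Sigma = C Sigma C' + S by vectorization.
.stationaryCompanionCov <- function(A, Q) {
  C <- companionMatrix(A)
  m <- nrow(C); D <- dim(A)[2L]
  S <- matrix(0, m, m)
  S[seq_len(D), seq_len(D)] <- Q
  M <- diag(m * m) - kronecker(C, C)
  Sigma <- matrix(solve(M, as.vector(S)), m, m)
  (Sigma + t(Sigma)) / 2
}

# Stationary mean of x_t = sum A_tau x_{t-tau} + mu.
.stationaryMean <- function(A, mu) {
  D <- dim(A)[2L]
  Asum <- matrix(0, D, D)
  for (tau in seq_len(dim(A)[1L]))
    Asum <- Asum + matrix(A[tau, , ], D, D)
  solve(diag(D) - Asum, mu)
}

# Lagged regression design for one trial: X is D x T; returns response
# rows t = P+1..T and predictors [x_{t-1}', ..., x_{t-P}', 1].
.lagDesign <- function(X, P) {
  D <- nrow(X); T <- ncol(X)
  n <- T - P
  Y <- t(X[, (P + 1L):T, drop = FALSE])
  Z <- matrix(1, n, P * D + 1L)
  for (tau in seq_len(P))
    Z[, (tau - 1L) * D + seq_len(D)] <-
      t(X[, (P + 1L - tau):(T - tau), drop = FALSE])
  list(Y = Y, Z = Z)
}

# Coefficient-matrix <-> (A, mu) packing. B is (P*D+1) x D with block tau
# equal to t(A_tau) and last row mu'.
.unpackB <- function(B, P, D) {
  A <- array(0, c(P, D, D))
  for (tau in seq_len(P))
    A[tau, , ] <- t(B[(tau - 1L) * D + seq_len(D), , drop = FALSE])
  list(A = A, mu = as.numeric(B[P * D + 1L, ]))
}

.packB <- function(A, mu) {
  P <- dim(A)[1L]; D <- dim(A)[2L]
  B <- matrix(0, P * D + 1L, D)
  for (tau in seq_len(P))
    B[(tau - 1L) * D + seq_len(D), ] <- t(matrix(A[tau, , ], D, D))
  B[P * D + 1L, ] <- mu
  B
}

#' Derive a child seed for a named stage
#'
#' One global seed fans out deterministically to per-stage seeds so each
#' stage is independently reproducible.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% (2^31 - 1))
}

# Run expr under a temporary seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  blocks <- lapply(seq_len(k), function(pos)
    cbind(sub[, seq_len(pos - 1L), drop = FALSE],
          k,
          sub[, seq_len(k - pos) + (pos - 1L), drop = FALSE]))
  do.call(rbind, blocks)
}

#' Best-permutation matching of estimated to true state labels
#'
#' State labels of a fitted model are arbitrary; this finds the
#' permutation of estimated labels that maximizes per-sample agreement
#' with a reference labeling (exact search over all `K!` permutations,
#' equivalent to the optimal assignment for this cost).
#'
#' @param estimated list or vector of integer state labels.
#' @param reference matching list or vector of integer reference labels.
#' @param k number of states (default: max label observed).
#' @return list with `perm` (index `z` of `perm[z]` is the reference label
#'   assigned to estimated label `z`), `accuracy` (fraction of samples
#'   agreeing after relabeling), and `relabeled` (the relabeled estimate,
#'   same shape as `estimated`).
#' @export
matchStates <- function(estimated, reference, k = NULL) {
  est <- if (is.list(estimated)) unlist(estimated) else estimated
  ref <- if (is.list(reference)) unlist(reference) else reference
  stopifnot(length(est) == length(ref))
  if (is.null(k)) k <- max(est, ref)
  perms <- .permutations(k)
  conf <- matrix(0, k, k)
  for (z in seq_len(k)) for (r in seq_len(k))
    conf[z, r] <- sum(est == z & ref == r)
  scores <- apply(perms, 1L, function(p)
    sum(conf[cbind(seq_len(k), p)]))
  best <- perms[which.max(scores), ]
  relab <- if (is.list(estimated))
    lapply(estimated, function(v) best[v]) else best[estimated]
  list(perm = best, accuracy = max(scores) / length(est),
       relabeled = relab)
}

# Permute the state axes of an ARHMMParams: state z of the result is
# state perm-inverse(z)... concretely newParams state r equals old state z
# where perm[z] = r.
.permuteParams <- function(params, perm) {
  K <- nStates(params)
  inv <- order(perm)
  A <- params@A[inv, , , , drop = FALSE]
  Q <- params@Q[inv, , , drop = FALSE]
  mu <- params@mu[inv, , drop = FALSE]
  trans <- params@trans[inv, inv, drop = FALSE]
  new("ARHMMParams", A = A, Q = Q, mu = mu, trans = trans,
      initDist = params@initDist[inv])
}
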