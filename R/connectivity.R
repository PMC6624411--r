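# Frequency-domain directed influence per state: partial directed
# coherence (PDC) from the state's MVAR coefficients, band integration,
# the cross-state dissimilarity score, and edge-list export.

#' MVAR transfer matrix at one frequency
#'
#' `Abar_jk(f) = delta_jk - sum_tau A[tau,j,k] exp(-2 pi i f tau)` with
#' `f` a normalized frequency in cycles per sample.
#'
#' @param A coefficient array `order x D x D`.
#' @param f normalized frequency in `[0, 0.5]`.
#' @return a `D x D` complex matrix.
#' @export
transferMatrix <- function(A, f) {
  stopifnot(f >= 0, f <= 0.5)
  D <- dim(A)[2L]
  out <- diag(D) + 0i
  for (tau in seq_len(dim(A)[1L]))
    out <- out - matrix(A[tau, , ], D, D) * exp(-2i * pi * f * tau)
  out
}

#' Partial directed coherence spectrum of one state's dynamics
#'
#' Column-normalized transfer matrix: `pi_jk(f) = Abar_jk(f) /
#' ||Abar_.k(f)||`, so that `sum_j |pi_jk(f)|^2 = 1` for every source
#' channel `k` and frequency. `|pi_jk|` measures the Granger-causal
#' outflow from channel `k` to channel `j` as a fraction of `k`'s total
#' outflow.
#'
#' @param A coefficient array `order x D x D`, or an
#'   [ARHMMParams-class] with `state`.
#' @param freqs frequency grid in Hz within `[0, rate/2]`; default 256
#'   evenly spaced points over the full range.
#' @param rate sampling rate in Hz (default 200).
#' @param state state index when `A` is an `ARHMMParams`.
#' @return a [PDCSpectrum-class].
#' @export
pdc <- function(A, freqs = NULL, rate = 200, state = 1L) {
  if (is(A, "ARHMMParams")) A <- arCoefficients(A, state)
  if (is.null(freqs)) freqs <- seq(0, rate / 2, length.out = 256L)
  if (any(freqs < 0 | freqs > rate / 2))
    stop("frequency grid must lie within [0, rate/2]")
  D <- dim(A)[2L]
  vals <- array(0i, c(length(freqs), D, D))
  for (fi in seq_along(freqs)) {
    Abar <- transferMatrix(A, freqs[fi] / rate)
    nrm <- sqrt(colSums(Mod(Abar)^2))
    if (any(nrm < 1e-300))
      stop("degenerate transfer-matrix column at f = ", freqs[fi], " Hz")
    vals[fi, , ] <- sweep(Abar, 2L, nrm, "/")
  }
  new("PDCSpectrum", freqs = freqs, values = vals, rate = rate)
}

#' Integrate PDC magnitude over a frequency band
#'
#' Trapezoidal integral of `|pi_jk(f)|` over the band, per directed edge.
#'
#' @param spec a [PDCSpectrum-class].
#' @param band length-2 numeric band in Hz; default the full grid.
#' @return an [IntegratedPDC-class].
#' @export
integratePDC <- function(spec, band = NULL) {
  stopifnot(is(spec, "PDCSpectrum"))
  if (is.null(band)) band <- range(spec@freqs)
  sel <- spec@freqs >= band[1L] & spec@freqs <= band[2L]
  if (sum(sel) < 2L) stop("band must contain at least two grid points")
  f <- spec@freqs[sel]
  D <- dim(spec@values)[2L]
  M <- matrix(0, D, D)
  for (j in seq_len(D)) for (k in seq_len(D))
    M[j, k] <- pracma::trapz(f, Mod(spec@values[sel, j, k]))
  new("IntegratedPDC", matrix = M, band = as.numeric(band))
}

#' Dissimilarity between two directed-network fingerprints
#'
#' Frobenius distance between the Frobenius-normalized matrices:
#' `d(P, R) = || P/||P||_F - R/||R||_F ||_F`. Scale-invariant, symmetric,
#' zero iff the normalized patterns coincide, with maximum 2 at
#' antipodal patterns.
#'
#' @param P,R [IntegratedPDC-class] objects or plain matrices of equal
#'   dimension.
#' @return the dissimilarity in `[0, 2]`.
#' @export
pdcDissimilarity <- function(P, R) {
  if (is(P, "IntegratedPDC")) P <- P@matrix
  if (is(R, "IntegratedPDC")) R <- R@matrix
  stopifnot(all(dim(P) == dim(R)))
  np <- sqrt(sum(abs(P)^2)); nr <- sqrt(sum(abs(R)^2))
  if (np == 0 || nr == 0) stop("zero-norm input matrix")
  sqrt(sum((P / np - R / nr)^2))
}

#' Export a directed edge list from an integrated-PDC matrix
#'
#' @param P an [IntegratedPDC-class] or `D x D` matrix; entry `(j, k)` is
#'   the influence of source `k` on target `j`.
#' @param labels channel labels of length `D`.
#' @param threshold minimum weight to keep an edge (default 0).
#' @param selfLoops keep `k -> k` edges (default `FALSE`).
#' @return data.frame with columns `source`, `target`, `weight`, sorted
#'   by decreasing weight.
#' @export
exportGraph <- function(P, labels = NULL, threshold = 0,
                        selfLoops = FALSE) {
  if (is(P, "IntegratedPDC")) P <- P@matrix
  D <- nrow(P)
  if (is.null(labels)) labels <- paste0("ch", seq_len(D))
  stopifnot(length(labels) == D)
  idx <- which(P >= threshold & P > 0, arr.ind = TRUE)
  if (!selfLoops) idx <- idx[idx[, 1L] != idx[, 2L], , drop = FALSE]
  out <- data.frame(source = labels[idx[, 2L]],
                    target = labels[idx[, 1L]],
                    weight = P[idx])
  out[order(-out$weight), , drop = FALSE]
}

#' Per-state integrated-PDC matrices of a fitted model
#'
#' @param params an [ARHMMParams-class].
#' @param freqs frequency grid (default 256 points over `[0, rate/2]`).
#' @param rate sampling rate in Hz.
#' @param band integration band (default full grid).
#' @return list of [IntegratedPDC-class], one per state.
#' @export
statePDC <- function(params, freqs = NULL, rate = 200, band = NULL) {
  lapply(seq_len(nStates(params)), function(z)
    integratePDC(pdc(params, freqs = freqs, rate = rate, state = z),
                 band = band))
}
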