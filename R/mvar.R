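#' Construct a spectral model from known MVAR coefficients
#'
#' Direct \linkS4class{SpectralModel} constructor, used when the true
#' generating coefficients are known (closed-form checks, simulation
#' oracles) rather than estimated from data.
#'
#' @param coeffs list of p coefficient matrices, regression convention
#'   (entry (i, j): influence of channel j at that lag on channel i now).
#' @param residCov innovation covariance (defaults to identity).
#' @param fs sampling rate in Hz.
#' @return a \linkS4class{SpectralModel}.
#' @export
spectralModel <- function(coeffs, residCov = NULL, fs = 1000) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  n <- nrow(coeffs[[1L]])
  if (is.null(residCov)) residCov <- diag(n)
  new("SpectralModel", order = length(coeffs), coeffs = coeffs,
      residCov = residCov, fs = fs, bic = numeric(0), scales = rep(1, n))
}

#' Extract MVAR coefficient matrices
#'
#' Coefficients of a fitted model, either in the standardized coordinates
#' the model was estimated in (per-channel z-scored signals; the
#' coordinates the spectral measures use) or mapped back to the original
#' signal units via the stored channel scales
#' (A_k = D B_k D^-1, D = diag of channel sds).
#'
#' @param model a \linkS4class{SpectralModel}.
#' @param units "standardized" (as fitted) or "original".
#' @return list of p coefficient matrices.
#' @export
mvarCoeffs <- function(model, units = c("standardized", "original")) {
  units <- match.arg(units)
  if (units == "standardized") return(model@coeffs)
  s <- model@scales
  lapply(model@coeffs, function(B) B * outer(s, 1 / s))
}

#' Fit a multivariate autoregressive model
#'
#' Multichannel least squares on the detrended, z-scored window. With
#' \code{order = "auto"} the order p in 1..maxOrder minimizing BIC is
#' selected (all candidates are fit on the common sample support of the
#' largest order, so their likelihoods are comparable). A near-singular
#' regressor Gram matrix triggers a ridge fallback with a warning stating
#' the regularization strength.
#'
#' @param window a \linkS4class{Recording} or channels x samples matrix
#'   (fs then defaults to 1000 Hz).
#' @param order integer MVAR order, or "auto".
#' @param maxOrder largest candidate order for "auto".
#' @return a \linkS4class{SpectralModel}.
#' @export
fitMVAR <- function(window, order = "auto", maxOrder = 10L) {
  x <- prep_window(window)
  fs <- if (is(window, "Recording")) window@fs else 1000
  n <- nrow(x); N <- ncol(x)
  auto <- identical(order, "auto")
  pmax <- if (auto) as.integer(maxOrder) else as.integer(order)
  stopifnot(pmax >= 1, N > 10 * pmax * n)
  Tn <- N - pmax
  Y <- x[, (pmax + 1):N, drop = FALSE]
  # Z rows: lag-1 block, lag-2 block, ... lag-pmax block.
  Z <- matrix(0, n * pmax, Tn)
  for (k in seq_len(pmax))
    Z[((k - 1) * n + 1):(k * n), ] <- x[, (pmax + 1 - k):(N - k), drop = FALSE]
  Gzz <- tcrossprod(Z)
  Gzy <- tcrossprod(Z, Y)
  Gyy <- tcrossprod(Y)
  fit_order <- function(p) {
    idx <- seq_len(n * p)
    G <- Gzz[idx, idx, drop = FALSE]
    At <- tryCatch(solve(G, Gzy[idx, , drop = FALSE]), error = function(e) NULL)
    lambda <- 0
    if (is.null(At) || !all(is.finite(At))) {
      lambda <- 1e-6 * mean(diag(G))
      warning(sprintf("near-singular regressors at order %d; ridge fallback (lambda = %.3g)",
                      p, lambda))
      At <- solve(G + lambda * diag(nrow(G)), Gzy[idx, , drop = FALSE])
    }
    sigma <- (Gyy - crossprod(Gzy[idx, , drop = FALSE], At)) / Tn
    sigma <- (sigma + t(sigma)) / 2
    list(At = At, sigma = sigma)
  }
  cand <- if (auto) seq_len(pmax) else pmax
  bics <- stats::setNames(rep(NA_real_, length(cand)), cand)
  fits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    fits[[i]] <- fit_order(p)
    det_s <- determinant(fits[[i]]$sigma, logarithm = TRUE)
    bics[i] <- as.numeric(det_s$modulus) + log(Tn) * p * n^2 / Tn
  }
  best <- which.min(bics)
  p <- cand[best]
  At <- fits[[best]]$At
  coeffs <- lapply(seq_len(p), function(k)
    t(At[((k - 1) * n + 1):(k * n), , drop = FALSE]))
  new("SpectralModel", order = as.integer(p), coeffs = coeffs,
      residCov = fits[[best]]$sigma, fs = fs,
      bic = if (auto) bics else numeric(0), scales = attr(x, "scales"))
}

# Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs) for each f (list of
# complex matrices).
abar_of_f <- function(model, freqs) {
  n <- nrow(model@residCov)
  lapply(freqs, function(f) {
    A <- diag(n) + 0i
    for (k in seq_along(model@coeffs))
      A <- A - model@coeffs[[k]] * exp(-2i * pi * f * k / model@fs)
    A
  })
}

check_band <- function(band, fs) {
  stopifnot(length(band) == 2, band[1] < band[2], band[1] > 0, band[2] < fs / 2)
}

#' Model-based coherence (COH1)
#'
#' Coherence derived from the cross-spectral density matrix
#' S(f) = H(f) Sigma_w H(f)* with H(f) = Abar(f)^-1:
#' C_ij(f) = |S_ij(f)| / sqrt(S_ii(f) S_jj(f)), averaged over nFreqs
#' equispaced frequencies in the band. Symmetric; diagonal zeroed.
#'
#' @param model a \linkS4class{SpectralModel}.
#' @param band frequency band (f_lo, f_hi) in Hz within (0, fs/2).
#' @param nFreqs number of evaluation frequencies.
#' @return a \linkS4class{MeasureMatrix} ("COH1").
#' @export
coh1 <- function(model, band = c(1, 45), nFreqs = 64) {
  check_band(band, model@fs)
  freqs <- seq(band[1], band[2], length.out = nFreqs)
  n <- nrow(model@residCov)
  acc <- matrix(0, n, n)
  for (A in abar_of_f(model, freqs)) {
    H <- solve(A)
    S <- H %*% model@residCov %*% Conj(t(H))
    p <- Re(diag(S))
    if (any(p <= 0)) stop("non-positive spectral power; model invalid")
    acc <- acc + Mod(S) / sqrt(outer(p, p))
  }
  C <- acc / nFreqs
  C <- (C + t(C)) / 2
  new_measure(C, "COH1", band = band)
}

#' Partial directed coherence (PDC)
#'
#' Column-normalized transform of Abar(f): the influence of source j on
#' target i at frequency f is pi(j -> i)(f) = |Abar_ij(f)| /
#' sqrt(sum_k |Abar_kj(f)|^2), so that sum_i pi(j -> i)(f)^2 = 1 for every
#' source j. Output entry (j, i) is the band mean of pi(j -> i)(f)
#' (source row -> target column convention); diagonal zeroed.
#'
#' @inheritParams coh1
#' @return a \linkS4class{MeasureMatrix} ("PDC").
#' @export
pdc <- function(model, band = c(1, 45), nFreqs = 64) {
  check_band(band, model@fs)
  freqs <- seq(band[1], band[2], length.out = nFreqs)
  n <- nrow(model@residCov)
  acc <- matrix(0, n, n)
  for (A in abar_of_f(model, freqs)) {
    m <- Mod(A)
    cn <- sqrt(colSums(m^2))
    if (any(cn == 0)) stop("zero source-column norm in Abar(f)")
    acc <- acc + t(m) / cn  # (j, i) = |Abar_ij| / cn_j
  }
  new_measure(acc / nFreqs, "PDC", band = band)
}
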