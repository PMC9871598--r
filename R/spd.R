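#' Symmetric square root of a positive semidefinite matrix
#'
#' Computes the unique symmetric PSD matrix `R` with `R %*% R == M` via the
#' spectral decomposition. Eigenvalues in `[-1e-10, 0)` are treated as
#' round-off and clipped to zero.
#'
#' @param m symmetric positive semidefinite matrix (symmetry checked to 1e-8).
#' @return Symmetric PSD matrix of the same dimension.
#' @export
matrix_sqrt_spd <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("`m` must be a square matrix")
  if (max(abs(m - t(m))) > 1e-8)
    stop("`m` is not symmetric within 1e-8")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-10)
    stop("not positive semidefinite: smallest eigenvalue ", min(e$values))
  vals <- pmax(e$values, 0)
  r <- e$vectors %*% (sqrt(vals) * t(e$vectors))
  (r + t(r)) / 2
}

#' Noise-whitening transform of ROI time series
#'
#' Applies `Y = sqrt(Omega) %*% X`: with `Omega` the temporal noise precision,
#' ordinary least-squares style fitting on `Y` is exactly the
#' precision-weighted fitting on `X`, i.e. the residual quadratic form
#' `(x - Xw)' Omega (x - Xw)` equals `||y - Yw||^2`. This is the plug-and-play
#' step that turns PC/SR into their noise-depressed variants. The result is
#' deliberately *not* re-centred or re-normalized (that would break the
#' identity); its `normalized` flag is cleared.
#'
#' @param ts normalized [fbn_ts] (or matrix with mean-0/unit-norm columns).
#' @param omega a `noise_precision` object or a T x T SPD matrix.
#' @return An [fbn_ts] holding the transformed series.
#' @export
transform_data <- function(ts, omega) {
  ts <- as_fbn_ts(ts)
  if (!ts$normalized)
    stop("`ts` must be centred/normalized before transforming (see center_normalize)")
  om <- omega_matrix(omega)
  if (nrow(om) != nrow(ts$data))
    stop("dimension mismatch: omega is ", nrow(om), " x ", ncol(om),
         " but the series has ", nrow(ts$data), " time points")
  y <- matrix_sqrt_spd(om) %*% ts$data
  dimnames(y) <- dimnames(ts$data)
  out <- fbn_ts(y, subject_id = ts$subject_id, normalized = FALSE)
  out
}

# pull the matrix out of a noise_precision or pass a plain matrix through
omega_matrix <- function(omega) {
  if (inherits(omega, "noise_precision")) omega$omega else as.matrix(omega)
}
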