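#' ROI time-series container
#'
#' Wraps a numeric matrix of BOLD-derived signals with `T` rows (time points)
#' and `N` columns (regions of interest) together with a subject identifier
#' and a flag recording whether the columns have been centred to mean zero
#' and scaled to unit L2 norm.
#'
#' @param data numeric matrix, time points in rows, ROIs in columns. At least
#'   3 time points and 2 ROIs; all entries finite.
#' @param subject_id character scalar identifying the subject.
#' @param normalized logical; `TRUE` only if every column already has zero
#'   mean and unit L2 norm (checked).
#'
#' @return An object of class `fbn_ts` with elements `data`, `subject_id`,
#'   `normalized`.
#' @export
#' @examples
#' ts <- fbn_ts(matrix(rnorm(60), 20, 3), subject_id = "sub-001")
#' ts <- center_normalize(ts)
#' colSums(ts$data^2)  # all 1
fbn_ts <- function(data, subject_id = "", normalized = FALSE) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (T time points x N ROIs)")
  if (nrow(data) < 3L)
    stop("need at least 3 time points, got ", nrow(data))
  if (ncol(data) < 2L)
    stop("need at least 2 ROIs, got ", ncol(data))
  if (!all(is.finite(data)))
    stop("time-series matrix contains non-finite values")
  obj <- structure(
    list(data = data, subject_id = as.character(subject_id)[1L],
         normalized = isTRUE(normalized)),
    class = "fbn_ts")
  if (obj$normalized && !is_normalized(data))
    stop("`normalized = TRUE` but columns are not mean-0 / unit-norm")
  obj
}

is_normalized <- function(x, tol = 1e-10) {
  all(abs(colMeans(x)) <= tol) &&
    all(abs(sqrt(colSums(x^2)) - 1) <= tol)
}

#' @export
print.fbn_ts <- function(x, ...) {
  cat("ROI time series", if (nzchar(x$subject_id)) paste0("'", x$subject_id, "'"),
      "\n  ", nrow(x$data), "time points x", ncol(x$data), "ROIs;",
      if (x$normalized) "centred/unit-norm columns" else "raw (not normalized)",
      "\n")
  invisible(x)
}

# Accept a bare matrix or an fbn_ts; returns an fbn_ts.
as_fbn_ts <- function(x, subject_id = "") {
  if (inherits(x, "fbn_ts")) return(x)
  fbn_ts(as.matrix(x), subject_id = subject_id)
}

#' Centre and normalize ROI time series
#'
#' Subtracts the temporal mean from each ROI column and rescales it to unit
#' L2 norm, the standing assumption of all estimators in the package (it
#' turns cross-products of columns into Pearson correlations). Idempotent.
#'
#' @param ts an [fbn_ts] object or a numeric T x N matrix.
#' @return An [fbn_ts] with zero-mean, unit-norm columns and the `normalized`
#'   flag set.
#' @details A constant column has no direction after centring and is
#'   rejected with an error naming the offending column.
#' @export
center_normalize <- function(ts) {
  ts <- as_fbn_ts(ts)
  if (ts$normalized) return(ts)
  x <- ts$data
  xc <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(xc^2))
  bad <- which(nrm <= .Machine$double.eps * nrow(x))
  if (length(bad))
    stop("constant column: ROI column ", bad[1L],
         " has zero variance and cannot be normalized")
  xn <- sweep(xc, 2L, nrm, "/")
  dimnames(xn) <- dimnames(x)
  fbn_ts(xn, subject_id = ts$subject_id, normalized = TRUE)
}
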