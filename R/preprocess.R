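#' Motion quality control
#'
#' A run is excluded when any translation magnitude exceeds
#' `trans_limit_mm` or any rotation magnitude exceeds `rot_limit_deg`
#' ("exceeding" is strict: maxima exactly at the limit are retained).
#' The decision is reported, never applied silently.
#'
#' @param run `bold_run` with a T x 6 motion table (3 translations in mm,
#'   3 rotations in degrees).
#' @param trans_limit_mm translation limit, default 3 mm.
#' @param rot_limit_deg rotation limit, default 3 degrees.
#' @return list with `exclude` (logical), `max_translation_mm`,
#'   `max_rotation_deg`, and per-axis maxima.
#' @export
motion_qc <- function(run, trans_limit_mm = 3, rot_limit_deg = 3) {
  if (is.null(run$motion)) stop("QC error: run has no motion table")
  m <- as.matrix(run$motion)
  stopifnot(ncol(m) == 6L)
  per_axis <- apply(abs(m), 2L, max)
  max_trans <- max(per_axis[1:3])
  max_rot <- max(per_axis[4:6])
  list(exclude = (max_trans > trans_limit_mm) || (max_rot > rot_limit_deg),
       max_translation_mm = max_trans,
       max_rotation_deg = max_rot,
       per_axis_max = per_axis,
       subject_id = run$subject_id)
}

#' Remove initial volumes
#'
#' Drops the first `k` time points (signal-equilibration scans) from the 4D
#' data and trims the motion table identically.
#'
#' @param run `bold_run`
#' @param k number of initial volumes to remove (default 10)
#' @return trimmed `bold_run`
#' @export
drop_initial_volumes <- function(run, k = 10L) {
  T_len <- dim(run$data)[4]
  if (T_len <= k) {
    stop(sprintf("length error: cannot drop %d of %d volumes", k, T_len))
  }
  if (k > 0L) {
    keep <- (k + 1L):T_len
    run$data <- run$data[, , , keep, drop = FALSE]
    run$motion <- run$motion[keep, , drop = FALSE]
    rownames(run$motion) <- NULL
    if (!is.null(run$nuisance)) {
      run$nuisance <- run$nuisance[keep, , drop = FALSE]
    }
  }
  run
}

#' Remove linear drift from a time series
#'
#' Least-squares residual after fitting intercept + linear trend; the output
#' has zero mean and zero linear trend.
#'
#' @param series numeric vector (length >= 3) or a time x series matrix
#'   (each column detrended).
#' @return same shape as the input
#' @export
linear_detrend <- function(series) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 3L) stop("degenerate-fit error: need at least 3 time points")
  t_c <- seq_len(n) - (n + 1) / 2
  out <- sweep(x, 2L, colMeans(x))
  slope <- crossprod(t_c, out) / sum(t_c^2)
  out <- out - outer(t_c, as.numeric(slope))
  if (is.vector(series)) as.numeric(out) else out
}

#' Ideal bandpass filter
#'
#' Zeroes every DFT bin whose frequency lies outside `[low_hz, high_hz]`
#' (DC always removed when `low_hz > 0`) and inverts the transform. The
#' ideal spectral mask is idempotent: filtering twice equals filtering once.
#'
#' @param series numeric vector or time x series matrix.
#' @param tr_seconds sampling interval (seconds).
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 <= low < high <= 1/(2 tr)`.
#' @return filtered series, real, same shape as input.
#' @export
bandpass <- function(series, tr_seconds, low_hz = 0.01, high_hz = 0.08) {
  nyq <- 1 / (2 * tr_seconds)
  if (low_hz < 0 || high_hz <= low_hz || high_hz > nyq + 1e-12) {
    stop("parameter error: band must satisfy 0 <= low < high <= Nyquist")
  }
  x <- as.matrix(series)
  n <- nrow(x)
  freqs <- c(0, seq_len(n - 1)) / (n * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs)   # fold to [0, Nyquist]
  keep <- freqs >= low_hz - 1e-12 & freqs <= high_hz + 1e-12
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  out <- Re(stats::mvfft(X, inverse = TRUE)) / n
  if (is.vector(series)) as.numeric(out) else out
}

#' Regress out nuisance signals
#'
#' Projects the series onto the orthogonal complement of the span of the
#' nuisance regressors plus an intercept; the residual is orthogonal to
#' every regressor column.
#'
#' @param series numeric vector or time x series matrix.
#' @param nuisance T x K matrix or data.frame of regressors (e.g. six motion
#'   parameters, white-matter mean, CSF mean, global mean).
#' @return residual series, same shape as input.
#' @export
regress_nuisance <- function(series, nuisance) {
  x <- as.matrix(series)
  N <- as.matrix(nuisance)
  if (nrow(N) != nrow(x)) stop("regressor rows must match series length")
  X <- cbind(intercept = 1, N)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("collinearity error: rank-deficient nuisance design (columns: ",
         paste(drop_cols, collapse = ", "), ")")
  }
  out <- qr.resid(qr_x, x)
  if (is.vector(series)) as.numeric(out) else out
}

#' Full per-run time-series cleaning
#'
#' Applies the post-alignment pipeline to one run: drop initial volumes,
#' linear detrend, ideal bandpass, and nuisance regression (six motion
#' parameters, white-matter and CSF components when present, and the global
#' mean), voxelwise in that order. Two cleaned versions are returned:
#' `bandlimited` feeds ReHo and connectivity; `broadband` (identical
#' pipeline without the bandpass step) feeds ALFF/fALFF, whose full-spectrum
#' denominator requires broadband input.
#'
#' @param run `bold_run`
#' @param drop initial volumes to remove (default 10)
#' @param band analysis band in Hz (default 0.01-0.08)
#' @param trans_limit_mm,rot_limit_deg motion QC limits
#' @return list with `bandlimited` and `broadband` (`bold_run`s) and `qc`
#'   (the [motion_qc()] report).
#' @export
preprocess_run <- function(run, drop = 10L, band = c(0.01, 0.08),
                           trans_limit_mm = 3, rot_limit_deg = 3) {
  qc <- motion_qc(run, trans_limit_mm, rot_limit_deg)
  run <- drop_initial_volumes(run, drop)
  dims <- dim(run$data)
  idx <- which(run$mask)
  flat <- matrix(run$data, nrow = prod(dims[1:3]))
  Y <- t(flat[idx, , drop = FALSE])          # T x V

  Y <- linear_detrend(Y)
  Yb <- bandpass(Y, run$tr_seconds, band[1], band[2])

  global_mean <- rowMeans(Y)
  nuis <- as.matrix(run$motion)
  if (!is.null(run$nuisance)) nuis <- cbind(nuis, as.matrix(run$nuisance))
  nuis <- cbind(nuis, global = global_mean)
  # the band-limited branch uses band-filtered regressors so the residual
  # stays inside the analysis band; the broadband branch uses them as is
  nuis_b <- bandpass(nuis, run$tr_seconds, band[1], band[2])
  keep_b <- apply(nuis_b, 2L, stats::sd) > 1e-12
  Yb <- regress_nuisance(Yb, nuis_b[, keep_b, drop = FALSE])
  Y <- regress_nuisance(Y, nuis)

  rebuild <- function(mat) {
    flat2 <- matrix(0, nrow = prod(dims[1:3]), ncol = dims[4])
    flat2[idx, ] <- t(mat)
    out <- run
    out$data <- array(flat2, dim = dims)
    out
  }
  list(bandlimited = rebuild(Yb), broadband = rebuild(Y), qc = qc)
}
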