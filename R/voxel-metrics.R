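#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Mean of the square root of the periodogram power over the frequency bins
#' inside the analysis band. The one-sided DFT amplitude spectrum
#' `2|X_k|/n` is used (DC excluded), so a pure in-band sinusoid of
#' amplitude `a` landing on a bin has ALFF close to `a` divided by the
#' number of in-band bins.
#'
#' @param series numeric time vector.
#' @param tr_seconds sampling interval in seconds.
#' @param band `c(low, high)` in Hz.
#' @return nonnegative scalar.
#' @export
alff <- function(series, tr_seconds, band = c(0.01, 0.08)) {
  sp <- amplitude_spectrum(as.matrix(series), tr_seconds)
  inb <- in_band_bins(sp$freqs, band)
  mean(sp$amp[inb, 1L])
}

#' Fractional ALFF (fALFF)
#'
#' Ratio of the in-band sum of square-root power to the full-spectrum sum
#' (DC excluded from both); a band-specificity index in `[0, 1]`.
#'
#' @inheritParams alff
#' @return scalar in `[0, 1]`.
#' @export
falff <- function(series, tr_seconds, band = c(0.01, 0.08)) {
  if (stats::sd(series) == 0) {
    stop("undefined-ratio error: zero-variance series")
  }
  sp <- amplitude_spectrum(as.matrix(series), tr_seconds)
  total <- sum(sp$amp[, 1L])
  inb <- in_band_bins(sp$freqs, band)
  sum(sp$amp[inb, 1L]) / total
}

# one-sided amplitude spectrum for a T x V matrix; DC excluded
amplitude_spectrum <- function(Y, tr_seconds) {
  n <- nrow(Y)
  if (n < 2L) stop("need at least 2 time points")
  kmax <- floor(n / 2)
  X <- stats::mvfft(Y)
  amp <- 2 * Mod(X[2:(kmax + 1L), , drop = FALSE]) / n
  freqs <- seq_len(kmax) / (n * tr_seconds)
  list(amp = amp, freqs = freqs)
}

in_band_bins <- function(freqs, band) {
  inb <- freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12
  if (!any(inb)) {
    stop("band-resolution error: no frequency bins inside the band")
  }
  inb
}

#' Kendall's coefficient of concordance (Kendall W)
#'
#' Concordance of `m` time series over `n` time points:
#' `W = 12 * sum((R_i - mean(R))^2) / (m^2 (n^3 - n))`, with `R_i` the sum
#' across series of the within-series rank at time `i`. Ties receive
#' midranks. `W = 1` for identical rank orderings, `W = 0` when rank sums
#' are all equal (e.g. two exactly reversed series).
#'
#' @param series_set m x n matrix, one series per row.
#' @return scalar in `[0, 1]`.
#' @export
kendall_w <- function(series_set) {
  X <- as.matrix(series_set)
  m <- nrow(X); n <- ncol(X)
  if (m < 2L || n < 2L) stop("kendall_w needs m >= 2 series of length >= 2")
  if (any(apply(X, 1L, function(r) max(r) == min(r)))) {
    warning("tie-degenerate series: constant row(s), using midranks")
  }
  Rk <- t(apply(X, 1L, rank))
  Ri <- colSums(Rk)
  12 * sum((Ri - mean(Ri))^2) / (m^2 * (n^3 - n))
}

# neighborhood offsets for ReHo: 7 (faces), 19 (faces+edges), 27 (full cube)
reho_offsets <- function(neighborhood) {
  if (!neighborhood %in% c(7L, 19L, 27L)) {
    stop("parameter error: neighborhood must be 7, 19 or 27")
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(neighborhood),
                 "7" = ord <= 1L, "19" = ord <= 2L, "27" = ord <= 3L)
  g[keep, , drop = FALSE]
}

#' Regional homogeneity (ReHo) map
#'
#' Kendall's W of each in-mask voxel's time series with its in-mask spatial
#' neighbors (default 27-voxel cube including the center). Boundary voxels
#' use whatever neighbors fall inside the mask; a voxel whose neighborhood
#' contains fewer than 2 in-mask voxels is an error.
#'
#' @param run `bold_run` (bandpassed data expected).
#' @param neighborhood 7, 19 or 27.
#' @return `voxel_map` with raw ReHo values in `[0, 1]`.
#' @export
reho_map <- function(run, neighborhood = 27L) {
  dims <- dim(run$data)
  mask <- run$mask
  idx <- which(mask)
  V <- length(idx)
  T_len <- dims[4]
  flat <- matrix(run$data, nrow = prod(dims[1:3]))
  Rk <- t(apply(flat[idx, , drop = FALSE], 1L, rank))   # V x T midranks

  ord <- array(0L, dim = dims[1:3])
  ord[idx] <- seq_len(V)
  coords <- which(mask, arr.ind = TRUE)
  offs <- reho_offsets(neighborhood)

  sumR <- matrix(0, V, T_len)
  mcount <- integer(V)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2]
    nbord <- ord[lin]
    present <- nbord > 0L
    rows <- which(ok)[present]
    sumR[rows, ] <- sumR[rows, ] + Rk[nbord[present], , drop = FALSE]
    mcount[rows] <- mcount[rows] + 1L
  }
  if (any(mcount < 2L)) {
    stop("ReHo error: neighborhood smaller than 2 voxels inside the mask")
  }
  S <- rowSums((sumR - mcount * (T_len + 1) / 2)^2)
  W <- 12 * S / (mcount^2 * (T_len^3 - T_len))
  vals <- array(0, dim = dims[1:3])
  vals[idx] <- W
  voxel_map(vals, mask, "ReHo")
}

#' Construct a voxel map
#'
#' @param values 3D numeric array
#' @param mask 3D logical array
#' @param metric_name one of "ALFF", "fALFF", "ReHo"
#' @param standardized logical flag
#' @return object of class `voxel_map`
#' @export
voxel_map <- function(values, mask, metric_name, standardized = FALSE) {
  structure(list(values = values, mask = mask, metric_name = metric_name,
                 standardized = standardized),
            class = "voxel_map")
}

#' Separable Gaussian smoothing
#'
#' Convolves a 3D volume (or each volume of a 4D series) with a separable
#' Gaussian of the stated full-width-half-maximum. The per-axis kernel has
#' `sigma_voxels = fwhm / (voxel_mm * 2 sqrt(2 ln 2))`, is truncated at 4
#' sigma, and is renormalized over the available support, so constant
#' fields (and field boundaries) are handled without attenuation. When a
#' mask is supplied, smoothing is renormalized within the mask and
#' out-of-mask voxels stay zero.
#'
#' @param volume 3D or 4D numeric array.
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param voxel_mm voxel size per axis in mm (default 3).
#' @param mask optional 3D logical array restricting the smoothing support.
#' @return array of the same shape.
#' @export
gaussian_smooth <- function(volume, fwhm_mm = 6, voxel_mm = c(3, 3, 3),
                            mask = NULL) {
  if (any(voxel_mm <= 0)) stop("parameter error: voxel size must be positive")
  if (fwhm_mm < 0) stop("parameter error: fwhm must be >= 0")
  if (fwhm_mm == 0) return(volume)
  nd <- length(dim(volume))
  stopifnot(nd %in% c(3L, 4L))
  sdims <- dim(volume)[1:3]
  voxel_mm <- rep_len(voxel_mm, 3L)

  support <- if (is.null(mask)) array(1, dim = sdims) else (mask * 1)
  num <- volume * as.vector(support)   # recycles over 4th dim when present
  den <- support
  for (axis in 1:3) {
    sigma <- fwhm_mm / (voxel_mm[axis] * 2 * sqrt(2 * log(2)))
    r <- ceiling(4 * sigma)
    kern <- stats::dnorm(-r:r, sd = sigma)
    kern <- kern / sum(kern)
    num <- conv_axis(num, axis, kern)
    den <- conv_axis(den, axis, kern)
  }
  out <- num / as.vector(pmax(den, .Machine$double.eps))
  if (!is.null(mask)) out <- out * as.vector(mask * 1)
  out
}

# zero-padded 1D convolution of a 3D/4D array along a spatial axis
conv_axis <- function(arr, axis, kern) {
  r <- (length(kern) - 1L) / 2L
  d <- dim(arr)
  n <- d[axis]
  out <- array(0, dim = d)
  for (s in -r:r) {
    w <- kern[s + r + 1L]
    src <- seq_len(n) + s
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    ia <- lapply(d, seq_len); ia[[axis]] <- src[ok]
    ib <- lapply(d, seq_len); ib[[axis]] <- which(ok)
    slice <- do.call(`[`, c(list(arr), ia, list(drop = FALSE)))
    cur <- do.call(`[`, c(list(out), ib, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), ib, list(value = cur + w * slice)))
  }
  out
}

#' Standardize a voxel map
#'
#' Transforms in-mask values to mean 0, standard deviation 1 (the map-level
#' standardization applied before group analysis); out-of-mask voxels are
#' untouched.
#'
#' @param map `voxel_map`
#' @return standardized `voxel_map`
#' @export
standardize_map <- function(map) {
  stopifnot(inherits(map, "voxel_map"))
  v <- map$values[map$mask]
  if (length(v) < 2L || stats::sd(v) == 0) {
    stop("degenerate-map error: zero in-mask variance")
  }
  out <- map
  out$values[map$mask] <- (v - mean(v)) / stats::sd(v)
  out$standardized <- TRUE
  out
}

#' Compute the three voxel metric maps for one subject
#'
#' Order contract: ALFF and fALFF smooth the 4D (broadband) data before the
#' spectral computation; ReHo is computed on the unsmoothed band-limited
#' data and its map is smoothed afterwards. Raw and standardized maps are
#' returned.
#'
#' @param pp result of [preprocess_run()] (or a list with `broadband` and
#'   `bandlimited` runs).
#' @param tr_seconds repetition time.
#' @param band analysis band in Hz.
#' @param fwhm_mm smoothing kernel FWHM (default 6 mm).
#' @param voxel_mm voxel size (default 3 mm isotropic).
#' @param neighborhood ReHo neighborhood (default 27).
#' @return list of six `voxel_map`s: `alff`, `falff`, `reho` (raw) and
#'   `alff_z`, `falff_z`, `reho_z` (standardized).
#' @export
voxel_metric_maps <- function(pp, tr_seconds = 2, band = c(0.01, 0.08),
                              fwhm_mm = 6, voxel_mm = c(3, 3, 3),
                              neighborhood = 27L) {
  bb <- pp$broadband
  mask <- bb$mask
  dims <- dim(bb$data)
  sm4d <- gaussian_smooth(bb$data, fwhm_mm, voxel_mm, mask = mask)
  idx <- which(mask)
  Y <- t(matrix(sm4d, nrow = prod(dims[1:3]))[idx, , drop = FALSE])
  sp <- amplitude_spectrum(Y, tr_seconds)
  inb <- in_band_bins(sp$freqs, band)
  alff_v <- colMeans(sp$amp[inb, , drop = FALSE])
  tot <- colSums(sp$amp)
  falff_v <- ifelse(tot > 0, colSums(sp$amp[inb, , drop = FALSE]) / tot, 0)
  mk <- function(v, name) {
    a <- array(0, dim = dims[1:3]); a[idx] <- v
    voxel_map(a, mask, name)
  }
  alff_map <- mk(alff_v, "ALFF")
  falff_map <- mk(falff_v, "fALFF")

  reho_raw <- reho_map(pp$bandlimited, neighborhood)
  reho_raw$values <- gaussian_smooth(reho_raw$values, fwhm_mm, voxel_mm,
                                     mask = mask)
  list(alff = alff_map, falff = falff_map, reho = reho_raw,
       alff_z = standardize_map(alff_map),
       falff_z = standardize_map(falff_map),
       reho_z = standardize_map(reho_raw))
}
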