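#' Specify a synthetic two-group cohort with known ground truth
#'
#' Defines every parameter of a simulated resting-state BOLD study: cohort
#' size, acquisition geometry and timing, the shared node-level correlation
#' structure, and the effects planted in group 1 (patients) relative to
#' group 0 (controls). Planted effects come in three forms: multiplicative
#' signal-amplitude factors per node, additive local-coherence deltas per
#' node, and additive connectivity deltas per edge applied on the Fisher-z
#' scale of the target correlation.
#'
#' Defaults mirror a typical clinical resting-state protocol: 27 patients and
#' 25 controls, 8 minutes of data at TR = 2 s (240 volumes), a 0.01-0.08 Hz
#' signal band, and a 90-node parcellation with block-structured baseline
#' connectivity (within-network r = 0.3, between-network r = 0.05).
#'
#' @param n_per_group integer vector `c(patients, controls)`.
#' @param grid_dims voxel counts per axis.
#' @param n_rois node count.
#' @param tr_seconds repetition time in seconds.
#' @param n_volumes time points acquired (before trimming).
#' @param band analysis frequency band in Hz.
#' @param base_corr symmetric positive-definite target correlation
#'   (`n_rois x n_rois`, unit diagonal); default block structure.
#' @param amp_effect named numeric, node index -> multiplicative amplitude
#'   factor for group 1 (e.g. `c("5" = 1.3)`).
#' @param coherence_effect named numeric, node index -> additive delta on the
#'   local-coherence fraction for group 1.
#' @param edge_effect data.frame with columns `i`, `j`, `dz`: additive
#'   Fisher-z connectivity delta on edge (i, j) for group 1.
#' @param coherence baseline shared-variance fraction of voxels within a
#'   parcel, in `[0, 1]`.
#' @param noise_sd voxel white-noise standard deviation multiplier.
#' @param motion_max_mm,motion_max_deg maximum simulated head displacement.
#' @param seed integer seed governing all randomness.
#' @return object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(n_per_group = c(patients = 27L, controls = 25L),
                              grid_dims = c(12L, 12L, 12L),
                              n_rois = 90L,
                              tr_seconds = 2,
                              n_volumes = 240L,
                              band = c(0.01, 0.08),
                              base_corr = NULL,
                              amp_effect = NULL,
                              coherence_effect = NULL,
                              edge_effect = NULL,
                              coherence = 0.5,
                              noise_sd = 1,
                              motion_max_mm = 1.5,
                              motion_max_deg = 1.5,
                              seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1L))
  n_rois <- as.integer(n_rois)
  if (n_rois < 2L) stop("n_rois must be >= 2")
  n_volumes <- as.integer(n_volumes)
  if (n_volumes <= 10L) stop("n_volumes must exceed 10")
  if (is.null(base_corr)) base_corr <- default_base_corr(n_rois)
  validate_corr(base_corr, n_rois)
  if (!is.null(amp_effect)) {
    if (any(amp_effect <= 0)) stop("amplitude factors must be > 0")
  }
  if (coherence < 0 || coherence > 1) stop("coherence must lie in [0, 1]")
  if (!is.null(coherence_effect)) {
    ctot <- coherence + coherence_effect
    if (any(ctot < 0 | ctot > 1)) stop("coherence + delta must lie in [0, 1]")
  }
  if (!is.null(edge_effect)) {
    stopifnot(all(c("i", "j", "dz") %in% names(edge_effect)))
    r0 <- base_corr[cbind(edge_effect$i, edge_effect$j)]
    r1 <- tanh(atanh(r0) + edge_effect$dz)
    if (any(abs(r1) >= 1 - 1e-9)) {
      stop("edge delta pushes |r| >= 1 on a planted edge")
    }
  }
  structure(list(n_per_group = n_per_group, grid_dims = as.integer(grid_dims),
                 n_rois = n_rois, tr_seconds = tr_seconds,
                 n_volumes = n_volumes, band = band, base_corr = base_corr,
                 amp_effect = amp_effect, coherence_effect = coherence_effect,
                 edge_effect = edge_effect, coherence = coherence,
                 noise_sd = noise_sd, motion_max_mm = motion_max_mm,
                 motion_max_deg = motion_max_deg, seed = as.integer(seed)),
            class = "ground_truth_spec")
}

validate_corr <- function(R, n) {
  if (!is.matrix(R) || nrow(R) != n || ncol(R) != n) {
    stop("base_corr must be ", n, "x", n)
  }
  if (max(abs(R - t(R))) > 1e-10) stop("base_corr must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) stop("base_corr must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("base_corr must be positive definite")
  invisible(TRUE)
}

#' Default block-structured baseline correlation
#'
#' Within-network correlation `within`, between-network `between`. For 90
#' nodes the blocks follow the packaged network lookup; otherwise nodes are
#' split into six contiguous blocks. Positive definite whenever
#' `0 <= between <= within < 1`.
#'
#' @param n_rois node count
#' @param within,between correlation levels
#' @return correlation matrix
#' @export
default_base_corr <- function(n_rois = 90L, within = 0.3, between = 0.05) {
  stopifnot(between >= 0, within >= between, within < 1)
  blocks <- if (n_rois == 90L) {
    as.integer(factor(default_network_table()$network))
  } else {
    ((seq_len(n_rois) - 1L) %% 6L) + 1L
  }
  same <- outer(blocks, blocks, "==")
  R <- matrix(between, n_rois, n_rois)
  R[same] <- within
  diag(R) <- 1
  R
}

#' Simulate band-limited node time series with a target correlation
#'
#' Filters white Gaussian noise through an ideal spectral mask on the
#' analysis band, standardizes each node series, then imposes the target
#' correlation via the symmetric square root of `target_corr`. The result
#' has (in expectation) the requested correlation and all of its spectral
#' power inside the band.
#'
#' @param target_corr positive-definite correlation matrix (nodes x nodes).
#' @param n_volumes number of time points.
#' @param tr_seconds sampling interval (seconds).
#' @param band `c(low, high)` in Hz.
#' @param seed integer seed.
#' @return nodes x time numeric matrix, rows approximately unit variance.
#' @export
simulate_roi_signals <- function(target_corr, n_volumes, tr_seconds = 2,
                                 band = c(0.01, 0.08), seed = 1L) {
  n <- nrow(target_corr)
  ev <- eigen(target_corr, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    stop("factorization error: target correlation is not positive definite")
  }
  set.seed(as.integer(seed))
  W <- matrix(stats::rnorm(n * n_volumes), nrow = n)
  Wf <- t(apply(W, 1L, bandpass, tr_seconds = tr_seconds,
                low_hz = band[1], high_hz = band[2]))
  sdv <- apply(Wf, 1L, stats::sd)
  Wf <- Wf / sdv
  S <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))   # symmetric sqrt
  S %*% Wf
}

#' Render node signals into a 4D BOLD run
#'
#' Each voxel of parcel `l` receives
#' `amp[l] * (sqrt(coh[l]) * s_l + noise_sd * sqrt(1 - coh[l]) * eps)`,
#' where `s_l` is the node signal and `eps` independent unit-variance white
#' noise, so that with `noise_sd = 1` the shared fraction of voxel variance
#' equals `coh[l]`. Optional nuisance components are added with
#' voxel-specific coefficients so nuisance regression can be exercised with
#' known truth. A smoothed-random-walk motion table is attached.
#'
#' @param atlas `atlas_volume`.
#' @param roi_signals nodes x time matrix, rows matching atlas labels.
#' @param amp per-node amplitude factors (recycled scalar allowed).
#' @param coherence per-node shared-variance fractions in `[0, 1]`.
#' @param noise_sd voxel noise standard deviation multiplier.
#' @param nuisance optional time x K matrix of nuisance series (e.g. white
#'   matter and CSF components) mixed into every voxel.
#' @param motion_max_mm,motion_max_deg maximum simulated displacement.
#' @param tr_seconds repetition time.
#' @param subject_id identifier stored on the run.
#' @param seed integer seed.
#' @return object of class `bold_run`: `data` (4D array), `tr_seconds`,
#'   `mask`, `motion` (T x 6 data.frame), `nuisance`, `subject_id`.
#' @export
render_bold <- function(atlas, roi_signals, amp = 1, coherence = 0.5,
                        noise_sd = 1, nuisance = NULL,
                        motion_max_mm = 1.5, motion_max_deg = 1.5,
                        tr_seconds = 2, subject_id = "sub-01", seed = 1L) {
  n_rois <- atlas$n_rois
  if (nrow(roi_signals) != n_rois) {
    stop("roi_signals rows must match atlas labels")
  }
  amp <- rep_len(amp, n_rois)
  coherence <- rep_len(coherence, n_rois)
  if (any(coherence < 0 | coherence > 1)) {
    stop("parameter error: coherence must lie in [0, 1]")
  }
  T_len <- ncol(roi_signals)
  dims <- atlas$dims
  set.seed(as.integer(seed))

  idx <- which(atlas$mask)
  lab <- atlas$labels[idx]
  n_vox <- length(idx)
  # voxel series as n_vox x T, then scatter into the 4D array
  V <- roi_signals[lab, , drop = FALSE] * (amp[lab] * sqrt(coherence[lab]))
  noise_scale <- amp[lab] * noise_sd * sqrt(1 - coherence[lab])
  V <- V + matrix(stats::rnorm(n_vox * T_len), n_vox, T_len) * noise_scale
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == T_len)
    B <- matrix(stats::rnorm(n_vox * ncol(nuisance), mean = 0.5, sd = 0.2),
                n_vox, ncol(nuisance))
    V <- V + B %*% t(nuisance)
  }
  data <- array(0, dim = c(dims, T_len))
  flat <- matrix(data, nrow = prod(dims))
  flat[idx, ] <- V
  data <- array(flat, dim = c(dims, T_len))

  motion <- simulate_motion(T_len, motion_max_mm, motion_max_deg)
  structure(list(data = data, tr_seconds = tr_seconds, mask = atlas$mask,
                 motion = motion, nuisance = nuisance,
                 subject_id = subject_id),
            class = "bold_run")
}

# smoothed random walk per parameter, each column rescaled to a random
# fraction of the allowed maximum so QC sees both clean and borderline runs
simulate_motion <- function(T_len, max_mm, max_deg) {
  one <- function(mx) {
    w <- cumsum(stats::rnorm(T_len))
    w <- stats::filter(w, rep(1 / 5, 5), sides = 2)
    w[is.na(w)] <- 0
    peak <- max(abs(w))
    if (peak == 0) return(rep(0, T_len))
    as.numeric(w / peak * stats::runif(1, 0.1, 1) * mx)
  }
  out <- data.frame(trans_x = one(max_mm), trans_y = one(max_mm),
                    trans_z = one(max_mm), rot_x = one(max_deg),
                    rot_y = one(max_deg), rot_z = one(max_deg))
  out
}

#' Generate a complete synthetic cohort
#'
#' Builds the atlas, draws per-subject node signals from the group-specific
#' target correlation (group 1 receives the planted edge deltas on the
#' Fisher-z scale, then back-transformation; amplitude and coherence effects
#' are applied at rendering), renders voxel data with nuisance components,
#' simulates motion, and draws demographic covariates. Fully deterministic
#' given the spec (including its seed).
#'
#' @param spec `ground_truth_spec`.
#' @return object of class `synthetic_cohort`: `runs` (list of `bold_run`),
#'   `atlas`, `covariates` (data.frame: subject, group, age, sex, education,
#'   bmi), `truth` (the spec plus realized per-group parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  n1 <- spec$n_per_group[1]; n0 <- spec$n_per_group[2]
  n <- n1 + n0
  atlas <- build_atlas(spec$grid_dims, spec$n_rois, seed = spec$seed)

  corr_g0 <- spec$base_corr
  corr_g1 <- apply_edge_effect(spec$base_corr, spec$edge_effect)
  amp_g0 <- rep(1, spec$n_rois)
  amp_g1 <- amp_g0
  if (!is.null(spec$amp_effect)) {
    amp_g1[as.integer(names(spec$amp_effect))] <- spec$amp_effect
  }
  coh_g0 <- rep(spec$coherence, spec$n_rois)
  coh_g1 <- coh_g0
  if (!is.null(spec$coherence_effect)) {
    ids <- as.integer(names(spec$coherence_effect))
    coh_g1[ids] <- coh_g1[ids] + spec$coherence_effect
  }

  group <- c(rep(1L, n1), rep(0L, n0))
  runs <- vector("list", n)
  set.seed(spec$seed)
  covariates <- draw_covariates(n, group)
  for (i in seq_len(n)) {
    sseed <- (as.numeric(spec$seed) * 7919 + i * 104729) %% 2147483647
    g <- group[i]
    sig <- simulate_roi_signals(if (g == 1L) corr_g1 else corr_g0,
                                spec$n_volumes, spec$tr_seconds, spec$band,
                                seed = sseed)
    nuis_seed <- (sseed + 9973) %% 2147483647L
    set.seed(nuis_seed)
    nuis <- cbind(wm = slow_series(spec$n_volumes),
                  csf = slow_series(spec$n_volumes))
    runs[[i]] <- render_bold(atlas, sig,
                             amp = if (g == 1L) amp_g1 else amp_g0,
                             coherence = if (g == 1L) coh_g1 else coh_g0,
                             noise_sd = spec$noise_sd, nuisance = nuis,
                             motion_max_mm = spec$motion_max_mm,
                             motion_max_deg = spec$motion_max_deg,
                             tr_seconds = spec$tr_seconds,
                             subject_id = sprintf("sub-%03d", i),
                             seed = (sseed + 17L) %% 2147483647L)
  }
  covariates$subject <- vapply(runs, function(r) r$subject_id, "")
  covariates <- covariates[, c("subject", "group", "age", "sex",
                               "education", "bmi")]
  truth <- list(spec = spec, corr_group0 = corr_g0, corr_group1 = corr_g1,
                amp_group1 = amp_g1, coherence_group1 = coh_g1)
  structure(list(runs = runs, atlas = atlas, covariates = covariates,
                 truth = truth),
            class = "synthetic_cohort")
}

apply_edge_effect <- function(R, edge_effect) {
  if (is.null(edge_effect) || nrow(edge_effect) == 0L) return(R)
  Z <- suppressWarnings(atanh(R))
  diag(Z) <- 0
  for (k in seq_len(nrow(edge_effect))) {
    i <- edge_effect$i[k]; j <- edge_effect$j[k]
    Z[i, j] <- Z[i, j] + edge_effect$dz[k]
    Z[j, i] <- Z[i, j]
  }
  R1 <- tanh(Z)
  diag(R1) <- 1
  if (any(abs(R1[upper.tri(R1)]) >= 1 - 1e-9)) {
    stop("edge delta pushes |r| >= 1")
  }
  # guard positive definiteness after the planted deltas
  ev <- eigen(R1, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-6)
    R1 <- ev$vectors %*% (vals * t(ev$vectors))
    R1 <- stats::cov2cor(R1)
  }
  R1
}

# slowly varying nuisance component (smoothed random walk, unit variance)
slow_series <- function(T_len) {
  w <- cumsum(stats::rnorm(T_len))
  w <- stats::filter(w, rep(1 / 9, 9), sides = 2)
  w[is.na(w)] <- 0
  w <- as.numeric(w)
  s <- stats::sd(w)
  if (s == 0) rep(0, T_len) else (w - mean(w)) / s
}

# demographics emulating a middle-aged clinical cohort
draw_covariates <- function(n, group) {
  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    pmin(pmax(x, lo), hi)
  }
  data.frame(group = group,
             age = round(rtrunc(n, 41, 13, 18, 60), 1),
             sex = stats::rbinom(n, 1L, 0.5),
             education = round(rtrunc(n, 12, 3, 6, 20), 1),
             bmi = round(rtrunc(n, 24, 3, 16, 35), 1))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d runs (%d patients / %d controls), %s grid, %d nodes\n",
              length(x$runs), sum(x$covariates$group == 1L),
              sum(x$covariates$group == 0L),
              paste(x$atlas$dims, collapse = "x"), x$atlas$n_rois))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Runs and atlas as uncompressed NIfTI, motion and covariates as TSV, and
#' the ground-truth echo as JSON.
#'
#' @param cohort `synthetic_cohort`
#' @param dir output directory (created if missing)
#' @return invisibly, the vector of files written
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (run in cohort$runs) {
    f_nii <- file.path(dir, paste0(run$subject_id, "_bold.nii"))
    RNifti::writeNifti(RNifti::asNifti(run$data), f_nii)
    f_mot <- file.path(dir, paste0(run$subject_id, "_motion.tsv"))
    utils::write.table(run$motion, f_mot, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, f_nii, f_mot)
  }
  f_atlas <- file.path(dir, "atlas.nii")
  RNifti::writeNifti(RNifti::asNifti(cohort$atlas$labels), f_atlas)
  f_cov <- file.path(dir, "covariates.tsv")
  utils::write.table(cohort$covariates, f_cov, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f_truth <- file.path(dir, "truth.json")
  truth <- cohort$truth$spec
  truth$base_corr <- NULL     # large; regenerable from the seed
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(files, f_atlas, f_cov, f_truth))
}
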