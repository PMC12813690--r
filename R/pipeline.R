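default_config <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_per_group = c(27L, 25L),
                    grid_dims = c(12L, 12L, 12L), n_rois = 90L,
                    tr_seconds = 2, n_volumes = 240L, coherence = 0.5,
                    noise_sd = 1, motion_max_mm = 1.5, motion_max_deg = 1.5,
                    amp_effect = NULL, coherence_effect = NULL,
                    edge_effect = NULL),
    input_dir = NULL,
    preprocess = list(drop = 10L, band = c(0.01, 0.08),
                      trans_limit_mm = 3, rot_limit_deg = 3),
    voxel = list(fwhm_mm = 6, voxel_mm = c(3, 3, 3), neighborhood = 27L),
    connectome = list(s_min = 0.05, s_max = 0.50, step = 0.01),
    graph = list(n_rand = 100L),
    stats = list(n_perm = 1000L, voxel_p = 0.01, cluster_p = 0.01, q = 0.05,
                 covariates_for_metrics = FALSE),
    classify = list(enabled = TRUE, combo = "C+G+N", alpha = 0.05,
                    C_grid = 2^(-5:5), beta_step = 0.1)
  )
}

merge_config <- function(defaults, user, path = "", errors) {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      errors$msg <- c(errors$msg, paste0("unknown key: ", full))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full,
                                      errors)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a run configuration
#'
#' Merges a (possibly empty) user document over the package defaults --
#' every default matching a stated protocol value (drop 10 volumes, band
#' 0.01-0.08 Hz, 6 mm FWHM, sparsity 0.05-0.50 step 0.01, selection alpha
#' 0.05, voxel/cluster p 0.01) -- then checks every invariant, reporting
#' all violations together.
#'
#' @param raw named list, or path to a YAML/JSON config file, or `NULL` for
#'   pure defaults
#' @return validated config list of class `run_config`
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw)) {
    raw <- if (grepl("\\.json$", raw)) jsonlite::read_json(raw,
                                                           simplifyVector = TRUE)
    else yaml::read_yaml(raw)
  }
  if (is.null(raw)) raw <- list()
  errors <- new.env()
  errors$msg <- character(0)
  cfg <- merge_config(default_config(), raw, "", errors)

  chk <- function(ok, msg) if (!isTRUE(ok)) errors$msg <- c(errors$msg, msg)
  b <- cfg$preprocess$band
  chk(length(b) == 2 && b[1] >= 0 && b[1] < b[2],
      "preprocess.band must be increasing c(low, high)")
  chk(cfg$preprocess$drop >= 0, "preprocess.drop must be >= 0")
  chk(cfg$voxel$fwhm_mm >= 0, "voxel.fwhm_mm must be >= 0")
  chk(cfg$voxel$neighborhood %in% c(7, 19, 27),
      "voxel.neighborhood must be 7, 19 or 27")
  cn <- cfg$connectome
  chk(cn$step > 0 && cn$s_min > 0 && cn$s_max <= 0.5 && cn$s_min <= cn$s_max,
      "connectome sparsity grid invalid (need 0 < s_min <= s_max <= 0.5, step > 0)")
  chk(cfg$graph$n_rand >= 1, "graph.n_rand must be >= 1")
  chk(cfg$stats$n_perm >= 100, "stats.n_perm must be >= 100")
  chk(cfg$stats$voxel_p > 0 && cfg$stats$voxel_p < 1,
      "stats.voxel_p must lie in (0, 1)")
  chk(cfg$stats$cluster_p > 0 && cfg$stats$cluster_p < 1,
      "stats.cluster_p must lie in (0, 1)")
  chk(cfg$classify$alpha > 0 && cfg$classify$alpha <= 1,
      "classify.alpha must lie in (0, 1]")
  chk(length(cfg$classify$C_grid) >= 1, "classify.C_grid must be nonempty")
  chk(cfg$classify$beta_step > 0 && cfg$classify$beta_step <= 1,
      "classify.beta_step must lie in (0, 1]")
  if (!isTRUE(cfg$simulate$enabled)) {
    chk(!is.null(cfg$input_dir) && dir.exists(cfg$input_dir) &&
          file.exists(file.path(cfg$input_dir, "atlas.nii")),
        "input_dir with atlas.nii required when simulate is disabled")
  }
  ok <- tryCatch(parse_combo(cfg$classify$combo), error = function(e) NULL)
  chk(!is.null(ok), "classify.combo must combine C, G, N")

  if (length(errors$msg) > 0L) {
    stop("config validation failed:\n  ",
         paste(errors$msg, collapse = "\n  "))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing `sub-*_bold.nii`, `sub-*_motion.tsv`,
#'   `atlas.nii` and `covariates.tsv`
#' @return `synthetic_cohort`-shaped list (without ground truth)
#' @export
read_cohort <- function(dir) {
  atlas_vals <- RNifti::readNifti(file.path(dir, "atlas.nii"))
  atlas_vals <- array(as.integer(round(atlas_vals)), dim = dim(atlas_vals))
  n_rois <- max(atlas_vals)
  atlas <- structure(list(labels = atlas_vals, mask = atlas_vals > 0L,
                          n_rois = n_rois, dims = dim(atlas_vals),
                          node_names = if (n_rois == 90L)
                            default_network_table()$name
                          else sprintf("ROI%03d", seq_len(n_rois)),
                          network_labels = if (n_rois == 90L)
                            default_network_table()$network else NULL),
                     class = "atlas_volume")
  covariates <- utils::read.delim(file.path(dir, "covariates.tsv"))
  runs <- lapply(covariates$subject, function(sid) {
    nii <- RNifti::readNifti(file.path(dir, paste0(sid, "_bold.nii")))
    data <- array(as.numeric(nii), dim = dim(nii))
    motion <- utils::read.delim(file.path(dir, paste0(sid, "_motion.tsv")))
    structure(list(data = data, tr_seconds = 2, mask = atlas$mask,
                   motion = motion, nuisance = NULL, subject_id = sid),
              class = "bold_run")
  })
  structure(list(runs = runs, atlas = atlas, covariates = covariates,
                 truth = NULL),
            class = "synthetic_cohort")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> motion QC + preprocessing -> voxel
#' metric maps with permutation-corrected group comparison -> per-subject
#' connectomes over the sparsity grid -> graph-metric curves with null
#' normalization -> FDR-corrected metric group tests -> multi-kernel SVM
#' classification with nested LOOCV and consensus connections. All outputs
#' are written under `out_dir` and hashed into a manifest; rerunning with an
#' identical config reproduces an identical manifest.
#'
#' @param config `run_config` from [validate_config()] (or anything it
#'   accepts)
#' @param out_dir output directory
#' @return invisibly, a list with `manifest`, the in-memory stage results
#'   and the manifest path
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  outputs <- character(0)
  add_out <- function(path) outputs <<- c(outputs, path)

  # --- stage 1: cohort ---
  if (isTRUE(cfg$simulate$enabled)) {
    note("simulate: generating cohort")
    s <- cfg$simulate
    spec <- ground_truth_spec(
      n_per_group = s$n_per_group, grid_dims = s$grid_dims,
      n_rois = s$n_rois, tr_seconds = s$tr_seconds,
      n_volumes = s$n_volumes, band = cfg$preprocess$band,
      amp_effect = unlist(s$amp_effect),
      coherence_effect = unlist(s$coherence_effect),
      edge_effect = if (is.null(s$edge_effect)) NULL else
        as.data.frame(s$edge_effect),
      coherence = s$coherence, noise_sd = s$noise_sd,
      motion_max_mm = s$motion_max_mm, motion_max_deg = s$motion_max_deg,
      seed = cfg$seed)
    cohort <- generate_cohort(spec)
  } else {
    note("load: reading cohort from %s", cfg$input_dir)
    cohort <- read_cohort(cfg$input_dir)
  }
  add_out(write_tsv(cohort$covariates, file.path(out_dir, "covariates.tsv")))
  RNifti::writeNifti(RNifti::asNifti(cohort$atlas$labels),
                     file.path(out_dir, "atlas.nii"))
  add_out(file.path(out_dir, "atlas.nii"))

  # --- stage 2: QC + preprocessing ---
  note("preprocess: %d runs", length(cohort$runs))
  pp_list <- lapply(cohort$runs, preprocess_run,
                    drop = cfg$preprocess$drop, band = cfg$preprocess$band,
                    trans_limit_mm = cfg$preprocess$trans_limit_mm,
                    rot_limit_deg = cfg$preprocess$rot_limit_deg)
  qc <- do.call(rbind, lapply(pp_list, function(p)
    data.frame(subject = p$qc$subject_id, exclude = p$qc$exclude,
               max_translation_mm = p$qc$max_translation_mm,
               max_rotation_deg = p$qc$max_rotation_deg)))
  add_out(write_tsv(qc, file.path(out_dir, "motion_qc.tsv")))

  # --- stage 3: voxel metrics + voxelwise stats ---
  note("voxel-metrics: ALFF/fALFF/ReHo maps")
  tr <- cohort$runs[[1]]$tr_seconds
  vm_list <- lapply(pp_list, voxel_metric_maps, tr_seconds = tr,
                    band = cfg$preprocess$band, fwhm_mm = cfg$voxel$fwhm_mm,
                    voxel_mm = cfg$voxel$voxel_mm,
                    neighborhood = cfg$voxel$neighborhood)
  group <- cohort$covariates$group
  covs <- as.matrix(cohort$covariates[, c("age", "sex", "education", "bmi")])
  # covariates that are constant or confounded with the group column would
  # make the design singular; keep only columns that add rank
  X0 <- cbind(1, group)
  keep <- logical(ncol(covs))
  for (k in seq_len(ncol(covs))) {
    keep[k] <- qr(cbind(X0, covs[, which(keep), drop = FALSE],
                        covs[, k]))$rank ==
      2L + sum(keep) + 1L
  }
  if (!all(keep)) {
    note("stats: dropping collinear/constant covariate(s): %s",
         paste(colnames(covs)[!keep], collapse = ", "))
  }
  covs <- covs[, keep, drop = FALSE]
  if (ncol(covs) == 0L) covs <- NULL
  stat_maps <- list()
  cluster_rows <- list()
  for (metric in c("alff_z", "falff_z", "reho_z")) {
    note("stats: permutation cluster correction for %s (%d perms)", metric,
         cfg$stats$n_perm)
    sm <- permutation_cluster_correct(
      lapply(vm_list, `[[`, metric), group, covs,
      n_perm = cfg$stats$n_perm, voxel_p = cfg$stats$voxel_p,
      cluster_p = cfg$stats$cluster_p,
      seed = (as.numeric(cfg$seed) * 17 + match(metric, c("alff_z", "falff_z", "reho_z"))) %% 2147483647)
    stat_maps[[metric]] <- sm
    f_t <- file.path(out_dir, paste0(metric, "_tmap.nii"))
    RNifti::writeNifti(RNifti::asNifti(sm$t_values), f_t)
    add_out(f_t)
    if (nrow(sm$surviving_clusters) > 0L) {
      cl <- sm$surviving_clusters
      cl$metric <- metric
      cluster_rows[[metric]] <- cl
    }
  }
  clusters <- if (length(cluster_rows) > 0L) do.call(rbind, cluster_rows) else
    data.frame(cluster = integer(0), size = integer(0),
               peak_voxel = integer(0), corrected_p = numeric(0),
               survives = logical(0), metric = character(0))
  add_out(write_tsv(clusters, file.path(out_dir, "clusters.tsv")))

  # --- stage 4-5: connectome + graph metrics ---
  note("connectome: %d-node matrices and sparsity series", cohort$atlas$n_rois)
  cm_list <- lapply(pp_list, function(p) {
    ts <- extract_roi_timeseries(p$bandlimited, cohort$atlas)
    fisher_z(pearson_matrix(ts))
  })
  gs_list <- lapply(cm_list, graph_series, s_min = cfg$connectome$s_min,
                    s_max = cfg$connectome$s_max, step = cfg$connectome$step)
  note("graph: metric curves with %d nulls per threshold", cfg$graph$n_rand)
  curves_list <- lapply(seq_along(gs_list), function(i)
    connectome_curves(gs_list[[i]], n_rand = cfg$graph$n_rand,
                      seed = (as.numeric(cfg$seed) * 1009 + i) %% 2147483647))
  auc_global <- do.call(rbind, lapply(curves_list, function(cv) cv$auc_global))
  add_out(write_tsv(data.frame(subject = cohort$covariates$subject,
                               auc_global),
                    file.path(out_dir, "global_auc.tsv")))

  # --- stage 6: metric group tests ---
  note("stats: FDR-corrected metric group tests")
  mt <- metric_group_tests(curves_list, group, q = cfg$stats$q,
                           covariates = if (isTRUE(cfg$stats$covariates_for_metrics))
                             covs else NULL)
  add_out(write_tsv(mt, file.path(out_dir, "metric_tests.tsv")))

  # --- stage 7: classification ---
  clf <- NULL
  if (isTRUE(cfg$classify$enabled)) {
    note("classify: nested LOOCV, combo %s", cfg$classify$combo)
    feats <- lapply(seq_along(cm_list), function(i)
      assemble_features(cm_list[[i]], curves_list[[i]],
                        subject_id = cohort$covariates$subject[i],
                        group = group[i]))
    clf <- nested_loocv(feats, combo = cfg$classify$combo,
                        alpha = cfg$classify$alpha,
                        C_grid = cfg$classify$C_grid,
                        beta_step = cfg$classify$beta_step, seed = cfg$seed)
    add_out(write_tsv(clf$folds, file.path(out_dir, "folds.tsv")))
    add_out(write_tsv(clf$consensus, file.path(out_dir, "consensus.tsv")))
    add_out(write_tsv(clf$summary$roc, file.path(out_dir, "roc.tsv")))
    summ <- clf$summary[c("accuracy", "sensitivity", "specificity", "auc")]
    jsonlite::write_json(summ, file.path(out_dir, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
    add_out(file.path(out_dir, "classification.json"))
  }

  # --- manifest ---
  checks <- tools::md5sum(sort(unique(outputs)))
  names(checks) <- basename(names(checks))
  manifest <- list(package_version = as.character(utils::packageVersion("connectoscope")),
                   seed = cfg$seed,
                   config = unclass(cfg),
                   files = as.list(checks))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  note("done in %.1f s", elapsed)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(manifest = manifest, manifest_path = manifest_path,
                 cohort = cohort, qc = qc, stat_maps = stat_maps,
                 curves = curves_list, metric_tests = mt,
                 classification = clf))
}
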