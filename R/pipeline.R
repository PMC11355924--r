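#' Experiment configuration
#'
#' Bundles every knob of the generate → curvature → project → measure →
#' (micro-FE) → train → evaluate pipeline. All seeds are explicit: there
#' are no wall-clock defaults, so a config reruns bit-identically.
#'
#' @param n_samples number of synthetic RVEs.
#' @param shape voxels per axis of each RVE.
#' @param spacing voxel size, mm.
#' @param bvtv_range range the per-sample target BV/TV is drawn from.
#' @param corrlen_range range of the generator correlation length (voxels).
#' @param aniso_range range of the z-axis anisotropy stretch (x, y stay 1).
#' @param smooth_sigma surface pre-smoothing for curvature meshes (voxels).
#' @param axis projection axis.
#' @param tasks character subset of `c("histomorphometric", "geometric",
#'   "stiffness")`: which target sets to measure and train on.
#' @param material tissue [material_model()] for the stiffness task.
#' @param fe_element `"tet"` or `"hex"`.
#' @param fe_tol micro-FE PCG tolerance.
#' @param min_bvtv,min_component_size exclusion-filter thresholds.
#' @param train_fraction train split fraction.
#' @param project_valid_only restrict projection images to vertices away
#'   from the cut planes (default TRUE: the clipped caps and rims are
#'   artificial surfaces whose curvature spikes are unrelated to the
#'   microstructure; set FALSE to sum every vertex).
#' @param cnn_overrides named list of [cnn_config()] overrides applied to
#'   every task preset (e.g. `list(n_epochs = 50)`).
#' @param seed master integer seed (required; drives sample seeds, splits,
#'   weight init).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_samples = 20L, shape = 32L, spacing = 0.035,
                              bvtv_range = c(0.1, 0.4),
                              corrlen_range = c(2, 5),
                              aniso_range = c(1, 2.5),
                              smooth_sigma = 1, axis = 3L,
                              tasks = "histomorphometric",
                              material = material_model(),
                              fe_element = "tet", fe_tol = 1e-6,
                              min_bvtv = 0.05, min_component_size = 64L,
                              train_fraction = 0.8, project_valid_only = TRUE,
                              cnn_overrides = list(), seed = NULL) {
  if (is.null(seed)) stop("experiment_config requires an explicit seed")
  tasks <- match.arg(tasks, c("histomorphometric", "geometric", "stiffness"),
                     several.ok = TRUE)
  structure(list(n_samples = as.integer(n_samples), shape = as.integer(shape),
                 spacing = spacing, bvtv_range = bvtv_range,
                 corrlen_range = corrlen_range, aniso_range = aniso_range,
                 smooth_sigma = smooth_sigma, axis = as.integer(axis),
                 tasks = tasks, material = material, fe_element = fe_element,
                 fe_tol = fe_tol, min_bvtv = min_bvtv,
                 min_component_size = as.integer(min_component_size),
                 train_fraction = train_fraction,
                 project_valid_only = isTRUE(project_valid_only),
                 cnn_overrides = cnn_overrides, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Round-trip an experiment config through YAML
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `write_experiment_config` returns `path`;
#'   `read_experiment_config` the config.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$material <- unclass(x$material)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$material <- do.call(material_model, x$material)
  do.call(experiment_config, x)
}

#' Build a synthetic curvature-regression dataset
#'
#' Generates `n_samples` trabecular-like RVEs with per-sample BV/TV,
#' feature size and anisotropy drawn from the configured ranges, runs the
#' curvature pipeline and the measurement stages, and stacks the 4-channel
#' projection images. Samples failing the exclusion filter (or a
#' measurement stage) are recorded with a machine-readable reason and
#' skipped.
#'
#' @param config an [experiment_config()].
#' @param progress print one line every 25 samples.
#' @return list with `images` (H x W x 4 x N array), `targets` (named list
#'   of data.frames per task), `manifest` (per-sample data.frame incl.
#'   exclusions), `config`.
#' @export
build_dataset <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  res <- dim_for_axis <- config$shape
  imgs <- array(0, c(res, res, 4L, 0L))
  img_list <- list()
  rows_h <- list(); rows_g <- list(); rows_s <- list()
  manifest <- list()
  kept <- 0L
  for (i in seq_len(config$n_samples)) {
    seed_i <- config$seed + 1000L + i
    par <- with_seed(seed_i, list(
      bvtv = runif(1, config$bvtv_range[1], config$bvtv_range[2]),
      corrlen = runif(1, config$corrlen_range[1], config$corrlen_range[2]),
      aniso = runif(1, config$aniso_range[1], config$aniso_range[2])))
    spec <- generator_spec(shape = config$shape, target_bvtv = par$bvtv,
                           correlation_length = par$corrlen,
                           anisotropy_scales = c(1, 1, par$aniso),
                           spacing = config$spacing, seed = seed_i)
    rec <- data.frame(sample = i, seed = seed_i, target_bvtv = par$bvtv,
                      correlation_length = par$corrlen, anisotropy = par$aniso,
                      included = FALSE, reason = NA_character_)
    out <- tryCatch({
      vol <- generate_grf_cube(spec)
      filt <- exclusion_filter(vol, config$min_bvtv, config$min_component_size)
      if (!filt$keep) {
        rec$reason <- filt$reason
        NULL
      } else {
        cp <- curvature_pipeline(vol, smooth_sigma = config$smooth_sigma)
        # raw (unscaled) projections: channel ranges are normalized over the
        # training split at training time, mirroring the target rescaling
        stack <- projection_stack(cp$mesh, cp$field, vol, axis = config$axis,
                                  rescale = FALSE,
                                  use_valid = config$project_valid_only)
        targets <- list()
        if ("histomorphometric" %in% config$tasks)
          targets$histomorphometric <-
            histomorphometry(vol, smooth_sigma = config$smooth_sigma,
                             mesh = cp$mesh, da_seed = seed_i)
        if ("geometric" %in% config$tasks) {
          dec <- decompose_trabeculae(vol)
          targets$geometric <- platerod_metrics(dec, vol)
        }
        if ("stiffness" %in% config$tasks) {
          ct <- homogenized_stiffness(vol, config$material,
                                      element = config$fe_element,
                                      tol = config$fe_tol)
          targets$stiffness <-
            as.data.frame(as.list(orthotropic_constants(ct)))
        }
        list(stack = stack, targets = targets)
      }
    }, error = function(e) {
      rec$reason <<- conditionMessage(e)
      NULL
    })
    if (!is.null(out)) {
      kept <- kept + 1L
      rec$included <- TRUE
      img_list[[kept]] <- out$stack
      if (!is.null(out$targets$histomorphometric))
        rows_h[[kept]] <- out$targets$histomorphometric
      if (!is.null(out$targets$geometric))
        rows_g[[kept]] <- out$targets$geometric
      if (!is.null(out$targets$stiffness))
        rows_s[[kept]] <- out$targets$stiffness
    }
    manifest[[i]] <- rec
    if (progress && i %% 25 == 0)
      message(sprintf("generated %d / %d samples", i, config$n_samples))
  }
  if (kept == 0L) stop("no samples survived the exclusion filter")
  images <- array(0, c(res, res, 4L, kept))
  for (k in seq_len(kept)) images[, , , k] <- img_list[[k]]
  targets <- list()
  if (length(rows_h)) targets$histomorphometric <- do.call(rbind, rows_h)
  if (length(rows_g)) targets$geometric <- do.call(rbind, rows_g)
  if (length(rows_s)) targets$stiffness <- do.call(rbind, rows_s)
  list(images = images, targets = targets,
       manifest = do.call(rbind, manifest), config = config)
}

task_preset <- function(task, config) {
  preset <- switch(task, histomorphometric = 1L, geometric = 2L,
                   stiffness = 3L)
  # the pipeline's training protocol: minibatches of 8 with dihedral
  # augmentation/symmetrization (the targets are invariant under in-plane
  # rotations and flips of the volume)
  overrides <- utils::modifyList(list(seed = config$seed, batch_size = 8L,
                                      augment = TRUE),
                                 config$cnn_overrides)
  do.call(cnn_preset, c(list(model = preset), overrides))
}

#' Run a full experiment
#'
#' Builds (or reuses) the dataset, trains one CNN per requested task on an
#' 80/20 split with training-split-only normalization, and writes the
#' manifest, per-sample target tables, per-task test-set reports,
#' predictions and loss histories as CSV into `outdir`. Rerunning with an
#' identical config reproduces all CSV outputs bit-identically.
#'
#' @param config an [experiment_config()].
#' @param outdir output directory (created if missing).
#' @param dataset optional prebuilt [build_dataset()] result.
#' @param progress forwarded to [build_dataset()].
#' @return list with `dataset`, `results` (per task: model, report), and
#'   `outdir`, invisibly.
#' @export
run_experiment <- function(config, outdir, dataset = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(dataset)) dataset <- build_dataset(config, progress)
  write.csv(dataset$manifest, file.path(outdir, "manifest.csv"),
            row.names = FALSE)
  write_experiment_config(config, file.path(outdir, "config.yaml"))
  results <- list()
  for (task in config$tasks) {
    targ <- dataset$targets[[task]]
    ok <- stats::complete.cases(targ)
    cfg <- task_preset(task, config)
    ev <- evaluate_cnn(dataset$images[, , , ok, drop = FALSE],
                       as.matrix(targ[ok, , drop = FALSE]), cfg)
    results[[task]] <- ev
    write.csv(targ, file.path(outdir, paste0("targets_", task, ".csv")),
              row.names = FALSE)
    write.csv(as.data.frame(ev$report),
              file.path(outdir, paste0("report_", task, ".csv")),
              row.names = FALSE)
    write.csv(data.frame(epoch = seq_along(ev$model$loss_history),
                         mse = ev$model$loss_history),
              file.path(outdir, paste0("loss_", task, ".csv")),
              row.names = FALSE)
    pred <- attr(ev$report, "predicted")
    colnames(pred) <- paste0("pred_", colnames(targ))
    write.csv(cbind(data.frame(test_index = ev$split$test), pred),
              file.path(outdir, paste0("predictions_", task, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(task = task,
           r_squared = stats::setNames(as.list(ev$report$r_squared),
                                       ev$report$target)),
      file.path(outdir, paste0("report_", task, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(list(dataset = dataset, results = results, outdir = outdir))
}

#' Channel-ablation run
#'
#' Trains the same architecture using only a subset of the four curvature
#' channels (mirroring single-curvature versus all-curvature input
#' comparisons), under the same split and seeds.
#'
#' @param dataset a [build_dataset()] result.
#' @param channel_subset character subset of `c("k1", "k2", "gaussian",
#'   "mean")`.
#' @param task which target set (default the first configured).
#' @param config optional [experiment_config()] (defaults to the
#'   dataset's).
#' @return an [evaluate_cnn()] result for the reduced input.
#' @export
ablation_run <- function(dataset, channel_subset,
                         task = dataset$config$tasks[1],
                         config = dataset$config) {
  kinds <- c("k1", "k2", "gaussian", "mean")
  if (length(channel_subset) == 0L)
    stop("channel subset must not be empty")
  if (!all(channel_subset %in% kinds))
    stop("channels must be among k1, k2, gaussian, mean")
  ch <- match(unique(channel_subset), kinds)
  targ <- dataset$targets[[task]]
  ok <- stats::complete.cases(targ)
  imgs <- dataset$images[, , ch, ok, drop = FALSE]
  cfg <- task_preset(task, config)
  evaluate_cnn(imgs, as.matrix(targ[ok, , drop = FALSE]), cfg)
}
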