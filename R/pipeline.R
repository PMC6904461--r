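#' Default run configuration
#'
#' Nested configuration for the end-to-end experiments. The defaults
#' reproduce the reference settings: 3000 training and 1000 validation
#' subjects, a synthetic pool of 5015 training and 1528 validation
#' patches, the structural-model constants of [scm_params()], and the
#' network settings of [net_config()]. Sub-seeds for each pipeline stage
#' are derived from the global seed by fixed offsets so stages can be
#' rerun independently.
#'
#' @param ... nested overrides, e.g.
#'   `run_config(cohort = list(train = 750))`.
#' @return A nested list of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 7, network = list(max_epochs = 5))
#' cfg$cohort$train
run_config <- function(...) {
  base <- list(
    seed = 1L,
    output_dir = "colliderfree-output",
    outcome_from_image = FALSE,
    cohort = list(train = 3000L, validation = 1000L),
    scm = unclass(scm_params()),
    imaging = list(n_patches = 6543L, size_range_mm2 = c(20, 600),
                   hetero_range = c(0.05, 4), dim = 100L,
                   spacing_mm = 0.7, train_frac = 5015 / 6543),
    network = unclass(net_config()),
    estimation = list(noise_mse = NULL, n_seeds = 3L))
  over <- list(...)
  validate_config_keys(over, base, "")
  cfg <- utils::modifyList(base, over)
  class(cfg) <- "run_config"
  cfg
}

validate_config_keys <- function(over, base, path) {
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown config field(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(base[[nm]])) && nm != "noise_mse")
      validate_config_keys(over[[nm]], base[[nm]], paste0(path, nm, "$"))
  }
  invisible(TRUE)
}

#' Read a run configuration from a YAML file
#'
#' Unknown fields raise a configuration error listing them.
#'
#' @param path YAML file whose blocks mirror [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Quarter-scale configuration
#'
#' Shrinks a configuration to a quarter of the reference problem size
#' (750/250 subjects, a proportionally smaller pool, 20 training epochs),
#' preserving every scientific setting. Useful for fast smoke runs; the
#' bias ordering between the constrained and unconstrained models is
#' already visible at this scale.
#'
#' @param cfg a [run_config()].
#' @return The rescaled `run_config`.
#' @export
quarter_scale <- function(cfg = run_config()) {
  cfg$cohort$train <- cfg$cohort$train %/% 4L
  cfg$cohort$validation <- cfg$cohort$validation %/% 4L
  cfg$imaging$n_patches <- cfg$imaging$n_patches %/% 4L
  cfg$network$max_epochs <- 20L
  cfg
}

# fixed per-stage seed offsets (kept below 2^31 for any small global seed)
stage_seed <- function(cfg, stage) {
  off <- c(pool = 101L, cohort_train = 202L, cohort_val = 303L,
           baseline_noise = 404L, train = 505L, outcome = 606L)
  as.integer(cfg$seed) + off[[stage]]
}

#' Simulate all experiment inputs
#'
#' Generates the synthetic image pool, samples training and validation
#' cohorts from the structural causal model, and matches each subject to
#' the pool image of its split with the closest standardized measured
#' features. With `outcome_from_image = TRUE` the outcome is re-drawn
#' after matching using the matched image's measured heterogeneity in
#' place of the simulated `z` (an alternative reading of how image and
#' outcome are coupled; the default keeps the simulated `z`).
#'
#' @param cfg a [run_config()].
#' @param pool optionally, a pre-built pool to reuse across replicates.
#' @return A list with `pool`, `cohort_train`, `cohort_val`,
#'   `matched_train`, `matched_val` and a `manifest` of stage seeds and
#'   data fingerprints.
#' @export
simulate_experiment <- function(cfg = run_config(), pool = NULL) {
  if (is.null(pool))
    pool <- generate_synthetic_pool(
      n_patches = cfg$imaging$n_patches,
      size_range_mm2 = cfg$imaging$size_range_mm2,
      hetero_range = cfg$imaging$hetero_range,
      seed = stage_seed(cfg, "pool"),
      spacing_mm = cfg$imaging$spacing_mm,
      dim = cfg$imaging$dim,
      train_frac = cfg$imaging$train_frac)
  params <- do.call(scm_params, cfg$scm)
  co_tr <- sample_cohort(cfg$cohort$train, params,
                         seed = stage_seed(cfg, "cohort_train"))
  co_va <- sample_cohort(cfg$cohort$validation, params,
                         seed = stage_seed(cfg, "cohort_val"))
  ma_tr <- match_images(co_tr, pool, "train")
  ma_va <- match_images(co_va, pool, "validation")
  if (isTRUE(cfg$outcome_from_image)) {
    set.seed(stage_seed(cfg, "outcome"))
    redraw <- function(ma) {
      ma$y <- rnorm(nrow(ma),
                    params$treatment_effect * ma$t +
                      params$coef_z * ma$z_prime +
                      params$coef_u1 * ma$u1 + params$outcome_offset,
                    params$sd_y_noise)
      ma
    }
    ma_tr <- redraw(ma_tr); ma_va <- redraw(ma_va)
  }
  manifest <- list(
    seeds = list(global = cfg$seed,
                 pool = stage_seed(cfg, "pool"),
                 cohort_train = stage_seed(cfg, "cohort_train"),
                 cohort_val = stage_seed(cfg, "cohort_val")),
    fingerprints = list(pool_pixels = sum(pool$pixels),
                        cohort_train_y = sum(co_tr$y),
                        cohort_val_y = sum(co_va$y),
                        matched_train_xprime = sum(ma_tr$x_prime)),
    sizes = list(n_train = nrow(co_tr), n_val = nrow(co_va),
                 pool_train = sum(pool$split == "train"),
                 pool_val = sum(pool$split == "validation")),
    treated_fraction = mean(c(co_tr$t, co_va$t)))
  list(pool = pool, cohort_train = co_tr, cohort_val = co_va,
       matched_train = ma_tr, matched_val = ma_va, manifest = manifest)
}

#' Write simulated artifacts to disk
#'
#' Serializes the pool, cohorts, matched tables and a manifest of seeds
#' and fingerprints under `cfg$output_dir`. Refuses to overwrite an
#' existing manifest unless `overwrite = TRUE`.
#'
#' @param cfg a [run_config()].
#' @param overwrite allow overwriting a previous run.
#' @return The simulation list, invisibly.
#' @export
cmd_simulate <- function(cfg = run_config(), overwrite = FALSE) {
  out <- cfg$output_dir
  manifest_path <- file.path(out, "manifest.yaml")
  if (file.exists(manifest_path) && !overwrite)
    stop("output already exists at ", out, "; use overwrite = TRUE")
  sim <- simulate_experiment(cfg)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  save_pool(sim$pool, file.path(out, "pool"))
  write_cohort(sim$cohort_train, file.path(out, "cohort_train.tsv"))
  write_cohort(sim$cohort_val, file.path(out, "cohort_val.tsv"))
  utils::write.table(sim$matched_train, file.path(out, "matched_train.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$matched_val, file.path(out, "matched_val.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(sim$manifest, manifest_path)
  invisible(sim)
}

# train one network variant and score it post hoc
run_variant <- function(sim, mode, cfg, seed,
                        x_prime_override = NULL) {
  net_cfg <- do.call(net_config, cfg$network)
  ma_tr <- sim$matched_train
  ma_va <- sim$matched_val
  if (!is.null(x_prime_override)) {
    ma_tr$x_prime <- x_prime_override$train
    ma_va$x_prime <- x_prime_override$val
  }
  net <- train_network(ma_tr, ma_va, sim$pool, mode = mode,
                       config = net_cfg, seed = seed)
  all_ma <- rbind(ma_tr, ma_va)
  acts <- extract_activations(net, all_ma, sim$pool)
  tr_idx <- seq_len(nrow(ma_tr))
  fit <- if (mode == "causal")
    causalnet_fit(acts, all_ma$t, all_ma$y, tr_idx, all_ma$x_prime)
  else
    biasednet_fit(acts, all_ma$t, all_ma$y, tr_idx, all_ma$x_prime)
  fit$net <- net
  fit
}

# measurement-noise calibration: explicit override or ground-truth run
calibrate_noise <- function(sim, cfg) {
  if (!is.null(cfg$estimation$noise_mse))
    return(unlist(cfg$estimation$noise_mse))
  ground_truth_measurement_error(sim$matched_train, sim$matched_val,
                                 sim$pool,
                                 config = do.call(net_config, cfg$network),
                                 seed = stage_seed(cfg, "train") + 90L)
}

#' Scale-mismatch sensitivity analysis
#'
#' Retrains the constrained network under collider scale mismatches: the
#' measured collider fed to the collider loss, the independence
#' regularizer and the diagnostics is re-measured on a different scale via
#' [collider_scale_transform()], while the data-generating mechanism and
#' the matching are unchanged. Mode pairs give (actual scale, measured
#' scale): `("area", "area")` re-measures on the raw area scale,
#' `("diameter", "volume")` a power-3 mismatch, `("volume", "diameter")`
#' a power-1/3 mismatch.
#'
#' @param sim a simulation from [simulate_experiment()].
#' @param cfg a [run_config()].
#' @param mode_pairs list of 2-element character vectors.
#' @param seed training seed.
#' @return Named list of `fit_summary` objects, one per pair.
#' @export
sensitivity_suite <- function(sim, cfg = run_config(),
                              mode_pairs = list(c("area", "area"),
                                                c("diameter", "volume"),
                                                c("volume", "diameter")),
                              seed = NULL) {
  if (is.null(seed)) seed <- stage_seed(cfg, "train") + 40L
  fits <- list()
  for (pair in mode_pairs) {
    mode <- pair_to_mode(pair)
    xo <- transform_train_val(sim$matched_train$x_prime,
                              sim$matched_val$x_prime, mode)
    fit <- run_variant(sim, "causal", cfg, seed, x_prime_override = xo)
    fit$model <- "CausalNet"
    fit$variables <- paste0(pair[1], " -> ", pair[2])
    fits[[paste(pair, collapse = "_")]] <- fit
  }
  fits
}

pair_to_mode <- function(pair) {
  key <- paste(tolower(pair), collapse = "/")
  mode <- switch(key, "area/area" = "area", "diameter/volume" = "volume",
                 "volume/diameter" = "diameter")
  if (is.null(mode)) stop("unknown scale pair: ", key)
  mode
}

# power transform standardized with training-set constants only
transform_train_val <- function(x_tr, x_va, mode,
                                meanlog = 2.35, sdlog = 0.285) {
  p <- switch(mode, identity = NA_real_, area = 1, volume = 3,
              diameter = 1 / 3)
  f <- function(x) if (mode == "identity") x else exp(x * sdlog + meanlog)^p
  v_tr <- f(x_tr); v_va <- f(x_va)
  mu <- mean(v_tr); s <- sd(v_tr)
  list(train = (v_tr - mu) / s, val = (v_va - mu) / s)
}

#' Reproduce the main results table
#'
#' Runs, for each replicate seed, the three regression baselines and the
#' two network variants on freshly simulated cohorts (the image pool is
#' generated once and reused), then averages the validation MSE and the
#' estimated ATE across replicates. Rows: regression on `t` only,
#' regression conditioning on the collider (`t, x', z'`), the
#' collider-free regression optimum (`t, z'`), the unconstrained network
#' (BiasedNet) and the constrained network (CausalNet).
#'
#' @param cfg a [run_config()].
#' @param n_seeds number of replicate seeds (default from the config).
#' @return A data.frame with columns `model`, `variables`, `mse_y`, `ate`,
#'   `mse_y_sd`, `ate_sd`, plus attribute `noise_mse` (the calibration
#'   used).
#' @export
reproduce_table2 <- function(cfg = run_config(), n_seeds = NULL) {
  if (is.null(n_seeds)) n_seeds <- cfg$estimation$n_seeds
  pool <- NULL
  noise <- NULL
  per_seed <- list()
  for (k in seq_len(n_seeds)) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + (k - 1L) * 1000L
    sim <- simulate_experiment(cfg_k, pool = pool)
    pool <- sim$pool
    if (is.null(noise)) noise <- calibrate_noise(sim, cfg_k)
    base <- regression_baselines(sim$cohort_train, sim$cohort_val,
                                 noise_mse = noise,
                                 seed = stage_seed(cfg_k, "baseline_noise"))
    bias <- run_variant(sim, "biased", cfg_k, stage_seed(cfg_k, "train") + 1L)
    caus <- run_variant(sim, "causal", cfg_k, stage_seed(cfg_k, "train") + 2L)
    per_seed[[k]] <- summary_table(list(base$t, base$t_xp_zp, base$t_zp,
                                        bias, caus))
  }
  out <- aggregate_replicates(per_seed)
  attr(out, "noise_mse") <- noise
  out
}

#' Reproduce the scale-mismatch sensitivity table
#'
#' @param cfg a [run_config()].
#' @param n_seeds replicate seeds for the reference regression row.
#' @return A data.frame with four rows: the collider-free regression
#'   reference and the three constrained-network scale modes.
#' @export
reproduce_table3 <- function(cfg = run_config(), n_seeds = NULL) {
  if (is.null(n_seeds)) n_seeds <- cfg$estimation$n_seeds
  sim <- simulate_experiment(cfg)
  noise <- calibrate_noise(sim, cfg)
  base <- regression_baselines(sim$cohort_train, sim$cohort_val,
                               noise_mse = noise,
                               seed = stage_seed(cfg, "baseline_noise"))
  base$t_zp$variables <- "area -> area"
  fits <- sensitivity_suite(sim, cfg)
  out <- summary_table(c(list(base$t_zp), fits))
  attr(out, "noise_mse") <- noise
  out
}

aggregate_replicates <- function(per_seed) {
  tab <- per_seed[[1]][, c("model", "variables")]
  mse <- sapply(per_seed, function(d) d$mse_y)
  ate <- sapply(per_seed, function(d) d$ate)
  if (is.null(dim(mse))) { mse <- matrix(mse, ncol = 1); ate <- matrix(ate, ncol = 1) }
  tab$mse_y <- rowMeans(mse)
  tab$ate <- rowMeans(ate)
  tab$mse_y_sd <- apply(mse, 1, sd)
  tab$ate_sd <- apply(ate, 1, sd)
  tab
}

#' Write a results table as TSV plus JSON
#'
#' @param tab a data.frame (e.g. from [reproduce_table2()]).
#' @param path output path without extension; `.tsv` and `.json` files
#'   are written.
#' @return `path`, invisibly.
#' @export
write_report <- function(tab, path) {
  utils::write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(tab, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
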