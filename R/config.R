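#' Full experiment configuration
#'
#' A single serializable object holding every knob of the pipeline, so that
#' a run is a pure function of (config, seeds).  Defaults reproduce the
#' standard study: 1,000 simulations, batch size 8, 50 TAG epochs, 1,000
#' comparator epochs, minimum TPR 0.95.
#'
#' @param n_sims simulations per dataset.
#' @param bounds a [stimulus_bounds()].
#' @param hair a [hair_config()].
#' @param rc an [rc_config()].
#' @param tag_train [train_config()] for the TAG family (and logistic).
#' @param mlp_train [train_config()] for the dense comparators.
#' @param min_tpr tolerated-FPR sensitivity floor.
#' @param roc_steps ROC threshold-grid size.
#' @param seeds evaluation seeds.
#' @param mlp_widths_1 widths swept for the single-hidden-layer comparator.
#' @param mlp_widths_3 widths swept for the three-hidden-layer comparator.
#' @param output_dir where [run_paper_pipeline()] writes artifacts.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_sims = 1000L,
                              bounds = stimulus_bounds(),
                              hair = hair_config(),
                              rc = rc_config(),
                              tag_train = train_config("rmsprop",
                                                       epochs = 50L),
                              mlp_train = train_config("adam", lr = 1e-3,
                                                       epochs = 1000L,
                                                       lambda = 0),
                              min_tpr = 0.95, roc_steps = 1001L,
                              seeds = 1:5,
                              mlp_widths_1 = 2^(1:10),
                              mlp_widths_3 = 2^(1:8),
                              output_dir = "cercatag_run") {
  structure(list(n_sims = as.integer(n_sims), bounds = bounds, hair = hair,
                 rc = rc, tag_train = tag_train, mlp_train = mlp_train,
                 min_tpr = min_tpr, roc_steps = as.integer(roc_steps),
                 seeds = as.integer(seeds),
                 mlp_widths_1 = as.integer(mlp_widths_1),
                 mlp_widths_3 = as.integer(mlp_widths_3),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' Checks every range and invariant and returns the violations as
#' human-readable messages (an empty character vector means the config is
#' valid); never throws.
#'
#' @param config an [experiment_config()]-shaped list.
#' @return character vector of violations.
#' @export
validate_config <- function(config) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  if (config$n_sims < 1) add("n_sims must be >= 1")
  b <- config$bounds
  for (nm in c("intensity", "attack_angle", "attack_speed", "attacker_size")) {
    r <- b[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      add(sprintf("stimulus bound '%s' must satisfy lo <= hi", nm))
  }
  if (any(b$attack_angle < 0 | b$attack_angle >= 360))
    add("attack-angle bounds must lie in [0, 360)")
  if (any(b$attack_speed <= 0)) add("attack speed must be positive")
  if (any(b$attacker_size < 0 | b$attacker_size > 1))
    add("attacker size must lie in [0, 1]")
  h <- config$hair
  if (h$n_hairs < 1) add("n_hairs must be >= 1")
  if (h$beta1 < 0 || h$beta1 > 1) add("beta1 must lie in [0, 1]")
  if (h$beta2 < 0 || h$beta2 > 1) add("beta2 must lie in [0, 1]")
  if (h$alpha <= 0) add("alpha must be positive")
  if (h$short_baseline_factor <= 0 || h$short_baseline_factor > 1)
    add("short_baseline_factor must lie in (0, 1]")
  r <- config$rc
  if (r$dt <= 0) add("integration step dt must be positive")
  if (r$dt >= r$R * r$C) add("dt must be below the RC time constant")
  for (tc_name in c("tag_train", "mlp_train")) {
    tc <- config[[tc_name]]
    if (tc$batch_size < 1) add(sprintf("%s: batch_size must be >= 1", tc_name))
    if (tc$epochs < 1) add(sprintf("%s: epochs must be >= 1", tc_name))
    if (tc$lambda < 0 || tc$l1 < 0)
      add(sprintf("%s: regularization coefficients must be >= 0", tc_name))
  }
  if (config$min_tpr <= 0 || config$min_tpr > 1)
    add("min_tpr must lie in (0, 1]")
  if (config$roc_steps < 2) add("roc_steps must be >= 2")
  if (!length(config$seeds)) add("at least one seed is required")
  v
}

#' Write/read an experiment configuration as YAML
#'
#' Round-trips through a plain-text file: `read_config(write_config(x))`
#' reproduces `x`.
#'
#' @param config an `experiment_config`.
#' @param path YAML file path.
#' @return `path` (write) / the config (read).
#' @export
write_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- experiment_config(
    n_sims = raw$n_sims,
    bounds = do.call(stimulus_bounds, raw$bounds),
    hair = do.call(hair_config, raw$hair),
    rc = do.call(rc_config, raw$rc),
    tag_train = do.call(train_config, raw$tag_train),
    mlp_train = do.call(train_config, raw$mlp_train),
    min_tpr = raw$min_tpr, roc_steps = raw$roc_steps, seeds = raw$seeds,
    mlp_widths_1 = raw$mlp_widths_1, mlp_widths_3 = raw$mlp_widths_3,
    output_dir = raw$output_dir)
  cfg
}

config_hash <- function(config) {
  # cheap content stamp: sum of the serialized bytes, hex-coded
  bytes <- serialize(rapply(unclass(config), as.numeric,
                            classes = "numeric", how = "list"), NULL)
  sprintf("%08x", sum(as.integer(bytes)) %% .Machine$integer.max)
}

#' Run the full study pipeline
#'
#' Composes dataset generation, TAG ablation training, the comparator width
#' sweep and evaluation, writing every artifact (datasets, trained
#' parameters, reports) under `config$output_dir`; each file name carries the
#' seed, and a manifest records the config hash.
#'
#' @param config an [experiment_config()].
#' @param mlp_seeds seeds used for the comparator sweep (defaults to the
#'   first evaluation seed).
#' @return list with `ablation`, `mlp_sweep`, `manifest` (invisibly also
#'   written to disk).
#' @export
run_paper_pipeline <- function(config = experiment_config(),
                               mlp_seeds = config$seeds[1]) {
  issues <- validate_config(config)
  if (length(issues))
    stopf("invalid config:\n  %s", paste(issues, collapse = "\n  "))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- config_hash(config)
  stage <- function(name, expr) {
    message(sprintf("[cercatag] stage %s", name))
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  datasets <- stage("build-dataset", lapply(config$seeds, function(s)
    build_dataset(config$n_sims, config$bounds, config$hair, config$rc,
                  seed = s)))
  for (i in seq_along(config$seeds))
    write_dataset_csv(datasets[[i]],
                      file.path(config$output_dir,
                                sprintf("dataset_seed%d_%s.csv",
                                        config$seeds[i], stamp)))
  ablation <- stage("ablation", run_ablation(
    seeds = config$seeds, n_sims = config$n_sims, bounds = config$bounds,
    hair = config$hair, rc = config$rc, cfg = config$tag_train,
    min_tpr = config$min_tpr, datasets = datasets))
  utils::write.csv(ablation$runs,
                   file.path(config$output_dir,
                             sprintf("ablation_%s.csv", stamp)),
                   row.names = FALSE)
  full <- ablation$params[["TAG I+L+G"]][[as.character(config$seeds[1])]]
  write_tag_params(full, file.path(config$output_dir,
                                   sprintf("tag_ILG_seed%d_%s.json",
                                           config$seeds[1], stamp)))
  write_weight_report(weight_report(full),
                      file.path(config$output_dir, "weight_report"))
  specs <- c(lapply(config$mlp_widths_1, function(w) mlp_spec(1, w)),
             lapply(config$mlp_widths_3, function(w) mlp_spec(3, w)))
  mlp <- stage("mlp-sweep", run_mlp_sweep(
    datasets[[1]], specs, config$mlp_train, seeds = mlp_seeds,
    min_tpr = config$min_tpr))
  utils::write.csv(mlp$runs,
                   file.path(config$output_dir,
                             sprintf("mlp_sweep_%s.csv", stamp)),
                   row.names = FALSE)
  manifest <- list(config_hash = stamp, seeds = config$seeds,
                   n_sims = config$n_sims,
                   files = list.files(config$output_dir, recursive = TRUE))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(ablation = ablation, mlp_sweep = mlp, manifest = manifest))
}
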