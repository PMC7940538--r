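#' ROC curve over a regular threshold grid
#'
#' The jump output is rectified into a binary decision by `score >=
#' threshold` as the threshold sweeps a regular grid on `[0, 1]`; true and
#' false positive rates are recorded at every threshold.
#'
#' @param scores predicted jump probabilities.
#' @param labels 0/1 attack labels (both classes must be present).
#' @param n_steps number of grid thresholds (default 1001).
#' @return data.frame of class `tag_roc` with columns `threshold`, `tpr`,
#'   `fpr`.
#' @export
roc_curve <- function(scores, labels, n_steps = 1001L) {
  if (length(scores) != length(labels))
    stopf("scores and labels differ in length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stopf("ROC needs at least one positive and one negative label")
  thresholds <- seq(0, 1, length.out = n_steps)
  # counts of scores >= t via the empirical CDF evaluated just below t
  pos <- sort(scores[labels == 1])
  neg <- sort(scores[labels == 0])
  tpr <- vapply(thresholds,
                function(t) sum(pos >= t) / n_pos, numeric(1))
  fpr <- vapply(thresholds,
                function(t) sum(neg >= t) / n_neg, numeric(1))
  structure(data.frame(threshold = thresholds, tpr = tpr, fpr = fpr),
            class = c("tag_roc", "data.frame"))
}

#' Tolerated false-positive rate
#'
#' The FPR that must be accepted to guarantee a minimum TPR: the minimum
#' FPR among grid thresholds whose TPR is at least `min_tpr` (by
#' monotonicity, the FPR at the largest such threshold).  If no threshold
#' attains `min_tpr` the trivial all-positive operating point (FPR 1) is
#' returned with a warning.
#'
#' @param roc a [roc_curve()] result.
#' @param min_tpr minimum true positive rate (default 0.95).
#' @return FPR in `[0, 1]`.
#' @export
tolerated_fpr <- function(roc, min_tpr = 0.95) {
  ok <- roc$tpr >= min_tpr
  if (!any(ok)) {
    warning("no threshold attains the minimum TPR; returning FPR at threshold 0")
    return(1)
  }
  min(roc$fpr[ok])
}

#' Akaike information criterion of a classifier
#'
#' `AIC = 2 k + 2 NLL` with `k` the number of trainable parameters
#' (including biases) and `NLL` the summed Bernoulli negative log-likelihood
#' of the jump output on the evaluation split.
#'
#' @param n_params trainable parameter count `k`.
#' @param scores predicted probabilities.
#' @param labels 0/1 labels.
#' @return AIC value.
#' @export
aic_score <- function(n_params, scores, labels) {
  p <- clip_prob(scores)
  nll <- -sum(labels * log(p) + (1 - labels) * log(1 - p))
  2 * n_params + 2 * nll
}

# jump scores of either model family on a split
model_scores <- function(params, dataset, split = "test") {
  d <- dataset_matrices(dataset, split)
  scores <- if (inherits(params, "tag_params"))
    tag_forward(params, d$X)$jump
  else mlp_forward(params, d$X)$jump
  list(scores = scores, labels = d$y)
}

#' Evaluate a trained model on the held-out split
#'
#' @param params trained `tag_params` or `mlp_params`.
#' @param dataset a `tag_dataset`.
#' @param min_tpr minimum TPR for the tolerated-FPR metric.
#' @param n_steps ROC threshold-grid size.
#' @param split evaluation split.
#' @return list of class `eval_report`: `model`, `n_params` (incl. biases),
#'   `tolerated_fpr`, `aic`, `roc`.
#' @export
evaluate_model <- function(params, dataset, min_tpr = 0.95,
                           n_steps = 1001L, split = "test") {
  sc <- model_scores(params, dataset, split)
  roc <- roc_curve(sc$scores, sc$labels, n_steps)
  if (inherits(params, "tag_params")) {
    variant <- attr(params, "mask")$variant
    k <- count_parameters(variant, include_biases = TRUE)
    id <- paste0("TAG ", variant)
  } else {
    spec <- attr(params, "spec")
    k <- mlp_count_parameters(spec)
    id <- if (spec$n_hidden_layers == 0) "logistic"
          else sprintf("MLP %dx%d", spec$n_hidden_layers, spec$width)
  }
  structure(list(model = id, n_params = k,
                 tolerated_fpr = tolerated_fpr(roc, min_tpr),
                 aic = aic_score(k, sc$scores, sc$labels), roc = roc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %-12s params %5d  tolerated FPR %.4f  AIC %.1f\n",
              x$model, x$n_params, x$tolerated_fpr, x$aic))
  invisible(x)
}

#' Ablation study of the TAG architecture
#'
#' For each seed, a fresh dataset is generated and every ablation variant
#' (plus the logistic comparator) is trained on it with shared mini-batches,
#' then evaluated on the held-out split.
#'
#' @param seeds integer seeds (>= 1 of them); datasets and batch orders are
#'   derived from these.
#' @param n_sims simulations per dataset.
#' @param variants TAG variants to include.
#' @param include_logistic also train the logistic comparator?
#' @param bounds,hair,rc generator configuration.
#' @param cfg a [train_config()] template (its seed is overridden per run).
#' @param min_tpr tolerated-FPR sensitivity floor.
#' @param datasets optional pre-built list of datasets, one per seed.
#' @return list with `runs` (data.frame: seed, model, n_params,
#'   tolerated_fpr, aic), `medians` (data.frame per model) and `params`
#'   (trained parameter objects indexed `[[model]][[seed]]`).
#' @export
run_ablation <- function(seeds = 1:5, n_sims = 1000,
                         variants = tag_variants(),
                         include_logistic = TRUE,
                         bounds = stimulus_bounds(), hair = hair_config(),
                         rc = rc_config(), cfg = train_config(),
                         min_tpr = 0.95, datasets = NULL) {
  stopifnot(length(seeds) >= 1)
  rows <- list()
  params_out <- list()
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    ds <- if (!is.null(datasets)) datasets[[si]]
          else build_dataset(n_sims, bounds, hair, rc, seed = seed)
    run_cfg <- cfg
    run_cfg$seed <- as.integer(seed)
    models <- list()
    for (v in variants) models[[paste0("TAG ", v)]] <- tag_init(tag_masks(v))
    if (include_logistic) models[["logistic"]] <- logistic_model(seed = seed)
    for (nm in names(models)) {
      trained <- train_model(models[[nm]], ds, run_cfg)
      rep <- evaluate_model(trained, ds, min_tpr)
      rows[[length(rows) + 1L]] <-
        data.frame(seed = seed, model = rep$model, n_params = rep$n_params,
                   tolerated_fpr = rep$tolerated_fpr, aic = rep$aic,
                   stringsAsFactors = FALSE)
      params_out[[nm]][[as.character(seed)]] <- trained
    }
  }
  runs <- do.call(rbind, rows)
  medians <- stats::aggregate(cbind(tolerated_fpr, aic) ~ model, runs, stats::median)
  list(runs = runs, medians = medians, params = params_out)
}

#' Width sweep of the dense comparators
#'
#' Trains an MLP per (hidden-layer count, width, seed) on the supplied
#' dataset with Adam over the same mini-batch stream as the TAG runs, and
#' evaluates tolerated FPR and AIC.
#'
#' @param dataset a `tag_dataset`.
#' @param specs list of [mlp_spec()]s; default covers the logarithmic sweep
#'   `{2,4,...,1024}` for one hidden layer and `{2,...,256}` for three.
#' @param cfg a [train_config()] template (Adam, 1,000 epochs by default).
#' @param seeds seeds for initialization and batch order.
#' @param min_tpr tolerated-FPR sensitivity floor.
#' @return list with `runs` data.frame (model, layers, width, n_params,
#'   seed, tolerated_fpr, aic) and `params` (trained models, named
#'   `"<model> seed<seed>"`).
#' @export
run_mlp_sweep <- function(dataset, specs = default_mlp_specs(),
                          cfg = train_config("adam", lr = 1e-3,
                                             epochs = 1000L, lambda = 0),
                          seeds = 1L, min_tpr = 0.95) {
  rows <- list()
  params_out <- list()
  for (spec in specs) for (seed in seeds) {
    run_cfg <- cfg
    run_cfg$seed <- as.integer(seed)
    model <- build_mlp(spec, seed = seed)
    trained <- train_model(model, dataset, run_cfg)
    rep <- evaluate_model(trained, dataset, min_tpr)
    rows[[length(rows) + 1L]] <-
      data.frame(model = rep$model, layers = spec$n_hidden_layers,
                 width = spec$width, n_params = rep$n_params, seed = seed,
                 tolerated_fpr = rep$tolerated_fpr, aic = rep$aic,
                 stringsAsFactors = FALSE)
    params_out[[sprintf("%s seed%d", rep$model, seed)]] <- trained
  }
  list(runs = do.call(rbind, rows), params = params_out)
}

#' @rdname run_mlp_sweep
#' @export
default_mlp_specs <- function() {
  c(lapply(2^(1:10), function(w) mlp_spec(1, w)),
    lapply(2^(1:8), function(w) mlp_spec(3, w)))
}

#' Pruning sweep of a trained comparator
#'
#' Magnitude-prunes the trained network at each percentile of the grid and
#' re-evaluates the tolerated FPR without retraining; reports the first grid
#' percentile at which the tolerated FPR strictly exceeds the TAG reference.
#'
#' @param trained a trained `mlp_params`.
#' @param dataset a `tag_dataset`.
#' @param percents pruning percentiles.
#' @param tag_reference the TAG tolerated FPR against which the crossing is
#'   located (optional).
#' @param min_tpr sensitivity floor.
#' @return list with `table` (pct, n_surviving, tolerated_fpr) and
#'   `crossing` (row at the first exceedance, or NULL).
#' @export
run_prune_sweep <- function(trained, dataset, percents = seq(0, 100, by = 5),
                            tag_reference = NULL, min_tpr = 0.95) {
  rows <- lapply(percents, function(pct) {
    pr <- prune_by_percentile(trained, pct)
    sc <- model_scores(pr$params, dataset)
    fpr <- if (stats::sd(sc$scores) == 0) 1
           else tolerated_fpr(roc_curve(sc$scores, sc$labels), min_tpr)
    data.frame(pct = pct, n_surviving = pr$n_surviving,
               tolerated_fpr = fpr)
  })
  tab <- do.call(rbind, rows)
  crossing <- NULL
  if (!is.null(tag_reference)) {
    hit <- which(tab$tolerated_fpr > tag_reference)
    if (length(hit)) crossing <- tab[min(hit), ]
  }
  list(table = tab, crossing = crossing)
}

#' Parameter-perturbation robustness of a trained TAG model
#'
#' Perturbs every masked weight with multiplicative or additive Gaussian
#' noise and re-evaluates the tolerated FPR without retraining.
#'
#' @param params trained `tag_params`.
#' @param dataset a `tag_dataset`.
#' @param noise_levels standard deviations of the perturbation.
#' @param n_draws Monte-Carlo draws per level.
#' @param mode `"multiplicative"` (`w * (1 + eps)`) or `"additive"`
#'   (`w + eps`).
#' @param seed RNG seed.
#' @param min_tpr sensitivity floor.
#' @return data.frame: noise level, mean, sd of tolerated FPR over draws.
#' @export
robustness_sweep <- function(params, dataset,
                             noise_levels = c(0, 0.1, 0.2, 0.5),
                             n_draws = 10L, mode = c("multiplicative",
                                                     "additive"),
                             seed = 1L, min_tpr = 0.95) {
  mode <- match.arg(mode)
  mask <- attr(params, "mask")
  msk <- tag_mask_numeric(mask)
  set.seed(seed)
  rows <- lapply(noise_levels, function(lv) {
    fprs <- vapply(seq_len(n_draws), function(i) {
      p <- params
      for (nm in c("W_ff", "W_lat", "glob_out", "w_jump")) {
        eps <- array(rnorm(length(p[[nm]]), 0, lv), dim = dim(p[[nm]]) %||%
                       length(p[[nm]]))
        p[[nm]] <- if (mode == "multiplicative") p[[nm]] * (1 + eps)
                   else p[[nm]] + eps * msk[[nm]]
      }
      sc <- model_scores(p, dataset)
      if (stats::sd(sc$scores) == 0) 1
      else tolerated_fpr(roc_curve(sc$scores, sc$labels), min_tpr)
    }, numeric(1))
    data.frame(noise = lv, mean_fpr = mean(fprs), sd_fpr = stats::sd(fprs))
  })
  do.call(rbind, rows)
}

#' Interpretation tables of a trained TAG model
#'
#' Lays the optimized weights out as pre/post-synaptic tables: feed-forward
#' (16 inputs x 7 interneurons, unconnected cells `NA`), lateral (7 x 7),
#' jump (1 x 7) and the 8 biases.
#'
#' @param params trained `tag_params` (any variant).
#' @return list of class `weight_report` with data.frames `ff` (16 x 7),
#'   `lateral` (7 x 7), `jump` (1 x 7) and `biases` (named, 8).
#' @export
weight_report <- function(params) {
  mask <- attr(params, "mask")
  ff <- t(params$W_ff)
  ff[t(!mask$ff)] <- NA_real_
  lat_full <- params$W_lat
  lat_full[!mask$lat] <- NA_real_
  # glob's outgoing regulatory synapses fill the glob (pre) column so the
  # 7 x 7 layout covers every pre/post interneuron pair
  if (mask$has_glob) lat_full[1:6, "glob"] <- params$glob_out
  jump <- as.data.frame(t(params$w_jump))
  jump[!mask$jump] <- NA_real_
  biases <- c(params$b, jump_bias = params$b_jump)
  biases[c(!mask$b, FALSE)] <- NA_real_
  structure(list(ff = as.data.frame(ff), lateral = as.data.frame(lat_full),
                 jump = jump, biases = biases),
            class = "weight_report")
}

#' Write a weight report as CSV tables
#'
#' @param report a [weight_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_weight_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$ff, file.path(dir, "weights_feedforward.csv"))
  utils::write.csv(report$lateral, file.path(dir, "weights_lateral.csv"))
  utils::write.csv(report$jump, file.path(dir, "weights_jump.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(neuron = names(report$biases),
                              bias = as.numeric(report$biases)),
                   file.path(dir, "biases.csv"), row.names = FALSE)
  invisible(dir)
}
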