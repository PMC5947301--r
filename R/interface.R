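#' Default run configuration
#'
#' The nested configuration driving a full run, with every default at its
#' standard value: 100/200/400 units, 10 x 10 motor and 10 x 20 visual
#' grids, command range -20..20 degrees, visual range 0..3 arm-units and
#' -90..90 degrees, joint range 0..180 degrees, learning rate 0.05, visual
#' availability 0.8 and 1,200,000 learning iterations; one-step tests from
#' posture (30, 60); reaching from posture (20, 40) with 7 targets at
#' distance 2 (4 loop iterations) and distance 3 (7 iterations).
#'
#' @return a nested list of class `run_config` with sections `arm`,
#'   `coding`, `network`, `training` and `experiments`.
#' @export
default_config <- function() {
  structure(list(
    arm = list(segment_length = 1, joint_range = c(0, 180)),
    coding = list(command_range = 20, distance_range = c(0, 3),
                  azimuth_range = c(-90, 90), n_motor_per_dim = c(10, 10),
                  n_visual_per_dim = c(10, 20)),
    network = list(n_hidden = 400, init_range = 0.1),
    training = list(eta = 0.05, n_iterations = 1200000,
                    visual_availability = 0.8, seed = 1,
                    checkpoint_every = NULL, episode_reset_every = NULL),
    experiments = list(
      forward_test = list(initial = c(30, 60), init_iterations = 20),
      inverse_test = list(initial = c(30, 60), init_iterations = 20),
      reach_within = list(distance = 2, azimuths = seq(-90, 90, by = 30),
                          n_loop = 4, initial = c(20, 40),
                          init_iterations = 20),
      reach_beyond = list(distance = 3, azimuths = seq(-90, 90, by = 30),
                          n_loop = 7, initial = c(20, 40),
                          init_iterations = 20)
    )
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Reads a (possibly partial, possibly empty) YAML file and merges it over
#' [default_config()]. An empty file therefore yields the full standard
#' configuration. Unknown keys at any nesting level are rejected, and the
#' merged configuration is validated (e.g. a non-positive learning rate is
#' a configuration error naming the field).
#'
#' @param path path to a YAML file.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_config()), user, path = character())
  cfg <- structure(cfg, class = "run_config")
  as_train_config(cfg)  # runs the field validations
  cfg
}

merge_config <- function(base, user, path) {
  if (!is.list(user)) {
    stop(sprintf("config section `%s` must be a mapping",
                 paste(path, collapse = ".")), call. = FALSE)
  }
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste(paste(c(path, ""), collapse = "."), unknown,
                       sep = "", collapse = ", ")), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], c(path, k))
    } else {
      # base[k] <- list(...) so an explicit null (YAML `~`) stays an entry
      base[k] <- list(unlist(user[[k]], use.names = FALSE))
    }
  }
  base
}

#' Save a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# flatten the nested run config into the trainer's flat train_config
as_train_config <- function(config, seed = NULL) {
  tr <- config$training
  train_config(
    eta = tr$eta, n_iterations = tr$n_iterations,
    visual_availability = tr$visual_availability,
    command_range = config$coding$command_range,
    joint_range = config$arm$joint_range,
    segment_length = config$arm$segment_length,
    distance_range = config$coding$distance_range,
    azimuth_range = config$coding$azimuth_range,
    n_motor_per_dim = config$coding$n_motor_per_dim,
    n_visual_per_dim = config$coding$n_visual_per_dim,
    n_hidden = config$network$n_hidden,
    init_range = config$network$init_range,
    seed = if (is.null(seed)) tr$seed else seed,
    checkpoint_every = tr$checkpoint_every,
    episode_reset_every = tr$episode_reset_every
  )
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Save / load a trained model
#'
#' The model file is self-describing: it carries the weight matrices, both
#' tuning-grid specifications, the full training configuration with its
#' hash and seed, and the iteration count, so any saved model can be probed
#' or re-scored without the session that created it.
#'
#' @param model a `reach_model`.
#' @param path file path (RDS container).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `reach_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "reach_model"))
  payload <- list(format = "reachnet-model", format_version = 1L,
                  package_version = as.character(utils::packageVersion("reachnet")),
                  config_hash = config_hash(model$config),
                  model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$format, "reachnet-model")) {
    stop(sprintf("`%s` is not a reachnet model file", path), call. = FALSE)
  }
  payload$model
}

#' Run the full experiment suite
#'
#' Trains a model (or reuses a supplied one), then runs the one-step
#' forward and inverse transformation tests and the within-reach and
#' out-of-reach reaching simulations, writing every table as CSV into
#' `out_dir`: `training_log.csv`, `forward_test.csv`, `inverse_test.csv`,
#' `reach_within.csv`, `reach_beyond.csv` (one block of rows per target),
#' and `summary.csv` with the headline metrics. The trained model is saved
#' as `model.rds`. Identical seed and configuration reproduce every number.
#'
#' @param config a `run_config` (default [default_config()]).
#' @param seed overrides `config$training$seed` when not `NULL`.
#' @param out_dir output directory, created if needed.
#' @param model optional pre-trained `reach_model` to reuse instead of
#'   training.
#' @return invisibly, a list with the trained model, all result tables and
#'   the summary metrics.
#' @export
run_experiment_suite <- function(config = default_config(), seed = NULL,
                                 out_dir = "reachnet-results", model = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tcfg <- as_train_config(config, seed = seed)
  if (is.null(model)) {
    message(sprintf("training: %s iterations, seed %d (config %s)",
                    format(tcfg$n_iterations, big.mark = ","), tcfg$seed,
                    config_hash(config)))
    model <- train(tcfg)
  }
  ex <- config$experiments

  fwd <- test_forward(model, initial = ex$forward_test$initial,
                      init_iterations = ex$forward_test$init_iterations)
  inv <- test_inverse(model, initial = ex$inverse_test$initial,
                      init_iterations = ex$inverse_test$init_iterations)
  run_reaches <- function(ex_spec) {
    tg <- reach_targets(ex_spec$distance, ex_spec$azimuths)
    do.call(rbind, lapply(seq_len(nrow(tg)), function(i) {
      tr <- reach(model, target = c(tg$r[i], tg$theta[i]),
                  initial = ex_spec$initial, n_loop = ex_spec$n_loop,
                  init_iterations = ex_spec$init_iterations)
      cbind(target_id = i, target_r = tg$r[i], target_theta = tg$theta[i],
            as.data.frame(tr))
    }))
  }
  within_df <- run_reaches(ex$reach_within)
  beyond_df <- run_reaches(ex$reach_beyond)

  summary_df <- suite_summary(model, fwd, inv, within_df, beyond_df)

  write_table <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = 6)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  if (!is.null(model$log)) write_table(model$log, "training_log.csv")
  write_table(fwd, "forward_test.csv")
  write_table(inv, "inverse_test.csv")
  write_table(within_df, "reach_within.csv")
  write_table(beyond_df, "reach_beyond.csv")
  write_table(summary_df, "summary.csv")
  save_model(model, file.path(out_dir, "model.rds"))

  invisible(list(model = model, forward_test = fwd, inverse_test = inv,
                 reach_within = within_df, reach_beyond = beyond_df,
                 summary = summary_df))
}

suite_summary <- function(model, fwd, inv, within_df, beyond_df) {
  final_rows <- function(df) df[df$step == max(df$step), ]
  first_rows <- function(df) df[df$step == 0, ]
  wf <- final_rows(within_df); w0 <- first_rows(within_df)
  bf <- final_rows(beyond_df)
  lateral <- abs(bf$target_theta) >= 60
  data.frame(
    metric = c("forward_probe_err_mean", "inverse_dist_gain_mean",
               "inverse_toward_target_frac",
               "within_initial_dist_mean", "within_final_dist_mean",
               "within_final_dist_ipsi", "within_final_dist_contra",
               "beyond_final_r_mean", "beyond_azimuth_sign_agreement"),
    value = c(mean(fwd$err), mean(inv$dist_gain),
              mean(inv$dist_gain < 0),
              mean(w0$dist_to_target), mean(wf$dist_to_target),
              mean(wf$dist_to_target[wf$target_theta > 0]),
              mean(wf$dist_to_target[wf$target_theta < 0]),
              mean(bf$r),
              mean(sign(bf$theta[lateral]) ==
                     sign(bf$target_theta[lateral])))
  )
}
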