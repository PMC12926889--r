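#' Write and read a trial dataset as CSV
#'
#' Serialises a `trial_data` object as two CSV files: `baseline.csv` (one
#' row per participant) and `longitudinal.csv` (one row per participant x
#' time point), the long-format interchange schema of the pipeline.
#'
#' @param data `trial_data` object.
#' @param dir output directory.
#' @return the directory, invisibly; `read_trial_csv` returns a
#'   `trial_data` object (without the generating config).
#' @export
write_trial_csv <- function(data, dir) {
  stopifnot(inherits(data, "trial_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE)
  utils::write.csv(data$longitudinal, file.path(dir, "longitudinal.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(dir) {
  bl <- utils::read.csv(file.path(dir, "baseline.csv"),
                        stringsAsFactors = FALSE)
  bl$arm <- factor(bl$arm, levels = trial_arms())
  bl$gender <- factor(bl$gender, levels = c("female", "male", "diverse"))
  bl$city_size <- factor(bl$city_size, levels = c("rural", "town", "city"))
  bl$living_situation <- factor(bl$living_situation,
                                levels = c("alone", "partner", "family"))
  lg <- utils::read.csv(file.path(dir, "longitudinal.csv"),
                        stringsAsFactors = FALSE)
  structure(list(baseline = bl, longitudinal = lg, config = NULL),
            class = "trial_data")
}

#' Serialise / reconstitute an imputation stack
#'
#' The stack is written as one CSV per completed dataset plus a YAML
#' manifest carrying M, iteration count, seed and per-variable methods.
#'
#' @param stack `imputation_stack`.
#' @param dir output directory.
#' @export
write_stack_csv <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in seq_len(stack$M))
    utils::write.csv(stack$imputations[[m]],
                     file.path(dir, sprintf("imputation_%02d.csv", m)),
                     row.names = FALSE)
  yaml::write_yaml(list(M = stack$M, iterations = stack$iterations,
                        seed = stack$seed,
                        method = as.list(stack$method)),
                   file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "stack.yaml"))
  imps <- lapply(seq_len(meta$M), function(m) {
    tt <- utils::read.csv(file.path(dir, sprintf("imputation_%02d.csv", m)),
                          stringsAsFactors = FALSE)
    tt$arm <- factor(tt$arm, levels = trial_arms())
    tt$gender <- factor(tt$gender, levels = c("female", "male", "diverse"))
    tt$city_size <- factor(tt$city_size,
                           levels = c("rural", "town", "city"))
    tt$living_situation <- factor(tt$living_situation,
                                  levels = c("alone", "partner", "family"))
    tt
  })
  structure(list(imputations = imps,
                 method = unlist(meta$method), M = meta$M,
                 iterations = meta$iterations, seed = meta$seed,
                 trace = NULL),
            class = "imputation_stack")
}

#' Read / write a trial configuration as YAML
#'
#' @param config a [trial_config()].
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$cost_params <- as.list(x$cost_params)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cp <- if (!is.null(x$cost_params))
    as.data.frame(x$cost_params, stringsAsFactors = FALSE) else NULL
  trial_config(
    n_per_arm = x$n_per_arm %||% 329L,
    n_centres = x$n_centres %||% 5L,
    n_practices = x$n_practices %||% 64L,
    arm_effects = x$arm_effects,
    cost_params = cp,
    missing_rate_target = x$missing_rate_target %||% 0.20,
    p_diverse = x$p_diverse %||% 0.008,
    effect_modifier = x$effect_modifier,
    seed = x$seed %||% 1L)
}
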