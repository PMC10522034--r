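#' Behavioural noise model for synthetic participants
#'
#' Motor noise is i.i.d. Gaussian execution noise added to the initiation
#' output `y_t0` before the midpoint error is computed, so it propagates
#' through the feedback correction and the learning updates, the way a real
#' participant's execution variability enters the loop. Observation noise is
#' measurement noise added to each recorded angle series last.
#'
#' @param motor_sd,observation_sd Standard deviations in degrees (>= 0).
#' @return List of class `vm_noise_model`.
#' @export
noise_model <- function(motor_sd = 0, observation_sd = 0) {
  if (motor_sd < 0 || observation_sd < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  structure(list(motor_sd = motor_sd, observation_sd = observation_sd),
            class = "vm_noise_model")
}

#' Generate one synthetic participant
#'
#' Runs the closed-loop forward model over a schedule with motor noise
#' injected into `y_t0` each trial, then adds observation noise to the three
#' recorded series. The result carries full provenance (spec, parameters,
#' noise model, seed) so it can be regenerated bit-identically.
#'
#' @param spec A [model_spec()].
#' @param params A [model_params()] vector (validated against the bounds).
#' @param schedule A [build_schedule()] result.
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise streams.
#' @param participant_id Label.
#' @return A `behavioural_dataset`: the schedule columns plus `imv`
#'   (initial movement vector), `mp_angle` (hand angle at midpoint crossing)
#'   and `ep_angle` (endpoint hand angle), with provenance attributes.
#' @export
generate_participant <- function(spec, params, schedule,
                                 noise = noise_model(), seed = 1L,
                                 participant_id = "synthetic_01") {
  validate_params(params, spec)
  sa <- schedule_arrays(schedule)
  n <- sa$n
  draws <- with_seed(seed, {
    list(motor = if (noise$motor_sd > 0)
           stats::rnorm(n, 0, noise$motor_sd) else numeric(n),
         obs = if (noise$observation_sd > 0)
           matrix(stats::rnorm(3L * n, 0, noise$observation_sd), n, 3L)
         else matrix(0, n, 3L))
  })
  P <- matrix(params[param_names(spec)], 1L,
              dimnames = list(NULL, param_names(spec)))
  res <- sim_core(sa, P, spec, motor_noise = matrix(draws$motor, n, 1L))
  ds <- cbind(as.data.frame(schedule),
              data.frame(imv = res$y_t0[, 1L] + draws$obs[, 1L],
                         mp_angle = res$y_tMP[, 1L] + draws$obs[, 2L],
                         ep_angle = res$y_tEP[, 1L] + draws$obs[, 3L]))
  structure(ds,
            participant_id = participant_id,
            provenance = list(kind = "synthetic", spec = spec,
                              params = params, noise = noise, seed = seed,
                              schedule_seed = attr(schedule, "seed"),
                              experiment_id = attr(schedule, "experiment_id")),
            experiment_id = attr(schedule, "experiment_id"),
            class = c("behavioural_dataset", "data.frame"))
}

#' Generate a trial-matched synthetic cohort
#'
#' All participants share one schedule (perturbations and uncertainty order
#' are trial-matched across participants, as in the experiments); each
#' participant gets an independent noise stream and, optionally,
#' participant-specific parameters.
#'
#' @param spec A [model_spec()].
#' @param params Either a single parameter vector shared by all participants
#'   (a point-mass parameter distribution) or a function `function(i)`
#'   returning the i-th participant's parameter vector.
#' @param n_participants Cohort size (default 20, the per-experiment sample
#'   size of the study design).
#' @param experiment_id 1, 2 or 3.
#' @param noise A [noise_model()].
#' @param seed Integer seed; the schedule and all per-participant noise seeds
#'   are derived from it.
#' @param schedule Optional pre-built schedule (overrides `experiment_id`).
#' @return List of `behavioural_dataset` objects, with the shared schedule as
#'   attribute `schedule`.
#' @export
generate_cohort <- function(spec, params, n_participants = 20L,
                            experiment_id = 1L, noise = noise_model(),
                            seed = 1L, schedule = NULL) {
  if (n_participants < 1) stop("'n_participants' must be >= 1", call. = FALSE)
  if (is.null(schedule)) schedule <- build_schedule(experiment_id, seed = seed)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                          n_participants))
  get_params <- if (is.function(params)) params else function(i) params
  cohort <- lapply(seq_len(n_participants), function(i) {
    generate_participant(spec, get_params(i), schedule, noise,
                         seed = sub_seeds[i],
                         participant_id = sprintf("synthetic_%02d", i))
  })
  attr(cohort, "schedule") <- schedule
  cohort
}

#' Default generating parameters per model family
#'
#' Mid-range parameter settings used as the reference synthetic generators:
#' feedforward uncertainty scaling decreasing with uncertainty (`nu_ff` =
#' 0.9, 0.6, 0.3, 0.05), feedback scaling likewise graded (`nu_fb` = 1.0,
#' 0.6, 0.3, 0), a slow state carrying the adaptation envelope in two-state
#' variants, and negative aim/bias amplitudes so that the aim is
#' compensatory (the model frame measures compensation as negative angles).
#'
#' @param spec A [model_spec()].
#' @return A [model_params()] vector.
#' @export
default_generator_params <- function(spec) {
  common <- list(alpha_fb = 0.05, beta_fb = 0.9, x_fb_init = 0.5,
                 nu_ff = c(0.9, 0.6, 0.3, 0.05),
                 nu_fb = c(1, 0.6, 0.3, 0), gamma = 0.7)
  fam <- switch(spec$family,
    error_scaling = list(alpha_f = 0.15, beta_f = 0.9, lambda_f = 0),
    retention_scaling = list(alpha_f = 0.05, beta_f = 0.95, lambda_f = 0),
    bias_scaling = list(alpha_f = 0.08, beta_f = 0.9, lambda_f = -6),
    state_aim_scaling = list(lambda_f = -9),
    output_aim_scaling = list(alpha_f = 0.08, beta_f = 0.9, lambda_f = -9))
  slow <- if (spec$n_states == 2L)
    list(alpha_s = 0.04, beta_s = 0.99, lambda_s = 0) else list()
  args <- c(list(spec = spec), common, fam, slow)
  if (spec$nonneg) args$lambda_f <- abs(args$lambda_f)
  do.call(model_params, args)
}

#' Adaptation extent of a dataset
#'
#' Mean initial movement vector over the last `last_n` adaptation trials, in
#' the reporting convention where compensation is positive (the model frame
#' is sign-flipped).
#'
#' @param dataset A `behavioural_dataset` (or any per-trial table with
#'   `phase` and `imv`).
#' @param last_n Window size (default 10).
#' @return Degrees (positive = toward full compensation).
#' @export
adaptation_extent <- function(dataset, last_n = 10L) {
  adapt <- which(dataset$phase == "adaptation")
  idx <- utils::tail(adapt, last_n)
  -mean(dataset$imv[idx])
}

#' Write / read a behavioural dataset
#'
#' Per-trial tab-separated table with columns `trial`, `phase`,
#' `rotation_deg`, `mp_uncertainty`, `ep_uncertainty`, `imv`, `mp_angle`,
#' `ep_angle`; missing uncertainty is an empty field.
#'
#' @param dataset A `behavioural_dataset`.
#' @param file Path.
#' @return `read_dataset` returns a `behavioural_dataset` (without synthetic
#'   provenance, which lives with the generator call).
#' @export
write_dataset <- function(dataset, file) {
  utils::write.table(as.data.frame(dataset), file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE)
  df$mp_uncertainty <- as.character(df$mp_uncertainty)
  df$ep_uncertainty <- as.character(df$ep_uncertainty)
  structure(df, provenance = list(kind = "observed"),
            class = c("behavioural_dataset", "data.frame"))
}
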