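#' Session state of the learning system
#'
#' The latent variables carried from trial to trial: the fast feedforward
#' state (the only feedforward state in one-state models), the slow
#' feedforward state (zero when `n_states = 1`), and the multiplicative gain
#' of the midpoint feedback correction.
#'
#' @param x_fast,x_slow Feedforward states in degrees.
#' @param x_fb Dimensionless feedback gain.
#' @return A named list of class `vm_session_state`.
#' @export
session_state <- function(x_fast = 0, x_slow = 0, x_fb = 0) {
  structure(list(x_fast = x_fast, x_slow = x_slow, x_fb = x_fb),
            class = "vm_session_state")
}

#' Feedforward motor output
#'
#' The motor plan issued at reach initiation: the fast state alone for
#' one-state models, the sum of fast and slow states for two-state models.
#'
#' @param state A [session_state()].
#' @param spec A [model_spec()].
#' @return Degrees.
#' @export
feedforward_output <- function(state, spec) {
  if (spec$n_states == 2L) state$x_fast + state$x_slow else state$x_fast
}

#' Sensory prediction error at midpoint
#'
#' The cursor error seen at midpoint: the hand angle at reach initiation plus
#' the imposed rotation (the target sits at 0 degrees, so an unadapted reach
#' under a 12-degree rotation sees a 12-degree error).
#'
#' @param y_t0 Hand angle at reach initiation (degrees).
#' @param rotation_deg Imposed rotation (degrees, CCW positive).
#' @return Degrees.
#' @export
midpoint_error <- function(y_t0, rotation_deg) y_t0 + rotation_deg

#' Sensory prediction error at endpoint
#'
#' The cursor error at endpoint: the (possibly feedback-corrected) hand angle
#' at midpoint plus the imposed rotation.
#'
#' @param y_tMP Hand angle at midpoint (degrees).
#' @param rotation_deg Imposed rotation (degrees).
#' @return Degrees.
#' @export
endpoint_error <- function(y_tMP, rotation_deg) y_tMP + rotation_deg

#' Midpoint feedback command
#'
#' The compensatory within-movement correction triggered by the midpoint
#' error: minus the feedback gain times the error, scaled by the
#' uncertainty-specific feedback scaling entry. Trials without a midpoint
#' feedback event (baseline trials, which have continuous veridical feedback,
#' and washout trials) issue no command.
#'
#' @param x_fb Feedback gain.
#' @param delta_MP Midpoint error (degrees).
#' @param nu_fb Length-4 feedback scaling vector (levels L, M, H, INF).
#' @param mp_level Uncertainty level of the midpoint feedback; `NA` means no
#'   midpoint feedback event and yields 0.
#' @return Degrees.
#' @export
feedback_command <- function(x_fb, delta_MP, nu_fb, mp_level) {
  if (length(mp_level) == 1L && is.na(mp_level)) return(0)
  -x_fb * delta_MP * nu_fb[level_index(mp_level)]
}

#' Feedback-gain update
#'
#' Between-trial adjustment of the feedback controller's gain in response to
#' the endpoint error. This update is not modulated by sensory uncertainty.
#'
#' @param x_fb Current gain.
#' @param delta_EP Endpoint error (degrees).
#' @param params Parameter vector with `beta_fb`, `alpha_fb`.
#' @return Updated gain.
#' @export
update_feedback_gain <- function(x_fb, delta_EP, params) {
  unname(params["beta_fb"] * x_fb + params["alpha_fb"] * delta_EP)
}

#' Slow feedforward state update
#'
#' The slow state is updated from the midpoint error and from the endpoint
#' error corrected for the feedback command issued at midpoint (the feedback
#' command is treated as an error signal), plus the slow bias. It is
#' independent of sensory uncertainty.
#'
#' @param x_slow Current slow state (degrees).
#' @param delta_MP,delta_EP Errors (degrees).
#' @param y_fb_MP Midpoint feedback command (degrees).
#' @param params Parameter vector with `beta_s`, `alpha_s`, `lambda_s`.
#' @param spec A [model_spec()]; must have `n_states = 2`.
#' @return Updated slow state (degrees).
#' @export
update_slow_state <- function(x_slow, delta_MP, delta_EP, y_fb_MP, params,
                              spec = NULL) {
  if (!is.null(spec) && spec$n_states != 2L)
    stop("the slow state exists only in two-state models", call. = FALSE)
  unname(params["beta_s"] * x_slow +
           params["alpha_s"] * delta_MP +
           params["alpha_s"] * (delta_EP - y_fb_MP) +
           params["lambda_s"])
}

#' Fast feedforward state update
#'
#' Dispatches on the model family. Writing `w = gamma * nu[mp] +
#' (1 - gamma) * nu[ep]` for the uncertainty-weighted scaling and `e_EP =
#' delta_EP - y_fb_MP` for the feedback-corrected endpoint error:
#'
#' * error-scaling: `beta*x + gamma*nu[mp]*alpha*delta_MP +
#'   (1-gamma)*nu[ep]*alpha*e_EP + lambda`
#' * retention-scaling: `w*beta*x + alpha*delta_MP + alpha*e_EP + lambda`
#' * bias-scaling: `beta*x + alpha*delta_MP + alpha*e_EP + w*lambda`
#' * state-aim-scaling: `w*lambda` (memoryless: no retention, no error term)
#' * output-aim-scaling: `beta*x + alpha*delta_MP + alpha*e_EP` (uncertainty
#'   does not touch the state; the scaled aim enters the output instead, see
#'   [aim_output()])
#'
#' `nu[mp]`/`nu[ep]` are the `nu_ff` entries selected by the trial's midpoint
#' and endpoint uncertainty levels; trials without an endpoint (or midpoint)
#' feedback event use the `INF` entry.
#'
#' @param x_fast Current fast state (degrees).
#' @param delta_MP,delta_EP Errors (degrees).
#' @param y_fb_MP Midpoint feedback command (degrees).
#' @param mp_level,ep_level Uncertainty levels (`NA` maps to `INF`).
#' @param params Parameter vector.
#' @param spec A [model_spec()].
#' @return Updated fast state (degrees).
#' @export
update_fast_state <- function(x_fast, delta_MP, delta_EP, y_fb_MP,
                              mp_level, ep_level, params, spec) {
  nu <- param_levels(params, "nu_ff")
  g <- unname(params["gamma"])
  nmp <- nu[level_index(mp_level)]
  nep <- nu[level_index(ep_level)]
  w <- g * nmp + (1 - g) * nep
  e_ep <- delta_EP - y_fb_MP
  lam <- unname(params["lambda_f"])
  al <- unname(params["alpha_f"])  # NA for state_aim (not a model parameter)
  be <- unname(params["beta_f"])
  out <- switch(spec$family,
    error_scaling =
      be * x_fast + g * nmp * al * delta_MP + (1 - g) * nep * al * e_ep + lam,
    retention_scaling =
      w * be * x_fast + al * delta_MP + al * e_ep + lam,
    bias_scaling =
      be * x_fast + al * delta_MP + al * e_ep + w * lam,
    state_aim_scaling =
      w * lam,
    output_aim_scaling =
      be * x_fast + al * delta_MP + al * e_ep,
    stop("unknown model family: ", spec$family, call. = FALSE))
  unname(out)
}

#' Output-aim term
#'
#' For the output-aim-scaling family only: the additive aim component of the
#' motor output, determined by the previous trial's uncertainty levels. The
#' first trial (and any trial preceded by a baseline/washout trial) uses the
#' `INF` entry.
#'
#' @param mp_level_prev,ep_level_prev Previous trial's uncertainty levels.
#' @param params Parameter vector.
#' @param spec A [model_spec()]; must be `output_aim_scaling`.
#' @return Degrees.
#' @export
aim_output <- function(mp_level_prev, ep_level_prev, params, spec) {
  if (spec$family != "output_aim_scaling")
    stop("aim_output is defined for the output_aim_scaling family only",
         call. = FALSE)
  nu <- param_levels(params, "nu_ff")
  g <- unname(params["gamma"])
  unname((g * nu[level_index(mp_level_prev)] +
            (1 - g) * nu[level_index(ep_level_prev)]) * params["lambda_f"])
}

#' Simulation controls
#'
#' @param zero_error_on_nofb If `TRUE`, error-driven update terms (and the
#'   feedback-gain update) are zeroed on events where no feedback was actually
#'   displayed (no-feedback `INF` events, missing endpoint feedback, washout).
#'   The default `FALSE` implements the fitted equations literally: latent
#'   errors are computed everywhere and the fitted `INF` scaling entries
#'   absorb the no-feedback condition.
#' @return List of class `vm_sim_control`.
#' @export
sim_control <- function(zero_error_on_nofb = FALSE) {
  structure(list(zero_error_on_nofb = isTRUE(zero_error_on_nofb)),
            class = "vm_sim_control")
}

## Precompute per-trial index/indicator arrays shared by the scalar and the
## population-vectorised simulators.
schedule_arrays <- function(schedule) {
  n <- nrow(schedule)
  adapt <- schedule$phase == "adaptation"
  mp_idx <- level_index(schedule$mp_uncertainty)
  ep_idx <- level_index(schedule$ep_uncertainty)
  ## previous-trial levels for the aim term; trial 1 has no predecessor and
  ## baseline/washout trials already map to the INF slot
  list(n = n,
       r = schedule$rotation_deg,
       adapt = adapt,
       mp_idx = mp_idx,
       ep_idx = ep_idx,
       prev_mp_idx = c(4L, mp_idx[-n]),
       prev_ep_idx = c(4L, ep_idx[-n]),
       saw_mp = adapt & mp_idx != 4L,
       saw_ep = adapt & !is.na(schedule$ep_uncertainty) & ep_idx != 4L)
}

## Core engine: simulates a session for a whole population of parameter
## vectors at once. P is an m x d matrix with columns named as in
## bounds_table(spec); motor_noise (n x m) is added to y_t0 before the
## midpoint error is computed so it propagates through feedback and learning.
## Between-trial learning operates on the target-compensation error (the
## sign-flipped cursor error), which drives the feedforward output toward -r.
## Returns n x m matrices of per-trial outputs and state traces.
sim_core <- function(sa, P, spec, control = sim_control(),
                     motor_noise = NULL) {
  n <- sa$n
  m <- nrow(P)
  fam <- spec$family
  two <- spec$n_states == 2L
  has_fast_dyn <- !fam %in% "state_aim_scaling"

  al_f <- if (has_fast_dyn) P[, "alpha_f"] else numeric(m)
  be_f <- if (has_fast_dyn) P[, "beta_f"] else numeric(m)
  lam_f <- P[, "lambda_f"]
  al_s <- if (two) P[, "alpha_s"] else numeric(m)
  be_s <- if (two) P[, "beta_s"] else numeric(m)
  lam_s <- if (two) P[, "lambda_s"] else numeric(m)
  al_fb <- P[, "alpha_fb"]
  be_fb <- P[, "beta_fb"]
  g <- P[, "gamma"]
  nu <- P[, paste0("nu_ff_", UNCERTAINTY_LEVELS), drop = FALSE]
  eta <- P[, paste0("nu_fb_", UNCERTAINTY_LEVELS), drop = FALSE]

  zero_nofb <- control$zero_error_on_nofb
  out_names <- c("y_t0", "y_tMP", "y_tEP", "delta_MP", "delta_EP",
                 "y_fb_MP", "y_aim", "x_fast", "x_slow", "x_fb")
  out <- lapply(out_names, function(nm) matrix(0, n, m))
  names(out) <- out_names

  xf <- numeric(m)
  xs <- numeric(m)
  xfb <- P[, "x_fb_init"]

  for (t in seq_len(n)) {
    mpi <- sa$mp_idx[t]
    epi <- sa$ep_idx[t]
    y_aim <- if (fam == "output_aim_scaling") {
      (g * nu[, sa$prev_mp_idx[t]] + (1 - g) * nu[, sa$prev_ep_idx[t]]) * lam_f
    } else numeric(m)
    y0 <- xf + (if (two) xs else 0) + y_aim
    if (!is.null(motor_noise)) y0 <- y0 + motor_noise[t, ]
    d_mp <- y0 + sa$r[t]
    y_fb <- if (sa$adapt[t]) -xfb * d_mp * eta[, mpi] else numeric(m)
    y_mp <- y0 + y_fb
    d_ep <- y_mp + sa$r[t]

    out$y_t0[t, ] <- y0
    out$y_tMP[t, ] <- y_mp
    out$y_tEP[t, ] <- y_mp   # no further command between midpoint and endpoint
    out$delta_MP[t, ] <- d_mp
    out$delta_EP[t, ] <- d_ep
    out$y_fb_MP[t, ] <- y_fb
    out$y_aim[t, ] <- y_aim
    out$x_fast[t, ] <- xf
    out$x_slow[t, ] <- xs
    out$x_fb[t, ] <- xfb

    ## learning signals: target-compensation errors (sign-flipped cursor
    ## errors); optionally zeroed where no feedback was displayed
    e_mp <- -d_mp
    e_ep <- -(d_ep - y_fb)
    d_gain <- d_ep
    if (zero_nofb) {
      if (!sa$saw_mp[t]) e_mp <- numeric(m)
      if (!sa$saw_ep[t]) {
        e_ep <- numeric(m)
        d_gain <- numeric(m)
      }
    }

    nmp <- nu[, mpi]
    nep <- nu[, epi]
    w <- g * nmp + (1 - g) * nep
    xf <- switch(fam,
      error_scaling =
        be_f * xf + g * nmp * al_f * e_mp + (1 - g) * nep * al_f * e_ep + lam_f,
      retention_scaling =
        w * be_f * xf + al_f * e_mp + al_f * e_ep + lam_f,
      bias_scaling =
        be_f * xf + al_f * e_mp + al_f * e_ep + w * lam_f,
      state_aim_scaling =
        w * lam_f,
      output_aim_scaling =
        be_f * xf + al_f * e_mp + al_f * e_ep)
    if (two) xs <- be_s * xs + al_s * e_mp + al_s * e_ep + lam_s
    xfb <- be_fb * xfb + al_fb * d_gain
  }
  out
}

#' Simulate a full session
#'
#' Folds the within-trial control equations and between-trial learning rules
#' over a trial schedule, deterministically (no noise). Per-trial motor
#' output is defined at three time points: reach initiation (`y_t0`, the
#' predicted initial movement vector), midpoint (`y_tMP`, after the feedback
#' command) and endpoint (`y_tEP = y_tMP`; no further command is issued
#' between the midpoint correction and the endpoint).
#'
#' Learning operates on the target-compensation error (the sign-flipped
#' cursor error), so adaptation drives the feedforward output toward minus
#' the rotation; reporting utilities flip the sign so that adaptation extent
#' is a positive number.
#'
#' @param schedule A [build_schedule()] result.
#' @param params A [model_params()] vector.
#' @param spec A [model_spec()].
#' @param control A [sim_control()].
#' @return Data frame with one row per trial: the schedule columns plus
#'   `y_t0`, `y_tMP`, `y_tEP`, `delta_MP`, `delta_EP`, `y_fb_MP`, `y_aim` and
#'   the state traces `x_fast`, `x_slow`, `x_fb` (states at trial start).
#' @export
simulate_session <- function(schedule, params, spec, control = sim_control()) {
  validate_params(params, spec)
  sa <- schedule_arrays(schedule)
  P <- matrix(params[param_names(spec)], 1L,
              dimnames = list(NULL, param_names(spec)))
  res <- sim_core(sa, P, spec, control)
  cbind(as.data.frame(schedule),
        as.data.frame(lapply(res, function(mat) mat[, 1L])))
}

#' Simulate a single trial
#'
#' One step of the session fold: computes the trial's outputs from the
#' current state and returns the updated state alongside them. The previous
#' trial is needed only by the output-aim family (its aim term reads the
#' previous trial's uncertainty levels).
#'
#' @param state A [session_state()].
#' @param trial One-row portion of a trial schedule (fields `phase`,
#'   `rotation_deg`, `mp_uncertainty`, `ep_uncertainty`).
#' @param prev_trial Previous trial's row, or `NULL` for the first trial.
#' @param params,spec Model parameters and specification.
#' @param control A [sim_control()].
#' @return List with `state` (updated) and `outputs` (named numeric vector).
#' @export
simulate_trial <- function(state, trial, prev_trial = NULL, params, spec,
                           control = sim_control()) {
  adapt <- trial$phase == "adaptation"
  y_aim <- if (spec$family == "output_aim_scaling") {
    aim_output(if (is.null(prev_trial)) NA else prev_trial$mp_uncertainty,
               if (is.null(prev_trial)) NA else prev_trial$ep_uncertainty,
               params, spec)
  } else 0
  y0 <- feedforward_output(state, spec) + y_aim
  d_mp <- midpoint_error(y0, trial$rotation_deg)
  y_fb <- if (adapt) {
    feedback_command(state$x_fb, d_mp, param_levels(params, "nu_fb"),
                     trial$mp_uncertainty)
  } else 0
  y_mp <- y0 + y_fb
  d_ep <- endpoint_error(y_mp, trial$rotation_deg)

  saw_mp <- adapt && !is.na(trial$mp_uncertainty) &&
    trial$mp_uncertainty != "INF"
  saw_ep <- adapt && !is.na(trial$ep_uncertainty) &&
    trial$ep_uncertainty != "INF"
  ## learning signals: target-compensation (sign-flipped) errors
  e_mp <- -d_mp
  e_ep_raw <- -d_ep
  e_fb <- -y_fb
  d_gain <- d_ep
  if (control$zero_error_on_nofb) {
    if (!saw_mp) e_mp <- 0
    if (!saw_ep) {
      e_ep_raw <- 0; e_fb <- 0; d_gain <- 0
    }
  }

  new_fast <- update_fast_state(state$x_fast, e_mp, e_ep_raw, e_fb,
                                trial$mp_uncertainty, trial$ep_uncertainty,
                                params, spec)
  new_slow <- if (spec$n_states == 2L) {
    update_slow_state(state$x_slow, e_mp, e_ep_raw, e_fb, params)
  } else 0
  new_fb <- update_feedback_gain(state$x_fb, d_gain, params)

  list(state = session_state(new_fast, new_slow, new_fb),
       outputs = c(y_t0 = y0, y_tMP = y_mp, y_tEP = y_mp,
                   delta_MP = d_mp, delta_EP = d_ep, y_fb_MP = y_fb,
                   y_aim = y_aim))
}
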