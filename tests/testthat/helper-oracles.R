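## Hand-made minimal schedule for unit tests (bypasses build_schedule so the
## trial layout is fully explicit).
make_sched <- function(phase, rotation, mp = NA, ep = NA, experiment = 1L) {
  n <- length(phase)
  structure(
    data.frame(trial = seq_len(n), phase = phase,
               rotation_deg = rotation,
               mp_uncertainty = rep_len(as.character(mp), n),
               ep_uncertainty = rep_len(as.character(ep), n),
               stringsAsFactors = FALSE),
    experiment_id = experiment, seed = 0L,
    class = c("trial_schedule", "data.frame"))
}

## Independent oracle: the classic unscaled one/two-state dynamics (single
## error signal per state update) with a midpoint feedback controller,
## written as a plain recursion. Learning uses the target-compensation error
## (target at zero). At nu == 1, eta == 1 the error-scaling family collapses
## onto this recursion with the same learning rate (its gamma-blend of the
## two error signals is convex, and the feedback-corrected endpoint error
## equals the midpoint error algebraically), while retention- and
## bias-scaling collapse onto it with twice the learning rate (their two
## error terms add).
classic_unscaled_sim <- function(sched, alpha_f, beta_f, lambda_f = 0,
                                 alpha_s = 0, beta_s = 0, lambda_s = 0,
                                 alpha_fb = 0, beta_fb = 0, x_fb0 = 0,
                                 two_state = TRUE) {
  n <- nrow(sched)
  out <- data.frame(y_t0 = numeric(n), y_tMP = numeric(n),
                    x_fast = numeric(n), x_slow = numeric(n),
                    x_fb = numeric(n))
  xf <- 0; xs <- 0; xfb <- x_fb0
  for (t in seq_len(n)) {
    y0 <- if (two_state) xf + xs else xf
    dmp <- y0 + sched$rotation_deg[t]
    yfb <- if (sched$phase[t] == "adaptation") -xfb * dmp else 0
    ymp <- y0 + yfb
    dep <- ymp + sched$rotation_deg[t]
    out$y_t0[t] <- y0; out$y_tMP[t] <- ymp
    out$x_fast[t] <- xf; out$x_slow[t] <- xs; out$x_fb[t] <- xfb
    e <- -dmp
    xf <- beta_f * xf + alpha_f * e + lambda_f
    if (two_state) xs <- beta_s * xs + alpha_s * e + lambda_s
    xfb <- beta_fb * xfb + alpha_fb * dep
  }
  out
}

## Shared fast DE settings for unit tests (kept deliberately small; the
## heavier acceptance settings live in test-acceptance.R).
fast_de <- function() de_control(popsize = 3, maxiter = 80, n_restarts = 1,
                                 polish_maxit = 40)
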