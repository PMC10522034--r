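spec2 <- model_spec("error_scaling", 2)

test_that("model specification validates its arguments", {
  expect_error(model_spec("error_scaling", 3), "1 or 2")
  expect_error(model_spec("error_scaling", 1, nonneg = TRUE), "two-state")
  expect_error(model_params(spec2, alpha_f = 2), "outside bounds")
  expect_error(model_params(spec2, nonsense = 1), "unknown parameter")
  expect_error(model_params(model_spec("error_scaling", 2), lambda_s = 0.5),
               "outside bounds")  # fixed at zero for this family
})

test_that("bounds tables transcribe the per-family bound regimes", {
  bt <- bounds_table(spec2)
  expect_identical(bt$lower[bt$parameter == "lambda_s"],
                   bt$upper[bt$parameter == "lambda_s"])
  expect_true(all(bt[bt$parameter %in% paste0("nu_fb_", uncertainty_levels()),
                     "upper"] == 1))
  bt_bias <- bounds_table(model_spec("bias_scaling", 1))
  expect_identical(bt_bias$lower[bt_bias$parameter == "nu_fb_L"], -1)
  bt_aim <- bounds_table(model_spec("output_aim_scaling", 2))
  expect_identical(bt_aim[bt_aim$parameter == "nu_fb_H", c("lower", "upper")],
                   data.frame(lower = -20, upper = 20,
                              row.names = which(bt_aim$parameter == "nu_fb_H")))
  bt_aim_nn <- bounds_table(model_spec("output_aim_scaling", 2, nonneg = TRUE))
  expect_identical(bt_aim_nn$lower[bt_aim_nn$parameter == "nu_fb_H"], 0)
  expect_identical(bt_aim_nn$lower[bt_aim_nn$parameter == "lambda_f"], 0)
  ## state-aim has no fast-state learning-rate/retention parameters
  expect_false(any(c("alpha_f", "beta_f") %in%
                     bounds_table(model_spec("state_aim_scaling", 2))$parameter))
})

test_that("free-parameter counts follow the bound table", {
  for (fam in c("error_scaling", "retention_scaling", "bias_scaling",
                "state_aim_scaling", "output_aim_scaling")) {
    for (ns in 1:2) {
      spec <- model_spec(fam, ns)
      bt <- bounds_table(spec)
      expect_identical(count_free_parameters(spec), sum(bt$lower < bt$upper))
      ## moving from two-state to one-state never increases k
      if (ns == 2)
        expect_gte(count_free_parameters(spec),
                   count_free_parameters(model_spec(fam, 1)))
    }
  }
  ## fixing a parameter (lower == upper) removes exactly one free parameter:
  ## the error/retention/bias two-state variants pin lambda_s
  expect_identical(count_free_parameters(model_spec("error_scaling", 2)),
                   nrow(bounds_table(model_spec("error_scaling", 2))) - 1L)
})

test_that("within-trial operations evaluate the control equations", {
  expect_identical(feedforward_output(session_state(0, 0), spec2), 0)
  expect_identical(feedforward_output(session_state(3, 4), spec2), 7)
  expect_identical(feedforward_output(session_state(3, 4),
                                      model_spec("error_scaling", 1)), 3)
  expect_identical(midpoint_error(0, 12), 12)
  expect_identical(midpoint_error(-12, 12), 0)
  expect_identical(midpoint_error(-5, 12), 7)
  expect_identical(endpoint_error(0, 12), 12)
  expect_identical(endpoint_error(-12, 12), 0)
  expect_identical(endpoint_error(-7, 12), 5)
  eta <- c(0.5, 0.5, 0.5, 0.5)
  expect_identical(feedback_command(1.0, 10, eta, "M"), -5.0)
  expect_identical(feedback_command(1.0, 0, eta, "L"), 0)
  expect_identical(feedback_command(1.0, 10, eta, NA), 0)
})

test_that("full-gain feedback cancels the rotation by endpoint", {
  ## hand-trace: x_fb = 1, eta = 1 at the midpoint level, no adaptation
  y_t0 <- 0
  d_mp <- midpoint_error(y_t0, 12)
  y_fb <- feedback_command(1.0, d_mp, rep(1, 4), "L")
  expect_identical(y_fb, -12)
  y_mp <- y_t0 + y_fb
  expect_identical(endpoint_error(y_mp, 12), 0)
})

test_that("between-trial updates evaluate the learning rules", {
  p <- model_params(spec2, alpha_s = 0.3, beta_s = 1, lambda_s = 0,
                    alpha_fb = 0.1, beta_fb = 1)
  expect_identical(update_feedback_gain(1, 0, p), 1)
  expect_equal(update_feedback_gain(0.5, 10,
                                    model_params(spec2, beta_fb = 0.8,
                                                 alpha_fb = 0.1)), 1.4)
  expect_identical(update_feedback_gain(3, 7,
                                        model_params(spec2, beta_fb = 0,
                                                     alpha_fb = 0)), 0)
  expect_identical(update_slow_state(0, 0, 0, 0, p), 0)
  p99 <- model_params(spec2, beta_s = 0.99, alpha_s = 0)
  expect_equal(update_slow_state(10, 0, 0, 0, p99), 9.9)
  p05 <- model_params(spec2, alpha_s = 0.05, beta_s = 1)
  expect_equal(update_slow_state(0, 12, 0, -12, p05),
               0.05 * 12 + 0.05 * (0 - (-12)))
  expect_error(update_slow_state(0, 1, 1, 0, p, model_spec("error_scaling", 1)),
               "two-state")
})

test_that("fast-state updates dispatch on the scaling family", {
  pe <- model_params(spec2, gamma = 1, nu_ff = c(0.5, 0.5, 0.5, 0.5),
                     alpha_f = 0.2, beta_f = 1, lambda_f = 0)
  expect_equal(update_fast_state(0, 10, 0, 0, "L", NA, pe, spec2), 1.0)
  sa <- model_spec("state_aim_scaling", 2)
  psa <- model_params(sa, gamma = 1, nu_ff = c(0.6, 0.6, 0.6, 0.6),
                      lambda_f = 5)
  for (x in c(-3, 0, 11))
    expect_equal(update_fast_state(x, 99, -99, 4, "M", "H", psa, sa), 3.0)
  ## bias-scaling at nu == 1 reduces to the unscaled update
  bs <- model_spec("bias_scaling", 2)
  pb <- model_params(bs, nu_ff = c(1, 1, 1, 1), alpha_f = 0.1, beta_f = 0.9,
                     lambda_f = 2)
  expect_equal(update_fast_state(5, 3, 1, -2, "L", "H", pb, bs),
               0.9 * 5 + 0.1 * 3 + 0.1 * (1 - (-2)) + 2)
})

test_that("the aim output term follows the previous trial's uncertainty", {
  oa <- model_spec("output_aim_scaling", 2)
  p0 <- model_params(oa, gamma = 1, nu_ff = c(0, 0, 0, 0), lambda_f = 7)
  expect_identical(aim_output("L", "L", p0, oa), 0)
  p1 <- model_params(oa, gamma = 0.5, nu_ff = c(1, 0, 0, 0), lambda_f = 4)
  expect_equal(aim_output("L", "M", p1, oa), 2.0)
  pc <- model_params(oa, gamma = 0.3, nu_ff = rep(0.4, 4), lambda_f = 5)
  for (mp in uncertainty_levels()) for (ep in uncertainty_levels())
    expect_equal(aim_output(mp, ep, pc, oa), 0.4 * 5)
  expect_error(aim_output("L", "L", p1, spec2), "output_aim")
})

test_that("an inert learner passes the rotation through unchanged", {
  sched <- make_sched(rep("adaptation", 3), 12, "L", NA)
  spec <- model_spec("error_scaling", 1)
  p <- model_params(spec, alpha_f = 0, beta_f = 0, lambda_f = 0,
                    alpha_fb = 0, beta_fb = 0, x_fb_init = 0,
                    nu_fb = c(0, 0, 0, 0))
  sim <- simulate_session(sched, p, spec)
  expect_identical(sim$y_t0, rep(0, 3))
  expect_identical(sim$delta_MP, rep(12, 3))
  expect_identical(sim$y_fb_MP, rep(0, 3))
  expect_identical(sim$y_tMP, rep(0, 3))
  expect_identical(sim$delta_EP, rep(12, 3))
  expect_identical(sim$x_fast, rep(0, 3))
})

test_that("one-state error-scaling converges to the fixed point under constant rotation", {
  ## x' = x - alpha * (x + r)  =>  x* = -r (geometric approach)
  sched <- make_sched(rep("adaptation", 60), 12, "L", NA)
  spec <- model_spec("error_scaling", 1)
  p <- model_params(spec, alpha_f = 0.1, beta_f = 1, lambda_f = 0, gamma = 1,
                    nu_ff = c(1, 1, 1, 1), nu_fb = c(0, 0, 0, 0),
                    alpha_fb = 0, beta_fb = 0, x_fb_init = 0)
  sim <- simulate_session(sched, p, spec)
  closed_form <- -12 * (1 - (1 - 0.1)^(seq_len(60) - 1))
  expect_equal(sim$y_t0, closed_form, tolerance = 1e-12)
})

test_that("washout output decays geometrically from the initial state", {
  sched <- make_sched(rep("washout", 30), 0)
  spec <- model_spec("error_scaling", 1)
  p <- model_params(spec, alpha_f = 0, beta_f = 0.9, lambda_f = 0,
                    alpha_fb = 0, beta_fb = 0, x_fb_init = 0)
  sim <- simulate_session(sched, p, spec)
  expect_equal(sim$x_fast, rep(0, 30))  # zero initial state stays zero
  ## seed a state by one adaptation trial then watch the pure-retention decay
  sched2 <- make_sched(c("adaptation", rep("washout", 29)), c(12, rep(0, 29)),
                       c("L", rep(NA, 29)), NA)
  p2 <- model_params(spec, alpha_f = 0.5, beta_f = 0.9, lambda_f = 0,
                     gamma = 1, nu_ff = c(1, 1, 1, 0), nu_fb = c(0, 0, 0, 0),
                     alpha_fb = 0, beta_fb = 0, x_fb_init = 0)
  sim2 <- simulate_session(sched2, p2, spec)
  x1 <- sim2$x_fast[2]
  expect_lt(x1, 0)  # compensatory after seeing a +12 error
  expect_equal(sim2$x_fast[2:30], x1 * 0.9^(0:28), tolerance = 1e-10)
})

test_that("feedback contributes nothing at reach initiation on any trial", {
  sch <- build_schedule(2, seed = 4)
  for (fam in c("error_scaling", "state_aim_scaling", "output_aim_scaling")) {
    spec <- model_spec(fam, 2)
    sim <- simulate_session(sch, default_generator_params(spec), spec)
    expect_equal(sim$y_t0, sim$x_fast + sim$x_slow + sim$y_aim,
                 tolerance = 1e-12)
  }
})

test_that("identity scaling collapses the three state-scaling families onto the unscaled dynamics", {
  ## classic single-error dynamics with learning rates (0.12, 0.04): the
  ## error-scaling family matches at the same rates (its gamma-blend is
  ## convex); retention-/bias-scaling match at half rates (their two error
  ## terms add, and the corrected endpoint error equals the midpoint error)
  sch <- build_schedule(2, seed = 21)
  oracle <- classic_unscaled_sim(sch, alpha_f = 0.12, beta_f = 0.85,
                                 lambda_f = 0.5, alpha_s = 0.04,
                                 beta_s = 0.985, lambda_s = 0,
                                 alpha_fb = 0.03, beta_fb = 0.92, x_fb0 = 0.4)
  ## the slow state uses the summed two-error update in every family, so its
  ## package rate is half the oracle's in all three cases
  rates <- list(error_scaling = c(0.12, 0.02),
                retention_scaling = c(0.06, 0.02),
                bias_scaling = c(0.06, 0.02))
  for (fam in names(rates)) {
    spec <- model_spec(fam, 2)
    p <- model_params(spec, alpha_f = rates[[fam]][1], beta_f = 0.85,
                      lambda_f = 0.5, alpha_s = rates[[fam]][2],
                      beta_s = 0.985, lambda_s = 0,
                      alpha_fb = 0.03, beta_fb = 0.92, x_fb_init = 0.4,
                      nu_ff = c(1, 1, 1, 1), nu_fb = c(1, 1, 1, 1),
                      gamma = 0.37)
    sim <- simulate_session(sch, p, spec)
    expect_equal(sim$y_t0, oracle$y_t0, tolerance = 1e-10)
    expect_equal(sim$y_tMP, oracle$y_tMP, tolerance = 1e-10)
  }
})

test_that("the slow state is invariant to permutations of the uncertainty schedule", {
  sch <- build_schedule(1, seed = 33)
  spec <- model_spec("error_scaling", 2)
  p <- model_params(spec, alpha_f = 0, beta_f = 0, lambda_f = 0,
                    alpha_s = 0.05, beta_s = 0.98,
                    nu_ff = c(0.9, 0.6, 0.3, 0.05), nu_fb = c(0, 0, 0, 0),
                    alpha_fb = 0, beta_fb = 0, x_fb_init = 0)
  ## with the fast state and feedback silenced, errors depend only on the
  ## rotation sequence, so permuting uncertainty labels must not move x_slow
  sim1 <- simulate_session(sch, p, spec)
  sch2 <- sch
  ad <- which(sch2$phase == "adaptation")
  set.seed(8)
  sch2$mp_uncertainty[ad] <- sample(sch2$mp_uncertainty[ad])
  sim2 <- simulate_session(sch2, p, spec)
  expect_equal(sim1$x_slow, sim2$x_slow, tolerance = 1e-12)
})

test_that("the state-aim fast state depends only on the previous trial's levels", {
  sa <- model_spec("state_aim_scaling", 2)
  p <- default_generator_params(sa)
  nu <- unname(p[paste0("nu_ff_", uncertainty_levels())])
  g <- unname(p["gamma"])
  for (mp in uncertainty_levels()) for (ep in uncertainty_levels()) {
    sched <- make_sched(rep("adaptation", 2), c(10, 10), mp, ep,
                        experiment = 3L)
    sim <- simulate_session(sched, p, sa)
    i_mp <- match(mp, uncertainty_levels())
    i_ep <- match(ep, uncertainty_levels())
    expect_equal(sim$x_fast[2],
                 (g * nu[i_mp] + (1 - g) * nu[i_ep]) * unname(p["lambda_f"]),
                 tolerance = 1e-12)
  }
})

test_that("simulate_session equals the fold of simulate_trial", {
  sch <- build_schedule(3, seed = 6)
  for (fam in c("error_scaling", "retention_scaling", "bias_scaling",
                "state_aim_scaling", "output_aim_scaling")) {
    for (ctrl in list(sim_control(), sim_control(zero_error_on_nofb = TRUE))) {
      spec <- model_spec(fam, 2)
      p <- default_generator_params(spec)
      sim <- simulate_session(sch, p, spec, ctrl)
      st <- session_state(0, 0, unname(p["x_fb_init"]))
      for (t in seq_len(12)) {
        step <- simulate_trial(st, sch[t, ],
                               if (t > 1) sch[t - 1, ] else NULL,
                               p, spec, ctrl)
        expect_equal(unname(step$outputs["y_t0"]), sim$y_t0[t],
                     tolerance = 1e-12)
        expect_equal(unname(step$outputs["y_tMP"]), sim$y_tMP[t],
                     tolerance = 1e-12)
        st <- step$state
      }
      expect_equal(st$x_fast, sim$x_fast[13], tolerance = 1e-12)
      expect_equal(st$x_slow, sim$x_slow[13], tolerance = 1e-12)
      expect_equal(st$x_fb, sim$x_fb[13], tolerance = 1e-12)
    }
  }
})

test_that("simulations stay finite within bounds for stable retention", {
  sch <- build_schedule(2, seed = 14)
  grid <- expand.grid(alpha = c(0.05, 0.3, 0.9), eta = c(0, 0.5, 1))
  for (fam in c("error_scaling", "retention_scaling", "bias_scaling")) {
    spec <- model_spec(fam, 2)
    for (i in seq_len(nrow(grid))) {
      p <- model_params(spec, alpha_f = grid$alpha[i], beta_f = 1,
                        alpha_s = grid$alpha[i] / 4, beta_s = 1,
                        lambda_f = 5, alpha_fb = 0, beta_fb = 1,
                        x_fb_init = 1, nu_ff = c(1, 0.6, 0.3, 0),
                        nu_fb = rep(grid$eta[i], 4), gamma = 0.5)
      sim <- simulate_session(sch, p, spec)
      expect_true(all(is.finite(sim$y_tMP)))
    }
  }
})

test_that("identical inputs give bitwise-identical simulations", {
  sch <- build_schedule(1, seed = 2)
  spec <- model_spec("output_aim_scaling", 2)
  p <- default_generator_params(spec)
  expect_identical(simulate_session(sch, p, spec),
                   simulate_session(sch, p, spec))
  expect_identical(nrow(simulate_session(sch, p, spec)), 300L)
})
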