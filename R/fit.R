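## Row indices of the trials entering the objective.
fitted_rows <- function(schedule, fit_phases) {
  rows <- which(schedule$phase %in% fit_phases)
  if (!length(rows)) stop("no trials in the fitted phases", call. = FALSE)
  rows
}

#' Sum-of-squares objective
#'
#' Simulates the session deterministically under `params` and returns the sum
#' over fitted trials of squared midpoint residuals plus squared endpoint
#' residuals (predicted vs observed hand angles). By default the adaptation
#' and washout phases are fitted (washout decay constrains the retention
#' parameters) and baseline is excluded; endpoint hand angles are fitted even
#' when no endpoint feedback was displayed (they are measured kinematically).
#'
#' @param params Parameter vector (within bounds for `spec`).
#' @param spec A [model_spec()].
#' @param dataset A `behavioural_dataset` aligned to its schedule.
#' @param fit_phases Phases entering the objective.
#' @param control A [sim_control()].
#' @return Squared-degrees objective value.
#' @export
objective <- function(params, spec, dataset,
                      fit_phases = c("adaptation", "washout"),
                      control = sim_control()) {
  rows <- fitted_rows(dataset, fit_phases)
  sim <- simulate_session(dataset, params, spec, control)
  sum((sim$y_tMP[rows] - dataset$mp_angle[rows])^2) +
    sum((sim$y_tEP[rows] - dataset$ep_angle[rows])^2)
}

#' Differential-evolution settings
#'
#' Classic rand/1/bin differential evolution over the box constraints of
#' [bounds_table()], with reflection at the bounds. The whole population is
#' evaluated at once through the vectorised session simulator. `popsize` is
#' the population size per free dimension (as in common implementations);
#' the search stops after `maxiter` generations or when the population's
#' objective spread falls below `tol` relative to its mean.
#'
#' @param popsize Population members per free dimension (default 6; the
#'   total population is capped to `[24, 120]`).
#' @param maxiter Maximum generations (default 250).
#' @param mutation Lower edge of the dithered differential weight (each
#'   generation draws F uniformly in `[mutation, 1]`; default 0.5).
#' @param recombination Crossover probability CR (default 0.9).
#' @param tol Relative convergence tolerance (default 1e-8).
#' @param n_restarts Independent seeded restarts; the best objective wins
#'   (default 2).
#' @param init_best_guess If `TRUE` (default) one member of each initial
#'   population is set to the bound-box midpoint.
#' @param polish_maxit Iteration cap of the bounded quasi-Newton (L-BFGS-B)
#'   polish applied to the best restart (0 disables polishing; default 60).
#' @return List of class `vm_de_control`.
#' @export
de_control <- function(popsize = 6, maxiter = 250, mutation = 0.5,
                       recombination = 0.9, tol = 1e-8, n_restarts = 2,
                       init_best_guess = TRUE, polish_maxit = 60) {
  structure(list(popsize = popsize, maxiter = maxiter, mutation = mutation,
                 recombination = recombination, tol = tol,
                 n_restarts = n_restarts,
                 init_best_guess = isTRUE(init_best_guess),
                 polish_maxit = polish_maxit),
            class = "vm_de_control")
}

## One seeded DE run; fn_batch takes an m x d matrix (columns = free
## parameters) and returns m objective values. Runs inside an isolated RNG
## stream set by the caller.
de_run <- function(fn_batch, lower, upper, ctrl) {
  d <- length(lower)
  np <- max(24L, min(120L, ceiling(ctrl$popsize * d)))
  span <- upper - lower
  pop <- matrix(stats::runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2L, span, "*"), 2L, lower, "+")
  if (ctrl$init_best_guess) pop[1L, ] <- (lower + upper) / 2
  cost <- fn_batch(pop)
  for (gen in seq_len(ctrl$maxiter)) {
    idx <- matrix(0L, np, 3L)
    for (j in 1:3) idx[, j] <- sample.int(np, np, replace = TRUE)
    ## resample collisions with the target index (cheap approximation of
    ## distinct-index sampling; exact distinctness is not required for
    ## convergence of rand/1/bin)
    ## dithered differential weight in [F, 1]: improves convergence on
    ## strongly coupled parameters without extra evaluations
    Fg <- stats::runif(1L, ctrl$mutation, 1)
    mut <- pop[idx[, 1L], , drop = FALSE] +
      Fg * (pop[idx[, 2L], , drop = FALSE] -
              pop[idx[, 3L], , drop = FALSE])
    ## reflect into the box
    lo <- matrix(lower, np, d, byrow = TRUE)
    hi <- matrix(upper, np, d, byrow = TRUE)
    mut <- pmin(pmax(mut, 2 * lo - mut), 2 * hi - mut)
    mut <- pmin(pmax(mut, lo), hi)
    cross <- matrix(stats::runif(np * d) < ctrl$recombination, np, d)
    force_dim <- cbind(seq_len(np), sample.int(d, np, replace = TRUE))
    cross[force_dim] <- TRUE
    trial <- ifelse(cross, mut, pop)
    tc <- fn_batch(trial)
    better <- tc <= cost
    pop[better, ] <- trial[better, , drop = FALSE]
    cost[better] <- tc[better]
    if (stats::sd(cost) <= ctrl$tol * (abs(mean(cost)) + 1e-12)) break
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], generations = gen)
}

#' Fit a model to one participant by differential evolution
#'
#' Global stochastic search for the parameters minimising [objective()]
#' within the bounds of [bounds_table()]. Fixed parameters (bounds with
#' `lower == upper`) are pinned; the free parameters are searched. The fit is
#' fully seeded: identical seeds give identical results.
#'
#' @param spec A [model_spec()].
#' @param dataset A `behavioural_dataset`.
#' @param seed Integer seed.
#' @param control A [de_control()].
#' @param fit_phases Phases entering the objective (see [objective()]).
#' @param sim_ctrl A [sim_control()].
#' @return A `vm_fit_result`: list with `spec`, `params` (full vector), `E`,
#'   `r2` (pooled across midpoint and endpoint residuals), `n_points`, `k`,
#'   `bic`, `seed`, `converged`, `generations`.
#' @export
fit_participant <- function(spec, dataset, seed = 1L, control = de_control(),
                            fit_phases = c("adaptation", "washout"),
                            sim_ctrl = sim_control()) {
  bt <- bounds_table(spec)
  free <- bt$lower < bt$upper
  nm <- bt$parameter
  rows <- fitted_rows(dataset, fit_phases)
  sa <- schedule_arrays(dataset)
  obs_mp <- dataset$mp_angle[rows]
  obs_ep <- dataset$ep_angle[rows]
  if (anyNA(obs_mp) || anyNA(obs_ep))
    stop("missing observed angles in the fitted phases", call. = FALSE)

  full_row <- stats::setNames(bt$lower, nm)  # fixed params sit at lower=upper
  fn_batch <- function(free_mat) {
    m <- nrow(free_mat)
    P <- matrix(full_row, m, length(nm), byrow = TRUE,
                dimnames = list(NULL, nm))
    P[, nm[free]] <- free_mat
    res <- sim_core(sa, P, spec, sim_ctrl)
    val <- colSums((res$y_tMP[rows, , drop = FALSE] - obs_mp)^2) +
      colSums((res$y_tEP[rows, , drop = FALSE] - obs_ep)^2)
    ## unstable dynamics (the bound box allows divergent regimes) overflow;
    ## give them a finite worst-case cost so selection can discard them
    val[!is.finite(val)] <- 1e300
    val
  }

  best <- with_seed(seed, {
    runs <- lapply(seq_len(control$n_restarts), function(i)
      de_run(fn_batch, bt$lower[free], bt$upper[free], control))
    b <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
    if (control$polish_maxit > 0) {
      fn1 <- function(x) fn_batch(matrix(x, 1L))
      pol <- try(stats::optim(b$par, fn1, method = "L-BFGS-B",
                              lower = bt$lower[free], upper = bt$upper[free],
                              control = list(maxit = control$polish_maxit)),
                 silent = TRUE)
      if (!inherits(pol, "try-error") && is.finite(pol$value) &&
          pol$value < b$value) {
        b$par <- pol$par
        b$value <- pol$value
      }
    }
    b
  })

  params <- full_row
  params[nm[free]] <- best$par
  E <- best$value
  obs <- c(obs_mp, obs_ep)
  tss <- sum((obs - mean(obs))^2)
  r2 <- 1 - E / tss
  k <- sum(free)
  n_points <- 2L * length(rows)
  structure(list(spec = spec, params = params, E = E, r2 = r2,
                 n_points = n_points, k = k,
                 bic = bic(n_points, k, r2),
                 seed = seed, converged = best$generations < control$maxiter,
                 generations = best$generations),
            class = "vm_fit_result")
}

#' @export
print.vm_fit_result <- function(x, ...) {
  cat(sprintf("Fit: %s | E = %.3f deg^2, R^2 = %.4f, k = %d, n = %d, BIC = %.2f\n",
              spec_label(x$spec), x$E, x$r2, x$k, x$n_points, x$bic))
  invisible(x)
}
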