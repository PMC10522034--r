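#' Backward-difference contrast scheme
#'
#' Coding matrix for an ordered factor in which each fitted coefficient
#' estimates the difference between adjacent levels (level j+1 minus level
#' j); on balanced one-way data the coefficients equal the adjacent-level
#' mean differences. Columns are centred (each sums to zero across levels).
#' Wraps the successive-differences coding of \pkg{MASS}.
#'
#' @param n_levels Number of ordered levels (>= 2).
#' @param labels Optional level labels.
#' @return A `contrast_scheme`: list with `levels` and `matrix`
#'   (`n_levels` x `n_levels - 1`, columns named `"l2-l1"` etc.).
#' @export
backward_difference_matrix <- function(n_levels,
                                       labels = paste0("l", seq_len(n_levels))) {
  if (n_levels < 2) stop("'n_levels' must be >= 2", call. = FALSE)
  m <- MASS::contr.sdif(n_levels)
  dimnames(m) <- list(labels,
                      paste0(labels[-1L], "-", labels[-n_levels]))
  structure(list(levels = labels, matrix = m), class = "contrast_scheme")
}

#' Group-average a cohort per trial
#'
#' Averages the three behavioural series across participants at each trial of
#' the shared schedule, and derives the per-trial cursor errors: the midpoint
#' error as initial movement vector plus rotation (the cursor error generated
#' by the initiation command) and the endpoint error as endpoint hand angle
#' plus rotation.
#'
#' @param cohort List of `behavioural_dataset` sharing one schedule.
#' @return Per-trial data frame with the schedule columns plus `imv`,
#'   `mp_angle`, `ep_angle`, `delta_mp`, `delta_ep`.
#' @export
group_average <- function(cohort) {
  sched <- as.data.frame(cohort[[1L]][, c("trial", "phase", "rotation_deg",
                                          "mp_uncertainty", "ep_uncertainty")])
  avg <- function(col)
    rowMeans(vapply(cohort, function(d) d[[col]], numeric(nrow(sched))))
  out <- cbind(sched, data.frame(imv = avg("imv"), mp_angle = avg("mp_angle"),
                                 ep_angle = avg("ep_angle")))
  out$delta_mp <- out$imv + out$rotation_deg
  out$delta_ep <- out$ep_angle + out$rotation_deg
  attr(out, "experiment_id") <- attr(cohort[[1L]], "experiment_id")
  out
}

#' Specify one of the study's regression analyses
#'
#' Three response variables are analysed on group-averaged adaptation-phase
#' data: the initial movement vector (`"imv"`), its trial-to-trial change
#' (`"delta_imv"`) — both with error and uncertainty predictors taken from
#' the previous trial — and feedback integration (`"fb_integration"`,
#' endpoint hand angle minus initial movement vector) with current-trial
#' predictors. `log(trial)` enters only the `imv` model. Experiment 1 has no
#' endpoint feedback, so its specs omit the endpoint-error terms; Experiment
#' 3's uncertainty factor is the four midpoint-by-endpoint trial types
#' (LL, LH, HL, HH), except for feedback integration, which uses the two
#' midpoint levels.
#'
#' @param response `"imv"`, `"delta_imv"` or `"fb_integration"`.
#' @param experiment_id 1, 2 or 3.
#' @return A `vm_regression_spec`.
#' @export
regression_spec <- function(response = c("imv", "delta_imv", "fb_integration"),
                            experiment_id = 1L) {
  response <- match.arg(response)
  if (!experiment_id %in% 1:3)
    stop("'experiment_id' must be 1, 2 or 3", call. = FALSE)
  lagged <- response != "fb_integration"
  structure(list(response = response,
                 experiment_id = as.integer(experiment_id),
                 lagged = lagged,
                 include_log_trial = response == "imv",
                 include_delta_ep = experiment_id >= 2L &&
                   response != "fb_integration"),
            class = "vm_regression_spec")
}

## Uncertainty factor values and contrast scheme for a regression spec.
uncertainty_factor <- function(gavg, rspec) {
  if (rspec$experiment_id == 3L) {
    if (rspec$response == "fb_integration") {
      lev <- c("L", "H")
      val <- gavg$mp_uncertainty
      cs <- backward_difference_matrix(2L, lev)
      colnames(cs$matrix) <- "sigma_MP"
    } else {
      lev <- c("LL", "LH", "HL", "HH")
      val <- paste0(gavg$mp_uncertainty, gavg$ep_uncertainty)
      cs <- backward_difference_matrix(4L, lev)
    }
  } else {
    lev <- UNCERTAINTY_LEVELS
    val <- gavg$mp_uncertainty
    cs <- backward_difference_matrix(4L, lev)
  }
  list(idx = match(val, lev), scheme = cs)
}

#' Build the design matrix and response of a regression analysis
#'
#' Adaptation-phase rows only; for the lagged specs (`imv`, `delta_imv`) the
#' uncertainty and error predictors are shifted to the previous adaptation
#' trial and the first adaptation trial (whose predecessor is a baseline
#' trial) is dropped. Columns follow the order of the study's coefficient
#' tables: intercept, uncertainty contrasts, midpoint error, its
#' uncertainty interactions, endpoint error and interactions (Experiments 2
#' and 3), and `log(trial)` for the `imv` model.
#'
#' @param gavg A [group_average()] table.
#' @param rspec A [regression_spec()].
#' @return A `vm_regression_design`: list with `X` (named design matrix
#'   including intercept), `y`, `terms` (per-column group labels), `rspec`.
#' @export
build_design <- function(gavg, rspec) {
  stopifnot(inherits(rspec, "vm_regression_spec"))
  adapt <- which(gavg$phase == "adaptation")
  if (anyNA(gavg$mp_uncertainty[adapt]))
    stop("missing uncertainty labels in the adaptation phase", call. = FALSE)
  uf <- uncertainty_factor(gavg, rspec)

  if (rspec$lagged) {
    rows <- adapt[-1L]       # first adaptation trial has no usable lag
    pred <- adapt[-length(adapt)]
  } else {
    rows <- adapt
    pred <- adapt
  }
  contr <- uf$scheme$matrix[uf$idx[pred], , drop = FALSE]
  d_mp <- gavg$delta_mp[pred]
  d_ep <- gavg$delta_ep[pred]

  y <- switch(rspec$response,
    imv = gavg$imv[rows],
    delta_imv = gavg$imv[rows] - gavg$imv[pred],
    fb_integration = gavg$ep_angle[rows] - gavg$imv[rows])

  X <- cbind(`(Intercept)` = 1, contr)
  groups <- c("intercept", rep("uncertainty", ncol(contr)))
  X <- cbind(X, delta_MP = d_mp, contr * d_mp)
  colnames(X)[(ncol(X) - ncol(contr) + 1L):ncol(X)] <-
    paste0(colnames(contr), ":delta_MP")
  groups <- c(groups, "delta_MP", rep("uncertainty:delta_MP", ncol(contr)))
  if (rspec$include_delta_ep) {
    X <- cbind(X, delta_EP = d_ep, contr * d_ep)
    colnames(X)[(ncol(X) - ncol(contr) + 1L):ncol(X)] <-
      paste0(colnames(contr), ":delta_EP")
    groups <- c(groups, "delta_EP", rep("uncertainty:delta_EP", ncol(contr)))
  }
  if (rspec$include_log_trial) {
    X <- cbind(X, log_trial = log(gavg$trial[rows]))
    groups <- c(groups, "log_trial")
  }
  structure(list(X = X, y = y,
                 terms = data.frame(name = colnames(X), group = groups,
                                    stringsAsFactors = FALSE),
                 rspec = rspec),
            class = "vm_regression_design")
}

#' Ordinary least-squares fit of a regression design
#'
#' Classical OLS on the explicit design matrix: coefficient estimates with
#' standard errors, t statistics, p values and 95\% confidence intervals,
#' model-level adjusted R-squared and overall F test, and (optionally) the
#' relative-importance share of each non-intercept column. Rank-deficient
#' designs raise an error naming the collinear columns.
#'
#' @param design A [build_design()] result, or a design matrix.
#' @param y Response (when `design` is a matrix).
#' @param relimp Compute relative importance per column (default `TRUE`).
#' @return A `vm_regression_result`: list with `coefficients` (data frame
#'   mirroring the study's table columns: coef, se, T, pval, CI bounds,
#'   relimp), `r2`, `adj_r2`, `F`, `df1`, `df2`, `F_pval`, `rss`, `n`.
#' @export
fit_regression <- function(design, y = NULL, relimp = TRUE) {
  if (inherits(design, "vm_regression_design")) {
    X <- design$X; y <- design$y
  } else {
    X <- as.matrix(design)
    if (is.null(y)) stop("'y' is required with a bare matrix", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  df2 <- n - p
  sigma2 <- rss / df2
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df2, lower.tail = FALSE)
  tcrit <- stats::qt(0.975, df2)
  has_int <- colnames(X)[1L] == "(Intercept)"
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  r2 <- 1 - rss / tss
  df1 <- p - as.integer(has_int)
  adj_r2 <- 1 - (1 - r2) * (n - as.integer(has_int)) / df2
  Fstat <- ((tss - rss) / df1) / sigma2
  coefs <- data.frame(name = colnames(X), coef = unname(beta),
                      se = unname(se), T = unname(tval), pval = unname(pval),
                      ci_lower = unname(beta - tcrit * se),
                      ci_upper = unname(beta + tcrit * se),
                      relimp = NA_real_, stringsAsFactors = FALSE)
  if (relimp && has_int && p > 1L) {
    shares <- relative_importance(X[, -1L, drop = FALSE], y)
    coefs$relimp[match(names(shares$shares), coefs$name)] <- shares$shares
  }
  structure(list(coefficients = coefs, r2 = r2, adj_r2 = adj_r2,
                 F = Fstat, df1 = df1, df2 = df2,
                 F_pval = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 rss = rss, n = n),
            class = "vm_regression_result")
}

#' @export
print.vm_regression_result <- function(x, digits = 3, ...) {
  cat(sprintf("OLS fit: adjusted R^2 = %.3f, F(%d,%d) = %.2f, p = %.3g\n",
              x$adj_r2, x$df1, x$df2, x$F, x$F_pval))
  print(cbind(x$coefficients[1], round(x$coefficients[-1], digits)),
        row.names = FALSE)
  invisible(x)
}

#' Joint F test of a group of columns
#'
#' Nested-model F test that the coefficients of the named columns are jointly
#' zero; used e.g. to test whether the uncertainty-by-error interaction terms
#' contribute beyond the main effects.
#'
#' @param design A [build_design()] result.
#' @param columns Column names, or a `terms` group label.
#' @return List with `F`, `df1`, `df2`, `pval`.
#' @export
joint_f_test <- function(design, columns) {
  X <- design$X; y <- design$y
  if (length(columns) == 1L && columns %in% design$terms$group)
    columns <- design$terms$name[design$terms$group == columns]
  if (!all(columns %in% colnames(X)))
    stop("unknown column(s): ",
         paste(setdiff(columns, colnames(X)), collapse = ", "), call. = FALSE)
  full <- fit_regression(X, y = y, relimp = FALSE)
  red <- fit_regression(X[, setdiff(colnames(X), columns), drop = FALSE],
                        y = y, relimp = FALSE)
  q <- length(columns)
  Fstat <- ((red$rss - full$rss) / q) / (full$rss / full$df2)
  list(F = Fstat, df1 = q, df2 = full$df2,
       pval = stats::pf(Fstat, q, full$df2, lower.tail = FALSE))
}

#' Relative importance of regressors (averaging over orderings)
#'
#' Decomposes the model R-squared into non-negative per-regressor shares by
#' averaging each regressor's sequential R-squared contribution over all
#' orders of entry (the LMG decomposition); shares sum to the full-model
#' R-squared. Computed by subset enumeration on the covariance matrix, so the
#' number of regressors is limited to 16.
#'
#' @param X Regressor matrix (no intercept column; an `(Intercept)` column
#'   is dropped if present). A [build_design()] result may be given instead.
#' @param y Response.
#' @param groups Optional per-column group labels; grouped shares are the
#'   sums of their columns' shares.
#' @return List with `shares` (named, per column), `group_shares` (when
#'   `groups` given), `r2` (full model).
#' @export
relative_importance <- function(X, y = NULL, groups = NULL) {
  if (inherits(X, "vm_regression_design")) {
    des <- X
    y <- des$y
    keep <- des$terms$group != "intercept"
    if (is.null(groups)) groups <- des$terms$group[keep]
    X <- des$X[, keep, drop = FALSE]
  }
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && colnames(X)[1L] == "(Intercept)")
    X <- X[, -1L, drop = FALSE]
  p <- ncol(X)
  if (p > 16L) stop("too many regressors for subset enumeration", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  S <- crossprod(Xc) / (length(y) - 1L)
  cvec <- drop(crossprod(Xc, yc)) / (length(y) - 1L)
  vy <- sum(yc^2) / (length(y) - 1L)

  n_masks <- bitwShiftL(1L, p)
  r2_of <- numeric(n_masks)
  bits <- lapply(seq_len(p), function(j) bitwShiftL(1L, j - 1L))
  members <- lapply(seq_len(n_masks) - 1L, function(mask)
    which(vapply(bits, function(b) bitwAnd(mask, b) > 0L, logical(1))))
  for (mask in seq_len(n_masks) - 1L) {
    s <- members[[mask + 1L]]
    if (!length(s)) next
    ## pseudo-inverse fallback keeps exactly collinear subsets well defined
    ## (the projection R^2 is unaffected by which solution is taken)
    sol <- tryCatch(solve(S[s, s, drop = FALSE], cvec[s]),
                    error = function(e) MASS::ginv(S[s, s, drop = FALSE]) %*%
                      cvec[s])
    r2_of[mask + 1L] <- drop(crossprod(cvec[s], sol)) / vy
  }
  sizes <- lengths(members)
  wts <- factorial(0:(p - 1L)) * factorial((p - 1L):0) / factorial(p)
  shares <- numeric(p)
  for (j in seq_len(p)) {
    bj <- bits[[j]]
    without_j <- which(vapply(seq_len(n_masks) - 1L,
                              function(mask) bitwAnd(mask, bj) == 0L,
                              logical(1))) - 1L
    contrib <- r2_of[without_j + bj + 1L] - r2_of[without_j + 1L]
    shares[j] <- sum(wts[sizes[without_j + 1L] + 1L] * contrib)
  }
  names(shares) <- colnames(X)
  out <- list(shares = shares, r2 = r2_of[n_masks])
  if (!is.null(groups))
    out$group_shares <- tapply(shares, groups, sum)
  out
}

#' Adaptation-versus-washout difference scores
#'
#' For each participant and uncertainty trial type, the difference between
#' mean accuracy over the last `last_n` adaptation trials of that type
#' (adaptation trials grouped by the previous trial's uncertainty, the
#' grouping under which the behaviour stratifies) and mean accuracy over the
#' first `first_n` washout trials, with accuracy in the
#' compensation-positive reporting convention. A short washout window limits
#' contamination from forgetting. Difference scores are compared across trial
#' types with a repeated-measures ANOVA (generalized eta-squared effect size)
#' and Bonferroni-corrected paired t-tests with Hedges g.
#'
#' @param cohort List of `behavioural_dataset`.
#' @param last_n Adaptation window per type (default 10).
#' @param first_n Washout window (default 3).
#' @return A `washout_analysis`: list with `scores` (participant x type),
#'   `anova` (F, df1, df2, pval, ges), `pairwise` (A, B, T, dof, p_corr,
#'   hedges).
#' @export
washout_difference_analysis <- function(cohort, last_n = 10L, first_n = 3L) {
  ds1 <- cohort[[1L]]
  exp_id <- attr(ds1, "experiment_id")
  exp3 <- !is.null(exp_id) && !is.na(exp_id) && exp_id == 3
  types <- if (exp3) c("LL", "LH", "HL", "HH") else UNCERTAINTY_LEVELS
  scores <- t(vapply(cohort, function(ds) {
    adapt <- which(ds$phase == "adaptation")
    wash <- which(ds$phase == "washout")
    if (length(adapt) < last_n || length(wash) < first_n)
      stop("insufficient trials for the washout analysis", call. = FALSE)
    lab <- if (exp3) paste0(ds$mp_uncertainty, ds$ep_uncertainty)
           else ds$mp_uncertainty
    prev_lab <- lab[adapt - 1L]
    prev_lab[!((adapt - 1L) %in% adapt)] <- NA  # predecessor outside adaptation
    acc <- -ds$imv  # compensation-positive accuracy
    wash_mean <- mean(acc[utils::head(wash, first_n)])
    vapply(types, function(ty) {
      idx <- adapt[which(prev_lab == ty)]
      mean(acc[utils::tail(idx, last_n)]) - wash_mean
    }, numeric(1))
  }, numeric(length(types))))
  rownames(scores) <- vapply(cohort, function(d)
    as.character(attr(d, "participant_id") %||% ""), "")
  if (any(rownames(scores) == ""))
    rownames(scores) <- paste0("p", seq_len(nrow(scores)))

  long <- data.frame(
    participant = factor(rep(rownames(scores), times = ncol(scores))),
    type = factor(rep(types, each = nrow(scores)), levels = types),
    score = as.vector(scores))
  fit <- stats::aov(score ~ type + Error(participant), data = long)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1L]]
  subj <- s[["Error: participant"]][[1L]]
  wr <- trimws(rownames(within))
  ss_type <- within[wr == "type", "Sum Sq"]
  ss_err <- within[wr == "Residuals", "Sum Sq"]
  ss_subj <- subj[trimws(rownames(subj)) == "Residuals", "Sum Sq"]
  anova <- list(F = within[wr == "type", "F value"],
                df1 = within[wr == "type", "Df"],
                df2 = within[wr == "Residuals", "Df"],
                pval = within[wr == "type", "Pr(>F)"],
                ges = ss_type / (ss_type + ss_subj + ss_err))

  combs <- utils::combn(types, 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- scores[, combs[1L, i]]
    b <- scores[, combs[2L, i]]
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(A = combs[1L, i], B = combs[2L, i],
               T = unname(tt$statistic), dof = unname(tt$parameter),
               p = tt$p.value, hedges = hedges_g_paired(a - b),
               stringsAsFactors = FALSE)
  }))
  pairwise$p_corr <- pmin(1, pairwise$p * nrow(pairwise))
  structure(list(scores = scores, anova = anova,
                 pairwise = pairwise[, c("A", "B", "T", "dof", "p_corr",
                                         "hedges")]),
            class = "washout_analysis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
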