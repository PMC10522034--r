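MODEL_FAMILIES <- c("error_scaling", "retention_scaling", "bias_scaling",
                    "state_aim_scaling", "output_aim_scaling")

#' Specify a state-space model variant
#'
#' A model is identified by its uncertainty-scaling family, the number of
#' feedforward states, and whether the non-negative parameter-bound regime is
#' used. The five families place the uncertainty scaling at different loci of
#' the learning system: the error term, the retention term, the bias term, a
#' memoryless state-level aim, or the motor output directly.
#'
#' `state_aim_scaling` has no fast-state learning-rate/retention parameters
#' (its fast state is fully determined by the previous trial's uncertainty);
#' the non-negative regime is defined for two-state models only (it constrains
#' parameter bounds so that the internal states stay non-negative; states are
#' never clipped at run time).
#'
#' @param family One of `"error_scaling"`, `"retention_scaling"`,
#'   `"bias_scaling"`, `"state_aim_scaling"`, `"output_aim_scaling"`.
#' @param n_states 1 or 2.
#' @param nonneg Logical; non-negative bound regime (two-state only).
#' @return A `vm_model_spec`.
#' @export
model_spec <- function(family = MODEL_FAMILIES, n_states = 2, nonneg = FALSE) {
  family <- match.arg(family)
  if (!n_states %in% c(1, 2)) stop("'n_states' must be 1 or 2", call. = FALSE)
  if (nonneg && n_states != 2)
    stop("the non-negative bound regime is defined for two-state models only",
         call. = FALSE)
  structure(list(family = family, n_states = as.integer(n_states),
                 nonneg = isTRUE(nonneg)),
            class = "vm_model_spec")
}

#' @export
print.vm_model_spec <- function(x, ...) {
  cat(sprintf("Model: %s, %d-state%s\n", x$family, x$n_states,
              if (x$nonneg) " (non-negative bounds)" else ""))
  invisible(x)
}

#' @export
format.vm_model_spec <- function(x, ...) {
  paste0(sub("_scaling", "", x$family), "-", x$n_states, "state",
         if (x$nonneg) "-nonneg" else "")
}

spec_label <- function(spec) format(spec)

is_aim_family <- function(family)
  family %in% c("state_aim_scaling", "output_aim_scaling")

#' Parameter bounds for a model variant
#'
#' Transcribes the study's parameter-bound table for the given family, state
#' count and bound regime. Fixed parameters are encoded as `lower == upper`
#' (e.g. the slow-state bias is fixed at 0 for the error-, retention- and
#' bias-scaling two-state models); parameters absent from a variant are
#' omitted from the table. The number of free parameters counted for BIC is
#' the number of rows with `lower < upper`.
#'
#' The aim families keep `lambda_f` as the (scaled) aim amplitude with bounds
#' (-10, 10) (non-negative regime: (0, 10)); `output_aim_scaling`
#' additionally carries fast-state `alpha_f`/`beta_f` in (0, 1), which govern
#' its unscaled feedforward update.
#'
#' @param spec A `vm_model_spec`.
#' @return Data frame with columns `parameter`, `lower`, `upper`.
#' @export
bounds_table <- function(spec) {
  stopifnot(inherits(spec, "vm_model_spec"))
  fam <- spec$family
  aim <- is_aim_family(fam)

  b <- list()
  if (fam != "state_aim_scaling") {
    b$alpha_f <- c(0, 1)
    b$beta_f  <- c(0, 1)
  }
  b$lambda_f <- if (spec$nonneg) c(0, 10) else c(-10, 10)
  if (spec$n_states == 2) {
    b$alpha_s  <- c(0, 1)
    b$beta_s   <- c(0, 1)
    b$lambda_s <- if (aim) c(0, 1) else c(0, 0)
  }
  b$alpha_fb  <- c(0, 1)
  b$beta_fb   <- c(-10, 10)
  b$x_fb_init <- c(-2, 2)
  for (l in UNCERTAINTY_LEVELS) b[[paste0("nu_ff_", l)]] <- c(0, 1)
  fb_bounds <- if (aim) {
    if (spec$nonneg) c(0, 20) else c(-20, 20)
  } else if (fam == "bias_scaling") c(-1, 1) else c(0, 1)
  for (l in UNCERTAINTY_LEVELS) b[[paste0("nu_fb_", l)]] <- fb_bounds
  ## literal transcription quirk of the source table: the bias-scaling
  ## non-negative column narrows only the fourth feedback-scaling entry
  if (fam == "bias_scaling" && spec$nonneg) b$nu_fb_INF <- c(0, 1)
  b$gamma <- c(0, 1)

  data.frame(parameter = names(b),
             lower = vapply(b, `[`, numeric(1), 1L),
             upper = vapply(b, `[`, numeric(1), 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Number of free parameters of a model variant
#'
#' Counts bound-table rows with `lower < upper`; this is the `k` entering the
#' BIC penalty.
#'
#' @param spec A `vm_model_spec`.
#' @return Integer count.
#' @export
count_free_parameters <- function(spec) {
  bt <- bounds_table(spec)
  sum(bt$lower < bt$upper)
}

param_names <- function(spec) bounds_table(spec)$parameter

#' Construct a model parameter vector
#'
#' Returns a named numeric vector in the canonical order of
#' [bounds_table()]. Unspecified parameters take neutral defaults (zero
#' biases, mid dynamics); all values are validated against the variant's
#' bounds. The 4-vectors `nu_ff` and `nu_fb` hold one scaling entry per
#' uncertainty level (L, M, H, INF); `nu_fb` is the feedback-command scaling
#' (the eta vector of the midpoint correction).
#'
#' @param spec A `vm_model_spec`.
#' @param ... Named scalar parameters, and/or `nu_ff`/`nu_fb` as length-4
#'   vectors.
#' @param validate Check bounds (default `TRUE`).
#' @return Named numeric vector of class `vm_model_params`.
#' @export
model_params <- function(spec, ..., validate = TRUE) {
  stopifnot(inherits(spec, "vm_model_spec"))
  defaults <- c(alpha_f = 0.1, beta_f = 0.9, lambda_f = 0,
                alpha_s = 0.05, beta_s = 0.98, lambda_s = 0,
                alpha_fb = 0.05, beta_fb = 0.9, x_fb_init = 0.5,
                nu_ff_L = 1, nu_ff_M = 1, nu_ff_H = 1, nu_ff_INF = 1,
                nu_fb_L = 1, nu_fb_M = 1, nu_fb_H = 1, nu_fb_INF = 1,
                gamma = 0.5)
  dots <- list(...)
  for (vec_name in c("nu_ff", "nu_fb")) {
    if (!is.null(dots[[vec_name]])) {
      v <- dots[[vec_name]]
      if (length(v) != 4L)
        stop(sprintf("'%s' must have length 4 (levels %s)", vec_name,
                     paste(UNCERTAINTY_LEVELS, collapse = ", ")),
             call. = FALSE)
      dots[paste0(vec_name, "_", UNCERTAINTY_LEVELS)] <- as.list(unname(v))
      dots[[vec_name]] <- NULL
    }
  }
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(dots)] <- unlist(dots)
  nm <- param_names(spec)
  p <- defaults[nm]
  if (validate) validate_params(p, spec)
  structure(p, class = "vm_model_params", spec = spec)
}

validate_params <- function(params, spec) {
  bt <- bounds_table(spec)
  p <- params[bt$parameter]
  if (anyNA(p))
    stop("missing parameter(s): ",
         paste(bt$parameter[is.na(p)], collapse = ", "), call. = FALSE)
  bad <- p < bt$lower - 1e-12 | p > bt$upper + 1e-12
  if (any(bad))
    stop("parameter(s) outside bounds: ",
         paste(sprintf("%s=%g not in (%g, %g)", bt$parameter[bad], p[bad],
                       bt$lower[bad], bt$upper[bad]), collapse = "; "),
         call. = FALSE)
  invisible(TRUE)
}

## Extract the nu_ff / nu_fb entries of a parameter vector as a length-4
## vector ordered L, M, H, INF.
param_levels <- function(params, which = c("nu_ff", "nu_fb")) {
  which <- match.arg(which)
  unname(params[paste0(which, "_", UNCERTAINTY_LEVELS)])
}

#' Write / read model parameters as a flat key-value file
#'
#' @param params A named parameter vector (e.g. from [model_params()]).
#' @param file Path.
#' @return `read_params` returns a named numeric vector.
#' @export
write_params <- function(params, file) {
  utils::write.table(data.frame(parameter = names(params),
                                value = as.numeric(params)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$value, df$parameter)
}
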