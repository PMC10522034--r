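#' Bayesian Information Criterion from variance explained
#'
#' `BIC = n * ln(1 - R^2) + k * ln(n)`; lower values are preferred. A perfect
#' fit (`R^2 >= 1`) degenerates the criterion and is signalled as an error.
#'
#' @param n Number of data points (residuals entering the objective).
#' @param k Number of free parameters.
#' @param r2 Proportion of variance explained (`< 1`).
#' @return BIC score (vectorised over its arguments).
#' @export
bic <- function(n, k, r2) {
  if (any(n < 1) || any(k < 0)) stop("need n >= 1 and k >= 0", call. = FALSE)
  if (any(r2 >= 1))
    stop("r2 >= 1: perfect fit degenerates the criterion", call. = FALSE)
  n * log(1 - r2) + k * log(n)
}

## Normalise a list of vm_fit_result (or a data.frame) into the long table
## (participant, model, bic, k) used by the comparison functions.
as_fit_table <- function(fits) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("participant", "model", "bic") %in% names(fits)))
    if (is.null(fits$k)) fits$k <- 0L
    return(fits[, c("participant", "model", "bic", "k")])
  }
  do.call(rbind, lapply(names(fits), function(pid) {
    data.frame(participant = pid,
               model = vapply(fits[[pid]], function(f) spec_label(f$spec), ""),
               bic = vapply(fits[[pid]], `[[`, numeric(1), "bic"),
               k = vapply(fits[[pid]], `[[`, numeric(1), "k"),
               stringsAsFactors = FALSE)
  }))
}

#' Rank models within participants by BIC
#'
#' Orders every participant's fitted models from best (smallest BIC, rank 1)
#' to worst, then tabulates how many participants placed each model at each
#' rank, alongside per-model mean and SD of BIC. Every participant must have
#' a fit for every model. Ties are broken deterministically by fewer free
#' parameters, then by model name; tied rows are flagged.
#'
#' @param fits Either a named list (participant -> list of `vm_fit_result`)
#'   or a data frame with columns `participant`, `model`, `bic` (and
#'   optionally `k`).
#' @return A `model_comparison`: list with `rows` (participant, model, bic,
#'   rank, tied), `summary` (per-model mean/sd BIC), `rank_counts`
#'   (model x rank matrix).
#' @export
rank_models <- function(fits) {
  tab <- as_fit_table(fits)
  models <- sort(unique(tab$model))
  grid <- table(tab$participant, tab$model)
  if (any(grid != 1L))
    stop("incomplete fit grid: every participant needs exactly one fit per model",
         call. = FALSE)
  parts <- split(tab, tab$participant)
  rows <- do.call(rbind, lapply(parts, function(df) {
    o <- order(df$bic, df$k, df$model)
    df <- df[o, ]
    df$rank <- seq_len(nrow(df))
    df$tied <- duplicated(df$bic) | duplicated(df$bic, fromLast = TRUE)
    df
  }))
  rownames(rows) <- NULL
  rank_counts <- table(factor(rows$model, levels = models), rows$rank)
  summary <- do.call(rbind, lapply(models, function(mdl) {
    b <- tab$bic[tab$model == mdl]
    data.frame(model = mdl, mean_bic = mean(b), sd_bic = stats::sd(b),
               stringsAsFactors = FALSE)
  }))
  structure(list(rows = rows, summary = summary, rank_counts = rank_counts),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (lower BIC preferred):\n")
  print(x$summary[order(x$summary$mean_bic), ], row.names = FALSE)
  invisible(x)
}

hedges_g_paired <- function(d) {
  df <- length(d) - 1L
  (mean(d) / stats::sd(d)) * (1 - 3 / (4 * df - 1))
}

#' Paired comparisons of BIC between model classes
#'
#' Paired t-tests of per-participant BIC between models, with Bonferroni
#' correction across the tested pairs and Hedges g effect sizes (bias-
#' corrected standardised mean paired difference). `grouping = "by_states"`
#' pairs each two-state variant with its one-state counterpart;
#' `grouping = "by_family"` compares all family pairs within each state
#' count; an explicit two-column matrix/data frame of model labels can be
#' given instead.
#'
#' @param fits As in [rank_models()].
#' @param grouping `"by_states"`, `"by_family"`, or a two-column table of
#'   model label pairs.
#' @return Data frame with `model_a`, `model_b`, `mean_diff`, `T`, `dof`,
#'   `p`, `p_corr`, `hedges`.
#' @export
paired_bic_tests <- function(fits, grouping = "by_states") {
  tab <- as_fit_table(fits)
  models <- sort(unique(tab$model))
  if (is.character(grouping)) {
    grouping <- match.arg(grouping, c("by_states", "by_family"))
    pairs <- if (grouping == "by_states") {
      two <- grep("-2state", models, value = TRUE)
      one <- sub("-2state", "-1state", two)
      keep <- one %in% models
      cbind(two[keep], one[keep])
    } else {
      by_states <- split(models, sub(".*-(\\d)state.*", "\\1", models))
      do.call(rbind, lapply(by_states, function(ms) {
        if (length(ms) < 2L) return(NULL)
        t(utils::combn(ms, 2L))
      }))
    }
  } else {
    pairs <- as.matrix(grouping)
  }
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no model pairs to compare", call. = FALSE)
  wide <- stats::reshape(tab[, c("participant", "model", "bic")],
                         idvar = "participant", timevar = "model",
                         direction = "wide")
  if (nrow(wide) < 2L)
    stop("insufficient data: need at least 2 participants", call. = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- wide[[paste0("bic.", pairs[i, 1])]]
    b <- wide[[paste0("bic.", pairs[i, 2])]]
    d <- a - b
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(model_a = pairs[i, 1], model_b = pairs[i, 2],
               mean_diff = mean(d), T = unname(tt$statistic),
               dof = unname(tt$parameter), p = tt$p.value,
               hedges = hedges_g_paired(d), stringsAsFactors = FALSE)
  }))
  res$p_corr <- stats::p.adjust(res$p, method = "bonferroni")
  res[, c("model_a", "model_b", "mean_diff", "T", "dof", "p", "p_corr",
          "hedges")]
}
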