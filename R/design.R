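#' @keywords internal
"_PACKAGE"

## Ordinal vocabulary of cursor-feedback uncertainty. INF is the no-feedback
## adaptation condition; baseline/washout trials carry NA ("none") instead so
## that "no feedback by design phase" stays distinguishable from the
## no-feedback adaptation condition.
UNCERTAINTY_LEVELS <- c("L", "M", "H", "INF")

#' Ordered uncertainty levels
#'
#' The four cursor-feedback uncertainty conditions, ordered from a single
#' veridical dot (`"L"`), through 50-point clouds with 0.5 cm (`"M"`) and
#' 1 cm (`"H"`) standard deviation, to no feedback at all (`"INF"`).
#'
#' @return Character vector `c("L", "M", "H", "INF")`.
#' @export
uncertainty_levels <- function() UNCERTAINTY_LEVELS

## Map level labels to the 1..4 index used by the nu/eta scaling vectors.
## NA ("none": baseline or washout) maps to the INF slot, the least
## informative entry, so the scaled equations stay defined on every trial.
level_index <- function(level) {
  idx <- match(as.character(level), UNCERTAINTY_LEVELS)
  idx[is.na(idx)] <- 4L
  idx
}

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Sample trial-by-trial visuomotor rotations
#'
#' Rotation magnitudes for the adaptation phase are drawn i.i.d. from a
#' Gaussian; the study design uses mean 12 degrees and standard deviation 4
#' degrees. Positive values displace the cursor counter-clockwise of the hand.
#'
#' @param n_trials Number of rotations to draw (>= 1).
#' @param mean_deg Mean rotation in degrees.
#' @param sd_deg Standard deviation in degrees (>= 0).
#' @param seed Optional integer seed; identical seeds give identical
#'   sequences, which is how perturbations are trial-matched across synthetic
#'   participants.
#' @return Numeric vector of rotations in degrees.
#' @export
sample_perturbations <- function(n_trials, mean_deg = 12, sd_deg = 4,
                                 seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("'n_trials' must be a positive count", call. = FALSE)
  if (sd_deg < 0) stop("'sd_deg' must be non-negative", call. = FALSE)
  with_seed(seed, stats::rnorm(as.integer(n_trials), mean_deg, sd_deg))
}

#' Build the trial schedule of one experiment
#'
#' Generates the full 300-trial design of one of the three experiments:
#' 20 baseline trials (veridical feedback, no rotation), 180 adaptation trials
#' (Gaussian rotations, uncertainty-coded feedback) and 100 washout trials
#' (no feedback, no rotation).
#'
#' The adaptation-phase uncertainty assignment is a seeded permutation of a
#' balanced label vector (45 trials per condition). Experiment 1 delivers
#' feedback at midpoint only (`ep_uncertainty` is `NA`); Experiment 2 delivers
#' matched midpoint and endpoint uncertainty; Experiment 3 crosses low/high
#' midpoint with low/high endpoint uncertainty (trial types LL, LH, HL, HH,
#' 45 each).
#'
#' @param experiment_id Integer 1, 2 or 3.
#' @param seed Integer seed controlling both the uncertainty interleaving and
#'   the rotation sequence (drawn once per schedule, trial-matched across
#'   participants).
#' @param rotation_mean_deg,rotation_sd_deg Parameters of the rotation
#'   distribution.
#' @return A `trial_schedule`: a data frame with columns `trial`, `phase`,
#'   `rotation_deg`, `mp_uncertainty`, `ep_uncertainty` and attributes
#'   `experiment_id` and `seed`.
#' @export
build_schedule <- function(experiment_id, seed,
                           rotation_mean_deg = 12, rotation_sd_deg = 4) {
  if (!experiment_id %in% 1:3)
    stop("'experiment_id' must be 1, 2 or 3", call. = FALSE)
  n_base <- 20L; n_adapt <- 180L; n_wash <- 100L
  out <- with_seed(seed, {
    rot <- stats::rnorm(n_adapt, rotation_mean_deg, rotation_sd_deg)
    if (experiment_id == 3L) {
      combos <- c("LL", "LH", "HL", "HH")
      lab <- sample(rep(combos, each = n_adapt / 4L))
      mp <- substr(lab, 1, 1)
      ep <- substr(lab, 2, 2)
    } else {
      mp <- sample(rep(UNCERTAINTY_LEVELS, each = n_adapt / 4L))
      ep <- if (experiment_id == 2L) mp else rep(NA_character_, n_adapt)
    }
    list(rot = rot, mp = mp, ep = ep)
  })
  sched <- data.frame(
    trial = seq_len(n_base + n_adapt + n_wash),
    phase = rep(c("baseline", "adaptation", "washout"),
                times = c(n_base, n_adapt, n_wash)),
    rotation_deg = c(rep(0, n_base), out$rot, rep(0, n_wash)),
    mp_uncertainty = c(rep(NA_character_, n_base), out$mp,
                       rep(NA_character_, n_wash)),
    ep_uncertainty = c(rep(NA_character_, n_base), out$ep,
                       rep(NA_character_, n_wash)),
    stringsAsFactors = FALSE
  )
  structure(sched,
            experiment_id = as.integer(experiment_id),
            seed = as.integer(seed),
            class = c("trial_schedule", "data.frame"))
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("Trial schedule: experiment %d, %d trials (seed %d)\n",
              attr(x, "experiment_id"), nrow(x), attr(x, "seed")))
  counts <- table(x$phase)[c("baseline", "adaptation", "washout")]
  cat(sprintf("  phases: baseline %d / adaptation %d / washout %d\n",
              counts[1], counts[2], counts[3]))
  invisible(x)
}

#' Generate a stimulus point cloud for one uncertainty level
#'
#' Feedback is rendered as a cloud of translucent circles centred on the
#' (perturbed) cursor position: a single zero-offset point for `"L"`, 50
#' points drawn from an isotropic 2-D Gaussian with per-axis SD 0.5 cm for
#' `"M"` and 1 cm for `"H"`, and an empty cloud for `"INF"` (no feedback).
#'
#' @param level One of `uncertainty_levels()`.
#' @param seed Optional integer seed.
#' @return A `stimulus_cloud`: list with `points` (n x 2 matrix of offsets in
#'   cm), `sd_cm` and `n_points`.
#' @export
generate_cloud <- function(level, seed = NULL) {
  level <- match.arg(as.character(level), UNCERTAINTY_LEVELS)
  sd_cm <- switch(level, L = 0, M = 0.5, H = 1, INF = NA_real_)
  n_points <- switch(level, L = 1L, M = 50L, H = 50L, INF = 0L)
  points <- if (level == "L") {
    matrix(0, 1L, 2L)
  } else if (level == "INF") {
    matrix(numeric(0), 0L, 2L)
  } else {
    with_seed(seed, matrix(stats::rnorm(2L * n_points, 0, sd_cm), n_points, 2L))
  }
  colnames(points) <- c("x_cm", "y_cm")
  structure(list(points = points, sd_cm = sd_cm, n_points = n_points,
                 level = level),
            class = "stimulus_cloud")
}

#' Angular subtense of a stimulus extent
#'
#' Converts a linear extent at a given radial distance into the arc-angle it
#' subtends, using the small-angle arc convention `extent / radius` radians.
#' With this convention a 0.5 cm extent subtends 5.73 degrees at the 5 cm
#' midpoint and 2.86 degrees at the 10 cm endpoint.
#'
#' @param sd_cm Linear extent in cm (e.g. the cloud SD).
#' @param radius_cm Radial distance in cm (> 0).
#' @return Arc-angle in degrees.
#' @export
angular_subtense <- function(sd_cm, radius_cm) {
  if (any(radius_cm <= 0)) stop("'radius_cm' must be positive", call. = FALSE)
  (sd_cm / radius_cm) * 180 / pi
}

#' Write / read a trial schedule as a delimited table
#'
#' One row per trial, tab-separated, header required; missing uncertainty
#' ("none") is encoded as an empty field.
#'
#' @param schedule A `trial_schedule`.
#' @param file Path to write to / read from.
#' @return `read_schedule` returns a `trial_schedule` (experiment id and seed
#'   are restored from a header comment when present).
#' @export
write_schedule <- function(schedule, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# experiment_id=%d seed=%d",
                     attr(schedule, "experiment_id"),
                     attr(schedule, "seed")), con)
  utils::write.table(as.data.frame(schedule), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(file) {
  first <- readLines(file, n = 1L)
  meta <- c(experiment_id = NA_integer_, seed = NA_integer_)
  if (startsWith(first, "#")) {
    m <- regmatches(first, gregexpr("[a-z_]+=-?[0-9]+", first))[[1]]
    for (kv in m) {
      kvs <- strsplit(kv, "=", fixed = TRUE)[[1]]
      meta[kvs[1]] <- as.integer(kvs[2])
    }
  }
  df <- utils::read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                          na.strings = "", stringsAsFactors = FALSE)
  df$mp_uncertainty <- as.character(df$mp_uncertainty)
  df$ep_uncertainty <- as.character(df$ep_uncertainty)
  structure(df,
            experiment_id = unname(meta["experiment_id"]),
            seed = unname(meta["seed"]),
            class = c("trial_schedule", "data.frame"))
}
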