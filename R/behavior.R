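# The four behavioral test metrics and the directional Z-score
# emotionality composite. Each per-test Z is signed so that a higher
# positive value means poorer performance; the composite is the
# equal-weight mean over the four tests.

#' Sucrose preference (%)
#'
#' Preference = sucrose intake / total liquid intake x 100. A lower
#' preference indicates anhedonia.
#'
#' @param sucrose_intake,water_intake consumed amounts (g), both >= 0 and
#'   not both zero.
#' @return Preference in percent, in `[0, 100]`.
#' @export
sucrose_preference <- function(sucrose_intake, water_intake) {
  if (any(sucrose_intake < 0) || any(water_intake < 0))
    stop("intakes must be non-negative")
  total <- sucrose_intake + water_intake
  if (any(total == 0))
    stop("total liquid intake is zero: animal must be excluded")
  100 * sucrose_intake / total
}

#' Social interaction ratio
#'
#' Time in the interaction zone with a target divided by the time without;
#' a ratio below 1 flags reduced sociability.
#'
#' @param time_with_target,time_without_target zone times (s).
#' @return A list with `ratio` and logical `reduced_sociability`.
#' @export
si_ratio <- function(time_with_target, time_without_target) {
  if (any(time_with_target < 0)) stop("times must be non-negative")
  if (any(time_without_target <= 0))
    stop("time without target must be positive")
  r <- time_with_target / time_without_target
  list(ratio = r, reduced_sociability = r < 1)
}

#' Forced-swim immobility within the scored window
#'
#' Sums the overlap of (merged) immobility intervals with the scored
#' window — by default the last 4 min of a 6-min test.
#'
#' @param intervals two-column matrix or data.frame of `(start, end)`
#'   times in seconds, within `[0, test_length]`.
#' @param test_length session length, s.
#' @param scored_window `(start, end)` of the scored window, s.
#' @return Total immobile time (s) inside the window.
#' @export
fst_immobility <- function(intervals, test_length = 360,
                           scored_window = c(120, 360)) {
  iv <- as.matrix(intervals)
  if (length(iv) == 0L) return(0)
  if (ncol(iv) != 2L) stop("`intervals` must have two columns (start, end)")
  if (any(iv[, 1] > iv[, 2])) stop("interval start exceeds its end")
  if (any(iv < 0) || any(iv > test_length))
    stop("interval outside the test session [0, ", test_length, "]")
  # merge overlaps, then clip to the window
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[i, 1] <= merged[last, 2])
      merged[last, 2] <- max(merged[last, 2], iv[i, 2])
    else merged <- rbind(merged, iv[i, ])
  }
  lo <- pmax(merged[, 1], scored_window[1])
  hi <- pmin(merged[, 2], scored_window[2])
  sum(pmax(hi - lo, 0))
}

#' Open-arm time metric of the elevated plus maze
#'
#' @param open_time time in the open arms (s), within `[0, session]`.
#' @param session session length, s (default 300).
#' @param as_percent return percent of session instead of seconds.
#' @return Seconds or percent.
#' @export
epm_open_metric <- function(open_time, session = 300, as_percent = FALSE) {
  if (any(open_time < 0)) stop("open-arm time must be non-negative")
  if (any(open_time > session))
    stop("open-arm time exceeds the session length")
  if (as_percent) 100 * open_time / session else open_time
}

# fixed valence of each test: +1 = higher raw value is worse
.metric_directions <- c(spt = -1, si_ratio = -1, epm_open = -1,
                        fst_immobility = +1)

#' Control-group reference for Z-score normalization
#'
#' Computes per-metric mean and SD of the control group, against which
#' every animal is standardized.
#'
#' @param cohort data.frame as returned by [simulate_cohort()] (columns
#'   `group`, `spt`, `si_ratio`, `epm_open`, `fst_immobility`).
#' @param control control group label (default `"sham"`).
#' @param metrics metric columns to use.
#' @return A `control_reference` list with `mu`, `sigma`, `directions`.
#' @export
control_reference <- function(cohort, control = "sham",
                              metrics = names(.metric_directions)) {
  ctl <- cohort[cohort$group == control, metrics, drop = FALSE]
  if (nrow(ctl) < 2L)
    stop("control group '", control, "' needs at least 2 animals")
  mu <- vapply(ctl, mean, numeric(1))
  sigma <- vapply(ctl, sd, numeric(1))
  if (any(sigma <= 0)) stop("control SD must be positive for every metric")
  structure(list(mu = mu, sigma = sigma,
                 directions = .metric_directions[metrics],
                 control = control),
            class = "control_reference")
}

#' Directional Z-score for a single metric
#'
#' `z = direction x (x - mu) / sigma` against the control reference, with
#' fixed directions: sucrose preference, SI ratio and open-arm time are
#' higher-is-better (direction -1), immobility is higher-is-worse (+1), so
#' a higher positive Z always indicates poorer performance.
#'
#' @param x raw metric value(s).
#' @param ref a [control_reference()], or a list with `mu`/`sigma` named
#'   vectors.
#' @param metric one of `"spt"`, `"si_ratio"`, `"epm_open"`,
#'   `"fst_immobility"`.
#' @return Z value(s).
#' @export
directional_z <- function(x, ref, metric) {
  if (!metric %in% names(.metric_directions))
    stop("unknown metric '", metric, "'")
  mu <- ref$mu[[metric]]; sigma <- ref$sigma[[metric]]
  if (sigma <= 0) stop("reference sigma must be positive")
  unname(.metric_directions[[metric]] * (x - mu) / sigma)
}

#' Composite behavioral emotionality Z-score
#'
#' Equal-weight mean of the per-test Z-scores,
#' `[Z(SPT) + Z(SIT) + Z(EPMT) + Z(FST)] / 4`.
#'
#' @param z numeric vector (or list) of per-test Z values.
#' @param allow_partial if `TRUE`, missing tests are dropped and the mean
#'   is taken over the available ones (logged); default requires all.
#' @return The composite Z.
#' @export
composite_z <- function(z, allow_partial = FALSE) {
  z <- unlist(z)
  if (length(z) == 0L || all(is.na(z))) stop("no Z-scores supplied")
  if (any(is.na(z))) {
    if (!allow_partial) stop("missing per-test Z-scores; set allow_partial")
    message("composite over ", sum(!is.na(z)), " of ", length(z), " tests")
  }
  mean(z, na.rm = TRUE)
}

#' Per-animal Z-score table
#'
#' Standardizes every animal in a cohort against the control group and
#' appends the composite emotionality score.
#'
#' @param cohort data.frame with `animal_id`, `group` and the four metric
#'   columns.
#' @param control control group label (default `"sham"`).
#' @param ref optional precomputed [control_reference()] (e.g. when the
#'   cohort itself has no control arm).
#' @return The cohort with added columns `z_spt`, `z_sit`, `z_epmt`,
#'   `z_fst` and `z_composite`.
#' @export
zscore_table <- function(cohort, control = "sham", ref = NULL) {
  if (is.null(ref)) ref <- control_reference(cohort, control)
  out <- cohort
  out$z_spt <- directional_z(cohort$spt, ref, "spt")
  out$z_sit <- directional_z(cohort$si_ratio, ref, "si_ratio")
  out$z_epmt <- directional_z(cohort$epm_open, ref, "epm_open")
  out$z_fst <- directional_z(cohort$fst_immobility, ref, "fst_immobility")
  out$z_composite <- rowMeans(out[, c("z_spt", "z_sit", "z_epmt", "z_fst")])
  out
}
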