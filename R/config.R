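#' Synthetic cohort configuration
#'
#' Builds and validates the configuration of the synthetic study generator.
#' Defaults emulate the pilot design the analyses assume: four monitoring
#' days, two prompts in each of four daily time blocks (09:00-12:00,
#' 12:00-15:00, 15:00-19:00, 19:00-22:00) of which the day's last prompt is
#' a retrospective one, one to three dietary-recall days per participant,
#' recall omission and clock-time displacement noise, a row-stochastic
#' misreport matrix linking true to reported activity intensity, and
#' per-level lognormal epoch count distributions concentrated inside the
#' Freedson bands.
#'
#' @param n_participants Number of participants.
#' @param n_days Monitoring days per participant (default 4).
#' @param prompts_per_block Prompts drawn per time block (default 2).
#' @param time_blocks 4x2 matrix of block start/end in minutes since
#'   midnight, rows ordered and non-overlapping.
#' @param eating_rate Mean true eating occasions per participant-day
#'   (Poisson; default 3.7, matching roughly 3-4 recall instances/day).
#' @param food_group_probs Probability vector over the six food groups.
#' @param recall_omission_prob Probability a true eating occasion is absent
#'   from the recall table (default 0.2).
#' @param recall_time_sd_min SD (minutes) of the centred Gaussian clock-time
#'   displacement applied to surviving recall instances (default 60).
#' @param recall_days_range Integer range; each participant contributes a
#'   uniform number of recall days in this range (default 1-3).
#' @param eat_window_min Lookback (minutes) within which a true eating
#'   occasion is endorsed at a momentary prompt (default 45).
#' @param pa_level_probs Probability vector over the four intensity levels
#'   governing the true activity bout process.
#' @param misreport_matrix 4x4 row-stochastic matrix, rows = true occasion
#'   level, columns = reported level (default estimated from observed
#'   reported-given-derived frequencies in the validation study design).
#' @param count_params List with numeric vectors `meanlog`, `sdlog` (length
#'   4, per level) and scalar `spill`, the probability a draw is not
#'   truncated to its level's cut-point band.
#' @param day_kcal_range Interval for simulated daily energy (kcal).
#' @param bout_mean_min Mean activity bout duration in minutes (default 30).
#' @param latency_range Minutes relative to the prompt within which the
#'   survey may be completed (default c(-5, 30), the availability window).
#' @param seed Integer seed; `generate_cohort()` is deterministic given the
#'   config (seed included).
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_participants = 41,
                          n_days = 4,
                          prompts_per_block = 2,
                          time_blocks = default_time_blocks(),
                          eating_rate = 3.7,
                          food_group_probs = default_food_group_probs(),
                          recall_omission_prob = 0.2,
                          recall_time_sd_min = 60,
                          recall_days_range = c(1L, 3L),
                          eat_window_min = 45,
                          pa_level_probs = c(0.55, 0.40, 0.045, 0.005),
                          misreport_matrix = default_misreport_matrix(),
                          count_params = default_count_params(),
                          day_kcal_range = c(1400, 3000),
                          bout_mean_min = 30,
                          latency_range = c(-5, 30),
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    prompts_per_block = as.integer(prompts_per_block),
    time_blocks = time_blocks,
    eating_rate = eating_rate,
    food_group_probs = food_group_probs,
    recall_omission_prob = recall_omission_prob,
    recall_time_sd_min = recall_time_sd_min,
    recall_days_range = as.integer(recall_days_range),
    eat_window_min = eat_window_min,
    pa_level_probs = pa_level_probs,
    misreport_matrix = misreport_matrix,
    count_params = count_params,
    day_kcal_range = day_kcal_range,
    bout_mean_min = bout_mean_min,
    latency_range = latency_range,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

#' @rdname cohort_config
#' @export
default_time_blocks <- function() {
  m <- matrix(c(9, 12, 12, 15, 15, 19, 19, 22) * 60, ncol = 2, byrow = TRUE)
  dimnames(m) <- list(c("morning", "midday", "afternoon", "evening"),
                      c("start", "end"))
  m
}

#' @rdname cohort_config
#' @export
default_food_group_probs <- function() {
  # recall-frequency-weighted mix of the five named groups plus a small
  # "other" mass; sums to 1
  p <- c(sweets = 404, salty = 426, fruits_vegetables = 347,
         entree = 294, breads_grains = 392)
  p <- 0.95 * p / sum(p)
  c(p, other = 0.05)
}

#' @rdname cohort_config
#' @export
default_misreport_matrix <- function() {
  # P(reported | true) per true level; rows sum to 1. Sedentary occasions
  # are reported faithfully; light/moderate occasions are frequently
  # reported as sedentary, mirroring the weak discrimination among
  # non-sedentary levels that validation studies of momentary self-report
  # find.
  m <- rbind(
    sedentary = c(0.914, 0.051, 0.030, 0.005),
    light     = c(0.736, 0.130, 0.070, 0.064),
    moderate  = c(0.433, 0.189, 0.243, 0.135),
    vigorous  = c(0.10,  0.10,  0.15,  0.65)
  )
  colnames(m) <- pa_levels()
  m / rowSums(m)
}

#' @rdname cohort_config
#' @export
default_count_params <- function() {
  list(
    meanlog = c(sedentary = log(30), light = log(450),
                moderate = log(3300), vigorous = log(7500)),
    sdlog = c(sedentary = 0.5, light = 0.5, moderate = 0.25, vigorous = 0.15),
    spill = 0.05
  )
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 0, cfg$n_days >= 0,
            cfg$prompts_per_block >= 0, cfg$eating_rate >= 0,
            cfg$recall_time_sd_min >= 0, cfg$eat_window_min >= 0,
            cfg$bout_mean_min > 0)
  tb <- cfg$time_blocks
  if (!is.matrix(tb) || ncol(tb) != 2) {
    stop("`time_blocks` must be a matrix with two columns", call. = FALSE)
  }
  if (any(tb[, 2] <= tb[, 1])) {
    stop("empty or inverted time block", call. = FALSE)
  }
  if (nrow(tb) > 1 && any(tb[-1, 1] < tb[-nrow(tb), 2])) {
    stop("time blocks overlap or are unordered", call. = FALSE)
  }
  check_prob <- function(p, name, len) {
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("`", name, "` must be a length-", len,
           " probability vector summing to 1", call. = FALSE)
    }
  }
  check_prob(cfg$food_group_probs, "food_group_probs", 6)
  check_prob(cfg$pa_level_probs, "pa_level_probs", 4)
  mm <- cfg$misreport_matrix
  if (!is.matrix(mm) || any(dim(mm) != c(4, 4)) || any(mm < 0) ||
      any(abs(rowSums(mm) - 1) > 1e-9)) {
    stop("`misreport_matrix` must be 4x4 row-stochastic", call. = FALSE)
  }
  if (cfg$recall_omission_prob < 0 || cfg$recall_omission_prob > 1) {
    stop("`recall_omission_prob` must be in [0, 1]", call. = FALSE)
  }
  stopifnot(length(cfg$recall_days_range) == 2,
            cfg$recall_days_range[1] >= 0,
            cfg$recall_days_range[2] >= cfg$recall_days_range[1])
  cp <- cfg$count_params
  stopifnot(length(cp$meanlog) == 4, length(cp$sdlog) == 4,
            all(cp$sdlog > 0), cp$spill >= 0, cp$spill <= 1)
  stopifnot(length(cfg$day_kcal_range) == 2,
            cfg$day_kcal_range[2] >= cfg$day_kcal_range[1])
  invisible(cfg)
}

#' Exclusion-filter thresholds
#'
#' The fixed screening constants of the validation analyses: a recall day is
#' biologically plausible when its energy lies in the closed interval
#' \[`kcal_min`, `kcal_max`\]; a momentary report is excluded when the
#' accelerometer counts are all zero for `zero_window_min` minutes on either
#' side of the response or the device was worn less than `min_wear_hours`
#' that day; the derived activity measure averages the `preprompt_avg_min`
#' minutes before the response.
#'
#' @param kcal_min,kcal_max Daily-energy plausibility bounds (kcal).
#' @param zero_window_min Zero-count flank width in minutes.
#' @param min_wear_hours Minimum daily wear time in hours.
#' @param preprompt_avg_min Pre-response averaging window in minutes.
#' @param nonwear_run_min Minimum consecutive-zero run (minutes) counted as
#'   non-wear when computing wear time.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(kcal_min = 500, kcal_max = 5000,
                              zero_window_min = 30, min_wear_hours = 5,
                              preprompt_avg_min = 5, nonwear_run_min = 60) {
  stopifnot(kcal_min <= kcal_max, zero_window_min > 0, min_wear_hours >= 0,
            preprompt_avg_min > 0, nonwear_run_min >= 1)
  structure(list(kcal_min = kcal_min, kcal_max = kcal_max,
                 zero_window_min = zero_window_min,
                 min_wear_hours = min_wear_hours,
                 preprompt_avg_min = preprompt_avg_min,
                 nonwear_run_min = nonwear_run_min),
            class = "filter_thresholds")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d participants x %d days; %d prompts per block (%d blocks)\n",
              x$n_participants, x$n_days, x$prompts_per_block,
              nrow(x$time_blocks)))
  cat(sprintf("  eating rate %.2f/day; recall omission %.2f, time SD %.0f min\n",
              x$eating_rate, x$recall_omission_prob, x$recall_time_sd_min))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
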