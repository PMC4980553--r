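#' Sample one day's interval-contingent prompt schedule
#'
#' Draws `prompts_per_block` prompt times uniformly within each of the
#' configured daily time blocks, sorts them, and flags the last prompt of
#' the day as the retrospective (past-3-hours) prompt; all earlier prompts
#' are real-time ("what were you doing right before this text?"). With the
#' default two prompts in each of four blocks this yields eight prompts per
#' day: seven real-time and one retrospective.
#'
#' Uses the current RNG state; call [set.seed()] (or use
#' [generate_cohort()], which seeds once from the config) for
#' reproducibility.
#'
#' @param config A [cohort_config()].
#' @param participant Participant identifier (carried into the output).
#' @param date The calendar day (`Date`).
#' @return Data frame with columns `participant_id`, `prompt_time`
#'   (POSIXct, minute resolution) and `prompt_type`
#'   (`"real_time"`/`"retrospective"`), sorted by time.
#' @export
sample_prompt_schedule <- function(config, participant, date) {
  validate_cohort_config(config)
  tb <- config$time_blocks
  p <- config$prompts_per_block
  mins <- unlist(lapply(seq_len(nrow(tb)), function(b) {
    sort(stats::runif(p, tb[b, 1], tb[b, 2]))
  }))
  mins <- floor(sort(mins))
  n <- length(mins)
  if (n == 0) {
    return(data.frame(participant_id = character(0),
                      prompt_time = as.POSIXct(character(0), tz = "UTC"),
                      prompt_type = character(0), stringsAsFactors = FALSE))
  }
  type <- rep("real_time", n)
  type[n] <- "retrospective"
  data.frame(
    participant_id = rep(as.character(participant), n),
    prompt_time = make_ts(as.Date(date), min_to_clock(mins)),
    prompt_type = type,
    stringsAsFactors = FALSE
  )
}

#' Apply recall error to true eating events
#'
#' Emulates the two dominant error modes of 24-hour dietary recall: each
#' true eating occasion is independently omitted with probability
#' `recall_omission_prob`, and surviving occasions have their clock time
#' displaced by centred Gaussian noise with SD `recall_time_sd_min` minutes
#' (clamped to the occasion's calendar day). Food groups are preserved.
#'
#' @param events Data frame with `participant_id`, `timestamp` (POSIXct)
#'   and `food_group`.
#' @param config A [cohort_config()].
#' @return Recall-style data frame: `participant_id`, `date`, `clock_time`
#'   ("HH:MM"), `food_group`.
#' @export
apply_recall_noise <- function(events, config) {
  validate_cohort_config(config)
  n <- nrow(events)
  keep <- if (n) stats::runif(n) >= config$recall_omission_prob else logical(0)
  ev <- events[keep, , drop = FALSE]
  m <- nrow(ev)
  date <- ts_date(ev$timestamp)
  mins <- mins_between(make_ts(date, "00:00"), ev$timestamp)
  if (m && config$recall_time_sd_min > 0) {
    mins <- mins + stats::rnorm(m, 0, config$recall_time_sd_min)
  }
  out <- data.frame(
    participant_id = ev$participant_id,
    date = date,
    clock_time = min_to_clock(pmin(pmax(mins, 0), 1439)),
    food_group = ev$food_group,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Simulate accelerometer epoch counts from a true activity track
#'
#' Draws one 60-second epoch count per tracked minute from the level's
#' lognormal distribution. With probability `1 - spill` the draw is
#' truncated to the level's Freedson cut-point band (so it classifies back
#' to its generating level); with probability `spill` it is untruncated,
#' giving controlled spill-over into neighbouring bands for recovery tests.
#' Counts are rounded to integers and clamped at zero (with a warning) if a
#' parameterisation ever produces a negative value.
#'
#' @param track Data frame with `participant_id`, `minute` (POSIXct epoch
#'   start) and `level` (intensity level).
#' @param config A [cohort_config()] supplying `count_params`.
#' @return Data frame `participant_id`, `epoch_start`, `counts`.
#' @export
simulate_epoch_counts <- function(track, config) {
  validate_cohort_config(config)
  n <- nrow(track)
  if (n == 0) {
    return(data.frame(participant_id = character(0),
                      epoch_start = as.POSIXct(character(0), tz = "UTC"),
                      counts = integer(0)))
  }
  cp <- config$count_params
  edges <- c(intensity_cutpoints(), Inf)
  lev <- match(as.character(track$level), pa_levels())
  if (anyNA(lev)) stop("unknown activity level in track", call. = FALSE)
  counts <- numeric(n)
  spill <- stats::runif(n) < cp$spill
  u <- stats::runif(n)
  for (k in 1:4) {
    i <- lev == k
    if (!any(i)) next
    lo <- edges[k]; hi <- edges[k + 1]
    plo <- stats::plnorm(lo, cp$meanlog[k], cp$sdlog[k])
    phi <- stats::plnorm(hi, cp$meanlog[k], cp$sdlog[k])
    # truncated-to-band draw via inverse CDF
    x <- stats::qlnorm(plo + u[i] * (phi - plo), cp$meanlog[k], cp$sdlog[k])
    x <- pmin(pmax(round(x), ceiling(lo)), if (is.finite(hi)) hi - 1 else Inf)
    # spill-over draws are untruncated
    xs <- round(stats::qlnorm(u[i], cp$meanlog[k], cp$sdlog[k]))
    counts[i] <- ifelse(spill[i], xs, x)
  }
  if (any(counts < 0)) {
    warning(sum(counts < 0), " negative simulated count(s) clamped to 0")
    counts[counts < 0] <- 0
  }
  data.frame(participant_id = track$participant_id,
             epoch_start = track$minute,
             counts = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic validation-study bundle
#'
#' Produces, deterministically from the config (which includes the seed), a
#' complete study bundle with the structure the validation analyses assume:
#' momentary prompt reports, a dietary-recall table, per-participant epoch
#' count streams, a participant attribute table, and the ground truth every
#' emitted record traces to.
#'
#' The generative story: each participant-day has true eating occasions
#' (Poisson, uniform over 08:00-22:00, multinomial food groups) and a true
#' per-minute activity track (alternating bouts with geometric durations).
#' Prompts follow the interval-contingent schedule; the survey is completed
#' uniformly within the availability window around the prompt, and the
#' completion time is the analysis timestamp. A prompt endorses eating (and
#' the relevant food groups) when a not-yet-reported true occasion falls
#' within the lookback window before completion; a given occasion is
#' endorsed at most once. The reported activity level is drawn from the
#' misreport matrix row of the occasion's true level, where the true
#' occasion level is the cut-point classification of the mean simulated
#' counts over the five minutes before completion — so an identity
#' misreport matrix with zero count spill-over yields a perfectly diagonal
#' reported-versus-derived cross-tabulation. Recall days (1-3 per
#' participant) pass the true occasions through [apply_recall_noise()] and
#' attach a plausible daily energy.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ema_cohort`: a list with `prompts`,
#'   `recall`, `epochs`, `participants`, `ground_truth` (list of
#'   `true_eating_events`, `true_activity`, `true_occasions`) and `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  np <- config$n_participants
  nd <- config$n_days
  ids <- sprintf("P%03d", seq_len(np))
  dates <- as.Date("2016-02-03") + seq_len(nd) - 1

  participants <- data.frame(
    participant_id = ids,
    gender = sample(c("female", "male"), np, TRUE, prob = c(0.7, 0.3)),
    race = sample(c("white", "nonwhite"), np, TRUE, prob = c(0.55, 0.45)),
    pell = sample(c("yes", "no"), np, TRUE, prob = c(0.35, 0.65)),
    stringsAsFactors = FALSE
  )

  # which days each participant recalls
  rdr <- config$recall_days_range
  recall_days <- lapply(seq_len(np), function(i) {
    choices <- seq(rdr[1], rdr[2])
    k <- if (length(choices) == 1) choices else sample(choices, 1)
    k <- min(k, nd)
    sort(sample(dates, k))
  })

  sched <- list(); events <- list(); track <- list()
  for (i in seq_len(np)) {
    for (d in seq_len(nd)) {
      sched[[length(sched) + 1]] <- sample_prompt_schedule(config, ids[i], dates[d])
      ne <- stats::rpois(1, config$eating_rate)
      if (ne > 0) {
        mins <- sort(floor(stats::runif(ne, 8 * 60, 22 * 60)))
        events[[length(events) + 1]] <- data.frame(
          participant_id = ids[i],
          timestamp = make_ts(dates[d], min_to_clock(mins)),
          food_group = sample(food_groups(), ne, TRUE,
                              prob = config$food_group_probs),
          stringsAsFactors = FALSE
        )
      }
      # piecewise-constant activity bouts over the full day
      lv <- character(0)
      while (length(lv) < 1440) {
        dur <- stats::rgeom(1, 1 / config$bout_mean_min) + 1
        lv <- c(lv, rep(sample(pa_levels(), 1, prob = config$pa_level_probs),
                        dur))
      }
      track[[length(track) + 1]] <- data.frame(
        participant_id = ids[i],
        minute = make_ts(dates[d], "00:00") + 60 * (0:1439),
        level = lv[1:1440],
        stringsAsFactors = FALSE
      )
    }
  }
  sched <- do.call(rbind, sched)
  true_events <- if (length(events)) do.call(rbind, events) else
    data.frame(participant_id = character(0),
               timestamp = as.POSIXct(character(0), tz = "UTC"),
               food_group = character(0))
  track <- do.call(rbind, track)
  epochs <- simulate_epoch_counts(track, config)

  # survey completion time within the availability window
  n <- nrow(sched)
  lat <- stats::runif(n, config$latency_range[1], config$latency_range[2])
  sched$timestamp <- floor_minute(sched$prompt_time + 60 * lat)

  # eating endorsements: each true occasion endorsed at most once, at the
  # first real-time prompt whose lookback window covers it
  sched <- sched[order(sched$participant_id, sched$timestamp), ]
  fg <- character(n); eating <- logical(n)
  consumed <- rep(FALSE, nrow(true_events))
  for (j in seq_len(n)) {
    t <- sched$timestamp[j]
    look <- if (sched$prompt_type[j] == "real_time") config$eat_window_min else 180
    cand <- which(true_events$participant_id == sched$participant_id[j] &
                    true_events$timestamp <= t &
                    true_events$timestamp >= t - 60 * look)
    if (sched$prompt_type[j] == "real_time") {
      cand <- cand[!consumed[cand]]
      consumed[cand] <- TRUE
    }
    if (length(cand)) {
      eating[j] <- TRUE
      fg[j] <- paste(unique(true_events$food_group[cand]), collapse = ";")
    }
  }

  # occasion-level true intensity = classification of the 5-min pre-window
  pm <- preprompt_mean_many(epochs, sched$participant_id, sched$timestamp,
                            window_min = 5)
  true_lev <- classify_intensity(ifelse(is.na(pm$mean_cpm), 0, pm$mean_cpm))
  rep_lev <- character(n)
  for (k in 1:4) {
    i <- which(as.integer(true_lev) == k)
    if (length(i)) {
      rep_lev[i] <- sample(pa_levels(), length(i), TRUE,
                           prob = config$misreport_matrix[k, ])
    }
  }
  sed_cats <- c("screen_time", "studying", "socializing", "riding", "other")
  prompts <- data.frame(
    participant_id = sched$participant_id,
    timestamp = sched$timestamp,
    prompt_time = sched$prompt_time,
    prompt_type = sched$prompt_type,
    eating = eating,
    drinking = stats::runif(n) < 0.3,
    physically_active = rep_lev != "sedentary",
    food_groups = fg,
    reported_pa_level = rep_lev,
    sedentary_activity = ifelse(rep_lev == "sedentary",
                                sample(sed_cats, n, TRUE), NA_character_),
    stringsAsFactors = FALSE
  )
  rownames(prompts) <- NULL

  # recall: noise-perturbed true occasions on each participant's recall days
  in_recall_day <- mapply(function(p, d) {
    d %in% recall_days[[match(p, ids)]]
  }, true_events$participant_id, ts_date(true_events$timestamp))
  recall <- apply_recall_noise(true_events[in_recall_day, , drop = FALSE],
                               config)
  kcal_key <- unique(recall[c("participant_id", "date")])
  if (nrow(kcal_key)) {
    kcal_key$day_kcal <- round(stats::runif(nrow(kcal_key),
                                            config$day_kcal_range[1],
                                            config$day_kcal_range[2]))
    recall <- merge(recall, kcal_key, by = c("participant_id", "date"),
                    sort = FALSE)
    recall <- recall[order(recall$participant_id, recall$date,
                           recall$clock_time), ]
    rownames(recall) <- NULL
  } else {
    recall$day_kcal <- numeric(0)
  }

  structure(list(
    prompts = prompts,
    recall = recall,
    epochs = epochs,
    participants = participants,
    ground_truth = list(
      true_eating_events = true_events,
      true_activity = track,
      true_occasions = data.frame(
        participant_id = sched$participant_id,
        timestamp = sched$timestamp,
        true_level = as.character(true_lev),
        preprompt_mean_cpm = pm$mean_cpm,
        stringsAsFactors = FALSE
      )
    ),
    config = config
  ), class = "ema_cohort")
}

#' Zero-noise variant of a cohort configuration
#'
#' Convenience wrapper turning off every error source: recall omission and
#' time displacement, activity misreporting (identity matrix) and count
#' spill-over, with all days recalled. Under this config day-level food
#' match rates are 100% for every group present and the
#' reported-versus-derived cross-tabulation is diagonal.
#'
#' @param ... Passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
zero_noise_config <- function(...) {
  args <- list(...)
  cp <- args$count_params %||% default_count_params()
  cp$spill <- 0
  mm <- diag(4); dimnames(mm) <- list(pa_levels(), pa_levels())
  defaults <- list(recall_omission_prob = 0, recall_time_sd_min = 0,
                   misreport_matrix = mm, count_params = cp)
  nd <- args$n_days %||% 4
  defaults$recall_days_range <- c(nd, nd)
  args <- utils::modifyList(defaults, args)
  do.call(cohort_config, args)
}

#' Write a synthetic bundle as delimited text
#'
#' Writes the study tables (`prompts.csv`, `recall.csv`, `epochs.csv`,
#' `participants.csv`) and the ground-truth files (`truth_events.csv`,
#' `truth_activity.csv`, `truth_occasions.csv`) with ISO-8601 timestamps
#' and one header row, in the schema [load_study()] reads.
#'
#' @param bundle An `ema_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ema_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    for (col in names(df)) {
      if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_ts(df[[col]])
      if (inherits(df[[col]], "Date")) df[[col]] <- as.character(df[[col]])
    }
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    path
  }
  paths <- c(
    prompts = w(bundle$prompts, "prompts.csv"),
    recall = w(bundle$recall, "recall.csv"),
    epochs = w(bundle$epochs, "epochs.csv"),
    participants = w(bundle$participants, "participants.csv"),
    truth_events = w(bundle$ground_truth$true_eating_events, "truth_events.csv"),
    truth_activity = w(bundle$ground_truth$true_activity, "truth_activity.csv"),
    truth_occasions = w(bundle$ground_truth$true_occasions, "truth_occasions.csv")
  )
  invisible(paths)
}

#' @export
print.ema_cohort <- function(x, ...) {
  cat("Synthetic mEMA validation cohort\n")
  cat(sprintf("  %d participants, %d prompt reports (%d real-time), %d recall rows, %d epochs\n",
              nrow(x$participants), nrow(x$prompts),
              sum(x$prompts$prompt_type == "real_time"),
              nrow(x$recall), nrow(x$epochs)))
  invisible(x)
}
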