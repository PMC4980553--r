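#' Load the three study tables
#'
#' Reads the delimited-text prompt-report, dietary-recall and accelerometer
#' epoch tables (plus an optional participant attribute table), validates
#' vocabularies and timestamps, and returns typed records. Malformed rows
#' (unparseable timestamp, unknown activity level) are rejected at the
#' record level and reported; a missing file is a hard error. If the recall
#' table carries raw food codes instead of food groups, `mapping` (a data
#' frame with `food_code`, `food_group`) translates them; unmapped codes
#' become `"other"` with a logged count. The instrument label "strenuous"
#' is accepted as a synonym of "vigorous". Epoch streams must be strictly
#' increasing at exact 60-second spacing per participant; a gap is a hard
#' error naming the first irregular interval.
#'
#' @param paths Named list/vector with elements `prompts`, `recall`,
#'   `epochs` and optionally `participants`.
#' @param mapping Optional food-code-to-group data frame.
#' @return A list of class `ema_study`: `prompts`, `recall`, `epochs`,
#'   `participants` (or `NULL`), `rejected` (data frame of rejected records
#'   with reasons) and `log` (character).
#' @export
load_study <- function(paths, mapping = NULL) {
  paths <- as.list(paths)
  for (nm in c("prompts", "recall", "epochs")) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      stop("missing input file for `", nm, "`", call. = FALSE)
    }
  }
  log <- character(0)
  rejected <- list()
  note_reject <- function(table, key, reason) {
    rejected[[length(rejected) + 1]] <<- data.frame(
      table = table, record = as.character(key), reason = reason,
      stringsAsFactors = FALSE)
  }

  pr <- utils::read.csv(paths$prompts, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "timestamp", "prompt_type", "eating",
            "physically_active", "food_groups", "reported_pa_level")
  miss <- setdiff(need, names(pr))
  if (length(miss)) stop("prompts table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ts <- parse_ts(pr$timestamp)
  lev <- tolower(pr$reported_pa_level)
  lev[lev == "strenuous"] <- "vigorous"
  ok_ts <- !is.na(ts)
  ok_lev <- lev %in% pa_levels()
  ok_fg <- vapply(fg_split(pr$food_groups),
                  function(v) all(v %in% food_groups()), logical(1))
  bad <- !(ok_ts & ok_lev & ok_fg)
  for (j in which(bad)) {
    reason <- if (!ok_ts[j]) "malformed timestamp" else
      if (!ok_lev[j]) "unknown activity level" else "unknown food group"
    note_reject("prompts", paste(pr$participant_id[j], pr$timestamp[j]), reason)
  }
  if (any(bad)) log <- log_line(log, "WARN",
                                paste(sum(bad), "prompt record(s) rejected"))
  prompts <- data.frame(
    participant_id = pr$participant_id,
    timestamp = ts,
    prompt_type = pr$prompt_type,
    eating = tolower(pr$eating) %in% c("true", "1", "yes"),
    physically_active = tolower(pr$physically_active) %in% c("true", "1", "yes"),
    food_groups = pr$food_groups,
    reported_pa_level = lev,
    stringsAsFactors = FALSE
  )[!bad, , drop = FALSE]
  if ("sedentary_activity" %in% names(pr)) {
    prompts$sedentary_activity <- pr$sedentary_activity[!bad]
  }
  rownames(prompts) <- NULL

  rc <- utils::read.csv(paths$recall, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "date", "clock_time", "day_kcal")
  miss <- setdiff(need, names(rc))
  if (length(miss)) stop("recall table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"food_group" %in% names(rc)) {
    if (!"food_code" %in% names(rc)) {
      stop("recall table needs `food_group` or `food_code`", call. = FALSE)
    }
    if (is.null(mapping)) stop("recall carries food codes but no `mapping` given",
                               call. = FALSE)
    idx <- match(rc$food_code, as.character(mapping$food_code))
    grp <- as.character(mapping$food_group)[idx]
    n_unmapped <- sum(is.na(idx))
    if (n_unmapped) {
      grp[is.na(idx)] <- "other"
      log <- log_line(log, "WARN", paste(n_unmapped,
                                         "unmapped food code(s) set to 'other'"))
      warning(n_unmapped, " unmapped food code(s) assigned to 'other'",
              call. = FALSE)
    }
    rc$food_group <- grp
  }
  rdate <- as.Date(rc$date)
  rmin <- suppressWarnings(clock_to_min(rc$clock_time))
  kcal <- suppressWarnings(as.numeric(rc$day_kcal))
  ok <- !is.na(rdate) & !is.na(rmin) & rmin >= 0 & rmin < 1440 &
    rc$food_group %in% food_groups() & !is.na(kcal)
  for (j in which(!ok)) {
    note_reject("recall", paste(rc$participant_id[j], rc$date[j], rc$clock_time[j]),
                "malformed recall record")
  }
  if (any(!ok)) log <- log_line(log, "WARN",
                                paste(sum(!ok), "recall record(s) rejected"))
  recall <- data.frame(
    participant_id = rc$participant_id,
    date = rdate,
    clock_time = rc$clock_time,
    food_group = rc$food_group,
    day_kcal = kcal,
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]
  rownames(recall) <- NULL

  ep <- utils::read.csv(paths$epochs, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "epoch_start", "counts")
  miss <- setdiff(need, names(ep))
  if (length(miss)) stop("epoch table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ets <- parse_ts(ep$epoch_start)
  cnt <- suppressWarnings(as.numeric(ep$counts))
  if (anyNA(ets)) stop("malformed epoch timestamp at row ",
                       which(is.na(ets))[1], call. = FALSE)
  if (anyNA(cnt) || any(cnt < 0)) {
    stop("epoch counts must be nonnegative numbers", call. = FALSE)
  }
  epochs <- data.frame(participant_id = ep$participant_id, epoch_start = ets,
                       counts = as.integer(cnt), stringsAsFactors = FALSE)
  epochs <- epochs[order(epochs$participant_id, epochs$epoch_start), ]
  rownames(epochs) <- NULL
  check_epoch_spacing(epochs)

  parts <- NULL
  if (!is.null(paths$participants) && file.exists(paths$participants)) {
    parts <- utils::read.csv(paths$participants, stringsAsFactors = FALSE)
  }

  structure(list(prompts = prompts, recall = recall, epochs = epochs,
                 participants = parts,
                 rejected = if (length(rejected)) do.call(rbind, rejected) else
                   data.frame(table = character(0), record = character(0),
                              reason = character(0)),
                 log = log),
            class = "ema_study")
}

check_epoch_spacing <- function(epochs) {
  for (id in unique(epochs$participant_id)) {
    t <- epochs$epoch_start[epochs$participant_id == id]
    if (length(t) < 2) next
    d <- diff(as.numeric(t))
    bad <- which(d != 60)
    if (length(bad)) {
      stop("irregular epoch interval for participant ", id, " after ",
           format_ts(t[bad[1]]), " (", d[bad[1]], " s)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Select analyzable diet participant-days
#'
#' Applies the diet-arm inclusion rule: a participant-day enters the
#' analysis only if it has (1) at least one momentary report endorsing a
#' food entry and (2) a biologically plausible recall day, i.e. daily
#' energy in the closed interval \[`kcal_min`, `kcal_max`\] (default
#' 500-5000 kcal). The candidate universe is every participant-day with at
#' least one completed real-time prompt. Kept days and the exclusion ledger
#' partition that universe exactly.
#'
#' @param prompts,recall Tables as returned by [load_study()] or
#'   [generate_cohort()].
#' @param thresholds A [filter_thresholds()].
#' @param include_retrospective Should retrospective prompts count towards
#'   the "has a food entry" condition and later matching? Default `FALSE`:
#'   the momentary comparison is only meaningful for real-time prompts.
#' @return List with `kept` (data frame `participant_id`, `date`,
#'   `day_kcal`) and `excluded` (`participant_id`, `date`, `reason`).
#' @export
filter_diet_days <- function(prompts, recall,
                             thresholds = filter_thresholds(),
                             include_retrospective = FALSE) {
  pr <- prompts[prompts$prompt_type == "real_time" | include_retrospective, ,
                drop = FALSE]
  pr$date <- ts_date(pr$timestamp)
  universe <- unique(pr[c("participant_id", "date")])
  has_food <- unique(pr[nchar(pr$food_groups) > 0,
                        c("participant_id", "date")])
  kcal <- unique(recall[c("participant_id", "date", "day_kcal")])

  key <- function(df) paste(df$participant_id, df$date)
  universe <- universe[order(key(universe)), , drop = FALSE]
  u <- key(universe)
  food_ok <- u %in% key(has_food)
  ik <- match(u, key(kcal))
  has_recall <- !is.na(ik)
  day_kcal <- kcal$day_kcal[ik]
  plausible <- has_recall & day_kcal >= thresholds$kcal_min &
    day_kcal <= thresholds$kcal_max

  keep <- food_ok & plausible
  reason <- rep(NA_character_, nrow(universe))
  reason[!food_ok] <- "no mEMA food entry"
  reason[food_ok & !has_recall] <- "no recall"
  reason[food_ok & has_recall & !plausible] <- "implausible recall"

  kept <- universe[keep, , drop = FALSE]
  kept$day_kcal <- day_kcal[keep]
  excluded <- universe[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Accelerometer wear time on a date
#'
#' Minutes of wear on a calendar date, defined as epochs on that date not
#' inside a run of at least `nonwear_run_min` (default 60) consecutive
#' zero-count epochs; zero runs are assessed on the participant's full
#' stream so a non-wear period spanning midnight is still recognised.
#'
#' @param series Epoch data frame for one participant (`epoch_start`,
#'   `counts`).
#' @param date Calendar day (`Date`).
#' @param nonwear_run_min Minimum zero run counted as non-wear.
#' @return Number of wear minutes on the date (0 if no epochs).
#' @export
wear_minutes <- function(series, date, nonwear_run_min = 60) {
  if (nrow(series) == 0) return(0)
  series <- series[order(series$epoch_start), , drop = FALSE]
  r <- rle(series$counts == 0)
  nonwear <- rep(r$values & r$lengths >= nonwear_run_min, r$lengths)
  on_date <- ts_date(series$epoch_start) == as.Date(date)
  sum(on_date & !nonwear)
}

#' Select analyzable physical-activity prompt occasions
#'
#' Applies the activity-arm exclusion rule to completed real-time prompts:
#' an occasion is excluded when the epoch counts are all zero for the 30
#' minutes before or the 30 minutes after the response (either fully-zero
#' flank indicates the device was not worn at the moment of report), when
#' the device was worn less than 5 hours on the prompt's day, or when no
#' epochs cover the flanking windows at all. Flank windows are
#' \[t-30, t) and \[t, t+30) over epoch starts.
#'
#' @param prompts,epochs Tables as returned by [load_study()] or
#'   [generate_cohort()].
#' @param thresholds A [filter_thresholds()].
#' @return List with `kept` (prompt rows) and `excluded` (`participant_id`,
#'   `timestamp`, `reason`).
#' @export
filter_pa_prompts <- function(prompts, epochs,
                              thresholds = filter_thresholds()) {
  pr <- prompts[prompts$prompt_type == "real_time", , drop = FALSE]
  n <- nrow(pr)
  reason <- rep(NA_character_, n)
  zw <- thresholds$zero_window_min
  min_wear <- thresholds$min_wear_hours * 60

  by_part <- split(seq_len(nrow(epochs)), epochs$participant_id)
  wear_cache <- new.env(parent = emptyenv())

  for (j in seq_len(n)) {
    id <- pr$participant_id[j]
    t <- pr$timestamp[j]
    idx <- by_part[[id]]
    if (is.null(idx)) { reason[j] <- "no accelerometry"; next }
    es <- epochs[idx, , drop = FALSE]
    before <- es$counts[es$epoch_start >= t - 60 * zw & es$epoch_start < t]
    after <- es$counts[es$epoch_start >= t & es$epoch_start < t + 60 * zw]
    if (length(before) == 0 || length(after) == 0) {
      reason[j] <- "no accelerometry"; next
    }
    if (all(before == 0) || all(after == 0)) {
      reason[j] <- "zero-count flank"; next
    }
    ckey <- paste(id, ts_date(t))
    wm <- wear_cache[[ckey]]
    if (is.null(wm)) {
      wm <- wear_minutes(es, ts_date(t), thresholds$nonwear_run_min)
      wear_cache[[ckey]] <- wm
    }
    if (wm < min_wear) reason[j] <- "insufficient wear time"
  }
  keep <- is.na(reason)
  excluded <- data.frame(participant_id = pr$participant_id[!keep],
                         timestamp = pr$timestamp[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  kept <- pr[keep, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}
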