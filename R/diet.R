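#' Day-level food-group match rates
#'
#' For each food group, the match denominator is the number of momentary
#' endorsements of the group across the analyzed participant-days; the
#' per-day numerator is the smaller of the day's momentary endorsement
#' count and the day's recall instance count for that group (summed over
#' days). A day with four momentary fruit-and-vegetable endorsements and
#' three recall instances contributes three matches of a potential four
#' (75%); the converse day contributes three of three (100%).
#'
#' @param prompts Prompt-report table; only real-time prompts are used
#'   unless `include_retrospective = TRUE`.
#' @param recall Eating-instance table.
#' @param days Optional kept-day set from [filter_diet_days()]
#'   (`participant_id`, `date`); when supplied, both tables are restricted
#'   to those participant-days.
#' @param groups Food groups to tabulate; by default the five named groups
#'   ("other" is carried through ingest but excluded from match statistics).
#' @param include_retrospective Include retrospective prompts' endorsements.
#' @return Object of class `day_match_summary`: list with `summary` (per
#'   group: `n_mema`, `n_recall`, `n_matched`, `match_rate` in percent,
#'   `NA` when the group was never endorsed) and `per_day` (audit rows:
#'   participant, date, group, counts, matched).
#' @export
day_match_rates <- function(prompts, recall, days = NULL,
                            groups = setdiff(food_groups(), "other"),
                            include_retrospective = FALSE) {
  pr <- prompts[prompts$prompt_type == "real_time" | include_retrospective, ,
                drop = FALSE]
  pr$date <- ts_date(pr$timestamp)
  rc <- recall
  if (!is.null(days)) {
    dk <- paste(days$participant_id, days$date)
    pr <- pr[paste(pr$participant_id, pr$date) %in% dk, , drop = FALSE]
    rc <- rc[paste(rc$participant_id, rc$date) %in% dk, , drop = FALSE]
  }
  day_keys <- unique(rbind(pr[c("participant_id", "date")],
                           rc[c("participant_id", "date")]))
  per_day <- list()
  for (g in groups) {
    mema <- pr[fg_has(pr$food_groups, g), c("participant_id", "date")]
    asa <- rc[rc$food_group == g, c("participant_id", "date")]
    k <- paste(day_keys$participant_id, day_keys$date)
    n_m <- as.integer(table(factor(paste(mema$participant_id, mema$date),
                                   levels = k)))
    n_r <- as.integer(table(factor(paste(asa$participant_id, asa$date),
                                   levels = k)))
    per_day[[g]] <- data.frame(
      participant_id = day_keys$participant_id, date = day_keys$date,
      food_group = g, n_mema = n_m, n_recall = n_r,
      n_matched = pmin(n_m, n_r), stringsAsFactors = FALSE)
  }
  per_day <- do.call(rbind, per_day)
  rownames(per_day) <- NULL
  agg <- lapply(groups, function(g) {
    d <- per_day[per_day$food_group == g, , drop = FALSE]
    n_mema <- sum(d$n_mema); n_matched <- sum(d$n_matched)
    data.frame(food_group = g, n_mema = n_mema, n_recall = sum(d$n_recall),
               n_matched = n_matched,
               match_rate = if (n_mema > 0) 100 * n_matched / n_mema else
                 NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, agg),
                 per_day = per_day[per_day$n_mema + per_day$n_recall > 0, ,
                                   drop = FALSE]),
            class = "day_match_summary")
}

#' @export
print.day_match_summary <- function(x, digits = 1, ...) {
  cat("Day-level food-group match rates\n")
  s <- x$summary
  s$match_rate <- round(s$match_rate, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

# minutes from each prompt to the nearest same-participant recall instance
# of `group` (Inf when none exists)
nearest_recall_gap <- function(prompts, recall, group) {
  rc <- recall[recall$food_group == group, , drop = FALSE]
  rt <- as.numeric(make_ts(rc$date, rc$clock_time)) / 60
  pt <- as.numeric(prompts$timestamp) / 60
  out <- rep(Inf, length(pt))
  sp <- split(rt, rc$participant_id)
  for (id in names(sp)) {
    i <- prompts$participant_id == id
    if (!any(i)) next
    out[i] <- vapply(pt[i], function(t) min(abs(sp[[id]] - t)), numeric(1))
  }
  out
}

#' Window-based match-rate (PPV) curve
#'
#' For each food group and half-width `w` in the grid, the denominator is
#' every momentary report endorsing the group and the numerator counts
#' those with at least one recall instance of the same group within the
#' closed window \[t-w, t+w\] around the report time. The curve is
#' monotone non-decreasing in `w`.
#'
#' @param prompts Real-time prompt reports (retrospective rows are dropped
#'   if present).
#' @param recall Eating-instance table.
#' @param grid Half-widths in minutes (default 6 to 480 by 6, i.e. 6 min to
#'   8 h on either side).
#' @param groups Food groups to evaluate.
#' @return Data frame `food_group`, `w`, `n_reports`, `n_matched`, `ppv`
#'   (percent; `NA` when the group is never endorsed).
#' @export
window_match_curve <- function(prompts, recall, grid = seq(6, 480, by = 6),
                               groups = setdiff(food_groups(), "other")) {
  if (length(grid) == 0) stop("empty window grid", call. = FALSE)
  if ("prompt_type" %in% names(prompts)) {
    prompts <- prompts[prompts$prompt_type == "real_time", , drop = FALSE]
  }
  out <- list()
  for (g in groups) {
    endorsed <- fg_has(prompts$food_groups, g)
    gap <- nearest_recall_gap(prompts[endorsed, , drop = FALSE], recall, g)
    den <- sum(endorsed)
    num <- vapply(grid, function(w) sum(gap <= w), numeric(1))
    out[[g]] <- data.frame(
      food_group = g, w = grid, n_reports = den, n_matched = num,
      ppv = if (den > 0) 100 * num / den else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sensitivity and specificity versus window width
#'
#' Treats every completed real-time prompt as an occasion. For food group
#' `g` and half-width `w`, the reference condition is "a recall instance of
#' `g` lies within \[t-w, t+w\] of the prompt time" and the test condition
#' is "the momentary report endorses `g`". Sensitivity is TP/(TP+FN) and
#' specificity TN/(TN+FP); cell counts sum to the occasion total at every
#' `w`. With recall times that are displaced copies of momentary eating
#' reports, widening `w` raises specificity's complement FP slower than it
#' converts FN to TP, giving the characteristic falling-sensitivity /
#' rising-specificity trade-off only when endorsements are sparse; both
#' directions are reported, not assumed.
#'
#' @inheritParams window_match_curve
#' @param occasions `"all"` (default) uses every completed real-time
#'   prompt as the occasion set; `"eating_only"` restricts to prompts
#'   endorsing at least one food group.
#' @return Data frame `food_group`, `w`, `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity` (percent; sensitivity `NA` when no
#'   reference-positives exist at that `w`).
#' @export
window_sens_spec <- function(prompts, recall, grid = seq(6, 480, by = 6),
                             groups = setdiff(food_groups(), "other"),
                             occasions = c("all", "eating_only")) {
  if (length(grid) == 0) stop("empty window grid", call. = FALSE)
  occasions <- match.arg(occasions)
  if ("prompt_type" %in% names(prompts)) {
    prompts <- prompts[prompts$prompt_type == "real_time", , drop = FALSE]
  }
  if (occasions == "eating_only") {
    prompts <- prompts[nchar(prompts$food_groups) > 0, , drop = FALSE]
  }
  n <- nrow(prompts)
  out <- list()
  for (g in groups) {
    test_pos <- fg_has(prompts$food_groups, g)
    gap <- nearest_recall_gap(prompts, recall, g)
    rows <- lapply(grid, function(w) {
      ref_pos <- gap <= w
      tp <- sum(test_pos & ref_pos); fp <- sum(test_pos & !ref_pos)
      fn <- sum(!test_pos & ref_pos); tn <- sum(!test_pos & !ref_pos)
      data.frame(food_group = g, w = w, tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else
                   NA_real_,
                 specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else
                   NA_real_,
                 stringsAsFactors = FALSE)
    })
    out[[g]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Subgroup chi-square tests of day-level matching
#'
#' Classifies every momentary food endorsement as matched or unmatched at
#' the day level and tests, per food group, whether the matched proportion
#' differs across a two-level participant attribute (gender, white versus
#' nonwhite, Pell grant status) with an uncorrected chi-square test on the
#' 2x2 table. Tables with any expected cell below 1 are flagged
#' unreliable.
#'
#' @param per_day The `per_day` component of a [day_match_rates()] result.
#' @param participants Participant attribute table.
#' @param grouping Name of the attribute column in `participants`.
#' @return Data frame per food group: `statistic`, `df`, `p_value`,
#'   `min_expected`, `reliable`, plus matched/unmatched counts per
#'   attribute level.
#' @export
subgroup_chisq <- function(per_day, participants, grouping) {
  if (!grouping %in% names(participants)) {
    stop("no column `", grouping, "` in participants", call. = FALSE)
  }
  attr_lev <- sort(unique(as.character(participants[[grouping]])))
  if (length(attr_lev) != 2) {
    stop("`", grouping, "` must have exactly two levels", call. = FALSE)
  }
  pd <- merge(per_day, participants[c("participant_id", grouping)],
              by = "participant_id")
  out <- list()
  for (g in unique(pd$food_group)) {
    d <- pd[pd$food_group == g, , drop = FALSE]
    tab <- matrix(0, 2, 2, dimnames = list(match = c("matched", "unmatched"),
                                           group = attr_lev))
    for (k in 1:2) {
      dk <- d[d[[grouping]] == attr_lev[k], , drop = FALSE]
      tab["matched", k] <- sum(dk$n_matched)
      tab["unmatched", k] <- sum(dk$n_mema - dk$n_matched)
    }
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      out[[g]] <- data.frame(food_group = g, statistic = NA_real_,
                             df = NA_integer_, p_value = NA_real_,
                             min_expected = 0, reliable = FALSE,
                             matched_1 = tab[1, 1], unmatched_1 = tab[2, 1],
                             matched_2 = tab[1, 2], unmatched_2 = tab[2, 2],
                             stringsAsFactors = FALSE)
      next
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    mexp <- min(ct$expected)
    out[[g]] <- data.frame(
      food_group = g, statistic = unname(ct$statistic),
      df = unname(ct$parameter), p_value = unname(ct$p.value),
      min_expected = mexp, reliable = mexp >= 1,
      matched_1 = tab[1, 1], unmatched_1 = tab[2, 1],
      matched_2 = tab[1, 2], unmatched_2 = tab[2, 2],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "grouping") <- grouping
  attr(out, "levels") <- attr_lev
  out
}

#' Build prompt-level occasions for the diet mixed model
#'
#' One row per real-time prompt and food group: outcome = the prompt
#' endorsed the group, predictor = the group appears anywhere in that
#' day's recall.
#'
#' @inheritParams day_match_rates
#' @return Data frame `participant_id`, `date`, `food_group`, `y` (0/1
#'   momentary endorsement), `x` (0/1 recall-day endorsement).
#' @export
diet_logit_occasions <- function(prompts, recall, days = NULL,
                                 groups = setdiff(food_groups(), "other")) {
  pr <- prompts[prompts$prompt_type == "real_time", , drop = FALSE]
  pr$date <- ts_date(pr$timestamp)
  if (!is.null(days)) {
    dk <- paste(days$participant_id, days$date)
    pr <- pr[paste(pr$participant_id, pr$date) %in% dk, , drop = FALSE]
  }
  out <- list()
  for (g in groups) {
    rg <- unique(paste(recall$participant_id[recall$food_group == g],
                       recall$date[recall$food_group == g]))
    out[[g]] <- data.frame(
      participant_id = pr$participant_id, date = pr$date, food_group = g,
      y = as.integer(fg_has(pr$food_groups, g)),
      x = as.integer(paste(pr$participant_id, pr$date) %in% rg),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mixed logistic model of momentary endorsement on recall endorsement
#'
#' Per food group, fits logit P(momentary endorsement) = b0 + b1 * recall
#' endorsement + participant random intercept (maximum likelihood, lme4)
#' and reports the odds ratio exp(b1) with a 95% Wald interval.
#' Non-convergence or quasi-separation yields a flagged `NA` row.
#'
#' @param occ Occasion table from [diet_logit_occasions()].
#' @return Data frame per food group: `or`, `ci_lo`, `ci_hi`, `p_value`,
#'   `sigma_u` (random-intercept SD), `converged`, `note`.
#' @export
diet_mixed_logit <- function(occ) {
  out <- list()
  for (g in unique(occ$food_group)) {
    d <- occ[occ$food_group == g, , drop = FALSE]
    f <- if (length(unique(d$x)) < 2 || length(unique(d$y)) < 2) {
      list(or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
           sigma_u = NA_real_, converged = FALSE,
           message = "degenerate predictor or outcome")
    } else fit_mixed_logit(d)
    out[[g]] <- data.frame(food_group = g, or = f$or, ci_lo = f$ci_lo,
                           ci_hi = f$ci_hi, p_value = f$p,
                           sigma_u = f$sigma_u, converged = f$converged,
                           note = trimws(f$message), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full diet validation arm
#'
#' Applies the inclusion filters, then computes day-level match rates,
#' window match and sensitivity/specificity curves, optional subgroup
#' chi-square tests, and the per-group mixed logistic agreement model.
#'
#' @param prompts,recall Study tables ([load_study()]/[generate_cohort()]).
#' @param participants Optional attribute table for subgroup tests.
#' @param thresholds A [filter_thresholds()].
#' @param grid Window half-widths in minutes.
#' @param groups Food groups analyzed.
#' @param subgroupings Attribute columns tested (those present in
#'   `participants` among `gender`, `race`, `pell`).
#' @return Object of class `diet_validation`.
#' @export
validate_diet <- function(prompts, recall, participants = NULL,
                          thresholds = filter_thresholds(),
                          grid = seq(6, 480, by = 6),
                          groups = setdiff(food_groups(), "other"),
                          subgroupings = c("gender", "race", "pell")) {
  filt <- filter_diet_days(prompts, recall, thresholds)
  pr <- prompts[prompts$prompt_type == "real_time", , drop = FALSE]
  pr$date <- ts_date(pr$timestamp)
  dk <- paste(filt$kept$participant_id, filt$kept$date)
  pr_kept <- pr[paste(pr$participant_id, pr$date) %in% dk, , drop = FALSE]
  rc_kept <- recall[paste(recall$participant_id, recall$date) %in% dk, ,
                    drop = FALSE]
  dm <- day_match_rates(prompts, recall, days = filt$kept, groups = groups)
  curve <- window_match_curve(pr_kept, rc_kept, grid, groups)
  ss <- window_sens_spec(pr_kept, rc_kept, grid, groups)
  chisq <- NULL
  if (!is.null(participants)) {
    subgroupings <- intersect(subgroupings, names(participants))
    # an attribute constant in this sample admits no subgroup comparison
    subgroupings <- subgroupings[vapply(subgroupings, function(gv)
      length(unique(participants[[gv]])) == 2, logical(1))]
    chisq <- lapply(subgroupings, function(gv)
      subgroup_chisq(dm$per_day, participants, gv))
    names(chisq) <- subgroupings
  }
  occ <- diet_logit_occasions(prompts, recall, days = filt$kept,
                              groups = groups)
  structure(list(
    days = filt$kept, exclusions = filt$excluded, day_match = dm,
    window_curve = curve, window_sens_spec = ss, chisq = chisq,
    mixed_logit = diet_mixed_logit(occ), occasions = occ,
    grid = grid, groups = groups, thresholds = thresholds
  ), class = "diet_validation")
}

#' @export
print.diet_validation <- function(x, ...) {
  cat("mEMA diet validation\n")
  cat(sprintf("  %d analyzed participant-days (%d excluded)\n",
              nrow(x$days), nrow(x$exclusions)))
  print(x$day_match)
  invisible(x)
}

#' @export
summary.diet_validation <- function(object, ...) {
  cat("mEMA diet validation\n")
  cat(sprintf("  analyzed participant-days: %d; excluded: %d\n",
              nrow(object$days), nrow(object$exclusions)))
  if (nrow(object$exclusions)) {
    print(table(object$exclusions$reason))
  }
  cat("\nDay-level match rates (%):\n")
  s <- object$day_match$summary
  s$match_rate <- round(s$match_rate, 1)
  print(s, row.names = FALSE)
  cat("\nMixed logistic agreement (OR of momentary on recall endorsement):\n")
  m <- object$mixed_logit
  m[c("or", "ci_lo", "ci_hi")] <- round(m[c("or", "ci_lo", "ci_hi")], 2)
  print(m[c("food_group", "or", "ci_lo", "ci_hi", "p_value", "converged")],
        row.names = FALSE)
  invisible(object)
}

#' Plot sensitivity and specificity against window half-width
#'
#' @param x A `diet_validation`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.diet_validation <- function(x, ...) {
  ss <- x$window_sens_spec
  groups <- unique(ss$food_group)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (stat in c("sensitivity", "specificity")) {
    m <- sapply(groups, function(g) ss[[stat]][ss$food_group == g])
    graphics::matplot(x$grid, m, type = "l", lty = 1, col = seq_along(groups),
                      xlab = "window half-width (min)", ylab = paste0(stat, " (%)"),
                      main = stat, ylim = c(0, 100), ...)
    graphics::legend("right", legend = groups, col = seq_along(groups),
                     lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}
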