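#' Mean counts over the pre-report window
#'
#' Arithmetic mean of the epoch counts whose epoch start lies in the
#' half-open window \[t - `window_min`, t) before a report, the measure of
#' accelerometer-derived activity at the occasion (the epoch containing
#' the report itself is excluded). Up to `window_min` epochs contribute;
#' the number that did is returned alongside.
#'
#' @param series Epoch data frame for one participant (`epoch_start`,
#'   `counts`).
#' @param t Report timestamp (POSIXct).
#' @param window_min Window width in minutes (default 5).
#' @return One-row data frame `mean_cpm`, `n_epochs` (`mean_cpm` is `NA`
#'   when no epoch falls in the window; such occasions are dropped by the
#'   caller with a logged reason).
#' @export
preprompt_mean <- function(series, t, window_min = 5) {
  x <- series$counts[series$epoch_start >= t - 60 * window_min &
                       series$epoch_start < t]
  data.frame(mean_cpm = if (length(x)) mean(x) else NA_real_,
             n_epochs = length(x))
}

# vectorised pre-window means for many (participant, timestamp) occasions
preprompt_mean_many <- function(epochs, ids, ts, window_min = 5) {
  n <- length(ids)
  mean_cpm <- rep(NA_real_, n)
  n_ep <- integer(n)
  sp <- split(seq_len(nrow(epochs)), epochs$participant_id)
  for (id in unique(ids)) {
    idx <- sp[[id]]
    i <- which(ids == id)
    if (is.null(idx)) next
    et <- as.numeric(epochs$epoch_start[idx])
    ec <- epochs$counts[idx]
    o <- order(et); et <- et[o]; ec <- ec[o]
    cs <- c(0, cumsum(ec))
    tn <- as.numeric(ts[i])
    lo <- findInterval(tn - 60 * window_min - 1e-6, et) + 1
    hi <- findInterval(tn - 1e-6, et)
    k <- pmax(hi - lo + 1, 0)
    s <- ifelse(k > 0, cs[hi + 1] - cs[lo], NA_real_)
    mean_cpm[i] <- s / ifelse(k > 0, k, NA)
    n_ep[i] <- k
  }
  data.frame(mean_cpm = mean_cpm, n_epochs = n_ep)
}

#' Build physical-activity analysis occasions
#'
#' Applies [filter_pa_prompts()] and then derives, for each surviving
#' real-time prompt, the pre-report mean CPM and its Freedson
#' classification alongside the reported level. Occasions with no epoch in
#' the averaging window are dropped with a logged reason.
#'
#' @param prompts,epochs Study tables.
#' @param thresholds A [filter_thresholds()].
#' @return Data frame of class `pa_occasions`: `participant_id`,
#'   `timestamp`, `reported_level`, `preprompt_mean_cpm`, `n_epochs`,
#'   `derived_level`; exclusion ledger in `attr(, "excluded")`.
#' @export
pa_occasions <- function(prompts, epochs, thresholds = filter_thresholds()) {
  filt <- filter_pa_prompts(prompts, epochs, thresholds)
  pr <- filt$kept
  pm <- preprompt_mean_many(epochs, pr$participant_id, pr$timestamp,
                            thresholds$preprompt_avg_min)
  dropped <- is.na(pm$mean_cpm)
  excluded <- filt$excluded
  if (any(dropped)) {
    excluded <- rbind(excluded, data.frame(
      participant_id = pr$participant_id[dropped],
      timestamp = pr$timestamp[dropped],
      reason = "no epochs in averaging window", stringsAsFactors = FALSE))
  }
  occ <- data.frame(
    participant_id = pr$participant_id[!dropped],
    timestamp = pr$timestamp[!dropped],
    reported_level = factor(pr$reported_pa_level[!dropped],
                            levels = pa_levels()),
    preprompt_mean_cpm = pm$mean_cpm[!dropped],
    n_epochs = pm$n_epochs[!dropped],
    stringsAsFactors = FALSE)
  occ$derived_level <- classify_intensity(occ$preprompt_mean_cpm)
  rownames(occ) <- NULL
  structure(occ, excluded = excluded, class = c("pa_occasions", "data.frame"))
}

#' Agreement statistics for a reported-versus-derived cross-tabulation
#'
#' Tabulates reported (rows) against accelerometer-derived (columns)
#' intensity levels and computes, per level, the five tabular agreement
#' parameters. The match rate conditions on the reported level
#' (diagonal / row total). Sensitivity and specificity condition on the
#' derived level: positives at level L are occasions whose derived level
#' is L, the test is "reported level is L", so sensitivity =
#' diagonal / column total and specificity = TN / (TN + FP). Likelihood
#' ratios are LR+ = sens/(1-spec) (undefined at spec = 1) and LR- =
#' (1-sens)/spec (undefined at spec = 0).
#'
#' @param x Either a [pa_occasions()]-style data frame with
#'   `reported_level` and `derived_level`, or a 4x4 count matrix with rows
#'   = reported and columns = derived levels (sedentary, light, moderate,
#'   vigorous).
#' @return Object of class `pa_agreement`: list with `crosstab` (4x4
#'   matrix), `margins` (row/column totals and percentages), `agreement`
#'   (per-level data frame with `match_rate`, `sensitivity`,
#'   `specificity` in percent and `lr_plus`, `lr_minus`) and `n`.
#' @examples
#' tab <- matrix(c(340, 209, 16, 0,
#'                 19, 37, 7, 0,
#'                 11, 20, 9, 0,
#'                 2, 18, 5, 1), nrow = 4, byrow = TRUE,
#'               dimnames = list(pa_levels(), pa_levels()))
#' crosstab_and_agreement(tab)
#' @export
crosstab_and_agreement <- function(x) {
  if (is.matrix(x)) {
    if (any(dim(x) != c(4, 4)) || any(x < 0)) {
      stop("cross-tab must be a nonnegative 4x4 matrix", call. = FALSE)
    }
    tab <- x
    dimnames(tab) <- list(reported = pa_levels(), derived = pa_levels())
  } else {
    if (nrow(x) == 0) stop("empty occasion set", call. = FALSE)
    tab <- table(factor(x$reported_level, levels = pa_levels()),
                 factor(x$derived_level, levels = pa_levels()))
    tab <- unclass(tab)
    dimnames(tab) <- list(reported = pa_levels(), derived = pa_levels())
  }
  n <- sum(tab)
  if (n == 0) stop("empty occasion set", call. = FALSE)
  structure(list(crosstab = tab,
                 margins = list(
                   row_n = rowSums(tab), col_n = colSums(tab),
                   row_pct = 100 * rowSums(tab) / n,
                   col_pct = 100 * colSums(tab) / n),
                 agreement = agreement_suite(tab), n = n),
            class = "pa_agreement")
}

#' Per-level agreement parameters from a 4x4 table
#'
#' @param tab 4x4 count matrix, rows = reported, columns = derived.
#' @return Data frame with one row per level: `match_rate`, `sensitivity`,
#'   `specificity` (percent), `lr_plus`, `lr_minus`.
#' @export
agreement_suite <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(4, 4)), all(tab >= 0))
  n <- sum(tab)
  rt <- rowSums(tab); ct <- colSums(tab); dg <- diag(tab)
  match_rate <- ifelse(rt > 0, 100 * dg / rt, NA_real_)
  sens <- ifelse(ct > 0, 100 * dg / ct, NA_real_)
  tn <- n - rt - ct + dg
  refneg <- n - ct
  spec <- ifelse(refneg > 0, 100 * tn / refneg, NA_real_)
  s <- sens / 100; p <- spec / 100
  lr_plus <- ifelse(!is.na(p) & p < 1, s / (1 - p), NA_real_)
  lr_minus <- ifelse(!is.na(p) & p > 0, (1 - s) / p, NA_real_)
  data.frame(level = pa_levels(), n_reported = as.integer(rt),
             n_derived = as.integer(ct), match_rate = match_rate,
             sensitivity = sens, specificity = spec,
             lr_plus = lr_plus, lr_minus = lr_minus,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pa_agreement <- function(x, ...) {
  cat("Reported vs accelerometer-derived activity (n =", x$n, "occasions)\n\n")
  tab <- cbind(x$crosstab, total = x$margins$row_n)
  print(tab)
  cat("\nAgreement parameters (match rate conditions on reported level;\n")
  cat("sensitivity/specificity on the derived level):\n")
  a <- x$agreement
  a$match_rate <- round(a$match_rate, 1)
  a$sensitivity <- round(a$sensitivity)
  a$specificity <- round(a$specificity)
  a$lr_plus <- round(a$lr_plus, 2)
  a$lr_minus <- round(a$lr_minus, 2)
  print(a, row.names = FALSE)
  invisible(x)
}

#' Mixed logistic odds ratio for one intensity level
#'
#' Odds that the derived level is L when L was reported versus when it was
#' not, from a logistic model with participant random intercepts: outcome
#' = (derived level == L), predictor = (reported level == L). Declared
#' undefined (with reason) when fewer than two participants contribute to
#' the L-by-L diagonal cell, as when a single participant supplies all
#' concordant vigorous occasions.
#'
#' @param occ A [pa_occasions()] table.
#' @param level Intensity level.
#' @return One-row data frame `level`, `or`, `ci_lo`, `ci_hi`, `p_value`,
#'   `sigma_u`, `converged`, `note`.
#' @export
pa_or_mixed_logit <- function(occ, level) {
  level <- match.arg(level, pa_levels())
  y <- as.integer(occ$derived_level == level)
  x <- as.integer(occ$reported_level == level)
  diag_participants <- unique(occ$participant_id[y == 1 & x == 1])
  if (length(diag_participants) < 2) {
    return(data.frame(level = level, or = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, p_value = NA_real_,
                      sigma_u = NA_real_, converged = FALSE,
                      note = "fewer than 2 participants in concordant cell",
                      stringsAsFactors = FALSE))
  }
  d <- data.frame(y = y, x = x, participant_id = occ$participant_id)
  f <- fit_mixed_logit(d)
  data.frame(level = level, or = f$or, ci_lo = f$ci_lo, ci_hi = f$ci_hi,
             p_value = f$p, sigma_u = f$sigma_u, converged = f$converged,
             note = trimws(f$message), stringsAsFactors = FALSE)
}

#' Pairwise Kolmogorov-Smirnov tests of derived-count distributions
#'
#' Two-sample KS tests of the pre-report mean CPM distributions between
#' every pair of reported levels (six comparisons), with the asymptotic
#' p-value. Pairs where either level has fewer than two occasions are
#' skipped with a notice.
#'
#' @param occ A [pa_occasions()] table.
#' @return Data frame `level_a`, `level_b`, `n_a`, `n_b`, `D`, `p_value`,
#'   `note`.
#' @export
ks_pairwise <- function(occ) {
  sp <- split(occ$preprompt_mean_cpm, occ$reported_level)
  levs <- pa_levels()
  out <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    a <- sp[[levs[i]]]; b <- sp[[levs[j]]]
    if (length(a) < 2 || length(b) < 2) {
      out[[length(out) + 1]] <- data.frame(
        level_a = levs[i], level_b = levs[j],
        n_a = length(a), n_b = length(b), D = NA_real_, p_value = NA_real_,
        note = "fewer than 2 occasions in a group", stringsAsFactors = FALSE)
      next
    }
    kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    out[[length(out) + 1]] <- data.frame(
      level_a = levs[i], level_b = levs[j], n_a = length(a), n_b = length(b),
      D = unname(kt$statistic), p_value = unname(kt$p.value), note = "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mixed linear model of log-transformed counts
#'
#' Fits ln(mean pre-report CPM + 1) on the reported level (categorical,
#' sedentary reference) with participant random intercepts by maximum
#' likelihood, and reports all pairwise level contrasts with 95% Wald
#' intervals. Each contrast is also back-transformed to a raw-count
#' difference relative to the model's sedentary mean:
#' exp(b0 + d_b) - exp(b0 + d_a), where d are the level effects.
#'
#' @param occ A [pa_occasions()] table.
#' @return Object of class `pa_logcount_lm`: list with `contrasts` (data
#'   frame `level_a`, `level_b`, `estimate`, `ci_lo`, `ci_hi`, `p_value`,
#'   `raw_cpm_diff`), `intercept` (sedentary mean of the log outcome),
#'   `sigma_u`, `sigma_e` and the lme4 `model`.
#' @export
logcount_mixed_lm <- function(occ) {
  lev_present <- levels(droplevels(occ$reported_level))
  if (length(lev_present) < 2) {
    stop("all occasions are at a single reported level", call. = FALSE)
  }
  d <- data.frame(y = log(occ$preprompt_mean_cpm + 1),
                  level = droplevels(occ$reported_level),
                  participant_id = occ$participant_id)
  fit <- fit_mixed_lm(d, y ~ level + (1 | participant_id))
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  b0 <- b[1]
  eff <- c(0, b[-1])            # level effects, reference first
  names(eff) <- lev_present
  k <- length(lev_present)
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    # contrast effect(j) - effect(i); reference has no vcov row
    L <- numeric(length(b))
    if (i > 1) L[i] <- -1
    if (j > 1) L[j] <- 1
    est <- sum(L * b)
    se <- sqrt(drop(t(L) %*% V %*% L))
    out[[length(out) + 1]] <- data.frame(
      level_a = lev_present[i], level_b = lev_present[j],
      estimate = est, se = se,
      ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
      p_value = 2 * stats::pnorm(-abs(est / se)),
      raw_cpm_diff = exp(b0 + eff[j]) - exp(b0 + eff[i]),
      stringsAsFactors = FALSE)
  }
  vc <- lme4::VarCorr(fit)
  structure(list(contrasts = do.call(rbind, out), intercept = unname(b0),
                 sigma_u = sqrt(unname(vc[[1]][1, 1])),
                 sigma_e = stats::sigma(fit), model = fit),
            class = "pa_logcount_lm")
}

#' @export
print.pa_logcount_lm <- function(x, ...) {
  cat("Mixed linear model of ln(pre-report CPM + 1)\n")
  cat(sprintf("  sedentary-reference intercept %.2f; participant SD %.2f; residual SD %.2f\n",
              x$intercept, x$sigma_u, x$sigma_e))
  ct <- x$contrasts
  ct[c("estimate", "ci_lo", "ci_hi")] <- round(ct[c("estimate", "ci_lo", "ci_hi")], 2)
  ct$raw_cpm_diff <- round(ct$raw_cpm_diff)
  print(ct[c("level_a", "level_b", "estimate", "ci_lo", "ci_hi", "p_value",
             "raw_cpm_diff")], row.names = FALSE)
  invisible(x)
}

#' Per-participant mean counts by reported level
#'
#' Summarises each participant's mean pre-report CPM at each reported
#' level and flags within-person ordering inversions: participants whose
#' mean counts are lower at the higher of two reported levels, the
#' phenomenon that makes population-level ordering misleading for
#' individuals.
#'
#' @param occ A [pa_occasions()] table.
#' @return List with `means` (participant x level means) and `inversions`
#'   (per level pair: participants with both levels, how many inverted).
#' @export
participant_level_means <- function(occ) {
  means <- stats::aggregate(preprompt_mean_cpm ~ participant_id + reported_level,
                            data = occ, FUN = mean)
  levs <- pa_levels()
  inv <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    a <- means[means$reported_level == levs[i], c("participant_id", "preprompt_mean_cpm")]
    b <- means[means$reported_level == levs[j], c("participant_id", "preprompt_mean_cpm")]
    m <- merge(a, b, by = "participant_id", suffixes = c("_a", "_b"))
    inv[[length(inv) + 1]] <- data.frame(
      level_a = levs[i], level_b = levs[j], n_both = nrow(m),
      n_inverted = sum(m$preprompt_mean_cpm_b < m$preprompt_mean_cpm_a),
      stringsAsFactors = FALSE)
  }
  list(means = means, inversions = do.call(rbind, inv))
}

#' Run the full physical-activity validation arm
#'
#' Builds the occasion set, then computes the reported-versus-derived
#' cross-tabulation with its agreement suite, per-level mixed-model odds
#' ratios, pairwise Kolmogorov-Smirnov tests, the mixed linear model of
#' logged counts, and the per-participant mean-by-level audit.
#'
#' @param prompts,epochs Study tables.
#' @param thresholds A [filter_thresholds()].
#' @return Object of class `pa_validation`.
#' @export
validate_pa <- function(prompts, epochs, thresholds = filter_thresholds()) {
  occ <- pa_occasions(prompts, epochs, thresholds)
  agg <- crosstab_and_agreement(occ)
  ors <- do.call(rbind, lapply(pa_levels(), function(l)
    pa_or_mixed_logit(occ, l)))
  structure(list(
    occasions = occ, exclusions = attr(occ, "excluded"),
    crosstab = agg, or_mixed = ors, ks = ks_pairwise(occ),
    logcount = logcount_mixed_lm(occ),
    participant_means = participant_level_means(occ),
    thresholds = thresholds
  ), class = "pa_validation")
}

#' @export
print.pa_validation <- function(x, ...) {
  cat("mEMA physical-activity validation\n")
  cat(sprintf("  %d occasions analyzed (%d prompts excluded)\n\n",
              nrow(x$occasions), nrow(x$exclusions)))
  print(x$crosstab)
  invisible(x)
}

#' @export
summary.pa_validation <- function(object, ...) {
  print(object)
  cat("\nMixed-model odds ratios (derived == reported level):\n")
  m <- object$or_mixed
  m[c("or", "ci_lo", "ci_hi")] <- round(m[c("or", "ci_lo", "ci_hi")], 2)
  print(m[c("level", "or", "ci_lo", "ci_hi", "p_value", "note")],
        row.names = FALSE)
  cat("\nKolmogorov-Smirnov pairwise comparisons:\n")
  k <- object$ks
  k$D <- round(k$D, 3)
  print(k, row.names = FALSE)
  cat("\n")
  print(object$logcount)
  invisible(object)
}

#' Plot empirical CDFs of derived counts by reported level
#'
#' @param x A `pa_validation`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pa_validation <- function(x, ...) {
  occ <- x$occasions
  sp <- split(log10(occ$preprompt_mean_cpm + 1), occ$reported_level)
  sp <- sp[vapply(sp, length, integer(1)) > 0]
  graphics::plot(NULL, xlim = range(unlist(sp)), ylim = c(0, 1),
                 xlab = "log10(pre-report CPM + 1)", ylab = "ECDF",
                 main = "Derived counts by reported level", ...)
  for (i in seq_along(sp)) {
    graphics::lines(stats::ecdf(sp[[i]]), col = i, do.points = FALSE)
  }
  graphics::legend("bottomright", legend = names(sp), col = seq_along(sp),
                   lty = 1, bty = "n")
  invisible(x)
}
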