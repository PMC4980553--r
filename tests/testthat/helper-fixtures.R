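# In-code fixtures and independent brute-force oracles used across tests.

ts_at <- function(date, clock) {
  as.POSIXct(paste(date, clock), format = "%Y-%m-%d %H:%M", tz = "UTC")
}

# minimal prompt-report rows
make_prompts <- function(participant, times, food_groups = "",
                         reported = "sedentary", type = "real_time",
                         date = "2016-02-03") {
  n <- length(times)
  data.frame(
    participant_id = rep(participant, n),
    timestamp = ts_at(date, times),
    prompt_type = rep(type, length.out = n),
    eating = nzchar(rep(food_groups, length.out = n)),
    physically_active = rep(reported, length.out = n) != "sedentary",
    food_groups = rep(food_groups, length.out = n),
    reported_pa_level = rep(reported, length.out = n),
    stringsAsFactors = FALSE
  )
}

make_recall <- function(participant, clocks, group, kcal = 2000,
                        date = "2016-02-03") {
  n <- length(clocks)
  data.frame(
    participant_id = rep(participant, n),
    date = as.Date(rep(date, length.out = n)),
    clock_time = clocks,
    food_group = rep(group, length.out = n),
    day_kcal = rep(kcal, length.out = n),
    stringsAsFactors = FALSE
  )
}

make_epochs <- function(participant, counts, start = "2016-02-03 00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(
    participant_id = rep(participant, length(counts)),
    epoch_start = t0 + 60 * (seq_along(counts) - 1),
    counts = as.integer(counts),
    stringsAsFactors = FALSE
  )
}

# the printed validation-study cross-tabulation (reported x derived)
table3_counts <- function() {
  matrix(c(340, 209, 16, 0,
           19, 37, 7, 0,
           11, 20, 9, 0,
           2, 18, 5, 1),
         nrow = 4, byrow = TRUE,
         dimnames = list(pa_levels(), pa_levels()))
}

# --- independent oracles -------------------------------------------------

# per-level agreement statistics by explicit 2x2 collapse, written
# independently of agreement_suite()
oracle_agreement <- function(tab) {
  n <- sum(tab)
  out <- NULL
  for (k in 1:4) {
    tp <- tab[k, k]
    fp <- sum(tab[k, ]) - tp        # reported k, derived other
    fn <- sum(tab[, k]) - tp        # derived k, reported other
    tn <- n - tp - fp - fn
    match_rate <- if (sum(tab[k, ]) > 0) 100 * tp / sum(tab[k, ]) else NA_real_
    sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    lrp <- if (!is.na(spec) && spec < 100) (sens / 100) / (1 - spec / 100) else NA_real_
    lrm <- if (!is.na(spec) && spec > 0) (1 - sens / 100) / (spec / 100) else NA_real_
    out <- rbind(out, c(match_rate, sens, spec, lrp, lrm))
  }
  colnames(out) <- c("match_rate", "sensitivity", "specificity",
                     "lr_plus", "lr_minus")
  out
}

# KS D as the max absolute ECDF gap over the pooled support
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# wear minutes by explicit run-length scan
oracle_wear <- function(counts, run = 60) {
  n <- length(counts)
  nonwear <- logical(n)
  i <- 1
  while (i <= n) {
    if (counts[i] == 0) {
      j <- i
      while (j < n && counts[j + 1] == 0) j <- j + 1
      if (j - i + 1 >= run) nonwear[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  sum(!nonwear)
}

# day-level match by explicit per-day min summation
oracle_day_match <- function(mema_counts, recall_counts) {
  100 * sum(pmin(mema_counts, recall_counts)) / sum(mema_counts)
}

# uncorrected 2x2 chi-square in closed form
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
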