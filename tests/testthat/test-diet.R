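test_that("day-level match follows the min-count rule in the worked cases", {
  # four momentary fruit/vegetable endorsements, three recall instances
  pr <- make_prompts("P1", c("09:30", "12:30", "16:00", "20:00"),
                     "fruits_vegetables")
  rc <- make_recall("P1", c("08:00", "13:00", "19:00"), "fruits_vegetables")
  dm <- day_match_rates(pr, rc)
  s <- dm$summary[dm$summary$food_group == "fruits_vegetables", ]
  expect_equal(s$n_mema, 4)
  expect_equal(s$n_matched, 3)
  expect_equal(s$match_rate, 75)
  # the converse: three momentary, four recall -> 3 of 3
  dm2 <- day_match_rates(make_prompts("P1", c("09:30", "12:30", "16:00"),
                                      "fruits_vegetables"),
                         make_recall("P1", c("08:00", "11:00", "13:00", "19:00"),
                                     "fruits_vegetables"))
  s2 <- dm2$summary[dm2$summary$food_group == "fruits_vegetables", ]
  expect_equal(s2$match_rate, 100)
  # a group never endorsed is reported missing, not zero
  expect_true(is.na(dm$summary$match_rate[dm$summary$food_group == "sweets"]))
})

test_that("day-level match equals brute-force per-day min summation", {
  set.seed(20)
  for (rep in 1:10) {
    n_days <- 6
    mema_n <- rpois(n_days, 2)
    recall_n <- rpois(n_days, 2)
    pr <- list(); rc <- list()
    for (d in seq_len(n_days)) {
      date <- as.character(as.Date("2016-02-03") + d - 1)
      if (mema_n[d] > 0) {
        pr[[d]] <- make_prompts("P1", sprintf("%02d:%02d", 9 + seq_len(mema_n[d]), 0),
                                "entree", date = date)
      }
      if (recall_n[d] > 0) {
        rc[[d]] <- make_recall("P1", sprintf("%02d:30", 9 + seq_len(recall_n[d])),
                               "entree", date = date)
      }
    }
    pr <- do.call(rbind, pr[!vapply(pr, is.null, TRUE)])
    rc <- do.call(rbind, rc[!vapply(rc, is.null, TRUE)])
    if (is.null(pr) || sum(mema_n) == 0) next
    if (is.null(rc)) rc <- make_recall("P1", character(0), "entree")
    dm <- day_match_rates(pr, rc)
    s <- dm$summary[dm$summary$food_group == "entree", ]
    expect_equal(s$match_rate, oracle_day_match(mema_n, recall_n))
    # dominance: recall >= momentary on every day forces 100%
    if (all(recall_n >= mema_n)) expect_equal(s$match_rate, 100)
  }
})

test_that("window match curve honours closed-interval boundary arithmetic", {
  pr <- make_prompts("P1", "12:00", "sweets")
  # recall instance exactly at the report time matches at every w
  rc0 <- make_recall("P1", "12:00", "sweets")
  cv0 <- window_match_curve(pr, rc0, grid = c(6, 12, 480))
  expect_equal(cv0$ppv[cv0$food_group == "sweets"], c(100, 100, 100))
  # 7 minutes after: unmatched at w=6, matched at w=12
  rc7 <- make_recall("P1", "12:07", "sweets")
  cv7 <- window_match_curve(pr, rc7, grid = c(6, 12))
  expect_equal(cv7$ppv[cv7$food_group == "sweets"], c(0, 100))
  # exactly w minutes away is inside the closed window
  rc6 <- make_recall("P1", "12:06", "sweets")
  cv6 <- window_match_curve(pr, rc6, grid = 6)
  expect_equal(cv6$ppv[cv6$food_group == "sweets"], 100)
  expect_error(window_match_curve(pr, rc0, grid = numeric(0)), "empty")
})

test_that("window curve and 2x2 tallies equal a brute-force all-pairs scan", {
  set.seed(25)
  groups <- setdiff(food_groups(), "other")
  for (rep in 1:5) {
    n <- 40
    times <- sprintf("%02d:%02d", sample(9:21, n, TRUE), sample(0:59, n, TRUE))
    fg <- vapply(seq_len(n), function(i)
      paste(sample(groups, sample(0:2, 1)), collapse = ";"), character(1))
    pr <- make_prompts("P1", times, "sweets")
    pr$food_groups <- fg
    m <- 30
    rc <- make_recall("P1",
                      sprintf("%02d:%02d", sample(7:23, m, TRUE),
                              sample(0:59, m, TRUE)),
                      sample(groups, m, TRUE))
    grid <- c(6, 30, 120, 480)
    cv <- window_match_curve(pr, rc, grid = grid, groups = groups)
    ss <- window_sens_spec(pr, rc, grid = grid, groups = groups)
    for (g in groups) for (w in grid) {
      endorsed <- grepl(g, pr$food_groups, fixed = TRUE)
      rt <- as.numeric(ts_at("2016-02-03", rc$clock_time[rc$food_group == g]))
      near <- vapply(as.numeric(pr$timestamp), function(t)
        length(rt) > 0 && min(abs(rt - t)) <= 60 * w, logical(1))
      row <- cv[cv$food_group == g & cv$w == w, ]
      expect_equal(row$n_matched, sum(endorsed & near))
      srow <- ss[ss$food_group == g & ss$w == w, ]
      expect_equal(c(srow$tp, srow$fp, srow$fn, srow$tn),
                   c(sum(endorsed & near), sum(endorsed & !near),
                     sum(!endorsed & near), sum(!endorsed & !near)))
      expect_equal(srow$tp + srow$fp + srow$fn + srow$tn, nrow(pr))
    }
    # PPV curves are monotone non-decreasing in w
    full <- window_match_curve(pr, rc, grid = seq(6, 480, 6), groups = groups)
    for (g in groups) {
      ppv <- full$ppv[full$food_group == g]
      expect_true(all(is.na(ppv)) || !is.unsorted(ppv[!is.na(ppv)]))
    }
  }
})

test_that("sensitivity extremes behave at identity and never-endorsed groups", {
  # recall is an exact copy of the momentary reports: sensitivity 100%
  pr <- make_prompts("P1", c("09:00", "13:00", "18:00"), "entree")
  rc <- make_recall("P1", c("09:00", "13:00", "18:00"), "entree")
  ss <- window_sens_spec(pr, rc, grid = 6, groups = "entree")
  expect_equal(ss$sensitivity, 100)
  # a group never endorsed scores 0 sensitivity wherever reference-positives exist
  ss2 <- window_sens_spec(pr, make_recall("P1", "09:00", "sweets"),
                          grid = c(6, 60), groups = "sweets")
  expect_equal(ss2$sensitivity, c(0, 0))
})

test_that("subgroup chi-square matches the closed form and detects planted gaps", {
  # hand-computable 2x2 table: matched 30/20, unmatched 10/20
  per_day <- data.frame(
    participant_id = c("A", "B"), date = as.Date("2016-02-03"),
    food_group = "entree", n_mema = c(40, 40), n_recall = c(30, 20),
    n_matched = c(30, 20))
  parts <- data.frame(participant_id = c("A", "B"),
                      gender = c("female", "male"))
  out <- subgroup_chisq(per_day, parts, "gender")
  expect_equal(out$statistic, oracle_chisq_2x2(30, 20, 10, 20))
  expect_equal(out$statistic, 16 / 3, tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_true(out$reliable)

  # balanced null at n=2000 endorsements: no signal
  set.seed(30)
  null_day <- data.frame(
    participant_id = rep(c("A", "B"), each = 20), date = as.Date("2016-02-03"),
    food_group = "sweets", n_mema = 50,
    n_matched = rbinom(40, 50, 0.8))
  null_day$n_recall <- null_day$n_matched
  out_null <- subgroup_chisq(null_day, parts[c(1, 2), ], "gender")
  expect_gt(out_null$p_value, 0.05)

  # planted 30-point match-rate gap at n=2000: overwhelming signal
  gap_day <- null_day
  gap_day$n_matched <- c(rbinom(20, 50, 0.85), rbinom(20, 50, 0.55))
  out_gap <- subgroup_chisq(gap_day, parts, "gender")
  expect_lt(out_gap$p_value, 0.001)
})

test_that("diet mixed logistic model flags degenerate inputs and matches glm in the no-variance limit", {
  set.seed(33)
  # independent outcome and predictor: CI covers the null OR of 1
  n_id <- 60; n_occ <- 12
  occ <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:n_id), each = n_occ),
    food_group = "entree",
    y = rbinom(n_id * n_occ, 1, 0.3),
    x = rbinom(n_id * n_occ, 1, 0.5))
  out <- diet_mixed_logit(occ)
  expect_true(out$converged)
  expect_true(out$ci_lo < 1 && out$ci_hi > 1)

  # no participant-level variance: estimate equals plain logistic regression
  set.seed(34)
  eta <- -0.5 + 1.2 * occ$x
  occ2 <- occ
  occ2$y <- rbinom(nrow(occ), 1, plogis(eta))
  out2 <- diet_mixed_logit(occ2)
  ref <- glm(y ~ x, binomial, occ2)
  expect_equal(log(out2$or), unname(coef(ref)[2]), tolerance = 1e-3)

  # constant predictor: flagged, not crashed
  occ3 <- occ; occ3$x <- 1L
  out3 <- diet_mixed_logit(occ3)
  expect_false(out3$converged)
  expect_true(is.na(out3$or))
})

test_that("the assembled diet validation carries consistent components", {
  b <- generate_cohort(cohort_config(n_participants = 6, n_days = 2, seed = 40))
  v <- validate_diet(b$prompts, b$recall, b$participants,
                     grid = seq(6, 480, 48))
  expect_s3_class(v, "diet_validation")
  expect_equal(sort(unique(v$window_curve$food_group)),
               sort(setdiff(food_groups(), "other")))
  # occasion conservation at every window width
  agg <- aggregate(cbind(tot = tp + fp + fn + tn) ~ w + food_group,
                   data = v$window_sens_spec, FUN = identity)
  expect_true(all(agg$tot == agg$tot[1]))
  expect_output(print(v), "diet validation")
})
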