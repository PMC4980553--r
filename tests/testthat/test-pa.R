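test_that("pre-report mean uses the half-open 5-minute window of epoch starts", {
  ep <- make_epochs("P1", rep(300, 120), start = "2016-02-03 09:00")
  t <- ts_at("2016-02-03", "10:00")
  expect_equal(preprompt_mean(ep, t)$mean_cpm, 300)
  ep2 <- make_epochs("P1", c(rep(999, 55), 0, 100, 200, 300, 400, 888),
                     start = "2016-02-03 09:00")
  # epochs at 09:55..09:59 average to 200; the 10:00 epoch is excluded
  pm <- preprompt_mean(ep2, t)
  expect_equal(pm$mean_cpm, 200)
  expect_equal(pm$n_epochs, 5)
  # no epochs in window
  expect_true(is.na(preprompt_mean(ep, ts_at("2016-02-03", "08:00"))$mean_cpm))
})

test_that("pre-report means equal a brute-force window scan on random streams", {
  set.seed(50)
  ep <- rbind(make_epochs("P1", rpois(600, 200), start = "2016-02-03 08:00"),
              make_epochs("P2", rpois(600, 500), start = "2016-02-03 08:00"))
  ids <- sample(c("P1", "P2"), 30, TRUE)
  ts <- ts_at("2016-02-03", sprintf("%02d:%02d", sample(8:17, 30, TRUE),
                                    sample(0:59, 30, TRUE)))
  got <- emavalid:::preprompt_mean_many(ep, ids, ts)
  for (j in 1:30) {
    e <- ep[ep$participant_id == ids[j], ]
    x <- e$counts[e$epoch_start >= ts[j] - 300 & e$epoch_start < ts[j]]
    expect_equal(got$mean_cpm[j], if (length(x)) mean(x) else NA_real_)
    expect_equal(got$n_epochs[j], length(x))
  }
})

test_that("the printed cross-tabulation reproduces its agreement statistics", {
  a <- crosstab_and_agreement(table3_counts())
  expect_equal(a$n, 694)
  s <- a$agreement
  expect_equal(round(s$match_rate, 1), c(60.2, 58.7, 22.5, 3.8))
  expect_equal(round(s$sensitivity), c(91, 13, 24, 100))
  expect_equal(round(s$specificity), c(30, 94, 95, 96))
  expect_equal(round(s$lr_plus, 2), c(1.31, 2.05, 5.16, 27.72))
  expect_equal(round(s$lr_minus, 2), c(0.29, 0.93, 0.79, 0.00))
  expect_equal(round(a$margins$row_pct[["sedentary"]], 1), 81.4)
  expect_equal(round(sum(a$margins$row_pct[c("sedentary", "light")]), 1), 90.5)
})

test_that("a diagonal table yields perfect agreement and zero LR-", {
  tab <- diag(c(10, 20, 30, 40))
  dimnames(tab) <- list(pa_levels(), pa_levels())
  s <- crosstab_and_agreement(tab)$agreement
  expect_equal(s$match_rate, rep(100, 4))
  expect_equal(s$sensitivity, rep(100, 4))
  expect_equal(s$specificity, rep(100, 4))
  expect_equal(s$lr_minus, rep(0, 4))
  expect_true(all(is.na(s$lr_plus)))  # undefined at specificity 1
  expect_error(crosstab_and_agreement(matrix(0, 4, 4)), "empty")
})

test_that("agreement suite equals the independent 2x2 collapse on random tables", {
  set.seed(55)
  for (rep in 1:25) {
    tab <- matrix(rpois(16, 20), 4, 4,
                  dimnames = list(pa_levels(), pa_levels()))
    got <- agreement_suite(tab)
    want <- oracle_agreement(tab)
    for (col in colnames(want)) {
      expect_equal(got[[col]], unname(want[, col]))
    }
  }
})

test_that("occasion-set margins are conserved through the cross-tab", {
  b <- generate_cohort(cohort_config(n_participants = 5, n_days = 2, seed = 60))
  occ <- pa_occasions(b$prompts, b$epochs)
  ct <- crosstab_and_agreement(occ)
  expect_equal(sum(ct$crosstab), nrow(occ))
  expect_equal(unname(ct$margins$row_n),
               unname(table(occ$reported_level)[pa_levels()]),
               ignore_attr = TRUE)
  expect_equal(nrow(occ) + nrow(attr(occ, "excluded")),
               sum(b$prompts$prompt_type == "real_time"))
})

test_that("mixed-model odds ratio applies the sparsity rule and tracks the marginal OR", {
  # single participant in the concordant vigorous cell: declared undefined
  set.seed(62)
  occ <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:10), each = 10),
    reported_level = factor("sedentary", levels = pa_levels()),
    derived_level = factor("sedentary", levels = pa_levels()),
    preprompt_mean_cpm = 50)
  occ$reported_level[1:5] <- "vigorous"
  occ$derived_level[1:5] <- "vigorous"
  out <- pa_or_mixed_logit(occ, "vigorous")
  expect_true(is.na(out$or))
  expect_match(out$note, "fewer than 2 participants")

  # no participant-level variance: mixed estimate approaches the
  # cross-product OR of the collapsed 2x2 table
  set.seed(63)
  n_id <- 50; n_occ <- 14
  rep_sed <- rbinom(n_id * n_occ, 1, 0.6)
  der_sed <- rbinom(n_id * n_occ, 1, plogis(-0.8 + 1.5 * rep_sed))
  occ2 <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:n_id), each = n_occ),
    reported_level = factor(ifelse(rep_sed == 1, "sedentary", "light"),
                            levels = pa_levels()),
    derived_level = factor(ifelse(der_sed == 1, "sedentary", "light"),
                           levels = pa_levels()),
    preprompt_mean_cpm = 50)
  out2 <- pa_or_mixed_logit(occ2, "sedentary")
  tab <- table(rep_sed, der_sed)
  marginal_or <- tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2])
  expect_equal(out2$or, marginal_or, tolerance = 0.05)

  # independence: CI covers 1
  set.seed(64)
  occ3 <- occ2
  occ3$derived_level <- sample(occ3$derived_level)
  out3 <- pa_or_mixed_logit(occ3, "sedentary")
  expect_true(out3$ci_lo < 1 && out3$ci_hi > 1)
})

test_that("KS statistics equal the brute-force maximum ECDF gap", {
  occ <- data.frame(
    participant_id = "P1",
    reported_level = factor(rep(c("sedentary", "light"), each = 3),
                            levels = pa_levels()),
    derived_level = factor("sedentary", levels = pa_levels()),
    preprompt_mean_cpm = c(1, 2, 3, 4, 5, 6))
  out <- ks_pairwise(occ)
  sl <- out[out$level_a == "sedentary" & out$level_b == "light", ]
  expect_equal(sl$D, 1)  # disjoint supports
  expect_equal(sl$note, "")
  expect_true(all(is.na(out$D[out$level_b == "vigorous"])))

  # identical samples: D = 0, p = 1
  occ2 <- occ
  occ2$preprompt_mean_cpm <- rep(c(10, 20, 30), 2)
  out2 <- ks_pairwise(occ2)
  sl2 <- out2[out2$level_a == "sedentary" & out2$level_b == "light", ]
  expect_equal(sl2$D, 0)
  expect_equal(sl2$p_value, 1)

  set.seed(70)
  for (rep in 1:10) {
    a <- rlnorm(40, 3, 1); b <- rlnorm(25, 3.5, 0.8)
    occ3 <- data.frame(
      participant_id = "P1",
      reported_level = factor(rep(c("sedentary", "light"), c(40, 25)),
                              levels = pa_levels()),
      derived_level = factor("sedentary", levels = pa_levels()),
      preprompt_mean_cpm = c(a, b))
    out3 <- ks_pairwise(occ3)
    sl3 <- out3[out3$level_a == "sedentary" & out3$level_b == "light", ]
    expect_equal(sl3$D, oracle_ks_D(a, b))
  }
})

test_that("log-count model recovers exact effects in the noise-free limit", {
  occ <- data.frame(
    participant_id = rep(c("P1", "P2"), each = 10),
    reported_level = factor(rep(c("sedentary", "light"), 10),
                            levels = pa_levels()),
    preprompt_mean_cpm = NA_real_)
  occ$preprompt_mean_cpm <- ifelse(occ$reported_level == "sedentary",
                                   exp(3) - 1, exp(4.5) - 1)
  fit <- logcount_mixed_lm(occ)
  ct <- fit$contrasts
  expect_equal(nrow(ct), 1)
  expect_equal(ct$estimate, 1.5, tolerance = 1e-6)
  expect_equal(ct$raw_cpm_diff, exp(4.5) - exp(3), tolerance = 1e-4)
  expect_error(logcount_mixed_lm(occ[occ$reported_level == "sedentary", ]),
               "single reported level")
})

test_that("log-count model matches ordinary least squares when variance is all residual", {
  set.seed(72)
  n_id <- 40; n_occ <- 12
  # identical level pattern per participant and residuals centred within
  # participant: the random-intercept variance estimate sits at zero, so
  # the mixed estimates must coincide with ordinary least squares
  lev1 <- factor(rep(pa_levels(), c(6, 3, 2, 1)), levels = pa_levels())
  lev <- rep(lev1, n_id)
  eff <- c(sedentary = 0, light = 1.7, moderate = 1.8, vigorous = 2.8)
  resid <- matrix(rnorm(n_id * n_occ, 0, 1), n_occ, n_id)
  resid <- sweep(resid, 2, colMeans(resid))
  y <- 3 + eff[as.character(lev)] + as.vector(resid)
  occ <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:n_id), each = n_occ),
    reported_level = lev,
    preprompt_mean_cpm = exp(y) - 1)
  fit <- logcount_mixed_lm(occ)
  ols <- lm(y ~ lev)
  got <- fit$contrasts
  sl <- got[got$level_a == "sedentary" & got$level_b == "light", ]
  expect_equal(sl$estimate, unname(coef(ols)["levlight"]), tolerance = 1e-3)
  mv <- got[got$level_a == "moderate" & got$level_b == "vigorous", ]
  expect_equal(mv$estimate,
               unname(coef(ols)["levvigorous"] - coef(ols)["levmoderate"]),
               tolerance = 1e-3)
})

test_that("within-person ordering inversions are detected", {
  occ <- data.frame(
    participant_id = rep(c("P1", "P2"), each = 4),
    reported_level = factor(rep(c("sedentary", "sedentary", "light", "light"), 2),
                            levels = pa_levels()),
    preprompt_mean_cpm = c(100, 120, 40, 60,   # P1 inverted
                           30, 50, 200, 240))  # P2 ordered
  pm <- participant_level_means(occ)
  sl <- pm$inversions[pm$inversions$level_a == "sedentary" &
                        pm$inversions$level_b == "light", ]
  expect_equal(sl$n_both, 2)
  expect_equal(sl$n_inverted, 1)
})

test_that("the assembled activity validation holds together on a synthetic cohort", {
  b <- generate_cohort(cohort_config(n_participants = 8, n_days = 2, seed = 80))
  v <- validate_pa(b$prompts, b$epochs)
  expect_s3_class(v, "pa_validation")
  expect_equal(sum(v$crosstab$crosstab), nrow(v$occasions))
  expect_equal(nrow(v$or_mixed), 4)
  expect_equal(nrow(v$ks), 6)
  expect_output(summary(v), "odds ratios")
})
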