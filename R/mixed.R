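# Mixed-model fitting wrappers. Both models are fit by maximum likelihood
# with lme4 defaults (bobyqa/Nelder-Mead as chosen by glmer; lmer with
# REML = FALSE); inference is by Wald intervals. Non-convergence and
# quasi-separation are flagged, never fatal.

fit_mixed_logit <- function(data, formula = y ~ x + (1 | participant_id)) {
  res <- list(beta = NA_real_, se = NA_real_, or = NA_real_,
              ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
              sigma_u = NA_real_, converged = FALSE, message = "")
  fit <- tryCatch(
    withCallingHandlers(
      suppressMessages(
        lme4::glmer(formula, data = data, family = stats::binomial())),
      warning = function(w) {
        res$message <<- paste(res$message, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) { res$message <<- conditionMessage(e); NULL })
  if (is.null(fit)) return(res)
  b <- lme4::fixef(fit)
  V <- withCallingHandlers(
    as.matrix(stats::vcov(fit)),
    warning = function(w) {
      res$message <<- paste(res$message, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  se <- sqrt(diag(V))
  # quasi-separation: implausibly large slope or exploded SE
  if (!is.finite(b[2]) || !is.finite(se[2]) || abs(b[2]) > 15 || se[2] > 15) {
    res$message <- paste(res$message, "apparent separation")
    return(res)
  }
  z <- b[2] / se[2]
  res$beta <- unname(b[2]); res$se <- unname(se[2])
  res$or <- exp(res$beta)
  res$ci_lo <- exp(res$beta - 1.96 * res$se)
  res$ci_hi <- exp(res$beta + 1.96 * res$se)
  res$p <- 2 * stats::pnorm(-abs(z))
  res$sigma_u <- sqrt(unname(lme4::VarCorr(fit)[[1]][1, 1]))
  res$converged <- !grepl("failed to converge", res$message, fixed = TRUE)
  res$fit <- fit
  res
}

fit_mixed_lm <- function(data, formula) {
  suppressMessages(withCallingHandlers(
    lme4::lmer(formula, data = data, REML = FALSE),
    warning = function(w) invokeRestart("muffleWarning")))
}
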