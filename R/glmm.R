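#' Fit a participant random-intercept (generalized) linear mixed model
#'
#' The analysis-stage model linking nightly sleep metrics to next-day
#' cognition: `outcome ~ 1 + predictors + (1 | participant)`, fitted by
#' maximum likelihood via glmmTMB. Two families are supported:
#'
#' * `"gaussian"` for reaction-time style outcomes;
#' * `"beta_zi"` for proportion outcomes in `[0, 1]` such as commission
#'   error rates: a beta response with a constant zero-inflation
#'   probability (`ziformula = ~1`), so days with exactly zero errors
#'   are carried by the inflation component rather than by squeezing
#'   transforms. Proportions equal to 1 (which the beta density cannot
#'   represent) are squeezed by `(y (n - 1) + 0.5) / n` as a fallback.
#'
#' Reported per predictor: estimate, SE, Wald `Z`, p-value, a
#' standardized estimate (from a refit on z-scaled predictors and, for
#' the Gaussian family, z-scaled outcome), and the 95% Wald CI of the
#' standardized estimate. Type III tests come from
#' `car::Anova(type = "III")` (Wald chi-square; with 1-df predictors the
#' chi-square equals the squared Z). Rows with missing outcome or
#' predictors are dropped listwise.
#'
#' @param data tibble with `participant` (or `participant_id`), the
#'   outcome column and predictor columns.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor column names (may be
#'   empty for an intercept-only model).
#' @param family `"gaussian"` or `"beta_zi"`.
#' @return An object of class `somnocog_glmm`: list with `fixed`
#'   (tibble: term, estimate, se, z, p, std_estimate, std_ci_lo,
#'   std_ci_hi), `typeIII` (tibble: term, chisq, df, p), `var_between`,
#'   `var_within` (`NA` for the beta family), `icc` (latent ICC with
#'   scale 1 for the beta family), `n_obs`, `n_participants`, `family`,
#'   `formula`, and the fitted `model`.
#' @export
fit_glmm <- function(data, outcome, predictors = character(0),
                     family = c("gaussian", "beta_zi")) {
  family <- match.arg(family)
  d <- as.data.frame(data)
  if (!"participant" %in% names(d)) {
    if ("participant_id" %in% names(d)) d$participant <- d$participant_id
    else stop("data must contain a participant (or participant_id) column")
  }
  keep <- stats::complete.cases(d[, c(outcome, predictors), drop = FALSE])
  d <- d[keep, , drop = FALSE]
  if (length(unique(d$participant)) < 2)
    stop("need at least 2 participants")
  d$participant <- factor(d$participant)

  rhs <- paste(c("1", predictors, "(1 | participant)"), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))

  if (family == "beta_zi") {
    y <- d[[outcome]]
    if (any(y < 0 | y > 1))
      stop("beta-family outcomes must lie in [0, 1]")
    n <- length(y)
    if (any(y == 1)) # squeeze exact ones; zeros go to the zi component
      d[[outcome]] <- ifelse(y == 1, (y * (n - 1) + 0.5) / n, y)
    fit <- glmmTMB::glmmTMB(fml, data = d,
                            family = glmmTMB::beta_family(),
                            ziformula = ~1, REML = FALSE)
  } else {
    fit <- glmmTMB::glmmTMB(fml, data = d, family = stats::gaussian(),
                            REML = FALSE)
  }
  if (!isTRUE(fit$sdr$pdHess))
    warning("model Hessian not positive definite; estimates may be unstable")

  co <- summary(fit)$coefficients$cond
  fixed <- tibble::tibble(term = rownames(co), estimate = co[, 1],
                          se = co[, 2], z = co[, 3], p = co[, 4])

  # standardized refit: z-scale numeric predictors (and outcome if Gaussian)
  dz <- d
  for (v in predictors)
    if (is.numeric(dz[[v]]) && sd(dz[[v]]) > 0)
      dz[[v]] <- as.numeric(scale(dz[[v]]))
  if (family == "gaussian" && sd(dz[[outcome]]) > 0)
    dz[[outcome]] <- as.numeric(scale(dz[[outcome]]))
  fitz <- if (family == "beta_zi")
    glmmTMB::glmmTMB(fml, data = dz, family = glmmTMB::beta_family(),
                     ziformula = ~1, REML = FALSE)
  else
    glmmTMB::glmmTMB(fml, data = dz, family = stats::gaussian(), REML = FALSE)
  coz <- summary(fitz)$coefficients$cond
  fixed$std_estimate <- coz[fixed$term, 1]
  fixed$std_ci_lo <- coz[fixed$term, 1] - 1.96 * coz[fixed$term, 2]
  fixed$std_ci_hi <- coz[fixed$term, 1] + 1.96 * coz[fixed$term, 2]

  t3 <- NULL
  if (length(predictors)) {
    a3 <- tryCatch(car::Anova(fit, type = "III"), error = function(e) NULL)
    if (!is.null(a3)) {
      terms3 <- rownames(a3)
      t3 <- tibble::tibble(term = terms3, chisq = a3[, "Chisq"],
                           df = a3[, "Df"], p = a3[, "Pr(>Chisq)"])
      t3 <- t3[t3$term != "(Intercept)", , drop = FALSE]
    }
  }

  vc <- glmmTMB::VarCorr(fit)$cond
  var_b <- if (length(vc)) as.numeric(vc$participant[1, 1]) else 0
  if (family == "gaussian") {
    var_w <- attr(vc, "sc")^2
    icc <- icc_from_variances(var_b, var_w)
  } else {
    var_w <- NA_real_
    icc <- latent_icc(var_b, 1)
  }

  structure(list(fixed = fixed, typeIII = t3, var_between = var_b,
                 var_within = var_w, icc = icc,
                 n_obs = nrow(d),
                 n_participants = nlevels(d$participant),
                 family = family, formula = deparse(fml), model = fit),
            class = "somnocog_glmm")
}

#' @exportS3Method base::print
print.somnocog_glmm <- function(x, ...) {
  cat("<somnocog_glmm> ", x$formula, "  [", x$family, ", ML]\n", sep = "")
  cat("  n =", x$n_obs, "obs /", x$n_participants, "participants\n")
  print(as.data.frame(x$fixed), digits = 3)
  cat(sprintf("  var_between = %.3f  var_within = %s  ICC%s = %.3f\n",
              x$var_between,
              ifelse(is.na(x$var_within), "-", sprintf("%.3f", x$var_within)),
              ifelse(x$family == "beta_zi", " (latent)", ""), x$icc))
  invisible(x)
}

# closed-form moment (one-way ANOVA) variance-component estimator for a
# balanced intercept-only random-intercept design; used as the fast refit
# engine inside the parametric bootstrap
anova_variance_components <- function(y, id) {
  id <- as.integer(factor(id))
  k <- max(id)
  n0 <- length(y) / k
  gm <- mean(y)
  gmeans <- tapply(y, id, mean)
  msb <- n0 * sum((gmeans - gm)^2) / (k - 1)
  msw <- sum((y - gmeans[id])^2) / (length(y) - k)
  var_b <- max((msb - msw) / n0, 0)
  c(var_between = var_b, var_within = msw)
}

#' Parametric bootstrap confidence interval for the ICC
#'
#' Simulates `n_boot` datasets from the fitted Gaussian random-intercept
#' model (new participant intercepts and residuals around the estimated
#' fixed-effect surface), re-estimates the variance components on each,
#' and returns percentile bounds of the ICC. Only the Gaussian family is
#' supported: reliable parametric bootstrapping is not available for the
#' zero-inflated beta model, whose ICC is reported on the latent scale
#' without an interval.
#'
#' Two refit engines are available: `"ml"` refits a random-intercept
#' model by maximum likelihood with `lme4::lmer` on every replicate;
#' `"anova"` uses the closed-form one-way ANOVA moment estimator, which
#' is orders of magnitude faster but only valid for intercept-only
#' models on balanced designs (it errors otherwise).
#'
#' @param fit a `somnocog_glmm` with `family == "gaussian"`.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed (the interval is deterministic given it).
#' @param level confidence level (default 0.95).
#' @param engine `"ml"` or `"anova"`.
#' @param max_fail_frac error out when more than this fraction of
#'   replicates fails to refit (default 0.2).
#' @return A list: `lower`, `upper`, `level`, `n_boot`, `n_failed`,
#'   `icc_boot` (the bootstrap draws).
#' @export
bootstrap_icc_ci <- function(fit, n_boot = 1000L, seed = 1L, level = 0.95,
                             engine = c("ml", "anova"),
                             max_fail_frac = 0.2) {
  engine <- match.arg(engine)
  stopifnot(inherits(fit, "somnocog_glmm"))
  if (fit$family != "gaussian")
    stop("parametric bootstrap is only available for Gaussian models")
  mf <- fit$model$frame
  id <- mf$participant
  outcome_col <- 1L # model frame: response first
  X <- stats::model.matrix(lme4::nobars(stats::as.formula(fit$formula)), mf)
  beta <- fit$fixed$estimate
  mu_fixed <- as.numeric(X %*% beta)
  k <- nlevels(factor(id))
  idx <- as.integer(factor(id))
  n <- nrow(mf)
  if (engine == "anova") {
    counts <- table(idx)
    if (ncol(X) > 1L || length(unique(counts)) != 1L)
      stop("engine = 'anova' requires an intercept-only model ",
           "on a balanced design")
  }
  set.seed(seed)
  sd_b <- sqrt(fit$var_between)
  sd_w <- sqrt(fit$var_within)
  icc_boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    y <- mu_fixed + rnorm(k, 0, sd_b)[idx] + rnorm(n, 0, sd_w)
    if (engine == "anova") {
      vc <- anova_variance_components(y, idx)
      if (sum(vc) > 0) icc_boot[b] <- vc[1] / sum(vc)
    } else {
      db <- mf
      db$.y_boot <- y
      refit <- tryCatch(
        lme4::lmer(stats::as.formula(
          paste(".y_boot ~",
                paste(c(colnames(X)[-1], "(1 | participant)"),
                      collapse = " + "))),
          data = db, REML = FALSE,
          control = lme4::lmerControl(check.conv.singular = "ignore",
                                      calc.derivs = FALSE)),
        error = function(e) NULL)
      if (!is.null(refit)) {
        vc <- lme4::VarCorr(refit)
        vb <- as.numeric(vc$participant[1, 1])
        vw <- attr(vc, "sc")^2
        if (vb + vw > 0) icc_boot[b] <- vb / (vb + vw)
      }
    }
  }
  n_failed <- sum(is.na(icc_boot))
  if (n_failed > max_fail_frac * n_boot)
    stop(n_failed, " of ", n_boot, " bootstrap refits failed")
  qs <- quantile(icc_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], level = level, n_boot = n_boot,
       n_failed = n_failed, icc_boot = icc_boot)
}

#' Simulated power for a sleep-predictor fixed effect
#'
#' Post-hoc style power simulation for the nightly-sleep design: for
#' each candidate slope `beta`, simulates participant-day data from the
#' random-intercept Gaussian model (`y = beta0 + beta x + u_i + e_ij`)
#' with a sleep predictor drawn per participant-day, fits the model by
#' maximum likelihood, and records the fraction of Wald tests rejecting
#' at level `alpha`. Power at `beta = 0` estimates the realised type-I
#' error; power is monotone non-decreasing in `|beta|` up to Monte Carlo
#' error.
#'
#' @param betas numeric vector of slopes to evaluate (outcome units per
#'   predictor unit).
#' @param n_participants,n_days design size.
#' @param var_between,var_within variance components of the generating
#'   model.
#' @param predictor_mean,predictor_sd distribution of the sleep
#'   predictor (truncated at 0, e.g. an event density).
#' @param beta0 intercept.
#' @param alpha test level.
#' @param n_sims simulations per beta (>= 100).
#' @param seed integer seed.
#' @return Tibble: `beta`, `power`, `n_sims`, `mc_se` (binomial Monte
#'   Carlo standard error).
#' @export
simulate_power <- function(betas, n_participants = 17L, n_days = 11L,
                           var_between = 2404.27, var_within = 1440.80,
                           predictor_mean = 4.2, predictor_sd = 2.85,
                           beta0 = 430, alpha = 0.05, n_sims = 200L,
                           seed = 1L) {
  if (n_sims < 100) stop("n_sims must be at least 100")
  idx <- rep(seq_len(n_participants), each = n_days)
  n <- length(idx)
  out <- lapply(seq_along(betas), function(j) {
    set.seed(derive_seed(seed, j))
    rej <- logical(n_sims)
    for (s in seq_len(n_sims)) {
      x <- pmax(rnorm(n, predictor_mean, predictor_sd), 0)
      y <- beta0 + betas[j] * x +
        rnorm(n_participants, 0, sqrt(var_between))[idx] +
        rnorm(n, 0, sqrt(var_within))
      d <- data.frame(y = y, x = x, participant = factor(idx))
      m <- tryCatch(
        lme4::lmer(y ~ x + (1 | participant), data = d, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE)),
        error = function(e) NULL)
      if (is.null(m)) next
      cf <- summary(m)$coefficients
      zst <- cf["x", "Estimate"] / cf["x", "Std. Error"]
      rej[s] <- abs(zst) > qnorm(1 - alpha / 2)
    }
    p <- mean(rej)
    tibble::tibble(beta = betas[j], power = p, n_sims = n_sims,
                   mc_se = sqrt(p * (1 - p) / n_sims))
  })
  do.call(rbind, out)
}
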