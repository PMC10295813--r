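#' Fit the condition-level mixed-effects model
#'
#' Fits `outcome ~ condition + group * time + (1 | participant)` by REML
#' (lme4), the standard model for block-level physiological/behavioral
#' outcomes in a two-group, two-timepoint repeated-measures design: the
#' condition factor carries the effect of interest while group, time and
#' their interaction are nuisance covariates. Nuisance terms with fewer than
#' two observed levels are dropped automatically.
#'
#' @param table Block-level data frame with columns `participant`,
#'   `condition`, the outcome, and optionally `group` and `time`.
#' @param outcome Name of the outcome column (e.g. `"frequency_hz"`,
#'   `"rvt_au"`, `"tracking_error_ms"`).
#' @return An object of class `condition_model`: list with the `lmerMod`
#'   fit, the model data, the outcome name, and the containment residual
#'   degrees of freedom used for Wald tests.
#' @export
fit_condition_model <- function(table, outcome) {
  stopifnot(is.data.frame(table), outcome %in% names(table))
  d <- table[is.finite(table[[outcome]]), , drop = FALSE]
  d$condition <- factor(d$condition)
  d$participant <- factor(d$participant)
  if (nlevels(d$participant) < 2L)
    stop("need at least 2 participants", call. = FALSE)
  if (nlevels(d$condition) < 2L)
    stop("singular design: factor `condition` has fewer than 2 levels",
         call. = FALSE)
  if (stats::sd(d[[outcome]]) == 0)
    stop("outcome is constant", call. = FALSE)

  fixed <- "condition"
  for (nm in c("group", "time")) {
    if (nm %in% names(d)) {
      d[[nm]] <- factor(d[[nm]])
      if (nlevels(d[[nm]]) >= 2L) fixed <- c(fixed, nm)
    }
  }
  if (all(c("group", "time") %in% fixed)) fixed <- c(fixed, "group:time")
  fml <- stats::as.formula(paste(outcome, "~", paste(fixed, collapse = " + "),
                                 "+ (1 | participant)"))
  fit <- lme4::lmer(fml, data = d, REML = TRUE)

  X <- lme4::getME(fit, "X")
  df_contain <- nrow(X) - qr(X)$rank - (nlevels(d$participant) - 1L)
  structure(list(fit = fit, data = d, outcome = outcome,
                 fixed_terms = fixed, df = df_contain),
            class = "condition_model")
}

#' @export
print.condition_model <- function(x, ...) {
  cat(sprintf("<condition_model> %s ~ %s + (1|participant), %d obs, df = %d\n",
              x$outcome, paste(x$fixed_terms, collapse = " + "),
              nrow(x$data), x$df))
  invisible(x)
}

#' Wald F test for the condition factor
#'
#' Joint test that all condition effects are zero, using the REML
#' fixed-effect covariance and the containment residual degrees of freedom
#' for the denominator.
#'
#' @param model A `condition_model`.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
condition_anova <- function(model) {
  stopifnot(inherits(model, "condition_model"))
  beta <- lme4::fixef(model$fit)
  V <- as.matrix(stats::vcov(model$fit))
  ci <- grep("^condition", names(beta))
  q <- length(ci)
  b <- beta[ci]
  W <- drop(t(b) %*% solve(V[ci, ci, drop = FALSE], b))
  Fst <- W / q
  list(F = Fst, df1 = q, df2 = model$df,
       p = stats::pf(Fst, q, model$df, lower.tail = FALSE))
}

#' Estimated marginal means and Tukey-adjusted pairwise contrasts
#'
#' Computes per-condition estimated marginal means (EMMs) -- model
#' predictions averaged over the nuisance factors' level grid -- and all
#' pairwise condition contrasts with familywise Tukey adjustment via the
#' studentized-range distribution. Each contrast estimate is exactly the
#' difference of its two EMMs.
#'
#' @param model A `condition_model` from [fit_condition_model()].
#' @param level Confidence level for EMM intervals (default 0.95).
#' @return An object of class `emm_result`: list with data frames `emmeans`
#'   (condition, mean, SE, df, CI) and `contrasts` (pair, estimate, SE, df,
#'   t, unadjusted and Tukey-adjusted p).
#' @export
emm_and_tukey <- function(model, level = 0.95) {
  stopifnot(inherits(model, "condition_model"))
  fit <- model$fit
  d <- model$data
  conds <- levels(d$condition)
  k <- length(conds)

  grid_vars <- list(condition = conds)
  for (nm in c("group", "time"))
    if (nm %in% model$fixed_terms) grid_vars[[nm]] <- levels(d[[nm]])
  grid <- expand.grid(grid_vars, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  for (nm in names(grid_vars))
    grid[[nm]] <- factor(grid[[nm]], levels = grid_vars[[nm]])

  fml <- stats::as.formula(paste("~", paste(model$fixed_terms, collapse = " + ")))
  Xg <- stats::model.matrix(fml, grid)
  beta <- lme4::fixef(fit)
  Xg <- Xg[, names(beta), drop = FALSE]
  V <- as.matrix(stats::vcov(fit))

  # averaging matrix: one row per condition, uniform over nuisance levels
  L <- t(vapply(conds, function(cn) {
    colMeans(Xg[grid$condition == cn, , drop = FALSE])
  }, numeric(ncol(Xg))))

  est <- drop(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  df <- model$df
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  emm <- data.frame(condition = conds, mean = est, SE = se, df = df,
                    lower = est - tcrit * se, upper = est + tcrit * se)

  pairs <- utils::combn(seq_len(k), 2)
  ctr <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    l <- L[i1, ] - L[i2, ]
    e <- sum(l * beta)
    s <- sqrt(drop(t(l) %*% V %*% l))
    tv <- e / s
    data.frame(contrast = paste(conds[i1], "-", conds[i2]),
               estimate = e, SE = s, df = df, t = tv,
               p_unadjusted = 2 * stats::pt(abs(tv), df, lower.tail = FALSE),
               p_tukey = stats::ptukey(sqrt(2) * abs(tv), k, df,
                                       lower.tail = FALSE),
               lower = e - tcrit * s, upper = e + tcrit * s)
  })
  structure(list(emmeans = emm, contrasts = do.call(rbind, ctr),
                 nmeans = k, df = df),
            class = "emm_result")
}

#' @export
print.emm_result <- function(x, ...) {
  cat("Estimated marginal means:\n")
  print(x$emmeans, row.names = FALSE, digits = 4)
  cat("\nTukey-adjusted pairwise comparisons:\n")
  print(x$contrasts[, c("contrast", "estimate", "SE", "df", "t", "p_tukey")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Within-participant correlation between two block-level outcomes
#'
#' Removes each participant's mean from both outcomes and correlates the
#' pooled centred values -- the classic repeated-measures correlation of
#' paired within-participant fluctuations (e.g. the breathing-rate vs depth
#' trade-off). The pooled estimator reports `df = N_obs - 2`; the
#' `"rm"` method reports the repeated-measures degrees of freedom
#' `N_obs - n_participants - 1` instead. Confidence intervals use the
#' Fisher z transform. Participants with zero within-participant variance in
#' either outcome are excluded with a warning.
#'
#' @param table Block-level data frame with `participant` and the two
#'   outcome columns.
#' @param x,y Outcome column names (defaults `"frequency_hz"`, `"rvt_au"`).
#' @param method `"pooled"` (default) or `"rm"` degrees of freedom.
#' @param level Confidence level (default 0.95).
#' @return List with `r`, `df`, `ci`, `p`, `n_obs`, `n_participants`,
#'   `method`.
#' @export
within_participant_correlation <- function(table, x = "frequency_hz",
                                           y = "rvt_au",
                                           method = c("pooled", "rm"),
                                           level = 0.95) {
  method <- match.arg(method)
  stopifnot(all(c("participant", x, y) %in% names(table)))
  d <- table[is.finite(table[[x]]) & is.finite(table[[y]]), , drop = FALSE]
  sp <- split(d, d$participant)
  sp <- Filter(function(g) nrow(g) >= 3L, sp)
  ok <- vapply(sp, function(g)
    stats::sd(g[[x]]) > 0 && stats::sd(g[[y]]) > 0, logical(1))
  if (any(!ok))
    warning(sum(!ok), " participant(s) with zero within-variance excluded")
  sp <- sp[ok]
  if (length(sp) == 0L) stop("no usable participants", call. = FALSE)
  cx <- unlist(lapply(sp, function(g) g[[x]] - mean(g[[x]])))
  cy <- unlist(lapply(sp, function(g) g[[y]] - mean(g[[y]])))
  n_obs <- length(cx)
  r <- stats::cor(cx, cy)
  df <- if (method == "pooled") n_obs - 2L else n_obs - length(sp) - 1L
  z <- atanh(r)
  se_z <- 1 / sqrt(df - 1)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  ci <- tanh(c(z - zc * se_z, z + zc * se_z))
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, ci = ci,
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       n_obs = n_obs, n_participants = length(sp), method = method)
}
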