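#' Alpha level from a peak-Z threshold
#'
#' Converts the peak-voxel Z threshold conventionally required for
#' familywise error correction into a per-test alpha: the upper-tail
#' standard-normal probability at the threshold, Bonferroni-divided by the
#' number of planned focal contrasts. At the conventional Z = 4.53 this
#' gives 2.95e-6, and 2.95e-7 after correction for 10 comparisons.
#'
#' @param peak_z Peak-voxel Z threshold.
#' @param n_tests Number of planned contrasts (>= 1).
#' @return List with `alpha_single` and `alpha_corrected`.
#' @export
derive_alpha <- function(peak_z, n_tests = 1) {
  if (!is.finite(peak_z)) stop("`peak_z` must be finite", call. = FALSE)
  if (n_tests < 1) stop("`n_tests` must be >= 1", call. = FALSE)
  a <- stats::pnorm(peak_z, lower.tail = FALSE)
  list(alpha_single = a, alpha_corrected = a / n_tests)
}

#' Per-test power required for a familywise power target
#'
#' For a family of independent tests that must all be significant, the
#' required per-test power is the n-th root of the familywise target:
#' 0.90^(1/10) = 0.9895 for 10 contrasts at familywise 0.90.
#'
#' @param familywise_power Target probability that all tests succeed.
#' @param n_tests Number of tests in the family.
#' @return Required per-test power.
#' @export
per_test_power <- function(familywise_power, n_tests = 1) {
  if (familywise_power <= 0 || familywise_power >= 1)
    stop("`familywise_power` must be in (0, 1)", call. = FALSE)
  if (n_tests < 1) stop("`n_tests` must be >= 1", call. = FALSE)
  familywise_power^(1 / n_tests)
}

#' Power-simulation specification
#'
#' Bundles the parameters of the Monte-Carlo minimum-sample-size analysis
#' for an fMRI contrast: per-participant contrast values are modelled as
#' Normal(effect_z, var_contrast + var_random) -- both printed variance
#' components perturb a participant's observed contrast -- and tested
#' against zero with a one-tailed one-sample t-test at the
#' Bonferroni-corrected alpha.
#'
#' @param familywise_power Familywise power target (default 0.90).
#' @param n_tests Number of focal contrasts (default 10).
#' @param peak_z Peak-voxel Z threshold defining alpha (default 4.53).
#' @param effect_z Simulated mean contrast effect (default 5.87).
#' @param var_contrast Variance of the contrast main effect (default 0.20).
#' @param var_random Participant random-effect variance (default 0.22).
#' @param n_sims Monte-Carlo draws per candidate N (>= 1000; default 20000).
#' @param n_grid Candidate sample sizes (default 2:15).
#' @param seed Integer seed.
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(familywise_power = 0.90, n_tests = 10,
                       peak_z = 4.53, effect_z = 5.87,
                       var_contrast = 0.20, var_random = 0.22,
                       n_sims = 20000, n_grid = 2:15, seed = 1L) {
  if (var_contrast < 0 || var_random < 0)
    stop("variances must be >= 0", call. = FALSE)
  if (n_sims < 1000)
    stop("`n_sims` must be >= 1000 for reportable results", call. = FALSE)
  if (length(n_grid) == 0L) stop("`n_grid` must be non-empty", call. = FALSE)
  structure(list(familywise_power = familywise_power, n_tests = n_tests,
                 peak_z = peak_z, effect_z = effect_z,
                 var_contrast = var_contrast, var_random = var_random,
                 n_sims = as.integer(n_sims), n_grid = sort(unique(n_grid)),
                 seed = as.integer(seed)),
            class = "power_spec")
}

#' Closed-form power of the one-sample t-test
#'
#' Noncentral-t power of a one-tailed one-sample t-test at significance
#' `alpha`: the independent analytic check on the Monte-Carlo estimate.
#'
#' @param n Sample size (>= 2).
#' @param effect Mean effect.
#' @param var_total Total variance of a participant's contrast value.
#' @param alpha One-tailed significance level.
#' @return Power (vectorized over `n`).
#' @export
power_analytic <- function(n, effect, var_total, alpha) {
  ncp <- effect / sqrt(var_total / n)
  tcrit <- stats::qt(1 - alpha, df = n - 1)
  stats::pt(tcrit, df = n - 1, ncp = ncp, lower.tail = FALSE)
}

#' Monte-Carlo minimum-N power simulation
#'
#' For each candidate sample size N, draws `n_sims` cohorts of N
#' per-participant contrast values from Normal(effect_z, var_contrast +
#' var_random), applies a one-tailed one-sample t-test against zero at the
#' Bonferroni-corrected alpha derived from `peak_z`, and estimates power as
#' the rejection fraction. The minimum N is the smallest candidate whose
#' estimated power reaches the per-test requirement
#' `familywise_power^(1/n_tests)`.
#'
#' @param spec A [power_spec()].
#' @return An object of class `power_result`: list with `alpha_single`,
#'   `alpha_corrected`, `per_test_power_required`, a data frame `power_by_n`
#'   (N, power, mc_se, power_analytic), and `min_n`.
#' @export
simulate_power <- function(spec = power_spec()) {
  stopifnot(inherits(spec, "power_spec"))
  al <- derive_alpha(spec$peak_z, spec$n_tests)
  req <- per_test_power(spec$familywise_power, spec$n_tests)
  var_total <- spec$var_contrast + spec$var_random
  set.seed(spec$seed)

  rows <- lapply(spec$n_grid, function(N) {
    X <- matrix(stats::rnorm(spec$n_sims * N, mean = spec$effect_z,
                             sd = sqrt(var_total)),
                nrow = spec$n_sims)
    m <- rowMeans(X)
    s2 <- (rowSums(X^2) - N * m^2) / (N - 1)
    tstat <- m / sqrt(s2 / N)
    p_hat <- mean(tstat > stats::qt(1 - al$alpha_corrected, df = N - 1))
    data.frame(N = N, power = p_hat,
               mc_se = sqrt(p_hat * (1 - p_hat) / spec$n_sims),
               power_analytic = power_analytic(N, spec$effect_z, var_total,
                                               al$alpha_corrected))
  })
  tab <- do.call(rbind, rows)
  ok <- tab$N[tab$power >= req]
  structure(list(alpha_single = al$alpha_single,
                 alpha_corrected = al$alpha_corrected,
                 per_test_power_required = req,
                 power_by_n = tab,
                 min_n = if (length(ok)) min(ok) else NA_integer_,
                 spec = spec),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> alpha = %.3g (corrected %.3g), required per-test power %.4f\n",
              x$alpha_single, x$alpha_corrected, x$per_test_power_required))
  print(x$power_by_n, row.names = FALSE, digits = 4)
  cat(sprintf("minimum N: %s\n", x$min_n))
  invisible(x)
}
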