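# Two-arm sample size and the analytic cost-effectiveness rule.

#' Two-arm trial design parameters
#'
#' Container for the quantities entering the two-arm normal-approximation
#' sample-size formula `n = F (sigma_1^2 + sigma_2^2) / d^2`, where
#' `F = (z_{1 - alpha/2} + z_{power})^2`.
#'
#' @param alpha Two-sided type-I error rate, in (0, 1).
#' @param power Target power `1 - beta`, in (0, 1).
#' @param d Difference in means to detect, in outcome units (`> 0`).
#' @param sd1,sd2 Per-arm outcome standard deviations (`> 0`); `sd2` defaults
#'   to `sd1`.
#' @return An object of class `trial_design`.
#' @examples
#' trial_design(d = 0.1, sd1 = 1)
#' @export
trial_design <- function(alpha = 0.05, power = 0.9, d, sd1, sd2 = sd1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (!is.finite(power) || power <= 0 || power >= 1) stop("`power` must be in (0, 1)", call. = FALSE)
  if (!is.finite(d) || d <= 0) stop("`d` must be > 0 (undetectable effect)", call. = FALSE)
  if (!is.finite(sd1) || sd1 <= 0 || !is.finite(sd2) || sd2 <= 0) {
    stop("standard deviations must be > 0", call. = FALSE)
  }
  structure(list(alpha = alpha, power = power, d = d, sd1 = sd1, sd2 = sd2),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Two-arm trial design: alpha = ", x$alpha, ", power = ", x$power,
      ", d = ", x$d, ", sd = (", x$sd1, ", ", x$sd2, ")\n", sep = "")
  invisible(x)
}

#' Per-arm sample size for a two-arm trial
#'
#' Normal-approximation sample size `n = F (sd1^2 + sd2^2) / d^2` with
#' `F = (z_{1 - alpha/2} + z_{power})^2`. No t-distribution or continuity
#' correction is applied. The value is returned unrounded so that downstream
#' cost comparisons stay exact; set `ceil = TRUE` to round up to whole
#' participants.
#'
#' @param design A [trial_design()].
#' @param ceil Round up to the next integer? Default `FALSE`.
#' @return Required sample size per arm (equal arms assumed).
#' @examples
#' required_n(trial_design(d = 0.1, sd1 = 1))  # ~2101.5 per arm
#' @export
required_n <- function(design, ceil = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  f <- (stats::qnorm(1 - design$alpha / 2) + stats::qnorm(design$power))^2
  n <- f * (design$sd1^2 + design$sd2^2) / design$d^2
  if (ceil) ceiling(n) else n
}

#' Specification of an outcome measure
#'
#' Describes one way of measuring the trial outcome: what it costs per
#' administration, how valid it is against the gold standard, how much
#' categorisation variance its scale adds, and how long it is (the burden
#' proxy used by the non-response model).
#'
#' @param unit_cost Cost per administered measurement (`> 0`), in any fixed
#'   currency unit.
#' @param validity_r Concurrent validity: correlation with the gold standard
#'   measured simultaneously, in (0, 1]; 1 for the gold standard itself.
#' @param sigma_c_sq Variance from outcome categorisation contributed by the
#'   measure's scale (squared outcome units, `>= 0`); 0 for the gold standard.
#' @param length_items Length of the instrument in items (`>= 1`), used as the
#'   participant-burden proxy.
#' @return An object of class `measure_spec`.
#' @examples
#' gold <- measure_spec(unit_cost = 50)
#' cheap <- measure_spec(unit_cost = 5, validity_r = 0.7, sigma_c_sq = 33.25,
#'                       length_items = 5)
#' @export
measure_spec <- function(unit_cost, validity_r = 1, sigma_c_sq = 0, length_items = 1) {
  if (!is.finite(unit_cost) || unit_cost <= 0) stop("`unit_cost` must be > 0", call. = FALSE)
  if (!is.finite(validity_r) || validity_r <= 0 || validity_r > 1) {
    stop("`validity_r` must be in (0, 1]", call. = FALSE)
  }
  if (!is.finite(sigma_c_sq) || sigma_c_sq < 0) stop("`sigma_c_sq` must be >= 0", call. = FALSE)
  if (!is.finite(length_items) || length_items < 1) stop("`length_items` must be >= 1", call. = FALSE)
  structure(list(unit_cost = unit_cost, validity_r = validity_r,
                 sigma_c_sq = sigma_c_sq, length_items = length_items),
            class = "measure_spec")
}

#' Effective outcome variance under an imperfect measure
#'
#' Combines the population outcome variance with the two noise sources of a
#' cheap measure. Under the default `mode = "error"` the classical
#' measurement-error model `yhat = y + e` is assumed, with the error variance
#' implied by the measure's concurrent validity `r` (so that
#' `cor(yhat, y) = r` when categorisation is ignored):
#' `sigma^2 + sigma_c^2 + sigma^2 (1 - r^2) / r^2`.
#' `mode = "attenuation"` instead treats low validity as shrinking the
#' detectable effect (`d -> r d`), equivalent to dividing the whole variance
#' by `r^2`: `(sigma^2 + sigma_c^2) / r^2`. The two coincide when
#' `sigma_c_sq = 0`, and for a gold standard (`r = 1`, `sigma_c_sq = 0`) both
#' return `sigma_sq` unchanged.
#'
#' @param sigma_sq Population outcome variance (`> 0`).
#' @param measure A [measure_spec()].
#' @param mode `"error"` (default) or `"attenuation"`.
#' @return Effective variance on the measured scale (squared outcome units).
#' @examples
#' m <- measure_spec(5, validity_r = 0.7)
#' effective_variance(100, m)  # ~204.08
#' @export
effective_variance <- function(sigma_sq, measure, mode = c("error", "attenuation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(measure, "measure_spec"))
  if (!is.finite(sigma_sq) || sigma_sq <= 0) stop("`sigma_sq` must be > 0", call. = FALSE)
  r <- measure$validity_r
  if (mode == "error") {
    sigma_sq + measure$sigma_c_sq + sigma_sq * (1 - r^2) / r^2
  } else {
    (sigma_sq + measure$sigma_c_sq) / r^2
  }
}

#' Cost-effectiveness decision between a gold-standard and a cheap measure
#'
#' For a fixed design (effect size, error rates, per-arm population SDs),
#' computes the per-arm sample size each measure needs once its effective
#' variance is accounted for, the total measurement cost of each trial (both
#' arms), and applies the analytic decision rule: the cheap measure is more
#' cost-effective exactly when its relative increase in effective variance is
#' smaller than the gold standard's relative increase in unit cost,
#' `variance_ratio < cost_ratio`. Ties go to the gold standard (it carries
#' less information-bias risk). Because total measurement cost is proportional
#' to effective variance times unit cost, the rule agrees exactly with a
#' direct comparison of total costs when sample sizes are left unrounded
#' (`ceil = FALSE`, the default).
#'
#' @param design A [trial_design()]; `sd1`, `sd2` are the per-arm *population*
#'   outcome SDs as measured by the gold standard.
#' @param gold,cheap [measure_spec()]s for the two candidate measures.
#' @param mode Validity model passed to [effective_variance()].
#' @param ceil Round sample sizes up before costing? Default `FALSE`. The
#'   decision itself always uses the analytic rule.
#' @return An object of class `cost_decision`: a list with
#'   `n_per_arm_gold`, `n_per_arm_cheap`, `total_cost_gold`,
#'   `total_cost_cheap`, `variance_ratio` (cheap:gold effective variance),
#'   `cost_ratio` (gold:cheap unit cost) and `cheap_is_cost_effective`.
#' @examples
#' des <- trial_design(d = 0.1, sd1 = 10)
#' decide_measure(des, measure_spec(50), measure_spec(5, 0.7, 33.25, 5))
#' @export
decide_measure <- function(design, gold, cheap, mode = c("error", "attenuation"),
                           ceil = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "trial_design"),
            inherits(gold, "measure_spec"), inherits(cheap, "measure_spec"))

  v_gold <- effective_variance(design$sd1^2, gold, mode) +
    effective_variance(design$sd2^2, gold, mode)
  v_cheap <- effective_variance(design$sd1^2, cheap, mode) +
    effective_variance(design$sd2^2, cheap, mode)

  f <- (stats::qnorm(1 - design$alpha / 2) + stats::qnorm(design$power))^2
  n_gold <- f * v_gold / design$d^2
  n_cheap <- f * v_cheap / design$d^2
  n_gold_cost <- if (ceil) ceiling(n_gold) else n_gold
  n_cheap_cost <- if (ceil) ceiling(n_cheap) else n_cheap

  structure(
    list(n_per_arm_gold = n_gold, n_per_arm_cheap = n_cheap,
         total_cost_gold = 2 * n_gold_cost * gold$unit_cost,
         total_cost_cheap = 2 * n_cheap_cost * cheap$unit_cost,
         variance_ratio = v_cheap / v_gold,
         cost_ratio = gold$unit_cost / cheap$unit_cost,
         cheap_is_cost_effective = (v_cheap / v_gold) < (gold$unit_cost / cheap$unit_cost)),
    class = "cost_decision"
  )
}

#' @export
print.cost_decision <- function(x, ...) {
  cat("Cost-effectiveness decision\n",
      "  n per arm        gold: ", format(x$n_per_arm_gold),
      "   cheap: ", format(x$n_per_arm_cheap), "\n",
      "  total cost       gold: ", format(x$total_cost_gold),
      "   cheap: ", format(x$total_cost_cheap), "\n",
      "  variance ratio (cheap:gold): ", format(x$variance_ratio), "\n",
      "  unit-cost ratio (gold:cheap): ", format(x$cost_ratio), "\n",
      "  cheap measure is ", if (x$cheap_is_cost_effective) "" else "NOT ",
      "more cost-effective\n", sep = "")
  invisible(x)
}
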