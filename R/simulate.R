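# Illustrative cost-ratio simulation over outcome SDs and category counts.

#' Configuration for the cost-ratio simulation
#'
#' Collects every parameter of the illustrative simulation comparing
#' cheap-but-noisy categorised measures against a gold standard over a grid of
#' population outcome standard deviations. Defaults encode the reference
#' scenario: 90% power, 5% alpha, a small effect (mean difference 0.1), low
#' concurrent validity (r = 0.7) for the cheap measures, unit costs of 50 and
#' 5 currency units per administration, a 100-level gold standard on 0--99
#' with a normally distributed outcome centred at 49.5, SDs from 0.5 to 25 in
#' steps of 0.5 (0 is excluded as degenerate), and cheap scales with 3, 5, 8,
#' 10 and 15 categories.
#'
#' The non-response penalty treats instrument length (items: the category
#' count for a cheap measure, `gold_levels` for the gold standard) as the
#' burden proxy. Response probabilities are anchored at `baseline_response_p`
#' for the shortest instrument in the scenario and scaled by the power law
#' `RQ^burden_slope`. With `response_scale = "rate"` (default) the power law
#' multiplies the response rate directly --- the reading under which doubling
#' burden cuts response by about a third and inflates recruitment by
#' `RQ^0.594`; `"odds"` applies it on the odds scale via [apply_to_rate()],
#' which is much weaker near a response rate of 1.
#'
#' @param alpha,power,d Design parameters; defaults 0.05, 0.9, 0.1.
#' @param validity_r Concurrent validity of the cheap measures; default 0.7.
#' @param gold_cost,cheap_cost Unit costs per administration; defaults 50, 5.
#' @param gold_levels Number of levels (items) of the gold standard; default
#'   100.
#' @param lo,hi,mu Scale range and outcome mean; defaults 0, 99, 49.5.
#' @param sd_grid Population outcome SDs; default `seq(0.5, 25, by = 0.5)`.
#' @param category_counts Cheap-measure category counts; default
#'   `c(3, 5, 8, 10, 15)`.
#' @param include_nonresponse Apply the non-response penalty? Default `FALSE`.
#' @param baseline_response_p Response probability of the shortest instrument,
#'   in (0, 1]; default 0.97 (simple instruments in large simple trials
#'   achieve near-complete follow-up). Setting it to 1 disables the penalty
#'   entirely.
#' @param lost_cost_equals_followed If `TRUE` (default) every recruited
#'   participant costs the full unit cost whether or not they respond; if
#'   `FALSE` only responders are billed.
#' @param burden_slope Power-law exponent; default -0.594.
#' @param response_scale `"rate"` (default) or `"odds"`.
#' @param validity_mode Passed to [effective_variance()]; default `"error"`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(alpha = 0.05, power = 0.9, d = 0.1,
                              validity_r = 0.7, gold_cost = 50, cheap_cost = 5,
                              gold_levels = 100, lo = 0L, hi = 99L, mu = 49.5,
                              sd_grid = seq(0.5, 25, by = 0.5),
                              category_counts = c(3, 5, 8, 10, 15),
                              include_nonresponse = FALSE,
                              baseline_response_p = 0.97,
                              lost_cost_equals_followed = TRUE,
                              burden_slope = -0.594,
                              response_scale = c("rate", "odds"),
                              validity_mode = c("error", "attenuation")) {
  response_scale <- match.arg(response_scale)
  validity_mode <- match.arg(validity_mode)
  if (gold_cost <= 0 || cheap_cost <= 0) stop("costs must be > 0", call. = FALSE)
  if (!length(sd_grid) || any(sd_grid <= 0)) {
    stop("`sd_grid` must be non-empty with positive SDs", call. = FALSE)
  }
  if (!length(category_counts) || any(category_counts < 1)) {
    stop("`category_counts` must be non-empty counts >= 1", call. = FALSE)
  }
  if (baseline_response_p <= 0 || baseline_response_p > 1) {
    stop("`baseline_response_p` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(alpha = alpha, power = power, d = d, validity_r = validity_r,
         gold_cost = gold_cost, cheap_cost = cheap_cost,
         gold_levels = gold_levels, lo = as.integer(lo), hi = as.integer(hi),
         mu = mu, sd_grid = sd_grid, category_counts = sort(category_counts),
         include_nonresponse = isTRUE(include_nonresponse),
         baseline_response_p = baseline_response_p,
         lost_cost_equals_followed = isTRUE(lost_cost_equals_followed),
         burden_slope = burden_slope, response_scale = response_scale,
         validity_mode = validity_mode),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Cost-simulation configuration\n")
  cat(sprintf("  design: alpha = %g, power = %g, d = %g\n", x$alpha, x$power, x$d))
  cat(sprintf("  measures: gold %g/unit (%d levels), cheap %g/unit (r = %g), categories {%s}\n",
              x$gold_cost, x$gold_levels, x$cheap_cost, x$validity_r,
              paste(x$category_counts, collapse = ", ")))
  cat(sprintf("  outcome: normal(mu = %g) on %d..%d, SD grid %g..%g (%d values)\n",
              x$mu, x$lo, x$hi, min(x$sd_grid), max(x$sd_grid), length(x$sd_grid)))
  cat(sprintf("  non-response: %s (baseline p = %g, slope = %g, %s scale)\n",
              if (x$include_nonresponse) "on" else "off",
              x$baseline_response_p, x$burden_slope, x$response_scale))
  invisible(x)
}

.response_probability <- function(rq, config) {
  mult <- response_multiplier(rq, config$burden_slope)
  p0 <- config$baseline_response_p
  if (p0 >= 1) return(1)  # infinite odds stay infinite under any multiplier
  if (config$response_scale == "rate") {
    pmin(pmax(p0 * mult, 1e-12), 1)
  } else {
    apply_to_rate(p0, mult)
  }
}

#' Run the cost-ratio simulation
#'
#' For every combination of population SD and cheap-measure category count:
#' builds the constrained discrete normal outcome distribution, obtains the
#' variance from outcome categorisation of the cheap scale, forms effective
#' per-arm variances (gold: validity 1, no categorisation error), converts
#' them to per-arm sample sizes, inflates recruitment by the reciprocal
#' response probability when the non-response penalty is on, and costs both
#' trials. The computation is fully analytic --- no random draws --- so
#' repeated runs are identical.
#'
#' @param config A [simulation_config()].
#' @return A data frame of class `cost_curves` with one row per (sd, M) cell:
#'   `sd`, `M`, `effective_var_cheap`, `effective_var_gold`, `n_cheap`,
#'   `n_gold`, `recruited_cheap`, `recruited_gold`, `total_cost_cheap`,
#'   `total_cost_gold`, `cost_ratio` (`total_cost_cheap / total_cost_gold`).
#'   The configuration is attached as attribute `"config"`.
#' @examples
#' curves <- run_cost_simulation(simulation_config(sd_grid = c(5, 10)))
#' @export
run_cost_simulation <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  f <- (stats::qnorm(1 - config$alpha / 2) + stats::qnorm(config$power))^2

  scales <- lapply(config$category_counts, make_scale, lo = config$lo, hi = config$hi)
  lengths_all <- c(config$category_counts, config$gold_levels)
  shortest <- min(lengths_all)
  p_of_length <- function(len) {
    if (!config$include_nonresponse) return(1)
    .response_probability(len / shortest, config)
  }
  p_gold <- p_of_length(config$gold_levels)
  p_cheap <- vapply(config$category_counts, p_of_length, numeric(1))

  rows <- vector("list", length(config$sd_grid) * length(config$category_counts))
  i <- 0L
  for (sd in config$sd_grid) {
    dist <- constrained_normal_distribution(sd, mu = config$mu,
                                            lo = config$lo, hi = config$hi)
    sigma_sq <- dist_variance(dist)
    v_gold <- 2 * sigma_sq  # validity 1, no categorisation error, equal arms
    n_gold <- f * v_gold / config$d^2
    for (j in seq_along(config$category_counts)) {
      i <- i + 1L
      sc2 <- categorisation_variance(dist, scales[[j]])$sigma_c_sq
      cheap <- measure_spec(config$cheap_cost, config$validity_r, sc2,
                            config$category_counts[j])
      v_cheap <- 2 * effective_variance(sigma_sq, cheap, config$validity_mode)
      n_cheap <- f * v_cheap / config$d^2
      recr_gold <- n_gold / p_gold
      recr_cheap <- n_cheap / p_cheap[j]
      billed_gold <- if (config$lost_cost_equals_followed) recr_gold else n_gold
      billed_cheap <- if (config$lost_cost_equals_followed) recr_cheap else n_cheap
      total_gold <- 2 * billed_gold * config$gold_cost
      total_cheap <- 2 * billed_cheap * config$cheap_cost
      rows[[i]] <- data.frame(
        sd = sd, M = config$category_counts[j],
        effective_var_cheap = v_cheap / 2, effective_var_gold = v_gold / 2,
        n_cheap = n_cheap, n_gold = n_gold,
        recruited_cheap = recr_cheap, recruited_gold = recr_gold,
        total_cost_cheap = total_cheap, total_cost_gold = total_gold,
        cost_ratio = total_cheap / total_gold
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("cost_curves", class(out))
  out
}

#' Plot cost-ratio curves
#'
#' One line per category count: the cheap:gold total-cost ratio against the
#' population outcome SD. Ratios below the dashed line at 1 mean the cheap
#' measure achieves the target power for less money.
#'
#' @param points A `cost_curves` data frame from [run_cost_simulation()].
#' @return A ggplot object.
#' @export
plot_cost_curves <- function(points) {
  stopifnot(is.data.frame(points), all(c("sd", "M", "cost_ratio") %in% names(points)))
  ggplot2::ggplot(points, ggplot2::aes(x = .data$sd, y = .data$cost_ratio,
                                       colour = factor(.data$M))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Population outcome SD",
                  y = "Total cost ratio (cheap : gold)",
                  colour = "Categories") +
    ggplot2::theme_minimal()
}

#' Write simulation curves to CSV (and optionally plot them)
#'
#' @param points A `cost_curves` data frame from [run_cost_simulation()].
#' @param path Path of the CSV file to write.
#' @param plot_path Optional path for a plot of the curves (written with
#'   [ggplot2::ggsave()]; the format follows the file extension). No plot file
#'   is produced when `NULL`.
#' @return `points`, invisibly.
#' @export
export_curves <- function(points, path, plot_path = NULL) {
  stopifnot(is.data.frame(points), nrow(points) > 0)
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  if (!is.null(plot_path)) {
    ggplot2::ggsave(plot_path, plot_cost_curves(points),
                    width = 7, height = 5, dpi = 150)
  }
  invisible(points)
}
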