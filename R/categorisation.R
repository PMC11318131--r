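# Variance from outcome categorisation.

#' Variance from outcome categorisation
#'
#' The variance from outcome categorisation, `sigma_c^2`, is the expected
#' squared difference between a participant's true outcome value and the
#' midpoint assigned to the outcome category containing it:
#' `sigma_c^2 = sum_m sum_{k in m} p(k) (k - ybar_m)^2`. With a one-category
#' scale every participant is assigned the midpoint of the whole range; that
#' special case is the *variance of non-measurement*, and the percentage
#' reduction relative to it measures how much information a categorised scale
#' retains. The reduction can be negative: a coarse scale whose midpoints sit
#' far from a concentrated distribution (e.g. a dichotomy applied to a tight
#' normal centred on the cut) is worse than no measurement at all.
#'
#' @param dist An [`outcome_distribution`][uniform_distribution] whose support
#'   lies within the scale range.
#' @param scale An [`outcome_scale`][make_scale] on the same range.
#' @return An object of class `categorisation_result`: a list with
#'   `sigma_c_sq`, `var_nonmeasurement` (the one-category value for the same
#'   distribution), `pct_reduction` (`100 * (1 - sigma_c_sq /
#'   var_nonmeasurement)`), and descriptors `M`, `family`, `sigma`.
#' @examples
#' u <- uniform_distribution()
#' categorisation_variance(u, make_scale(5))   # 33.25, 96% reduction
#' categorisation_variance(u, make_scale(10))  # 8.25, 99% reduction
#' @export
categorisation_variance <- function(dist, scale) {
  stopifnot(inherits(dist, "outcome_distribution"), inherits(scale, "outcome_scale"))
  if (dist$lo < scale$lo || dist$hi > scale$hi) {
    stop("distribution support [", dist$lo, ", ", dist$hi,
         "] extends beyond the scale range [", scale$lo, ", ", scale$hi, "]",
         call. = FALSE)
  }
  pos <- dist$support - scale$lo + 1L
  mids <- scale$midpoints[scale$assignment[pos]]
  sigma_c_sq <- sum(dist$pmf * (dist$support - mids)^2)

  centre <- (scale$lo + scale$hi) / 2
  var_nm <- dist_variance(dist, center = centre)
  structure(
    list(sigma_c_sq = sigma_c_sq,
         var_nonmeasurement = var_nm,
         pct_reduction = 100 * (1 - sigma_c_sq / var_nm),
         M = scale$M, family = dist$family, sigma = dist$sigma),
    class = "categorisation_result"
  )
}

#' @export
print.categorisation_result <- function(x, ...) {
  lbl <- if (x$family == "uniform") "uniform" else paste0(x$family, " (sd = ", x$sigma, ")")
  cat("Variance from categorisation (", x$M, " categories, ", lbl, ")\n",
      "  sigma_c^2          = ", format(x$sigma_c_sq), "\n",
      "  non-measurement    = ", format(x$var_nonmeasurement), "\n",
      "  reduction          = ", sprintf("%.1f%%", x$pct_reduction), "\n",
      sep = "")
  invisible(x)
}

#' Grid of categorisation variances
#'
#' Computes `sigma_c^2` and the percentage reduction in the variance of
#' non-measurement for every combination of category count and outcome
#' distribution, reproducing the layout of the package's reference table: one
#' row per (category count, distribution) cell.
#'
#' @param category_counts Integer vector of category counts; default
#'   `c(1, 2, 3, 5, 8, 10, 15, 100)`.
#' @param sds Standard deviations for the constrained normal distributions;
#'   default `c(5, 10, 15, 20, 25)`. May be empty (`numeric(0)`) for a
#'   uniform-only table.
#' @param lo,hi,mu Scale range and normal mean; defaults 0, 99, 49.5.
#' @param include_uniform Include the uniform-distribution column? Default
#'   `TRUE`.
#' @param midpoint Midpoint convention passed to [make_scale()].
#' @return A data frame with columns `M`, `family`, `sd`, `sigma_c_sq`,
#'   `pct_reduction` (`sd` is `NA` for the uniform rows).
#' @examples
#' variance_table(category_counts = c(1, 5, 10), sds = numeric(0))
#' @export
variance_table <- function(category_counts = c(1, 2, 3, 5, 8, 10, 15, 100),
                           sds = c(5, 10, 15, 20, 25),
                           lo = 0L, hi = 99L, mu = (lo + hi) / 2,
                           include_uniform = TRUE,
                           midpoint = c("halfrange", "mean")) {
  midpoint <- match.arg(midpoint)
  if (!length(category_counts)) stop("no category counts supplied", call. = FALSE)
  dists <- lapply(sds, constrained_normal_distribution, mu = mu, lo = lo, hi = hi)
  names(dists) <- as.character(sds)
  if (include_uniform) dists <- c(dists, list(uniform = uniform_distribution(lo, hi)))
  if (!length(dists)) stop("no distributions requested", call. = FALSE)

  rows <- lapply(category_counts, function(M) {
    scale <- make_scale(M, lo, hi, midpoint = midpoint)
    do.call(rbind, lapply(names(dists), function(nm) {
      res <- categorisation_variance(dists[[nm]], scale)
      data.frame(M = M, family = dists[[nm]]$family,
                 sd = if (nm == "uniform") NA_real_ else as.numeric(nm),
                 sigma_c_sq = res$sigma_c_sq, pct_reduction = res$pct_reduction)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a variance table in the wide "variance (reduction%)" layout
#'
#' @param tab A data frame from [variance_table()].
#' @return A character matrix with one row per category count and one column
#'   per distribution, each cell formatted as `"variance (reduction%)"`.
#' @export
format_variance_table <- function(tab) {
  stopifnot(all(c("M", "family", "sd", "sigma_c_sq", "pct_reduction") %in% names(tab)))
  tab$col <- ifelse(tab$family == "uniform", "uniform", paste0("sd=", tab$sd))
  cols <- unique(tab$col)
  ms <- unique(tab$M)
  out <- matrix("", nrow = length(ms), ncol = length(cols),
                dimnames = list(M = as.character(ms), distribution = cols))
  for (i in seq_len(nrow(tab))) {
    out[as.character(tab$M[i]), tab$col[i]] <-
      sprintf("%.2f (%.1f%%)", tab$sigma_c_sq[i], tab$pct_reduction[i])
  }
  out
}
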