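# Categorised outcome scales over an integer gold-standard range.

.on_half_grid <- function(x, tol = 1e-8) abs(2 * x - round(2 * x)) < tol

.snap_half_grid <- function(x, tol = 1e-8) {
  ifelse(.on_half_grid(x, tol), round(2 * x) / 2, x)
}

#' Build a categorised outcome scale
#'
#' Partitions the integer range `lo:hi` of a gold-standard outcome scale into
#' `M` ordered categories and assigns each category a representative midpoint
#' value. Category boundaries are the equal division of the continuous range
#' `[lo, hi]` into `M` parts; an integer falling exactly on an interior cut
#' belongs to the category above it.
#'
#' Two midpoint conventions are available:
#'
#' * `"halfrange"` (default): when every interior cut point lies on the scale's
#'   half-unit grid, each category's midpoint is halfway from its first integer
#'   to the next cut (the last category ends at `hi`). On a 0--99 scale this
#'   gives the dichotomy midpoints 24.75 and 74.5 (the lower category read as
#'   the range 0 to 49.5, the upper as 50 to 99) and the three-way midpoints
#'   16.5, 49.5 and 82.5. When the cuts are not half-unit representable, the
#'   midpoint of the category's integer range is used instead, so scales whose
#'   categories hold an equal number of integers (e.g. 5 or 10 categories on
#'   0--99) get the ordinary midpoints 9.5, 29.5, ... This mixed convention is
#'   the one under which the package's reference variance tables are exact.
#' * `"mean"`: the arithmetic mean of the integers in the category, i.e. the
#'   value minimising the within-category squared error for a uniform outcome.
#'
#' @param M Number of categories (integer, `1 <= M <= hi - lo + 1`).
#' @param lo,hi Integer scale endpoints (inclusive); defaults 0 and 99.
#' @param midpoint Midpoint convention, `"halfrange"` (default) or `"mean"`.
#'
#' @return An object of class `outcome_scale`: a list with elements `M`, `lo`,
#'   `hi`, `boundaries` (the `M + 1` continuous cut points), `midpoints`
#'   (length `M`), `assignment` (category index for each integer in `lo:hi`)
#'   and `midpoint_convention`.
#'
#' @examples
#' make_scale(2)            # midpoints 24.75, 74.5
#' make_scale(5)$midpoints  # 9.5, 29.5, 49.5, 69.5, 89.5
#' @export
make_scale <- function(M, lo = 0L, hi = 99L, midpoint = c("halfrange", "mean")) {
  midpoint <- match.arg(midpoint)
  if (length(M) != 1L || !is.finite(M) || M != round(M)) {
    stop("`M` must be a single integer", call. = FALSE)
  }
  if (lo != round(lo) || hi != round(hi)) {
    stop("`lo` and `hi` must be integers", call. = FALSE)
  }
  if (hi <= lo) stop("`hi` must be greater than `lo`", call. = FALSE)
  n_points <- hi - lo + 1
  if (M < 1) stop("`M` must be at least 1", call. = FALSE)
  if (M > n_points) {
    stop("more categories (", M, ") than scale points (", n_points, ")",
         call. = FALSE)
  }

  cuts <- .snap_half_grid(lo + (0:M) * (hi - lo) / M)
  k <- lo:hi
  idx <- findInterval(k, cuts, rightmost.closed = TRUE)

  # identity categorisation: every category is a single integer and is its
  # own midpoint, whatever the convention
  halfrange_ok <- M < n_points && (M == 1 || all(.on_half_grid(cuts[2:M])))
  midpoints <- vapply(seq_len(M), function(m) {
    ints <- k[idx == m]
    a <- min(ints)
    b <- max(ints)
    if (midpoint == "mean") {
      mean(ints)
    } else if (halfrange_ok) {
      u <- if (m == M) hi else cuts[m + 1]
      (a + u) / 2
    } else {
      (a + b) / 2
    }
  }, numeric(1))

  structure(
    list(M = as.integer(M), lo = as.integer(lo), hi = as.integer(hi),
         boundaries = cuts, midpoints = midpoints, assignment = idx,
         midpoint_convention = midpoint),
    class = "outcome_scale"
  )
}

#' Categories of an outcome scale as a data frame
#'
#' @param x An `outcome_scale`.
#' @param ... Unused.
#' @return A data frame with one row per category: `category`, `first`, `last`
#'   (integer range covered) and `midpoint`.
#' @export
as.data.frame.outcome_scale <- function(x, ...) {
  k <- x$lo:x$hi
  data.frame(
    category = seq_len(x$M),
    first = vapply(seq_len(x$M), function(m) min(k[x$assignment == m]), numeric(1)),
    last = vapply(seq_len(x$M), function(m) max(k[x$assignment == m]), numeric(1)),
    midpoint = x$midpoints
  )
}

#' @export
print.outcome_scale <- function(x, ...) {
  cat("Outcome scale: ", x$M, " categories on ", x$lo, "..", x$hi,
      " (midpoints: ", x$midpoint_convention, ")\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
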