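#' Overlap between an ignited set and a core
#'
#' Splits the `n` nodes into the four cells of the ignited-by-core-member
#' contingency table and returns the fractions (summing to 1): ignited core
#' members, ignited non-members ("spill-over"), non-ignited core members
#' ("incomplete ignition"), and the rest. A perfect ignition-core/s_max-core
#' match has both off-diagonal fractions equal to 0.
#'
#' @param ignited integer indices of ignited nodes (in `1..n`).
#' @param core integer indices of core members (in `1..n`).
#' @param n total node count.
#' @return Named numeric vector:
#'   `ignited_core`, `ignited_noncore`, `core_not_ignited`, `neither`.
#' @export
core_overlap <- function(ignited, core, n) {
  stopifnot(all(ignited %in% seq_len(n)), all(core %in% seq_len(n)))
  ignited <- unique(ignited)
  core <- unique(core)
  c(ignited_core = length(intersect(ignited, core)) / n,
    ignited_noncore = length(setdiff(ignited, core)) / n,
    core_not_ignited = length(setdiff(core, ignited)) / n,
    neither = (n - length(union(ignited, core))) / n)
}

#' Squared Spearman rank correlation
#'
#' The explained variance of the rank relation between two per-node
#' quantities (ties handled with average ranks). Pairs where either value is
#' `NA` are dropped under the default censoring rule — the natural treatment
#' for never-ignited nodes, whose first-ignition `G` is undefined.
#'
#' @param x,y numeric vectors of equal length.
#' @param censor `"drop_na"` (default) or `"none"` (NAs are an error).
#' @return `rho^2` in `[0, 1]`, with attribute `n_censored`.
#' @export
rank_r2 <- function(x, y, censor = c("drop_na", "none")) {
  censor <- match.arg(censor)
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  if (censor == "none" && !all(keep)) stop("NA values present", call. = FALSE)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input after censoring: rank correlation undefined",
         call. = FALSE)
  }
  r2 <- stats::cor(x, y, method = "spearman")^2
  attr(r2, "n_censored") <- sum(!keep)
  r2
}

#' Bootstrap percentile interval for the squared Spearman correlation
#'
#' Resamples node pairs `(x_i, y_i)` jointly with replacement, recomputes
#' `rho^2` per replica, and returns the point estimate with the (2.5, 97.5)
#' percentile interval. Two results are called significantly different when
#' their percentile intervals do not overlap. Degenerate replicas (constant
#' `x` or `y` after resampling) are redrawn, up to `max_redraw` times each.
#'
#' @param x,y numeric vectors (NA pairs censored as in [rank_r2()]).
#' @param n_boot number of replicas (>= 100; the reference protocol uses
#'   10000).
#' @param seed integer seed.
#' @param max_redraw redraw cap per degenerate replica.
#' @return A list of class `correlation_result`: `rho_squared`, `ci`
#'   (percentiles 2.5 and 97.5), `n_boot`, `n_censored`, `seed`.
#' @export
bootstrap_r2 <- function(x, y, n_boot = 10000L, seed = 1L, max_redraw = 100L) {
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  point <- rank_r2(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  set.seed(as.integer(seed))
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    for (try in seq_len(max_redraw)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]
      if (stats::sd(xb) > 0 && stats::sd(yb) > 0) break
      if (try == max_redraw) stop("too many degenerate bootstrap replicas",
                                  call. = FALSE)
    }
    reps[b] <- stats::cor(xb, yb, method = "spearman")^2
  }
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  structure(list(rho_squared = as.numeric(point),
                 ci = ci, n_boot = as.integer(n_boot),
                 n_censored = attr(point, "n_censored"),
                 seed = as.integer(seed)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<rank correlation> rho^2 = %.3f, percentile (2.5, 97.5) = (%.3f, %.3f), %d replicas\n",
              x$rho_squared, x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}
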