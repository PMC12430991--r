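# Left-truncated normal on [a, Inf). No CRAN truncnorm dependency; the four
# helpers below are the standard closed forms on top of pnorm/qnorm/dnorm.

tn_alpha <- function(location, scale, lower) (lower - location) / scale

#' Analytic mean of a left-truncated normal
#'
#' @param location,scale Parameters of the parent normal distribution
#'   (`scale > 0`).
#' @param lower Left truncation bound.
#' @return The mean of the normal truncated to `[lower, Inf)`.
#' @keywords internal
tn_mean <- function(location, scale, lower = 0) {
  a <- tn_alpha(location, scale, lower)
  location + scale * exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

#' @rdname tn_mean
#' @keywords internal
tn_median <- function(location, scale, lower = 0) {
  tn_quantile(0.5, location, scale, lower)
}

tn_quantile <- function(p, location, scale, lower = 0) {
  pa <- pnorm(tn_alpha(location, scale, lower))
  location + scale * qnorm(pa + p * (1 - pa))
}

tn_sample <- function(n, location, scale, lower = 0) {
  tn_quantile(stats::runif(n), location, scale, lower)
}

tn_density <- function(x, location, scale, lower = 0) {
  z <- pnorm(tn_alpha(location, scale, lower), lower.tail = FALSE)
  ifelse(x < lower, 0, dnorm((x - location) / scale) / (scale * z))
}

#' Fit a left-truncated normal to a (median, mean) pair
#'
#' Finds the `(location, scale)` of a normal distribution truncated to
#' `[lower_bound, Inf)` whose analytic median and mean match the targets,
#' by two-dimensional root finding on the closed-form moment equations.
#'
#' A left-truncated normal is right-skewed, so its mean strictly exceeds its
#' median whenever the truncation has any effect; target pairs with
#' `mean_target <= median_target` are therefore rejected, as are fits whose
#' required scale exceeds `scale_max` (by default 35% of the median target,
#' which keeps the fitted mass well away from the bound and the sample median
#' tightly concentrated).
#'
#' @param median_target,mean_target Target median and mean; both must exceed
#'   `lower_bound` and satisfy `mean_target > median_target`.
#' @param lower_bound Left truncation bound (default 0, for nonnegative
#'   physiological/behavioral features).
#' @param scale_max Upper bound on the admissible scale; `Inf` disables it.
#' @return A list with `location`, `scale`, `lower`, and the achieved
#'   `median` and `mean` (matching the targets to better than 1e-6).
#' @examples
#' fit <- fit_location_scale(1.0, 1.1, 0)
#' fit$location; fit$scale
#' @export
fit_location_scale <- function(median_target, mean_target, lower_bound = 0,
                               scale_max = 0.35 * median_target) {
  stopifnot(is.numeric(median_target), is.numeric(mean_target))
  if (median_target <= lower_bound || mean_target <= lower_bound) {
    stop("targets must lie strictly above the lower bound", call. = FALSE)
  }
  if (mean_target <= median_target) {
    stop(
      "no left-truncated normal has mean <= median (the family is ",
      "right-skewed); targets (median = ", median_target, ", mean = ",
      mean_target, ") are infeasible",
      call. = FALSE
    )
  }
  # unknowns: location and log(scale); start near the untruncated guess
  resid <- function(par) {
    loc <- par[1]
    sc <- exp(par[2])
    c(
      tn_median(loc, sc, lower_bound) - median_target,
      tn_mean(loc, sc, lower_bound) - mean_target
    )
  }
  start <- c(median_target, log(max(4 * (mean_target - median_target), 1e-3 * median_target)))
  sol <- tryCatch(
    suppressWarnings(pracma::fsolve(resid, start, tol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(sol) || max(abs(resid(sol$x))) > 1e-6) {
    # fall back to damped least squares before giving up
    obj <- function(par) sum(resid(par)^2)
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-16, maxit = 5000))
    sol <- list(x = opt$par)
    if (max(abs(resid(sol$x))) > 1e-6) {
      stop("no truncated-normal solution found for targets (median = ",
           median_target, ", mean = ", mean_target, ")", call. = FALSE)
    }
  }
  location <- sol$x[1]
  scale <- exp(sol$x[2])
  if (scale > scale_max) {
    stop("fitted scale ", signif(scale, 4), " exceeds scale_max ",
         signif(scale_max, 4), "; targets imply more skew than admissible",
         call. = FALSE)
  }
  list(
    location = location, scale = scale, lower = lower_bound,
    median = tn_median(location, scale, lower_bound),
    mean = tn_mean(location, scale, lower_bound)
  )
}
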