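#' Fit a three-component Gaussian mixture to SNP read ratios
#'
#' Fits, by expectation-maximisation, the univariate mixture
#' \deqn{f(r) = \sum_{k=1}^{3} \lambda_k \, \phi(r; \mu_k, \sigma_k)}
#' to a sample of reference read ratios, from the fixed deterministic
#' initialisation `mu = (0.25, 0.5, 0.75)`, `sigma = 0.05` and equal
#' weights.  `k = 3` is fixed: the components absorb the low, central and
#' high dosage peaks of the ratio histogram, and their mixing weights are
#' the "peak heights" summarised by [peak_ratio()].  The fit is fully
#' deterministic given the data; the log-likelihood is non-decreasing
#' across iterations and the algorithm stops when its relative improvement
#' falls below `tol`.
#'
#' Components whose standard deviation collapses below `sigma_floor`
#' (typically because a peak is empty) are floored there and the fit is
#' flagged `degenerate` with `converged = FALSE`.
#'
#' @param ratios Numeric vector of ratios in (0,1), or a `ratio_set` from
#'   [compute_ratios()].
#' @param init_mu Initial component means (sorted internally).
#' @param init_sigma Initial standard deviation, recycled to 3.
#' @param fixed_means If `TRUE`, component means are held at `init_mu` and
#'   only weights and standard deviations are updated.
#' @param tol Relative log-likelihood improvement at which EM stops.
#' @param max_iter Maximum EM iterations.
#' @param sigma_floor Lower bound on component standard deviations.
#' @param sample_id Optional sample label carried into reports.
#'
#' @return An object of class `ratio_mixture` with elements `mu`, `sigma`,
#'   `lambda` (each length 3, sorted by mean), `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, `degenerate`, `n`, `data`.
#'
#' @examples
#' set.seed(1)
#' r <- c(rnorm(300, 0.25, 0.04), rnorm(400, 0.5, 0.04),
#'        rnorm(300, 0.75, 0.04))
#' fit <- fit_ratio_mixture(r)
#' fit
#' peak_ratio(fit)
#' @export
fit_ratio_mixture <- function(ratios,
                              init_mu = c(0.25, 0.5, 0.75),
                              init_sigma = 0.05,
                              fixed_means = FALSE,
                              tol = 1e-8,
                              max_iter = 1000,
                              sigma_floor = 1e-4,
                              sample_id = NULL) {
  if (inherits(ratios, "ratio_set")) {
    sample_id <- sample_id %||% attr(ratios, "sample_id")
    ratios <- ratios$ratio
  }
  x <- as.numeric(ratios)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 30) stop("need at least 30 ratios to fit the mixture",
                   call. = FALSE)
  if (any(init_mu <= 0) || any(init_mu >= 1)) {
    stop("`init_mu` must lie strictly inside (0, 1)", call. = FALSE)
  }
  mu <- sort(as.numeric(init_mu))
  if (length(mu) != 3L) stop("`init_mu` must have length 3", call. = FALSE)
  sigma <- rep_len(as.numeric(init_sigma), 3L)
  lambda <- rep(1 / 3, 3L)

  dens <- function(mu, sigma, lambda) {
    # n x 3 matrix of lambda_k * N(x; mu_k, sigma_k)
    vapply(1:3, function(k) lambda[k] * stats::dnorm(x, mu[k], sigma[k]),
           numeric(n))
  }
  ll_of <- function(d) sum(log(rowSums(d)))

  d <- dens(mu, sigma, lambda)
  ll <- ll_of(d)
  trace <- ll
  degenerate <- FALSE
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    post <- d / rowSums(d)                        # E-step responsibilities
    nk <- colSums(post)
    empty <- nk < 1e-10                           # keep dead components put
    lambda <- nk / n
    if (!fixed_means) {
      mu_new <- colSums(post * x) / nk
      mu[!empty] <- mu_new[!empty]
    }
    sigma_new <- sqrt(colSums(post * (x - rep(mu, each = n))^2) / nk)
    sigma[!empty] <- sigma_new[!empty]
    if (any(!is.finite(sigma)) || any(sigma < sigma_floor)) {
      sigma[!is.finite(sigma) | sigma < sigma_floor] <- sigma_floor
      degenerate <- TRUE
    }
    d <- dens(mu, sigma, lambda)
    ll_new <- ll_of(d)
    trace <- c(trace, ll_new)
    if (is.finite(ll_new) && is.finite(ll) &&
        (ll_new - ll) < tol * abs(ll)) {
      converged <- !degenerate
      ll <- ll_new
      break
    }
    ll <- ll_new
  }

  ord <- order(mu)
  structure(
    list(
      mu = mu[ord], sigma = sigma[ord], lambda = lambda[ord],
      loglik = ll, loglik_trace = trace, n_iter = iter,
      converged = converged, degenerate = degenerate,
      n = n, data = x, sample_id = sample_id,
      fixed_means = fixed_means
    ),
    class = "ratio_mixture"
  )
}

#' @export
print.ratio_mixture <- function(x, digits = 4, ...) {
  cat("Three-component Gaussian mixture of SNP read ratios\n")
  if (!is.null(x$sample_id)) cat("  sample:", x$sample_id, "\n")
  cat(sprintf("  n = %d, logLik = %.3f, %d EM iterations%s\n", x$n,
              x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  tab <- rbind(mu = x$mu, sigma = x$sigma, lambda = x$lambda)
  colnames(tab) <- c("low", "mid", "high")
  print(round(tab, digits))
  cat(sprintf("  peak ratio (minor/central weight): %.4f\n",
              peak_ratio(x)))
  invisible(x)
}

#' @export
summary.ratio_mixture <- function(object, ...) {
  out <- list(
    components = data.frame(
      component = c("low", "mid", "high"),
      mu = object$mu, sigma = object$sigma, lambda = object$lambda
    ),
    n = object$n, loglik = object$loglik,
    peak_ratio = peak_ratio(object),
    category = classify_ploidy(peak_ratio(object)),
    converged = object$converged, degenerate = object$degenerate
  )
  class(out) <- "summary.ratio_mixture"
  out
}

#' @export
print.summary.ratio_mixture <- function(x, ...) {
  print(x$components, row.names = FALSE)
  cat(sprintf("n = %d  logLik = %.3f  peak ratio = %.4f  category = %s\n",
              x$n, x$loglik, x$peak_ratio, x$category))
  invisible(x)
}

#' @export
coef.ratio_mixture <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma, lambda = object$lambda)
}

#' @export
logLik.ratio_mixture <- function(object, ...) {
  structure(object$loglik, df = if (object$fixed_means) 5 else 8,
            nobs = object$n, class = "logLik")
}

#' Draw new ratios from a fitted mixture
#'
#' @param object A `ratio_mixture` fit.
#' @param nsim Number of draws.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Numeric vector of simulated ratios.
#' @export
simulate.ratio_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    k <- sample.int(3L, nsim, replace = TRUE, prob = object$lambda)
    stats::rnorm(nsim, object$mu[k], object$sigma[k])
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Plot a ratio histogram with the fitted mixture density
#'
#' @param x A `ratio_mixture` fit.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @param ... Further arguments to `hist`.
#' @export
plot.ratio_mixture <- function(x, breaks = 50, ...) {
  graphics::hist(x$data, breaks = breaks, freq = FALSE,
                 xlab = "reference read ratio",
                 main = x$sample_id %||% "SNP read ratio mixture", ...)
  grid_x <- seq(0, 1, length.out = 401)
  for (k in 1:3) {
    graphics::lines(grid_x,
                    x$lambda[k] * stats::dnorm(grid_x, x$mu[k], x$sigma[k]),
                    col = k + 1, lwd = 2)
  }
  graphics::lines(grid_x, vapply(grid_x, function(g) {
    sum(x$lambda * stats::dnorm(g, x$mu, x$sigma))
  }, numeric(1)), lwd = 2)
  invisible(x)
}

#' Minor-to-central peak weight ratio of a fitted mixture
#'
#' Summarises a fitted read-ratio mixture as the mean weight of the two
#' outer components (the 0.25 and 0.75 dosage peaks) relative to the weight
#' of the central 0.5 component:
#' `mean(lambda_low, lambda_high) / lambda_mid`.  Diploids score well below
#' 1 (outer peaks nearly empty); functional tetraploids score near or above
#' 1.  `inverse = TRUE` returns the reciprocal orientation
#' (central / mean of outer weights) for users who prefer it.
#'
#' @param fit A `ratio_mixture` object.
#' @param inverse Return `lambda_mid / mean(lambda_low, lambda_high)`
#'   instead.
#' @return A non-negative number (`Inf`, with a warning, if the relevant
#'   denominator weight is zero).
#' @export
peak_ratio <- function(fit, inverse = FALSE) {
  stopifnot(inherits(fit, "ratio_mixture"))
  minor <- mean(fit$lambda[c(1L, 3L)])
  central <- fit$lambda[2L]
  num <- if (inverse) central else minor
  den <- if (inverse) minor else central
  if (den == 0) {
    warning("denominator peak weight is zero; returning Inf")
    return(Inf)
  }
  num / den
}

#' Average peak ratios across individuals of a species
#'
#' @param peak_ratios Numeric vector of per-individual peak ratios (one or
#'   more individuals; the replicate design uses two per species).
#' @return Their arithmetic mean.
#' @export
species_ratio <- function(peak_ratios) {
  x <- as.numeric(peak_ratios)
  if (!length(x)) stop("need at least one individual", call. = FALSE)
  mean(x)
}

#' Classify a species-level peak ratio into a ploidy category
#'
#' Observed species fall into three groups of peak ratio: a diploid-like
#' group (roughly 0.25-0.4), an intermediate group (0.53-0.72) consistent
#' with an older, partially rediploidised duplication, and a
#' tetraploid-like group (1.02-1.18) where the outer peaks rival the
#' central one.  The default cut points 0.45 and 0.9 fall between those
#' observed ranges; they are configuration, not constants of nature.
#'
#' @param species_mean_ratio Non-negative peak ratio(s).
#' @param t_low Boundary between diploid-like and intermediate.
#' @param t_high Boundary between intermediate and tetraploid-like.
#' @return Character vector with levels `"diploid-like"`,
#'   `"intermediate"`, `"tetraploid-like"`.
#' @export
classify_ploidy <- function(species_mean_ratio, t_low = 0.45, t_high = 0.9) {
  x <- as.numeric(species_mean_ratio)
  if (any(x < 0, na.rm = TRUE)) {
    stop("peak ratios must be non-negative", call. = FALSE)
  }
  ifelse(x < t_low, "diploid-like",
         ifelse(x < t_high, "intermediate", "tetraploid-like"))
}
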