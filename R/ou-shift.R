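#' Detect optimum shifts on a phylogeny by LASSO-selected OU regression
#'
#' Fits the OU trait model on an ultrametric tree and locates branches
#' carrying optimum shifts, without predetermining their number or
#' placement.  For each selection strength `alpha` on a log-spaced grid
#' the tip traits and the branch design matrix ([ou_design()]) are
#' whitened through the Cholesky factor of the OU covariance
#' ([ou_covariance()]); a LASSO path over the branch coefficients proposes
#' candidate shift sets, each candidate is refitted by generalised least
#' squares, and the candidate minimising the information criterion over
#' the whole path and grid is returned.  The procedure is deterministic
#' given its inputs.
#'
#' The default criterion `"ebic"` is the plain BIC plus
#' `2 * s * log(#branches)` for `s` shifts (an extended BIC): searching
#' every branch of the tree for shifts multiplies the ways the model can
#' overfit, and the extra term prices that search in, keeping the
#' no-shift false-positive rate low.  `criterion = "bic"` gives the plain
#' BIC with `s + 3` parameters (shift offsets, root optimum, `alpha`,
#' `sigma2`); it is markedly more permissive on trees with many branches.
#' Ties are broken toward fewer shifts.
#'
#' Shift placements on the two branches stemming from the root are
#' mutually unresolvable (a shift on one is a shift of opposite effect on
#' the other, absorbed by the root optimum); such equivalences are listed
#' in the fitted object's `equivalences` field.
#'
#' @param tree Ultrametric `phylo` tree with >= 4 tips; rescaled to unit
#'   height internally (see [scale_tree()]).
#' @param traits Named numeric vector of tip traits covering every tip.
#' @param criterion `"ebic"` (default) or `"bic"`.
#' @param alpha_grid Selection strengths to profile over; default 20
#'   log-spaced points between 0.01 and 100 (in units of 1 / tree
#'   height).
#' @param nlambda Length of each LASSO path.
#' @param max_shifts Largest candidate shift set retained from the path;
#'   default `max(1, floor(n_tips / 4))`.
#'
#' @return An object of class `ou_shift_fit`: `shift_edges` (row indices
#'   of `tree$edge`), `beta` (per-shift regression offsets on the
#'   attenuated-indicator scale), `tip_effect` (the resulting
#'   displacement of descendant tip expectations, in trait units),
#'   `theta0`, `alpha`, `sigma2`, `loglik`,
#'   `score`, `criterion`, `fitted`, `residuals`, `equivalences`,
#'   `support` (populated by [bootstrap_support()]).
#'
#' @examples
#' tr <- scale_tree(ape::compute.brlen(ape::stree(16, "balanced"), 1))
#' cfg <- ou_sim_config(tr, shift_edges = 2L, offsets = 3,
#'                      alpha = 2, sigma2 = 0.5, seed = 5)
#' y <- simulate_ou_traits(cfg)
#' detect_shifts(tr, y)
#' @export
detect_shifts <- function(tree, traits,
                          criterion = c("ebic", "bic"),
                          alpha_grid = NULL,
                          nlambda = 50,
                          max_shifts = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 4L) stop("need at least 4 tips to detect shifts", call. = FALSE)
  if (is.null(names(traits)) || !all(tree$tip.label %in% names(traits))) {
    stop("`traits` must be named and cover every tip of the tree",
         call. = FALSE)
  }
  tree <- scale_tree(tree)
  y <- as.numeric(traits[tree$tip.label])
  if (any(!is.finite(y))) stop("non-finite trait values", call. = FALSE)
  E <- nrow(tree$edge)
  if (is.null(alpha_grid)) {
    alpha_grid <- exp(seq(log(0.01), log(100), length.out = 20))
  }
  if (any(alpha_grid < 0)) stop("`alpha_grid` must be >= 0", call. = FALSE)
  max_shifts <- max_shifts %||% max(1L, floor(n / 4))

  tips <- edge_tip_sets(tree)
  ind <- matrix(0, n, E)
  for (e in seq_len(E)) ind[tips[[e]], e] <- 1
  tt <- tree_times(tree)

  score_of <- function(ll, s) {
    b <- -2 * ll + (s + 3) * log(n)
    if (criterion == "ebic") b <- b + 2 * s * log(E)
    b
  }

  # Per-alpha whitened responses/designs, computed once.
  layers <- lapply(alpha_grid, function(alpha) {
    V0 <- ou_covariance(tree, alpha, sigma2 = 1)
    U <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(U)) stop("singular OU covariance at alpha = ", alpha,
                         call. = FALSE)
    w <- exp(-alpha * (tt$height - tt$t_end)) -
      exp(-alpha * (tt$height - tt$t_start))
    X <- ind * rep(w, each = n)
    list(alpha = alpha,
         logdet = 2 * sum(log(diag(U))),
         Xw = backsolve(U, cbind(`(intercept)` = 1, X), transpose = TRUE),
         yw = backsolve(U, y, transpose = TRUE))
  })

  # Scale-aware variance floor: below it a fit is numerically exact and
  # models are compared on parameter count alone.
  s2_floor <- 1e-16 * (1 + mean(y^2))

  # GLS fit of one support set, profiled over the alpha grid.
  eval_support <- function(supp) {
    s <- length(supp)
    best <- NULL
    for (lay in layers) {
      Z <- lay$Xw[, c(1L, supp + 1L), drop = FALSE]
      ls <- stats::lm.fit(Z, lay$yw)
      rss <- sum(ls$residuals^2)
      sigma2 <- max(rss / n, s2_floor)
      ll <- -n / 2 * log(2 * pi * sigma2) - lay$logdet / 2 - n / 2
      score <- score_of(ll, s)
      if (is.null(best) || score < best$score) {
        best <- list(supp = supp, coefs = ls$coefficients,
                     sigma2 = sigma2, loglik = ll, score = score,
                     alpha = lay$alpha)
      }
    }
    best
  }

  # Candidate shift sets: the empty set, every single branch, and the
  # support sets traversed by the LASSO path at each alpha.
  supports <- c(list(integer()),
                if (max_shifts >= 1L) lapply(seq_len(E), function(e) e))
  for (lay in layers) {
    lasso <- glmnet::glmnet(lay$Xw, lay$yw, intercept = FALSE,
                            standardize = FALSE,
                            penalty.factor = c(0, rep(1, E)),
                            nlambda = nlambda)
    for (col in seq_len(ncol(lasso$beta))) {
      v <- which(as.numeric(lasso$beta[-1L, col]) != 0)
      if (length(v) > 1L && length(v) <= max_shifts) {
        supports <- c(supports, list(v))
      }
    }
  }
  supports <- unique(supports)

  best <- NULL
  for (supp in supports) {
    cand <- eval_support(supp)
    if (is.null(best) ||
        cand$score < best$score - 1e-9 ||
        (abs(cand$score - best$score) <= 1e-9 &&
         length(cand$supp) < length(best$supp))) {
      best <- cand
    }
  }

  # Backward elimination: dropping a shift must not improve the score.
  while (length(best$supp) > 1L) {
    improved <- FALSE
    for (drop in seq_along(best$supp)) {
      cand <- eval_support(best$supp[-drop])
      if (cand$score < best$score - 1e-9) {
        best <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }

  supp <- best$supp
  coefs <- best$coefs
  theta0 <- coefs[1L]
  beta <- if (length(supp)) coefs[-1L] else numeric()
  w_best <- exp(-best$alpha * (tt$height - tt$t_end)) -
    exp(-best$alpha * (tt$height - tt$t_start))
  Xb <- ind * rep(w_best, each = n)
  fitted <- drop(cbind(1, Xb[, supp, drop = FALSE]) %*% coefs)
  names(fitted) <- tree$tip.label
  # displacement of descendant tip expectations, in trait units
  tip_effect <- if (length(supp)) unname(beta * w_best[supp]) else numeric()

  # unresolvable placements: same or complementary descendant tip set
  equivalences <- lapply(supp, function(e) {
    s1 <- tips[[e]]
    alt <- which(vapply(seq_len(E), function(f) {
      f != e && (identical(tips[[f]], s1) ||
                 identical(tips[[f]], sort(setdiff(seq_len(n), s1))))
    }, logical(1)))
    alt
  })
  names(equivalences) <- as.character(supp)

  structure(
    list(
      tree = tree, traits = stats::setNames(y, tree$tip.label),
      shift_edges = as.integer(supp), beta = unname(beta),
      tip_effect = tip_effect,
      theta0 = unname(theta0), alpha = best$alpha, sigma2 = best$sigma2,
      loglik = best$loglik, score = best$score, criterion = criterion,
      n = n, fitted = fitted, residuals = y - fitted,
      equivalences = equivalences, support = NULL,
      settings = list(alpha_grid = alpha_grid, nlambda = nlambda,
                      max_shifts = max_shifts)
    ),
    class = "ou_shift_fit"
  )
}

#' @export
print.ou_shift_fit <- function(x, ...) {
  cat("OU optimum-shift model\n")
  cat(sprintf("  %d tips, criterion %s, alpha = %.4g, sigma2 = %.4g\n",
              x$n, x$criterion, x$alpha, x$sigma2))
  cat(sprintf("  logLik = %.3f, score = %.3f, root optimum = %.4g\n",
              x$loglik, x$score, x$theta0))
  if (!length(x$shift_edges)) {
    cat("  no shifts selected\n")
  } else {
    tab <- data.frame(edge = x$shift_edges,
                      tip_effect = round(x$tip_effect, 4))
    if (!is.null(x$support)) tab$support <- x$support
    print(tab, row.names = FALSE)
    eq <- x$equivalences[lengths(x$equivalences) > 0]
    if (length(eq)) {
      cat("  equivalent placements:",
          paste(sprintf("%s ~ {%s}", names(eq),
                        vapply(eq, paste, "", collapse = ",")),
                collapse = "; "), "\n")
    }
  }
  invisible(x)
}

#' @export
summary.ou_shift_fit <- function(object, ...) {
  tips <- edge_tip_sets(object$tree)
  shifts <- if (length(object$shift_edges)) {
    data.frame(
      edge = object$shift_edges,
      offset = object$beta,
      tip_effect = object$tip_effect,
      n_descendant_tips = lengths(tips[object$shift_edges]),
      clade = vapply(tips[object$shift_edges], function(s) {
        paste(object$tree$tip.label[s][seq_len(min(3, length(s)))],
              collapse = ",")
      }, ""),
      support = if (is.null(object$support)) NA_real_ else object$support
    )
  } else {
    data.frame(edge = integer(), offset = numeric(),
               tip_effect = numeric(),
               n_descendant_tips = integer(), clade = character(),
               support = numeric())
  }
  out <- list(shifts = shifts, alpha = object$alpha,
              sigma2 = object$sigma2, theta0 = object$theta0,
              loglik = object$loglik, score = object$score,
              criterion = object$criterion, n = object$n)
  class(out) <- "summary.ou_shift_fit"
  out
}

#' @export
print.summary.ou_shift_fit <- function(x, ...) {
  cat(sprintf(
    "OU shift model: %d shifts (%s), alpha %.4g, sigma2 %.4g, theta0 %.4g\n",
    nrow(x$shifts), x$criterion, x$alpha, x$sigma2, x$theta0))
  if (nrow(x$shifts)) print(x$shifts, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ou_shift_fit <- function(object, ...) {
  c(theta0 = object$theta0,
    stats::setNames(object$beta,
                    paste0("edge", object$shift_edges)))
}

#' @export
logLik.ou_shift_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$shift_edges) + 3,
            nobs = object$n, class = "logLik")
}

#' @export
fitted.ou_shift_fit <- function(object, ...) object$fitted

#' @export
residuals.ou_shift_fit <- function(object, ...) object$residuals

#' Simulate tip traits from a fitted shift model
#'
#' Draws multivariate-normal tip traits around the fitted expectations
#' under the fitted OU covariance.
#'
#' @param object An `ou_shift_fit`.
#' @param nsim Number of replicate trait vectors.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A tips-by-`nsim` matrix.
#' @export
simulate.ou_shift_fit <- function(object, nsim = 1, seed = NULL, ...) {
  U <- chol(ou_covariance(object$tree, object$alpha, object$sigma2))
  draw <- function() {
    z <- matrix(stats::rnorm(object$n * nsim), object$n, nsim)
    sweep(crossprod(U, z), 1L, object$fitted, `+`)
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  rownames(out) <- object$tree$tip.label
  out
}

#' Plot a fitted shift model on its tree
#'
#' @param x An `ou_shift_fit`.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.ou_shift_fit <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  if (length(x$shift_edges)) {
    lab <- sprintf("%+.2f%s", x$tip_effect,
                   if (is.null(x$support)) "" else
                     sprintf(" (%.2f)", x$support))
    ape::edgelabels(lab, x$shift_edges, frame = "rect", bg = "gold")
  }
  invisible(x)
}

#' Residual-bootstrap support for detected shifts
#'
#' Assigns a confidence level to each detected shift by non-parametric
#' bootstrap of phylogenetically uncorrelated residuals: the fit's
#' residuals are whitened through the Cholesky factor of the fitted OU
#' covariance (making them uncorrelated and standardised), resampled with
#' replacement, coloured back through the covariance and added to the
#' fitted tip expectations; [detect_shifts()] is rerun on each replicate
#' with the original settings, and a shift's support is the fraction of
#' replicates in which its branch (or an unresolvable equivalent
#' placement) is selected.
#'
#' @param fit An `ou_shift_fit`.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return The fit with `support` filled in (a numeric vector aligned
#'   with `shift_edges`); the per-branch selection frequencies over all
#'   branches are attached as attribute `edge_frequency`.
#' @export
bootstrap_support <- function(fit, n_boot = 100, seed = 1) {
  stopifnot(inherits(fit, "ou_shift_fit"))
  if (n_boot < 2) stop("`n_boot` must be >= 2", call. = FALSE)
  tree <- fit$tree
  n <- fit$n
  E <- nrow(tree$edge)
  U <- chol(ou_covariance(tree, fit$alpha, fit$sigma2))
  z <- backsolve(U, fit$residuals, transpose = TRUE) # whitened residuals
  tips <- edge_tip_sets(tree)
  comp <- function(s) sort(setdiff(seq_len(n), s))

  edge_hits <- numeric(E)
  for (r in seq_len(n_boot)) {
    z_star <- with_seed(seed + r, sample(z, n, replace = TRUE))
    y_star <- fit$fitted + drop(crossprod(U, z_star))
    names(y_star) <- tree$tip.label
    ref <- detect_shifts(tree, y_star, criterion = fit$criterion,
                         alpha_grid = fit$settings$alpha_grid,
                         nlambda = fit$settings$nlambda,
                         max_shifts = fit$settings$max_shifts)
    edge_hits[ref$shift_edges] <- edge_hits[ref$shift_edges] + 1
  }
  freq <- edge_hits / n_boot
  support <- vapply(fit$shift_edges, function(e) {
    eqv <- which(vapply(seq_len(E), function(f) {
      identical(tips[[f]], tips[[e]]) ||
        identical(tips[[f]], comp(tips[[e]]))
    }, logical(1)))
    min(1, sum(freq[eqv]))
  }, numeric(1))
  fit$support <- support
  attr(fit$support, "edge_frequency") <- freq
  fit
}
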