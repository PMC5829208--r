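# Tree geometry helpers shared by the OU simulator and the shift detector.
# All times are measured from the root; an ultrametric tree of height T has
# every tip at time T.

tree_times <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  n_tip <- length(tree$tip.label)
  list(
    depth = depth,
    height = max(depth[seq_len(n_tip)]),
    t_start = depth[tree$edge[, 1L]],
    t_end = depth[tree$edge[, 2L]],
    n_tip = n_tip
  )
}

# Tip indices descending from each edge (child clade), as a list over
# tree$edge rows.
edge_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, tree$edge[, 2L], type = "tips")
  lapply(desc, function(d) sort(as.integer(d[d <= n_tip])))
}

assert_ultrametric <- function(tree, rel_tol = 1e-6) {
  tt <- tree_times(tree)
  tip_depth <- tt$depth[seq_len(tt$n_tip)]
  dev <- abs(tip_depth - tt$height)
  if (max(dev) > rel_tol * tt$height) {
    worst <- which.max(dev)
    stop(sprintf(
      "tree is not ultrametric: tip '%s' deviates by %.3g from height %.6g (max allowed %.3g)",
      tree$tip.label[worst], max(dev), tt$height, rel_tol * tt$height
    ), call. = FALSE)
  }
  invisible(tt)
}

#' Rescale an ultrametric tree to unit height
#'
#' Divides every branch length by the root-to-tip height so the tree has
#' height exactly 1 (the scale on which selection strength `alpha` and
#' diffusion variance `sigma2` are expressed throughout the shift
#' analysis).  The input must already be ultrametric to within
#' `tol * height`; dating/smoothing is upstream of this package.
#'
#' @param tree An ultrametric `phylo` tree.
#' @param tol Relative tolerance on tip-height agreement.
#' @return The tree with height 1.
#' @export
scale_tree <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  tt <- assert_ultrametric(tree, rel_tol = tol)
  tree$edge.length <- tree$edge.length / tt$height
  tree
}

#' Ornstein-Uhlenbeck covariance matrix over tips
#'
#' For an ultrametric tree and tips i, j with shared root-to-MRCA time
#' t_ij and patristic distance d_ij, the OU covariance (root held at the
#' optimum) is
#' \deqn{V_{ij} = \frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
#'       (1 - e^{-2\alpha t_{ij}}),}
#' which degrades to the Brownian-motion covariance `sigma2 * t_ij` as
#' `alpha -> 0`.
#'
#' @param tree Ultrametric `phylo` tree.
#' @param alpha Selection strength, >= 0.
#' @param sigma2 Diffusion variance.
#' @return A symmetric positive-definite tips-by-tips matrix.
#' @export
ou_covariance <- function(tree, alpha, sigma2 = 1) {
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  t_shared <- ape::vcv(tree)
  if (alpha < 1e-12) return(sigma2 * t_shared)
  T_h <- max(diag(t_shared))
  d <- 2 * (T_h - t_shared) # patristic distance on an ultrametric tree
  sigma2 / (2 * alpha) * exp(-alpha * d) * (1 - exp(-2 * alpha * t_shared))
}

#' OU expectation design matrix over branches
#'
#' Column `b` gives, for every tip descending from branch `b`, the
#' attenuated effect of an optimum change on that branch:
#' \deqn{x_{ib} = e^{-\alpha (T - t_{end}(b))} - e^{-\alpha (T - t_{start}(b))}}
#' and 0 for non-descendants.  On an ultrametric tree the entry is
#' constant within the descendant clade, so each column is a scaled clade
#' indicator; as `alpha` grows, the entry for a terminal branch approaches
#' 1 (the shift expresses its full offset), while ancient optima are
#' forgotten.  At `alpha = 0` the matrix is identically zero: in the
#' Brownian limit optima have no effect.
#'
#' @param tree Ultrametric `phylo` tree.
#' @param alpha Selection strength, >= 0.
#' @return A tips-by-branches matrix, columns ordered like `tree$edge`
#'   rows.
#' @export
ou_design <- function(tree, alpha) {
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  tt <- tree_times(tree)
  w <- exp(-alpha * (tt$height - tt$t_end)) -
    exp(-alpha * (tt$height - tt$t_start))
  tips <- edge_tip_sets(tree)
  X <- matrix(0, nrow = tt$n_tip, ncol = nrow(tree$edge))
  for (e in seq_along(tips)) X[tips[[e]], e] <- w[e]
  rownames(X) <- tree$tip.label
  X
}

#' Simulate tip traits under an OU model with optimum shifts
#'
#' Draws one multivariate-normal realisation of tip traits under the OU
#' process parameterised by an [ou_sim_config()].  The root sits at the
#' base optimum `theta0`; each shift adds a persistent offset to the
#' optimum of its branch and all descendant lineages, so tip `i`'s
#' expectation is
#' \deqn{E[y_i] = \theta_0 + \sum_{s \; ancestral} \Delta_s
#'       (1 - e^{-\alpha (T - t_{start}(s))}).}
#'
#' @param config An [ou_sim_config()].
#' @return Named numeric vector of tip traits, with attribute
#'   `expectation` (the exact OU means).
#' @export
simulate_ou_traits <- function(config) {
  stopifnot(inherits(config, "ou_sim_config"))
  tree <- config$tree
  tt <- assert_ultrametric(tree, rel_tol = 1e-9)
  mu <- rep(config$theta0, tt$n_tip)
  names(mu) <- tree$tip.label
  if (length(config$shift_edges)) {
    tips <- edge_tip_sets(tree)
    for (i in seq_along(config$shift_edges)) {
      e <- config$shift_edges[i]
      eff <- config$offsets[i] *
        (1 - exp(-config$alpha * (tt$height - tt$t_start[e])))
      mu[tips[[e]]] <- mu[tips[[e]]] + eff
    }
  }
  V <- ou_covariance(tree, config$alpha, config$sigma2)
  U <- chol(V)
  y <- with_seed(config$seed,
                 drop(mu + crossprod(U, stats::rnorm(tt$n_tip))))
  names(y) <- tree$tip.label
  attr(y, "expectation") <- mu
  y
}
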