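# Independent oracles and small fixture builders used across the suite.

# Balanced ultrametric tree of unit height.
balanced_tree <- function(n) {
  scale_tree(ape::compute.brlen(ape::stree(n, "balanced"), 1))
}

# Exact chromatic number by backtracking with symmetry breaking (vertex v
# may only open one new color).  Practical for graphs of <= ~14 vertices.
chromatic_number <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0L)
  color <- integer(n)
  feasible <- function(v, k) {
    if (v > n) return(TRUE)
    max_used <- if (v == 1L) 0L else max(color[seq_len(v - 1L)])
    for (cc in seq_len(min(max_used + 1L, k))) {
      if (!any(adj[v, ] & color == cc)) {
        color[v] <<- cc
        if (feasible(v + 1L, k)) return(TRUE)
        color[v] <<- 0L
      }
    }
    FALSE
  }
  k <- 1L
  repeat {
    color[] <- 0L
    if (feasible(1L, k)) return(k)
    k <- k + 1L
  }
}

# Direct maximisation of the 3-component Gaussian mixture log-likelihood
# (softmax weights, raw means, log standard deviations) by multi-start
# BFGS; independent of the EM path it cross-checks.
gmm3_loglik <- function(par, x) {
  w <- exp(c(0, par[1:2]))
  w <- w / sum(w)
  mu <- par[3:5]
  sig <- exp(par[6:8])
  sum(log(w[1] * stats::dnorm(x, mu[1], sig[1]) +
          w[2] * stats::dnorm(x, mu[2], sig[2]) +
          w[3] * stats::dnorm(x, mu[3], sig[3])))
}

gmm3_direct_ml <- function(x) {
  starts <- list(
    c(0, 0, 0.25, 0.50, 0.75, log(0.05), log(0.05), log(0.05)),
    c(0, 0, 0.20, 0.50, 0.80, log(0.08), log(0.08), log(0.08)),
    c(log(2), 0, 0.30, 0.50, 0.70, log(0.04), log(0.06), log(0.04))
  )
  best <- -Inf
  for (s in starts) {
    o <- try(stats::optim(s, function(p) -gmm3_loglik(p, x),
                          method = "BFGS",
                          control = list(maxit = 5000, reltol = 1e-14)),
             silent = TRUE)
    if (!inherits(o, "try-error")) best <- max(best, -o$value)
  }
  best
}

# Draw from a known 3-component mixture (for EM fixtures).
rgmm3 <- function(n, w, mu, sig, seed) {
  set.seed(seed)
  k <- sample.int(3L, n, replace = TRUE, prob = w)
  stats::rnorm(n, mu[k], sig[k])
}

# Build a contig_alignment by hand from phased read groups: `groups` is a
# list of lists(n, bases) where bases is a named vector pos -> base; each
# group contributes n identical reads covering [start, end].
phased_alignment <- function(groups, start = 1L, end = 100L,
                             contig_length = 100L) {
  reads <- list()
  calls <- list()
  idx <- 0L
  for (g in groups) {
    for (i in seq_len(g$n)) {
      idx <- idx + 1L
      id <- sprintf("r%03d", idx)
      reads[[idx]] <- data.frame(read_id = id, start = start, end = end,
                                 stringsAsFactors = FALSE)
      if (length(g$bases)) {
        calls[[length(calls) + 1L]] <- data.frame(
          read_id = id, pos = as.integer(names(g$bases)),
          base = unname(g$bases), stringsAsFactors = FALSE)
      }
    }
  }
  contig_alignment(
    contig = "c1", contig_length = contig_length,
    reads = do.call(rbind, reads),
    calls = if (length(calls)) do.call(rbind, calls) else
      data.frame(read_id = character(), pos = integer(),
                 base = character(), stringsAsFactors = FALSE)
  )
}

# Whether a fitted shift set matches the true edge up to the unresolvable
# same-or-complementary-tip-set equivalence.
shift_recovered <- function(fit, e_true, tree = fit$tree) {
  tips <- ploidyshift:::edge_tip_sets(tree)
  n <- length(tree$tip.label)
  se <- fit$shift_edges
  length(se) >= 1 && all(vapply(se, function(e) {
    identical(tips[[e]], tips[[e_true]]) ||
      identical(tips[[e]], sort(setdiff(seq_len(n), tips[[e_true]])))
  }, logical(1)))
}

# A ratio_mixture shell with prescribed weights, for arithmetic tests of
# peak_ratio.
mixture_shell <- function(lambda, mu = c(0.25, 0.5, 0.75), sigma = 0.05) {
  structure(list(mu = mu, sigma = rep_len(sigma, 3), lambda = lambda,
                 loglik = 0, n = 100L, converged = TRUE,
                 degenerate = FALSE, fixed_means = FALSE),
            class = "ratio_mixture")
}
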