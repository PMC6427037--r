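# Posterior-predictive checks for the zero-inflated bleaching fit.
#
# A plain mean-based Bayesian P-value is uninformative when half the
# observations are zeros, so the check is split: (i) fit to the mean of
# the non-zero values, and (ii) a separate comparison of the zero
# pattern - how often replicates reproduce an observed zero, and how
# much bleaching they predict when they overestimate it.

#' Simulate replicate datasets from the posterior
#'
#' For each of `n_rep` posterior draws (taken evenly across the pooled
#' chains), simulates a full replicate dataset from the fitted
#' observation model, conditioning on that draw's site effects (a
#' "mixed" predictive replicate, matching what a JAGS monitor of
#' replicated data would produce).
#'
#' @param draws a `posterior_draws`.
#' @param n_rep number of replicate datasets.
#' @param seed RNG seed for the replicate simulation.
#' @return integer matrix `n_rep x N`.
#' @export
simulate_replicates <- function(draws, n_rep = 500, seed = 1L) {
  stopifnot(inherits(draws, "posterior_draws"))
  cols <- c("b0", paste0("gamma[", seq_along(draws$covariate_names), "]"),
            "k", paste0("a[", seq_len(draws$data$S), "]"))
  m <- draws_matrix(draws, cols)
  pick <- unique(round(seq(1, nrow(m), length.out = min(n_rep, nrow(m)))))
  Z <- draws$data$Z
  site <- draws$data$site
  J <- ncol(Z)
  with_seed(seed, {
    t(vapply(pick, function(r) {
      b0 <- m[r, 1L]
      gam <- m[r, 1L + seq_len(J)]
      k <- m[r, J + 2L]
      a <- m[r, (J + 2L) + seq_len(draws$data$S)]
      p <- exp(b0 + drop(Z %*% gam) + a[site])
      as.numeric(stats::rnbinom(length(p), mu = p, size = k))
    }, numeric(draws$data$N)))
  })
}

#' Posterior-predictive checks for the bleaching model
#'
#' Computes both components at once: the non-zero Bayesian P-value (the
#' fraction of replicates whose mean over non-zero values exceeds the
#' observed mean over non-zero values) and the zero-pattern statistics
#' (fraction of replicate values that are zero at observed-zero
#' positions; mean and sd of replicate bleaching at those positions when
#' the replicate overestimates, i.e. is positive).
#'
#' @param draws a `posterior_draws`.
#' @param n_rep replicate datasets to simulate.
#' @param seed RNG seed (fixed seed => bit-reproducible results).
#' @return object of class `ppc_result`: list with `bayes_p_nonzero`,
#'   `zero_match_rate`, `overestimate_mean_bleaching`,
#'   `overestimate_sd`, `n_rep`.
#' @export
posterior_predictive_check <- function(draws, n_rep = 500, seed = 1L) {
  rep <- simulate_replicates(draws, n_rep, seed)
  o <- draws$data$o
  res <- list(bayes_p_nonzero = NA_real_, zero_match_rate = NA_real_,
              overestimate_mean_bleaching = NA_real_,
              overestimate_sd = NA_real_, n_rep = nrow(rep))

  if (any(o > 0)) {
    obs_mean <- mean(o[o > 0])
    rep_means <- apply(rep, 1, function(r) if (any(r > 0))
      mean(r[r > 0]) else 0)
    res$bayes_p_nonzero <- mean(rep_means > obs_mean)
  } else {
    warning("no non-zero observations: non-zero Bayesian P-value undefined")
  }

  zidx <- which(o == 0)
  if (length(zidx)) {
    at_zero <- rep[, zidx, drop = FALSE]
    res$zero_match_rate <- mean(at_zero == 0)
    pos <- at_zero[at_zero > 0]
    if (length(pos)) {
      res$overestimate_mean_bleaching <- mean(pos)
      res$overestimate_sd <- stats::sd(pos)
    }
  }
  structure(res, class = "ppc_result")
}

#' @rdname posterior_predictive_check
#' @export
ppc_nonzero <- function(draws, n_rep = 500, seed = 1L) {
  posterior_predictive_check(draws, n_rep, seed)$bayes_p_nonzero
}

#' @rdname posterior_predictive_check
#' @export
ppc_zero <- function(draws, n_rep = 500, seed = 1L) {
  r <- posterior_predictive_check(draws, n_rep, seed)
  r[c("zero_match_rate", "overestimate_mean_bleaching", "overestimate_sd")]
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("<ppc_result> non-zero Bayesian P = ",
      formatC(x$bayes_p_nonzero, digits = 3, format = "f"),
      "; zero match rate = ",
      formatC(x$zero_match_rate, digits = 3, format = "f"),
      "; overestimate = ",
      formatC(x$overestimate_mean_bleaching, digits = 2, format = "f"),
      "% (sd ", formatC(x$overestimate_sd, digits = 2, format = "f"),
      "%), ", x$n_rep, " replicates\n", sep = "")
  invisible(x)
}
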