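# Shared input checks for the Bayesian SNP model.
.check_bayes_inputs <- function(y, W, X, weights, prior, sigma2_g,
                                sigma2_e) {
  stopifnot(is.matrix(W), is.numeric(W), length(y) == nrow(W))
  if (is.null(X)) X <- matrix(1, length(y), 1)
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric design matrix")
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(nrow(X) == length(y), length(weights) == length(y),
            all(weights > 0), inherits(prior, "mixture_prior"),
            sigma2_g > 0, sigma2_e > 0)
  list(X = X, weights = weights,
       sigma2k = prior$variance_fractions * sigma2_g)
}

#' EM warm start for the mixture-prior SNP model
#'
#' Iterative conditional-expectation sweeps: for each SNP, component
#' responsibilities are computed from the normal-mixture marginal
#' likelihood of its weighted association with the current residual, the
#' effect is set to its responsibility-weighted conditional posterior
#' mean, and the residual updated in place; fixed effects are re-solved
#' by weighted least squares each sweep. Stops when the largest absolute
#' effect change falls below `tol`.
#'
#' @param y response (DRP) vector.
#' @param W standardized genotype matrix (animals x SNPs).
#' @param X fixed-effect design matrix (default: intercept).
#' @param prior a [mixture_prior()].
#' @param weights per-record weights (inverse residual-variance
#'   multipliers; default 1).
#' @param sigma2_g,sigma2_e additive genetic and residual variances.
#' @param tol convergence tolerance on the max absolute effect change
#'   (default 1e-7).
#' @param max_iter sweep cap (default 2200).
#' @return list: `effects`, `responsibilities` (SNPs x 4), `fixed_effects`,
#'   `iterations`, `converged`.
#' @export
em_warm_start <- function(y, W, X = NULL, prior = mixture_prior(),
                          weights = NULL, sigma2_g = 1, sigma2_e = 1,
                          tol = 1e-7, max_iter = 2200L) {
  ck <- .check_bayes_inputs(y, W, X, weights, prior, sigma2_g, sigma2_e)
  if (!is.finite(tol)) {  # tol = Inf contract: exactly one sweep
    max_iter <- 1L
    tol <- 0
  }
  if (tol < 0) stop("tol must be positive")
  fit <- .bayesr_em_cpp(y, W, ck$X, ck$weights, prior$proportions,
                        ck$sigma2k, sigma2_e, tol, as.integer(max_iter))
  list(effects = as.vector(fit$v), responsibilities = fit$resp,
       fixed_effects = as.vector(fit$b), iterations = fit$iterations,
       converged = fit$converged)
}

#' One Gibbs chain of the four-component BayesR model
#'
#' Single-site Gibbs sampling: each iteration samples the fixed effects
#' from their weighted least-squares conditional, then visits SNPs in a
#' freshly randomized order, sampling each SNP's mixture-component
#' indicator from its 4-way conditional posterior (the null component
#' forcing a zero effect) and, for non-null draws, the effect from its
#' conditional normal; the residual is maintained incrementally with the
#' DRP weights as inverse residual-variance multipliers. Outputs are
#' post-burn-in averages; component probabilities are Rao-Blackwellized.
#'
#' @inheritParams em_warm_start
#' @param iters,burnin total and discarded iteration counts.
#' @param seed integer seed (chains with equal seeds are bit-identical).
#' @param start optional starting effect vector (e.g. the EM warm start).
#' @param sample_sigma2e sample the residual variance from its
#'   scaled-inverse-chi-square conditional (default `FALSE`: fixed).
#' @return list: `snp_effects` (posterior means), `component_post`
#'   (SNPs x 4), `fixed_effects`, `sigma2_e`.
#' @export
run_gibbs_chain <- function(y, W, X = NULL, prior = mixture_prior(),
                            weights = NULL, sigma2_g = 1, sigma2_e = 1,
                            iters = 10000L, burnin = 2000L, seed = 1L,
                            start = NULL, sample_sigma2e = FALSE) {
  if (iters <= burnin || burnin < 0)
    stop("need iters > burnin >= 0")
  ck <- .check_bayes_inputs(y, W, X, weights, prior, sigma2_g, sigma2_e)
  v0 <- if (is.null(start)) numeric(ncol(W)) else start
  stopifnot(length(v0) == ncol(W))
  set.seed(seed)
  fit <- .bayesr_gibbs_cpp(y, W, ck$X, ck$weights, prior$proportions,
                           ck$sigma2k, sigma2_e, as.integer(iters),
                           as.integer(burnin), v0, sample_sigma2e,
                           4, sigma2_e)
  list(snp_effects = as.vector(fit$v_hat), component_post = fit$comp_post,
       fixed_effects = as.vector(fit$b_hat), sigma2_e = fit$sigma2_e)
}

#' Fit the mixture-prior Bayesian SNP model (EM warm start + chains)
#'
#' Runs [em_warm_start()] once, then launches `n_chains` Gibbs chains
#' from the warm start with seeds `base_seed + 1, ..., base_seed +
#' n_chains`, and averages posterior-mean effects and component
#' probabilities across chains. GEBV for any animal set are `W v_hat`
#' (fixed effects excluded).
#'
#' @inheritParams run_gibbs_chain
#' @param n_chains number of averaged chains (default 5).
#' @param base_seed chain seeds are derived from this.
#' @param em_tol,em_max_iter warm-start controls.
#' @return object of class `bayesr_fit`: `snp_effects`, `component_post`,
#'   `fixed_effects`, `chain_count`, `iterations` (list), `seeds`,
#'   `em` (warm-start summary).
#' @export
run_embayesr <- function(y, W, X = NULL, prior = mixture_prior(),
                         weights = NULL, sigma2_g = 1, sigma2_e = 1,
                         iters = 10000L, burnin = 2000L, n_chains = 5L,
                         base_seed = 1L, em_tol = 1e-7,
                         em_max_iter = 2200L, sample_sigma2e = FALSE) {
  em <- em_warm_start(y, W, X, prior, weights, sigma2_g, sigma2_e,
                      tol = em_tol, max_iter = em_max_iter)
  seeds <- base_seed + seq_len(n_chains)
  v_acc <- numeric(ncol(W))
  cp_acc <- matrix(0, ncol(W), 4)
  b_acc <- NULL
  chain_v <- matrix(NA_real_, ncol(W), n_chains)
  for (ci in seq_len(n_chains)) {
    ch <- tryCatch(
      run_gibbs_chain(y, W, X, prior, weights, sigma2_g, sigma2_e,
                      iters = iters, burnin = burnin, seed = seeds[ci],
                      start = em$effects, sample_sigma2e = sample_sigma2e),
      error = function(e) stop("chain ", ci, ": ", conditionMessage(e)))
    v_acc <- v_acc + ch$snp_effects
    cp_acc <- cp_acc + ch$component_post
    b_acc <- if (is.null(b_acc)) ch$fixed_effects else
      b_acc + ch$fixed_effects
    chain_v[, ci] <- ch$snp_effects
  }
  structure(list(snp_effects = v_acc / n_chains,
                 component_post = cp_acc / n_chains,
                 fixed_effects = b_acc / n_chains,
                 chain_count = n_chains,
                 chain_effects = chain_v,
                 iterations = list(em_iters = em$iterations,
                                   gibbs_iters = iters, burnin = burnin),
                 seeds = seeds, em = em[c("iterations", "converged")]),
            class = "bayesr_fit")
}

#' @export
print.bayesr_fit <- function(x, ...) {
  cat(sprintf(paste0("bayesr_fit: %d SNPs, %d chains x %d iterations ",
                     "(burn-in %d), EM %d sweeps\n"),
              length(x$snp_effects), x$chain_count,
              x$iterations$gibbs_iters, x$iterations$burnin,
              x$iterations$em_iters))
  cat(sprintf("mean null-component probability: %.3f\n",
              mean(x$component_post[, 1])))
  invisible(x)
}
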