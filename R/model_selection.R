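#' Fixed-effects group Bayes factor from cross-validated evidence
#'
#' Treats participants as fixed effects: the group log Bayes factor is the
#' sum over participants of per-participant log-evidence differences,
#' reported in base 10.
#'
#' @param ev evidence matrix from [cv_logevidence()] (participants x
#'   models, natural-log units).
#' @param model_a,model_b column names or indices to compare (a vs b).
#' @return log10 Bayes factor in favour of `model_a`.
#' @examples
#' ev <- cbind(a = c(1, 2, 3), b = c(0, 0, 0))
#' fixed_effects_log10_bf(ev, "a", "b")  # 6/log(10)
#' @export
fixed_effects_log10_bf <- function(ev, model_a = 1, model_b = 2) {
  a <- ev[, model_a]; b <- ev[, model_b]
  if (anyNA(a) || anyNA(b)) stop("evidence missing for some participant")
  sum(a - b) / log(10)
}

#' Random-effects Bayesian model selection
#'
#' Variational inference on population model frequencies: with a
#' Dirichlet(alpha0) prior over frequencies, iterate the posterior model
#' assignments `u_nk proportional to exp(ev_nk + psi(alpha_k) - psi(sum alpha))`
#' and the concentration update `alpha_k = alpha0_k + sum_n u_nk` until the
#' concentrations move by less than `tol`. Exceedance probabilities (the
#' posterior probability that model k is the most frequent) are estimated
#' by Dirichlet Monte-Carlo.
#'
#' @param ev evidence matrix (participants x models), natural-log units.
#' @param prior_alpha Dirichlet prior concentration (default 1 per model).
#' @param tol convergence tolerance on the concentrations (default 1e-6).
#' @param max_iter iteration cap (default 10000).
#' @param n_samples Monte-Carlo draws for the exceedance step.
#' @param seed seed for the exceedance sampler.
#' @return list of class `bms_result`: `alpha`, `expected_freq`, `p_exc`,
#'   `u` (posterior assignments), `n_iter`, `converged`.
#' @export
random_effects_bms <- function(ev, prior_alpha = 1, tol = 1e-6,
                               max_iter = 10000L, n_samples = 1e6, seed = 1L) {
  ev <- as.matrix(ev)
  if (any(!is.finite(ev))) stop("non-finite model evidence")
  n <- nrow(ev); K <- ncol(ev)
  if (n < 2 || K < 2) stop("need >= 2 participants and >= 2 models")
  alpha0 <- rep_len(prior_alpha, K)
  alpha <- alpha0
  u <- matrix(NA_real_, n, K, dimnames = dimnames(ev))
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    lu <- sweep(ev, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)            # log-sum-exp stabilisation
    u <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new; converged <- TRUE; break
    }
    alpha <- alpha_new
  }
  names(alpha) <- colnames(ev)
  structure(list(alpha = alpha, expected_freq = alpha / sum(alpha),
                 p_exc = exceedance(alpha, n_samples = n_samples, seed = seed),
                 u = u, n_iter = it, converged = converged),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects BMS (", x$n_iter, " iterations",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  print(round(rbind(alpha = x$alpha, expected_freq = x$expected_freq,
                    p_exc = x$p_exc), 4))
  invisible(x)
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Monte-Carlo frequency with which each component is the largest in a
#' draw from Dirichlet(alpha). For K = 2 this equals the regularised
#' incomplete beta `1 - I_0.5(alpha_1, alpha_2)` (see tests).
#'
#' @param alpha Dirichlet concentration vector.
#' @param n_samples number of draws (default 1e6).
#' @param seed integer seed.
#' @return probability vector summing to 1.
#' @export
exceedance <- function(alpha, n_samples = 1e6, seed = 1L) {
  set.seed(as.integer(seed))
  K <- length(alpha)
  g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              ncol = K)
  win <- max.col(g, ties.method = "random")
  p <- tabulate(win, nbins = K) / n_samples
  names(p) <- names(alpha)
  p
}
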