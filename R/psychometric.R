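#' Specify a probit decision model
#'
#' The family extends the base psychometric model
#' `P(anger) = Phi(w*x + b)` with association terms: a *bias* term for
#' association k adds `beta_k * a_k` to the decision variable (a criterion
#' shift, maximal at neutral stimuli); a *sensitivity* term adds
#' `gamma_k * c_k * x` with congruence `c_k = a_k * sign(x)` (zero at
#' neutral, maximal at intermediate evidence). A given association may
#' enter as bias or sensitivity, not both.
#'
#' @param name model name; the built-ins "base", "bias", "sensitivity" and
#'   "full" set the term lists for you ("bias"/"sensitivity" take the
#'   association in `terms`; "full" is the three-way additive bias model).
#' @param bias_terms,sensitivity_terms character subsets of
#'   c("shared","idio","induced") for custom models.
#' @param terms association used by the "bias"/"sensitivity" shortcuts
#'   (default "shared").
#' @return list of class `psych_model`.
#' @examples
#' psych_model("bias", terms = "shared")
#' psych_model("full")
#' @export
psych_model <- function(name = "base", bias_terms = character(),
                        sensitivity_terms = character(), terms = "shared") {
  known <- c("shared", "idio", "induced")
  if (name == "bias" && !length(bias_terms)) bias_terms <- terms
  if (name == "sensitivity" && !length(sensitivity_terms)) sensitivity_terms <- terms
  if (name == "full" && !length(bias_terms)) bias_terms <- known
  stopifnot(all(bias_terms %in% known), all(sensitivity_terms %in% known))
  if (length(intersect(bias_terms, sensitivity_terms)))
    stop("a term may not appear as both bias and sensitivity")
  structure(list(name = name, bias_terms = bias_terms,
                 sensitivity_terms = sensitivity_terms, link = "probit"),
            class = "psych_model")
}

#' @export
print.psych_model <- function(x, ...) {
  cat("Probit decision model '", x$name, "'", sep = "")
  if (length(x$bias_terms)) cat("; bias:", paste(x$bias_terms, collapse = ","))
  if (length(x$sensitivity_terms))
    cat("; sensitivity:", paste(x$sensitivity_terms, collapse = ","))
  cat("\n")
  invisible(x)
}

# Merge trials with association labels into the covariate frame the model
# family consumes: evidence_x, response, and +-1 columns a_shared/a_idio/
# a_induced. Neutral-evidence congruence is 0 by the sign(x) factor later.
#' Prepare the model frame for fitting
#'
#' @param trials trial table (test phase is selected; rows without a
#'   response are dropped).
#' @param labels association labels (participant, face, *_label); omit if
#'   the trial table already carries `a_shared`/`a_idio`/`a_induced`.
#' @return data.frame with participant, evidence_x, response, y (1 =
#'   anger), a_shared, a_idio, a_induced, block, face.
#' @export
model_frame <- function(trials, labels = NULL) {
  tt <- trials[trials$phase == "test" & !is.na(trials$response) &
                 trials$response != "none", , drop = FALSE]
  if (!is.null(labels)) {
    i <- match(paste(tt$participant, tt$face),
               paste(labels$participant, labels$face))
    if (anyNA(i)) stop("labels missing for some participant x face cells")
    tt$a_shared <- label_to_num(labels$shared_label[i])
    tt$a_idio <- label_to_num(labels$idio_label[i])
    tt$a_induced <- label_to_num(labels$induced_label[i])
  }
  tt$y <- as.integer(tt$response == "anger")
  tt
}

# Design matrix of the linear-in-parameters probit family:
# columns x, 1, a_k (bias), c_k*x (sensitivity).
.model_matrix <- function(spec, data) {
  terms <- union(spec$bias_terms, spec$sensitivity_terms)
  need <- if (length(terms)) paste0("a_", terms) else character()
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing label column(s) for active model terms: ",
         paste(missing_cols, collapse = ", "))
  X <- cbind(x = data$evidence_x, b = 1)
  for (k in spec$bias_terms)
    X <- cbind(X, setNames(data.frame(data[[paste0("a_", k)]]),
                           paste0("beta_", k)))
  sx <- sign(data$evidence_x)
  for (k in spec$sensitivity_terms)
    X <- cbind(X, setNames(data.frame(data[[paste0("a_", k)]] * sx * data$evidence_x),
                           paste0("gamma_", k)))
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing label for an active model term")
  X
}

.model_bounds <- function(spec) {
  nb <- length(spec$bias_terms); ns <- length(spec$sensitivity_terms)
  list(lower = c(0, -5, rep(-5, nb), rep(-5, ns)),
       upper = c(20, 5, rep(5, nb), rep(5, ns)))
}

#' Probability of an "anger" response under a model
#'
#' `P = Phi((w + sum_k gamma_k*c_k)*x + b + sum_k beta_k*a_k)` with
#' congruence `c_k = a_k*sign(x)`; probabilities are clipped to
#' [1e-9, 1-1e-9] for likelihood use.
#'
#' @param spec a [psych_model()].
#' @param params named list/vector with `w`, `b`, and `beta_<term>` /
#'   `gamma_<term>` entries for the active terms.
#' @param data covariate frame from [model_frame()] (needs evidence_x and
#'   the active `a_*` columns).
#' @return numeric vector of probabilities.
#' @examples
#' d <- data.frame(evidence_x = 0.5)
#' p_anger(psych_model("base"), list(w = 1, b = 0.2), d)  # Phi(0.7)
#' @export
p_anger <- function(spec, params, data) {
  params <- unlist(params)
  X <- .model_matrix(spec, data)
  theta <- params[colnames(X)]
  # accept 'w' for the x column and 'b' for the intercept
  theta[1] <- params[["w"]]; theta[2] <- params[["b"]]
  if (anyNA(theta)) stop("missing parameter for an active model term")
  clip_prob(stats::pnorm(drop(X %*% theta)))
}

# Bernoulli negative log-likelihood and analytic gradient of the probit GLM.
.probit_nll <- function(theta, X, y) {
  p <- clip_prob(stats::pnorm(drop(X %*% theta)))
  -sum(y * log(p) + (1 - y) * log1p(-p))
}
.probit_grad <- function(theta, X, y) {
  eta <- drop(X %*% theta)
  p <- clip_prob(stats::pnorm(eta))
  -drop(crossprod(X, stats::dnorm(eta) * (y - p) / (p * (1 - p))))
}

# Bounded quasi-Newton probit fit, optionally multi-start.
.probit_fit <- function(X, y, lower, upper, starts) {
  best <- NULL
  conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(starts[i, ], .probit_nll, .probit_grad,
                            X = X, y = y, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = 1e7, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("probit fit failed from every start")
  list(par = best$par, value = best$value, converged = conv)
}

#' Fit a probit decision model by maximum likelihood
#'
#' Minimises the Bernoulli negative log-likelihood with bounded L-BFGS-B
#' from `n_starts` jittered starting points (bounds: w in [0,20], |b|,
#' |beta|, |gamma| <= 5). If no start converges the best iterate is still
#' returned, flagged `converged = FALSE`.
#'
#' @param spec a [psych_model()].
#' @param data covariate frame from [model_frame()] for one participant.
#' @param n_starts number of jittered starts (default 5).
#' @param seed seed for the start jitter.
#' @return list of class `fit_result`: `w`, `b`, `beta` (named), `gamma`
#'   (named), `neg_loglik`, `converged`, `n_trials`, `par`.
#' @export
fit_mle <- function(spec, data, n_starts = 5L, seed = 1L) {
  y <- data$y
  if (length(y) < 2 || length(unique(y)) < 2)
    warning("both response classes should be present for a stable fit")
  X <- .model_matrix(spec, data)
  bd <- .model_bounds(spec)
  set.seed(as.integer(seed))
  p <- ncol(X)
  starts <- matrix(0, n_starts, p, dimnames = list(NULL, colnames(X)))
  starts[, 1] <- 1
  if (n_starts > 1) {
    jit <- matrix(stats::runif((n_starts - 1) * p, -0.5, 0.5), n_starts - 1, p)
    starts[-1, ] <- sweep(jit, 2, starts[1, ], "+")
    starts <- pmin(pmax(starts, matrix(bd$lower, n_starts, p, byrow = TRUE)),
                   matrix(bd$upper, n_starts, p, byrow = TRUE))
  }
  fit <- .probit_fit(X, y, bd$lower, bd$upper, starts)
  par <- fit$par
  names(par) <- colnames(X)
  res <- list(spec = spec, w = unname(par[1]), b = unname(par[2]),
              beta = par[grep("^beta_", names(par))],
              gamma = par[grep("^gamma_", names(par))],
              neg_loglik = fit$value, converged = fit$converged,
              n_trials = length(y), par = par)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Probit fit (", x$spec$name, "): w=", round(x$w, 3), " b=",
      round(x$b, 3), sep = "")
  if (length(x$beta)) cat(" ", paste(names(x$beta), round(x$beta, 3),
                                     sep = "=", collapse = " "))
  if (length(x$gamma)) cat(" ", paste(names(x$gamma), round(x$gamma, 3),
                                      sep = "=", collapse = " "))
  cat("  -logL=", round(x$neg_loglik, 2), " (n=", x$n_trials, ")\n", sep = "")
  invisible(x)
}

# Held-out log-likelihood of a fitted parameter vector.
.heldout_loglik <- function(spec, par, data) {
  X <- .model_matrix(spec, data)
  p <- clip_prob(stats::pnorm(drop(X %*% par[colnames(X)])))
  sum(data$y * log(p) + (1 - data$y) * log1p(-p))
}

# Stratified fold assignment: within each stratum trials are shuffled and
# dealt round-robin so every fold sees every face/emotion combination.
.make_folds <- function(data, k, seed, stratify = TRUE) {
  n <- nrow(data)
  set.seed(as.integer(seed))
  if (k >= n) return(seq_len(n))  # leave-one-out
  fold <- integer(n)
  if (stratify) {
    strat <- interaction(data$emotion_displayed, data$face, drop = TRUE)
    for (s in levels(strat)) {
      idx <- which(strat == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
  } else {
    fold <- rep_len(sample.int(k), n)[sample.int(n)]
  }
  fold
}

#' Cross-validated log-evidence per participant and model
#'
#' Ten-fold (by default) cross-validation of the model log-likelihood: each
#' model is fitted on nine folds and scored on the held-out fold; the sum of
#' held-out log-likelihoods is the model evidence, implicitly penalising
#' complexity. Folds are stratified by displayed emotion x face and shared
#' across models. `k` equal to the trial count reduces to leave-one-out.
#'
#' @param specs list of [psych_model()] objects (named or auto-named).
#' @param data covariate frame from [model_frame()]; may contain several
#'   participants.
#' @param k number of folds (default 10).
#' @param seed seed for fold assignment (and fit starts).
#' @param stratify stratify folds by emotion x face (default TRUE; the
#'   procedure errors if a training split misses a face).
#' @param n_starts multistarts per fit (default 5).
#' @return matrix participants x models of summed out-of-fold
#'   log-likelihoods, with attributes `k` and `seed`.
#' @export
cv_logevidence <- function(specs, data, k = 10L, seed = 1L, stratify = TRUE,
                           n_starts = 5L) {
  if (inherits(specs, "psych_model")) specs <- list(specs)
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    names(specs) <- vapply(specs, `[[`, "", "name")
  parts <- sort(unique(data$participant))
  ev <- matrix(NA_real_, length(parts), length(specs),
               dimnames = list(parts, names(specs)))
  for (pi in seq_along(parts)) {
    d <- data[data$participant == parts[pi], , drop = FALSE]
    fold <- .make_folds(d, k, seed = seed + pi, stratify = stratify)
    kk <- max(fold)
    for (f in seq_len(kk)) {
      train <- d[fold != f, , drop = FALSE]
      if (stratify && kk < nrow(d) &&
          !all(unique(d$face) %in% unique(train$face)))
        stop("stratification failed: a face is absent from a training fold")
      test <- d[fold == f, , drop = FALSE]
      for (m in seq_along(specs)) {
        fit <- fit_mle(specs[[m]], train, n_starts = n_starts,
                       seed = seed + f)
        ll <- .heldout_loglik(specs[[m]], fit$par, test)
        ev[pi, m] <- if (f == 1) ll else ev[pi, m] + ll
      }
    }
  }
  structure(ev, k = k, seed = seed)
}

#' Accuracy by association label and displayed emotion
#'
#' Proportion of correct responses per participant in the four cells of the
#' (association label x displayed emotion) design, test phase only, neutral
#' trials excluded. Cell columns are ordered anger_anger, anger_fear,
#' fear_anger, fear_fear (label_emotion), so the congruence interaction
#' contrast is (c1 - c2) - (c3 - c4).
#'
#' @param data covariate frame from [model_frame()] including `correct`.
#' @param type association type: "shared", "idio" or "induced".
#' @return matrix participants x 4 cell accuracies.
#' @export
accuracy_by_condition <- function(data, type = c("shared", "idio", "induced")) {
  type <- match.arg(type)
  a <- data[[paste0("a_", type)]]
  d <- data[data$emotion_displayed != "neutral" & !is.na(data$correct), ,
            drop = FALSE]
  a <- a[data$emotion_displayed != "neutral" & !is.na(data$correct)]
  lab <- ifelse(a > 0, "anger", "fear")
  parts <- sort(unique(d$participant))
  cells <- c("anger_anger", "anger_fear", "fear_anger", "fear_fear")
  out <- matrix(NA_real_, length(parts), 4, dimnames = list(parts, cells))
  cond <- paste(lab, d$emotion_displayed, sep = "_")
  agg <- tapply(d$correct, list(d$participant, cond), mean)
  out[, colnames(agg)] <- agg[as.character(parts), , drop = FALSE]
  out
}

#' Fit a model separately to the two halves of the experiment
#'
#' Splits each participant's trials by block (first half vs second half of
#' the block sequence) and fits `spec` to each half, for paired tests of
#' parameter stability over the session.
#'
#' @param spec a [psych_model()].
#' @param data covariate frame from [model_frame()] with a `block` column.
#' @param split block index at/below which trials belong to the first half
#'   (default: half the largest block index).
#' @param n_starts,seed passed to [fit_mle()].
#' @return list with `first` and `second`: lists of `fit_result` per
#'   participant (names = participant ids).
#' @export
fit_halves <- function(spec, data, split = NULL, n_starts = 5L, seed = 1L) {
  if (is.null(split)) split <- max(data$block) / 2
  parts <- sort(unique(data$participant))
  fit_part <- function(d, off) lapply(seq_along(parts), function(i)
    fit_mle(spec, d[d$participant == parts[i], , drop = FALSE],
            n_starts = n_starts, seed = seed + off + i))
  first <- fit_part(data[data$block <= split, , drop = FALSE], 0L)
  second <- fit_part(data[data$block > split, , drop = FALSE], 1000L)
  names(first) <- names(second) <- parts
  list(first = first, second = second)
}
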