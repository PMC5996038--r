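#' Leave-one-out decomposition into shared and idiosyncratic components
#'
#' For each participant j, their per-face values (post-test ratings or
#' per-face decision biases) are regressed, without intercept, on the mean
#' of all other participants' values for the same faces:
#' `value(i, j) = beta_j * mean_{subj != j}[value(i, .)] + eps(i, j)`.
#' The regressor is the *shared* component, the residual the
#' *idiosyncratic* component; the two are orthogonal within participant by
#' least squares. Values are mean-centered per participant first so the
#' no-intercept regression is well-behaved.
#'
#' @param values numeric matrix, participants x faces, no missing cells.
#' @param source "ratings" (behavioural study) or "decision_bias" (EEG
#'   study); recorded on the result.
#' @param center mean-center each participant's values first (default TRUE).
#' @return list of class `loo_decomposition`: `mean_of_others` (matrix),
#'   `beta` (per participant), `residual` (matrix), `source`, `values`
#'   (the centered input).
#' @export
loo_decompose <- function(values, source = c("ratings", "decision_bias"),
                          center = TRUE) {
  source <- match.arg(source)
  values <- as.matrix(values)
  np <- nrow(values); nf <- ncol(values)
  if (np < 3) stop("need at least 3 participants")
  if (nf < 2) stop("need at least 2 faces")
  if (anyNA(values)) stop("missing cells in the value matrix")
  if (is.null(rownames(values))) rownames(values) <- seq_len(np)
  if (center) values <- values - rowMeans(values)
  tot <- colSums(values)
  m <- (matrix(tot, np, nf, byrow = TRUE) - values) / (np - 1)
  dimnames(m) <- dimnames(values)
  beta <- numeric(np)
  resid <- values
  for (j in seq_len(np)) {
    if (stats::sd(m[j, ]) == 0)
      stop("constant mean-of-others regressor for participant ",
           rownames(values)[j])
    beta[j] <- sum(values[j, ] * m[j, ]) / sum(m[j, ]^2)
    resid[j, ] <- values[j, ] - beta[j] * m[j, ]
  }
  names(beta) <- rownames(values)
  structure(list(mean_of_others = m, beta = beta, residual = resid,
                 source = source, values = values),
            class = "loo_decomposition")
}

#' @export
print.loo_decomposition <- function(x, ...) {
  cat("Leave-one-out decomposition of", x$source, ":",
      nrow(x$values), "participants x", ncol(x$values), "faces\n")
  cat("  beta: mean", round(mean(x$beta), 3), " range [",
      round(min(x$beta), 3), ",", round(max(x$beta), 3), "]\n")
  invisible(x)
}

#' Label faces by shared, idiosyncratic and induced association
#'
#' Shared labels come from a per-participant median split of the
#' mean-of-others component ("anger" when it strictly exceeds the median,
#' the "otherwise" branch assigning ties to "fear"); idiosyncratic labels
#' from the sign of the leave-one-out residual ("anger" iff eps > 0).
#'
#' @param decomp a [loo_decompose()] result.
#' @param induced data.frame (participant, face, induced_label); optional.
#' @return data.frame (participant, face, shared_value, idio_value,
#'   shared_label, idio_label, induced_label) with attribute
#'   `degenerate_idio` flagging participants whose residuals are all zero
#'   and `residual_median` as a diagnostic.
#' @export
label_faces <- function(decomp, induced = NULL) {
  m <- decomp$mean_of_others; e <- decomp$residual
  np <- nrow(m); nf <- ncol(m)
  parts <- rownames(m)
  out <- data.frame(participant = rep(parts, each = nf),
                    face = rep(colnames(m) %||% seq_len(nf), times = np))
  out$shared_value <- as.vector(t(m))
  out$idio_value <- as.vector(t(e))
  med <- apply(m, 1, stats::median)
  out$shared_label <- ifelse(out$shared_value > rep(med, each = nf),
                             "anger", "fear")
  out$idio_label <- ifelse(out$idio_value > 0, "anger", "fear")
  if (!is.null(induced)) {
    i <- match(paste(out$participant, out$face),
               paste(induced$participant, induced$face))
    out$induced_label <- induced$induced_label[i]
  }
  attr(out, "degenerate_idio") <- parts[apply(e, 1, function(r) all(r == 0))]
  attr(out, "residual_median") <- apply(e, 1, stats::median)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-face decision biases from choice behaviour
#'
#' For each participant, jointly fits a shared perceptual sensitivity `w`
#' and one additive bias `b_i` per face under
#' `P(anger) = Phi(w*x + b_face)` by maximum likelihood (bounded
#' quasi-Newton on the Bernoulli likelihood; |b_i| <= 5, w in [0, 20]).
#' Faces whose bias lands on the bound (e.g. single-class responses at
#' every level) are flagged.
#'
#' @param trials trial table with responses; only test-phase trials enter.
#' @return list of class `decision_bias_table`: `bias` (participants x
#'   faces matrix), `sensitivity` (per participant), `flagged` (logical
#'   matrix, bias at bounds).
#' @export
estimate_decision_bias <- function(trials) {
  tt <- trials[trials$phase == "test" & !is.na(trials$response) &
                 trials$response != "none", , drop = FALSE]
  parts <- sort(unique(tt$participant))
  faces <- sort(unique(tt$face))
  nf <- length(faces)
  bias <- matrix(NA_real_, length(parts), nf, dimnames = list(parts, faces))
  wv <- setNames(numeric(length(parts)), parts)
  for (pi in seq_along(parts)) {
    d <- tt[tt$participant == parts[pi], , drop = FALSE]
    fidx <- match(d$face, faces)
    D <- matrix(0, nrow(d), nf)
    D[cbind(seq_len(nrow(d)), fidx)] <- 1
    X <- cbind(x = d$evidence_x, D)
    colnames(X) <- c("x", paste0("b", faces))
    y <- as.integer(d$response == "anger")
    fit <- .probit_fit(X, y, lower = c(0, rep(-5, nf)),
                       upper = c(20, rep(5, nf)),
                       starts = matrix(c(1, rep(0, nf)), 1))
    wv[pi] <- fit$par[1]
    bias[pi, ] <- fit$par[-1]
  }
  structure(list(bias = bias, sensitivity = wv,
                 flagged = abs(bias) >= 5 - 1e-6),
            class = "decision_bias_table")
}

#' Induced-association checks on post-test ratings
#'
#' Tests whether ratings carry any trace of the induced assignment: per
#' participant, the AUC (Mann-Whitney, ties 0.5) of ratings for
#' induced-anger vs induced-fear faces, with a group t-test against the
#' chance level 0.5; plus a paired t-test of the mean rating for
#' induced-anger vs induced-fear faces.
#'
#' @param ratings data.frame (participant, face, rating).
#' @param labels data.frame (participant, face, induced_label).
#' @return list: `auc` (per participant), `auc_mean`, `auc_sem`,
#'   `auc_test` (t-test vs 0.5), `mean_diff` (per participant),
#'   `paired_test`.
#' @export
check_induced_in_ratings <- function(ratings, labels) {
  i <- match(paste(ratings$participant, ratings$face),
             paste(labels$participant, labels$face))
  if (anyNA(i)) stop("induced labels missing for some cells")
  ind <- labels$induced_label[i]
  parts <- sort(unique(ratings$participant))
  auc <- md <- setNames(numeric(length(parts)), parts)
  for (pi in seq_along(parts)) {
    sel <- ratings$participant == parts[pi]
    r <- ratings$rating[sel]; l <- ind[sel]
    auc[pi] <- auc_mw(r[l == "anger"], r[l == "fear"])
    md[pi] <- mean(r[l == "anger"]) - mean(r[l == "fear"])
  }
  list(auc = auc, auc_mean = mean(auc),
       auc_sem = stats::sd(auc) / sqrt(length(auc)),
       auc_test = one_sample_t(auc, mu = 0.5),
       mean_diff = md, paired_test = one_sample_t(md, mu = 0))
}

#' Independence of the induced assignment from shared/idiosyncratic values
#'
#' Per participant, regresses the +-1 induced coding on the shared
#' component and (separately) on the idiosyncratic residuals, then tests
#' the regression coefficients against zero across participants.
#'
#' @param decomp a [loo_decompose()] result.
#' @param induced data.frame (participant, face, induced_label) aligned
#'   with the decomposition's rows/columns.
#' @return list with `shared` and `idio`, each containing the
#'   per-participant coefficients and the group t-test.
#' @export
independence_tests <- function(decomp, induced) {
  m <- decomp$mean_of_others; e <- decomp$residual
  parts <- rownames(m); faces <- colnames(m) %||% seq_len(ncol(m))
  key <- paste(induced$participant, induced$face)
  coef_on <- function(reg) {
    vapply(seq_along(parts), function(j) {
      i <- match(paste(parts[j], faces), key)
      y <- label_to_num(induced$induced_label[i])
      x <- reg[j, ]
      if (stats::sd(x) == 0) return(0)
      unname(stats::coef(stats::lm(y ~ x))[2])
    }, 0)
  }
  cs <- coef_on(m); ci <- coef_on(e)
  list(shared = list(coef = setNames(cs, parts), test = one_sample_t(cs)),
       idio = list(coef = setNames(ci, parts), test = one_sample_t(ci)))
}

#' Correlate the shared component with social attribute ratings
#'
#' Pearson correlation of the per-face shared component (group mean of the
#' leave-one-out shared values) with mean dominance and trustworthiness
#' ratings.
#'
#' @param shared_per_face numeric vector, one shared value per face.
#' @param attributes data.frame (face, dominance, trustworthiness) aligned
#'   by position.
#' @return list of `pearson_cor()` results, one per attribute.
#' @export
correlate_attributes <- function(shared_per_face, attributes) {
  list(dominance = pearson_cor(shared_per_face, attributes$dominance),
       trustworthiness = pearson_cor(shared_per_face,
                                     attributes$trustworthiness))
}
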