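#' Hyperparameters of the generative observer model
#'
#' Observers judge a face as angry with probability
#' `Phi(w*x + b + beta_shared*a_shared + beta_idio*a_idio + beta_induced*a_induced)`
#' where `x` is the signed emotion evidence and each `a` is a +-1
#' face-emotion association label. Shared face values `s` (common to all
#' observers) and idiosyncratic values `eps` (observer-specific, centered
#' per face) drive the association labels and the post-test ratings; the
#' induced assignment never enters the ratings.
#'
#' Defaults reflect the ordering of the three bias strengths in the
#' behavioural findings this package models: shared > idiosyncratic >>
#' induced, with the induced criterion shift an order of magnitude weaker.
#'
#' @param w perceptual sensitivity (> 0).
#' @param b stimulus-independent response bias.
#' @param beta_shared,beta_idio,beta_induced additive criterion shifts for
#'   the three association types.
#' @param sigma_s standard deviation of the shared face values (>= 0).
#' @param sigma_e standard deviation of the idiosyncratic values (>= 0).
#' @param rating_gain_shared,rating_gain_idio loadings of the post-test
#'   rating on the shared and idiosyncratic components.
#' @param rating_noise_sd rating noise standard deviation (>= 0).
#' @param attr_gain_dominance,attr_gain_trust loadings of the dominance
#'   (positive) and trustworthiness (negative) attribute ratings on the
#'   shared face value.
#' @param attr_noise_sd attribute rating noise standard deviation.
#' @return list of class `observer_hyperparams`.
#' @export
observer_hyperparams <- function(w = 1.5, b = 0, beta_shared = 0.35,
                                 beta_idio = 0.25, beta_induced = 0.08,
                                 sigma_s = 1, sigma_e = 1,
                                 rating_gain_shared = 0.5,
                                 rating_gain_idio = 0.3,
                                 rating_noise_sd = 0.2,
                                 attr_gain_dominance = 1,
                                 attr_gain_trust = -0.8,
                                 attr_noise_sd = 1.5) {
  h <- as.list(environment())
  if (h$w <= 0) stop("'w' must be positive")
  for (f in c("sigma_s", "sigma_e", "rating_noise_sd", "attr_noise_sd"))
    if (h[[f]] < 0) stop("'", f, "' must be non-negative")
  class(h) <- "observer_hyperparams"
  h
}

#' Sample a cohort's generative parameters
#'
#' Draws the shared face values `s ~ Normal(0, sigma_s)` (one per face,
#' common to all participants) and the idiosyncratic values
#' `eps ~ Normal(0, sigma_e)` (participant x face), then centers `eps`
#' per face across participants so the shared/idiosyncratic split is exact
#' by construction.
#'
#' @param config a [study_design()].
#' @param hyper an [observer_hyperparams()].
#' @param seed integer seed.
#' @return list of class `generative_params` with elements `s` (length
#'   n_faces), `eps` (n_participants x n_faces), and the scalar weights of
#'   `hyper`.
#' @export
sample_observer <- function(config = study_design(),
                            hyper = observer_hyperparams(), seed = 1L) {
  set.seed(as.integer(seed))
  s <- stats::rnorm(config$n_faces, 0, hyper$sigma_s)
  eps <- matrix(stats::rnorm(config$n_participants * config$n_faces, 0,
                             hyper$sigma_e),
                nrow = config$n_participants)
  if (config$n_participants > 1)
    eps <- sweep(eps, 2, colMeans(eps))  # exact per-face centering
  out <- c(list(s = s, eps = eps, n_participants = config$n_participants,
                n_faces = config$n_faces), unclass(hyper))
  class(out) <- "generative_params"
  out
}

#' True association labels implied by the generative parameters
#'
#' The shared label of face i is the sign of its shared value `s_i`, the
#' idiosyncratic label the sign of the observer-specific residual
#' `eps_ij` (positive = anger; exact zeros fall to fear), and the induced
#' label comes from the experimental assignment.
#'
#' @param params a `generative_params` object.
#' @param induced data.frame (participant, face, induced_label), e.g. from
#'   [induced_assignment()] or the `induced_label` columns of a trial table.
#' @return data.frame (participant, face, shared_value, idio_value,
#'   shared_label, idio_label, induced_label).
#' @export
true_association_labels <- function(params, induced) {
  np <- params$n_participants; nf <- params$n_faces
  grid <- expand.grid(face = seq_len(nf), participant = seq_len(np))
  lab <- data.frame(participant = grid$participant, face = grid$face)
  lab$shared_value <- params$s[lab$face]
  lab$idio_value <- params$eps[cbind(lab$participant, lab$face)]
  lab$shared_label <- ifelse(lab$shared_value > 0, "anger", "fear")
  lab$idio_label <- ifelse(lab$idio_value > 0, "anger", "fear")
  key <- paste(induced$participant, induced$face)
  lab$induced_label <- induced$induced_label[
    match(paste(lab$participant, lab$face), key)]
  if (anyNA(lab$induced_label))
    stop("induced assignment missing for some participant x face cells")
  lab
}
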