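#' Simulate anger/fear responses for a trial-table skeleton
#'
#' Fills the `response` and `correct` columns of a skeleton produced by
#' [build_design()]. The probability of an "anger" response is
#' `Phi(w*x + b + beta_shared*a_shared + beta_idio*a_idio +
#' beta_induced*a_induced)` with `a_* = +1` for anger-associated faces and
#' `-1` for fear-associated faces.
#'
#' @param skeleton trial table from [build_design()].
#' @param params `generative_params` from [sample_observer()].
#' @param labels association labels, e.g. [true_association_labels()];
#'   must cover every participant x face in the skeleton.
#' @param seed integer seed.
#' @return the trial table with `response` ("anger"/"fear") and `correct`
#'   (logical, NA on neutral trials) filled in.
#' @export
simulate_responses <- function(skeleton, params, labels, seed = 1L) {
  set.seed(as.integer(seed))
  key <- paste(labels$participant, labels$face)
  i <- match(paste(skeleton$participant, skeleton$face), key)
  if (anyNA(i)) stop("labels missing for some participant x face cells")
  a_s <- label_to_num(labels$shared_label[i])
  a_i <- label_to_num(labels$idio_label[i])
  a_n <- label_to_num(labels$induced_label[i])
  eta <- params$w * skeleton$evidence_x + params$b +
    params$beta_shared * a_s + params$beta_idio * a_i +
    params$beta_induced * a_n
  p <- stats::pnorm(eta)
  skeleton$response <- ifelse(stats::runif(nrow(skeleton)) < p, "anger", "fear")
  skeleton$correct <- ifelse(skeleton$emotion_displayed == "neutral", NA,
                             skeleton$response == skeleton$emotion_displayed)
  skeleton
}

#' Simulate post-test ratings
#'
#' Ratings load on the shared and idiosyncratic face values only
#' (`rating = squash(g_s*s_i + g_i*eps_ij + noise)`); the induced
#' assignment never enters, so ratings carry no information about it by
#' construction. The squash is a clip to the signed rating scale [-1, +1]
#' (+1 = "always expressed anger").
#'
#' @param params `generative_params` from [sample_observer()].
#' @param seed integer seed.
#' @return data.frame (participant, face, rating).
#' @export
simulate_ratings <- function(params, seed = 1L) {
  set.seed(as.integer(seed))
  np <- params$n_participants; nf <- params$n_faces
  noise <- matrix(stats::rnorm(np * nf, 0, params$rating_noise_sd), nrow = np)
  r <- params$rating_gain_shared * matrix(params$s, np, nf, byrow = TRUE) +
    params$rating_gain_idio * params$eps + noise
  r <- pmin(pmax(r, -1), 1)
  data.frame(participant = rep(seq_len(np), each = nf),
             face = rep(seq_len(nf), times = np),
             rating = as.vector(t(r)))
}

#' Simulate dominance and trustworthiness attribute ratings
#'
#' Mean attribute ratings per face from an independent rater sample:
#' dominance loads positively and trustworthiness negatively on the shared
#' face value, plus rating noise.
#'
#' @param params `generative_params`.
#' @param gain_dominance,gain_trust,noise_sd overrides of the hyperparameter
#'   defaults stored in `params`.
#' @param seed integer seed.
#' @return data.frame (face, dominance, trustworthiness).
#' @export
simulate_attribute_ratings <- function(params,
                                       gain_dominance = params$attr_gain_dominance,
                                       gain_trust = params$attr_gain_trust,
                                       noise_sd = params$attr_noise_sd,
                                       seed = 1L) {
  set.seed(as.integer(seed))
  nf <- params$n_faces
  data.frame(face = seq_len(nf),
             dominance = gain_dominance * params$s + stats::rnorm(nf, 0, noise_sd),
             trustworthiness = gain_trust * params$s + stats::rnorm(nf, 0, noise_sd))
}

#' Ratings as a participant x face matrix
#'
#' @param ratings data.frame (participant, face, rating).
#' @return numeric matrix with one row per participant, one column per face.
#' @export
rating_matrix <- function(ratings) {
  parts <- sort(unique(ratings$participant))
  faces <- sort(unique(ratings$face))
  m <- matrix(NA_real_, length(parts), length(faces),
              dimnames = list(parts, faces))
  m[cbind(match(ratings$participant, parts), match(ratings$face, faces))] <-
    ratings$rating
  if (anyNA(m)) stop("missing participant x face cells in ratings")
  m
}
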