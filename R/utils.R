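#' Clip probabilities away from 0 and 1
#'
#' Bernoulli log-likelihoods diverge at exactly 0 or 1; all model
#' probabilities are clipped to [eps, 1 - eps] before entering a likelihood.
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping margin (default 1e-9).
#' @return clipped numeric vector.
#' @keywords internal
clip_prob <- function(p, eps = 1e-9) {
  pmin(pmax(p, eps), 1 - eps)
}

# Named sub-streams spawned from one master seed so that each pipeline stage
# is independently reproducible. Order is fixed: adding a stream appends.
.fb_streams <- c("design", "observer", "responses", "ratings", "attributes",
                 "eeg", "folds", "perm", "bms", "misc")

#' Derive named stage seeds from a master seed
#'
#' @param master integer master seed.
#' @return named integer vector, one seed per pipeline stage.
#' @examples
#' derive_seeds(1)[["design"]]
#' @export
derive_seeds <- function(master) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  s <- sample.int(.Machine$integer.max - 1L, length(.fb_streams))
  names(s) <- .fb_streams
  s
}

#' @rdname derive_seeds
#' @param stream stage name, one of the fixed stream names.
#' @export
sub_seed <- function(master, stream) {
  stream <- match.arg(stream, .fb_streams)
  unname(derive_seeds(master)[stream])
}

#' Map anger/fear labels to the +-1 coding used by the decision models
#'
#' Anger is +1, fear is -1, matching the signed evidence axis.
#'
#' @param label character vector of "anger"/"fear".
#' @return numeric vector in \{+1, -1\}.
#' @export
label_to_num <- function(label) {
  stopifnot(all(label %in% c("anger", "fear")))
  ifelse(label == "anger", 1, -1)
}

#' Mann-Whitney AUC with ties scored 0.5
#'
#' Area under the ROC curve for separating `pos` from `neg` scores, computed
#' from the rank-sum identity; tied scores contribute one half.
#'
#' @param pos scores of the positive class.
#' @param neg scores of the negative class.
#' @return AUC in [0, 1].
#' @examples
#' auc_mw(c(.9, .2), c(.8, .1))  # 0.75
#' @export
auc_mw <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
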