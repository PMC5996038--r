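#' Study design configuration
#'
#' Describes the anger/fear categorisation experiment: participants see
#' `n_faces` identities over `n_blocks` blocks. Faces are split into
#' disjoint sets of `faces_per_block_set` identities; each set is used for a
#' contiguous run of blocks. Every block opens with an induction period
#' (each face of the set shown `induction_reps` times at the maximal morph
#' level, expressing only its induced emotion) followed by a test period of
#' `test_trials_per_block` trials using morph levels 1..(max_morph_level-1)
#' of both emotions plus neutral stimuli, balanced per face over the set's
#' blocks.
#'
#' @param n_participants number of observers (default 31).
#' @param n_faces number of face identities (default 32).
#' @param n_blocks number of blocks (default 8).
#' @param faces_per_block_set identities per block set (default 16); must be
#'   even so the induced anger/fear halves balance.
#' @param induction_reps repetitions of each face in a block's induction
#'   period (default 3); 0 disables induction.
#' @param test_trials_per_block test-period trials per block (default 112).
#' @param max_morph_level maximal morph level, used only in induction
#'   (default 7); test trials use levels 1..(max_morph_level - 1).
#' @param response_deadline_s response deadline in seconds (default 2).
#' @param stim_duration_s stimulus duration in seconds (default 0.25).
#' @return an object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$n_blocks
#' @export
study_design <- function(n_participants = 31L, n_faces = 32L, n_blocks = 8L,
                         faces_per_block_set = 16L, induction_reps = 3L,
                         test_trials_per_block = 112L, max_morph_level = 7L,
                         response_deadline_s = 2, stim_duration_s = 0.25) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_faces = as.integer(n_faces),
              n_blocks = as.integer(n_blocks),
              faces_per_block_set = as.integer(faces_per_block_set),
              induction_reps = as.integer(induction_reps),
              test_trials_per_block = as.integer(test_trials_per_block),
              max_morph_level = as.integer(max_morph_level),
              response_deadline_s = response_deadline_s,
              stim_duration_s = stim_duration_s)
  for (f in c("n_participants", "n_faces", "n_blocks", "faces_per_block_set",
              "max_morph_level"))
    if (cfg[[f]] < 1) stop("'", f, "' must be a positive integer")
  if (cfg$induction_reps < 0) stop("'induction_reps' must be >= 0")
  if (cfg$faces_per_block_set %% 2L != 0L)
    stop("'faces_per_block_set' must be even to balance induced labels")
  if (cfg$n_faces %% cfg$faces_per_block_set != 0L)
    stop("'n_faces' must be a multiple of 'faces_per_block_set'")
  n_sets <- cfg$n_faces %/% cfg$faces_per_block_set
  if (cfg$n_blocks %% n_sets != 0L)
    stop("'n_blocks' must be a multiple of the number of face sets (", n_sets, ")")
  cfg$n_sets <- n_sets
  cfg$blocks_per_set <- cfg$n_blocks %/% n_sets
  cfg$n_levels <- cfg$max_morph_level - 1L  # test-period levels 1..n_levels
  # per-face test trials over its set of blocks
  tpf <- cfg$test_trials_per_block * cfg$blocks_per_set / cfg$faces_per_block_set
  if (tpf != round(tpf))
    stop("test trials cannot be divided evenly across faces")
  tpf <- as.integer(tpf)
  # each (emotion, level) pair nn_reps times, remainder neutral
  nn_reps <- tpf %/% (2L * cfg$n_levels + 2L)
  n_neutral <- tpf - 2L * cfg$n_levels * nn_reps
  if (nn_reps < 1L || n_neutral < 0L || tpf %% cfg$blocks_per_set != 0L)
    stop("test-period counts cannot be balanced for this configuration")
  cfg$trials_per_face <- tpf
  cfg$nonneutral_reps <- nn_reps
  cfg$neutral_reps <- n_neutral
  class(cfg) <- "study_design"
  cfg
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_participants, "participants x", x$n_faces,
      "faces,", x$n_blocks, "blocks\n")
  cat("  induction:", x$faces_per_block_set * x$induction_reps,
      "trials/block at morph level", x$max_morph_level, "\n")
  cat("  test:", x$test_trials_per_block, "trials/block, levels 1..",
      x$n_levels, " of both emotions + ", x$neutral_reps,
      " neutral per face/set\n", sep = "")
  invisible(x)
}

#' Signed evidence for a displayed emotion
#'
#' Morph level l of anger maps to +l/n_levels, of fear to -l/n_levels and
#' neutral to 0, a linear symmetric evidence axis.
#'
#' @param emotion character vector in \{"anger","fear","neutral"\}.
#' @param level integer morph level (0 for neutral).
#' @param n_levels number of test-period levels (default 6).
#' @return signed numeric evidence.
#' @export
evidence_x <- function(emotion, level, n_levels = 6L) {
  sgn <- ifelse(emotion == "anger", 1, ifelse(emotion == "fear", -1, 0))
  sgn * level / n_levels
}

#' Randomly assign induced face-emotion pairings
#'
#' For each participant, half the faces in every block set are paired with
#' anger and the other half with fear, independently across participants.
#'
#' @param config a `study_design`.
#' @param seed integer seed.
#' @return data.frame (participant, face, induced_label).
#' @export
induced_assignment <- function(config = study_design(), seed = 1L) {
  set.seed(as.integer(seed))
  fpbs <- config$faces_per_block_set
  face_set <- rep(seq_len(config$n_sets), each = fpbs)
  out <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    lab <- character(config$n_faces)
    for (g in seq_len(config$n_sets)) {
      idx <- which(face_set == g)
      ang <- sample(idx, fpbs %/% 2L)
      lab[idx] <- "fear"; lab[ang] <- "anger"
    }
    out[[p]] <- data.frame(participant = p, face = seq_len(config$n_faces),
                           induced_label = lab)
  }
  do.call(rbind, out)
}

#' Build the trial-table skeleton of the experiment
#'
#' Generates, per participant and block, the induction rows (faces of the
#' block's set at the maximal morph level, expressing their induced emotion)
#' followed by the test rows (both emotions at levels 1..n_levels plus
#' neutral, balanced per face over the set's blocks), with trial order
#' shuffled within periods. Responses are left empty; see
#' [simulate_responses()].
#'
#' @param config a `study_design`.
#' @param seed integer seed; the induced assignment and all shuffles are
#'   deterministic given it.
#' @return data.frame with columns participant, block, trial, phase, face,
#'   emotion_displayed, morph_level, evidence_x, induced_label, response,
#'   correct.
#' @examples
#' tt <- build_design(study_design(n_participants = 1), seed = 1)
#' table(tt$phase) / 8
#' @export
build_design <- function(config = study_design(), seed = 1L) {
  ind <- induced_assignment(config, seed = seed)
  set.seed(as.integer(seed) + 1L)
  fpbs <- config$faces_per_block_set
  face_set <- rep(seq_len(config$n_sets), each = fpbs)
  set_of_block <- rep(seq_len(config$n_sets), each = config$blocks_per_set)
  nlev <- config$n_levels
  # per-face test schedule template: (emotion, level) pairs
  sched <- rbind(
    data.frame(emotion = rep(c("anger", "fear"),
                             each = nlev * config$nonneutral_reps),
               level = rep(rep(seq_len(nlev), times = config$nonneutral_reps), 2)),
    if (config$neutral_reps > 0)
      data.frame(emotion = "neutral", level = rep(0L, config$neutral_reps)))
  per_block <- config$trials_per_face %/% config$blocks_per_set
  out <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    plab <- ind$induced_label[ind$participant == p]
    # assign each face's schedule rows to the blocks of its set
    test_rows <- vector("list", config$n_faces)
    for (f in seq_len(config$n_faces)) {
      ord <- sched[sample.int(nrow(sched)), , drop = FALSE]
      blocks <- which(set_of_block == face_set[f])
      ord$block <- rep(blocks, each = per_block)
      ord$face <- f
      test_rows[[f]] <- ord
    }
    test_all <- do.call(rbind, test_rows)
    brows <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      g <- set_of_block[b]
      faces_b <- which(face_set == g)
      # induction period
      if (config$induction_reps > 0) {
        fi <- rep(faces_b, times = config$induction_reps)
        fi <- fi[sample.int(length(fi))]
        indu <- data.frame(participant = p, block = b, phase = "induction",
                           face = fi, emotion_displayed = plab[fi],
                           morph_level = config$max_morph_level)
      } else indu <- NULL
      tb <- test_all[test_all$block == b, , drop = FALSE]
      tb <- tb[sample.int(nrow(tb)), , drop = FALSE]
      test <- data.frame(participant = p, block = b, phase = "test",
                         face = tb$face, emotion_displayed = tb$emotion,
                         morph_level = tb$level)
      brows[[b]] <- rbind(indu, test)
      brows[[b]]$trial <- seq_len(nrow(brows[[b]]))
    }
    out[[p]] <- do.call(rbind, brows)
  }
  tt <- do.call(rbind, out)
  tt$evidence_x <- evidence_x(tt$emotion_displayed, tt$morph_level, nlev)
  tt$induced_label <- ind$induced_label[
    match(paste(tt$participant, tt$face), paste(ind$participant, ind$face))]
  tt$response <- NA_character_
  tt$correct <- NA
  rownames(tt) <- NULL
  tt[, c("participant", "block", "trial", "phase", "face",
         "emotion_displayed", "morph_level", "evidence_x", "induced_label",
         "response", "correct")]
}
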