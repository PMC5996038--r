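# Shared fixture builders; everything is generated in code at test time.

# Simulate a small cohort end to end (design, observer, responses).
sim_cohort <- function(n_participants = 5, hyper = observer_hyperparams(),
                       seed = 1, design_args = list()) {
  d <- do.call(study_design,
               c(list(n_participants = n_participants), design_args))
  tt <- build_design(d, seed = seed)
  pars <- sample_observer(d, hyper, seed = seed + 1)
  ind <- unique(tt[, c("participant", "face", "induced_label")])
  truth <- true_association_labels(pars, ind)
  tt <- simulate_responses(tt, pars, truth, seed = seed + 2)
  list(design = d, trials = tt, params = pars, induced = ind, truth = truth)
}

# Minimal covariate frame for direct model fitting: n trials with evidence
# drawn from the morph-level grid and iid +-1 association labels.
sim_model_frame <- function(n, w = 1.5, b = 0, beta = c(shared = 0, idio = 0,
                                                        induced = 0),
                            seed = 1) {
  set.seed(seed)
  x <- sample(c(-(6:1), 0, 1:6) / 6, n, replace = TRUE)
  a_s <- sample(c(-1, 1), n, replace = TRUE)
  a_i <- sample(c(-1, 1), n, replace = TRUE)
  a_n <- sample(c(-1, 1), n, replace = TRUE)
  eta <- w * x + b + beta[["shared"]] * a_s + beta[["idio"]] * a_i +
    beta[["induced"]] * a_n
  y <- stats::rbinom(n, 1, stats::pnorm(eta))
  data.frame(participant = 1, evidence_x = x, y = y,
             response = ifelse(y == 1, "anger", "fear"),
             a_shared = a_s, a_idio = a_i, a_induced = a_n,
             phase = "test", face = 1, block = 1,
             emotion_displayed = ifelse(x > 0, "anger",
                                        ifelse(x < 0, "fear", "neutral")))
}

# Synthetic multi-subject encoding experiment: epochs with the default
# forward model (shared at 270 ms, emotion at 390 ms) and per-subject
# encoding time courses.
sim_encoding_cohort <- function(n_subjects = 8, n_trials = 300,
                                gen = eeg_gen_params(), seed = 1) {
  set.seed(seed)
  tcs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    x <- sample(c(-(6:1), 0, 1:6) / 6, n_trials, replace = TRUE)
    shared <- stats::rnorm(n_trials)
    cov <- data.frame(emotion = x, shared = shared)
    trials <- data.frame(trial = seq_len(n_trials))
    ep <- simulate_eeg(trials, cov, gen, seed = seed + 100 + s)
    tcs[[s]] <- encode(ep, cov)
  }
  tcs
}
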