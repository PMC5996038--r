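#' Configuration for a full simulated study
#'
#' Bundles the design, generative hyperparameters and analysis settings
#' behind [run_all()]. Every stage seed is derived from the single master
#' seed, so a configuration fully determines the report.
#'
#' @param design list of [study_design()] arguments for the behavioural
#'   study.
#' @param hyper list of [observer_hyperparams()] arguments.
#' @param assoc_types association types to run the bias-vs-sensitivity
#'   model comparison on.
#' @param k_folds cross-validation folds (default 10).
#' @param n_starts multistarts per model fit.
#' @param eeg list: `enabled`, `n_subjects`, `n_perm` (cluster
#'   permutations), `noise_sd`, `congruence_amplitude` (coupling of the
#'   congruence components; the stimulus-independent one enters negated).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(design = list(), hyper = list(),
                       assoc_types = c("shared", "idio", "induced"),
                       k_folds = 10L, n_starts = 5L,
                       eeg = list(), seed = 1L) {
  eeg_def <- list(enabled = TRUE, n_subjects = 24L, n_perm = 1000L,
                  noise_sd = 2, congruence_amplitude = 0.5)
  eeg <- utils::modifyList(eeg_def, eeg)
  structure(list(design = design, hyper = hyper, assoc_types = assoc_types,
                 k_folds = as.integer(k_folds), n_starts = as.integer(n_starts),
                 eeg = eeg, seed = as.integer(seed)),
            class = "run_config")
}

# Unique (participant, face, induced_label) rows of a trial table.
.induced_from_trials <- function(trials) {
  unique(trials[, c("participant", "face", "induced_label")])
}

#' Run the complete simulate-analyse pipeline
#'
#' Simulates the behavioural study (design, observers, responses, post-test
#' and attribute ratings), runs the leave-one-out decomposition, the
#' induced-association null checks, the accuracy interaction ANOVAs, the
#' bias-vs-sensitivity model selection per association type, the full
#' additive-bias model with its stability split, and (optionally) the EEG
#' study: per-face decision biases, synthetic epochs, encoding time
#' courses with cluster statistics, jackknife latencies and the
#' congruence contrasts.
#'
#' @param config a [run_config()].
#' @param out optional directory; if given, the report is written there as
#'   `report.json` and the main tables as CSV.
#' @return nested report list (invisibly returns `out` paths as attribute
#'   when written).
#' @export
run_all <- function(config = run_config(), out = NULL) {
  seeds <- derive_seeds(config$seed)
  design <- do.call(study_design, config$design)
  hyper <- do.call(observer_hyperparams, config$hyper)

  trials <- build_design(design, seed = seeds[["design"]])
  params <- sample_observer(design, hyper, seed = seeds[["observer"]])
  induced <- .induced_from_trials(trials)
  truth <- true_association_labels(params, induced)
  trials <- simulate_responses(trials, params, truth,
                               seed = seeds[["responses"]])
  ratings <- simulate_ratings(params, seed = seeds[["ratings"]])
  attributes <- simulate_attribute_ratings(params, seed = seeds[["attributes"]])

  decomp <- loo_decompose(rating_matrix(ratings), source = "ratings")
  labels <- label_faces(decomp, induced)
  induced_check <- check_induced_in_ratings(ratings, labels)
  indep <- independence_tests(decomp, induced)
  shared_per_face <- colMeans(decomp$mean_of_others)
  attr_corr <- correlate_attributes(shared_per_face, attributes)

  mf <- model_frame(trials, labels)
  report <- list(
    seed = config$seed,
    loo_beta_test = one_sample_t(decomp$beta),
    induced_auc = list(mean = induced_check$auc_mean,
                       sem = induced_check$auc_sem,
                       test = induced_check$auc_test,
                       rating_diff_bf = bf_null_ttest(induced_check$mean_diff)),
    independence = list(shared = indep$shared$test, idio = indep$idio$test),
    attribute_correlations = attr_corr,
    accuracy_anova = lapply(setNames(nm = config$assoc_types), function(ty)
      rm_anova_2x2(accuracy_by_condition(mf, ty))))

  # bias vs sensitivity model selection per association type
  report$model_selection <- lapply(setNames(nm = config$assoc_types),
                                   function(ty) {
    specs <- list(bias = psych_model("bias", terms = ty),
                  sensitivity = psych_model("sensitivity", terms = ty))
    ev <- cv_logevidence(specs, mf, k = config$k_folds,
                         seed = seeds[["folds"]], n_starts = config$n_starts)
    bms <- random_effects_bms(ev, seed = seeds[["bms"]])
    list(log10_bf = fixed_effects_log10_bf(ev, "bias", "sensitivity"),
         expected_freq = bms$expected_freq, p_exc = bms$p_exc)
  })

  # full additive-bias model: per-participant fits + group tests
  full <- psych_model("full")
  parts <- sort(unique(mf$participant))
  fits <- lapply(parts, function(p)
    fit_mle(full, mf[mf$participant == p, ], n_starts = config$n_starts,
            seed = seeds[["misc"]] + p))
  B <- t(vapply(fits, function(f) f$beta, numeric(3)))
  report$full_model <- list(
    mean_beta = colMeans(B),
    tests = lapply(setNames(colnames(B), colnames(B)), function(cn)
      one_sample_t(B[, cn])),
    shared_vs_idio = paired_t(B[, "beta_shared"], B[, "beta_idio"]),
    shared_vs_induced = paired_t(B[, "beta_shared"], B[, "beta_induced"]),
    idio_vs_induced = paired_t(B[, "beta_idio"], B[, "beta_induced"]))

  halves <- fit_halves(full, mf, n_starts = config$n_starts,
                       seed = seeds[["misc"]])
  hb <- function(fl, k) vapply(fl, function(f) f$beta[[k]], 0)
  report$half_split <- lapply(setNames(nm = colnames(B)), function(cn)
    paired_t(hb(halves$first, cn), hb(halves$second, cn)))

  if (isTRUE(config$eeg$enabled))
    report$eeg <- .run_eeg_study(config, design, hyper, seeds)

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trials, file.path(out, "trials.csv"), row.names = FALSE)
    utils::write.csv(ratings, file.path(out, "ratings.csv"), row.names = FALSE)
    utils::write.csv(labels, file.path(out, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(.simplify_report(report),
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# EEG study: same task without induction, decision-bias decomposition,
# synthetic epochs and the encoding analyses.
.run_eeg_study <- function(config, design, hyper, seeds) {
  dargs <- utils::modifyList(config$design,
                             list(n_participants = config$eeg$n_subjects,
                                  induction_reps = 0L))
  edesign <- do.call(study_design, dargs)
  trials <- build_design(edesign, seed = seeds[["design"]] + 1L)
  hyper$beta_induced <- 0  # no induction periods in the EEG study
  params <- sample_observer(edesign, hyper, seed = seeds[["observer"]] + 1L)
  truth <- true_association_labels(params, .induced_from_trials(trials))
  trials <- simulate_responses(trials, params, truth,
                               seed = seeds[["responses"]] + 1L)

  db <- estimate_decision_bias(trials)
  decomp <- loo_decompose(db$bias, source = "decision_bias")
  labels <- label_faces(decomp, .induced_from_trials(trials))

  amp <- config$eeg$congruence_amplitude
  cpw <- setNames(rep(1, 9), cp_channels())
  entries <- list(
    list(covariate = "shared", onset = 0.270, peak = 0.290, amplitude = 1,
         weights = cpw),
    list(covariate = "emotion", onset = 0.390, peak = 0.410, amplitude = 1,
         weights = cpw),
    list(covariate = "cong_shared", onset = 0.45, peak = 0.50,
         amplitude = amp, weights = cpw),
    list(covariate = "cong_idio", onset = 0.45, peak = 0.50,
         amplitude = amp, weights = cpw),
    list(covariate = "cong_stim", onset = 0.45, peak = 0.50,
         amplitude = -amp, weights = cpw))
  gen <- eeg_gen_params(entries = entries, noise_sd = config$eeg$noise_sd)

  parts <- sort(unique(trials$participant))
  tcs <- vector("list", length(parts))
  regs <- vector("list", length(parts))
  cong_tcs <- vector("list", length(parts))
  cong_shared <- vector("list", length(parts))
  sub_epochs <- vector("list", length(parts))
  sub_covs <- vector("list", length(parts))
  for (si in seq_along(parts)) {
    tt <- trials[trials$participant == parts[si] & trials$phase == "test", ]
    # forward-model congruence uses the true generative labels
    creg <- congruence_regressors(tt, truth)
    gen_cov <- data.frame(emotion = tt$evidence_x,
                          shared = params$s[tt$face],
                          cong_shared = creg$shared,
                          cong_idio = creg$idio,
                          cong_stim = creg$stim_independent)
    ep <- simulate_eeg(tt, gen_cov, gen, seed = seeds[["eeg"]] + si)
    # analysis covariates use the estimated decomposition
    i <- match(paste(tt$participant, tt$face),
               paste(labels$participant, labels$face))
    ana_cov <- data.frame(emotion = tt$evidence_x,
                          shared = labels$shared_value[i])
    tcs[[si]] <- encode(ep, ana_cov)
    regs[[si]] <- congruence_regressors(tt, labels)
    cong_shared[[si]] <- regs[[si]]$shared > 0
    sub_epochs[[si]] <- ep
    sub_covs[[si]] <- ana_cov
  }
  times <- tcs[[1]]$times
  Bsh <- stack_betas(tcs, "shared")
  Bem <- stack_betas(tcs, "emotion")
  ti500 <- which.min(abs(times - 0.5))
  cong <- congruence_contrast(sub_epochs, regs)
  split <- split_encoding_by_congruence(sub_epochs, sub_covs, cong_shared,
                                        seed = seeds[["perm"]])
  list(
    encoding_at_500 = list(emotion = one_sample_t(Bem[, ti500]),
                           shared = one_sample_t(Bsh[, ti500])),
    clusters = list(
      shared = group_cluster_test(Bsh, n_perm = config$eeg$n_perm,
                                  seed = seeds[["perm"]], times = times),
      emotion = group_cluster_test(Bem, n_perm = config$eeg$n_perm,
                                   seed = seeds[["perm"]] + 1L, times = times)),
    latency = jackknife_latency(Bsh, Bem, times),
    congruence = cong[c("betas_at", "tests", "at")],
    split_by_congruence = split[c("cells", "interaction", "at")])
}

# Strip heavyweight members so the JSON report stays readable.
.simplify_report <- function(x) {
  if (inherits(x, "test_result")) return(unclass(x))
  if (inherits(x, "latency_estimate")) return(unclass(x))
  if (inherits(x, "cluster_result")) return(x$clusters)
  if (is.list(x)) return(lapply(x, .simplify_report))
  x
}
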