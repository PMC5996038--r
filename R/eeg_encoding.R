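#' Single-subject encoding regression
#'
#' Averages the epochs over the centro-parietal channels and, at each
#' timepoint, regresses the single-trial signal on the covariates
#' (simultaneously, with an intercept). Covariates are z-scored across
#' trials by default so betas are comparable across subjects; covariate
#' pairs with |r| > 0.99 abort the fit.
#'
#' @param epochs an `eeg_epochs` object.
#' @param covariates data.frame of per-trial covariates (numeric).
#' @param channels channels to average (default [cp_channels()]).
#' @param zscore z-score covariates across trials (default TRUE; turn off
#'   for fixed +-1 contrast regressors).
#' @return list of class `encoding_timecourse`: `beta` (covariate x time
#'   matrix), `times`, `covariates`.
#' @export
encode <- function(epochs, covariates, channels = cp_channels(),
                   zscore = TRUE) {
  covariates <- as.data.frame(covariates)
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop("requested channels missing from the epochs")
  Y <- apply(epochs$data[, ci, , drop = FALSE], c(1, 3), mean)  # trial x time
  Z <- as.matrix(covariates)
  if (any(apply(Z, 2, stats::sd) == 0)) stop("constant covariate")
  if (zscore) Z <- scale(Z)
  if (ncol(Z) > 1) {
    r <- stats::cor(Z)
    if (any(abs(r[upper.tri(r)]) > 0.99)) stop("collinear covariates (|r| > 0.99)")
  }
  X <- cbind(1, Z)
  B <- solve(crossprod(X), crossprod(X, Y))   # (1+k) x time
  beta <- B[-1, , drop = FALSE]
  rownames(beta) <- colnames(covariates)
  structure(list(beta = beta, times = epochs$times,
                 covariates = colnames(covariates)),
            class = "encoding_timecourse")
}

#' Stack per-subject encoding time courses
#'
#' @param timecourses list of `encoding_timecourse` objects with identical
#'   time axes and covariates.
#' @param covariate covariate name to extract.
#' @return matrix subjects x time of betas, with the time axis as attribute.
#' @export
stack_betas <- function(timecourses, covariate) {
  times <- timecourses[[1]]$times
  B <- t(vapply(timecourses, function(tc) {
    stopifnot(identical(tc$times, times))
    tc$beta[covariate, ]
  }, numeric(length(times))))
  attr(B, "times") <- times
  B
}

# Contiguous supra-threshold clusters of a t time course.
.find_clusters <- function(tvals, tcrit) {
  supra <- abs(tvals) > tcrit
  if (!any(supra))
    return(data.frame(start = integer(), end = integer(), mass = numeric()))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  data.frame(start = starts[idx], end = ends[idx],
             mass = vapply(idx, function(i)
               sum(abs(tvals[starts[i]:ends[i]])), 0))
}

#' Cluster-based permutation test of a group encoding time course
#'
#' Pointwise one-sample t-tests across subjects; contiguous samples with
#' two-sided p below `threshold_p` form clusters scored by summed |t|. The
#' null distribution of the maximal cluster mass is built by randomly
#' sign-flipping whole subjects, and each observed cluster is assigned the
#' exceedance probability of its mass under that null.
#'
#' @param betas matrix subjects x time (e.g. from [stack_betas()]).
#' @param threshold_p cluster-forming pointwise threshold (default 0.05).
#' @param n_perm number of sign-flip permutations (default 1000).
#' @param seed integer seed.
#' @param times optional time axis for reporting (s).
#' @return list of class `cluster_result`: `clusters` (data.frame start,
#'   end, t_start, t_end, mass, p), `tvals`, `tcrit`, `n_perm`, `seed`.
#' @export
group_cluster_test <- function(betas, threshold_p = 0.05, n_perm = 1000L,
                               seed = 1L, times = attr(betas, "times")) {
  n <- nrow(betas); nt <- ncol(betas)
  tcrit <- stats::qt(1 - threshold_p / 2, n - 1)
  ss <- colSums(betas^2)                       # invariant under sign flips
  t_of <- function(m) {
    v <- pmax((ss - n * m^2) / (n - 1), 0)
    out <- ifelse(v > 0, m / sqrt(v / n),
                  ifelse(m == 0, 0, sign(m) * Inf))
    out
  }
  tvals <- t_of(colMeans(betas))
  obs <- .find_clusters(tvals, tcrit)
  set.seed(as.integer(seed))
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  M <- S %*% betas / n                         # perm x time means
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    cl <- .find_clusters(t_of(M[i, ]), tcrit)
    null_max[i] <- if (nrow(cl)) max(cl$mass) else 0
  }
  obs$p <- vapply(obs$mass, function(m)
    (1 + sum(null_max >= m)) / (n_perm + 1), 0)
  if (!is.null(times)) {
    obs$t_start <- times[obs$start]
    obs$t_end <- times[obs$end]
  }
  structure(list(clusters = obs, tvals = tvals, tcrit = tcrit,
                 n_perm = n_perm, seed = seed, times = times),
            class = "cluster_result")
}

# Half-maximum onset of a positive-going curve, linearly interpolated
# between the bracketing samples.
.onset_half_max <- function(curve, times, frac = 0.5) {
  ip <- which.max(curve)
  peak <- curve[ip]
  if (!is.finite(peak) || peak <= 0) return(NA_real_)
  thr <- frac * peak
  cross <- which(curve[seq_len(ip)] >= thr)[1]
  if (is.na(cross)) return(NA_real_)
  if (cross == 1) return(times[1])
  t0 <- times[cross - 1]; t1 <- times[cross]
  v0 <- curve[cross - 1]; v1 <- curve[cross]
  t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
}

#' Jackknife comparison of encoding onset latencies
#'
#' Onset latency of a condition is the (interpolated) first time its grand
#' average time course exceeds `frac` of its peak. The latency difference
#' between two conditions is tested with the jackknife procedure:
#' latencies are re-estimated on each leave-one-subject-out grand average,
#' the t statistic over those estimates is divided by (n - 1) to undo the
#' variance shrinkage the jackknife induces, and referred to t with
#' n - 1 df.
#'
#' @param betas1,betas2 matrices subjects x time for the two conditions.
#' @param times time axis (s).
#' @param frac onset criterion as fraction of peak (default 0.5).
#' @return list of class `latency_estimate`: `latency_ms` (named, from the
#'   full grand averages), `diff_ms` (condition 2 minus condition 1),
#'   `t`, `df`, `p`, `jackknife_diff_ms`.
#' @export
jackknife_latency <- function(betas1, betas2, times, frac = 0.5) {
  n <- nrow(betas1)
  stopifnot(nrow(betas2) == n, ncol(betas1) == length(times),
            ncol(betas2) == length(times))
  l1 <- .onset_half_max(colMeans(betas1), times, frac)
  l2 <- .onset_half_max(colMeans(betas2), times, frac)
  d <- vapply(seq_len(n), function(i) {
    o1 <- .onset_half_max(colMeans(betas1[-i, , drop = FALSE]), times, frac)
    o2 <- .onset_half_max(colMeans(betas2[-i, , drop = FALSE]), times, frac)
    o2 - o1
  }, 0)
  if (stats::sd(d) == 0) {
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    tval <- (mean(d) / (stats::sd(d) / sqrt(n))) / (n - 1)
  }
  p <- 2 * stats::pt(-abs(tval), n - 1)
  structure(list(latency_ms = c(cond1 = l1, cond2 = l2) * 1000,
                 diff_ms = (l2 - l1) * 1000, t = tval, df = n - 1, p = p,
                 jackknife_diff_ms = d * 1000),
            class = "latency_estimate")
}

#' Per-trial congruence regressors
#'
#' For each trial, +1 when the response matches the face's association
#' label and -1 otherwise, for the shared and idiosyncratic associations;
#' the stimulus-independent regressor scores agreement with the
#' participant's overall response tendency (their majority response).
#'
#' @param trials responded trial rows for one participant.
#' @param labels association labels covering the participant's faces.
#' @return data.frame (shared, idio, stim_independent) of +-1 regressors.
#' @export
congruence_regressors <- function(trials, labels) {
  i <- match(paste(trials$participant, trials$face),
             paste(labels$participant, labels$face))
  if (anyNA(i)) stop("labels missing for some trials")
  agree <- function(lab) ifelse(trials$response == lab, 1, -1)
  overall <- if (mean(trials$response == "anger") > 0.5) "anger" else "fear"
  data.frame(shared = agree(labels$shared_label[i]),
             idio = agree(labels$idio_label[i]),
             stim_independent = agree(rep(overall, nrow(trials))))
}

#' Congruence contrast on decision-related EEG activity
#'
#' One multiple regression per subject of the centro-parietal signal on
#' the three +-1 congruence regressors (shared, idiosyncratic,
#' stimulus-independent), then a group t-test of each beta at the sample
#' nearest `at` seconds. Positive betas mean larger activity before
#' congruent responses.
#'
#' @param epochs_list list of `eeg_epochs`, one per subject.
#' @param regressor_list list of regressor data.frames (one per subject,
#'   e.g. from [congruence_regressors()]).
#' @param at readout latency in seconds (default 0.5).
#' @return list: `betas_at` (subject x regressor matrix), `tests` (group
#'   t-test per regressor), `timecourses` (per-subject
#'   `encoding_timecourse`s), `at`.
#' @export
congruence_contrast <- function(epochs_list, regressor_list, at = 0.5) {
  tcs <- Map(function(ep, reg) encode(ep, reg, zscore = FALSE),
             epochs_list, regressor_list)
  times <- tcs[[1]]$times
  ti <- which.min(abs(times - at))
  regs <- tcs[[1]]$covariates
  betas_at <- sapply(regs, function(rg) stack_betas(tcs, rg)[, ti])
  tests <- lapply(regs, function(rg) one_sample_t(betas_at[, rg]))
  names(tests) <- regs
  list(betas_at = betas_at, tests = tests, timecourses = tcs,
       at = times[ti])
}

#' Encoding split by response congruence
#'
#' Encodes each covariate separately on trials whose response was congruent
#' vs incongruent with an association, optionally subsampling the larger
#' split so both use equally many trials, and tests the 2x2
#' (covariate x congruence) interaction of the betas at `at` seconds with
#' the repeated-measures contrast.
#'
#' @param epochs_list list of `eeg_epochs` per subject.
#' @param covariates_list list of per-subject covariate data.frames (two
#'   columns: the covariate whose encoding is response-locked first).
#' @param congruent_list list of per-subject logical vectors (TRUE =
#'   congruent response).
#' @param at readout latency (s).
#' @param equalize subsample to equal trial counts (default TRUE).
#' @param seed subsampling seed.
#' @return list: `cells` (subject x 4 matrix, columns cov1_cong,
#'   cov1_incong, cov2_cong, cov2_incong), `interaction`
#'   ([rm_anova_2x2()] result), `tests` (per-cell group t), `at`.
#' @export
split_encoding_by_congruence <- function(epochs_list, covariates_list,
                                         congruent_list, at = 0.5,
                                         equalize = TRUE, seed = 1L) {
  set.seed(as.integer(seed))
  covs <- colnames(as.data.frame(covariates_list[[1]]))
  stopifnot(length(covs) == 2)
  n <- length(epochs_list)
  cells <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c(paste0(covs[1], c("_cong", "_incong")),
                                          paste0(covs[2], c("_cong", "_incong")))))
  for (s in seq_len(n)) {
    ep <- epochs_list[[s]]
    cv <- as.data.frame(covariates_list[[s]])
    cg <- congruent_list[[s]]
    ic <- which(cg); ii <- which(!cg)
    if (equalize) {
      m <- min(length(ic), length(ii))
      ic <- sample(ic, m); ii <- sample(ii, m)
    }
    sub <- function(idx) {
      e2 <- ep; e2$data <- ep$data[idx, , , drop = FALSE]
      e2$trial_index <- ep$trial_index[idx]
      e2
    }
    ti <- which.min(abs(ep$times - at))
    for (ci in 1:2) {
      tc_c <- encode(sub(ic), cv[ic, ci, drop = FALSE])
      tc_i <- encode(sub(ii), cv[ii, ci, drop = FALSE])
      cells[s, 2 * ci - 1] <- tc_c$beta[1, ti]
      cells[s, 2 * ci] <- tc_i$beta[1, ti]
    }
  }
  tests <- lapply(colnames(cells), function(cc) one_sample_t(cells[, cc]))
  names(tests) <- colnames(cells)
  list(cells = cells, interaction = rm_anova_2x2(cells), tests = tests,
       at = at)
}
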