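test_that("identical observers give beta = 1 and zero residuals", {
  v <- matrix(rep(c(2, -1, 0.5, -1.5), each = 4), nrow = 4)
  dec <- loo_decompose(v)
  expect_equal(unname(dec$beta), rep(1, 4), tolerance = 1e-12)
  expect_equal(max(abs(dec$residual)), 0, tolerance = 1e-12)
})

test_that("leave-one-out regression matches the two-point hand solution", {
  # participants 1-3 identical, participant 4 mirrored; rows are zero-mean
  # so centering changes nothing. Hand OLS: for p4, mean-of-others = (1,-1)
  # => beta = -1, residuals 0; for p1, mean-of-others = (1/3,-1/3)
  # => beta = (2/3)/(2/9) = 3, residuals 0.
  v <- rbind(c(1, -1), c(1, -1), c(1, -1), c(-1, 1))
  dec <- loo_decompose(v)
  expect_equal(unname(dec$beta[4]), -1, tolerance = 1e-12)
  expect_equal(unname(dec$beta[1]), 3, tolerance = 1e-12)
  expect_equal(max(abs(dec$residual)), 0, tolerance = 1e-12)
  expect_equal(unname(dec$mean_of_others[4, ]), c(1, -1))
})

test_that("a constant mean-of-others regressor is rejected by name", {
  # with 3 participants the other two cancel for participants 1 and 2
  v <- rbind(c(1, -1), c(1, -1), c(-1, 1))
  rownames(v) <- c("s1", "s2", "s3")
  expect_error(loo_decompose(v), "s1")
})

test_that("residuals are orthogonal to the regressor and LOO means are exact", {
  set.seed(21)
  for (i in 1:5) {
    v <- matrix(rnorm(12 * 16), nrow = 12)
    dec <- loo_decompose(v)
    # orthogonality within participant
    dots <- rowSums(dec$residual * dec$mean_of_others)
    expect_lt(max(abs(dots)), 1e-8)
    # leave-one-out identity against the direct mean
    j <- sample(12, 1)
    expect_equal(dec$mean_of_others[j, ],
                 colMeans(dec$values[-j, ]), tolerance = 1e-12)
  }
})

test_that("median split labels half the faces shared-anger", {
  v <- matrix(rnorm(6 * 10), nrow = 6)
  dec <- loo_decompose(v)
  lab <- label_faces(dec)
  tab <- table(lab$participant, lab$shared_label)
  expect_true(all(tab == 5))
})

test_that("zero residuals fall to the tie rule and are flagged", {
  # dyadic values keep the leave-one-out arithmetic exact
  v <- matrix(rep((-4:3) / 4, each = 4), nrow = 4)
  dec <- loo_decompose(v)
  lab <- label_faces(dec)
  expect_true(all(lab$idio_label == "fear"))
  expect_identical(attr(lab, "degenerate_idio"), rownames(dec$values))
})

test_that("labels are invariant under common positive affine rescaling", {
  set.seed(31)
  v <- matrix(rnorm(8 * 12), nrow = 8)
  l1 <- label_faces(loo_decompose(v))
  l2 <- label_faces(loo_decompose(3.7 * v + 0.4))
  expect_identical(l1$shared_label, l2$shared_label)
  expect_identical(l1$idio_label, l2$idio_label)
})

test_that("estimated shared labels recover the generative signs", {
  p <- sample_observer(study_design(),
                       observer_hyperparams(rating_noise_sd = 0.02,
                                            rating_gain_idio = 0.05), seed = 14)
  dec <- loo_decompose(rating_matrix(simulate_ratings(p, seed = 15)))
  lab <- label_faces(dec)
  # the estimator's target is the median split of the true shared values
  truth_lab <- ifelse(p$s[as.integer(lab$face)] > median(p$s),
                      "anger", "fear")
  expect_gt(mean(lab$shared_label == truth_lab), 0.95)
})

test_that("per-face decision biases recover injected criterion shifts", {
  # one observer, 8 faces; faces 1-4 carry bias +beta, faces 5-8 -beta
  set.seed(41)
  n <- 10000; beta <- 0.4; w <- 1.5
  face <- sample(8, n, replace = TRUE)
  x <- sample(c(-(6:1), 0, 1:6) / 6, n, replace = TRUE)
  b_true <- ifelse(face <= 4, beta, -beta)
  y <- rbinom(n, 1, pnorm(w * x + b_true))
  tt <- data.frame(participant = 1, phase = "test", face = face,
                   evidence_x = x, response = ifelse(y == 1, "anger", "fear"))
  db <- estimate_decision_bias(tt)
  expect_equal(unname(db$sensitivity), w, tolerance = 0.15)
  expect_equal(mean(db$bias[1, 1:4]) - mean(db$bias[1, 5:8]), 2 * beta,
               tolerance = 0.1)
  expect_false(any(db$flagged))

  # the same joint MLE through the standard probit GLM, as cross-check
  g <- glm(y ~ 0 + x + factor(face), family = binomial(probit))
  expect_equal(unname(db$bias[1, ]), unname(coef(g)[-1]), tolerance = 1e-3)
  expect_equal(unname(db$sensitivity), unname(coef(g)[1]), tolerance = 1e-3)
})

test_that("an unbiased observer yields near-zero per-face biases", {
  set.seed(42)
  n <- 8000
  face <- sample(8, n, replace = TRUE)
  x <- sample(c(-(6:1), 0, 1:6) / 6, n, replace = TRUE)
  y <- rbinom(n, 1, pnorm(1.5 * x))
  tt <- data.frame(participant = 1, phase = "test", face = face,
                   evidence_x = x, response = ifelse(y == 1, "anger", "fear"))
  db <- estimate_decision_bias(tt)
  expect_lt(max(abs(db$bias)), 0.2)
})

test_that("more trials shrink the spread of the bias estimates", {
  est_sd <- function(n, seeds) {
    ests <- vapply(seeds, function(sd0) {
      set.seed(sd0)
      face <- sample(4, n, replace = TRUE)
      x <- sample(c(-(6:1), 0, 1:6) / 6, n, replace = TRUE)
      y <- rbinom(n, 1, pnorm(1.5 * x))
      tt <- data.frame(participant = 1, phase = "test", face = face,
                       evidence_x = x,
                       response = ifelse(y == 1, "anger", "fear"))
      estimate_decision_bias(tt)$bias[1, 1]
    }, 0)
    sd(ests)
  }
  expect_gt(est_sd(400, 1:10), est_sd(3200, 1:10))
})

test_that("AUC matches brute-force pair counting", {
  brute_auc <- function(pos, neg) {
    s <- 0
    for (a in pos) for (f in neg)
      s <- s + (a > f) + 0.5 * (a == f)
    s / (length(pos) * length(neg))
  }
  # the 4-face toy: ratings (.9,.8,.2,.1), induced labels (A,F,A,F)
  expect_equal(auc_mw(c(0.9, 0.2), c(0.8, 0.1)), 0.75)
  expect_equal(brute_auc(c(0.9, 0.2), c(0.8, 0.1)), 0.75)
  set.seed(51)
  for (i in 1:5) {
    pos <- round(rnorm(9), 1); neg <- round(rnorm(7), 1)  # forces some ties
    expect_equal(auc_mw(pos, neg), brute_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("induced checks hit the degenerate endpoints", {
  lab <- data.frame(participant = rep(1, 4), face = 1:4,
                    induced_label = c("anger", "fear", "anger", "fear"))
  same <- data.frame(participant = 1, face = 1:4, rating = rep(0.3, 4))
  expect_equal(unname(check_induced_in_ratings(same, lab)$auc), 0.5)
  ordered <- data.frame(participant = 1, face = 1:4,
                        rating = c(0.9, 0.1, 0.8, 0.2))
  expect_equal(unname(check_induced_in_ratings(ordered, lab)$auc), 1)
})

test_that("induced assignment is independent of both components", {
  co <- sim_cohort(n_participants = 12, seed = 61)
  p <- co$params
  dec <- loo_decompose(rating_matrix(simulate_ratings(p, seed = 62)))
  it <- independence_tests(dec, co$induced)
  expect_gt(it$shared$test$p, 0.01)
  expect_gt(it$idio$test$p, 0.01)
  # zero residuals force a zero idiosyncratic coefficient (dyadic values
  # keep the residuals exactly zero)
  v <- matrix(rep((-16:15) / 16, each = 12), nrow = 12)
  dec0 <- loo_decompose(v)
  it0 <- independence_tests(dec0, co$induced)
  expect_equal(unname(it0$idio$coef), rep(0, 12))
  # a contaminated assignment (tracking the residuals) is detected
  bad <- co$induced
  key <- paste(bad$participant, bad$face)
  eps <- dec$residual[cbind(bad$participant, as.integer(bad$face))]
  bad$induced_label <- ifelse(eps > 0, "anger", "fear")
  itb <- independence_tests(dec, bad)
  expect_lt(itb$idio$test$p, 1e-4)
})

test_that("attribute correlations recover sign and magnitude", {
  expect_equal(correlate_attributes(1:10, data.frame(face = 1:10,
    dominance = 1:10, trustworthiness = -(1:10)))$dominance$r, 1)
  expect_equal(correlate_attributes(1:10, data.frame(face = 1:10,
    dominance = 1:10, trustworthiness = -(1:10)))$trustworthiness$r, -1)
  # default generator gains give dominance-positive, trust-negative
  p <- sample_observer(study_design(), seed = 71)
  at <- simulate_attribute_ratings(p, seed = 72)
  cc <- correlate_attributes(p$s, at)
  expect_gt(cc$dominance$r, 0)
  expect_lt(cc$trustworthiness$r, 0)
})
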