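# PUK kernel, SMO training, metrics, balanced CV protocol, window scan.

test_that("PUK kernel has unit diagonal, symmetry and the Lorentzian value", {
  p <- puk_params(omega = 1, sigma = 1)
  expect_equal(puk_kernel(c(1, 2), c(1, 2), p), 1)
  expect_equal(puk_kernel(0, 1, p), 1 / 5)  # 1/(1 + 4*(2^1 - 1))
  set.seed(1)
  x <- matrix(rnorm(40), 8)
  K <- puk_kernel(x, x, puk_params(omega = 2.3, sigma = 0.7))
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_equal(diag(K), rep(1, 8))
  expect_true(all(K > 0 & K <= 1))
  # strictly decreasing in distance
  expect_gt(puk_kernel(0, 0.5, p), puk_kernel(0, 1.5, p))
  expect_error(puk_kernel(c(1, 2), c(1, 2, 3), p), "dimension")
  expect_error(puk_params(omega = -1), "omega")
})

test_that("PUK Gram matrices are positive semidefinite on random data", {
  set.seed(2)
  for (i in 1:5) {
    x <- matrix(rnorm(30 * sample(2:6, 1)), 30)
    K <- puk_kernel(x, x, puk_params(omega = runif(1, 0.5, 3),
                                     sigma = runif(1, 0.3, 2)))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("SMO separates separable data and flips with relabelling", {
  x <- matrix(c(0, 0.1, -0.1, 10, 10.1, 9.9), ncol = 1)
  y <- c(-1, -1, -1, 1, 1, 1)
  m <- train_smo(x, y, puk_params(), scale = FALSE)
  expect_equal(predict(m, x), y)
  dec <- predict(m, x, type = "decision")
  m2 <- train_smo(x, -y, puk_params(), scale = FALSE)
  expect_equal(predict(m2, x, type = "decision"), -dec, tolerance = 1e-6)
  expect_error(train_smo(x, rep(1, 6)), "single class")
  # decision values move continuously with the input
  d0 <- predict(m, matrix(5), type = "decision")
  d1 <- predict(m, matrix(5 + 1e-9), type = "decision")
  expect_lt(abs(d1 - d0), 1e-6)
})

test_that("SMO dual matches an independent QP solver on random problems", {
  skip_if_not_installed("kernlab")
  set.seed(3)
  for (rep in 1:5) {
    n <- 50
    x <- matrix(rnorm(n * 4), n)
    y <- sign(x[, 1] + 0.5 * rnorm(n)); y[y == 0] <- 1
    pp <- puk_params(C = 1, tolerance = 1e-6)
    K <- puk_kernel(x, x, pp)
    m <- train_smo(x, y, pp, scale = FALSE)
    # KKT gap at convergence is within tolerance
    expect_lte(m$gap, pp$tolerance)
    Q <- (y %*% t(y)) * K
    qp <- kernlab::ipop(c = rep(-1, n), H = Q, A = t(y), b = 0, r = 0,
                        l = rep(0, n), u = rep(pp$C, n), sigf = 9)
    obj_ref <- oracle_dual_objective(kernlab::primal(qp), y, K)
    expect_equal(m$objective, obj_ref, tolerance = 1e-4 * max(1, abs(obj_ref)))
    # equality constraint of our own solution
    sv_y <- sign(m$coef)
    expect_equal(sum(m$coef), 0, tolerance = 1e-8)
  }
})

test_that("models survive a bundle round trip with identical decisions", {
  set.seed(4)
  recs <- lapply(1:5, function(i) random_record(sprintf("p%d", i), 40, 4))
  segs <- extract_windows(recs, 5)
  fm <- fit_features(segs, "refinement")
  xx <- feature_transform(fm, segs)
  m <- train_smo(xx, segs$label, scale = FALSE, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  save_model_bundle(f, fm, m, config = list(seed = 7))
  back <- load_model_bundle(f)
  x2 <- feature_transform(back$feature_model, segs)
  expect_equal(x2, xx, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(predict(back$svm, x2, type = "decision"),
               predict(m, xx, type = "decision"), tolerance = 1e-12)
})

test_that("metrics follow the four formulae with degenerate conventions", {
  m <- compute_metrics(list(TP = 10, FN = 0, TN = 10, FP = 0))
  expect_equal(c(m$sn, m$sp, m$acc, m$mcc), c(100, 100, 100, 1))
  m2 <- compute_metrics(list(TP = 5, FN = 5, TN = 5, FP = 5))
  expect_equal(c(m2$acc, m2$mcc), c(50, 0))
  m3 <- compute_metrics(list(TP = 8, FN = 2, TN = 6, FP = 4))
  expect_equal(c(m3$sn, m3$sp, m3$acc), c(80, 60, 70))
  expect_equal(m3$mcc, 40 / sqrt(9600), tolerance = 1e-12)
  expect_equal(m3$mcc, 0.4082, tolerance = 1e-3)
  # zero MCC denominator factor -> 0 with warning; zero Sn denominator -> NA
  expect_warning(m4 <- compute_metrics(list(TP = 0, FN = 0, TN = 5, FP = 5)),
                 "MCC")
  expect_equal(m4$mcc, 0)
  expect_true(is.na(m4$sn))
  expect_error(compute_metrics(list(TP = -1, FN = 0, TN = 0, FP = 0)), "negative")

  set.seed(12)
  for (i in 1:1000) {
    q <- sample(1:50, 4, TRUE)
    got <- compute_metrics(list(TP = q[1], FN = q[2], TN = q[3], FP = q[4]))
    ora <- oracle_metrics(q[1], q[2], q[3], q[4])
    expect_equal(c(got$sn, got$sp, got$acc, got$mcc),
                 c(ora$sn, ora$sp, ora$acc, ora$mcc), tolerance = 1e-10)
  }
})

test_that("balanced CV has the right shape, determinism and error handling", {
  recs <- simulate_dataset(sim_config(n_proteins = 30L,
                                      length_range = c(50L, 60L),
                                      binding_rate = 0.06, seed = 5L))
  segs <- extract_windows(recs, 7)
  rep1 <- balanced_cv(segs, "refinement", folds = 5, resamples = 3, seed = 99)
  expect_s3_class(rep1, "cv_report")
  expect_equal(nrow(rep1$folds), 15)
  expect_equal(nrow(rep1$resamples), 3)
  # averages are the arithmetic mean of what they summarize
  expect_equal(rep1$average$mcc, mean(rep1$resamples$mcc))
  expect_equal(rep1$average$acc, mean(rep1$resamples$acc))
  # same seed -> bit-identical report
  rep2 <- balanced_cv(segs, "refinement", folds = 5, resamples = 3, seed = 99)
  expect_identical(rep1, rep2)
  # positives outnumbering negatives is an error
  pos <- segs[segs$label == 1]
  few_neg <- c(pos, segs[which(segs$label == -1)[1:6]])
  expect_error(balanced_cv(few_neg), "fewer negatives")
})

test_that("fitted artifacts depend only on training folds (no leakage)", {
  set.seed(6)
  recs <- lapply(1:6, function(i) random_record(sprintf("p%d", i), 40, 4))
  segs <- extract_windows(recs, 5)
  n <- length(segs)
  tr <- 1:160; te <- 161:n
  fm1 <- fit_features(segs[tr], "refinement")
  # permute the held-out labels: fit artifacts and decisions are unchanged
  segs_perm <- segs
  segs_perm$label[te] <- sample(segs_perm$label[te])
  fm2 <- fit_features(segs_perm[tr], "refinement")
  expect_identical(fm1, fm2)
  m1 <- train_smo(feature_transform(fm1, segs[tr]), segs$label[tr], scale = FALSE)
  d1 <- predict(m1, feature_transform(fm1, segs[te]), type = "decision")
  m2 <- train_smo(feature_transform(fm2, segs_perm[tr]), segs_perm$label[tr],
                  scale = FALSE)
  d2 <- predict(m2, feature_transform(fm2, segs_perm[te]), type = "decision")
  expect_identical(d1, d2)
})

test_that("window scan reports one CV per size and prefers the motif span", {
  recs <- simulate_dataset(sim_config(n_proteins = 40L,
                                      length_range = c(60L, 70L),
                                      binding_rate = 0.05, signal = 1,
                                      influence = 7L, seed = 13L))
  scan <- window_scan(recs, sizes = c(5, 7, 9), feature_set = "refinement",
                      resamples = 2, seed = 14)
  expect_length(scan$reports, 3)
  expect_equal(scan$summary$L, c(5, 7, 9))
  expect_equal(scan$best_L, scan$summary$L[which.max(scan$summary$mcc)])
  expect_error(window_scan(recs, sizes = c(4, 6)), "odd")

  # feature-less degenerate data: every window identical, MCC ~ 0
  mono <- lapply(1:4, function(i)
    protein_record(sprintf("m%d", i), strrep("A", 40),
                   binding_positions = sample.int(40, 4),
                   ss_track = strrep("C", 40), sa_track = rep(0.5, 40)))
  segs_mono <- extract_windows(mono, 5)
  rep_mono <- suppressWarnings(
    balanced_cv(segs_mono, "component", resamples = 2, seed = 15))
  expect_lte(abs(rep_mono$average$mcc), 0.3)
})
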