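# Position frequency/weight matrices, conservation index and the S score.

test_that("frequency matrix follows the square-root pseudocount form", {
  # 4 segments, all showing 'A' in a single column
  fm <- build_frequency_matrix(rep("A", 4))
  expect_equal(fm$A, 21)
  expect_equal(unname(fm$p[1, "A"]), (4 + 2 / 21) / 6, tolerance = 1e-12)
  expect_equal(unname(fm$p[1, "C"]), (2 / 21) / 6, tolerance = 1e-12)
  expect_equal(unname(fm$p[1, "A"]), 0.682540, tolerance = 1e-5)
  expect_equal(unname(fm$p[1, "C"]), 0.015873, tolerance = 1e-4)
  expect_equal(sum(fm$p[1, ]), 1, tolerance = 1e-12)
  # pseudocounts forbid zero probabilities
  expect_true(all(fm$p > 0))
  expect_error(build_frequency_matrix(character(0)), "at least one|empty")
})

test_that("row sums are exactly 1 and counts are conserved on random input", {
  set.seed(11)
  for (i in 1:25) {
    n_seg <- sample(1:20, 1); L <- sample(1:6, 1)
    A <- sample(2:6, 1)
    ab <- toy_alphabet(letters[1:A])
    enc <- matrix(sample.int(A, n_seg * L, TRUE), n_seg, L)
    fm <- build_frequency_matrix(enc, ab)
    expect_equal(unname(rowSums(fm$p)), rep(1, L), tolerance = 1e-12)
    expect_equal(unname(rowSums(fm$n)), fm$N)
    expect_equal(fm$N, rep(n_seg, L))
  }
})

test_that("background probabilities are add-one smoothed pooled frequencies", {
  ab <- toy_alphabet(c("A", "B", "X"))
  enc <- rbind(c(1L, 2L), c(1L, 2L))  # pool "AB","AB": A=2, B=2, X=0
  p0 <- background_probabilities(enc, ab)
  expect_equal(unname(p0), c(3, 3, 1) / 7)
  expect_equal(sum(p0), 1)
  # uniform pool gives uniform background; uniform option always does
  enc_u <- rbind(1:3, 1:3)
  expect_equal(unname(background_probabilities(enc_u, ab)), rep(1 / 3, 3))
  expect_equal(unname(background_probabilities(enc, ab, method = "uniform")),
               rep(1 / 3, 3))
})

test_that("weight matrix is the log-ratio to background with cached extremes", {
  ab <- toy_alphabet(c("A", "B"))
  enc <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  fm <- build_frequency_matrix(enc, ab)
  p0 <- c(0.5, 0.5)
  wm <- build_weight_matrix(fm, p0)
  # balanced columns: p = p0 -> m = 0 rows
  expect_equal(unname(wm$m), matrix(0, 2, 2), tolerance = 1e-12)
  expect_equal(wm$m_min, c(0, 0))
  # direct arithmetic: p/p0 = 2 -> log 2
  fm2 <- fm; fm2$p <- matrix(c(0.5, 0.5, 0.5, 0.5), 2)
  wm2 <- build_weight_matrix(fm2, c(0.25, 0.75))
  expect_equal(wm2$m[1, 1], log(2))
  expect_true(all(wm2$m >= wm2$m_min & wm2$m <= wm2$m_max))
  expect_error(build_weight_matrix(fm, c(0, 1)), "positive")
})

test_that("conservation index spans [0,100] with entropy endpoints", {
  A <- 21
  expect_equal(conservation_index(matrix(1 / A, 1, A)), 0, tolerance = 1e-10)
  expect_equal(conservation_index(matrix(c(1, rep(0, A - 1)), 1, A)), 100)
  # the pseudocounted single-column example evaluates near 48.24
  fm <- build_frequency_matrix(rep("A", 4))
  expect_equal(conservation_index(fm)[1], 48.236, tolerance = 1e-3)
  expect_equal(conservation_index(fm), oracle_cons(fm$p), tolerance = 1e-10)
})

test_that("segment score hits its min/max cases and the L=1 midpoint", {
  ab <- toy_alphabet(c("a", "b", "c"))
  wm <- structure(list(property = "AA", L = 1L, symbols = ab$symbols, A = 3L,
                       m = matrix(c(1, 0, -1), 1), p0 = rep(1 / 3, 3),
                       m_min = -1, m_max = 1), class = "weight_matrix")
  expect_equal(score_segment(wm, 50, matrix(2L, 1, 1)), 0.5)
  expect_equal(score_segment(wm, 50, matrix(1L, 1, 1)), 1)
  expect_equal(score_segment(wm, 50, matrix(3L, 1, 1)), 0)
  # degenerate denominator: all conservation zero -> S = 0 with warning
  expect_warning(s0 <- score_segment(wm, 0, matrix(1L, 1, 1)), "degenerate")
  expect_equal(s0, 0)
  expect_error(score_segment(wm, 50, matrix(1L, 1, 2)), "length")
})

test_that("scores lie in [0,1] and argmax/argmin segments reach the bounds", {
  set.seed(21)
  for (i in 1:15) {
    L <- sample(2:5, 1); A <- sample(2:5, 1)
    ab <- toy_alphabet(letters[1:A])
    enc <- matrix(sample.int(A, 12 * L, TRUE), 12, L)
    fm <- build_frequency_matrix(enc, ab)
    p0 <- background_probabilities(enc, ab)
    wm <- build_weight_matrix(fm, p0)
    cons <- conservation_index(fm)
    test_enc <- matrix(sample.int(A, 6 * L, TRUE), 6, L)
    s <- score_segment(wm, cons, test_enc)
    expect_true(all(s >= 0 & s <= 1))
    argmax <- matrix(apply(wm$m, 1, which.max), 1)
    argmin <- matrix(apply(wm$m, 1, which.min), 1)
    expect_equal(score_segment(wm, cons, argmax), 1, tolerance = 1e-12)
    expect_equal(score_segment(wm, cons, argmin), 0, tolerance = 1e-12)
  }
})

test_that("conservation and score are invariant to the logarithm base", {
  set.seed(31)
  for (i in 1:10) {
    L <- sample(2:4, 1); A <- sample(3:6, 1)
    ab <- toy_alphabet(letters[1:A])
    enc <- matrix(sample.int(A, 10 * L, TRUE), 10, L)
    fm <- build_frequency_matrix(enc, ab)
    p0 <- background_probabilities(enc, ab)
    cons <- conservation_index(fm)
    expect_equal(cons, oracle_cons(fm$p, base = 10), tolerance = 1e-10)
    wm <- build_weight_matrix(fm, p0)
    obs <- sample.int(A, L, TRUE)
    expect_score_matches(wm, cons, obs,
                         m_oracle = oracle_weight(fm$p, p0, base = 10),
                         c_oracle = oracle_cons(fm$p, 10))
  }
})

test_that("production matrices agree with the literal-formula oracle", {
  set.seed(41)
  for (i in 1:50) {
    L <- sample(1:4, 1); A <- sample(2:4, 1); n_seg <- sample(1:20, 1)
    ab <- toy_alphabet(letters[1:A])
    enc <- matrix(sample.int(A, n_seg * L, TRUE), n_seg, L)
    fm <- build_frequency_matrix(enc, ab)
    ora <- oracle_freq(enc, A)
    expect_equal(unname(fm$p), ora$p, tolerance = 1e-10)
    p0 <- background_probabilities(enc, ab)
    wm <- build_weight_matrix(fm, p0)
    expect_equal(unname(wm$m), oracle_weight(ora$p, p0), tolerance = 1e-10)
    cons <- conservation_index(fm)
    expect_equal(cons, oracle_cons(ora$p), tolerance = 1e-10)
    obs <- sample.int(A, L, TRUE)
    expect_score_matches(wm, cons, obs)
  }
})

test_that("position features are paired weight-matrix lookups of length 2L", {
  set.seed(51)
  recs <- lapply(1:4, function(i) random_record(sprintf("p%d", i), 30, 4))
  segs <- extract_windows(recs, 7)
  enc <- encode_matrix(segs, "AA")
  pos_i <- segs$label == 1; neg_i <- segs$label == -1
  ab <- attr(enc, "alphabet")
  ep <- enc[pos_i, , drop = FALSE]; attr(ep, "alphabet") <- ab
  en <- enc[neg_i, , drop = FALSE]; attr(en, "alphabet") <- ab
  model <- train_position_model(ep, en)
  pf <- position_features(model, enc)
  expect_equal(ncol(pf), 2 * 7)
  # lookups match the matrices entry by entry
  expect_equal(pf[3, 2], unname(model$pos$weight$m[2, enc[3, 2]]))
  expect_equal(pf[3, 7 + 2], unname(model$neg$weight$m[2, enc[3, 2]]))
  # identical classes give mirrored halves
  model_same <- train_position_model(ep, ep)
  pf_same <- position_features(model_same, enc)
  expect_equal(pf_same[, 1:7], pf_same[, 8:14])
  # one-hot alternative has dimension L * A
  oh <- position_features(model, enc, mode = "onehot")
  expect_equal(ncol(oh), 7 * 21)
  expect_equal(unname(rowSums(oh)), rep(7, nrow(oh)))
})

test_that("s_features yield ten bounded scores in fixed property order", {
  set.seed(61)
  recs <- lapply(1:4, function(i) random_record(sprintf("p%d", i), 30, 4))
  segs <- extract_windows(recs, 5)
  fm <- fit_features(segs, "refinement", standardize = FALSE)
  sf <- s_features(fm$models, segs)
  expect_equal(ncol(sf), 10)
  expect_equal(colnames(sf)[1:2], c("AA.Spos", "AA.Sneg"))
  expect_true(all(sf >= 0 & sf <= 1))
  # identical positive/negative training sets give equal pairs
  pos_segs <- segs[segs$label == 1]
  models_same <- lapply(setNames(nm = c("AA", "HYD", "CHG", "SS", "SA")),
                        function(p) {
                          e <- encode_matrix(pos_segs, p)
                          train_position_model(e, e)
                        })
  sf2 <- s_features(models_same, segs)
  for (k in c(1, 3, 5, 7, 9)) expect_equal(sf2[, k], sf2[, k + 1])
  expect_error(s_features(fm$models[1:4], segs), "missing")
})

test_that("segments from the positive set score higher on the positive model", {
  recs <- simulate_dataset(sim_config(n_proteins = 40L,
                                      length_range = c(60L, 80L),
                                      binding_rate = 0.05, signal = 1,
                                      seed = 99L))
  segs <- extract_windows(recs, 7)
  pos <- segs[segs$label == 1]
  fm <- fit_features(segs, "refinement", standardize = FALSE)
  sf <- s_features(fm$models, pos)
  # on average >= 100 planted-motif segments, the positive-model AA score
  # exceeds the negative-model AA score
  expect_gte(length(pos), 100)
  expect_gt(mean(sf[, "AA.Spos"]), mean(sf[, "AA.Sneg"]))
})
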