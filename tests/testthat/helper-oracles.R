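# Independent literal-formula oracles: straight loops, no caching, no
# vectorization. These are the reference the production code is checked
# against; they must stay naive.

oracle_freq <- function(enc, A) {
  L <- ncol(enc); n_seg <- nrow(enc)
  n <- matrix(0, L, A)
  for (i in seq_len(L))
    for (s in seq_len(n_seg))
      n[i, enc[s, i]] <- n[i, enc[s, i]] + 1
  N <- numeric(L)
  for (i in seq_len(L)) N[i] <- sum(n[i, ])
  p <- matrix(0, L, A)
  for (i in seq_len(L))
    for (j in seq_len(A))
      p[i, j] <- (n[i, j] + sqrt(N[i]) / A) / (N[i] + sqrt(N[i]))
  list(n = n, N = N, p = p)
}

oracle_weight <- function(p, p0, base = exp(1)) {
  m <- matrix(0, nrow(p), ncol(p))
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      m[i, j] <- log(p[i, j] / p0[j], base = base)
  m
}

oracle_cons <- function(p, base = exp(1)) {
  A <- ncol(p)
  C <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    h <- 0
    for (j in seq_len(A))
      if (p[i, j] > 0) h <- h + p[i, j] * log(p[i, j], base = base)
    C[i] <- (100 / log(A, base = base)) * (h + log(A, base = base))
  }
  C
}

oracle_score <- function(m, C, obs) {
  L <- nrow(m)
  num <- den <- 0
  for (i in seq_len(L)) {
    mmin <- min(m[i, ]); mmax <- max(m[i, ])
    num <- num + C[i] * (m[i, obs[i]] - mmin)
    den <- den + C[i] * (mmax - mmin)
  }
  num / den
}

# compare production score to the literal oracle; a NaN oracle (zero
# denominator: every position uninformative) corresponds to the documented
# S = 0 convention
expect_score_matches <- function(wm, cons, obs, m_oracle = unname(wm$m),
                                 c_oracle = cons) {
  ora <- oracle_score(m_oracle, c_oracle, obs)
  got <- suppressWarnings(score_segment(wm, cons, matrix(obs, 1)))
  if (is.nan(ora)) testthat::expect_equal(got, 0)
  else testthat::expect_equal(got, ora, tolerance = 1e-10)
}

oracle_D <- function(x) {
  N <- sum(x)
  acc <- if (N > 0) N * log(N) else 0
  for (v in x) if (v > 0) acc <- acc - v * log(v)
  acc
}

oracle_ID <- function(x, y) oracle_D(x + y) - oracle_D(x) - oracle_D(y)

oracle_metrics <- function(TP, FN, TN, FP) {
  sn <- 100 * TP / (TP + FN)
  sp <- 100 * TN / (TN + FP)
  acc <- 100 * (TP + TN) / (TP + TN + FP + FN)
  mcc <- (TP * TN - FP * FN) /
    sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  list(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

# dual objective of an SVC solution computed from first principles
oracle_dual_objective <- function(alpha, y, K) {
  sum(alpha) - 0.5 * as.numeric(t(alpha * y) %*% K %*% (alpha * y))
}

# random protein with tracks, for fixture building
random_record <- function(id, len, n_bind = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  protein_record(id, paste(sample(aa, len, TRUE), collapse = ""),
                 binding_positions = if (n_bind) sample.int(len, n_bind) else integer(0),
                 ss_track = paste(sample(c("H", "E", "C"), len, TRUE), collapse = ""),
                 sa_track = round(runif(len), 4))
}

# fabricate a small alphabet for alphabet-generic operations
toy_alphabet <- function(symbols) {
  structure(list(name = "AA", symbols = symbols, pad = symbols[length(symbols)],
                 size = length(symbols)), class = "property_alphabet")
}
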