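#' Pseudocounted position frequency matrix
#'
#' Builds the per-position symbol probability matrix from a set of
#' equal-length encoded segments. With \code{n[i,j]} the count of symbol
#' \code{j} at position \code{i}, \code{N[i]} the number of segments and
#' \code{A} the alphabet size, probabilities are
#' \deqn{p_{i,j} = (n_{i,j} + \sqrt{N_i}/A) / (N_i + \sqrt{N_i}),}
#' a square-root pseudocount that guarantees every row sums to exactly 1 and
#' every entry is strictly positive. For the amino-acid alphabet A = 21
#' (20 residues plus the pseudo residue 'X'); for the other property
#' alphabets A is the respective alphabet size.
#'
#' @param encoded integer encoding matrix (from [encode_matrix]) or a
#'   character vector of residue window strings (AA-type alphabets).
#' @param alphabet a property alphabet from [ion_alphabets] (only needed
#'   when \code{encoded} has no alphabet attribute).
#' @return a \code{freq_matrix}: list with \code{property}, \code{L},
#'   \code{symbols}, counts \code{n} (L x A), totals \code{N}, and
#'   probabilities \code{p} (L x A).
#' @export
build_frequency_matrix <- function(encoded, alphabet = NULL) {
  enc <- .as_encoding(encoded, alphabet)
  ab <- attr(enc, "alphabet")
  if (nrow(enc) < 1L) stop("at least one segment is required")
  L <- ncol(enc); A <- ab$size
  n <- matrix(0L, L, A)
  for (j in seq_len(A)) n[, j] <- colSums(enc == j)
  N <- rowSums(n)
  p <- (n + sqrt(N) / A) / (N + sqrt(N))
  dimnames(n) <- dimnames(p) <- list(NULL, ab$symbols)
  structure(list(property = ab$name, L = L, symbols = ab$symbols,
                 A = A, n = n, N = N, p = p),
            class = "freq_matrix")
}

.as_encoding <- function(encoded, alphabet = NULL) {
  if (is.matrix(encoded) && !is.null(attr(encoded, "alphabet"))) return(encoded)
  if (is.character(encoded)) {
    if (is.null(alphabet)) alphabet <- ion_alphabets$AA
    if (!alphabet$name %in% c("AA"))
      stop("window strings can only be encoded under the AA alphabet here; ",
           "use encode_matrix() for property ", alphabet$name)
    return(encode_matrix(.string_only_segments(encoded), "AA"))
  }
  if (is.matrix(encoded)) {
    if (is.null(alphabet)) stop("integer matrix needs an explicit alphabet")
    attr(encoded, "alphabet") <- alphabet
    return(encoded)
  }
  stop("unsupported encoding input")
}

#' Background symbol probabilities
#'
#' Add-one smoothed pooled symbol frequencies over all positions of all
#' supplied segments (both classes pooled), or the uniform distribution.
#' Strictly positive, sums to 1.
#'
#' @param encoded integer encoding matrix of the pooled training segments.
#' @param alphabet property alphabet (if not carried by \code{encoded}).
#' @param method \code{"pooled"} (default) or \code{"uniform"}.
#' @return numeric vector of length A, named by symbol.
#' @export
background_probabilities <- function(encoded, alphabet = NULL,
                                     method = c("pooled", "uniform")) {
  method <- match.arg(method)
  enc <- .as_encoding(encoded, alphabet)
  ab <- attr(enc, "alphabet")
  A <- ab$size
  p0 <- if (method == "uniform") rep(1 / A, A) else {
    counts <- tabulate(enc, nbins = A)
    (counts + 1) / (sum(counts) + A)
  }
  names(p0) <- ab$symbols
  p0
}

#' Position weight matrix (log-ratio to background)
#'
#' \deqn{m_{i,j} = \log(p_{i,j} / p_{0,j})} with per-row minima and maxima
#' cached for the min-max normalized segment score. Natural logarithm is
#' used; the downstream conservation index and S score are invariant to the
#' base.
#'
#' @param freq a \code{freq_matrix}.
#' @param p0 strictly positive background vector summing to 1.
#' @return a \code{weight_matrix}: list with \code{m} (L x A), \code{p0},
#'   \code{m_min}, \code{m_max}, \code{property}, \code{L}, \code{symbols}.
#' @export
build_weight_matrix <- function(freq, p0) {
  stopifnot(inherits(freq, "freq_matrix"))
  if (length(p0) != freq$A) stop("background length != alphabet size")
  if (any(p0 <= 0)) stop("background probabilities must be strictly positive")
  m <- log(sweep(freq$p, 2L, p0, "/"))
  structure(list(property = freq$property, L = freq$L, symbols = freq$symbols,
                 A = freq$A, m = m, p0 = p0,
                 m_min = apply(m, 1L, min), m_max = apply(m, 1L, max)),
            class = "weight_matrix")
}

#' Positional conservation index
#'
#' Rescaled negative Shannon entropy of each matrix row:
#' \deqn{C_i = \frac{100}{\log A}\Big(\sum_j p_{i,j}\log p_{i,j} + \log A\Big),}
#' ranging from 0 (uniform position) to 100 (fully conserved position),
#' independent of the logarithm base.
#'
#' @param freq a \code{freq_matrix}, or a plain row-stochastic probability
#'   matrix.
#' @return numeric vector of per-position conservation values in [0, 100].
#' @export
conservation_index <- function(freq) {
  p <- if (inherits(freq, "freq_matrix")) freq$p else as.matrix(freq)
  A <- ncol(p)
  plogp <- p * log(p)
  plogp[p == 0] <- 0  # 0 log 0 := 0
  C <- (100 / log(A)) * (rowSums(plogp) + log(A))
  pmin(pmax(C, 0), 100)  # guard floating-point drift at the extremes
}

#' Conservation-weighted segment score
#'
#' Min-max normalized, conservation-weighted sum of weight-matrix lookups
#' along a segment:
#' \deqn{S = \frac{\sum_i C_i (m_{i,j(i)} - m_{i,\min})}
#'             {\sum_i C_i (m_{i,\max} - m_{i,\min})} \in [0, 1],}
#' where \code{j(i)} is the symbol observed at position \code{i}. A zero
#' denominator (every position degenerate or unconserved) yields S = 0 with
#' a warning rather than an error, so degenerate training folds do not abort
#' a cross-validation run.
#'
#' @param weight a \code{weight_matrix}.
#' @param cons conservation vector of length L.
#' @param encoded integer encoding matrix (n x L) or single encoded row.
#' @return numeric vector of scores in [0, 1].
#' @export
score_segment <- function(weight, cons, encoded) {
  stopifnot(inherits(weight, "weight_matrix"))
  enc <- if (is.matrix(encoded)) encoded else matrix(as.integer(encoded), nrow = 1L)
  if (ncol(enc) != weight$L)
    stop("encoded length ", ncol(enc), " != matrix window length ", weight$L)
  L <- weight$L
  den <- sum(cons * (weight$m_max - weight$m_min))
  obs <- matrix(weight$m[cbind(rep(seq_len(L), each = nrow(enc)), as.vector(enc))],
                nrow = nrow(enc))
  num <- as.vector(obs %*% cons - sum(cons * weight$m_min))
  if (den <= 0) {
    warning("degenerate score denominator; returning S = 0")
    return(rep(0, nrow(enc)))
  }
  pmin(pmax(num / den, 0), 1)
}

#' Train a two-class position score model for one property
#'
#' Fits positive-class and negative-class frequency matrices, a shared
#' background, the corresponding weight matrices and conservation vectors.
#'
#' @param enc_pos,enc_neg integer encoding matrices of the positive and
#'   negative training segments (same alphabet and L).
#' @param background \code{"pooled"} or \code{"uniform"} (see
#'   [background_probabilities]).
#' @return a \code{position_model}: list with elements \code{pos} and
#'   \code{neg} (each \code{freq}, \code{weight}, \code{cons}), plus
#'   \code{p0}, \code{property}, \code{L}.
#' @export
train_position_model <- function(enc_pos, enc_neg,
                                 background = c("pooled", "uniform")) {
  background <- match.arg(background)
  ab <- attr(enc_pos, "alphabet")
  if (is.null(ab) || is.null(attr(enc_neg, "alphabet")))
    stop("encodings must carry their alphabet (use encode_matrix)")
  if (ab$name != attr(enc_neg, "alphabet")$name || ncol(enc_pos) != ncol(enc_neg))
    stop("positive and negative encodings must share alphabet and L")
  pooled <- rbind(enc_pos, enc_neg)
  attr(pooled, "alphabet") <- ab
  p0 <- background_probabilities(pooled, method = background)
  side <- function(enc) {
    freq <- build_frequency_matrix(enc)
    list(freq = freq, weight = build_weight_matrix(freq, p0),
         cons = conservation_index(freq))
  }
  structure(list(property = ab$name, L = ncol(enc_pos), p0 = p0,
                 pos = side(enc_pos), neg = side(enc_neg)),
            class = "position_model")
}

#' @export
print.position_model <- function(x, ...) {
  cat("<position_model>", x$property, "L =", x$L,
      "| mean C+ =", round(mean(x$pos$cons), 2),
      "mean C- =", round(mean(x$neg$cons), 2), "\n")
  invisible(x)
}

#' Per-position weight-matrix features (2L per property)
#'
#' For every window position, looks up the observed symbol's weight in the
#' positive and in the negative class matrix, giving a 2L-dimensional
#' vector: the L positive-matrix values followed by the L negative-matrix
#' values.
#'
#' @param model a \code{position_model}.
#' @param encoded integer encoding matrix (n x L).
#' @param mode \code{"weight"} (default; weight-matrix lookups) or
#'   \code{"onehot"} (raw per-position indicator encoding of dimension
#'   L x A, model-independent).
#' @return numeric matrix n x 2L (or n x L*A for \code{"onehot"}).
#' @export
position_features <- function(model, encoded, mode = c("weight", "onehot")) {
  mode <- match.arg(mode)
  enc <- if (is.matrix(encoded)) encoded else matrix(as.integer(encoded), nrow = 1L)
  if (mode == "onehot") {
    A <- attr(enc, "alphabet")$size
    if (is.null(A)) A <- max(enc)
    out <- matrix(0, nrow(enc), ncol(enc) * A)
    for (i in seq_len(ncol(enc)))
      out[cbind(seq_len(nrow(enc)), (i - 1L) * A + enc[, i])] <- 1
    return(out)
  }
  stopifnot(inherits(model, "position_model"))
  if (ncol(enc) != model$L)
    stop("encoded length ", ncol(enc), " != model window length ", model$L)
  L <- model$L
  idx <- cbind(rep(seq_len(L), each = nrow(enc)), as.vector(enc))
  cbind(matrix(model$pos$weight$m[idx], nrow = nrow(enc)),
        matrix(model$neg$weight$m[idx], nrow = nrow(enc)))
}

#' Ten-dimensional S-score features
#'
#' For each of the five properties (AA, HYD, CHG, SS, SA, in that order)
#' scores the segment against the positive-class and negative-class
#' matrices, yielding the pairs (S+, S-) concatenated into a fixed-order
#' 10-vector per segment.
#'
#' @param models named list of \code{position_model}, one per property.
#' @param segs a [segment_set] with the tracks the models need.
#' @param encodings optional precomputed list of encoding matrices keyed by
#'   property (skips re-encoding).
#' @return numeric matrix n x 10, columns
#'   \code{<property>.S<pos|neg>}.
#' @export
s_features <- function(models, segs, encodings = NULL) {
  missing <- setdiff(PROPERTY_ORDER, names(models))
  if (length(missing))
    stop("missing position model(s) for: ", paste(missing, collapse = ","))
  cols <- lapply(PROPERTY_ORDER, function(p) {
    m <- models[[p]]
    enc <- if (!is.null(encodings)) encodings[[p]] else encode_matrix(segs, p)
    cbind(score_segment(m$pos$weight, m$pos$cons, enc),
          score_segment(m$neg$weight, m$neg$cons, enc))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(t(outer(PROPERTY_ORDER, c("Spos", "Sneg"), paste, sep = ".")))
  out
}
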