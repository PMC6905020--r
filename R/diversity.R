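#' Diversity measure of a discrete source
#'
#' For a count vector \code{X = (n_1, ..., n_s)} with total \code{N}:
#' \deqn{D(X) = N \log N - \sum_i n_i \log n_i,}
#' with the convention \eqn{0 \log 0 = 0} and natural logarithm. D is
#' nonnegative and zero exactly when all mass sits on one symbol.
#'
#' @param x nonnegative count vector (a \code{DiversitySource}).
#' @return nonnegative real.
#' @examples
#' diversity_measure(c(1, 1))  # 2 log 2
#' @export
diversity_measure <- function(x) {
  if (any(x < 0)) stop("counts must be nonnegative")
  .nlogn(sum(x)) - sum(.nlogn(x))
}

.nlogn <- function(v) ifelse(v > 0, v * log(v), 0)

#' Diversity measure of a mixed source
#'
#' \deqn{D(X, Y) = (N+M)\log(N+M) - \sum_i (n_i + m_i)\log(n_i + m_i),}
#' i.e. the diversity of the element-wise sum of the two sources.
#'
#' @param x,y count vectors over the same alphabet.
#' @return nonnegative real; symmetric in its arguments.
#' @export
mixed_diversity <- function(x, y) {
  if (length(x) != length(y))
    stop("sources live on different alphabets (lengths ", length(x),
         " vs ", length(y), ")")
  diversity_measure(x + y)
}

#' Increment of diversity between two sources
#'
#' \deqn{ID(X, Y) = D(X + Y) - D(X) - D(Y) \ge 0,}
#' a symmetric compositional dissimilarity that is zero iff the two count
#' vectors are proportional.
#'
#' @param x,y count vectors over the same alphabet.
#' @return nonnegative real.
#' @export
diversity_increment <- function(x, y) {
  max(mixed_diversity(x, y) - diversity_measure(x) - diversity_measure(y), 0)
}

#' Standard discrete source of one training class
#'
#' Pools the symbol counts of all positions of all training segments of one
#' class into a single count vector over the property alphabet — the
#' reference source that test segments are compared to by increment of
#' diversity.
#'
#' @param encoded integer encoding matrix of the class's training segments.
#' @param alphabet property alphabet (if not carried by \code{encoded}).
#' @return a \code{diversity_source}: named count vector with attributes
#'   \code{property} and \code{total}.
#' @export
build_standard_source <- function(encoded, alphabet = NULL) {
  enc <- .as_encoding(encoded, alphabet)
  ab <- attr(enc, "alphabet")
  if (nrow(enc) == 0L) stop("no training segments for the standard source")
  counts <- tabulate(enc, nbins = ab$size)
  names(counts) <- ab$symbols
  structure(counts, property = ab$name, total = sum(counts),
            class = "diversity_source")
}

#' Ten-dimensional increment-of-diversity features
#'
#' For each property in fixed order (AA, HYD, CHG, SS, SA) computes the
#' increment of diversity between the segment's own symbol counts (a
#' length-L source) and the positive-class and negative-class standard
#' sources, giving the pairs (ID+, ID-) concatenated into a 10-vector.
#'
#' @param sources named list per property, each a list with elements
#'   \code{pos} and \code{neg} of class \code{diversity_source}.
#' @param segs a [segment_set].
#' @param encodings optional precomputed encodings keyed by property.
#' @return numeric matrix n x 10, columns \code{<property>.ID<pos|neg>}.
#' @export
id_features <- function(sources, segs, encodings = NULL) {
  missing <- setdiff(PROPERTY_ORDER, names(sources))
  if (length(missing))
    stop("missing standard source(s) for: ", paste(missing, collapse = ","))
  cols <- lapply(PROPERTY_ORDER, function(p) {
    enc <- if (!is.null(encodings)) encodings[[p]] else encode_matrix(segs, p)
    cnt <- .count_matrix(enc)
    cbind(.id_vs_source(cnt, sources[[p]]$pos),
          .id_vs_source(cnt, sources[[p]]$neg))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(t(outer(PROPERTY_ORDER, c("IDpos", "IDneg"), paste, sep = ".")))
  out
}

# vectorized ID of each count-matrix row against one fixed source
.id_vs_source <- function(cnt, src) {
  if (ncol(cnt) != length(src))
    stop("segment counts and source have different alphabet sizes")
  y <- as.numeric(src)
  Dy <- diversity_measure(y)
  N <- rowSums(cnt); M <- sum(y)
  Dx <- .nlogn(N) - rowSums(.nlogn(cnt))
  mixed <- .nlogn(N + M) - rowSums(.nlogn(sweep(cnt, 2L, y, "+")))
  pmax(mixed - Dx - Dy, 0)
}
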