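#' Fit the feature extractor on training segments
#'
#' Fits everything the chosen feature set needs from the \emph{training}
#' segments only: per-property position score models (frequency, weight and
#' conservation matrices) for the position and S-score features, standard
#' diversity sources for the ID features, and per-dimension
#' standardization statistics. Nothing from held-out segments leaks into
#' the fit.
#'
#' Feature sets:
#' \itemize{
#'   \item \code{component}: 39-dim composition vectors (5 property blocks).
#'   \item \code{position}: per-position weight-matrix lookups, 2L per
#'     property (10L total) — or one-hot site encodings with
#'     \code{position_mode = "onehot"}.
#'   \item \code{refinement}: 20-dim — the 10 ID values followed by the 10
#'     S scores.
#'   \item \code{all}: concatenation of the three blocks above.
#' }
#'
#' @param train_segs training [segment_set] (both classes present for
#'   position/refinement sets).
#' @param feature_set one of \code{"component"}, \code{"position"},
#'   \code{"refinement"}, \code{"all"}.
#' @param background background estimator for the weight matrices
#'   (\code{"pooled"} or \code{"uniform"}).
#' @param position_mode \code{"weight"} or \code{"onehot"} site features.
#' @param standardize compute and apply zero-mean/unit-variance scaling
#'   (statistics from the training segments).
#' @return a \code{feature_model}.
#' @export
fit_features <- function(train_segs,
                         feature_set = c("refinement", "component",
                                         "position", "all"),
                         background = c("pooled", "uniform"),
                         position_mode = c("weight", "onehot"),
                         standardize = TRUE) {
  feature_set <- match.arg(feature_set)
  background <- match.arg(background)
  position_mode <- match.arg(position_mode)
  needs_fit <- feature_set %in% c("position", "refinement", "all")
  models <- sources <- NULL
  if (needs_fit) {
    pos_i <- which(train_segs$label == 1L)
    neg_i <- which(train_segs$label == -1L)
    if (!length(pos_i) || !length(neg_i))
      stop("position/refinement features need both classes in training data")
    models <- list(); sources <- list()
    for (p in PROPERTY_ORDER) {
      enc <- encode_matrix(train_segs, p)
      ab <- attr(enc, "alphabet")
      ep <- enc[pos_i, , drop = FALSE]; attr(ep, "alphabet") <- ab
      en <- enc[neg_i, , drop = FALSE]; attr(en, "alphabet") <- ab
      models[[p]] <- train_position_model(ep, en, background = background)
      sources[[p]] <- list(pos = build_standard_source(ep),
                           neg = build_standard_source(en))
    }
  }
  fm <- structure(list(feature_set = feature_set, L = train_segs$L,
                       background = background, position_mode = position_mode,
                       models = models, sources = sources, scale = NULL),
                  class = "feature_model")
  if (standardize) {
    raw <- .raw_features(fm, train_segs)
    ctr <- colMeans(raw); s <- apply(raw, 2L, stats::sd)
    s[s == 0 | is.na(s)] <- 1
    fm$scale <- list(center = ctr, sd = s)
  }
  fm
}

#' @export
print.feature_model <- function(x, ...) {
  cat("<feature_model>", x$feature_set, "features, L =", x$L,
      if (!is.null(x$scale)) "(standardized)\n" else "(raw)\n")
  invisible(x)
}

.raw_features <- function(fm, segs) {
  if (segs$L != fm$L)
    stop("segment window length ", segs$L, " != feature model L ", fm$L)
  encodings <- NULL
  if (fm$feature_set %in% c("position", "refinement", "all"))
    encodings <- lapply(stats::setNames(PROPERTY_ORDER, PROPERTY_ORDER),
                        function(p) encode_matrix(segs, p))
  blocks <- list()
  if (fm$feature_set %in% c("component", "all"))
    blocks$component <- component_features(segs)
  if (fm$feature_set %in% c("position", "all")) {
    pos <- lapply(PROPERTY_ORDER, function(p)
      position_features(fm$models[[p]], encodings[[p]], mode = fm$position_mode))
    blocks$position <- do.call(cbind, pos)
  }
  if (fm$feature_set %in% c("refinement", "all"))
    blocks$refinement <- refinement_features(fm$models, fm$sources, segs,
                                             encodings = encodings)
  do.call(cbind, blocks)
}

#' Compute (standardized) features for segments
#'
#' Applies a fitted [fit_features] model to any segment set with the same
#' window length.
#'
#' @param fm a \code{feature_model}.
#' @param segs a [segment_set].
#' @return numeric feature matrix, standardized if the model was fitted
#'   with \code{standardize = TRUE}.
#' @export
feature_transform <- function(fm, segs) {
  raw <- .raw_features(fm, segs)
  if (!is.null(fm$scale))
    raw <- sweep(sweep(raw, 2L, fm$scale$center), 2L, fm$scale$sd, "/")
  raw
}

#' Twenty-dimensional refinement features
#'
#' The 10 increment-of-diversity values ([id_features]) followed by the 10
#' conservation-weighted matrix scores ([s_features]); within each block
#' the order is property-major (AA, HYD, CHG, SS, SA) with the
#' positive-model value before the negative-model value.
#'
#' @param models per-property \code{position_model} list.
#' @param sources per-property standard-source list.
#' @param segs a [segment_set].
#' @param encodings optional precomputed encodings keyed by property.
#' @return numeric matrix n x 20.
#' @export
refinement_features <- function(models, sources, segs, encodings = NULL) {
  cbind(id_features(sources, segs, encodings = encodings),
        s_features(models, segs, encodings = encodings))
}
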