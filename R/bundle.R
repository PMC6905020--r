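#' Save a trained model bundle
#'
#' Serializes a fitted feature model (position frequency/weight matrices,
#' conservation vectors, backgrounds, diversity sources, standardization)
#' together with the SMO SVM (support vectors, dual coefficients, bias,
#' kernel parameters) to a single human-readable JSON file, so trained
#' models are inspectable, diffable and portable.
#'
#' @param path output JSON path.
#' @param feature_model a [fit_features] result.
#' @param svm an \code{smo_model}.
#' @param config optional named list recorded verbatim (e.g. seed, data
#'   provenance).
#' @export
save_model_bundle <- function(path, feature_model, svm, config = list()) {
  ser_freq <- function(f) list(property = f$property, L = f$L, A = f$A,
                               symbols = f$symbols, n = f$n, N = f$N, p = f$p)
  ser_weight <- function(w) list(m = w$m, p0 = as.numeric(w$p0),
                                 m_min = w$m_min, m_max = w$m_max)
  ser_model <- function(m) list(property = m$property, L = m$L,
                                p0 = as.numeric(m$p0),
                                pos = list(freq = ser_freq(m$pos$freq),
                                           weight = ser_weight(m$pos$weight),
                                           cons = m$pos$cons),
                                neg = list(freq = ser_freq(m$neg$freq),
                                           weight = ser_weight(m$neg$weight),
                                           cons = m$neg$cons))
  ser_source <- function(s) list(counts = as.numeric(s),
                                 property = attr(s, "property"))
  bundle <- list(
    format = "ionseg-model-bundle",
    version = 1L,
    config = config,
    feature_model = list(
      feature_set = feature_model$feature_set, L = feature_model$L,
      background = feature_model$background,
      position_mode = feature_model$position_mode,
      scale = feature_model$scale,
      models = if (is.null(feature_model$models)) NULL else
        lapply(feature_model$models, ser_model),
      sources = if (is.null(feature_model$sources)) NULL else
        lapply(feature_model$sources, function(s)
          list(pos = ser_source(s$pos), neg = ser_source(s$neg)))),
    svm = list(sv = svm$sv, coef = svm$coef, b = svm$b,
               params = unclass(svm$params), dim = svm$dim,
               objective = svm$objective, seed = svm$seed))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trained model bundle
#'
#' @param path JSON path written by [save_model_bundle].
#' @return list with elements \code{feature_model}, \code{svm},
#'   \code{config}.
#' @export
load_model_bundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$format, "ionseg-model-bundle"))
    stop(path, " is not an ionseg model bundle")
  de_freq <- function(f) structure(list(property = f$property, L = f$L,
                                        symbols = f$symbols, A = f$A,
                                        n = as.matrix(f$n), N = f$N,
                                        p = as.matrix(f$p)),
                                   class = "freq_matrix")
  de_weight <- function(w, f) structure(list(property = f$property, L = f$L,
                                             symbols = f$symbols, A = f$A,
                                             m = as.matrix(w$m), p0 = w$p0,
                                             m_min = w$m_min, m_max = w$m_max),
                                        class = "weight_matrix")
  de_model <- function(m) structure(list(property = m$property, L = m$L,
                                         p0 = m$p0,
                                         pos = list(freq = de_freq(m$pos$freq),
                                                    weight = de_weight(m$pos$weight, m$pos$freq),
                                                    cons = m$pos$cons),
                                         neg = list(freq = de_freq(m$neg$freq),
                                                    weight = de_weight(m$neg$weight, m$neg$freq),
                                                    cons = m$neg$cons)),
                                    class = "position_model")
  de_source <- function(s) structure(as.numeric(s$counts),
                                     property = s$property,
                                     total = sum(as.numeric(s$counts)),
                                     class = "diversity_source")
  fmb <- b$feature_model
  fm <- structure(list(feature_set = fmb$feature_set, L = fmb$L,
                       background = fmb$background,
                       position_mode = fmb$position_mode,
                       models = if (is.null(fmb$models)) NULL else
                         lapply(fmb$models, de_model),
                       sources = if (is.null(fmb$sources)) NULL else
                         lapply(fmb$sources, function(s)
                           list(pos = de_source(s$pos), neg = de_source(s$neg))),
                       scale = if (is.null(fmb$scale)) NULL else
                         list(center = fmb$scale$center, sd = fmb$scale$sd)),
                  class = "feature_model")
  sb <- b$svm
  svm <- structure(list(sv = as.matrix(sb$sv), coef = sb$coef, b = sb$b,
                        params = do.call(puk_params, sb$params[c("omega", "sigma", "C", "tolerance")]),
                        scale = NULL, objective = sb$objective,
                        iterations = NA_integer_, gap = NA_real_,
                        seed = sb$seed, dim = sb$dim),
                   class = "smo_model")
  list(feature_model = fm, svm = svm, config = b$config)
}
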