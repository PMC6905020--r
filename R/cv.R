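#' Balanced-resampling stratified cross-validation
#'
#' The negative windows of a residue-level dataset outnumber positives by
#' orders of magnitude, so each of \code{resamples} rounds draws a random
#' negative subset equal in size to the positive set (without replacement),
#' then runs stratified \code{folds}-fold cross-validation on the balanced
#' set. Feature extractors (position matrices, diversity sources,
#' standardization) are fitted on the training folds only. Per resample the
#' fold confusion counts are pooled and metrics computed; the final figures
#' are the arithmetic mean over resamples (\code{fold_averaging =
#' "per_fold"} averages per-fold metrics instead).
#'
#' @param segs a [segment_set] holding all windows (both classes).
#' @param feature_set feature set passed to [fit_features].
#' @param folds number of CV folds (default 5).
#' @param resamples number of balanced negative draws (default 10).
#' @param params [puk_params] for the SVM.
#' @param seed integer seed; the full report is bit-identical for a given
#'   seed.
#' @param background,position_mode passed to [fit_features].
#' @param fold_averaging \code{"pooled"} (pool fold counts per resample,
#'   default) or \code{"per_fold"}.
#' @return a \code{cv_report}: \code{config}, per-fold table \code{folds},
#'   per-resample table \code{resamples}, and \code{average} metrics.
#' @export
balanced_cv <- function(segs, feature_set = "refinement", folds = 5L,
                        resamples = 10L, params = puk_params(), seed = 1L,
                        background = "pooled", position_mode = "weight",
                        fold_averaging = c("pooled", "per_fold")) {
  fold_averaging <- match.arg(fold_averaging)
  pos_i <- which(segs$label == 1L)
  neg_i <- which(segs$label == -1L)
  n_pos <- length(pos_i)
  if (n_pos < folds || length(neg_i) < folds)
    stop("need at least ", folds, " segments of each class")
  if (length(neg_i) < n_pos)
    stop("fewer negatives (", length(neg_i), ") than positives (", n_pos,
         "); balanced resampling is impossible")
  set.seed(as.integer(seed))
  fold_rows <- list()
  res_rows <- list()
  for (r in seq_len(resamples)) {
    bal_neg <- sample(neg_i, n_pos)
    idx <- c(pos_i, bal_neg)
    # stratified: positives and sampled negatives assigned to folds separately
    fold_of <- c(sample(rep_len(seq_len(folds), n_pos)),
                 sample(rep_len(seq_len(folds), n_pos)))
    pooled <- list(TP = 0L, FN = 0L, TN = 0L, FP = 0L)
    per_fold_metrics <- list()
    for (f in seq_len(folds)) {
      tr <- idx[fold_of != f]; te <- idx[fold_of == f]
      if (!length(te)) stop("empty fold; reduce the number of folds")
      cc <- .cv_fold(segs, tr, te, feature_set, params, background,
                     position_mode)
      met <- suppressWarnings(compute_metrics(cc))
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(resample = r, fold = f, TP = cc$TP, FN = cc$FN,
                   TN = cc$TN, FP = cc$FP, sn = met$sn, sp = met$sp,
                   acc = met$acc, mcc = met$mcc)
      pooled <- Map(`+`, pooled, cc[c("TP", "FN", "TN", "FP")])
      per_fold_metrics[[f]] <- met
    }
    rm <- if (fold_averaging == "pooled") {
      suppressWarnings(compute_metrics(pooled))
    } else {
      avg <- function(k) mean(vapply(per_fold_metrics, `[[`, 0, k))
      list(sn = avg("sn"), sp = avg("sp"), acc = avg("acc"), mcc = avg("mcc"))
    }
    res_rows[[r]] <- data.frame(resample = r, sn = rm$sn, sp = rm$sp,
                                acc = rm$acc, mcc = rm$mcc)
  }
  folds_df <- do.call(rbind, fold_rows)
  res_df <- do.call(rbind, res_rows)
  average <- list(sn = mean(res_df$sn), sp = mean(res_df$sp),
                  acc = mean(res_df$acc), mcc = mean(res_df$mcc))
  structure(list(
    config = list(feature_set = feature_set, L = segs$L, folds = folds,
                  resamples = resamples, seed = as.integer(seed),
                  params = params, background = background,
                  position_mode = position_mode,
                  fold_averaging = fold_averaging,
                  n_pos = n_pos, n_neg_pool = length(neg_i)),
    folds = folds_df, resamples = res_df, average = average),
    class = "cv_report")
}

# one train/test fold: fit features + SVM on tr, evaluate on te
.cv_fold <- function(segs, tr, te, feature_set, params, background,
                     position_mode) {
  fm <- fit_features(segs[tr], feature_set = feature_set,
                     background = background, position_mode = position_mode)
  xtr <- feature_transform(fm, segs[tr])
  xte <- feature_transform(fm, segs[te])
  model <- train_smo(xtr, segs$label[tr], params = params, scale = FALSE)
  pred <- predict(model, xte)
  confusion_counts(segs$label[te], pred)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$config$feature_set, "features, L =", x$config$L, ":",
      x$config$resamples, "x", x$config$folds, "balanced CV (seed",
      paste0(x$config$seed, ")\n"))
  cat(sprintf("  average: Sn %.1f%%  Sp %.1f%%  Acc %.1f%%  MCC %.3f\n",
              x$average$sn, x$average$sp, x$average$acc, x$average$mcc))
  invisible(x)
}

#' Write a CV report to TSV and JSON
#'
#' @param report a \code{cv_report}.
#' @param prefix output path prefix; writes \code{<prefix>.tsv} (per-fold
#'   table) and \code{<prefix>.json} (config, per-resample and average
#'   metrics).
#' @export
write_cv_report <- function(report, prefix) {
  utils::write.table(report$folds, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- list(config = report$config[setdiff(names(report$config), "params")],
              puk = unclass(report$config$params),
              resamples = report$resamples, average = report$average)
  jsonlite::write_json(out, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(prefix)
}

#' Window-size scan
#'
#' Runs [balanced_cv] at each odd window length in \code{sizes} and selects
#' the length maximizing the average MCC (ties broken toward the smaller
#' window).
#'
#' @param records list of \code{protein_record} with annotations (and
#'   tracks if the feature set needs them).
#' @param sizes odd window lengths to scan (default 5, 7, ..., 17).
#' @param feature_set,folds,resamples,params,seed,... passed to
#'   [balanced_cv].
#' @return a \code{window_scan} object: \code{reports} (one
#'   \code{cv_report} per size), \code{summary} data.frame, and
#'   \code{best_L}.
#' @export
window_scan <- function(records, sizes = seq(5L, 17L, by = 2L),
                        feature_set = "refinement", folds = 5L,
                        resamples = 10L, params = puk_params(), seed = 1L,
                        ...) {
  sizes <- as.integer(sizes)
  if (any(sizes %% 2L == 0L | sizes < 3L))
    stop("window sizes must be odd integers >= 3")
  reports <- lapply(sizes, function(L) {
    segs <- extract_windows(records, L)
    balanced_cv(segs, feature_set = feature_set, folds = folds,
                resamples = resamples, params = params, seed = seed, ...)
  })
  names(reports) <- as.character(sizes)
  summary <- data.frame(
    L = sizes,
    sn = vapply(reports, function(r) r$average$sn, 0),
    sp = vapply(reports, function(r) r$average$sp, 0),
    acc = vapply(reports, function(r) r$average$acc, 0),
    mcc = vapply(reports, function(r) r$average$mcc, 0))
  best_L <- sizes[which.max(summary$mcc)]  # which.max takes the first max: smaller L wins ties
  structure(list(reports = reports, summary = summary, best_L = best_L),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat("<window_scan> best L =", x$best_L, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
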