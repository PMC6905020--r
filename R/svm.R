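#' Pearson VII universal kernel parameters
#'
#' The PUK kernel's shape exponent \code{omega}, half-width \code{sigma},
#' the SVM box constraint \code{C} and the solver's KKT tolerance. All must
#' be strictly positive. Defaults omega = sigma = C = 1 mirror the common
#' toolkit defaults; none of them is dimensionful once features are
#' standardized.
#'
#' @param omega Pearson-width (tailing) exponent; omega = 1 gives a
#'   Lorentzian profile, large omega approaches a Gaussian.
#' @param sigma kernel half-width on the standardized feature scale.
#' @param C soft-margin box constraint.
#' @param tolerance KKT convergence tolerance of the SMO solver.
#' @return a \code{puk_params} list.
#' @export
puk_params <- function(omega = 1, sigma = 1, C = 1, tolerance = 1e-3) {
  stopifnot(omega > 0, sigma > 0, C > 0, tolerance > 0)
  structure(list(omega = omega, sigma = sigma, C = C, tolerance = tolerance),
            class = "puk_params")
}

#' Pearson VII (PUK) kernel
#'
#' \deqn{K(x, y) = \Big[1 + \big(2\,\lVert x-y\rVert\,
#'   \sqrt{2^{1/\omega}-1}/\sigma\big)^2\Big]^{-\omega} \in (0, 1],}
#' a distance-based universal kernel interpolating between Lorentzian
#' (omega = 1) and Gaussian-like (large omega) profiles. K(x, x) = 1 and K
#' decreases strictly with distance.
#'
#' @param x,y numeric vectors of equal length, or matrices with one
#'   observation per row (then the full cross-kernel matrix is returned).
#' @param params a [puk_params] object.
#' @return scalar kernel value, or an \code{nrow(x) x nrow(y)} matrix.
#' @examples
#' puk_kernel(0, 1, puk_params(omega = 1, sigma = 1))  # 1/(1+4) = 0.2
#' @export
puk_kernel <- function(x, y, params = puk_params()) {
  if (is.matrix(x) || is.matrix(y)) {
    x <- rbind(x); y <- rbind(y)
    if (ncol(x) != ncol(y)) stop("dimension mismatch: ", ncol(x), " vs ", ncol(y))
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    d2[d2 < 0] <- 0
  } else {
    if (length(x) != length(y)) stop("dimension mismatch: ", length(x), " vs ", length(y))
    d2 <- sum((x - y)^2)
  }
  cst <- 4 * (2^(1 / params$omega) - 1) / params$sigma^2
  1 / (1 + cst * d2)^params$omega
}

#' Train a PUK-kernel SVM by sequential minimal optimization
#'
#' Solves the soft-margin SVC dual on the precomputed PUK Gram matrix with
#' a from-scratch SMO solver (maximal-violating-pair working-set selection,
#' analytic two-variable updates). The solver is deterministic; the seed
#' argument is recorded for provenance only.
#'
#' @param x numeric feature matrix (one row per example).
#' @param y labels in \{+1, -1\} (numeric, or a factor/logical coerced with
#'   the positive class mapped to +1).
#' @param params a [puk_params].
#' @param scale standardize columns to zero mean / unit variance before the
#'   kernel (statistics stored in the model). Use \code{FALSE} when the
#'   caller standardized already.
#' @param seed recorded in the model; the fit itself is deterministic.
#' @param max_iter SMO iteration cap.
#' @return an \code{smo_model}: support vectors, dual coefficients
#'   (alpha * y), bias, kernel parameters, scaling statistics, dual
#'   objective and convergence diagnostics.
#' @export
train_smo <- function(x, y, params = puk_params(), scale = TRUE, seed = NULL,
                      max_iter = NULL) {
  x <- as.matrix(x)
  y <- .as_pm1(y)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)")
  if (!all(is.finite(x))) stop("non-finite feature values")
  if (length(unique(y)) < 2L)
    stop("training data contains a single class; need both +1 and -1")
  scl <- NULL
  if (isTRUE(scale)) {
    scl <- list(center = colMeans(x), sd = apply(x, 2L, stats::sd))
    scl$sd[scl$sd == 0 | is.na(scl$sd)] <- 1
    x <- sweep(sweep(x, 2L, scl$center), 2L, scl$sd, "/")
  }
  if (is.null(max_iter)) max_iter <- max(20000L, 300L * nrow(x))
  K <- puk_kernel(x, x, params)
  sol <- smo_solve(K, as.numeric(y), params$C, params$tolerance, max_iter)
  if (!sol$converged)
    stop("SMO did not converge within ", max_iter, " iterations (KKT gap ",
         format(sol$gap), ")")
  sv <- which(sol$alpha > 1e-10 * params$C)
  structure(list(sv = x[sv, , drop = FALSE],
                 coef = sol$alpha[sv] * y[sv],
                 b = sol$b, params = params, scale = scl,
                 objective = sol$objective, iterations = sol$iterations,
                 gap = sol$gap, seed = seed, dim = ncol(x)),
            class = "smo_model")
}

.as_pm1 <- function(y) {
  if (is.factor(y)) y <- as.integer(y == levels(y)[2L]) * 2L - 1L
  if (is.logical(y)) y <- ifelse(y, 1L, -1L)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 / -1")
  y
}

#' @export
print.smo_model <- function(x, ...) {
  cat("<smo_model>", length(x$coef), "support vectors, dim =", x$dim,
      "| dual objective", format(x$objective, digits = 6),
      "| KKT gap", format(x$gap, digits = 3), "\n")
  invisible(x)
}

#' Predict with a trained SMO model
#'
#' Decision value \eqn{f(x) = \sum_i \alpha_i y_i K(x_i, x) + b}; predicted
#' label is its sign, with an exact zero counted as positive.
#'
#' @param object an \code{smo_model}.
#' @param newdata feature matrix on the training layout.
#' @param type \code{"class"} (+1/-1 labels) or \code{"decision"}.
#' @param ... unused.
#' @export
predict.smo_model <- function(object, newdata,
                              type = c("class", "decision"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != object$dim)
    stop("feature dimension ", ncol(x), " != training dimension ", object$dim)
  if (!is.null(object$scale))
    x <- sweep(sweep(x, 2L, object$scale$center), 2L, object$scale$sd, "/")
  dec <- as.vector(puk_kernel(x, object$sv, object$params) %*% object$coef) + object$b
  if (type == "decision") dec else ifelse(dec >= 0, 1L, -1L)
}
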