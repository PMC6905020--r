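#' Cut proteins into overlapping fixed-length windows
#'
#' Slides an odd-length window of length \code{L} along each protein so that
#' every residue appears once as the window centre. \code{(L-1)/2} dummy
#' residues 'X' are appended at both termini, so terminal residues get valid
#' windows too. A window is labelled positive iff its centre residue is an
#' annotated binding position. SS and SA tracks, when present, are windowed
#' alongside the sequence (pads carry 'X' / NA).
#'
#' @param records a \code{protein_record} or list of them.
#' @param L odd window length >= 3.
#' @return a \code{segment_set}: list with per-segment fields
#'   \code{protein_id}, \code{center}, \code{window} (length-L string),
#'   \code{ss} (length-L string or NULL), \code{sa} (n x L matrix or NULL),
#'   \code{label} (+1 / -1), and scalar \code{L}.
#' @examples
#' r <- protein_record("p1", "ACDEF", binding_positions = 3)
#' extract_windows(r, 5)
#' @export
extract_windows <- function(records, L) {
  L <- as.integer(L)
  if (is.na(L) || L < 3L || L %% 2L == 0L)
    stop("window length L must be an odd integer >= 3, got ", L)
  if (inherits(records, "protein_record")) records <- list(records)
  parts <- lapply(records, .windows_one, L = L)
  segs <- list(
    protein_id = unlist(lapply(parts, `[[`, "protein_id"), use.names = FALSE),
    center = unlist(lapply(parts, `[[`, "center"), use.names = FALSE),
    window = unlist(lapply(parts, `[[`, "window"), use.names = FALSE),
    ss = NULL, sa = NULL,
    label = unlist(lapply(parts, `[[`, "label"), use.names = FALSE),
    L = L)
  has_ss <- vapply(parts, function(p) !is.null(p$ss), TRUE)
  has_sa <- vapply(parts, function(p) !is.null(p$sa), TRUE)
  if (all(has_ss)) segs$ss <- unlist(lapply(parts, `[[`, "ss"), use.names = FALSE)
  if (all(has_sa)) segs$sa <- do.call(rbind, lapply(parts, `[[`, "sa"))
  structure(segs, class = "segment_set")
}

.windows_one <- function(record, L) {
  stopifnot(inherits(record, "protein_record"))
  n <- nchar(record$sequence)
  w <- (L - 1L) %/% 2L
  pad <- strrep("X", w)
  padded <- paste0(pad, record$sequence, pad)
  starts <- seq_len(n)
  window <- substring(padded, starts, starts + L - 1L)
  label <- ifelse(seq_len(n) %in% record$binding_positions, 1L, -1L)
  out <- list(protein_id = rep(record$id, n), center = seq_len(n),
              window = window, label = label, ss = NULL, sa = NULL)
  if (!is.null(record$ss_track)) {
    padded_ss <- paste0(pad, record$ss_track, pad)
    out$ss <- substring(padded_ss, starts, starts + L - 1L)
  }
  if (!is.null(record$sa_track)) {
    padded_sa <- c(rep(NA_real_, w), record$sa_track, rep(NA_real_, w))
    out$sa <- t(vapply(starts, function(s) padded_sa[s:(s + L - 1L)],
                       numeric(L)))
  }
  out
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set>", length(x$window), "segments, L =", x$L, ";",
      sum(x$label == 1L), "positive /", sum(x$label == -1L), "negative;",
      if (is.null(x$ss)) "no SS;" else "SS;",
      if (is.null(x$sa)) "no SA\n" else "SA\n")
  invisible(x)
}

#' @export
length.segment_set <- function(x) length(x$window)

#' Subset a segment set
#' @param x a \code{segment_set}.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.segment_set` <- function(x, i, ...) {
  structure(list(protein_id = x$protein_id[i], center = x$center[i],
                 window = x$window[i],
                 ss = if (is.null(x$ss)) NULL else x$ss[i],
                 sa = if (is.null(x$sa)) NULL else x$sa[i, , drop = FALSE],
                 label = x$label[i], L = x$L),
            class = "segment_set")
}

#' Bind segment sets with equal L
#' @param ... segment sets.
#' @export
c.segment_set <- function(...) {
  xs <- list(...)
  Ls <- unique(vapply(xs, `[[`, 0L, "L"))
  if (length(Ls) != 1L) stop("segment sets have different window lengths")
  all_ss <- all(vapply(xs, function(x) !is.null(x$ss), TRUE))
  all_sa <- all(vapply(xs, function(x) !is.null(x$sa), TRUE))
  structure(list(
    protein_id = unlist(lapply(xs, `[[`, "protein_id"), use.names = FALSE),
    center = unlist(lapply(xs, `[[`, "center"), use.names = FALSE),
    window = unlist(lapply(xs, `[[`, "window"), use.names = FALSE),
    ss = if (all_ss) unlist(lapply(xs, `[[`, "ss"), use.names = FALSE) else NULL,
    sa = if (all_sa) do.call(rbind, lapply(xs, `[[`, "sa")) else NULL,
    label = unlist(lapply(xs, `[[`, "label"), use.names = FALSE),
    L = Ls), class = "segment_set")
}
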