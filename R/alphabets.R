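#' @title Property alphabets
#' @description
#' The five residue-property alphabets used throughout the package. Symbol
#' order is fixed and feature vectors are order-sensitive; the last symbol of
#' every alphabet is its pad class, to which the dummy residue 'X' (and any
#' position outside the protein) maps.
#'
#' \itemize{
#'   \item \code{AA}: the 20 standard amino acids (alphabetical one-letter
#'     order) plus the pseudo amino acid \code{X} (21 symbols; \code{X} is
#'     both the 21st residue symbol and the pad class).
#'   \item \code{HYD}: hydropathy classes — strongly hydrophilic
#'     (R,D,E,N,Q,K,H), strongly hydrophobic (L,I,V,A,M,F), weakly
#'     hydrophilic (S,T,Y,W), proline, glycine, cysteine, pad (7).
#'   \item \code{CHG}: polarization charge — positive (K,R,P), negative
#'     (D,E), uncharged (rest), pad (4).
#'   \item \code{SS}: predicted secondary structure — helix \code{H}, sheet
#'     \code{E}, coil \code{C}, pad (4).
#'   \item \code{SA}: relative solvent accessibility — exposed (value
#'     strictly greater than 0.25), buried, pad (3).
#' }
#' @format A named list of alphabet objects with elements \code{name},
#'   \code{symbols} (ordered, pad last) and \code{pad} (the pad symbol).
#' @export
ion_alphabets <- local({
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk <- function(name, symbols) {
    structure(list(name = name, symbols = symbols, pad = symbols[length(symbols)],
                   size = length(symbols)),
              class = "property_alphabet")
  }
  list(
    AA  = mk("AA", c(aa20, "X")),
    HYD = mk("HYD", c("sphil", "sphob", "wphil", "pro", "gly", "cys", "pad")),
    CHG = mk("CHG", c("pos", "neg", "unc", "pad")),
    SS  = mk("SS", c("H", "E", "C", "pad")),
    SA  = mk("SA", c("exp", "bur", "pad"))
  )
})

#' @export
print.property_alphabet <- function(x, ...) {
  cat("Property alphabet", x$name, "with", x$size, "symbols:",
      paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

# Fixed property order used for every concatenated feature block.
PROPERTY_ORDER <- c("AA", "HYD", "CHG", "SS", "SA")

# residue letter -> class index lookups (pad/unknown handled by the callers)
.hyd_class <- local({
  m <- character(0)
  m[strsplit("RDENQKH", "")[[1]]] <- "sphil"
  m[strsplit("LIVAMF", "")[[1]]]  <- "sphob"
  m[strsplit("STYW", "")[[1]]]    <- "wphil"
  m["P"] <- "pro"; m["G"] <- "gly"; m["C"] <- "cys"
  m
})

.chg_class <- local({
  m <- character(0)
  m[c("K", "R", "P")] <- "pos"
  m[c("D", "E")] <- "neg"
  rest <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                  c("K", "R", "P", "D", "E"))
  m[rest] <- "unc"
  m
})

#' Encode one segment under a property alphabet
#'
#' Maps every position of a window to its symbol under the chosen property.
#' Pad positions (the dummy residue 'X') always map to the alphabet's pad
#' class. The \code{SS} and \code{SA} properties read the segment's
#' secondary-structure and solvent-accessibility tracks rather than the
#' residue letters; an SA value strictly greater than 0.25 is exposed,
#' otherwise buried.
#'
#' @param segment a single-row [segment_set] (see [extract_windows]), or a
#'   plain character string of residues for the residue-based properties.
#' @param property one of \code{"AA"}, \code{"HYD"}, \code{"CHG"},
#'   \code{"SS"}, \code{"SA"}.
#' @return character vector of length L of symbol names.
#' @examples
#' encode_segment("XKDAX", "CHG")
#' encode_segment("RLSPG", "HYD")
#' @export
encode_segment <- function(segment, property) {
  property <- match.arg(property, PROPERTY_ORDER)
  if (is.character(segment) && length(segment) == 1L) {
    if (property %in% c("SS", "SA"))
      stop("property '", property, "' needs a segment with tracks, not a bare string")
    segment <- .string_only_segments(segment)
  }
  enc <- encode_matrix(segment, property)
  ion_alphabets[[property]]$symbols[enc[1L, ]]
}

# minimal segment_set wrapper around bare window strings (residue props only)
.string_only_segments <- function(windows) {
  if (!length(windows)) stop("at least one segment is required")
  L <- unique(nchar(windows))
  if (length(L) != 1L) stop("windows have unequal lengths")
  structure(list(protein_id = rep("seg", length(windows)),
                 center = rep(NA_integer_, length(windows)),
                 window = toupper(windows), ss = NULL, sa = NULL,
                 label = rep(-1L, length(windows)), L = as.integer(L)),
            class = "segment_set")
}

#' Encode a segment set as an integer symbol matrix
#'
#' Workhorse encoder: one row per segment, one column per window position,
#' entries are 1-based indices into the property alphabet's symbol order.
#'
#' @param segs a [segment_set].
#' @param property property name (see [ion_alphabets]).
#' @return integer matrix n x L with attribute \code{"alphabet"}.
#' @export
encode_matrix <- function(segs, property) {
  property <- match.arg(property, PROPERTY_ORDER)
  ab <- ion_alphabets[[property]]
  n <- length(segs$window)
  L <- segs$L
  chars <- matrix(unlist(strsplit(segs$window, ""), use.names = FALSE),
                  nrow = n, ncol = L, byrow = TRUE)
  enc <- switch(property,
    AA = {
      e <- match(chars, ab$symbols)
      e[is.na(e)] <- ab$size  # unknown residue -> X class
      e
    },
    HYD = {
      cls <- .hyd_class[chars]
      e <- match(cls, ab$symbols)
      e[is.na(e)] <- ab$size
      e
    },
    CHG = {
      cls <- .chg_class[chars]
      e <- match(cls, ab$symbols)
      e[is.na(e)] <- ab$size
      e
    },
    SS = {
      if (is.null(segs$ss))
        stop("secondary-structure track missing for protein(s) ",
             paste(unique(segs$protein_id), collapse = ","),
             "; property SS cannot be encoded")
      sschars <- matrix(unlist(strsplit(segs$ss, ""), use.names = FALSE),
                        nrow = n, ncol = L, byrow = TRUE)
      e <- match(sschars, ab$symbols)
      e[is.na(e)] <- ab$size  # pads carry 'X'
      e
    },
    SA = {
      if (is.null(segs$sa))
        stop("solvent-accessibility track missing for protein(s) ",
             paste(unique(segs$protein_id), collapse = ","),
             "; property SA cannot be encoded")
      sa <- segs$sa
      e <- ifelse(is.na(sa), ab$size, ifelse(sa > 0.25, 1L, 2L))
      matrix(as.integer(e), nrow = n, ncol = L)
    })
  enc <- matrix(as.integer(enc), nrow = n, ncol = L)
  attr(enc, "alphabet") <- ab
  enc
}

#' Composition vector of an encoded segment
#'
#' Frequency of each alphabet symbol in one encoded window, in the
#' alphabet's fixed symbol order. Entries are nonnegative and sum to 1.
#'
#' @param encoded character vector of symbols (as from [encode_segment]) or
#'   an integer-encoded row.
#' @param property property name.
#' @return numeric vector of length = alphabet size, named by symbol.
#' @export
composition_vector <- function(encoded, property) {
  property <- match.arg(property, PROPERTY_ORDER)
  ab <- ion_alphabets[[property]]
  if (is.character(encoded)) {
    idx <- match(encoded, ab$symbols)
    if (anyNA(idx))
      stop("symbol(s) outside the ", property, " alphabet: ",
           paste(unique(encoded[is.na(idx)]), collapse = ","))
  } else idx <- as.integer(encoded)
  if (length(idx) == 0L) stop("empty segment")
  v <- tabulate(idx, nbins = ab$size) / length(idx)
  names(v) <- ab$symbols
  v
}

# composition matrix for all segments of one property: n x A
.composition_matrix <- function(enc) {
  ab <- attr(enc, "alphabet")
  n <- nrow(enc); A <- ab$size
  counts <- matrix(0L, n, A)
  for (j in seq_len(A)) counts[, j] <- rowSums(enc == j)
  counts / ncol(enc)
}

# raw symbol counts per segment: n x A integer
.count_matrix <- function(enc) {
  ab <- attr(enc, "alphabet")
  n <- nrow(enc); A <- ab$size
  counts <- matrix(0L, n, A)
  for (j in seq_len(A)) counts[, j] <- rowSums(enc == j)
  counts
}

#' Component (composition) features over all five properties
#'
#' Concatenates the composition vectors of a segment set under AA, HYD, CHG,
#' SS and SA, in that order, giving a 21+7+4+4+3 = 39-dimensional vector per
#' segment. Each block sums to 1, so the full vector sums to 5.
#'
#' @param segs a [segment_set] with SS and SA tracks attached.
#' @return numeric matrix n x 39 with named columns
#'   \code{<property>.<symbol>}.
#' @export
component_features <- function(segs) {
  blocks <- lapply(PROPERTY_ORDER, function(p) {
    enc <- encode_matrix(segs, p)
    m <- .composition_matrix(enc)
    colnames(m) <- paste(p, ion_alphabets[[p]]$symbols, sep = ".")
    m
  })
  do.call(cbind, blocks)
}
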