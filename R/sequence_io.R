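#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a list of protein records with empty binding
#' annotations. Record ids are the first whitespace-delimited token of the
#' header; sequences are uppercased. Nonstandard residue letters
#' (B, Z, U, O, J) are mapped to the unknown residue 'X' with a warning.
#'
#' @param path path to a FASTA file.
#' @return list of \code{protein_record} objects (fields \code{id},
#'   \code{sequence}, \code{binding_positions}, \code{ss_track},
#'   \code{sa_track}).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  seqs <- toupper(as.character(set))
  if (any(grepl("[0-9]", seqs)))
    stop("sequence containing digits in ", path, " (ids: ",
         paste(ids[grepl("[0-9]", seqs)], collapse = ","), ")")
  bad <- grepl("[BZUOJ]", seqs)
  if (any(bad)) {
    warning("nonstandard residue letters (B/Z/U/O/J) mapped to 'X' in: ",
            paste(ids[bad], collapse = ","))
    seqs <- gsub("[BZUOJ]", "X", seqs)
  }
  recs <- Map(function(id, s) protein_record(id, s), ids, seqs)
  names(recs) <- ids
  recs
}

#' Construct a protein record
#'
#' @param id record identifier.
#' @param sequence residue string (uppercased).
#' @param binding_positions integer vector of 1-based binding residue
#'   indices.
#' @param ss_track optional H/E/C string of the same length as
#'   \code{sequence}.
#' @param sa_track optional numeric vector in [0,1] of the same length.
#' @return a \code{protein_record}.
#' @export
protein_record <- function(id, sequence, binding_positions = integer(0),
                           ss_track = NULL, sa_track = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  binding_positions <- sort(unique(as.integer(binding_positions)))
  if (length(binding_positions) &&
      (min(binding_positions) < 1L || max(binding_positions) > n))
    stop("binding position out of range [1,", n, "] for protein ", id)
  if (!is.null(ss_track) && nchar(ss_track) != n)
    stop("ss_track length ", nchar(ss_track), " != sequence length ", n,
         " for protein ", id)
  if (!is.null(sa_track) && length(sa_track) != n)
    stop("sa_track length ", length(sa_track), " != sequence length ", n,
         " for protein ", id)
  structure(list(id = id, sequence = sequence,
                 binding_positions = binding_positions,
                 ss_track = ss_track, sa_track = sa_track),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, "-", nchar(x$sequence), "residues,",
      length(x$binding_positions), "binding;",
      if (is.null(x$ss_track)) "no SS;" else "SS;",
      if (is.null(x$sa_track)) "no SA\n" else "SA\n")
  invisible(x)
}

#' Write protein records to FASTA
#'
#' @param records list of \code{protein_record}.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read binding-site annotations
#'
#' Parses a tab-separated annotation file with columns
#' \code{protein_id}, \code{ligand_id}, \code{positions} (space-separated
#' 1-based residue indices) and merges the positions into the matching
#' records (union over rows). Rows can optionally be restricted to one
#' ligand id.
#'
#' @param path annotation TSV path.
#' @param records list of \code{protein_record} to annotate.
#' @param ligand optional ligand id; when given, only matching rows are
#'   used. Default pools all rows.
#' @return the records with \code{binding_positions} populated.
#' @export
read_binding_annotations <- function(path, records, ligand = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  ids <- vapply(records, `[[`, "", "id")
  names(records) <- ids
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed annotation row (need 3 tab fields): ", ln)
    pid <- f[1]; lig <- f[2]
    if (!is.null(ligand) && lig != ligand) next
    if (!pid %in% ids) stop("annotation references unknown protein id: ", pid)
    toks <- strsplit(trimws(f[3]), "[[:space:]]+")[[1]]
    pos <- suppressWarnings(as.integer(toks))
    if (anyNA(pos)) stop("malformed position '", toks[which(is.na(pos))[1]],
                         "' for protein ", pid)
    n <- nchar(records[[pid]]$sequence)
    if (any(pos < 1L | pos > n))
      stop("binding position ", pos[which(pos < 1L | pos > n)[1]],
           " out of range [1,", n, "] for protein ", pid)
    records[[pid]]$binding_positions <-
      sort(unique(c(records[[pid]]$binding_positions, pos)))
  }
  records
}

#' Write binding-site annotations
#'
#' @param records list of \code{protein_record}.
#' @param path output TSV path.
#' @param ligand ligand id written in the second column.
#' @export
write_binding_annotations <- function(records, path, ligand = "ION") {
  rows <- vapply(records, function(r) {
    if (!length(r$binding_positions)) return(NA_character_)
    paste(r$id, ligand, paste(r$binding_positions, collapse = " "), sep = "\t")
  }, "")
  writeLines(rows[!is.na(rows)], path)
  invisible(path)
}

#' Attach predicted structure tracks to records
#'
#' Reads per-protein secondary-structure strings (H/E/C) and/or relative
#' solvent-accessibility values in [0,1] from tab-separated files and
#' attaches them, length-checked, to the records. SA values outside [0,1]
#' by at most 1e-9 are clamped with a warning; larger excursions are
#' errors. The tracks are consumed as given (they come from an upstream
#' structure predictor); no prediction happens here.
#'
#' @param records list of \code{protein_record}.
#' @param ss_path optional TSV \code{protein_id<TAB>ss_string}.
#' @param sa_path optional TSV \code{protein_id<TAB>v1 v2 ...}.
#' @return records with tracks attached.
#' @export
attach_tracks <- function(records, ss_path = NULL, sa_path = NULL) {
  ids <- vapply(records, `[[`, "", "id")
  names(records) <- ids
  if (!is.null(ss_path)) {
    for (ln in .track_lines(ss_path)) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      pid <- f[1]; ss <- gsub("[[:space:]]", "", f[2])
      if (!pid %in% ids) stop("SS track references unknown protein id: ", pid)
      n <- nchar(records[[pid]]$sequence)
      if (nchar(ss) != n)
        stop("SS track length ", nchar(ss), " != sequence length ", n,
             " for protein ", pid)
      if (grepl("[^HEC]", ss))
        stop("SS track for ", pid, " contains letters outside {H,E,C}")
      records[[pid]]$ss_track <- ss
    }
  }
  if (!is.null(sa_path)) {
    for (ln in .track_lines(sa_path)) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      pid <- f[1]
      if (!pid %in% ids) stop("SA track references unknown protein id: ", pid)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(f[2]), "[[:space:]]+")[[1]]))
      if (anyNA(vals)) stop("unparseable SA value for protein ", pid)
      n <- nchar(records[[pid]]$sequence)
      if (length(vals) != n)
        stop("SA track length ", length(vals), " != sequence length ", n,
             " for protein ", pid)
      out <- vals < 0 | vals > 1
      if (any(out)) {
        if (all(vals[out] > -1e-9 & vals[out] < 1 + 1e-9)) {
          warning("SA values for ", pid, " clamped to [0,1]")
          vals <- pmin(pmax(vals, 0), 1)
        } else stop("SA value outside [0,1] for protein ", pid)
      }
      records[[pid]]$sa_track <- vals
    }
  }
  records
}

.track_lines <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  lines <- readLines(path)
  lines[!grepl("^\\s*(#|$)", lines)]
}

#' Write structure tracks
#'
#' @param records list of \code{protein_record}.
#' @param ss_path,sa_path output paths (either may be NULL to skip).
#' @export
write_tracks <- function(records, ss_path = NULL, sa_path = NULL) {
  if (!is.null(ss_path)) {
    rows <- vapply(records, function(r)
      if (is.null(r$ss_track)) NA_character_ else paste(r$id, r$ss_track, sep = "\t"), "")
    writeLines(rows[!is.na(rows)], ss_path)
  }
  if (!is.null(sa_path)) {
    rows <- vapply(records, function(r)
      if (is.null(r$sa_track)) NA_character_ else
        paste(r$id, paste(formatC(r$sa_track, format = "g", digits = 10),
                          collapse = " "), sep = "\t"), "")
    writeLines(rows[!is.na(rows)], sa_path)
  }
  invisible(NULL)
}

#' Filter records by minimum sequence length
#'
#' Optional dataset-construction filter (chains shorter than a cutoff carry
#' little window context); disabled by default.
#'
#' @param records list of \code{protein_record}.
#' @param min_length keep records with strictly more residues than this.
#' @export
filter_by_length <- function(records, min_length = 50L) {
  records[vapply(records, function(r) nchar(r$sequence) > min_length, TRUE)]
}
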