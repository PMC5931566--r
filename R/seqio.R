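#' Construct a set of protein records
#'
#' A protein set is a plain data frame with one row per protein and columns
#' `id`, `description`, `sequence`, `length` plus the annotation columns
#' `compartment` (one of C/M/O), `go_terms` (list column), `phospho`
#' (logical), `psm` (integer) and `partial` (logical). Sequences are
#' uppercased and validated against the 21-letter alphabet (20 canonical
#' amino acids plus the ambiguity code X).
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param description Free-text descriptions (default empty).
#' @param compartment Optional compartment codes in `{C, M, O}` (NA allowed).
#' @param go_terms Optional list of character vectors of GO terms.
#' @param phospho,partial Optional logical flags (NA allowed).
#' @param psm Optional non-negative integer peptide-spectrum-match counts.
#' @return Data frame of class `protein_set`.
#' @export
protein_records <- function(id, sequence, description = "",
                            compartment = NA_character_, go_terms = NULL,
                            phospho = NA, psm = NA_integer_, partial = NA) {
  n <- length(id)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != n) stop("id and sequence lengths differ", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate protein ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  validate_sequences(sequence, id)
  if (is.null(go_terms)) go_terms <- rep(list(character(0)), n)
  compartment <- as.character(rep_len(compartment, n))
  bad <- !is.na(compartment) & !compartment %in% c("C", "M", "O")
  if (any(bad)) {
    stop("unknown compartment code(s): ",
         paste(unique(compartment[bad]), collapse = ", "), call. = FALSE)
  }
  psm <- rep_len(as.integer(psm), n)
  if (any(!is.na(psm) & psm < 0)) stop("psm must be non-negative", call. = FALSE)
  out <- data.frame(
    id = id,
    description = rep_len(as.character(description), n),
    sequence = sequence,
    length = nchar(sequence),
    compartment = compartment,
    phospho = rep_len(as.logical(phospho), n),
    psm = psm,
    partial = rep_len(as.logical(partial), n),
    stringsAsFactors = FALSE
  )
  out$go_terms <- go_terms
  class(out) <- c("protein_set", "data.frame")
  out
}

# Reject empty sequences and characters outside {20 AA} + X, naming the
# offending record and 1-based position.
validate_sequences <- function(sequence, id) {
  if (any(!nzchar(sequence))) {
    stop("empty sequence for record ", id[!nzchar(sequence)][1], call. = FALSE)
  }
  hit <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  bad <- which(hit > 0)
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf("illegal residue '%s' in record %s at position %d",
                 substr(sequence[i], hit[i], hit[i]), id[i], hit[i]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' The header up to the first whitespace is the record id, the remainder the
#' description. Sequences are uppercased; any character outside the 20
#' canonical amino acids plus X, and any duplicated id, is a parse error.
#'
#' @param path Path to a FASTA file.
#' @return A `protein_set` data frame (empty, with a warning, for an empty
#'   file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("malformed FASTA in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (length(aa) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(protein_records(character(0), character(0)))
  }
  headers <- names(aa)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 trimws(sub("^\\S+\\s+", "", headers)), "")
  protein_records(id = id, sequence = as.character(aa), description = desc)
}

#' Write protein records to a FASTA file
#'
#' @param records A `protein_set` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(nzchar(records$description),
                paste(records$id, records$description), records$id)
  aa <- Biostrings::AAStringSet(setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read per-residue score tracks from TSV
#'
#' Expects columns `protein_id`, `predictor`, `position`, `score`. Positions
#' must be contiguous from 1 within each (protein, predictor) track; when
#' `records` is supplied each track must be exactly as long as its protein.
#' This is also the import interface for externally computed predictor
#' output (e.g. neural-network predictors that cannot be run locally).
#'
#' @param path TSV file with a header row; `#` comment lines are skipped.
#' @param records Optional `protein_set` to validate track lengths against.
#' @return Long data frame `protein_id`, `predictor`, `position`, `score`,
#'   ordered by (protein_id, predictor, position).
#' @export
read_score_table <- function(path, records = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "predictor", "position", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("score table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  df$position <- as.integer(df$position)
  df$score <- as.numeric(df$score)
  validate_score_tracks(df, records)
}

# Shared validation for internally built and imported score tables.
validate_score_tracks <- function(df, records = NULL) {
  df <- df[order(df$protein_id, df$predictor, df$position), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$protein_id, df$predictor, sep = "\r")
  for (k in unique(key)) {
    pos <- df$position[key == k]
    L <- length(pos)
    if (!identical(pos, seq_len(L))) {
      stop("track ", sub("\r", "/", k),
           ": positions must be contiguous 1..L without gaps or duplicates",
           call. = FALSE)
    }
    if (!is.null(records)) {
      pid <- df$protein_id[key == k][1]
      j <- match(pid, records$id)
      if (is.na(j)) stop("track references unknown protein ", pid, call. = FALSE)
      if (records$length[j] != L) {
        stop("track ", sub("\r", "/", k), " has length ", L,
             " but protein has length ", records$length[j], call. = FALSE)
      }
    }
  }
  df
}

#' Write score (or call) tracks as TSV
#'
#' Schema mirrors [read_score_table()] so that package output can be
#' re-imported unchanged.
#'
#' @param tracks Long data frame `protein_id`, `predictor`, `position`,
#'   `score`.
#' @param path Output path.
#' @param provenance Optional provenance header (see [write_report_tsv()]).
#' @return The path, invisibly.
#' @export
write_score_table <- function(tracks, path, provenance = NULL) {
  write_report_tsv(tracks, path, provenance)
}

#' Attach annotations to protein records
#'
#' Reads a TSV keyed by protein id with any of the columns `compartment`
#' (C/M/O), `go_terms` (`;`-separated), `phospho` (0/1), `psm` (integer),
#' `partial` (0/1) and fills the matching columns of `records`. Ids absent
#' from the table keep empty annotations; table rows whose id matches no
#' record are skipped with a warning; unknown compartment codes are an
#' error.
#'
#' @param path Annotation TSV with a `protein_id` column.
#' @param records A `protein_set` data frame.
#' @return The annotated `protein_set`.
#' @export
read_annotations <- function(path, records) {
  ann <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(ann)) {
    stop("annotation table must have a protein_id column", call. = FALSE)
  }
  unknown <- !ann$protein_id %in% records$id
  if (any(unknown)) {
    warning("skipping ", sum(unknown),
            " annotation row(s) with unknown protein id: ",
            paste(utils::head(ann$protein_id[unknown], 5), collapse = ", "),
            call. = FALSE)
    ann <- ann[!unknown, , drop = FALSE]
  }
  idx <- match(ann$protein_id, records$id)
  if ("compartment" %in% names(ann)) {
    comp <- as.character(ann$compartment)
    bad <- !is.na(comp) & !comp %in% c("C", "M", "O")
    if (any(bad)) {
      stop("unknown compartment code(s): ",
           paste(unique(comp[bad]), collapse = ", "), call. = FALSE)
    }
    records$compartment[idx] <- comp
  }
  if ("phospho" %in% names(ann)) records$phospho[idx] <- as.logical(as.integer(ann$phospho))
  if ("partial" %in% names(ann)) records$partial[idx] <- as.logical(as.integer(ann$partial))
  if ("psm" %in% names(ann)) records$psm[idx] <- as.integer(ann$psm)
  if ("go_terms" %in% names(ann)) {
    terms <- strsplit(as.character(ann$go_terms), "[;,]\\s*")
    terms <- lapply(terms, function(x) x[nzchar(x)])
    records$go_terms[idx] <- terms
  }
  records
}

#' Filter records on spectral support and sequence completeness
#'
#' Mirrors the record-level filters applied to mass-spectrometry
#' identifications before disorder analysis: keep proteins with at least
#' `min_psm` peptide-spectrum matches and drop proteins for which only a
#' partial sequence is available. Records lacking the `psm` annotation are
#' treated as having unlimited support, and records lacking the `partial`
#' flag as complete, so the filters only ever act on explicit flags.
#'
#' @param records A `protein_set` data frame.
#' @param min_psm Minimum PSM count to keep (default 0).
#' @param exclude_partial Drop records flagged partial (default TRUE).
#' @return The filtered `protein_set`, original order preserved.
#' @export
filter_records <- function(records, min_psm = 0, exclude_partial = TRUE) {
  psm <- ifelse(is.na(records$psm), Inf, records$psm)
  partial <- ifelse(is.na(records$partial), FALSE, records$partial)
  keep <- psm >= min_psm & (!exclude_partial | !partial)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
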