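#' Length of the longest disordered run
#'
#' @param calls Logical per-residue call vector (`TRUE` = disordered).
#' @return Integer length of the longest maximal run of `TRUE`; 0 if none.
#' @export
longest_run <- function(calls) {
  if (length(calls) == 0) stop("empty call track", call. = FALSE)
  r <- rle(as.logical(calls))
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else as.integer(max(runs))
}

#' Percent of disordered residues
#'
#' @param calls Logical per-residue call vector.
#' @return `100 * sum(calls) / length(calls)`.
#' @export
percent_disorder <- function(calls) {
  if (length(calls) == 0) stop("empty call track", call. = FALSE)
  100 * sum(calls) / length(calls)
}

# Fixed LDR bin labels, partitioning the non-negative integers.
ldr_bin_labels <- function() c("0~9", "10~29", "30~49", "50~99", "100<")

#' Bin a longest-disordered-region length
#'
#' Inclusive integer bins `0~9`, `10~29`, `30~49`, `50~99`, and `100<`
#' (meaning LDR >= 100), jointly partitioning all non-negative integers.
#'
#' @param ldr Integer vector of LDR values (>= 0).
#' @return Character vector of bin labels.
#' @export
ldr_bin <- function(ldr) {
  if (any(ldr < 0)) stop("ldr must be non-negative", call. = FALSE)
  cut(ldr, breaks = c(-1, 9, 29, 49, 99, Inf),
      labels = ldr_bin_labels()) |> as.character()
}

#' Per-protein, per-predictor disorder summaries
#'
#' @param calls Long call data frame (`protein_id`, `predictor`, `position`,
#'   `call`), e.g. from [predict_disorder()].
#' @param records The `protein_set` the calls refer to; a call track for a
#'   protein absent from `records`, or of the wrong length, is an error.
#' @return Data frame with one row per (protein, predictor), ordered by
#'   (protein_id, predictor): `protein_id`, `predictor`, `length`,
#'   `n_disordered`, `percent_disorder`, `ldr`, `ldr_bin`.
#' @export
summarize_disorder <- function(calls, records) {
  calls <- calls[order(calls$protein_id, calls$predictor, calls$position), ]
  key <- paste(calls$protein_id, calls$predictor, sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  rows <- lapply(groups, function(ix) {
    pid <- calls$protein_id[ix[1]]
    j <- match(pid, records$id)
    if (is.na(j)) stop("call track for unknown protein ", pid, call. = FALSE)
    v <- as.logical(calls$call[ix])
    if (length(v) != records$length[j]) {
      stop("call track for ", pid, " has length ", length(v),
           " but protein has length ", records$length[j], call. = FALSE)
    }
    L <- longest_run(v)
    data.frame(protein_id = pid, predictor = calls$predictor[ix[1]],
               length = length(v), n_disordered = sum(v),
               percent_disorder = percent_disorder(v),
               ldr = L, ldr_bin = ldr_bin(L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$protein_id, out$predictor), ]
  rownames(out) <- NULL
  out
}

#' Per-predictor LDR-bin frequency table
#'
#' Tabulates, per predictor, how many proteins fall in each LDR length
#' range, with percentages relative to the total number of proteins
#' (rounded half-up to one decimal in `percent_rounded`; the raw value is
#' kept in `percent`).
#'
#' @param summaries Output of [summarize_disorder()] over one protein
#'   universe.
#' @param total Denominator for percentages; defaults to the number of
#'   proteins summarised for each predictor.
#' @return Data frame `predictor`, `ldr_bin`, `count`, `percent`,
#'   `percent_rounded` with all five bins present for every predictor.
#' @export
bin_frequency_table <- function(summaries, total = NULL) {
  if (nrow(summaries) == 0) {
    return(data.frame(predictor = character(0), ldr_bin = character(0),
                      count = integer(0), percent = numeric(0),
                      percent_rounded = numeric(0), stringsAsFactors = FALSE))
  }
  labs <- ldr_bin_labels()
  rows <- lapply(split(summaries, summaries$predictor), function(s) {
    n <- if (is.null(total)) nrow(s) else total
    cnt <- table(factor(s$ldr_bin, levels = labs))
    data.frame(predictor = s$predictor[1], ldr_bin = labs,
               count = as.integer(cnt), percent = 100 * as.integer(cnt) / n,
               percent_rounded = round_half_up(100 * as.integer(cnt) / n, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
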