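# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals (reports use half-up at one
# decimal; base round() is round-half-even and would print 2.25 -> 2.2).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's random stream. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sliding-window weighted mean with truncation at the ends.
# vals: per-position values (0 where weight is 0), w: 0/1 weights,
# window: odd width. Positions whose window holds no weighted residue get NA.
window_mean <- function(vals, w, window) {
  L <- length(vals)
  half <- window %/% 2
  cs_v <- c(0, cumsum(vals * w))
  cs_w <- c(0, cumsum(w))
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + half, L)
  tot <- cs_v[hi + 1L] - cs_v[lo]
  cnt <- cs_w[hi + 1L] - cs_w[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

check_odd_window <- function(window, minimum = 1) {
  if (length(window) != 1 || !is.finite(window) || window < minimum ||
      window %% 2 != 1) {
    stop("`window` must be an odd integer >= ", minimum, ", got ", window,
         call. = FALSE)
  }
  as.integer(window)
}

# Split a sequence string into a character vector of residues.
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# Atomic text write: write to a temp file in the target directory, then rename.
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

# Serialise a data.frame as TSV lines (no quoting; logical as 0/1).
df_to_tsv_lines <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.logical(df[[j]])) df[[j]] <- as.integer(df[[j]])
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(x) paste(x, collapse = ";"), "")
    }
  }
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0) return(header)
  body <- do.call(paste, c(lapply(df, format, trim = TRUE, scientific = FALSE,
                                  digits = 15),
                           sep = "\t"))
  c(header, body)
}

#' Write a report table as TSV
#'
#' Writes a tab-separated table with optional `#`-prefixed provenance header
#' lines (package version, seed, parameters). The file is written atomically
#' (temp file + rename) so a failed run never leaves a partial report.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param provenance Optional named list recorded as `# key: value` lines.
#' @return The path, invisibly.
#' @export
write_report_tsv <- function(df, path, provenance = NULL) {
  head_lines <- character(0)
  if (!is.null(provenance)) {
    prov <- c(list(package = paste0("idptools ",
                                    as.character(utils::packageVersion("idptools")))),
              provenance)
    head_lines <- vapply(seq_along(prov), function(i) {
      sprintf("# %s: %s", names(prov)[i], paste(prov[[i]], collapse = " "))
    }, "")
  }
  write_lines_atomic(c(head_lines, df_to_tsv_lines(df)), path)
}

#' Read a report TSV written by [write_report_tsv()]
#'
#' @param path File path; `#` header lines are skipped.
#' @return Data frame.
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
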