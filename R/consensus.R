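#' IDP-calling criteria
#'
#' Two calling modes over per-predictor disorder summaries:
#' * `strict`: a protein is an IDP when its longest disordered region (LDR)
#'   reaches `ldr_strict` residues (default 30).
#' * `extended`: additionally admits proteins with an intermediate LDR
#'   (`ldr_low <= LDR < ldr_strict`) whose overall percent disorder exceeds
#'   `percent_min`. The long-region clause does not itself require a
#'   minimum percent.
#'
#' The intermediate band is half-open (`10 <= LDR < 30` at the defaults) so
#' the two clauses partition the LDR axis.
#'
#' @param mode `"strict"` or `"extended"`.
#' @param ldr_strict LDR at or above which a protein is always an IDP.
#' @param ldr_low Lower LDR bound of the extended clause.
#' @param percent_min Percent disorder that the extended clause must exceed.
#' @return List of class `idp_criteria`.
#' @export
idp_criteria <- function(mode = c("strict", "extended"), ldr_strict = 30,
                         ldr_low = 10, percent_min = 10) {
  mode <- match.arg(mode)
  if (!(ldr_low < ldr_strict)) stop("ldr_low must be < ldr_strict", call. = FALSE)
  if (percent_min < 0) stop("percent_min must be >= 0", call. = FALSE)
  structure(list(mode = mode, ldr_strict = ldr_strict, ldr_low = ldr_low,
                 percent_min = percent_min), class = "idp_criteria")
}

#' Call proteins as IDPs from disorder summaries
#'
#' @param summaries Data frame with columns `ldr` and `percent_disorder`
#'   (one row per protein x predictor, see [summarize_disorder()]).
#' @param criteria An [idp_criteria()] object.
#' @return Logical vector, one call per summary row.
#' @export
call_idp <- function(summaries, criteria = idp_criteria()) {
  stopifnot(inherits(criteria, "idp_criteria"))
  long <- summaries$ldr >= criteria$ldr_strict
  if (criteria$mode == "strict") return(long)
  mid <- summaries$ldr >= criteria$ldr_low &
    summaries$ldr < criteria$ldr_strict &
    summaries$percent_disorder > criteria$percent_min
  long | mid
}

#' Per-protein IDP calls across predictors, and their k-of-n consensus
#'
#' @param calls Data frame with columns `protein_id`, `predictor` and a
#'   logical `idp` column (one row per protein x predictor); every
#'   predictor must cover the same protein universe.
#' @param k Number of supporting predictors required (default: all of
#'   them, i.e. the intersection).
#' @return Data frame `protein_id`, one 0/1 column per predictor,
#'   `n_supporting`, `consensus`.
#' @export
consensus_table <- function(calls, k = NULL) {
  preds <- sort(unique(calls$predictor))
  n <- length(preds)
  if (is.null(k)) k <- n
  if (k < 1 || k > n) {
    stop("k must be between 1 and the number of predictors (", n, ")",
         call. = FALSE)
  }
  universes <- lapply(split(calls$protein_id, calls$predictor),
                      function(x) sort(unique(x)))
  if (length(unique(universes)) != 1) {
    stop("predictors cover unequal protein universes", call. = FALSE)
  }
  ids <- universes[[1]]
  wide <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (p in preds) {
    sub <- calls[calls$predictor == p, ]
    wide[[p]] <- as.integer(sub$idp[match(ids, sub$protein_id)])
  }
  wide$n_supporting <- as.integer(rowSums(as.matrix(wide[preds])))
  wide$consensus <- wide$n_supporting >= k
  wide
}

#' Proteins called IDP by at least k predictors
#'
#' With `k` equal to the number of predictors this is the intersection of
#' the per-predictor IDP sets ("selected by all software"); with `k = 1`
#' the union.
#'
#' @inheritParams consensus_table
#' @return Character vector of protein ids.
#' @export
consensus_sets <- function(calls, k = NULL) {
  tab <- consensus_table(calls, k)
  tab$protein_id[tab$consensus]
}

#' Intersect an IDP set with a boolean annotation
#'
#' E.g. cross-referencing an identified protein set against a
#' phosphoproteome: which members carry the flag, and what fraction of the
#' source set they represent.
#'
#' @param idp_set Character vector of protein ids.
#' @param records Annotated `protein_set`.
#' @param flag Name of a logical annotation column (e.g. `"phospho"`).
#' @return List with `ids` (flagged members), `n`, and `percent`
#'   (`100 * n / length(idp_set)`, half-up rounded to one decimal).
#' @export
intersect_with_annotation <- function(idp_set, records, flag = "phospho") {
  if (!flag %in% names(records) || !is.logical(records[[flag]])) {
    stop("`flag` must name a logical annotation column", call. = FALSE)
  }
  fl <- records[[flag]][match(idp_set, records$id)]
  fl[is.na(fl)] <- FALSE
  ids <- idp_set[fl]
  pct <- if (length(idp_set) == 0) 0 else 100 * length(ids) / length(idp_set)
  list(ids = ids, n = length(ids), percent = round_half_up(pct, 1))
}
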