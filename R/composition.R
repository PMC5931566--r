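# Per-protein amino-acid count matrix (n x 20); X is not counted.
aa_count_matrix <- function(records) {
  aa <- amino_acids()
  counts <- t(vapply(records$sequence, function(s) {
    tabulate(factor(seq_chars(s), levels = aa), nbins = 20)
  }, integer(20), USE.NAMES = FALSE))
  colnames(counts) <- aa
  rownames(counts) <- records$id
  counts
}

#' Pooled amino-acid composition of a protein set
#'
#' Residues are pooled across all records; the ambiguity code X is
#' excluded from both counts and the denominator.
#'
#' @param records A `protein_set` data frame.
#' @return List of class `composition_profile` with `counts` (named integer
#'   vector over the 20 amino acids), `fractions` (summing to 1) and
#'   `n_residues`.
#' @export
pooled_composition <- function(records) {
  if (nrow(records) == 0) stop("empty record set", call. = FALSE)
  counts <- colSums(aa_count_matrix(records))
  total <- sum(counts)
  if (total == 0) stop("no non-X residues in record set", call. = FALSE)
  structure(list(counts = counts, fractions = counts / total,
                 n_residues = total),
            class = "composition_profile")
}

#' Relative enrichment of a query composition versus a background
#'
#' Per amino acid a, `enrichment(a) = (Cq(a) - Cb(a)) / Cb(a)` where Cq and
#' Cb are the query and background fractions. Positive values mean the
#' residue is over-represented in the query set. Amino acids absent from
#' the background are reported as NA rather than divided by zero.
#'
#' @param query,background `composition_profile` objects (or record sets,
#'   which are pooled first).
#' @return Data frame `amino_acid`, `query_fraction`, `background_fraction`,
#'   `enrichment`, one row per amino acid in fixed alphabetical order.
#' @export
aa_enrichment <- function(query, background) {
  if (is.data.frame(query)) query <- pooled_composition(query)
  if (is.data.frame(background)) background <- pooled_composition(background)
  cq <- query$fractions[amino_acids()]
  cb <- background$fractions[amino_acids()]
  enr <- ifelse(cb > 0, (cq - cb) / cb, NA_real_)
  data.frame(amino_acid = amino_acids(), query_fraction = unname(cq),
             background_fraction = unname(cb), enrichment = unname(enr),
             stringsAsFactors = FALSE)
}

#' Bootstrap confidence intervals and significance for composition enrichment
#'
#' Resamples proteins (not residues — residues within a protein are not
#' independent) with replacement, independently within the query and
#' background sets. Each of the B replicates recomputes pooled compositions
#' and per-amino-acid enrichment; the confidence interval is the empirical
#' `(alpha/2, 1 - alpha/2)` quantile band, and the two-sided p-value is
#' `2 * min(frac(replicate <= 0), frac(replicate >= 0))` clipped to
#' `[2/B, 1]`. Results are deterministic given `seed`. No multiple-testing
#' correction is applied by default (set `bonferroni = TRUE` for a
#' 20-residue Bonferroni adjustment of the significance flags).
#'
#' @param query_records,background_records Non-empty `protein_set` data
#'   frames.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed for the resampling RNG.
#' @param alpha Two-sided significance level (default 0.05).
#' @param bonferroni Apply a Bonferroni correction across the 20 amino
#'   acids when flagging significance (default FALSE).
#' @return Data frame `amino_acid`, `query_fraction`, `background_fraction`,
#'   `enrichment`, `ci_low`, `ci_high`, `p_value`, `significant`, one row
#'   per amino acid in fixed alphabetical order.
#' @export
bootstrap_enrichment <- function(query_records, background_records,
                                 B = 1000, seed = NULL, alpha = 0.05,
                                 bonferroni = FALSE) {
  if (B < 100) stop("B must be >= 100 (quantiles are unstable below that)",
                    call. = FALSE)
  if (nrow(query_records) == 0 || nrow(background_records) == 0) {
    stop("both record sets must be non-empty", call. = FALSE)
  }
  cq_mat <- aa_count_matrix(query_records)
  cb_mat <- aa_count_matrix(background_records)
  point <- aa_enrichment(pooled_composition(query_records),
                         pooled_composition(background_records))
  nq <- nrow(cq_mat)
  nb <- nrow(cb_mat)
  rep_enr <- with_seed(seed, {
    iq <- matrix(sample.int(nq, nq * B, replace = TRUE), nrow = B)
    ib <- matrix(sample.int(nb, nb * B, replace = TRUE), nrow = B)
    out <- matrix(NA_real_, nrow = B, ncol = 20)
    for (b in seq_len(B)) {
      fq <- colSums(cq_mat[iq[b, ], , drop = FALSE])
      fb <- colSums(cb_mat[ib[b, ], , drop = FALSE])
      fq <- fq / sum(fq)
      fb <- fb / sum(fb)
      out[b, ] <- ifelse(fb > 0, (fq - fb) / fb, NA_real_)
    }
    out
  })
  ci <- apply(rep_enr, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
              names = FALSE)
  pv <- apply(rep_enr, 2, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) return(NA_real_)
    p <- 2 * min(mean(r <= 0), mean(r >= 0))
    min(max(p, 2 / B), 1)
  })
  thr <- if (bonferroni) alpha / 20 else alpha
  out <- point
  out$ci_low <- ci[1, ]
  out$ci_high <- ci[2, ]
  out$p_value <- pv
  out$significant <- !is.na(pv) & pv < thr
  out
}
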