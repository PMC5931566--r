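#' Run the full disorder-annotation pipeline
#'
#' Convenience orchestration: predict per-residue disorder with the
#' built-in predictors (plus any imported external call tracks), summarise
#' per protein, tabulate LDR bins, and apply consensus IDP calling. When
#' `out_dir` is given, deterministic TSV/JSON reports with provenance
#' headers are written atomically; two runs from the same inputs produce
#' byte-identical report bodies.
#'
#' @param records A `protein_set` data frame (or a FASTA path).
#' @param criteria [idp_criteria()] used for per-predictor IDP calls.
#' @param k Consensus threshold (default: all predictors).
#' @param ch_params,pe_params Predictor parameters.
#' @param extra_calls Optional long call data frame of imported predictor
#'   tracks (`protein_id`, `predictor`, `position`, `call`), e.g. binarized
#'   output of [read_score_table()].
#' @param out_dir Optional output directory for reports.
#' @param seed Seed recorded in report headers (the pipeline itself is
#'   deterministic; the seed documents upstream data generation).
#' @return List with `scores`, `calls`, `summaries`, `bin_table`,
#'   `idp_calls`, `consensus`, `idp_ids`.
#' @export
run_pipeline <- function(records, criteria = idp_criteria("extended"),
                         k = NULL,
                         ch_params = charge_hydropathy_params(),
                         pe_params = energy_model_params(),
                         extra_calls = NULL, out_dir = NULL, seed = NULL) {
  if (is.character(records)) records <- read_fasta(records)
  pred <- predict_disorder(records, ch_params = ch_params,
                           pe_params = pe_params)
  calls <- pred$calls
  if (!is.null(extra_calls)) {
    calls <- rbind(calls, extra_calls[names(calls)])
    calls <- calls[order(calls$protein_id, calls$predictor, calls$position), ]
    rownames(calls) <- NULL
  }
  summaries <- summarize_disorder(calls, records)
  bins <- bin_frequency_table(summaries)
  idp_calls <- data.frame(protein_id = summaries$protein_id,
                          predictor = summaries$predictor,
                          idp = call_idp(summaries, criteria),
                          stringsAsFactors = FALSE)
  cons <- consensus_table(idp_calls, k)
  idp_ids <- cons$protein_id[cons$consensus]
  res <- list(scores = pred$scores, calls = calls, summaries = summaries,
              bin_table = bins, idp_calls = idp_calls, consensus = cons,
              idp_ids = idp_ids)
  if (!is.null(out_dir)) {
    prov <- list(seed = if (is.null(seed)) "NA" else seed,
                 criteria = paste(criteria$mode, criteria$ldr_strict,
                                  criteria$ldr_low, criteria$percent_min),
                 k = if (is.null(k)) "all" else k)
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_score_table(res$scores, file.path(out_dir, "scores.tsv"), prov)
    write_report_tsv(res$calls, file.path(out_dir, "calls.tsv"), prov)
    write_report_tsv(res$summaries, file.path(out_dir, "summary.tsv"), prov)
    write_report_tsv(res$bin_table, file.path(out_dir, "bin_table.tsv"), prov)
    write_report_tsv(res$consensus, file.path(out_dir, "consensus.tsv"), prov)
    write_lines_atomic(
      jsonlite::toJSON(list(idp_ids = res$idp_ids), pretty = TRUE),
      file.path(out_dir, "idp_ids.json"))
  }
  res
}
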