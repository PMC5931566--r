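# Shared fixtures: random sequences, tiny FASTA/TSV writers, a realistic
# null composition for calibration simulations.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_seq <- function(L, x_rate = 0, aa = amino_acids()) {
  chars <- sample(aa, L, replace = TRUE)
  if (x_rate > 0) {
    flip <- runif(L) < x_rate
    chars[flip] <- "X"
  }
  paste(chars, collapse = "")
}

write_tmp_fasta <- function(headers, seqs) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

write_tmp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Average-proteome-like residue frequencies for null simulations.
null_composition <- function() {
  p <- c(A = 0.083, C = 0.014, D = 0.054, E = 0.067, F = 0.039, G = 0.071,
         H = 0.023, I = 0.059, K = 0.058, L = 0.097, M = 0.024, N = 0.040,
         P = 0.047, Q = 0.039, R = 0.055, S = 0.066, T = 0.054, V = 0.069,
         W = 0.011, Y = 0.029)
  p / sum(p)
}

# Records of i.i.d. sequences from a composition.
records_from_composition <- function(n, L, comp, prefix = "p") {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(names(comp), L, replace = TRUE, prob = comp), collapse = "")
  }, "")
  protein_records(id = sprintf("%s%04d", prefix, seq_len(n)), sequence = seqs)
}
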