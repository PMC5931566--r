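test_that("longest_run handles degenerate and mixed patterns", {
  expect_equal(longest_run(rep(FALSE, 50)), 0L)
  expect_equal(longest_run(rep(TRUE, 50)), 50L)
  pat <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(longest_run(pat), 5L)
  expect_error(longest_run(logical(0)), "empty")
})

test_that("longest_run equals exhaustive window enumeration", {
  set.seed(33)
  for (i in 1:30) {
    calls <- runif(sample(1:200, 1)) < runif(1)
    expect_equal(longest_run(calls), oracle_longest_run(calls))
  }
})

test_that("percent_disorder is the disordered fraction in percent", {
  expect_equal(percent_disorder(c(rep(TRUE, 5), rep(FALSE, 5))), 50)
  expect_equal(percent_disorder(rep(FALSE, 7)), 0)
  expect_equal(percent_disorder(c(rep(TRUE, 33), rep(FALSE, 267))), 11)
})

test_that("LDR bins partition the non-negative integers as printed", {
  expect_equal(ldr_bin(c(0, 9, 10, 29, 30, 49, 50, 99, 100, 250)),
               c("0~9", "0~9", "10~29", "10~29", "30~49", "30~49",
                 "50~99", "50~99", "100<", "100<"))
  expect_error(ldr_bin(-1), "non-negative")
  # every integer lands in exactly one bin
  expect_false(anyNA(ldr_bin(0:500)))
})

test_that("summaries aggregate calls per protein and predictor", {
  rec <- protein_records(c("b", "a"), c(strrep("E", 40), strrep("K", 10)))
  pat <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  calls <- rbind(
    data.frame(protein_id = "b", predictor = "p1", position = 1:40,
               call = TRUE),
    data.frame(protein_id = "a", predictor = "p1", position = 1:10,
               call = pat),
    data.frame(protein_id = "a", predictor = "p2", position = 1:10,
               call = FALSE))
  s <- summarize_disorder(calls, rec)
  expect_equal(s$protein_id, c("a", "a", "b"))  # deterministic ordering
  expect_equal(s$predictor, c("p1", "p2", "p1"))
  a1 <- s[s$protein_id == "a" & s$predictor == "p1", ]
  expect_equal(a1$n_disordered, 8)
  expect_equal(a1$percent_disorder, 80)
  expect_equal(a1$ldr, 5L)
  expect_equal(a1$ldr_bin, "0~9")
  b1 <- s[s$protein_id == "b", ]
  expect_equal(c(b1$n_disordered, b1$percent_disorder, b1$ldr), c(40, 100, 40))
  expect_equal(b1$ldr_bin, "30~49")
  # ldr == 0 iff n_disordered == 0
  expect_true(all((s$ldr == 0) == (s$n_disordered == 0)))
})

test_that("orphan and wrong-length call tracks are errors", {
  rec <- protein_records("a", "MKAG")
  orphan <- data.frame(protein_id = "zz", predictor = "p", position = 1:4,
                       call = TRUE)
  expect_error(summarize_disorder(orphan, rec), "unknown protein")
  short <- data.frame(protein_id = "a", predictor = "p", position = 1:3,
                      call = TRUE)
  expect_error(summarize_disorder(short, rec), "length")
})

test_that("bin frequency table mirrors the printed layout and rounding", {
  # 682 proteins of which 16 sit in the first bin for one predictor
  ldrs <- c(rep(5, 16), rep(15, 160), rep(35, 198), rep(60, 181),
            rep(120, 127))
  rec <- protein_records(sprintf("p%03d", seq_along(ldrs)),
                         rep(strrep("A", 200), length(ldrs)))
  summaries <- data.frame(protein_id = rec$id, predictor = "pondr_like",
                          length = 200, n_disordered = ldrs,
                          percent_disorder = 100 * ldrs / 200, ldr = ldrs,
                          ldr_bin = ldr_bin(ldrs))
  tab <- bin_frequency_table(summaries)
  expect_equal(tab$count, c(16L, 160L, 198L, 181L, 127L))
  expect_equal(tab$percent_rounded[1], 2.3)
  expect_equal(sum(tab$count), 682L)
  expect_equal(sum(tab$percent), 100, tolerance = 1e-12)
})

test_that("bin table handles empty input and even splits", {
  empty <- bin_frequency_table(
    data.frame(protein_id = character(0), predictor = character(0),
               ldr_bin = character(0)))
  expect_equal(nrow(empty), 0)
  ldrs <- c(1, 2, 15, 20, 35, 40, 60, 70, 110, 150)
  summaries <- data.frame(protein_id = paste0("p", 1:10), predictor = "q",
                          ldr_bin = ldr_bin(ldrs))
  tab <- bin_frequency_table(summaries)
  expect_equal(tab$percent_rounded, rep(20, 5))
})

test_that("summaries are invariant under protein-id relabeling", {
  set.seed(5)
  calls <- data.frame(protein_id = "one", predictor = "p", position = 1:60,
                      call = runif(60) < 0.4)
  rec1 <- protein_records("one", rand_seq(60))
  calls2 <- transform(calls, protein_id = "two")
  rec2 <- protein_records("two", rec1$sequence)
  s1 <- summarize_disorder(calls, rec1)
  s2 <- summarize_disorder(calls2, rec2)
  expect_equal(s1[c("percent_disorder", "ldr", "n_disordered")],
               s2[c("percent_disorder", "ldr", "n_disordered")])
})
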