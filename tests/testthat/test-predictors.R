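test_that("charge-hydropathy matches hand evaluation on homopolymers", {
  # I: rescaled hydropathy 1.0, charge 0 -> 2.785 - 1.151 everywhere
  s_ile <- strrep("I", 40)
  expect_equal(charge_hydropathy_score(s_ile), rep(1.634, 40),
               tolerance = 1e-12)
  # K: rescaled (-3.9+4.5)/9, charge +1
  s_lys <- strrep("K", 40)
  expected <- 2.785 * (0.6 / 9) - 1 - 1.151
  expect_equal(charge_hydropathy_score(s_lys), rep(expected, 40),
               tolerance = 1e-12)
  expect_true(all(binarize(charge_hydropathy_score(s_lys), 0,
                           "disordered_if_below")))
  expect_false(any(binarize(charge_hydropathy_score(s_ile), 0,
                            "disordered_if_below")))
})

test_that("single-residue sequence collapses the window to a point", {
  expect_equal(charge_hydropathy_score("K"), 2.785 * (0.6 / 9) - 1 - 1.151)
  expect_error(charge_hydropathy_score("KK",
                                       charge_hydropathy_params(window = 4)),
               "odd")
})

test_that("X residues are excluded with renormalisation", {
  p <- charge_hydropathy_params(window = 3)
  # IXI: every window mean is over I only
  expect_equal(charge_hydropathy_score("IXI", p), c(1.634, 1.634, 1.634),
               tolerance = 1e-12)
  # all-X window is NA and binarizes to ordered
  expect_true(is.na(charge_hydropathy_score("XXX", p)[2]))
  expect_false(any(binarize(charge_hydropathy_score("XXX", p), 0,
                            "disordered_if_below")))
})

test_that("pairwise-energy matches the closed form on toy models", {
  m <- matrix(0, 20, 20, dimnames = list(amino_acids(), amino_acids()))
  m["A", "A"] <- -1
  m["G", "G"] <- -1
  p <- energy_model_params(window = 5, matrix = m, midpoint = -0.5,
                           slope = 0.25)
  sc <- pairwise_energy_score(strrep("A", 12), p)
  expect_equal(sc, rep(1 / (1 + exp(2)), 12), tolerance = 1e-12)
  expect_false(any(binarize(sc, 0.5, "disordered_if_at_or_above")))
  # alternating context is half A half G -> e = -0.5 -> boundary score 0.5,
  # resolved as disordered by the at-or-above tie rule
  alt <- pairwise_energy_score("AGAGAGAGAGAG", p)
  interior <- alt[3:10]
  expect_equal(interior, rep(0.5, 8), tolerance = 1e-12)
  expect_true(all(binarize(interior, 0.5, "disordered_if_at_or_above")))
  # zero matrix: constant scores whatever the sequence
  p0 <- energy_model_params(window = 5,
                            matrix = matrix(0, 20, 20,
                                            dimnames = list(amino_acids(),
                                                            amino_acids())),
                            midpoint = -0.5, slope = 0.25)
  set.seed(7)
  sc0 <- pairwise_energy_score(rand_seq(30), p0)
  expect_equal(unname(sc0), rep(sc0[1], 30))
})

test_that("energy predictor rejects windows without context", {
  expect_error(pairwise_energy_score("AAAA",
                                     energy_model_params(window = 1)),
               "window.*3")
})

test_that("both predictors match brute-force oracles on random sequences", {
  set.seed(101)
  scale <- default_hydropathy_scale()
  charge <- default_charge_rule()
  m <- default_energy_matrix()
  for (i in 1:40) {
    L <- sample(5:30, 1)
    s <- rand_seq(L, x_rate = 0.1)
    w <- sample(c(3, 5, 7), 1)
    got_ch <- charge_hydropathy_score(s, charge_hydropathy_params(window = w))
    exp_ch <- oracle_charge_hydropathy(s, w, scale, charge)
    expect_equal(got_ch, exp_ch, tolerance = 1e-9)
    got_pe <- pairwise_energy_score(s, energy_model_params(window = w,
                                                           matrix = m))
    exp_pe <- oracle_pairwise_energy(s, w, m, midpoint = -0.15, slope = 0.05)
    expect_equal(got_pe, exp_pe, tolerance = 1e-9)
  }
})

test_that("raising hydropathy at constant charge never lowers CH scores", {
  set.seed(202)
  p <- charge_hydropathy_params(window = 7)
  for (i in 1:20) {
    s <- rand_seq(30)
    chars <- strsplit(s, "")[[1]]
    # swap a neutral residue for the most hydrophobic neutral residue (I)
    neutral <- which(!chars %in% c("K", "R", "D", "E", "I"))
    if (length(neutral) == 0) next
    j <- sample(neutral, 1)
    chars2 <- chars
    chars2[j] <- "I"
    s2 <- paste(chars2, collapse = "")
    expect_true(all(charge_hydropathy_score(s2, p) -
                      charge_hydropathy_score(s, p) >= -1e-12))
  }
})

test_that("homopolymer scores are translation invariant in the interior", {
  for (w in c(5, 21, 51)) {
    s <- strrep("E", 120)
    sc <- charge_hydropathy_score(s, charge_hydropathy_params(window = w))
    interior <- sc[(w %/% 2 + 1):(120 - w %/% 2)]
    expect_equal(unname(interior), rep(interior[1], length(interior)))
    pe <- pairwise_energy_score(s, energy_model_params(window = max(w, 3)))
    interior_pe <- pe[(w %/% 2 + 1):(120 - w %/% 2)]
    expect_equal(unname(interior_pe), rep(interior_pe[1], length(interior_pe)))
  }
})

test_that("binarize applies thresholds and tie rules per direction", {
  expect_equal(binarize(c(-0.2, 0.3), 0, "disordered_if_below"),
               c(TRUE, FALSE))
  expect_equal(binarize(c(0, 0), 0, "disordered_if_below"), c(FALSE, FALSE))
  expect_equal(binarize(c(0.5, 0.5), 0.5, "disordered_if_at_or_above"),
               c(TRUE, TRUE))
})

test_that("energy matrices are validated and round-trip through TSV", {
  m <- default_energy_matrix()
  expect_equal(m, t(m))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_matrix(m, path)
  expect_equal(read_energy_matrix(path), m, tolerance = 1e-12)
  bad <- m
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(pairwise_energy_score("AAAA",
                                     energy_model_params(matrix = bad)),
               "symmetric")
})

test_that("predictors recover planted disorder at high balanced accuracy", {
  comps <- fig5_like_compositions()
  spec <- synthetic_spec(n_proteins = 40, length_range = c(400, 800),
                         region_length_range = c(80, 180),
                         regions_range = c(0, 2), seed = 7)
  g <- generate_proteome(spec)
  truth <- g$truth$score == 1
  pred <- predict_disorder(g$records)
  for (meth in c("charge_hydropathy", "pairwise_energy")) {
    calls <- pred$calls[pred$calls$predictor == meth, ]
    calls <- calls[order(calls$protein_id, calls$position), ]
    tr <- g$truth[order(g$truth$protein_id, g$truth$position), ]
    stopifnot(identical(calls$protein_id, tr$protein_id))
    sens <- mean(calls$call[tr$score == 1])
    spec_ <- mean(!calls$call[tr$score == 0])
    expect_gt((sens + spec_) / 2, 0.9)
  }
})
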