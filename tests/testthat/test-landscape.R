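# Game classification, grid scans, and region bookkeeping.

test_that("canonical matrices classify to their textbook classes", {
  classify <- function(game) {
    classify_game(find_nash_ilp(game), game, "C", "D")$label
  }
  expect_equal(classify(canonical_pd()), "prisoners_dilemma")
  expect_equal(classify(canonical_snowdrift()), "snowdrift")
  expect_equal(classify(canonical_harmony()), "mutually_beneficial")

  dead <- matrix_game(matrix(-0.05, 2, 2), labels = c("C", "D"),
                      death_rate = -0.05)
  expect_equal(classify(dead), "non_viable")

  # non-producer dead in every profile; the producer thrives only in
  # mutual production, so (D,D) is weakly Nash alongside (C,C)
  dom <- matrix_game(rbind(c(2, -0.05), c(-0.05, -0.05)),
                     labels = c("C", "D"), death_rate = -0.05)
  expect_equal(classify(dom), "producer_dominance")

  expect_error(classify_game(find_nash_ilp(random_game(2, 3)),
                             random_game(2, 3), "s1", "s2"),
               class = "fbagames_input_error")
})

test_that("classification agrees with the payoff-ordering table on random games", {
  set.seed(77)
  for (rep in 1:300) {
    vals <- sample(seq(0.5, 8, by = 0.5), 4)  # distinct positive payoffs
    R <- vals[1]; S <- vals[2]; T <- vals[3]; P <- vals[4]
    g <- matrix_game(rbind(c(R, S), c(T, P)), labels = c("C", "D"))
    got <- classify_game(find_nash_ilp(g), g, "C", "D")$label
    expected <-
      if (T > R && P > S) {
        if (R > P) "prisoners_dilemma" else "other"
      } else if (T > R && S > P) "snowdrift"
      else if (R > T && !(P > S)) "mutually_beneficial"
      else if (R > T && P > S) "other"     # coordination: both pure Nash
      else "other"
    expect_equal(got, expected,
                 label = sprintf("R=%g S=%g T=%g P=%g -> %s", R, S, T, P, got))
  }
})

test_that("enumerating amino-acid pairs matches the combinatorial count", {
  pairs <- enumerate_amino_acid_pairs(amino_acids(),
                                      exclusions = list(c("Ala", "Ile")))
  expect_equal(nrow(pairs), 189L)
  expect_false(any(pairs$a == "Ala" & pairs$b == "Ile"))
  # deterministic lexicographic order
  expect_true(!is.unsorted(pairs$a))

  expect_equal(nrow(enumerate_amino_acid_pairs(c("x", "y", "z"))), 3L)
  expect_error(enumerate_amino_acid_pairs(c("x", "x", "y")),
               "duplicate", class = "fbagames_input_error")
  expect_error(enumerate_amino_acid_pairs(c("x", "y"),
                                          exclusions = list(c("x", "q"))),
               class = "fbagames_input_error")
})

test_that("a 1x1 grid equals a direct classify call", {
  fac <- sucrose_factory(glucose_medium = 2)
  ls <- scan_landscape(fac,
                       axis1 = list(name = "atp_cost_x", values = 0.6),
                       axis2 = list(name = "capture_efficiency_e",
                                    values = 0.3))
  expect_equal(nrow(ls$cells), 1L)
  cell <- fac(atp_cost_x = 0.6, capture_efficiency_e = 0.3)
  game <- build_payoff_tensor(cell$model, unname(cell$genotypes))
  direct <- classify_game(find_nash_ilp(game), game, "WT", "MT")
  expect_equal(ls$cells$game_class[1], direct$label)
})

test_that("the sustainable region is downward-closed in leakiness", {
  aa <- make_two_amino_acid_fixture()
  vals <- seq(0, 100, by = 20)
  ls <- scan_landscape(two_amino_acid_factory(aa),
                       axis1 = list(name = "leakiness_A", values = vals),
                       axis2 = list(name = "leakiness_B", values = vals))
  m <- sustainable_region(ls)
  expect_true(m["0", "0"])  # zero leak is always sustainable
  expect_false(m["100", "100"])
  # reducing either leak from a sustainable cell stays sustainable;
  # equivalently the non-viable region is upward-closed
  for (i in seq_len(nrow(m))) {
    expect_true(all(diff(m[i, ]) <= 0))
    expect_true(all(diff(m[, i]) <= 0))
  }
})

test_that("landscape TSV export carries all per-cell records", {
  fac <- sucrose_factory(glucose_medium = 2)
  ls <- scan_landscape(fac,
                       axis1 = list(name = "atp_cost_x",
                                    values = c(0.2, 1.2)),
                       axis2 = list(name = "capture_efficiency_e",
                                    values = c(0.2, 0.8)))
  path <- tempfile(fileext = ".tsv")
  write_landscape(ls, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(back), 4L)
  expect_true(all(c("atp_cost_x", "capture_efficiency_e", "game_class",
                    "nash_profiles", "producer_viable") %in% colnames(back)))
  expect_equal(back$game_class, ls$cells$game_class)
})
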