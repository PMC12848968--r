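test_that("bond-length change is the maximum relative change over bonds", {
  geom <- cbind(x = c(0, 1, 2), y = 0, z = 0)
  bonds <- data.frame(i = c(1, 2), j = c(2, 3))
  expect_equal(max_bond_change(geom, geom, bonds), 0)
  # one bond stretched 1.0 -> 1.5
  red <- geom; red[3, 1] <- 2.5
  expect_equal(max_bond_change(geom, red, bonds), 0.5)
  # 1.0 -> 1.2 stays under the default threshold
  red2 <- geom; red2[3, 1] <- 2.2
  expect_equal(max_bond_change(geom, red2, bonds), 0.2)
  expect_error(max_bond_change(geom, geom[1:2, ], bonds), "mismatched")
})

test_that("spin contamination is measured against S(S+1)", {
  expect_equal(s_squared_deviation(0.75, 2), 0)
  expect_equal(s_squared_deviation(0.86, 2), 0.86 / 0.75 - 1)
  expect_gt(s_squared_deviation(0.86, 2), 0.10)
  expect_equal(s_squared_deviation(0.78, 2), 0.04)
  expect_equal(s_squared_deviation(2.1, 3), 0.05)
  expect_equal(s_squared_deviation(0, 1), 0)
  expect_error(s_squared_deviation(0.5, 1), "inconsistent")
})

test_that("the engineered fixture trips each filter exactly once", {
  recs <- gen_curation_fixtures(seed = 1)
  expect_length(recs, 10L)
  res <- apply_filters(recs)
  expect_length(res$kept, 6L)
  expect_equal(nrow(res$removed), 4L)
  expect_setequal(res$removed$reason,
                  c("bond_change", "spin_contamination",
                    "imaginary_frequency", "electrostatic_range"))
  # removal reasons match the engineered outcomes
  expected <- vapply(recs, `[[`, character(1), "expected_outcome")
  ids <- vapply(recs, `[[`, character(1), "molecule_id")
  for (k in seq_len(nrow(res$removed))) {
    i <- match(res$removed$molecule_id[k], ids)
    expect_equal(res$removed$reason[k], expected[i])
  }
  # order preserved, kept + removed partitions the input
  expect_identical(res$report$molecule_id, ids)
  expect_equal(length(res$kept) + nrow(res$removed), length(recs))
})

test_that("filter outcomes are order-independent and threshold-driven", {
  recs <- gen_curation_fixtures(seed = 2)
  res1 <- apply_filters(recs)
  res2 <- apply_filters(rev(recs))
  kept1 <- sort(vapply(res1$kept, `[[`, character(1), "molecule_id"))
  kept2 <- sort(vapply(res2$kept, `[[`, character(1), "molecule_id"))
  expect_identical(kept1, kept2)
  # non-binding thresholds keep everything
  loose <- list(bond_change = Inf, spin = Inf, freq_tol = Inf,
                electrostatic = c(-Inf, Inf))
  expect_length(apply_filters(recs, loose)$kept, length(recs))
})

test_that("boundary electrostatics are kept; missing fields are flagged", {
  recs <- gen_curation_fixtures(seed = 3, n_clean = 2)
  ok <- recs[vapply(recs, function(r)
    r$expected_outcome == "kept", logical(1))]
  r <- ok[[1]]
  for (be in c(-4.0, -0.1)) {
    r$bulk_electrostatic <- be
    expect_equal(redoxgnn:::.check_record(r, curation_thresholds()),
                 "kept")
  }
  r$bulk_electrostatic <- -0.05
  expect_equal(redoxgnn:::.check_record(r, curation_thresholds()),
               "electrostatic_range")
  r$bulk_electrostatic <- NA
  expect_match(redoxgnn:::.check_record(r, curation_thresholds()),
               "^error:")
  r2 <- ok[[1]]; r2$frequencies <- list()
  expect_match(redoxgnn:::.check_record(r2, curation_thresholds()),
               "^error:")
})

test_that("imaginary frequencies are any negative wavenumber", {
  recs <- gen_curation_fixtures(seed = 4, n_clean = 1)
  r <- recs[[which(vapply(recs, function(x)
    x$expected_outcome == "kept", logical(1)))[1]]]
  r$frequencies$reduced <- c(-0.5, 100)
  expect_equal(redoxgnn:::.check_record(r, curation_thresholds()),
               "imaginary_frequency")
})

test_that("XYZ files round-trip", {
  el <- c("C", "O", "H")
  xyz <- matrix(rnorm(9), 3, dimnames = list(NULL, c("x", "y", "z")))
  tf <- tempfile(fileext = ".xyz")
  write_xyz(el, xyz, tf, comment = "fixture")
  back <- read_xyz(tf)
  expect_identical(back$elements, el)
  expect_equal(back$coords, xyz, tolerance = 1e-7, ignore_attr = TRUE)
})
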