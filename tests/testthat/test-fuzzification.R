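test_that("interval fuzzification keeps bounds and takes the midpoint as mode", {
  expect_equal(unclass(tfn_from_interval(evidence_interval(4, 12))),
               unclass(tfn(4, 8, 12)))
  expect_equal(unclass(tfn_from_interval(evidence_interval(5, 5))), unclass(tfn(5)))
  expect_equal(unclass(tfn_from_interval(evidence_interval(0, 10))),
               unclass(tfn(0, 5, 10)))
  expect_error(evidence_interval(3, 1), "low > high")

  set.seed(3)
  for (rep in 1:50) {
    b <- sort(stats::runif(2, -5, 50))
    out <- tfn_from_interval(evidence_interval(b[1], b[2]))
    expect_true(out[[1]] <= out[[2]] && out[[2]] <= out[[3]])
    expect_equal(out[[2]], mean(b))
  }
})

test_that("linguistic scale maps the closed five-label vocabulary", {
  expect_equal(unclass(tfn_from_linguistic("VL")), unclass(tfn(1, 1, 3)))
  expect_equal(unclass(tfn_from_linguistic("L")), unclass(tfn(1, 3, 5)))
  expect_equal(unclass(tfn_from_linguistic("M")), unclass(tfn(3, 5, 7)))
  expect_equal(unclass(tfn_from_linguistic("H")), unclass(tfn(5, 7, 9)))
  expect_equal(unclass(tfn_from_linguistic("VH")), unclass(tfn(7, 9, 9)))
  expect_error(tfn_from_linguistic("XL"), "unknown linguistic term")
  expect_equal(nrow(linguistic_scale()), 5L)
})

test_that("packaged study fixture carries the golden property matrix", {
  dm <- load_study_fixture()
  expect_equal(nrow(dm$alternatives), 5L)
  expect_equal(nrow(dm$criteria), 6L)

  golden <- list(
    A1 = list(C1 = c(20, 45, 65), C2 = c(1.5, 3.5, 6.0), C3 = c(40, 60, 70),
              C4 = c(24, 48, 100), C5 = c(85, 92, 99)),
    A2 = list(C1 = c(3.5, 7.0, 11), C2 = c(0.1, 0.2, 0.4), C3 = c(60, 75, 90),
              C4 = c(50, 100, 200), C5 = c(90, 95, 99)),
    A3 = list(C1 = c(2.0, 5.0, 15), C2 = c(0.5, 1.0, 3.0), C3 = c(80, 90, 95),
              C4 = c(4, 8, 12), C5 = c(90, 96, 99)),
    A4 = list(C1 = c(35, 47, 60), C2 = c(1.2, 1.7, 2.5), C3 = c(20, 40, 50),
              C4 = c(24, 48, 72), C5 = c(75, 85, 90)),
    A5 = list(C1 = c(15, 30, 52), C2 = c(0.8, 1.5, 2.2), C3 = c(30, 55, 70),
              C4 = c(12, 16, 24), C5 = c(85, 90, 95))
  )
  for (code in names(golden)) {
    for (id in names(golden[[code]])) {
      expect_equal(unname(unclass(dm_cell(dm, code, id))), golden[[code]][[id]],
                   info = paste(code, id))
    }
  }

  # documented default cost-index column (package assumption, not source data)
  c6 <- list(A1 = "L", A2 = "L", A3 = "M", A4 = "H", A5 = "M")
  for (code in names(c6)) {
    expect_equal(unclass(dm_cell(dm, code, "C6")),
                 unclass(tfn_from_linguistic(c6[[code]])), info = code)
  }

  expect_equal(dm$criteria$direction,
               c("benefit", "benefit", "benefit", "target_range", "benefit", "cost"))
  expect_equal(dm$criteria$target_lo[4], 12)
  expect_equal(dm$criteria$target_hi[4], 26)
})

test_that("study weights match the fixture weight table", {
  w <- study_weights()
  expect_s3_class(w, "weight_vector")
  expect_equal(w$id, paste0("C", 1:6))
  expect_equal(unname(as.matrix(w[, c("l", "m", "u")])),
               matrix(c(0.20, 0.25, 0.30,
                        0.15, 0.20, 0.25,
                        0.10, 0.15, 0.20,
                        0.10, 0.15, 0.20,
                        0.15, 0.20, 0.25,
                        0.05, 0.05, 0.10), ncol = 3, byrow = TRUE))
  expect_equal(w$global, c(0.252, 0.184, 0.121, 0.121, 0.215, 0.107))
  expect_equal(sum(w$global), 1, tolerance = 1e-12)
})

test_that("fixture round-trips bit-for-bit through JSON and CSV", {
  dm <- load_study_fixture()
  tmp <- tempfile(fileext = ".json")
  write_decision_matrix_json(dm, tmp, weights = study_weights())
  back <- read_decision_matrix_json(tmp)
  expect_identical(back$cells, dm$cells)
  expect_identical(back$criteria$direction, dm$criteria$direction)
  expect_identical(back$alternatives$code, dm$alternatives$code)

  tmp2 <- tempfile(fileext = ".csv")
  write_decision_matrix_csv(dm, tmp2)
  back2 <- read_decision_matrix_csv(tmp2)
  expect_identical(back2$cells, dm$cells)
})
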