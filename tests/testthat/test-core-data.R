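test_that("goodness_of_fit matches hand arithmetic and handles edge cases", {
  q <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(q$r_squared, 1)
  expect_equal(q$mse, 0)
  expect_equal(q$rmse, 0)

  # SStot = 2, SSres = 1
  q <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(q$r_squared, 0.5)
  expect_equal(q$mse, 1 / 3)
  expect_equal(q$rmse, 0.5773503, tolerance = 1e-6)
  expect_equal(q$n_points, 3L)

  expect_error(goodness_of_fit(c(1, 1, 1), c(1, 2, 3)), "identical")
  expect_error(goodness_of_fit(1:3, 1:4), "length")
  # R^2 may be negative for fits worse than the mean; never clipped
  expect_lt(goodness_of_fit(c(1, 2, 3), c(10, -5, 8))$r_squared, 0)
})

test_that("goodness_of_fit invariants: permutation equivariance and rmse^2 = mse", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    obs <- rnorm(n, 100, 10)
    pred <- obs + rnorm(n, 0, 3)
    q <- goodness_of_fit(obs, pred)
    expect_equal(q$rmse^2, q$mse, tolerance = 1e-12)
    perm <- sample(n)
    qp <- goodness_of_fit(obs[perm], pred[perm])
    expect_equal(qp$r_squared, q$r_squared)
    expect_equal(qp$mse, q$mse)
    expect_equal(qp$rmse, q$rmse)
  }
})

test_that("relative_change reproduces the reported percent summaries", {
  # effective diffusivity 30 -> 40 degC and 50 -> 60 degC endpoints
  expect_equal(relative_change(8.728, 10.410), 19.27, tolerance = 1e-3)
  expect_equal(relative_change(12.690, 11.050), -12.92, tolerance = 1e-3)
  expect_equal(relative_change(5, 5), 0)
  expect_equal(relative_change(10, 5), -50)
  expect_error(relative_change(0, 1), "non-zero")
})

test_that("extraction_curve and study_dataset enforce their invariants", {
  expect_error(extraction_curve(c(10, 10, 30), c(1, 2, 3), 50), "strictly increasing")
  expect_error(extraction_curve(c(30, 20, 10), c(1, 2, 3), 50), "strictly increasing")
  expect_error(extraction_curve(c(10, 20), c(1, -2), 50), "non-negative")
  expect_error(extraction_curve(c(10, 20), c(1, NA), 50), "finite")
  expect_error(extraction_curve(c(10, 20), c(1, 2, 3), 50), "same length")

  cv <- extraction_curve(c(10, 20), c(1, 2), 50)
  expect_error(study_dataset(list(cv, cv)), "duplicate")
  expect_error(study_dataset(list(cv), particle_radius = 0), "particle_radius")
  cv2 <- extraction_curve(c(10, 20), c(1, 2), 50, replicate = 2L)
  expect_s3_class(study_dataset(list(cv, cv2)), "study_dataset")
})

test_that("read_curves sorts, remaps dialects, and rejects bad input", {
  df <- data.frame(time = c(20, 10, 30), concentration = c(2, 1, 3),
                   temperature = 50, method = "UAE", replicate = 1)
  ds <- read_curves(write_fixture_csv(df))
  expect_length(ds$curves, 1)
  expect_equal(ds$curves[[1]]$times, c(10, 20, 30))
  expect_equal(ds$curves[[1]]$concentrations, c(1, 2, 3))

  # dialect remap
  names(df)[3] <- "temp_C"
  ds <- read_curves(write_fixture_csv(df), dialect = c(temperature = "temp_C"))
  expect_equal(ds$curves[[1]]$temperature, 50)

  # missing column named in the error
  expect_error(read_curves(write_fixture_csv(df)), "temperature")

  # non-numeric concentration cites the row
  df2 <- data.frame(time = c(10, 20, 30), concentration = c("1", "NA", "3"),
                    temperature = 50, method = "UAE", replicate = 1)
  expect_error(read_curves(write_fixture_csv(df2)), "row 2")

  # duplicate time within a group
  df3 <- data.frame(time = c(10, 10, 30), concentration = c(1, 2, 3),
                    temperature = 50, method = "UAE", replicate = 1)
  expect_error(read_curves(write_fixture_csv(df3)), "duplicate time")
})

test_that("write_curves / read_curves round-trips a dataset with meta columns", {
  ds <- generate_pso_dataset(synthetic_spec(replicates = 2, seed = 7))
  # attach a meta annotation
  for (i in seq_along(ds$curves)) ds$curves[[i]]$meta$ethanol_pct <- 50
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves(ds, path)
  back <- read_curves(path)
  expect_length(back$curves, length(ds$curves))
  key <- function(cv) paste(cv$temperature, cv$method, cv$replicate)
  orig <- ds$curves[order(vapply(ds$curves, key, character(1)))]
  got <- back$curves[order(vapply(back$curves, key, character(1)))]
  for (i in seq_along(orig)) {
    expect_equal(got[[i]]$times, orig[[i]]$times, tolerance = 1e-9)
    expect_equal(got[[i]]$concentrations, orig[[i]]$concentrations,
                 tolerance = 1e-9)
    expect_equal(as.numeric(got[[i]]$meta$ethanol_pct), 50)
  }
  # tab-separated variant
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_curves(ds, path2, sep = "\t")
  expect_length(read_curves(path2)$curves, length(ds$curves))
})

test_that("celsius_to_kelvin uses the +273 offset consistently", {
  expect_equal(celsius_to_kelvin(30), 303)
  expect_equal(celsius_to_kelvin(c(30, 70)), c(303, 343))
})
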