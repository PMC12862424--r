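small_spec <- function(seed = 3) {
  phantom_spec(spacing = rep(0.3, 3), footprint_shape = "ribbon",
               superficial_patch_area = 0, seed = seed)
}

test_that("run_phantom writes volume and truth files deterministically", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  rep1 <- run_phantom(small_spec(), out1, format = "nrrd")
  rep2 <- run_phantom(small_spec(), out2, format = "nrrd")
  expect_true(all(file.exists(rep1$outputs)))
  expect_identical(unname(tools::md5sum(rep1$outputs[["volume"]])),
                   unname(tools::md5sum(rep2$outputs[["volume"]])))
  truth <- jsonlite::read_json(rep1$outputs[["truth"]],
                               simplifyVector = TRUE)
  expect_equal(truth$deep_area,
               (13.4 - 3.98) * 3.98 + pi * (3.98 / 2)^2)
  expect_equal(rep1$seeds[["phantom"]], 3L)
})

test_that("invalid phantom parameters raise usage errors naming the field", {
  err <- tryCatch(phantom_spec(ulna_head_radius = -2), error = identity)
  expect_s3_class(err, "fp_error_usage")
  expect_match(conditionMessage(err), "ulna_head_radius")
})

test_that("run_extract_measure produces a reproducible morphometry table", {
  ph <- generate_phantom(small_spec())
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  r1 <- run_extract_measure(ph$volume, output_dir = out1,
                            landmarks = list(fovea = ph$truth$landmarks$fovea))
  r2 <- run_extract_measure(ph$volume, output_dir = out2,
                            landmarks = list(fovea = ph$truth$landmarks$fovea))
  t1 <- read.csv(r1$outputs[["csv"]]); t2 <- read.csv(r2$outputs[["csv"]])
  expect_identical(t1, t2)
  expect_equal(t1$region, "deep")
  expect_lt(abs(t1$area_mm2 - ph$truth$deep_area) / ph$truth$deep_area,
            0.05)
  expect_true(all(c("deep.overlap", "deep.final_patch") %in%
                    names(r1$stage_voxels)))
})

test_that("extraction failures surface as typed errors through the runner", {
  ph <- generate_phantom(small_spec())
  vol <- ph$volume
  vol$voxels[vol$voxels == 3L] <- 0L
  out <- withr::local_tempdir()
  expect_error(run_extract_measure(vol, output_dir = out),
               class = "fp_error_precondition")
})

test_that("run_stats dispatches to the three statistical modes", {
  out <- withr::local_tempdir()
  pw <- run_stats(mode = "power", f2 = 2.62, n = 11, k = 6, alpha = 0.05,
                  output_dir = out)
  expect_s3_class(pw, "power_result")
  expect_equal(pw$power, posthoc_power(2.62, 11, 6, 0.05)$power)
  expect_true(file.exists(file.path(out, "stats_power.json")))

  tab <- data.frame(a = c(1, 5, 9, 4), b = c(1, 5, 9, 4))
  ic <- run_stats(tab, mode = "icc")
  expect_equal(ic$estimate, 1)
  expect_equal(ic$band, "excellent")

  set.seed(51)
  dat <- data.frame(y = rnorm(12), p1 = rnorm(12), p2 = rnorm(12))
  rg <- run_stats(dat, mode = "regress", response = "y")
  expect_equal(unname(rg$coefficients),
               unname(ols_oracle(dat[c("p1", "p2")], dat$y)),
               tolerance = 1e-8)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2,3,4,\"", "x"), bad)
  expect_error(suppressWarnings(run_stats(bad, mode = "icc")),
               class = "fp_error_input")
})

test_that("stats accept CSV input from the measurement pipeline", {
  tab <- simulate_paired_measurements(20, 9, 1, 1, seed = 9)
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, csv, row.names = FALSE)
  res <- run_stats(csv, mode = "icc")
  expect_s3_class(res, "icc_result")
  expect_equal(res$n_pairs, 20)
})
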