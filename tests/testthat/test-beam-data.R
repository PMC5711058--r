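test_that("type constructors enforce their invariants", {
  d <- seq(0.5, 32, by = 0.5)
  v <- exp(-0.04 * d) * (1 - exp(-2.8 * d))
  expect_s3_class(pdd_curve(10, d, 100 * v / max(v)), "pdd_curve")
  expect_error(pdd_curve(10, d, 99.4 * v / max(v)), "not normalized to 100")
  expect_error(pdd_curve(10, c(1, 2, 2, 3), c(90, 100, 99, 98)),
               "strictly increasing")
  expect_error(pdd_curve(10, c(1, 2, 3), c(-1, 100, 50)), "positive")

  expect_error(of_table(c(5, 15, 20), c(0.96, 1.03, 1.05)),
               "reference field size missing")
  expect_error(of_table(c(5, 10, 15), c(0.96, 1.0, 0.99)),
               "strictly increasing")
  expect_error(of_table(c(5, 10), c(0.96, 1.002)), "exactly 1")

  expect_error(scan_profile("crossline", 5, 10, c(1, 2, 3), c(1, 1, 1)),
               "bracket the central axis")
  expect_error(scan_profile("crossline", 5, 10, c(-1, -1, 1), c(1, 1, 1)),
               "strictly increasing")

  expect_error(dose_plane(5, 10, c(0, 1, 3), c(0, 1, 2),
                          matrix(1, 3, 3)), "uniformly spaced")
  expect_error(dose_plane(5, 10, c(0, 1, 2), c(0, 1, 2),
                          matrix(-1, 3, 3)), "negative dose")

  expect_error(dose_measurements("m", 10, 1.5, 1.5, dose = -5), "positive")
})

test_that("BCF tables accept marginal above-unity cells but reject implausible ones", {
  ent <- matrix(c(0.99, 0.995), 1, 2, dimnames = list("10", c("1.5", "6.5")))
  ext <- matrix(c(0.98, 0.97), 1, 2, dimnames = list("10", c("6.5", "11.5")))
  expect_s3_class(bcf_table("m", 0.67, ent, ext), "bcf_table")

  ent_hi <- ent; ent_hi[1, 1] <- 1.001
  expect_warning(bcf_table("m", 0.67, ent_hi, ext), "exceed 1")
  ent_bad <- ent; ent_bad[1, 1] <- 1.02
  expect_error(bcf_table("m", 0.67, ent_bad, ext), "outside")
  ent_low <- ent; ent_low[1, 1] <- 0.85
  expect_error(bcf_table("m", 0.67, ent_low, ext), "outside")

  ent_dup <- rbind(ent, ent); rownames(ent_dup) <- c("10", "10")
  expect_error(bcf_table("m", 0.67, ent_dup, ext), "duplicate|increasing")
})

test_that("bundled measured BCF tables load with every cell intact", {
  expect_warning(bcf_reference_table("clinac21ex"), "exceed 1")
  cl <- clinac_table()
  sy <- synergy_table()
  expect_equal(dim(cl$entrance), c(4, 7))
  expect_equal(dim(cl$exit), c(4, 6))
  expect_equal(dim(sy$entrance), c(4, 7))
  expect_equal(dim(sy$exit), c(4, 6))
  expect_false(anyNA(c(cl$entrance, cl$exit, sy$entrance, sy$exit)))
  # spot values from the measured tables
  expect_equal(unname(cl$entrance["20", " 1.5"]), 0.972)
  expect_equal(unname(cl$entrance["20", "26.5"]), 1.001)
  expect_equal(unname(sy$exit["20", "31.5"]), 0.960)
  expect_equal(cl$tpr2010, 0.669)
  expect_equal(sy$tpr2010, 0.687)
})

test_that("beam dataset round-trips through the CSV directory format", {
  beam <- test_beam()
  dir <- withr::local_tempdir()
  write_beam_dataset(beam, dir)
  back <- read_beam_dataset(dir)
  expect_equal(length(back$pdd), 4)
  expect_equal(back$machine_id, beam$machine_id)
  expect_equal(back$d_dmax, beam$d_dmax)
  expect_equal(back$of$factors, beam$of$factors)
  expect_equal(length(back$profiles), length(beam$profiles))
  # PDD serialized at 1 decimal of percent
  for (fs in names(beam$pdd)) {
    expect_equal(back$pdd[[fs]]$depths, beam$pdd[[fs]]$depths)
    expect_equal(back$pdd[[fs]]$values, beam$pdd[[fs]]$values,
                 tolerance = 0.051)
  }
  expect_profiles_equal(back$profiles[[1]], beam$profiles[[1]])
})

test_that("beam directory reading reports broken inputs by file", {
  beam <- test_beam()
  dir <- withr::local_tempdir()
  write_beam_dataset(beam, dir)

  # output factor table without the reference row
  ofd <- read.csv(file.path(dir, "of.csv"))
  write.csv(ofd[ofd$field_size_cm != 10, ], file.path(dir, "of.csv"),
            row.names = FALSE)
  expect_error(read_beam_dataset(dir), "reference field size missing")
  write.csv(ofd, file.path(dir, "of.csv"), row.names = FALSE)

  # de-normalized PDD
  p <- read.csv(file.path(dir, "pdd_10.csv"))
  p$pdd_percent <- p$pdd_percent * 0.994
  write.csv(p, file.path(dir, "pdd_10.csv"), row.names = FALSE)
  expect_error(read_beam_dataset(dir), "not normalized to 100")

  # non-monotone depth grid, error names file and row
  p <- read.csv(file.path(dir, "pdd_10.csv"))
  p$depth_cm[5] <- p$depth_cm[3]
  write.csv(p, file.path(dir, "pdd_10.csv"), row.names = FALSE)
  expect_error(read_beam_dataset(dir), "non-monotone depth grid in pdd_10.csv at row 5")
})

test_that("BCF tables round-trip exactly at three decimals", {
  cl <- clinac_table()
  path <- withr::local_tempfile(fileext = ".csv")
  suppressWarnings(write_bcf_table(cl, path))
  back <- suppressWarnings(read_bcf_table(path))
  expect_identical(back$entrance, cl$entrance)
  expect_identical(back$exit, cl$exit)
  expect_equal(back$machine_id, cl$machine_id)
  expect_equal(back$tpr2010, cl$tpr2010)
})

test_that("measurement sets and dose planes round-trip through CSV", {
  beam <- test_beam()
  m <- generate_measurements(beam, test_deficit(), noise_sd = 0, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  back <- read_measurements(path)
  expect_equal(back$dose_cgy, m$dose_cgy)
  expect_equal(back$backscatter_cm, m$backscatter_cm)

  pl <- truth_exit_plane(beam, test_deficit(), 10, 11.5)
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_dose_plane(pl, ppath)
  pback <- read_dose_plane(ppath)
  expect_equal(pback$depth, pl$depth)
  expect_equal(pback$field_size, pl$field_size)
  expect_equal(pback$x_coords, pl$x_coords)
  expect_equal(pback$dose, pl$dose, tolerance = 1e-5)
})
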