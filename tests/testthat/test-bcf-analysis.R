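test_that("compute_bcf is the dose ratio with plausibility guards", {
  expect_equal(compute_bcf(100, 100), 1.0)
  expect_equal(compute_bcf(96.3, 100), 0.963)
  expect_warning(compute_bcf(100.5, 100), "exceed 1")
  expect_error(compute_bcf(89, 100), "outside")
  expect_error(compute_bcf(102, 100), "outside")
  expect_error(compute_bcf(-1, 100), "positive")
})

test_that("noiseless measurement grids recover the generator's deficit exactly", {
  beam <- test_beam()
  def <- test_deficit()
  m <- generate_measurements(beam, def, noise_sd = 0, seed = 1)
  tab <- build_bcf_table(m, beam)
  truth <- synthetic_bcf_table(def)
  expect_lt(max(abs(tab$entrance - truth$entrance)), 1e-10)
  expect_lt(max(abs(tab$exit - truth$exit)), 1e-10)
  # per-pair closed loop over the exit grid
  grid <- expand.grid(fs = c(5, 10, 15, 20), d = seq(6.5, 31.5, by = 5))
  full <- dose_full_backscatter(beam, grid$fs, grid$d)
  got <- compute_bcf(full * deficit_bcf(def, "exit", grid$fs, grid$d), full)
  expect_lt(max(abs(got - deficit_bcf(def, "exit", grid$fs, grid$d))), 1e-10)
})

test_that("measurements matching the reference dose give an all-ones table", {
  beam <- test_beam()
  grid <- rbind(
    expand.grid(fs = c(5, 10), d = 1.5, t = c(1.5, 6.5)),
    expand.grid(fs = c(5, 10), d = c(6.5, 11.5), t = 1.5))
  m <- dose_measurements("m", grid$fs, grid$d, grid$t,
                         dose = dose_full_backscatter(beam, grid$fs, grid$d))
  tab <- build_bcf_table(m, beam)
  expect_true(all(abs(tab$entrance - 1) < 1e-12))
  expect_true(all(abs(tab$exit - 1) < 1e-12))
})

test_that("an incomplete measurement grid is reported by cell", {
  beam <- test_beam()
  def <- test_deficit()
  m <- generate_measurements(beam, def, noise_sd = 0, seed = 1)
  drop <- !(abs(m$field_size_cm - 15) < 1e-9 & abs(m$depth_cm - 21.5) < 1e-9)
  expect_error(build_bcf_table(m[drop, ], beam),
               "missing cells.*\\(15x15, 21.5 cm\\)")
})

test_that("recovery from 0.5%-noise measurements stays within the 3-sigma band", {
  beam <- test_beam()
  def <- test_deficit()
  truth <- synthetic_bcf_table(def)
  m <- generate_measurements(beam, def, noise_sd = 0.005, seed = 1)
  tab <- suppressWarnings(build_bcf_table(m, beam))
  worst <- max(abs(tab$entrance - truth$entrance),
               abs(tab$exit - truth$exit)) * 100
  expect_lt(worst, 1.5)
})

test_that("summaries reproduce the measured tables' extrema", {
  s_cl <- summarize_bcf(clinac_table())
  expect_equal(s_cl$min_entrance$value, 0.972)
  expect_equal(s_cl$min_entrance$field_size, 20)
  expect_equal(s_cl$min_entrance$key, 1.5)
  expect_equal(s_cl$max_exit$value, 0.995)
  expect_lte(s_cl$max_reduction_pct, 0.5)

  s_sy <- summarize_bcf(synergy_table())
  expect_equal(s_sy$min_entrance$value, 0.978)
  expect_equal(s_sy$min_exit$value, 0.960)

  s_ones <- summarize_bcf(ones_table())
  expect_equal(s_ones$min_entrance$value, 1.0)
  expect_equal(s_ones$max_exit$value, 1.0)
  expect_equal(s_ones$max_reduction_pct, 0)
})

test_that("cross-machine comparison uses unsigned means per block", {
  cmp <- compare_bcf_tables(clinac_table(), synergy_table())
  expect_equal(round(unname(cmp$entrance["mean_pct"]), 1), 0.1)

  same <- compare_bcf_tables(clinac_table(), clinac_table())
  expect_equal(unname(same$entrance), c(0, 0))
  expect_equal(unname(same$exit), c(0, 0))

  one_a <- bcf_table("a", 0.67,
                     matrix(0.99, 1, 1, dimnames = list("10", "1.5")),
                     matrix(0.99, 1, 1, dimnames = list("10", "6.5")))
  one_b <- bcf_table("b", 0.67,
                     matrix(0.97, 1, 1, dimnames = list("10", "1.5")),
                     matrix(0.97, 1, 1, dimnames = list("10", "6.5")))
  cmp1 <- compare_bcf_tables(one_a, one_b)
  expect_equal(unname(cmp1$entrance), c(2.0, 0.0))

  bad <- synthetic_bcf_table(test_deficit(), fs_list = c(5, 10))
  expect_error(compare_bcf_tables(clinac_table(), bad), "different grids")
})

test_that("SSD invariance check measures per-cell percent differences", {
  cl <- clinac_table()
  expect_equal(unname(ssd_invariance_check(cl, cl)), c(0, 0))

  pert <- cl
  pert$entrance[2, 3] <- pert$entrance[2, 3] + 0.005
  expect_equal(unname(ssd_invariance_check(cl, pert)["max_diff_pct"]), 0.5)

  # the generator's backscatter deficit is divergence-free, so fixed-SSD and
  # isocentric campaigns with the same session noise agree exactly
  beam <- test_beam()
  def <- test_deficit()
  m_fix <- generate_measurements(beam, def, noise_sd = 0.005, seed = 9,
                                 geometry = "fixed_ssd")
  m_iso <- generate_measurements(beam, def, noise_sd = 0.005, seed = 9,
                                 geometry = "isocentric")
  t_fix <- suppressWarnings(build_bcf_table(m_fix, beam))
  t_iso <- suppressWarnings(build_bcf_table(m_iso, beam))
  chk <- ssd_invariance_check(t_fix, t_iso)
  expect_lt(unname(chk["max_diff_pct"]), 1)
})

test_that("noiseless deficit tables satisfy the expected monotonic shape", {
  def <- test_deficit()
  tab <- synthetic_bcf_table(def)
  # entrance BCF non-decreasing in backscatter thickness, reaching unity
  for (i in seq_len(nrow(tab$entrance)))
    expect_true(all(diff(tab$entrance[i, ]) >= 0))
  expect_equal(deficit_bcf(def, "entrance", 20, 1000), 1.0)
  # exit BCF <= 1 and decreasing with depth and field size
  expect_true(all(tab$exit <= 1))
  for (i in seq_len(nrow(tab$exit)))
    expect_true(all(diff(tab$exit[i, ]) <= 0))
  for (j in seq_len(ncol(tab$exit)))
    expect_true(all(diff(tab$exit[, j]) <= 0))
  # entrance BCF decreasing with field size at fixed thickness
  for (j in seq_len(ncol(tab$entrance)))
    expect_true(all(diff(tab$entrance[, j]) <= 0))
})
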