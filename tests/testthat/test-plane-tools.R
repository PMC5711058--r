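test_that("central-axis normalization rescales, is idempotent and scale-invariant", {
  pos <- seq(-5, 5, by = 0.2)
  p <- scan_profile("crossline", 5, 10, pos, 50 * exp(-pos^2 / 8))
  n <- normalize_profile(p)
  expect_equal(interpolate(n, 0), 1)
  expect_equal(n$values, p$values / 50)
  # idempotence
  expect_profiles_equal(normalize_profile(n), n)
  # scale invariance
  p2 <- p; p2$values <- p$values * 7.3
  expect_profiles_equal(normalize_profile(p2), n)
  # symmetry preservation
  expect_equal(n$values, rev(n$values))
  # zero central-axis value
  bad <- scan_profile("crossline", 5, 10, pos, abs(pos))
  expect_error(normalize_profile(bad), "positive")
})

test_that("cross-multiplied planes have the defining separable structure", {
  pos <- seq(-8, 8, by = 0.2)
  flat <- scan_profile("crossline", 5, 8, pos, rep(2.5, length(pos)))
  flat_y <- scan_profile("inline", 5, 8, pos, rep(4, length(pos)))
  pl <- synthesize_plane(flat, flat_y, d_cax = 50)
  expect_true(all(abs(pl$dose - 50) < 1e-12))

  px <- scan_profile("crossline", 5, 8, pos, 80 * exp(-pos^2 / 10))
  py <- scan_profile("inline", 5, 8, pos, 60 * exp(-pos^2 / 14))
  pl <- synthesize_plane(px, py, d_cax = 85.2)
  expect_equal(plane_cax_dose(pl), 85.2)

  # grid values equal the direct outer product of the closed-form profiles
  direct <- 85.2 * outer(exp(-pl$x_coords^2 / 10), exp(-pl$y_coords^2 / 14))
  expect_lt(max(abs(pl$dose - direct)), 1e-12)

  # the y = 0 row is exactly d_cax times the normalized crossline profile
  j0 <- which(abs(pl$y_coords) < 1e-12)
  expect_lt(max(abs(pl$dose[, j0] - 85.2 * exp(-pl$x_coords^2 / 10))), 1e-12)

  # separability identity at random points
  set.seed(5)
  ix <- sample(seq_along(pl$x_coords), 200, replace = TRUE)
  iy <- sample(seq_along(pl$y_coords), 200, replace = TRUE)
  lhs <- pl$dose[cbind(ix, iy)] * plane_cax_dose(pl)
  rhs <- pl$dose[cbind(ix, j0)] * pl$dose[cbind(j0, iy)]
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  mism <- scan_profile("inline", 9, 8, pos, rep(1, length(pos)))
  expect_error(synthesize_plane(px, mism, 50), "different depths")
  expect_error(synthesize_plane(px, py, -1), "positive")
})

test_that("profile extraction inverts synthesis on the grid and on the diagonal", {
  beam <- test_beam()
  px <- normalize_profile(extract_profile(
    truth_exit_plane(beam, test_deficit(), 20, 21.5), "crossline"))
  expect_equal(interpolate(px, 0), 1)

  pos <- seq(-8, 8, by = 0.2)
  gx <- scan_profile("crossline", 5, 8, pos, 80 * exp(-pos^2 / 10))
  gy <- scan_profile("inline", 5, 8, pos, 60 * exp(-pos^2 / 14))
  pl <- synthesize_plane(gx, gy, d_cax = 70)

  # native-spacing crossline extraction returns exact grid values
  ex <- extract_profile(pl, "crossline")
  j0 <- which(abs(pl$y_coords) < 1e-12)
  expect_equal(ex$positions, pl$x_coords)
  expect_lt(max(abs(ex$values - pl$dose[, j0])), 1e-12)

  # round trip against the normalized source profile
  nx <- normalize_profile(gx)
  expect_lt(max(abs(ex$values - 70 * interpolate(nx, ex$positions))), 1e-9)

  # diagonal of a separable plane follows the closed form
  dg <- extract_profile(pl, "diagonal", spacing = 0.35)
  ny <- normalize_profile(gy)
  s <- dg$positions / sqrt(2)
  want <- 70 * interpolate(nx, s) * interpolate(ny, s)
  expect_lt(max(abs(dg$values - want)), 1e-9)

  # uniform plane gives a flat profile on every axis
  u <- flat_plane(42, n = 21, spacing = 0.4)
  for (ax in c("crossline", "inline", "diagonal"))
    expect_true(all(abs(extract_profile(u, ax)$values - 42) < 1e-12))

  expect_error(extract_profile(pl, "crossline", spacing = 0), "positive")
})

test_that("relative profile comparison localizes differences by field region", {
  pos <- seq(-16, 16, by = 0.2)
  depth <- 21.5
  base <- scan_profile("crossline", depth, 20, pos,
                       0.5 * (pracma::erf((12.15 - pos) / 0.5) +
                              pracma::erf((12.15 + pos) / 0.5)))
  a <- normalize_profile(base)
  cmp0 <- compare_relative_profiles(a, a)
  expect_true(all(abs(cmp0$table$diff) < 1e-12))

  # off-axis-only scaling leaves the centre untouched
  b <- a
  b$values <- a$values * ifelse(abs(pos) > 2, 1.02, 1)
  cmp <- compare_relative_profiles(a, b)
  ctr <- abs(cmp$table$position_cm) < 1.8
  expect_true(all(abs(cmp$table$diff[ctr]) < 1e-12))
  expect_gt(cmp$max_abs_shoulder, 0)

  # a shoulder-boost TPS emulation shows its largest deviation in the shoulder
  beam <- test_beam()
  def <- test_deficit()
  truth <- truth_exit_plane(beam, def, 20, 31.5)
  emu <- emulate_tps_plane(beam, def, tps_emulator_spec("shoulder_boost"),
                           20, 31.5)
  pa <- normalize_profile(extract_profile(truth, "crossline"))
  pb <- normalize_profile(extract_profile(emu, "crossline"))
  cmp2 <- compare_relative_profiles(pa, pb)
  expect_gt(cmp2$max_abs_shoulder, cmp2$max_abs_field)
  i_max <- which.max(abs(cmp2$table$diff))
  expect_equal(cmp2$table$region[i_max], "shoulder")

  # disjoint position ranges cannot be compared
  left <- scan_profile("crossline", 5, 10, seq(-4, 0, 0.5), rep(1, 9))
  right <- scan_profile("crossline", 5, 10, seq(0, 4, 0.5), rep(1, 9))
  expect_error(compare_relative_profiles(left, right), "overlap")
})
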