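# Shared fixtures, built once per run.

test_beam <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_beam()
    cache
  }
})

test_deficit <- function() backscatter_deficit_spec()

clinac_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressWarnings(bcf_reference_table("clinac21ex"))
    cache
  }
})

synergy_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- bcf_reference_table("synergy")
    cache
  }
})

# small random plane on a coarse grid for gamma oracle comparisons
tiny_plane <- function(seed, n = 7, spacing = 0.5, depth = 5, fs = 2,
                       lo = 50, hi = 100) {
  set.seed(seed)
  half <- (n - 1) / 2 * spacing
  x <- seq(-half, half, by = spacing)
  dose_plane(depth, fs, x, x, matrix(stats::runif(n * n, lo, hi), n, n))
}

# uniform-dose plane
flat_plane <- function(value, n = 7, spacing = 0.5, depth = 5, fs = 2) {
  half <- (n - 1) / 2 * spacing
  x <- seq(-half, half, by = spacing)
  dose_plane(depth, fs, x, x, matrix(value, n, n))
}

# all-ones BCF table on the standard measurement grid
ones_table <- function(fs = c(5, 10, 15, 20),
                       thickness = seq(1.5, 31.5, by = 5),
                       depths = seq(6.5, 31.5, by = 5)) {
  ent <- matrix(1, length(fs), length(thickness),
                dimnames = list(format(fs), format(thickness)))
  ext <- matrix(1, length(fs), length(depths),
                dimnames = list(format(fs), format(depths)))
  bcf_table("ones", 0.67, ent, ext)
}

# coarse criteria keeping the exhaustive oracle cheap
coarse_criteria <- function() {
  gamma_criteria(dose_percent = 3, dta_mm = 3, search_radius_factor = 2,
                 subsample_step_mm = 1)
}

expect_profiles_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$positions, b$positions, tolerance = tol)
  expect_equal(a$values, b$values, tolerance = tol)
}
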