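test_that("rendered profiles conserve area and peak position", {
  for (fwhm in c(0.05, 0.3, 2)) {
    prof <- render_profile(
      tibble::tibble(mass = c(100, 101, 102.5),
                     probability = c(0.5, 0.3, 0.2)),
      fwhm = fwhm)
    expect_equal(attr(prof, "area"), 1, tolerance = 1e-6)
  }
  single <- render_profile(tibble::tibble(mass = 500, probability = 1),
                           fwhm = 0.1)
  expect_equal(single$mass[which.max(single$intensity)], 500,
               tolerance = 0.02)
  # resolving power: FWHM = mass / R
  rp <- render_profile(tibble::tibble(mass = 1000, probability = 1),
                       resolving_power = 1e4)
  expect_equal(attr(rp, "fwhm"), 0.1)
})

test_that("two equal sticks resolve or merge according to the FWHM", {
  sticks <- tibble::tibble(mass = c(100, 101), probability = c(0.5, 0.5))
  n_maxima <- function(prof) {
    # half-open comparison so a symmetric plateau counts once
    y <- prof$intensity
    sum(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
          y[2:(length(y) - 1)] >= y[3:length(y)])
  }
  expect_identical(n_maxima(render_profile(sticks, fwhm = 0.5)), 2L)
  expect_identical(n_maxima(render_profile(sticks, fwhm = 2)), 1L)
})

test_that("FWHM/sigma conversion uses 2 sqrt(2 ln 2)", {
  expect_equal(fwhm_from_sigma(249), 586, tolerance = 1e-3)
  expect_equal(sigma_from_fwhm(fwhm_from_sigma(1.7)), 1.7)
})

test_that("profile rendering validates its grid", {
  sticks <- tibble::tibble(mass = c(100, 110), probability = c(0.5, 0.5))
  expect_error(render_profile(sticks, fwhm = 1, mass_range = c(99, 111)),
               "mass_range")
  expect_error(render_profile(sticks), "exactly one")
  expect_error(render_profile(sticks, fwhm = 1, resolving_power = 1e5),
               "exactly one")
})

test_that("binning accumulates weights and applies pseudo-counts", {
  # uniform points spanning the bins: equal fractions
  b <- bin_distribution(seq(0.05, 3.95, by = 0.1), n_bins = 4,
                        range = c(0, 4))
  expect_equal(b$fraction, rep(0.25, 4))
  expect_equal(sum(b$fraction), 1, tolerance = 1e-12)
  # all mass on one point at weight scale W: fractions (W+1, 1)/(W+2)
  for (W in c(1, 10, 1000)) {
    b2 <- bin_distribution(0.25, weights = W, n_bins = 2, range = c(0, 1))
    expect_equal(b2$fraction, c(W + 1, 1) / (W + 2))
  }
  expect_error(bin_distribution(rep(2, 5), n_bins = 2), "degenerate")
  expect_error(bin_distribution(1:5, n_bins = 1), "n_bins")
})

test_that("divergence measures satisfy the defining identities", {
  # P = (0.5, 0.5) vs Q = (0.25, 0.75), by hand
  P <- bin_distribution(c(0.25, 0.75), weights = c(1, 1), n_bins = 2,
                        pseudo_count = 0, range = c(0, 1))
  Q <- bin_distribution(c(0.25, 0.75), weights = c(1, 3), n_bins = 2,
                        pseudo_count = 0, range = c(0, 1))
  expect_equal(kl_divergence(P, Q), 0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(kl_divergence(P, P), 0)
  expect_equal(binned_entropy(P), log(2))
  # H(P,Q) = H(P) + D_KL for random binned pairs
  set.seed(21)
  for (i in 1:10) {
    x <- stats::runif(50); y <- stats::runif(60)
    rng <- c(-0.1, 1.1)
    p <- bin_distribution(x, n_bins = 20, range = rng)
    q <- bin_distribution(y, n_bins = 20, range = rng)
    expect_lt(abs(cross_entropy(p, q) -
                    (binned_entropy(p) + kl_divergence(p, q))), 1e-12)
    expect_gte(kl_divergence(p, q), 0)
  }
  # mismatched edges are rejected
  p <- bin_distribution(1:5, n_bins = 4)
  q <- bin_distribution(1:5, n_bins = 4, range = c(0, 6))
  expect_error(kl_divergence(p, q), "incompatible")
})

test_that("normality report returns the three measures and honors Gibbs",
{
  r <- normality_report("C6H6N6O6S2", j = 2, n_bins = 100)
  expect_gt(r$n_peaks, 1)
  expect_gte(r$kl, 0)
  expect_lt(abs(r$cross_entropy - (r$entropy + r$kl)), 1e-12)
  # single fine peak: zero-width support, divergence undefined
  r0 <- normality_report("C10", j = 2, n_bins = 100)
  expect_identical(r0$n_peaks, 1L)
  expect_true(is.na(r0$kl))
})

test_that("sampled normality mode is seed-reproducible", {
  a <- normality_report("C6H6N6O6S2", j = 2, n_bins = 50, mode = "sample",
                        seed = 5, count_scale = 1e4)
  b <- normality_report("C6H6N6O6S2", j = 2, n_bins = 50, mode = "sample",
                        seed = 5, count_scale = 1e4)
  expect_identical(a, b)
  c <- normality_report("C6H6N6O6S2", j = 2, n_bins = 50, mode = "sample",
                        seed = 6, count_scale = 1e4)
  expect_false(identical(a$kl, c$kl))
})
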