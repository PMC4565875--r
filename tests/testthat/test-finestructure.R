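tab <- isotope_table()

test_that("fine-peak counting solves the bounded money-exchange problem", {
  expect_identical(count_fine_peaks("C2H2N2O2S2", 0, tab), 1)
  expect_identical(count_fine_peaks("C2H2N2O2S2", 1, tab), 5)
  expect_identical(count_fine_peaks("C2H2N2O2S2", 2, tab), 17)
  # one-offset-per-element cases read off directly
  expect_identical(count_fine_peaks("C10", 3, tab), 1)
  expect_identical(count_fine_peaks("S1", 2, tab), 1)  # 34S only
  expect_identical(count_fine_peaks("S2", 2, tab), 2)  # 34S or 33S2
  # atom bounds bind: one H cannot host two 2H
  expect_identical(count_fine_peaks("C1H1", 2, tab), 1)
})

test_that("counts match exhaustive enumeration on small formulas", {
  for (fc in list(c(C = 2, H = 2, N = 2, O = 2, S = 2),
                  c(C = 1, O = 3, S = 2), c(H = 2, N = 2, S = 3))) {
    oa <- oracle_aggregated(fc, tab)
    for (i in seq_len(nrow(oa))) {
      expect_identical(
        count_fine_peaks(as_iso_formula(fc), oa$j[i], tab),
        as.numeric(oa$n_peaks[i]))
    }
  }
})

test_that("counts are non-decreasing in each atom count at fixed j", {
  base <- c(C = 2, H = 2, N = 2, O = 2, S = 2)
  for (el in names(base)) {
    bigger <- base
    bigger[el] <- bigger[el] + 3
    for (j in 1:4) {
      expect_gte(count_fine_peaks(as_iso_formula(bigger), j, tab),
                 count_fine_peaks(as_iso_formula(base), j, tab))
    }
  }
})

test_that("full enumeration reproduces counts and aggregated probabilities", {
  for (fc in list(c(C = 2, H = 2, N = 2, O = 2, S = 2),
                  c(C = 1, H = 1, N = 1, O = 1, S = 1),
                  c(O = 3, S = 3))) {
    f <- as_iso_formula(fc)
    oa <- oracle_aggregated(fc, tab)
    for (j in oa$j[oa$j <= 6]) {
      fine <- enumerate_fine_peaks(f, j, tab, min_prob = 0)
      expect_identical(nrow(fine), as.integer(oa$n_peaks[oa$j == j]))
      expect_lt(abs(sum(fine$probability) - oa$q[oa$j == j]) /
                  oa$q[oa$j == j], 1e-9)
      expect_lt(abs(attr(fine, "q_j") - oa$q[oa$j == j]) /
                  oa$q[oa$j == j], 1e-9)
      # composition invariants
      heavy <- neutron_denominations(f, tab)
      cnt <- as.matrix(fine[, heavy$isotope, drop = FALSE])
      expect_true(all(cnt %*% heavy$neutron_offset == j))
    }
  }
})

test_that("the j = 1 variant of a CHNOS molecule is the five single
          substitutions", {
  fine <- enumerate_fine_peaks("C2H2N2O2S2", 1, tab)
  expect_identical(nrow(fine), 5L)
  cnt <- as.matrix(fine[, c("13C", "2H", "15N", "17O", "18O",
                            "33S", "34S", "36S")])
  expect_true(all(rowSums(cnt) == 1))
  expect_true(all(colSums(cnt[, c("13C", "2H", "15N", "17O", "33S")]) == 1))
})

test_that("monoisotopic variant is the single all-light peak", {
  fine <- enumerate_fine_peaks("C3H4O2", 0, tab)
  expect_identical(nrow(fine), 1L)
  f <- parse_formula("C3H4O2")
  p_expected <- prod(purrr::map_dbl(names(f), function(el) {
    tab$abundance[tab$element == el][1]^f[[el]]
  }))
  expect_equal(fine$probability, p_expected)
  expect_equal(fine$mass, monoisotopic_mass(f, tab))
})

test_that("enumeration beyond the attainable neutron count is empty", {
  fine <- enumerate_fine_peaks("C2", 5, tab)
  expect_identical(nrow(fine), 0L)
})

test_that("pruning keeps only peaks above the relative floor", {
  fine_all <- enumerate_fine_peaks("C5H5N5O5S5", 3, tab, min_prob = 0)
  fine_cut <- enumerate_fine_peaks("C5H5N5O5S5", 3, tab, min_prob = 1e-3)
  qj <- attr(fine_all, "q_j")
  expect_true(all(fine_cut$probability >= 1e-3 * qj))
  expect_identical(
    nrow(fine_cut), sum(fine_all$probability >= 1e-3 * qj))
  expect_lte(attr(fine_cut, "captured"), attr(fine_all, "captured"))
  expect_equal(attr(fine_all, "captured"), qj, tolerance = 1e-12)
})

test_that("specific isotopologue probabilities follow the multinomial", {
  # against dmultinom on a one-element case
  d <- tab[tab$element == "S", ]
  p <- fine_peak_probability("S5", c("33S" = 1, "34S" = 2), tab)
  expect_equal(p$probability,
               stats::dmultinom(c(2, 1, 2, 0), prob = d$abundance))
  expect_identical(p$j, 5L)
  expect_error(fine_peak_probability("S1", c("33S" = 2), tab),
               "exceed")
  expect_error(fine_peak_probability("S1", c("13C" = 1), tab), "absent")
})

test_that("closed-form spread uses the 2H/15N mass-per-neutron extremes", {
  h <- tab[tab$element == "H", ]
  n <- tab[tab$element == "N", ]
  mu2h <- h$mass_Da[2] - h$mass_Da[1]
  mu15n <- n$mass_Da[2] - n$mass_Da[1]
  expect_equal(max_spread("C2H2N2O2S2", 1, tab), mu2h - mu15n)
  expect_equal(max_spread("C2H2N2O2S2", 7, tab), 7 * (mu2h - mu15n))
  expect_identical(max_spread("C2H2N2O2S2", 0, tab), 0)
})

test_that("bounded spread is exact and never exceeds the closed form", {
  for (fc in list(c(C = 2, H = 2, N = 2, O = 2, S = 2),
                  c(C = 10, O = 5), c(H = 3, N = 1, S = 2))) {
    f <- as_iso_formula(fc)
    oa <- oracle_aggregated(fc, tab)
    for (j in oa$j[oa$j >= 1 & oa$j <= 6]) {
      b <- max_spread(f, j, tab, mode = "bounded")
      expect_equal(b, oa$spread[oa$j == j], tolerance = 1e-9)
      expect_lte(b, max_spread(f, j, tab, mode = "eq7") + 1e-15)
    }
  }
  # equality whenever enough H and N atoms exist
  expect_equal(max_spread("C2H4N4O2S2", 3, tab, mode = "bounded"),
               max_spread("C2H4N4O2S2", 3, tab, mode = "eq7"))
  # no H or N available: strictly below the closed form
  expect_lt(max_spread("C10O5", 2, tab, mode = "bounded"),
            max_spread("C10O5", 2, tab, mode = "eq7"))
})

test_that("mean spacing divides width by the exact peak count", {
  sp <- mean_spacing("C2H2N2O2S2", 1, tab)
  expect_equal(sp, max_spread("C2H2N2O2S2", 1, tab) / 5)
  expect_equal(mean_spacing("C2H2N2O2S2", 1, tab, width = "sigma", k = 0), 0)
  agg <- aggregated_distribution("C2H2N2O2S2", tab)
  s1 <- mean_spacing("C2H2N2O2S2", 1, tab, width = "sigma", k = 2, agg = agg)
  s2 <- mean_spacing("C2H2N2O2S2", 1, tab, width = "sigma", k = 4, agg = agg)
  expect_equal(s2, 2 * s1)
  # single-peak variant: spacing undefined
  expect_error(mean_spacing("C3", 2, tab), "undefined")
})

test_that("ion sampling is reproducible and reports exact mean occupancy", {
  s <- sample_ions(1000, n_ions = 300, seed = 42)
  expect_identical(s$mean_occupancy, 0.3)
  expect_identical(sum(attr(s, "occupancy")), 300L)
  s2 <- sample_ions(1000, n_ions = 300, seed = 42)
  expect_identical(attr(s, "occupancy"), attr(s2, "occupancy"))
  s3 <- sample_ions(1000, n_ions = 300, seed = 43)
  expect_false(identical(attr(s, "occupancy"), attr(s3, "occupancy")))
  z <- sample_ions(50, n_ions = 0, seed = 1)
  expect_identical(z$occupied_fraction, 0)
  fine <- enumerate_fine_peaks("C2H2N2O2S2", 2, tab)
  sf <- sample_ions(fine, n_ions = 100, seed = 7)
  expect_identical(sf$n_peaks, 17L)
  expect_identical(sum(attr(sf, "occupancy")), 100L)
})

test_that("sampling does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(sample_ions(100, 10, seed = 3))
  expect_identical(.Random.seed, before)
})
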