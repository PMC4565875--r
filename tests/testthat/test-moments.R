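tab <- isotope_table()

test_that("single-carbon distribution reproduces the table abundances", {
  a <- aggregated_distribution("C1", tab)
  c_rec <- tab[tab$element == "C", ]
  expect_equal(a$q, c_rec$abundance)
  expect_equal(a$variance, c(0, 0))
  expect_equal(a$entropy, c(0, 0))
  expect_equal(a$center_mass, c_rec$mass_Da)
  expect_identical(most_abundant_variant(a), 0L)
})

test_that("generating-function path matches exhaustive enumeration", {
  cases <- list(c(C = 1, H = 1, N = 1, O = 1, S = 1),
                c(C = 2, H = 2, N = 2, O = 2, S = 2),
                c(C = 3, O = 3, S = 2),
                c(H = 4, S = 3),
                c(N = 2, O = 4))
  for (fc in cases) {
    oa <- oracle_aggregated(fc, tab)
    agg <- as.data.frame(aggregated_distribution(as_iso_formula(fc), tab,
                                                 coverage = 1,
                                                 j_max = max(oa$j)))
    m <- merge(oa, agg, by = "j")
    expect_equal(nrow(m), nrow(oa))
    expect_lt(max(abs(m$q.x - m$q.y) / m$q.x), 1e-9)
    expect_lt(max(abs(m$center_mass.x - m$center_mass.y) / m$center_mass.x),
              1e-9)
    expect_lt(max(abs(m$variance.x - m$variance.y) /
                    pmax(m$variance.x, 1e-6)), 1e-9)
    expect_lt(max(abs(m$entropy.x - m$entropy.y) /
                    pmax(m$entropy.x, 1e-3)), 1e-9)
  }
})

test_that("aggregated distribution is normalized and mean-consistent", {
  for (fs in list("C50H80N20O30S5", "C2934H4615N781O897S39")) {
    agg <- aggregated_distribution(fs, tab)
    expect_gte(attr(agg, "coverage"), 1 - 1e-11)
    expect_true(all(agg$q >= 0))
    expect_true(all(agg$variance >= 0))
    expect_true(all(agg$entropy >= 0))
    mbar <- sum(agg$q * agg$center_mass) / sum(agg$q)
    expect_lt(abs(mbar - attr(agg, "average_mass")), 1e-6)
  }
})

test_that("most abundant variant breaks ties toward the smaller j", {
  fake <- tibble::tibble(j = c(3L, 5L, 7L), q = c(0.2, 0.3, 0.3))
  expect_identical(most_abundant_variant(fake), 5L)
})

test_that("generic CHNOS j = 1 variant has positive entropy (5 fine peaks)", {
  agg <- aggregated_distribution("C2H2N2O2S2", tab)
  expect_identical(count_fine_peaks("C2H2N2O2S2", 1, tab), 5)
  expect_gt(agg$entropy[agg$j == 1], 0)
})

test_that("variance decomposition satisfies the ANOVA identity", {
  for (fc in list(c(C = 1, H = 1, N = 1, O = 1, S = 1),
                  c(C = 3, H = 4, O = 2, S = 1))) {
    vd <- variance_decomposition(as_iso_formula(fc), tab)
    expect_lt(abs(vd$total - (vd$within + vd$between)) / vd$total, 1e-12)
    expect_lt(abs(vd$total - vd$total_closed_form) / vd$total, 1e-9)
    ft <- oracle_fine_table(fc, tab)
    mbar <- sum(ft$p * ft$m)
    brute_total <- sum(ft$p * (ft$m - mbar)^2)
    expect_lt(abs(vd$total - brute_total) / brute_total, 1e-9)
  }
})

test_that("closed-form total variance holds up to large molecules", {
  vd <- variance_decomposition("C19754H31033N5431O5909S167", tab)
  expect_lt(abs(vd$total - vd$total_closed_form) / vd$total, 1e-9)
})

test_that("homoatomic two-isotope molecules have zero within-variance", {
  agg <- aggregated_distribution("C2", tab)
  expect_equal(agg$variance, rep(0, nrow(agg)))
  vd <- variance_decomposition("C2", tab)
  expect_equal(vd$within, 0)
})

test_that("entropy decomposition splits total into within + between", {
  # every aggregated variant of C5 is a single fine peak
  ed <- entropy_decomposition("C5", tab)
  expect_equal(ed$within, 0)
  expect_equal(ed$total, ed$between)
  fc <- c(C = 1, H = 1, N = 1, O = 1, S = 1)
  ed <- entropy_decomposition(as_iso_formula(fc), tab)
  ft <- oracle_fine_table(fc, tab)
  brute <- -sum(ft$p * log(ft$p))
  expect_lt(abs(ed$total - brute) / brute, 1e-9)
  expect_lt(abs(ed$total - (ed$within + ed$between)) / ed$total, 1e-12)
  expect_true(all(c(ed$within, ed$between) >= 0))
})

test_that("fine-structure entropy is zero exactly for single-peak variants", {
  for (fs in c("C4H6", "C2O3", "N2S2")) {
    agg <- aggregated_distribution(fs, tab, coverage = 1)
    for (i in seq_len(nrow(agg))) {
      n <- count_fine_peaks(fs, agg$j[i], tab)
      if (n == 1) {
        expect_lt(agg$entropy[i], 1e-10)
      } else {
        expect_gt(agg$entropy[i], 0)
      }
    }
  }
})

test_that("entropy unit can be reported in bits", {
  nats <- entropy_decomposition("C2H2N2O2S2", tab)
  bits <- entropy_decomposition("C2H2N2O2S2", tab, unit = "bits")
  expect_equal(bits$total, nats$total / log(2))
})

test_that("explicit j window and coverage behave as documented", {
  a <- aggregated_distribution("C100", tab, j_max = 5)
  expect_lte(max(a$j), 5L)
  expect_lt(attr(a, "coverage"), 1)
  expect_error(aggregated_distribution("C1", tab, coverage = 0), "coverage")
})
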