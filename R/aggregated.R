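#' Aggregated isotope distribution with fine-structure moments and entropy
#'
#' Computes, for every neutron index j (number of additional neutrons
#' relative to the monoisotopic variant), the probability q_j of the
#' aggregated isotopic variant together with the moments and entropy of its
#' fine structure: the center mass E(m_j), the variance
#' Var(m_j) = E(m_j^2) - E(m_j)^2, and the information-theory entropy H(j) of
#' the fine peaks within the variant. Everything is obtained by convolving,
#' element by element, per-atom coefficient vectors that carry
#' (sum p, sum p*m, sum p*m^2, sum -p*log p) per neutron index, raised to the
#' atom counts by repeated squaring. No fine structure is ever enumerated, so
#' the cost is polynomial in the molecule size.
#'
#' @param formula Formula string or [parse_formula()] result.
#' @param table Isotope table (see [isotope_table()]).
#' @param coverage Target total probability to capture; the j window is
#'   extended until `sum(q_j) >= coverage`. Default captures all but 1e-12.
#' @param j_max Optional explicit upper bound on j, overriding the automatic
#'   window (the window is otherwise mean +/- 12 envelope standard deviations
#'   of the neutron-count distribution).
#' @param unit Entropy unit, `"nats"` (natural log, default) or `"bits"`.
#'
#' @return A tibble of class `iso_aggregated` with one row per attainable j
#'   in the computed window and columns `j`, `q` (probability),
#'   `center_mass` (Da), `variance` (Da^2), `sigma` (Da) and `entropy`.
#'   Attributes: `formula`, `monoisotopic`, `average_mass`, `coverage`
#'   (sum of q over the window), `unit`, `provenance`.
#'
#' @details Masses are accumulated as offsets from the per-variant affine
#'   reference (monoisotopic mass + j * 13C-neutron mass), so the
#'   accumulated magnitudes stay of the order of the fine-structure spread
#'   and the variance subtraction E(m^2) - E(m)^2 does not cancel
#'   catastrophically even for megadalton molecules. The entropy uses the
#'   identity H(j) = (sum_k -p_jk log p_jk)/q_j + log q_j; because fine
#'   peaks are lumped isotope-count classes (not labeled-atom
#'   configurations), the -p log p accumulator is built per element from
#'   multinomial composition probabilities and then convolved across
#'   elements, where it is additive.
#'
#' @examples
#' agg <- aggregated_distribution("C2934H4615N781O897S39")
#' most_abundant_variant(agg)
#' @export
aggregated_distribution <- function(formula, table = isotope_table(),
                                    coverage = 1 - 1e-12, j_max = NULL,
                                    unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  f <- as_iso_formula(formula, table)
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1) {
    stop("`coverage` must be in (0, 1]", call. = FALSE)
  }
  recs <- lapply(names(f), element_records, table = table)
  names(recs) <- names(f)
  counts <- as.numeric(f)

  stats_j <- neutron_count_stats(recs, counts)
  attain <- stats_j$attainable_max
  jmax <- if (!is.null(j_max)) {
    min(as.integer(j_max), attain)
  } else {
    min(attain, ceiling(stats_j$mean + 12 * sqrt(stats_j$var) + 12))
  }

  cref <- .neutron_ref_mass(table)
  repeat {
    acc <- gf_molecule(recs, counts, jmax, cref)
    cov <- sum(acc$S0)
    # an explicit j_max is an override: no window growth
    if (!is.null(j_max) || cov >= coverage || jmax >= attain) break
    # The measured defect can be dominated by floating-point accumulation;
    # a Bernstein bound on the true right-tail mass of the neutron count
    # (independent per-atom increments bounded by the largest offset)
    # decides whether the window itself is actually sufficient.
    t <- jmax - stats_j$mean
    bmax <- max(purrr::map_dbl(recs, ~ max(.x$offset)))
    tail_bound <- if (t > 0) {
      exp(-t^2 / (2 * (stats_j$var + bmax * t / 3)))
    } else 1
    if (tail_bound <= 1 - coverage) break
    jmax <- min(attain, max(jmax * 2L, jmax + 16L))
  }

  mono <- monoisotopic_mass(f, table)
  j <- seq.int(0L, jmax)
  keep <- acc$S0 > 0
  q <- acc$S0[keep]
  jk <- j[keep]
  e1 <- acc$S1[keep] / q
  e2 <- acc$S2[keep] / q
  v <- pmax(0, e2 - e1^2)
  h <- pmax(0, acc$L1[keep] / q + log(q))
  if (unit == "bits") h <- h / log(2)

  out <- tibble::tibble(
    j = jk,
    q = q,
    center_mass = mono + jk * cref + e1,
    variance = v,
    sigma = sqrt(v),
    entropy = h
  )
  attr(out, "formula") <- format(f)
  attr(out, "monoisotopic") <- mono
  attr(out, "average_mass") <- average_mass(f, table)
  attr(out, "coverage") <- cov
  attr(out, "unit") <- unit
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- c("iso_aggregated", class(out))
  out
}

# Reference mass per neutron used as the affine offset origin (13C - 12C);
# any constant works, this one zeroes the dominant carbon contribution.
.neutron_ref_mass <- function(table) {
  if ("C" %in% table$element) {
    r <- element_records(table, "C")
    if (length(r$dmass) > 1) return(r$dmass[2])
  }
  1.003354835
}

# Closed-form mean/variance of the total neutron count (sum of independent
# per-atom neutron counts), used to size the j window.
neutron_count_stats <- function(recs, counts) {
  mean_j <- 0; var_j <- 0; attain <- 0
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    mu <- sum(r$abundance * r$offset)
    m2 <- sum(r$abundance * r$offset^2)
    mean_j <- mean_j + counts[i] * mu
    var_j <- var_j + counts[i] * (m2 - mu^2)
    attain <- attain + counts[i] * max(r$offset)
  }
  list(mean = mean_j, var = var_j, attainable_max = attain)
}

# ---- generating-function accumulator arithmetic -------------------------
# A "gf" is a list of 3 aligned numeric vectors over j = 0..deg:
#   S0[j] = sum_k p, S1[j] = sum_k p*m~, S2[j] = sum_k p*m~^2,
# where m~ is the mass offset relative to j * cref. Products of independent
# parts convolve: masses add, probabilities multiply. Moments may be
# accumulated atom by atom because all atom-level configurations that merge
# into one isotopologue share the same mass; the entropy accumulator may
# not (it needs the lumped multinomial probabilities) and is built per
# element by `element_entropy_poly()` instead.

gf_single_atom <- function(rec, cref) {
  adj <- rec$dmass - rec$offset * cref
  deg <- max(rec$offset)
  S0 <- numeric(deg + 1L); S1 <- S0; S2 <- S0
  for (i in seq_along(rec$offset)) {
    k <- rec$offset[i] + 1L
    p <- rec$abundance[i]
    S0[k] <- S0[k] + p
    S1[k] <- S1[k] + p * adj[i]
    S2[k] <- S2[k] + p * adj[i]^2
  }
  list(S0 = S0, S1 = S1, S2 = S2)
}

gf_conv <- function(x, y, jmax) {
  nx <- length(x); ny <- length(y)
  n <- min(jmax + 1L, nx + ny - 1L)
  out <- numeric(n)
  for (k in seq_len(min(nx, n))) {
    xv <- x[k]
    if (xv != 0) {
      hi <- min(n, k + ny - 1L)
      out[k:hi] <- out[k:hi] + xv * y[seq_len(hi - k + 1L)]
    }
  }
  out
}

gf_mul <- function(a, b, jmax) {
  list(
    S0 = gf_conv(a$S0, b$S0, jmax),
    S1 = gf_conv(a$S1, b$S0, jmax) + gf_conv(a$S0, b$S1, jmax),
    S2 = gf_conv(a$S2, b$S0, jmax) + 2 * gf_conv(a$S1, b$S1, jmax) +
      gf_conv(a$S0, b$S2, jmax)
  )
}

gf_sq <- function(a, jmax) {
  list(
    S0 = gf_conv(a$S0, a$S0, jmax),
    S1 = 2 * gf_conv(a$S1, a$S0, jmax),
    S2 = 2 * gf_conv(a$S2, a$S0, jmax) + 2 * gf_conv(a$S1, a$S1, jmax)
  )
}

gf_one <- function() list(S0 = 1, S1 = 0, S2 = 0)

gf_pow <- function(base, n, jmax) {
  res <- gf_one()
  while (n > 0) {
    if (n %% 2 == 1) res <- gf_mul(res, base, jmax)
    n <- n %/% 2
    if (n > 0) base <- gf_sq(base, jmax)
  }
  res
}

gf_molecule <- function(recs, counts, jmax, cref) {
  acc <- gf_one()
  eS0 <- 1; eL1 <- 0
  for (i in seq_along(recs)) {
    atom <- gf_single_atom(recs[[i]], cref)
    acc <- gf_mul(acc, gf_pow(atom, counts[i], jmax), jmax)
    ep <- element_entropy_poly(recs[[i]], counts[i], jmax)
    eL1 <- gf_conv(eL1, ep$S0, jmax) + gf_conv(eS0, ep$L1, jmax)
    eS0 <- gf_conv(eS0, ep$S0, jmax)
  }
  # pad to full window
  n <- jmax + 1L
  acc$L1 <- eL1
  lapply(acc, function(v) c(v, numeric(n - length(v))))
}

# Per-element entropy accumulator: S0[j'] = sum of multinomial composition
# probabilities with j' extra neutrons, L1[j'] = sum of p * (-log p) over
# the same compositions. Built by expanding the element's heavy-isotope
# compositions with sequential-binomial log-probabilities:
#   p = prod_i choose(n - atoms_used_before_i, c_i) a_i^{c_i} * a0^{n-u}.
# Atom-count and neutron bounds keep the expansion polynomial.
element_entropy_poly <- function(rec, n, jmax) {
  heavy <- which(rec$offset > 0 & rec$abundance > 0)
  la <- log(ifelse(rec$abundance > 0, rec$abundance, 1))
  j <- 0L; u <- 0L; lp <- 0
  for (i in heavy) {
    d <- rec$offset[i]
    reps <- pmin(n - u, (jmax - j) %/% d) + 1L
    if (sum(reps) > 2e7) {
      stop("entropy composition expansion too large; reduce the j window",
           call. = FALSE)
    }
    idx <- rep.int(seq_along(j), reps)
    c_new <- sequence(reps) - 1L
    lp <- lp[idx] + lchoose(n - u[idx], c_new) + c_new * la[i]
    j <- j[idx] + c_new * d
    u <- u[idx] + c_new
  }
  lp <- lp + (n - u) * la[1]
  P <- exp(lp)
  S0 <- numeric(jmax + 1L); L1 <- S0
  g <- rowsum(cbind(P, P * (-lp)), j + 1L)
  ids <- as.integer(rownames(g))
  S0[ids] <- g[, 1L]
  L1[ids] <- g[, 2L]
  list(S0 = S0, L1 = L1)
}

#' Most abundant aggregated variant
#'
#' The neutron index j* with the largest aggregated probability q_j; ties are
#' broken toward the smaller j.
#'
#' @param agg An `iso_aggregated` tibble from [aggregated_distribution()].
#' @return Integer neutron index.
#' @examples
#' most_abundant_variant(aggregated_distribution("C2H2N2O2S2"))
#' @export
most_abundant_variant <- function(agg) {
  stopifnot(nrow(agg) > 0)
  agg$j[which.max(agg$q)]
}

#' Variance decomposition of the full fine-structure distribution
#'
#' Splits the total variance of the isotopic distribution (fine structure
#' included) into the weighted within-variant variance and the
#' between-variant variance of the center masses, in the manner of a one-way
#' analysis of variance:
#' total = sum_j q_j Var(m_j) + sum_j q_j (E(m_j) - mbar)^2.
#' Because atom masses are independent, the total also equals the closed
#' form sum over elements of n_e * Var(single-atom isotope mass), which is
#' returned for reference.
#'
#' @inheritParams aggregated_distribution
#' @param agg Optionally, a precomputed [aggregated_distribution()] for
#'   `formula` (saves recomputation).
#' @return A one-row tibble with columns `within`, `between`, `total`
#'   (all Da^2), `total_closed_form` (Da^2), `mean_mass` (Da) and
#'   `coverage`.
#' @examples
#' variance_decomposition("C2H2N2O2S2")
#' @export
variance_decomposition <- function(formula, table = isotope_table(),
                                   agg = NULL, coverage = 1 - 1e-12) {
  f <- as_iso_formula(formula, table)
  if (is.null(agg)) {
    agg <- aggregated_distribution(f, table, coverage = coverage)
  }
  q <- agg$q / sum(agg$q)
  mbar <- sum(q * agg$center_mass)
  within <- sum(q * agg$variance)
  between <- sum(q * (agg$center_mass - mbar)^2)
  closed <- sum(purrr::map_dbl(names(f), function(el) {
    r <- element_records(table, el)
    mu <- sum(r$abundance * r$mass)
    sum(r$abundance * (r$mass - mu)^2)
  }) * as.numeric(f))
  tibble::tibble(
    within = within,
    between = between,
    total = within + between,
    total_closed_form = closed,
    mean_mass = mbar,
    coverage = attr(agg, "coverage")
  )
}

#' Entropy decomposition of the full fine-structure distribution
#'
#' Splits the information-theory entropy of the complete isotopologue
#' distribution into the weighted within-variant fine-structure entropies and
#' the entropy of the aggregated distribution itself:
#' total = sum_j q_j H(j) + (-sum_j q_j log q_j).
#'
#' @inheritParams variance_decomposition
#' @param unit `"nats"` (default) or `"bits"`.
#' @return A one-row tibble with columns `within`, `between`, `total` and
#'   `unit`.
#' @examples
#' entropy_decomposition("C2H2N2O2S2")
#' @export
entropy_decomposition <- function(formula, table = isotope_table(),
                                  agg = NULL, coverage = 1 - 1e-12,
                                  unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  if (is.null(agg)) {
    agg <- aggregated_distribution(formula, table, coverage = coverage,
                                   unit = unit)
  } else if (!identical(attr(agg, "unit"), unit)) {
    stop("`agg` was computed with a different entropy unit", call. = FALSE)
  }
  q <- agg$q / sum(agg$q)
  base <- if (unit == "bits") log(2) else 1
  within <- sum(q * agg$entropy)
  between <- -sum(q[q > 0] * log(q[q > 0])) / base
  tibble::tibble(within = within, between = between,
                 total = within + between, unit = unit)
}

#' @export
print.iso_aggregated <- function(x, ...) {
  cat("<iso_aggregated> ", attr(x, "formula"),
      "  monoisotopic ", format(attr(x, "monoisotopic")),
      " Da, coverage ", format(attr(x, "coverage")), "\n", sep = "")
  NextMethod()
}
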