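#' Gaussian FWHM/sigma conversion
#'
#' For a Gaussian peak, `FWHM = 2 sqrt(2 ln 2) * sigma` (~2.3548 sigma).
#'
#' @param sigma,fwhm Peak width parameters (Da).
#' @return The converted width (Da).
#' @examples
#' fwhm_from_sigma(249)  # ~586 Da
#' @export
fwhm_from_sigma <- function(sigma) sigma * 2 * sqrt(2 * log(2))

#' @rdname fwhm_from_sigma
#' @export
sigma_from_fwhm <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Render a stick spectrum as a finite-resolution profile
#'
#' Convolves a stick set (masses and probabilities) with Gaussian peak
#' shapes on a uniform mass grid. Each stick contributes a Gaussian of area
#' equal to its probability, so a normalized stick set yields a profile of
#' unit area. The width is given either directly as a FWHM or as a resolving
#' power R, in which case each stick's FWHM is `mass / R` (evaluated at that
#' stick's mass).
#'
#' @param sticks Data frame with columns `mass` (Da) and `probability`.
#' @param fwhm Peak full width at half maximum (Da); give this or
#'   `resolving_power`.
#' @param resolving_power Dimensionless resolving power `m / FWHM`.
#' @param grid_step Grid spacing (Da); defaults to a tenth of the smallest
#'   FWHM.
#' @param mass_range Optional length-2 grid range (Da); must cover every
#'   stick +/- 5 FWHM, otherwise an error is raised. Defaults to exactly
#'   that coverage.
#' @return A tibble of class `iso_profile` with columns `mass` and
#'   `intensity` (density per Da); attributes `fwhm` (per-stick vector) and
#'   `area` (trapezoidal area).
#' @examples
#' prof <- render_profile(
#'   tibble::tibble(mass = c(100, 100.5), probability = c(0.5, 0.5)),
#'   fwhm = 0.2)
#' @export
render_profile <- function(sticks, fwhm = NULL, resolving_power = NULL,
                           grid_step = NULL, mass_range = NULL) {
  if (!all(c("mass", "probability") %in% names(sticks)) ||
      nrow(sticks) < 1L) {
    stop("`sticks` needs >= 1 row with columns `mass` and `probability`",
         call. = FALSE)
  }
  if (is.null(fwhm) == is.null(resolving_power)) {
    stop("give exactly one of `fwhm` or `resolving_power`", call. = FALSE)
  }
  w <- if (!is.null(fwhm)) {
    if (fwhm <= 0) stop("`fwhm` must be positive", call. = FALSE)
    rep(fwhm, nrow(sticks))
  } else {
    if (resolving_power <= 0) {
      stop("`resolving_power` must be positive", call. = FALSE)
    }
    sticks$mass / resolving_power
  }
  sig <- sigma_from_fwhm(w)
  need <- c(min(sticks$mass - 5 * w), max(sticks$mass + 5 * w))
  if (is.null(mass_range)) {
    mass_range <- need
  } else if (mass_range[1] > need[1] + 1e-12 ||
             mass_range[2] < need[2] - 1e-12) {
    stop("`mass_range` must cover every stick +/- 5 FWHM (",
         format(need[1]), ", ", format(need[2]), ")", call. = FALSE)
  }
  if (is.null(grid_step)) grid_step <- min(w) / 10
  grid <- seq(mass_range[1], mass_range[2], by = grid_step)
  intensity <- rep(0, length(grid))
  for (i in seq_len(nrow(sticks))) {
    intensity <- intensity +
      sticks$probability[i] * stats::dnorm(grid, sticks$mass[i], sig[i])
  }
  out <- tibble::tibble(mass = grid, intensity = intensity)
  attr(out, "fwhm") <- w
  attr(out, "area") <- trapz_area(grid, intensity)
  class(out) <- c("iso_profile", class(out))
  out
}

trapz_area <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Discretize weighted masses into equal-width bins with pseudo-counts
#'
#' Places weighted points into `n_bins` equal-width bins spanning `range`
#' (default: the data range), adds `pseudo_count` to every bin's accumulated
#' weight so that no bin is empty, and normalizes to fractions. Distributions
#' meant to be compared (e.g. by Kullback-Leibler divergence) must be binned
#' with identical edges; pass a shared `range`.
#'
#' @param x Numeric vector of masses, or a data frame with columns `mass`
#'   and `weight`.
#' @param weights Optional weights aligned with `x` (default 1 each). The
#'   weight scale matters: pseudo-counts of 1 are added on the same scale.
#' @param n_bins Number of bins (>= 2).
#' @param pseudo_count Count added to every bin before normalization.
#' @param range Length-2 bin range; points outside are clipped into the
#'   boundary bins.
#' @return A tibble of class `iso_binned` with columns `bin`, `lower`,
#'   `upper`, `fraction`; attributes `edges` and `pseudo_count`.
#' @examples
#' bin_distribution(c(1, 2, 3), n_bins = 2)
#' @export
bin_distribution <- function(x, weights = NULL, n_bins = 1000,
                             pseudo_count = 1, range = NULL) {
  if (is.data.frame(x)) {
    weights <- weights %||% x$weight
    x <- x$mass
  }
  if (length(x) < 1L) stop("need at least one point", call. = FALSE)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  weights <- weights %||% rep(1, length(x))
  if (length(weights) != length(x)) {
    stop("`weights` must match `x` in length", call. = FALSE)
  }
  range <- range %||% c(min(x), max(x))
  if (diff(range) <= 0) {
    stop("degenerate (zero-width) bin range; cannot discretize",
         call. = FALSE)
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)
  counts <- as.vector(tapply(weights, factor(idx, levels = seq_len(n_bins)),
                             sum, default = 0))
  counts <- counts + pseudo_count
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    lower = edges[-(n_bins + 1L)],
    upper = edges[-1L],
    fraction = counts / sum(counts)
  )
  attr(out, "edges") <- edges
  attr(out, "pseudo_count") <- pseudo_count
  class(out) <- c("iso_binned", class(out))
  out
}

check_same_edges <- function(p, q) {
  ep <- attr(p, "edges"); eq <- attr(q, "edges")
  if (is.null(ep) || is.null(eq) || length(ep) != length(eq) ||
      max(abs(ep - eq)) > 1e-9 * max(abs(ep) + abs(eq))) {
    stop("binned distributions have incompatible bin edges", call. = FALSE)
  }
}

#' Entropy, cross-entropy and Kullback-Leibler divergence of binned
#' distributions
#'
#' `kl_divergence(p, q)` is `sum_i P(i) ln(P(i)/Q(i))`, the information lost
#' when Q approximates P; `cross_entropy(p, q)` is `-sum_i P(i) ln Q(i)`;
#' `binned_entropy(p)` is `-sum_i P(i) ln P(i)`. The identity
#' `H(P, Q) = H(P) + D_KL(P||Q)` holds to floating-point rounding. Both
#' distributions must share identical bin edges; pseudo-counts guarantee
#' strictly positive Q.
#'
#' @param p,q `iso_binned` distributions on identical edges.
#' @return A scalar in nats.
#' @examples
#' b1 <- bin_distribution(c(1, 2), n_bins = 2, range = c(0, 3))
#' b2 <- bin_distribution(c(1, 1, 2), n_bins = 2, range = c(0, 3))
#' kl_divergence(b1, b2)
#' @export
kl_divergence <- function(p, q) {
  check_same_edges(p, q)
  P <- p$fraction; Q <- q$fraction
  pos <- P > 0
  sum(P[pos] * (log(P[pos]) - log(Q[pos])))
}

#' @rdname kl_divergence
#' @export
cross_entropy <- function(p, q) {
  check_same_edges(p, q)
  P <- p$fraction; Q <- q$fraction
  pos <- P > 0
  -sum(P[pos] * log(Q[pos]))
}

#' @rdname kl_divergence
#' @export
binned_entropy <- function(p) {
  P <- p$fraction
  pos <- P > 0
  -sum(P[pos] * log(P[pos]))
}

#' Divergence of a fine-structure cluster from normality
#'
#' Builds the discrete fine-structure distribution P of the aggregated
#' variant `j` (default: the most abundant) from enumerated fine peaks, and
#' a normal reference Q with the cluster's generating-function mean and
#' variance discretized on the same bins, then reports entropy,
#' cross-entropy and Kullback-Leibler divergence. As molecules grow, the
#' fine structure approaches normality and the divergence shrinks.
#'
#' Both distributions are expressed as virtual ion counts (`count_scale`
#' ions in total) before `pseudo_count` is added to every bin, mirroring the
#' treatment of finite samples; the pseudo-counts keep Q strictly positive.
#' With `mode = "sample"`, P is instead built from `count_scale` ions drawn
#' multinomially from the fine peaks (seeded), emulating a finite-ion
#' measurement with run-to-run spread.
#'
#' @inheritParams count_fine_peaks
#' @param j Neutron index; default is the most abundant variant.
#' @param n_bins,pseudo_count Binning parameters (see [bin_distribution()]).
#' @param min_prob Enumeration floor relative to q_j (see
#'   [enumerate_fine_peaks()]).
#' @param count_scale Virtual number of ions used to express both
#'   distributions as counts.
#' @param mode `"enumerate"` (deterministic, default) or `"sample"`.
#' @param seed Seed for `mode = "sample"`.
#' @param max_peaks Passed to [enumerate_fine_peaks()].
#' @return A one-row tibble with `formula`, `j`, `n_peaks`, `captured`,
#'   `entropy`, `cross_entropy`, `kl` (nats). If the variant has fewer than
#'   two fine peaks its support has zero width and no discretization exists:
#'   the three measures are `NA` (divergence undefined).
#' @examples
#' normality_report("C6H6N6O6S2", j = 2, n_bins = 50)
#' @export
normality_report <- function(formula, j = NULL, table = isotope_table(),
                             n_bins = 1000, pseudo_count = 1,
                             min_prob = 1e-6, count_scale = 1e6,
                             mode = c("enumerate", "sample"), seed = NULL,
                             max_peaks = 2e6) {
  mode <- match.arg(mode)
  f <- as_iso_formula(formula, table)
  agg <- aggregated_distribution(f, table)
  if (is.null(j)) j <- most_abundant_variant(agg)
  j <- check_j(j)
  row <- which(agg$j == j)
  if (length(row) == 0L) {
    stop("j = ", j, " has no probability mass for this formula",
         call. = FALSE)
  }
  fine <- enumerate_fine_peaks(f, j, table, min_prob = min_prob,
                               max_peaks = max_peaks)
  base <- tibble::tibble(formula = format(f), j = j, n_peaks = nrow(fine),
                         captured = attr(fine, "captured"))
  if (nrow(fine) < 2L || diff(range(fine$mass)) <= 0) {
    return(dplyr::mutate(base, entropy = NA_real_,
                         cross_entropy = NA_real_, kl = NA_real_))
  }
  # shared edges over the fine support, one bin-width margin each side
  lo <- min(fine$mass); hi <- max(fine$mass)
  margin <- (hi - lo) / n_bins
  rng <- c(lo - margin, hi + margin)

  w_p <- if (mode == "enumerate") {
    fine$probability / sum(fine$probability) * count_scale
  } else {
    draw <- function() as.numeric(
      stats::rmultinom(1L, size = round(count_scale),
                       prob = fine$probability))
    if (is.null(seed)) draw() else with_local_seed(seed, draw())
  }
  P <- bin_distribution(fine$mass, weights = w_p, n_bins = n_bins,
                        pseudo_count = pseudo_count, range = rng)
  edges <- attr(P, "edges")
  qw <- diff(stats::pnorm(edges, mean = agg$center_mass[row],
                          sd = agg$sigma[row]))
  Q <- bin_distribution((edges[-1] + edges[-length(edges)]) / 2,
                        weights = qw * count_scale, n_bins = n_bins,
                        pseudo_count = pseudo_count, range = rng)
  dplyr::mutate(base,
                entropy = binned_entropy(P),
                cross_entropy = cross_entropy(P, Q),
                kl = kl_divergence(P, Q))
}
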