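#' Exact number of fine peaks of an aggregated variant
#'
#' Counts the distinct isotopologues (fine peaks) of the aggregated variant
#' with `j` additional neutrons. Two fine peaks are distinct if and only if
#' any element's isotope counts differ. This is a bounded money-exchange
#' problem: the heavy isotopes are coins whose denominations are their
#' neutron offsets ({1,1,1,1,2,1,2,4} for 13C, 2H, 15N, 17O, 18O, 33S, 34S,
#' 36S), the target sum is j, and each element's heavy-isotope counts are
#' jointly bounded by its atom count. The count is computed exactly by
#' per-element bounded-composition polynomials convolved across elements.
#'
#' @inheritParams monoisotopic_mass
#' @param j Neutron index (non-negative integer).
#' @return The exact count as a double (exact up to 2^53, far beyond every
#'   molecule of practical interest; larger counts are correctly rounded
#'   floating-point values).
#' @examples
#' count_fine_peaks("C2H2N2O2S2", 1)  # 5
#' count_fine_peaks("C2H2N2O2S2", 2)  # 17
#' @export
count_fine_peaks <- function(formula, j, table = isotope_table()) {
  f <- as_iso_formula(formula, table)
  j <- check_j(j)
  if (j == 0) return(1)
  poly <- rep(0, j + 1L); poly[1] <- 1
  for (el in names(f)) {
    r <- element_records(table, el)
    epoly <- element_count_poly(r$offset[r$offset > 0], f[[el]], j)
    poly <- gf_conv(poly, epoly, j)
  }
  poly[j + 1L]
}

check_j <- function(j) {
  if (!is.numeric(j) || length(j) != 1L || is.na(j) || j < 0 ||
      j != round(j)) {
    stop("`j` must be a single non-negative integer", call. = FALSE)
  }
  as.integer(j)
}

# Number of heavy-isotope count vectors of one element summing to each
# neutron total 0..j, with the joint bound sum(counts) <= n_atoms.
# DP over (neutron total, atoms used); every heavy isotope adds >= 1
# neutron, so atoms used is also bounded by j.
element_count_poly <- function(offsets, n_atoms, j) {
  ucap <- min(n_atoms, j)
  W <- matrix(0, nrow = j + 1L, ncol = ucap + 1L)
  W[1L, 1L] <- 1
  for (d in offsets) {
    if (d > j) next
    for (u in seq_len(ucap)) {
      rows <- (d:j) + 1L
      W[rows, u + 1L] <- W[rows, u + 1L] + W[rows - d, u]
    }
  }
  rowSums(W)
}

#' Probability and mass of one specific fine peak
#'
#' Evaluates the multinomial probability and the exact mass of a single
#' isotopologue given its heavy-isotope counts (all remaining atoms are the
#' light isotope). Probabilities are computed in the log domain.
#'
#' @inheritParams count_fine_peaks
#' @param counts Named vector of heavy-isotope counts, names being isotope
#'   labels from the table (e.g. `c("13C" = 213, "2H" = 3)`).
#' @return A one-row tibble with `mass` (Da), `probability`,
#'   `log_probability` and `j` (total additional neutrons).
#' @examples
#' fine_peak_probability("C2H2N2O2S2", c("18O" = 1))
#' @export
fine_peak_probability <- function(formula, counts, table = isotope_table()) {
  f <- as_iso_formula(formula, table)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("`counts` must be a named vector of isotope labels", call. = FALSE)
  }
  bad <- setdiff(names(counts), table$isotope)
  if (length(bad) > 0) {
    stop("unknown isotope label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lp <- 0; dm <- 0; jtot <- 0L
  for (el in names(f)) {
    r <- element_records(table, el)
    n <- f[[el]]
    c_heavy <- vapply(r$isotope, function(lbl) {
      if (lbl %in% names(counts)) as.numeric(counts[[lbl]]) else 0
    }, numeric(1))
    c_heavy[1] <- 0  # light slot filled below
    if (sum(c_heavy) > n) {
      stop("isotope counts for element ", el, " exceed its atom count",
           call. = FALSE)
    }
    c_full <- c_heavy
    c_full[1] <- n - sum(c_heavy)
    lp <- lp + lgamma(n + 1) - sum(lgamma(c_full + 1)) +
      sum(c_full[r$abundance > 0] * log(r$abundance[r$abundance > 0]))
    if (any(c_full > 0 & r$abundance == 0)) lp <- -Inf
    dm <- dm + sum(c_full * r$dmass)
    jtot <- jtot + as.integer(sum(c_full * r$offset))
  }
  extra <- setdiff(names(counts),
                   unlist(lapply(names(f), function(el)
                     element_records(table, el)$isotope)))
  if (length(extra) > 0) {
    stop("isotope(s) ", paste(extra, collapse = ", "),
         " belong to elements absent from the formula", call. = FALSE)
  }
  tibble::tibble(mass = monoisotopic_mass(f, table) + dm,
                 probability = exp(lp), log_probability = lp, j = jtot)
}

#' Enumerate the fine structure of an aggregated variant
#'
#' Lists the isotopologues making up the aggregated variant with `j`
#' additional neutrons, with their heavy-isotope compositions, exact masses
#' and multinomial probabilities. Enumeration walks element-by-element
#' neutron allocations with branch-and-bound pruning: a partial product is
#' abandoned as soon as even the best completion cannot reach
#' `min_prob * q_j`, so only peaks above the threshold (relative to the
#' variant's aggregated probability) are generated.
#'
#' @inheritParams count_fine_peaks
#' @param min_prob Probability floor relative to q_j; peaks with
#'   `p < min_prob * q_j` are pruned. `0` enumerates everything (feasible
#'   only for small j / small molecules).
#' @param max_peaks Safety cap; enumeration stops with an error if more
#'   peaks than this survive pruning.
#' @return A tibble of class `iso_fine` with one column per heavy isotope
#'   present in the formula (named by isotope label), plus `mass` (Da) and
#'   `probability`, sorted by decreasing probability. Attributes: `j`,
#'   `q_j`, `captured` (sum of retained probabilities), `min_prob`,
#'   `formula`. A `j` beyond the formula's attainable neutron count yields
#'   an empty structure.
#' @examples
#' enumerate_fine_peaks("C2H2N2O2S2", 1)
#' @export
enumerate_fine_peaks <- function(formula, j, table = isotope_table(),
                                 min_prob = 0, max_peaks = 2e6) {
  f <- as_iso_formula(formula, table)
  j <- check_j(j)
  if (min_prob < 0 || min_prob >= 1) {
    stop("`min_prob` must be in [0, 1)", call. = FALSE)
  }
  recs <- lapply(names(f), element_records, table = table)
  names(recs) <- names(f)
  attain <- sum(purrr::map_dbl(recs, ~ max(.x$offset)) * as.numeric(f))
  heavy_labels <- unlist(lapply(recs, function(r) r$isotope[r$offset > 0]))

  empty <- function(qj) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(heavy_labels)), heavy_labels))
    out$mass <- numeric(0); out$probability <- numeric(0)
    fine_structure(out, j, qj, 0, min_prob, format(f))
  }
  if (j > attain) return(empty(0))

  qj <- aggregated_q(f, table, j)
  thresh_lp <- if (min_prob > 0) log(min_prob) + log(qj) else -Inf

  comps <- lapply(seq_along(recs), function(i) {
    element_compositions(recs[[i]], as.integer(f[[i]]), j)
  })
  # best attainable log-probability per element per allocated neutron count
  best <- lapply(comps, function(cp) {
    vapply(0:j, function(je) {
      rows <- cp$j == je
      if (any(rows)) max(cp$lp[rows]) else -Inf
    }, numeric(1))
  })
  # suffix_bound[[e]][r+1]: best total lp achievable by elements e..E with
  # exactly r neutrons, via max-plus convolution from the right
  nel <- length(recs)
  suffix <- vector("list", nel + 1L)
  suffix[[nel + 1L]] <- c(0, rep(-Inf, j))
  for (e in rev(seq_len(nel))) {
    nxt <- suffix[[e + 1L]]
    cur <- rep(-Inf, j + 1L)
    for (je in 0:j) {
      b <- best[[e]][je + 1L]
      if (is.finite(b)) {
        idx <- (je:j) + 1L
        cand <- b + nxt[seq_len(j - je + 1L)]
        cur[idx] <- pmax(cur[idx], cand)
      }
    }
    suffix[[e]] <- cur
  }

  part <- list(jp = 0L, lp = 0, dm = 0,
               cnt = matrix(0, nrow = 1L, ncol = 0L))
  for (e in seq_len(nel)) {
    cp <- comps[[e]]
    nxt <- suffix[[e + 1L]]
    blocks <- vector("list", j + 1L)
    last <- e == nel
    for (je in 0:j) {
      rows <- which(cp$j == je)
      if (length(rows) == 0L) next
      rem <- j - part$jp - je
      ok_part <- if (last) rem == 0L else rem >= 0L
      if (!any(ok_part)) next
      bound_rest <- ifelse(rem >= 0L, nxt[pmax(rem, 0L) + 1L], -Inf)
      keep_p <- which(ok_part &
                        part$lp + best[[e]][je + 1L] + bound_rest >= thresh_lp)
      if (length(keep_p) == 0L) next
      np <- length(keep_p); nc <- length(rows)
      ip <- rep(keep_p, each = nc)
      ic <- rep(rows, times = np)
      lp_new <- part$lp[ip] + cp$lp[ic]
      sel <- if (last) {
        # bound is exact for the last element: lp_new is the final lp
        lp_new >= thresh_lp
      } else {
        lp_new + nxt[(j - part$jp[ip] - je) + 1L] >= thresh_lp
      }
      if (!any(sel)) next
      ip <- ip[sel]; ic <- ic[sel]; lp_new <- lp_new[sel]
      blocks[[je + 1L]] <- list(
        jp = part$jp[ip] + je,
        lp = lp_new,
        dm = part$dm[ip] + cp$dm[ic],
        cnt = cbind(part$cnt[ip, , drop = FALSE],
                    cp$counts[ic, , drop = FALSE])
      )
    }
    blocks <- blocks[!vapply(blocks, is.null, logical(1))]
    if (length(blocks) == 0L) return(empty(qj))
    part <- list(
      jp = unlist(lapply(blocks, `[[`, "jp")),
      lp = unlist(lapply(blocks, `[[`, "lp")),
      dm = unlist(lapply(blocks, `[[`, "dm")),
      cnt = do.call(rbind, lapply(blocks, `[[`, "cnt"))
    )
    if (length(part$jp) > max_peaks) {
      stop("enumeration exceeds max_peaks = ", max_peaks,
           "; raise `min_prob` or `max_peaks`", call. = FALSE)
    }
  }

  p <- exp(part$lp)
  ord <- order(p, decreasing = TRUE)
  cnt <- part$cnt[ord, , drop = FALSE]
  colnames(cnt) <- heavy_labels
  out <- tibble::as_tibble(cnt)
  out$mass <- monoisotopic_mass(f, table) + part$dm[ord]
  out$probability <- p[ord]
  fine_structure(out, j, qj, sum(p), min_prob, format(f))
}

fine_structure <- function(tbl, j, qj, captured, min_prob, formula) {
  attr(tbl, "j") <- j
  attr(tbl, "q_j") <- qj
  attr(tbl, "captured") <- captured
  attr(tbl, "min_prob") <- min_prob
  attr(tbl, "formula") <- formula
  class(tbl) <- c("iso_fine", class(tbl))
  tbl
}

#' @export
print.iso_fine <- function(x, ...) {
  cat("<iso_fine> ", attr(x, "formula"), "  j = ", attr(x, "j"),
      ", ", nrow(x), " peaks, captured ",
      format(attr(x, "captured")), " of q_j = ", format(attr(x, "q_j")),
      "\n", sep = "")
  NextMethod()
}

# q_j only, via the probability-generating polynomial (cheap: no moments).
aggregated_q <- function(f, table, j) {
  poly <- 1
  for (el in names(f)) {
    r <- element_records(table, el)
    base <- numeric(max(r$offset) + 1L)
    base[r$offset + 1L] <- r$abundance
    poly <- gf_conv(poly, poly_pow(base, f[[el]], j), j)
  }
  if (length(poly) >= j + 1L) poly[j + 1L] else 0
}

poly_pow <- function(base, n, jmax) {
  res <- 1
  while (n > 0) {
    if (n %% 2 == 1) res <- gf_conv(res, base, jmax)
    n <- n %/% 2
    if (n > 0) base <- gf_conv(base, base, jmax)
  }
  res
}

# All heavy-isotope count vectors of one element with neutron totals 0..j,
# with multinomial log-probabilities and delta masses.
element_compositions <- function(rec, n_atoms, j) {
  heavy <- which(rec$offset > 0)
  d <- rec$offset[heavy]
  res_counts <- list(); res_j <- integer(0)
  recur <- function(i, left_atoms, left_j, acc) {
    if (i > length(d)) {
      res_counts[[length(res_counts) + 1L]] <<- acc
      res_j[[length(res_j) + 1L]] <<- j - left_j
      return(invisible())
    }
    cmax <- min(left_atoms, left_j %/% d[i])
    for (ci in 0:cmax) {
      recur(i + 1L, left_atoms - ci, left_j - ci * d[i], c(acc, ci))
    }
  }
  recur(1L, n_atoms, j, integer(0))
  counts <- do.call(rbind, res_counts)
  if (is.null(counts)) counts <- matrix(0L, nrow = 1L, ncol = length(d))
  n_heavy <- rowSums(counts)
  n_light <- n_atoms - n_heavy
  la <- log(ifelse(rec$abundance > 0, rec$abundance, NA_real_))
  lp <- lgamma(n_atoms + 1) - lgamma(n_light + 1) -
    rowSums(lgamma(counts + 1)) + n_light * la[1]
  for (k in seq_along(heavy)) {
    ck <- counts[, k]
    contrib <- ifelse(ck > 0, ck * la[heavy[k]], 0)
    contrib[is.na(contrib)] <- -Inf
    lp <- lp + contrib
  }
  dm <- as.vector(counts %*% rec$dmass[heavy])
  list(counts = counts, j = res_j, lp = lp, dm = dm)
}

#' Maximum spread of a fine-structure cluster
#'
#' The spread is the difference between the heaviest and lightest fine
#' variants of the aggregated variant with `j` additional neutrons. Mode
#' `"eq7"` returns the closed-form upper bound
#' `j * (mu_2H - mu_15N)`, where `mu_2H` and `mu_15N` are the largest and
#' smallest mass-per-additional-neutron ratios in the isotope table (reached
#' by 2H and 15N): the heaviest variant packs all extra neutrons into
#' deuterium, the lightest into 15N. Mode `"bounded"` returns the exact
#' attainable max - min mass difference under the formula's atom-count
#' constraints, computed by per-element max-plus/min-plus dynamic programs;
#' it equals the closed form whenever `j <= min(n_H, n_N)` and is smaller
#' otherwise.
#'
#' @inheritParams count_fine_peaks
#' @param mode `"eq7"` (closed-form upper bound) or `"bounded"` (exact).
#' @return Spread in Da (0 for `j = 0`; `NA` in bounded mode if `j` is not
#'   attainable).
#' @examples
#' max_spread("C2H2N2O2S2", 1)
#' max_spread("C10O5", 2, mode = "bounded")
#' @export
max_spread <- function(formula, j, table = isotope_table(),
                       mode = c("eq7", "bounded")) {
  mode <- match.arg(mode)
  f <- as_iso_formula(formula, table)
  j <- check_j(j)
  if (j == 0) return(0)
  if (mode == "eq7") {
    ex <- mpn_extremes(table)
    return(j * (ex$upper - ex$lower))
  }
  mx <- extreme_mass_offset(f, table, j, maximize = TRUE)
  mn <- extreme_mass_offset(f, table, j, maximize = FALSE)
  if (!is.finite(mx) || !is.finite(mn)) return(NA_real_)
  mx - mn
}

# Exact extreme (max or min) total delta-mass over isotopologues with j
# additional neutrons, honoring per-element joint atom bounds. Max-plus DP:
# per element best[j'] over compositions, then combined across elements.
extreme_mass_offset <- function(f, table, j, maximize = TRUE) {
  combine <- if (maximize) pmax else pmin
  worst <- if (maximize) -Inf else Inf
  total <- c(0, rep(worst, j))
  for (el in names(f)) {
    r <- element_records(table, el)
    eb <- element_extreme_poly(r, f[[el]], j, maximize)
    new <- rep(worst, j + 1L)
    for (je in 0:j) {
      if (!is.finite(eb[je + 1L])) next
      idx <- (je:j) + 1L
      new[idx] <- combine(new[idx], eb[je + 1L] + total[seq_len(j - je + 1L)])
    }
    total <- new
  }
  total[j + 1L]
}

element_extreme_poly <- function(rec, n_atoms, j, maximize = TRUE) {
  heavy <- which(rec$offset > 0)
  d <- rec$offset[heavy]; dm <- rec$dmass[heavy]
  combine <- if (maximize) pmax else pmin
  worst <- if (maximize) -Inf else Inf
  ucap <- min(n_atoms, j)
  B <- matrix(worst, nrow = j + 1L, ncol = ucap + 1L)
  B[1L, 1L] <- 0
  for (k in seq_along(d)) {
    if (d[k] > j) next
    for (u in seq_len(ucap)) {
      rows <- (d[k]:j) + 1L
      B[rows, u + 1L] <- combine(B[rows, u + 1L], B[rows - d[k], u] + dm[k])
    }
  }
  apply(B, 1L, function(x) {
    fin <- x[is.finite(x)]
    if (length(fin) == 0L) worst else if (maximize) max(fin) else min(fin)
  })
}

#' Mean spacing between fine peaks
#'
#' Divides an estimate of the fine-structure cluster width by the exact
#' number of fine peaks. The width is either the closed-form maximum spread
#' (`width = "spread"`) or `k` standard deviations of the cluster
#' (`width = "sigma"`, with sigma from the generating-function variance; a
#' symmetric +/- k/2 sigma window corresponds to `k` total widths of sigma).
#'
#' @inheritParams count_fine_peaks
#' @param width `"spread"` (closed-form maximum spread) or `"sigma"`
#'   (`k * sigma` total width).
#' @param k Width multiplier for `width = "sigma"`.
#' @param agg Optional precomputed aggregated distribution for `formula`.
#' @return Mean spacing in Da per fine peak.
#' @examples
#' mean_spacing("C2H2N2O2S2", 1)
#' @export
mean_spacing <- function(formula, j, table = isotope_table(),
                         width = c("spread", "sigma"), k = 4, agg = NULL) {
  width <- match.arg(width)
  f <- as_iso_formula(formula, table)
  j <- check_j(j)
  n <- count_fine_peaks(f, j, table)
  if (n < 2) {
    stop("fewer than 2 fine peaks at j = ", j, "; spacing undefined",
         call. = FALSE)
  }
  w <- if (width == "spread") {
    max_spread(f, j, table, mode = "eq7")
  } else {
    if (is.null(agg)) agg <- aggregated_distribution(f, table)
    row <- which(agg$j == j)
    if (length(row) == 0L) stop("j = ", j, " not in the computed window",
                                call. = FALSE)
    k * agg$sigma[row]
  }
  w / n
}

#' Multinomial ion-count sampling over fine peaks
#'
#' Draws a finite number of ions over the fine peaks of a cluster (or over a
#' hypothetical set of equally abundant peaks) and reports occupancy
#' statistics. This quantifies the counting-statistics limit: when the mean
#' occupancy is far below 1 ion per peak, the fine-structure profile cannot
#' be characterized no matter the resolving power.
#'
#' @param x An `iso_fine` tibble (ions are distributed according to its
#'   `probability` column, renormalized), or a single integer number of
#'   equally abundant peaks.
#' @param n_ions Number of ions detected (non-negative integer).
#' @param seed Optional integer seed for reproducible draws.
#' @return A one-row tibble with `n_ions`, `n_peaks`, `mean_occupancy`
#'   (`n_ions / n_peaks`, exact), `occupied_fraction` (fraction of peaks
#'   holding at least one ion), `max_occupancy` and `seed`. The full
#'   occupancy vector is attached as attribute `occupancy`.
#' @examples
#' sample_ions(2e4, n_ions = 2e3, seed = 1)
#' @export
sample_ions <- function(x, n_ions, seed = NULL) {
  if (inherits(x, "iso_fine") || is.data.frame(x)) {
    prob <- x$probability
    if (is.null(prob) || nrow(x) < 1L) {
      stop("`x` must have a probability column with at least one peak",
           call. = FALSE)
    }
    prob <- prob / sum(prob)
  } else if (is.numeric(x) && length(x) == 1L && x >= 1) {
    prob <- rep(1 / x, x)
  } else {
    stop("`x` must be a fine-structure table or a peak count", call. = FALSE)
  }
  if (!is.numeric(n_ions) || n_ions < 0 || n_ions != round(n_ions)) {
    stop("`n_ions` must be a non-negative integer", call. = FALSE)
  }
  n_peaks <- length(prob)
  draw <- function() {
    if (n_ions == 0) rep(0L, n_peaks)
    else as.integer(stats::rmultinom(1L, size = n_ions, prob = prob))
  }
  occ <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  out <- tibble::tibble(
    n_ions = as.integer(n_ions),
    n_peaks = n_peaks,
    mean_occupancy = n_ions / n_peaks,
    occupied_fraction = mean(occ > 0L),
    max_occupancy = if (n_peaks > 0) max(occ) else 0L,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  attr(out, "occupancy") <- occ
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
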