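# Independent brute-force oracle: exhaustively enumerates every isotopologue
# of a small molecule and derives per-variant probabilities, center masses,
# variances, entropies, counts and spreads directly from the enumeration.
# Probabilities come from stats::dmultinom; nothing here touches the
# package's generating-function, DP or pruning code.

# All compositions of n atoms over r isotope slots (rows sum to n).
oracle_compositions <- function(n, r) {
  if (r == 1L) return(matrix(n, 1L, 1L))
  do.call(rbind, lapply(0:n, function(k) {
    cbind(k, oracle_compositions(n - k, r - 1L))
  }))
}

# Full isotopologue table: one row per distinct isotope-count vector of the
# molecule, with probability, exact mass, and neutron total.
oracle_fine_table <- function(counts, tab) {
  per_el <- lapply(names(counts), function(el) {
    d <- tab[tab$element == el, ]
    combos <- oracle_compositions(counts[[el]], nrow(d))
    list(
      p = apply(combos, 1L, function(k) stats::dmultinom(k, prob = d$abundance)),
      m = as.vector(combos %*% d$mass_Da),
      j = as.vector(combos %*% d$neutron_offset)
    )
  })
  Reduce(function(a, b) {
    i <- rep(seq_along(a$p), times = length(b$p))
    k <- rep(seq_along(b$p), each = length(a$p))
    list(p = a$p[i] * b$p[k], m = a$m[i] + b$m[k], j = a$j[i] + b$j[k])
  }, per_el)
}

# Aggregate the enumeration by neutron index.
oracle_aggregated <- function(counts, tab) {
  ft <- oracle_fine_table(counts, tab)
  js <- sort(unique(ft$j))
  rows <- lapply(js, function(jv) {
    sel <- ft$j == jv
    p <- ft$p[sel]; m <- ft$m[sel]
    q <- sum(p)
    e1 <- sum(p * m) / q
    w <- p / q
    # two-pass variance: avoids the catastrophic cancellation of
    # E(m^2) - E(m)^2 at absolute-mass scale
    data.frame(j = jv, q = q, center_mass = e1,
               variance = sum(w * (m - e1)^2),
               entropy = -sum(w[w > 0] * log(w[w > 0])),
               n_peaks = sum(sel),
               spread = max(m) - min(m))
  })
  do.call(rbind, rows)
}

# Deterministic roster of small CHNOS formulas for oracle sweeps: every
# formula with per-element counts <= 2, a stratified slice of the counts <= 3
# formulas with at most 12 atoms, and the single-element extremes.
oracle_formula_set <- function() {
  g2 <- expand.grid(C = 0:2, H = 0:2, N = 0:2, O = 0:2, S = 0:2)
  g2 <- g2[rowSums(g2) > 0, ]
  g3 <- expand.grid(C = 0:3, H = 0:3, N = 0:3, O = 0:3, S = 0:3)
  g3 <- g3[rowSums(g3) > 0 & rowSums(g3) <= 12 & apply(g3, 1, max) == 3, ]
  g3 <- g3[seq(1, nrow(g3), by = 3), ]
  singles <- data.frame(C = c(12, 0, 0, 0, 0, 6, 0),
                        H = c(0, 12, 0, 0, 0, 0, 6),
                        N = c(0, 0, 12, 0, 0, 0, 0),
                        O = c(0, 0, 0, 12, 0, 6, 0),
                        S = c(0, 0, 0, 0, 12, 0, 6))
  g <- rbind(g2, g3, singles)
  lapply(seq_len(nrow(g)), function(i) {
    v <- unlist(g[i, ])
    v[v > 0]
  })
}
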