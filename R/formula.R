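#' Parse an elemental formula string
#'
#' Parses plain formula strings such as `"C2934H4615N781O897S39"` or `"H2O"`
#' into a named count vector. An omitted count means one atom. Parentheses,
#' charge states, adducts and isotope-labelled atoms are not part of the
#' dialect.
#'
#' @param text A single formula string.
#' @param table Isotope table used to decide which element symbols are
#'   supported (see [isotope_table()]).
#' @return An object of class `iso_formula`: a named integer vector of atom
#'   counts, one entry per element, in canonical (Hill-like) order: C first,
#'   then H, then the remaining elements alphabetically.
#' @examples
#' parse_formula("C2934H4615N781O897S39")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text, table = isotope_table()) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single formula string", call. = FALSE)
  }
  if (!nzchar(text)) stop("empty formula string", call. = FALSE)
  known <- unique(table$element)
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      stop("malformed formula at position ", pos, " of \"", text, "\"",
           call. = FALSE)
    }
    sym <- m[2]
    # prefer the longest symbol known to the table; fall back to one letter
    if (!sym %in% known && nchar(sym) == 2L && substr(sym, 1, 1) %in% known) {
      sym <- substr(sym, 1, 1)
      m[3] <- ""
      m[1] <- sym
    }
    if (!sym %in% known) {
      stop("unsupported element \"", sym, "\" at position ", pos,
           " (not in the active isotope table)", call. = FALSE)
    }
    cnt <- if (nzchar(m[3])) suppressWarnings(as.integer(m[3])) else 1L
    if (is.na(cnt) || cnt < 1L) {
      stop("invalid count for element ", sym, " at position ", pos,
           call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m[1])
  }
  new_iso_formula(counts)
}

new_iso_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    stop("formula has no atoms", call. = FALSE)
  }
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  counts <- counts[ord]
  storage.mode(counts) <- "integer"
  structure(counts, class = "iso_formula")
}

#' Coerce to an `iso_formula`
#'
#' Accepts a formula string, a named numeric vector of atom counts, or an
#' existing `iso_formula`.
#'
#' @param x Formula string, named count vector, or `iso_formula`.
#' @inheritParams parse_formula
#' @return An `iso_formula`.
#' @export
as_iso_formula <- function(x, table = isotope_table()) {
  if (inherits(x, "iso_formula")) return(x)
  if (is.character(x)) return(parse_formula(x, table))
  if (is.numeric(x) && !is.null(names(x))) {
    if (any(x < 0) || any(x != round(x))) {
      stop("atom counts must be non-negative integers", call. = FALSE)
    }
    unknown <- setdiff(names(x)[x > 0], unique(table$element))
    if (length(unknown) > 0) {
      stop("unsupported element(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    return(new_iso_formula(round(x)))
  }
  stop("cannot interpret `x` as a chemical formula", call. = FALSE)
}

#' @export
format.iso_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.iso_formula <- function(x, ...) {
  cat("<iso_formula> ", format(x), "  (", sum(x), " atoms)\n", sep = "")
  invisible(x)
}

#' Build a poly-averagine formula
#'
#' Scales the averagine model unit
#' C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 (an "average amino-acid residue")
#' by `n_units` and rounds each element count half-up, independently. The
#' resulting family of poly-averagines approximates peptides and proteins of
#' arbitrary size; `n_units = 2000` gives C9877H15517N2715O2955S83 (~222 kDa)
#' and `n_units = 4000` gives C19754H31033N5431O5909S167 (~444 kDa).
#'
#' @param n_units Positive number of averagine units.
#' @return An `iso_formula`.
#' @examples
#' averagine_formula(2000)
#' @export
averagine_formula <- function(n_units) {
  if (!is.numeric(n_units) || length(n_units) != 1L || !is.finite(n_units) ||
      n_units <= 0) {
    stop("`n_units` must be a single positive number", call. = FALSE)
  }
  coefs <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
  counts <- floor(n_units * coefs + 0.5)  # round half up, per element
  new_iso_formula(counts)
}

#' Averagine unit stoichiometry
#'
#' The per-unit element coefficients of the averagine model.
#' @return Named numeric vector of coefficients for C, H, N, O, S.
#' @export
averagine_coefficients <- function() {
  c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
}

#' Monoisotopic and average mass
#'
#' The monoisotopic mass is the mass of the isotopologue composed entirely of
#' each element's lightest isotope; the average mass weights every isotope by
#' its abundance.
#'
#' @param formula Formula string or `iso_formula`.
#' @inheritParams parse_formula
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C2934H4615N781O897S39")
#' average_mass("H2O")
#' @export
monoisotopic_mass <- function(formula, table = isotope_table()) {
  f <- as_iso_formula(formula, table)
  sum(purrr::map_dbl(names(f), function(el) {
    element_records(table, el)$mass[1]
  }) * as.numeric(f))
}

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(formula, table = isotope_table()) {
  f <- as_iso_formula(formula, table)
  sum(purrr::map_dbl(names(f), function(el) {
    r <- element_records(table, el)
    sum(r$abundance * r$mass)
  }) * as.numeric(f))
}

#' Heavy-isotope neutron denominations of a formula
#'
#' Lists the "coin denominations" of the bounded money-exchange view of fine
#' structure: every heavy isotope available to the formula together with its
#' neutron offset. For a CHNOS molecule these are
#' (13C, 2H, 15N, 17O, 18O, 33S, 34S, 36S) with offsets (1,1,1,1,2,1,2,4).
#'
#' @inheritParams monoisotopic_mass
#' @return A tibble with columns `element`, `isotope`, `neutron_offset`,
#'   ordered by the formula's element order, then offset.
#' @examples
#' neutron_denominations("C2H2N2O2S2")
#' @export
neutron_denominations <- function(formula, table = isotope_table()) {
  f <- as_iso_formula(formula, table)
  purrr::map_dfr(names(f), function(el) {
    r <- element_records(table, el)
    heavy <- r$offset > 0
    tibble::tibble(element = el,
                   isotope = r$isotope[heavy],
                   neutron_offset = r$offset[heavy])
  })
}
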