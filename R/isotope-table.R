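#' Load the pinned isotope data table
#'
#' Reads the table of stable-isotope masses and abundances used by every
#' computation in the package. The pinned table covers C, H, N, O, P and S
#' with AME atomic masses and IUPAC 2005 representative abundances; a
#' different table (e.g. with adjusted abundances or extra elements) can be
#' supplied through `path` in the same columnar text format.
#'
#' @param path Optional path to a replacement table. The file is
#'   tab-separated with columns `element`, `isotope`, `nucleons`, `mass_Da`,
#'   `abundance`; lines starting with `#` are comments.
#' @param provenance Free-text source tag attached to the returned table.
#'   Defaults to a tag describing the pinned table (or the file name for an
#'   override).
#'
#' @return A tibble of class `iso_table` with columns `element`, `isotope`,
#'   `nucleons`, `mass_Da`, `abundance` and `neutron_offset` (nucleon count
#'   minus the element's lightest isotope's), sorted by element and offset,
#'   with a `provenance` attribute.
#'
#' @details The table is validated on load: per-element abundances must sum
#'   to 1 within 1e-9, every element must have an isotope at neutron offset 0,
#'   and offsets must be strictly increasing within an element. The
#'   mass-per-additional-neutron ratio `(mass - lightest mass)/offset` is well
#'   defined for every heavy isotope; its extremes over the table (reached by
#'   2H above and 15N below for the pinned table) bound the attainable spread
#'   of a fine-structure cluster.
#'
#' @examples
#' tab <- isotope_table()
#' dplyr::filter(tab, element == "S")
#' @export
isotope_table <- function(path = NULL, provenance = NULL) {
  if (is.null(path)) {
    if (!is.null(.isofine_env$default_table)) {
      return(.isofine_env$default_table)
    }
    path <- system.file("extdata", "isotope_table_chnops.tsv",
                        package = "isofine", mustWork = TRUE)
    provenance <- provenance %||%
      "pinned CHNOPS table: AME masses, IUPAC 2005 representative abundances"
    cache <- TRUE
  } else {
    provenance <- provenance %||% paste0("user table: ", basename(path))
    cache <- FALSE
  }
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("element", "isotope", "nucleons", "mass_Da", "abundance")
  if (!all(needed %in% names(raw))) {
    stop("isotope table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  tab <- tibble::as_tibble(raw[needed]) |>
    dplyr::group_by(.data$element) |>
    dplyr::arrange(.data$nucleons, .by_group = TRUE) |>
    dplyr::mutate(neutron_offset = .data$nucleons - min(.data$nucleons)) |>
    dplyr::ungroup()
  validate_isotope_table(tab)
  attr(tab, "provenance") <- provenance
  class(tab) <- c("iso_table", class(tab))
  if (cache) .isofine_env$default_table <- tab
  tab
}

.isofine_env <- new.env(parent = emptyenv())

validate_isotope_table <- function(tab) {
  by_el <- split(tab, tab$element)
  for (el in names(by_el)) {
    d <- by_el[[el]]
    if (abs(sum(d$abundance) - 1) > 1e-9) {
      stop("abundances of element ", el, " sum to ", sum(d$abundance),
           ", expected 1 within 1e-9", call. = FALSE)
    }
    if (d$neutron_offset[1] != 0L) {
      stop("element ", el, " lacks a neutron-offset-0 isotope", call. = FALSE)
    }
    if (any(diff(d$neutron_offset) <= 0)) {
      stop("neutron offsets of element ", el, " are not strictly increasing",
           call. = FALSE)
    }
    if (any(d$abundance < 0) || any(d$abundance > 1)) {
      stop("abundances of element ", el, " outside [0, 1]", call. = FALSE)
    }
    if (any(diff(d$mass_Da) <= 0)) {
      stop("isotope masses of element ", el, " are not increasing",
           call. = FALSE)
    }
  }
  invisible(tab)
}

# Per-element building blocks used by the generating-function and DP code:
# delta masses are relative to the element's lightest isotope so that large
# monoisotopic masses never enter the accumulations.
element_records <- function(table, element) {
  d <- table[table$element == element, ]
  if (nrow(d) == 0L) {
    stop("element ", element, " not present in the isotope table",
         call. = FALSE)
  }
  list(
    element = element,
    isotope = d$isotope,
    offset = d$neutron_offset,
    mass = d$mass_Da,
    dmass = d$mass_Da - d$mass_Da[1],
    abundance = d$abundance
  )
}

#' Mass-per-additional-neutron ratios of the heavy isotopes
#'
#' For every isotope with at least one extra neutron, the ratio
#' `(mass - lightest mass) / neutron offset`. The maximum and minimum of this
#' ratio (2H and 15N for the pinned table) determine the heaviest and
#' lightest fine variants of an aggregated isotopic variant and hence its
#' maximum spread.
#'
#' @inheritParams count_fine_peaks
#' @return A tibble with columns `element`, `isotope`, `neutron_offset` and
#'   `mass_per_neutron` (Da), sorted by decreasing ratio.
#' @examples
#' mass_per_neutron()
#' @export
mass_per_neutron <- function(table = isotope_table()) {
  table |>
    dplyr::group_by(.data$element) |>
    dplyr::mutate(mass_per_neutron =
                    (.data$mass_Da - min(.data$mass_Da)) / .data$neutron_offset) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$neutron_offset > 0) |>
    dplyr::select("element", "isotope", "neutron_offset", "mass_per_neutron") |>
    dplyr::arrange(dplyr::desc(.data$mass_per_neutron))
}

# Extreme mass-per-neutron ratios (2H upper, 15N lower for the pinned table).
mpn_extremes <- function(table) {
  mpn <- mass_per_neutron(table)
  list(upper = mpn$mass_per_neutron[1],
       lower = mpn$mass_per_neutron[nrow(mpn)])
}
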