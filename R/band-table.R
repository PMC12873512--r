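#' Raman band assignments for cuticle constituents
#'
#' Reference table of Raman shift positions (cm^-1, 785 nm excitation) used
#' both by [assign_bands()] to score measured spectra and by
#' [generate_raman_cube()] to build synthetic endmember spectra. Compound
#' classes cover the chemistry of dwarf-shrub leaf cuticles: the cutin
#' polyester matrix, pentacyclic triterpenoids (including the 746 cm^-1 band
#' specific to ursolic/oleanolic acid), flavonoids and the generic aromatic
#' ring stretch, anthocyanin-leaning bands, cinnamic acids, and crystalline
#' long-chain alkanes of epicuticular waxes.
#'
#' @return a tibble with columns `class` (compound class label),
#'   `wavenumber` (cm^-1) and `height` (relative band height used when
#'   constructing synthetic endmembers).
#' @export
#' @examples
#' raman_band_table()
raman_band_table <- function() {
  tibble::tribble(
    ~class,              ~wavenumber, ~height,
    "cutin",                    1443,     1.0,
    "cutin",                    1306,     0.8,
    "triterpenoid",              463,     0.7,
    "triterpenoid",              532,     0.8,
    "triterpenoid",              564,     0.7,
    "triterpenoid",              683,     0.8,
    "triterpenoid",              729,     0.9,
    "triterpenoid",              746,     1.0,
    "flavonoid",                1570,     1.0,
    "flavonoid",                1250,     0.9,
    "aromatic_ring",            1607,     1.0,
    "anthocyanin",               631,     0.8,
    "anthocyanin",              1630,     1.0,
    "cinnamic_acid",            1630,     1.0,
    "cinnamic_acid",            1170,     0.8,
    "alkane_crystalline",       1064,     1.0,
    "alkane_crystalline",       1133,     0.9,
    "alkane_crystalline",       1297,     1.0
  )
}

# classes that can serve as generator endmembers; flavonoid endmembers carry
# the aromatic ring stretch as well, matching how flavonoid-rich layers look
endmember_bands <- function(label) {
  tbl <- raman_band_table()
  classes <- switch(label,
    flavonoid = c("flavonoid", "aromatic_ring"),
    label
  )
  out <- tbl[tbl$class %in% classes, ]
  if (nrow(out) == 0L) {
    abort(sprintf(
      "unknown endmember label `%s`; see raman_band_table() for classes.", label
    ))
  }
  out
}

#' Synthetic endmember spectrum for a compound class
#'
#' Builds a pure-component spectrum as a sum of Gaussian bands at the
#' positions in [raman_band_table()]. Band shape is Gaussian with a common
#' full width at half maximum; real cuticle bands are Voigt-like but a
#' Gaussian is adequate for generating test data with known band areas.
#'
#' @param label compound class (`"cutin"`, `"triterpenoid"`, `"flavonoid"`,
#'   `"cinnamic_acid"`, `"anthocyanin"`, `"alkane_crystalline"`).
#' @param wavenumbers numeric axis (cm^-1) on which to evaluate the spectrum.
#' @param fwhm full width at half maximum of every band, cm^-1. Default 12.
#' @return numeric vector of intensities, same length as `wavenumbers`,
#'   peak-normalised to 1.
#' @export
endmember_spectrum <- function(label, wavenumbers, fwhm = 12) {
  bands <- endmember_bands(label)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  spec <- rep(0, length(wavenumbers))
  for (i in seq_len(nrow(bands))) {
    spec <- spec + bands$height[i] *
      exp(-((wavenumbers - bands$wavenumber[i])^2) / (2 * sigma^2))
  }
  if (max(spec) > 0) spec <- spec / max(spec)
  spec
}
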