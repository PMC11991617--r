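# Component absorptivity library and the forward absorbance model.
#
# The model for a phantom at temperature T on wavelength grid lambda:
#
#   A(lambda) = A_w(lambda) * (1 - kappa * c_total)            water + displacement
#             + sum_i eps_i(lambda) * c_i                      solute absorption
#             + off * c_beads + slope * c_beads * (lambda - l0) scattering baseline
#             + dA/dT(lambda) * (T - T_ref)                    temperature
#
# All curves are sums of Gaussian bands held as data in the library object, so
# every physical assumption is configurable rather than baked into code.

#' Wavelength grid constructor
#'
#' @param n Number of wavelengths (the prototype uses 112 lasers).
#' @param min_nm,max_nm Grid span in nm; must lie in 1300-2500 nm.
#' @return Strictly increasing numeric vector of wavelengths (nm).
#' @export
wavelength_grid <- function(n = 112, min_nm = 1350, max_nm = 2450) {
  if (n < 2) abort("`n` must be >= 2.")
  if (min_nm >= max_nm) abort("`min_nm` must be < `max_nm`.")
  if (min_nm < 1300 || max_nm > 2500) {
    abort("Wavelength grid must lie within 1300-2500 nm.")
  }
  seq(min_nm, max_nm, length.out = n)
}

gaussian_bands <- function(center_nm, sd_nm, amplitude) {
  tibble::tibble(center_nm = center_nm, sd_nm = sd_nm, amplitude = amplitude)
}

#' Component absorptivity library for the forward simulator
#'
#' Bundles the spectral model used to synthesize phantom absorbance spectra:
#' per-component absorptivity curves (sums of Gaussian bands, AU*dL/(mg*cm)),
#' the water absorbance baseline (AU), a temperature-sensitivity curve
#' (AU/degC), a water-displacement coefficient, and a bead-scattering
#' baseline model (offset + slope in wavelength per mg/dL of beads).
#'
#' Defaults place glucose bands in the first-overtone (~1590, 1730 nm) and
#' combination (~2100, 2270 nm) regions with amplitudes giving a
#' 100-200 uAU-scale signal at 500 mg/dL; water peaks near 1450 and 1940 nm.
#'
#' @param glucose_bands,triton_bands,saline_bands,germall_bands Band tables
#'   (`center_nm`, `sd_nm`, `amplitude`) for each absorbing solute.
#' @param water_bands Band table for the water absorbance baseline (AU).
#' @param water_offset Constant water baseline offset, AU.
#' @param dAdT_bands Band table for dA/dT (AU per degC).
#' @param displacement_per_mgdl Fractional water volume displaced per mg/dL of
#'   total solute (mass concentration / solute density).
#' @param scatter_offset_per_mgdl Absorbance offset per mg/dL of beads, AU.
#' @param scatter_slope_per_nm_mgdl Absorbance slope per nm per mg/dL of beads.
#' @param scatter_center_nm Wavelength where the scattering slope term is zero.
#' @param t_ref_c Reference temperature, degC.
#' @param range_nm Wavelength span over which the library is defined.
#' @return An object of class `absorptivity_library`.
#' @export
absorptivity_library <- function(
    glucose_bands = gaussian_bands(c(1590, 1730, 2100, 2270),
                                   c(35, 30, 45, 40),
                                   c(2.2e-7, 1.8e-7, 3.0e-7, 2.6e-7)),
    triton_bands = gaussian_bands(c(1710, 2310), c(40, 50), c(1.2e-7, 1.0e-7)),
    saline_bands = gaussian_bands(2000, 300, 3e-8),
    germall_bands = gaussian_bands(2050, 60, 5e-8),
    water_bands = gaussian_bands(c(1450, 1940, 2500), c(45, 55, 120),
                                 c(0.35, 1.10, 0.60)),
    water_offset = 0.05,
    dAdT_bands = gaussian_bands(c(1920, 1990), c(40, 40), c(5e-4, -5e-4)),
    displacement_per_mgdl = 6.5e-6,
    scatter_offset_per_mgdl = 1.5e-5,
    scatter_slope_per_nm_mgdl = -5e-9,
    scatter_center_nm = 1900,
    t_ref_c = 32,
    range_nm = c(1300, 2500)) {
  check_number(displacement_per_mgdl, "displacement_per_mgdl", min = 0)
  lib <- list(
    components = list(glucose = glucose_bands, triton = triton_bands,
                      saline = saline_bands, germall = germall_bands),
    water_bands = water_bands, water_offset = water_offset,
    dAdT_bands = dAdT_bands,
    displacement_per_mgdl = displacement_per_mgdl,
    scatter = list(offset_per_mgdl = scatter_offset_per_mgdl,
                   slope_per_nm_mgdl = scatter_slope_per_nm_mgdl,
                   center_nm = scatter_center_nm),
    t_ref_c = t_ref_c, range_nm = range_nm
  )
  structure(lib, class = "absorptivity_library")
}

#' Evaluate a component absorptivity curve
#'
#' @param lib An [absorptivity_library()].
#' @param component One of "glucose", "triton", "saline", "germall", or
#'   "water" (returns the water absorbance baseline in AU).
#' @param wavelength_nm Wavelengths at which to evaluate.
#' @return Numeric vector: absorptivity in AU*dL/(mg*cm), or AU for water.
#' @export
absorptivity <- function(lib, component, wavelength_nm) {
  if (component == "water") {
    return(eval_bands(lib$water_bands, wavelength_nm) + lib$water_offset)
  }
  bands <- lib$components[[component]]
  if (is.null(bands)) abort(sprintf("Unknown component '%s'.", component))
  eval_bands(bands, wavelength_nm)
}

as_concentrations <- function(recipe) {
  if (is.data.frame(recipe)) {
    if (nrow(recipe) != 1) abort("`recipe` must be a single phantom (one row).")
    recipe <- as.list(recipe)
  }
  comps <- c("glucose", "beads", "triton", "saline", "germall")
  conc <- vapply(comps, function(k) {
    v <- recipe[[paste0(k, "_mgdl")]] %||% recipe[[k]] %||% 0
    as.double(v)
  }, double(1))
  if (any(conc < 0)) abort("Component concentrations must be >= 0.")
  conc
}

#' Simulate a noiseless phantom absorbance spectrum
#'
#' Forward model: water baseline scaled by the displaced water fraction, plus
#' Beer-Lambert solute terms linear in each concentration, a bead-scattering
#' offset/slope baseline, and a temperature term. See
#' [absorptivity_library()] for the model pieces.
#'
#' @param recipe One design row (or named list) with `glucose_mgdl`,
#'   `beads_mgdl`, `triton_mgdl`, `saline_mgdl`, `germall_mgdl` (missing
#'   components default to 0).
#' @param grid Wavelength grid (nm), within the library span.
#' @param lib An [absorptivity_library()].
#' @param temperature_c Sample temperature, degC.
#' @return A tibble with `wavelength_nm` and `absorbance_au`.
#' @export
simulate_absorbance <- function(recipe, grid = wavelength_grid(),
                                lib = absorptivity_library(),
                                temperature_c = lib$t_ref_c) {
  if (min(grid) < lib$range_nm[1] || max(grid) > lib$range_nm[2]) {
    abort(sprintf("Grid span [%g, %g] nm lies outside the library range [%g, %g] nm.",
                  min(grid), max(grid), lib$range_nm[1], lib$range_nm[2]))
  }
  conc <- as_concentrations(recipe)
  c_total <- sum(conc)
  f_water <- max(0, 1 - lib$displacement_per_mgdl * c_total)

  a <- absorptivity(lib, "water", grid) * f_water
  for (k in names(lib$components)) {
    a <- a + absorptivity(lib, k, grid) * conc[[k]]
  }
  a <- a + lib$scatter$offset_per_mgdl * conc[["beads"]] +
    lib$scatter$slope_per_nm_mgdl * conc[["beads"]] * (grid - lib$scatter$center_nm) +
    eval_bands(lib$dAdT_bands, grid) * (temperature_c - lib$t_ref_c)

  tibble::tibble(wavelength_nm = grid, absorbance_au = a)
}
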