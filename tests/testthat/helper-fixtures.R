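# Shared fixtures: everything is generated in code at test time.

table1_design <- function() build_design()

# A quiet absorptivity library: only glucose absorbs, no displacement, no
# scattering, no temperature term. Used for exact Beer-Lambert checks.
glucose_only_library <- function(bands = NULL) {
  absorptivity_library(
    glucose_bands = bands %||% tibble::tibble(
      center_nm = c(1590, 2100), sd_nm = c(35, 45), amplitude = c(2.2e-7, 3.0e-7)),
    triton_bands = tibble::tibble(center_nm = double(), sd_nm = double(), amplitude = double()),
    saline_bands = tibble::tibble(center_nm = double(), sd_nm = double(), amplitude = double()),
    germall_bands = tibble::tibble(center_nm = double(), sd_nm = double(), amplitude = double()),
    dAdT_bands = tibble::tibble(center_nm = double(), sd_nm = double(), amplitude = double()),
    displacement_per_mgdl = 0, scatter_offset_per_mgdl = 0,
    scatter_slope_per_nm_mgdl = 0
  )
}

no_variation <- function() {
  measurement_variation(offset_sd_au = 0, slope_sd_au_per_nm = 0,
                        curvature_sd_au = 0, pathlength_scale_sd = 0,
                        temperature_jitter_c = 0, baseline_wander_sd_au = 0)
}

# Noise-free instrument profile with n_scans processed scans.
quiet_profile <- function(n_scans = 100) {
  list(name = "quiet", scan_rate = 1, duration_s = n_scans,
       noise_rms_uau = 0, pairwise_average = FALSE, trim_s = NULL,
       native_points = NULL, native_range_nm = NULL)
}

# Wide spectra tibble from an explicit matrix (scans x wavelengths).
make_spectra <- function(m, wavelengths = seq(1350, 2450, length.out = ncol(m)),
                         scan_rate = 1, phantom_id = "P01") {
  nirphantom:::new_spectra_tbl(m, wavelengths,
                               (seq_len(nrow(m)) - 1) / scan_rate,
                               phantom_id = phantom_id)
}

`%||%` <- rlang::`%||%`
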