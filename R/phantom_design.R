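# Phantom design and gravimetric recipe math.

#' Published concentration levels for the glucose x scatterer phantom design
#'
#' Seven glucose and seven polystyrene-bead concentration levels (mg/dL) used
#' to construct the 49-phantom full-cross design. The bead spacing is
#' irregular (1712 then 1734); the printed values are kept verbatim.
#'
#' @return A list with numeric vectors `glucose` and `beads` (mg/dL).
#' @export
design_levels <- function() {
  list(
    glucose = c(0, 82.5, 167.5, 250, 332.5, 417.5, 500),
    beads   = c(1466, 1588, 1712, 1734, 1956, 2078, 2200)
  )
}

#' Build the 7 x 7 phantom design
#'
#' Crosses seven glucose levels with seven scattering (polystyrene bead)
#' levels into 49 unique phantoms, with fixed concentrations of Triton X-100,
#' saline and Germall preservative in every phantom. Rows are ordered by
#' (glucose, beads) and labelled P01..P49.
#'
#' @param glucose_levels,bead_levels Exactly 7 distinct concentrations each,
#'   in mg/dL. Defaults are the published levels from [design_levels()].
#' @param triton_mgdl,saline_mgdl,germall_mgdl Fixed component targets, mg/dL.
#' @return A tibble with one row per phantom: `phantom_id`, `glucose_mgdl`,
#'   `beads_mgdl`, `triton_mgdl`, `saline_mgdl`, `germall_mgdl`.
#' @examples
#' design <- build_design()
#' nrow(design)            # 49
#' design_glucose_sd(design)  # ~166.8 mg/dL
#' @export
build_design <- function(glucose_levels = design_levels()$glucose,
                         bead_levels = design_levels()$beads,
                         triton_mgdl = 800, saline_mgdl = 966,
                         germall_mgdl = 100) {
  check_axis <- function(x, axis) {
    if (length(x) != 7) {
      abort(sprintf("`%s` axis must have exactly 7 levels, got %d.", axis, length(x)))
    }
    if (anyDuplicated(x)) {
      abort(sprintf("`%s` axis has duplicate levels; all 7 must be distinct.", axis))
    }
    check_number(x, axis, min = 0)
  }
  check_axis(glucose_levels, "glucose")
  check_axis(bead_levels, "beads")

  grid <- tidyr::expand_grid(
    glucose_mgdl = sort(glucose_levels),
    beads_mgdl = sort(bead_levels)
  )
  grid |>
    dplyr::mutate(
      phantom_id = sprintf("P%02d", dplyr::row_number()),
      triton_mgdl = triton_mgdl,
      saline_mgdl = saline_mgdl,
      germall_mgdl = germall_mgdl,
      .before = 1
    )
}

#' Population standard deviation of the design glucose concentrations
#'
#' @param design A design tibble from [build_design()].
#' @return Population SD (divisor n) of the 49 glucose values, mg/dL. For the
#'   published levels this is 166.8 mg/dL.
#' @export
design_glucose_sd <- function(design) {
  g <- design$glucose_mgdl
  sqrt(mean((g - mean(g))^2))
}

#' Gravimetric stock mass to dispense
#'
#' Mass of stock solution that delivers a target concentration in a flask:
#' m = C_target * V_flask * rho_stock / C_stock. Units: C in mg/dL, V in mL,
#' rho in g/mL; the mg/dL units cancel and mL * g/mL leaves grams.
#'
#' @param c_target_mgdl Target concentration in the phantom, mg/dL.
#' @param v_flask_ml Flask (total sample) volume, mL.
#' @param rho_stock_g_ml Measured stock solution density, g/mL.
#' @param c_stock_mgdl Stock solution concentration, mg/dL (> 0).
#' @param component Optional component name used in error messages.
#' @return Mass to dispense, grams. Vectorized over all arguments.
#' @export
stock_mass <- function(c_target_mgdl, v_flask_ml, rho_stock_g_ml, c_stock_mgdl,
                       component = NULL) {
  check_number(c_target_mgdl, "c_target_mgdl", min = 0)
  check_number(v_flask_ml, "v_flask_ml", min = 0)
  check_number(rho_stock_g_ml, "rho_stock_g_ml", min = 0, strict_min = TRUE)
  if (any(c_stock_mgdl <= 0)) {
    who <- component %||% "component"
    abort(sprintf("Stock concentration for %s must be > 0 (division by C_stock).", who))
  }
  c_target_mgdl * v_flask_ml * rho_stock_g_ml / c_stock_mgdl
}

#' Final concentration achieved by a dispensed volume
#'
#' C_final = V_dispensed * C_stock / V_sample, where V_sample is the total
#' phantom volume (sum of all component additions).
#'
#' @param v_dispensed_ml Dispensed stock volume (mass / density), mL.
#' @param c_stock_mgdl Stock concentration, mg/dL.
#' @param v_sample_ml Total sample volume, mL (> 0).
#' @return Final concentration, mg/dL. Vectorized.
#' @export
final_concentration <- function(v_dispensed_ml, c_stock_mgdl, v_sample_ml) {
  check_number(v_dispensed_ml, "v_dispensed_ml", min = 0)
  if (any(v_sample_ml <= 0)) abort("`v_sample_ml` must be > 0.")
  v_dispensed_ml * c_stock_mgdl / v_sample_ml
}

#' Default stock solution table
#'
#' Stock concentrations for Triton X-100 (10,000 mg/dL), Germall
#' (2,000 mg/dL) and glucose (1,500 mg/dL) follow the study preparation; the
#' bead suspension is used as purchased (10% w/v = 10,000 mg/dL) and saline is
#' a 10x concentrate. Densities are plausible pycnometer values for aqueous
#' stocks; water is carried as its own "stock" so the recipe sums to the flask
#' volume.
#'
#' @return A tibble with columns `component`, `c_stock_mgdl`, `rho_g_ml`.
#' @export
default_stocks <- function() {
  tibble::tribble(
    ~component, ~c_stock_mgdl, ~rho_g_ml,
    "beads",    10000,         1.005,
    "triton",   10000,         1.011,
    "saline",   9660,          1.007,
    "germall",  2000,          1.002,
    "glucose",  1500,          1.006
  )
}

#' Compute gravimetric recipes for every phantom in a design
#'
#' For each phantom and component, computes the stock mass to dispense
#' ([stock_mass()]), the dispensed volume (mass / stock density), and the
#' recomputed final concentration ([final_concentration()]). Water is added
#' last to bring each phantom to the flask volume, so the total sample volume
#' equals the sum of all component additions.
#'
#' @param design A design tibble from [build_design()].
#' @param stocks Stock table as in [default_stocks()].
#' @param v_flask_ml Flask volume per phantom, mL.
#' @param water_rho_g_ml Density of the water make-up, g/mL.
#' @return A tibble with one row per phantom x component (components in
#'   addition order: beads, triton, water, saline, germall, glucose):
#'   `phantom_id`, `component`, `target_mgdl`, `c_stock_mgdl`, `rho_g_ml`,
#'   `mass_g`, `volume_ml`, `final_mgdl`, `v_sample_ml`.
#' @export
phantom_recipes <- function(design, stocks = default_stocks(), v_flask_ml = 50,
                            water_rho_g_ml = 0.998) {
  comps <- c("beads", "triton", "saline", "germall", "glucose")
  missing <- setdiff(comps, stocks$component)
  if (length(missing)) {
    abort(paste0("`stocks` is missing components: ", paste(missing, collapse = ", ")))
  }

  long <- design |>
    tidyr::pivot_longer(dplyr::all_of(paste0(comps, "_mgdl")),
                        names_to = "component", values_to = "target_mgdl") |>
    dplyr::mutate(component = sub("_mgdl$", "", .data$component)) |>
    dplyr::select("phantom_id", "component", "target_mgdl") |>
    dplyr::left_join(stocks, by = "component") |>
    dplyr::mutate(
      mass_g = stock_mass(.data$target_mgdl, v_flask_ml, .data$rho_g_ml,
                          .data$c_stock_mgdl),
      volume_ml = .data$mass_g / .data$rho_g_ml
    )

  water <- long |>
    dplyr::summarise(solute_ml = sum(.data$volume_ml), .by = "phantom_id") |>
    dplyr::mutate(
      component = "water", target_mgdl = NA_real_, c_stock_mgdl = NA_real_,
      rho_g_ml = water_rho_g_ml,
      volume_ml = v_flask_ml - .data$solute_ml,
      mass_g = .data$volume_ml * water_rho_g_ml
    ) |>
    dplyr::select(-"solute_ml")
  if (any(water$volume_ml < 0)) {
    abort("Component additions exceed the flask volume; increase `v_flask_ml` or stock concentrations.")
  }

  order_tbl <- tibble::tibble(
    component = c("beads", "triton", "water", "saline", "germall", "glucose"),
    add_order = 1:6
  )
  dplyr::bind_rows(long, water) |>
    dplyr::mutate(
      v_sample_ml = v_flask_ml,
      final_mgdl = dplyr::if_else(
        .data$component == "water", NA_real_,
        final_concentration(.data$volume_ml, .data$c_stock_mgdl, v_flask_ml)
      )
    ) |>
    dplyr::left_join(order_tbl, by = "component") |>
    dplyr::arrange(.data$phantom_id, .data$add_order) |>
    dplyr::select(-"add_order")
}
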