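# Wall shear stress <-> volumetric flow rate for laminar flow in the
# rectangular microchannel, and pump flow from stroke volume x frequency.

#' Default culture-medium viscosity (Pa s)
#'
#' Dynamic viscosity of serum-supplemented culture medium at 37 C,
#' 6.5e-4 Pa s. With the default channel geometry (1 mm x 250 um) this
#' value maps wall shear stresses of 0.01 and 0.5 dyn/cm2 to pump flow
#' rates of 1 and 48 ul/min (nearest integer).
#' @export
MEDIUM_VISCOSITY_PA_S <- 6.5e-4

.check_flow_args <- function(width_mm, height_um, viscosity_pa_s) {
  if (!is.finite(width_mm) || width_mm <= 0 ||
      !is.finite(height_um) || height_um <= 0 ||
      !is.finite(viscosity_pa_s) || viscosity_pa_s <= 0) {
    stop("channel width, height and viscosity must be positive",
         call. = FALSE)
  }
}

#' Flow rate producing a target wall shear stress
#'
#' For fully developed laminar flow between parallel plates (valid for wide,
#' shallow rectangular channels, h << w) the wall shear stress is
#' `tau = 6 mu Q / (w h^2)`, so the flow rate for a target shear is
#' `Q = tau w h^2 / (6 mu)`.
#'
#' @param tau_dyn_cm2 Wall shear stress, dyn/cm2 (1 dyn/cm2 = 0.1 Pa).
#' @param width_mm Channel width, mm.
#' @param height_um Channel height, um.
#' @param viscosity_pa_s Dynamic viscosity, Pa s.
#' @return Volumetric flow rate in ul/min.
#' @examples
#' shear_to_flow(0.5)   # ~48 ul/min
#' shear_to_flow(0.01)  # ~1 ul/min
#' @export
shear_to_flow <- function(tau_dyn_cm2, width_mm = 1, height_um = 250,
                          viscosity_pa_s = MEDIUM_VISCOSITY_PA_S) {
  .check_flow_args(width_mm, height_um, viscosity_pa_s)
  if (any(tau_dyn_cm2 < 0)) stop("shear stress must be >= 0", call. = FALSE)
  tau_pa <- tau_dyn_cm2 * 0.1
  w_m <- width_mm * 1e-3
  h_m <- height_um * 1e-6
  q_m3_s <- tau_pa * w_m * h_m^2 / (6 * viscosity_pa_s)
  q_m3_s * 1e9 * 60  # m3/s -> ul/min
}

#' Wall shear stress produced by a flow rate
#'
#' Exact inverse of [shear_to_flow()]: `tau = 6 mu Q / (w h^2)`.
#'
#' @param q_ul_min Volumetric flow rate, ul/min.
#' @inheritParams shear_to_flow
#' @return Wall shear stress in dyn/cm2.
#' @export
flow_to_shear <- function(q_ul_min, width_mm = 1, height_um = 250,
                          viscosity_pa_s = MEDIUM_VISCOSITY_PA_S) {
  .check_flow_args(width_mm, height_um, viscosity_pa_s)
  if (any(q_ul_min < 0)) stop("flow rate must be >= 0", call. = FALSE)
  q_m3_s <- q_ul_min / (1e9 * 60)
  w_m <- width_mm * 1e-3
  h_m <- height_um * 1e-6
  tau_pa <- 6 * viscosity_pa_s * q_m3_s / (w_m * h_m^2)
  tau_pa / 0.1
}

#' Pump flow rate from stroke volume and frequency
#'
#' The recirculating micropumps are displacement pumps: the delivered flow
#' rate is the calibrated average stroke volume times the pumping frequency.
#'
#' @param stroke_volume_ul Average stroke volume, ul/cycle.
#' @param frequency_cpm Pumping frequency, cycles/min.
#' @return Flow rate in ul/min.
#' @examples
#' pump_flow_rate(0.5, 96)  # 48 ul/min
#' @export
pump_flow_rate <- function(stroke_volume_ul, frequency_cpm) {
  if (any(stroke_volume_ul < 0) || any(frequency_cpm < 0)) {
    stop("stroke volume and frequency must be non-negative", call. = FALSE)
  }
  stroke_volume_ul * frequency_cpm
}
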