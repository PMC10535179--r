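#' Default lumped thermal parameters of the mill circuit
#'
#' Single-capacity heat balance of the mill-plus-holding-tank circuit:
#' a fraction `eta_heat` of the stirrer power enters as heat, the chiller
#' removes `UA * (T - T_coolant)`, and the lumped heat capacity is `C_th`.
#' Milling pauses when the outlet temperature reaches `T_max` (35 C) and
#' resumes once it has relaxed to `T_restart`.
#'
#' The heat-transfer constants are nominal values for a laboratory
#' recirculating mill with a small chiller; only the cycle-counting logic,
#' not absolute cycle counts, should be compared across systems.
#'
#' @param eta_heat Fraction of stirrer power converted to heat.
#' @param UA_W_K Overall heat-transfer conductance to the coolant, W/K.
#' @param C_th_J_K Lumped heat capacity, J/K.
#' @param T_coolant_C,T_start_C,T_max_C,T_restart_C Temperatures, C.
#' @return Named list of thermal parameters.
#' @export
thermal_defaults <- function(eta_heat = 0.9, UA_W_K = 3, C_th_J_K = 3000,
                             T_coolant_C = 8, T_start_C = 20,
                             T_max_C = 35, T_restart_C = 20) {
  if (UA_W_K <= 0 || C_th_J_K <= 0) {
    stop("UA and C_th must be positive", call. = FALSE)
  }
  if (T_restart_C >= T_max_C) stop("T_restart must be below T_max", call. = FALSE)
  list(eta_heat = eta_heat, UA_W_K = UA_W_K, C_th_J_K = C_th_J_K,
       T_coolant_C = T_coolant_C, T_start_C = T_start_C,
       T_max_C = T_max_C, T_restart_C = T_restart_C)
}

#' Simulate the intermittent milling schedule under a temperature cutoff
#'
#' Integrates the lumped heat balance
#' `dT/dt = (eta_heat * P - UA * (T - T_coolant)) / C_th` exactly (the ODE is
#' linear, so each heating or cooling leg is an exponential relaxation with
#' closed-form hitting times). Milling stops whenever the temperature
#' reaches `T_max`, the suspension cools (no heat source) to `T_restart`,
#' and milling resumes, until the cumulative milling time reaches
#' `total_min`. A run whose steady-state temperature stays below `T_max`
#' gives a single uninterrupted segment.
#'
#' @param p_watt Average stirrer power during milling, W (>= 0).
#' @param thermal Thermal parameters, see [thermal_defaults()].
#' @param total_min Total cumulative milling time, minutes.
#' @return Object of class `thermal_schedule`: list with `cycles` (tibble of
#'   wall-clock `mill_start`, `mill_stop`, `cool_stop` minutes), `n_cycles`,
#'   and the inputs. Milling durations sum to `total_min` exactly.
#' @examples
#' simulate_thermal_cycles(120)$n_cycles
#' simulate_thermal_cycles(0)$n_cycles   # no heat source: one segment
#' @export
simulate_thermal_cycles <- function(p_watt, thermal = thermal_defaults(),
                                    total_min = 180) {
  stopifnot(p_watt >= 0, total_min > 0)
  if (thermal$UA_W_K <= 0 || thermal$C_th_J_K <= 0) {
    stop("UA and C_th must be positive", call. = FALSE)
  }
  if (thermal$T_restart_C >= thermal$T_max_C) {
    stop("T_restart must be below T_max", call. = FALSE)
  }
  tau_min <- thermal$C_th_J_K / thermal$UA_W_K / 60
  t_inf_mill <- thermal$T_coolant_C + thermal$eta_heat * p_watt / thermal$UA_W_K
  t_inf_cool <- thermal$T_coolant_C
  # time for T to relax from `from` towards `t_inf` until it reaches `to`
  leg_time <- function(from, to, t_inf) tau_min * log((t_inf - from) / (t_inf - to))

  cycles <- list()
  milled <- 0
  wall <- 0
  temp <- thermal$T_start_C
  repeat {
    remaining <- total_min - milled
    if (t_inf_mill <= thermal$T_max_C || temp >= t_inf_mill) {
      # never reaches the cutoff: mill the remainder in one go
      dur <- remaining
    } else {
      t_hit <- leg_time(temp, thermal$T_max_C, t_inf_mill)
      dur <- min(t_hit, remaining)
    }
    cyc <- c(mill_start = wall, mill_stop = wall + dur)
    milled <- milled + dur
    wall <- wall + dur
    if (milled >= total_min - 1e-12) {
      cycles[[length(cycles) + 1L]] <- c(cyc, cool_stop = wall)
      break
    }
    # cutoff reached: cool to the restart temperature with the stirrer off
    t_cool <- leg_time(thermal$T_max_C, thermal$T_restart_C, t_inf_cool)
    wall <- wall + t_cool
    temp <- thermal$T_restart_C
    cycles[[length(cycles) + 1L]] <- c(cyc, cool_stop = wall)
  }
  cyc_df <- tibble::as_tibble(do.call(rbind, cycles))
  # make milling durations sum to total_min exactly despite float accumulation
  dur <- cyc_df$mill_stop - cyc_df$mill_start
  err <- total_min - sum(dur)
  cyc_df$mill_stop[nrow(cyc_df)] <- cyc_df$mill_stop[nrow(cyc_df)] + err
  cyc_df$cool_stop[nrow(cyc_df)] <- max(cyc_df$cool_stop[nrow(cyc_df)],
                                        cyc_df$mill_stop[nrow(cyc_df)])
  structure(
    list(cycles = cyc_df, n_cycles = nrow(cyc_df), p_watt = p_watt,
         thermal = thermal, total_min = total_min),
    class = "thermal_schedule"
  )
}
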