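# Readout-electronics model for the 8x8 piezoresistive pressure array:
# pressure -> resistance -> amplifier voltage -> ADC counts, with and
# without the crosstalk-elimination drive scheme, plus per-cell calibration.

#' Piezoresistive sensor characteristic
#'
#' The sensor resistance is inversely proportional to applied pressure,
#' \eqn{R_x = K_{p-r} / P}, where the characteristic constant `k_pr`
#' (ohm kPa) is a property of the sensing film. The default is chosen so
#' that, with the default [circuit_config()], the full children's pressure
#' range 0--700 kPa maps inside the ADC span without saturation.
#'
#' @param k_pr Sensor characteristic constant in ohm kPa; must be > 0.
#' @return An object of class `sensor_char`.
#' @export
sensor_char <- function(k_pr = 1.2e6) {
  stopifnot(is.numeric(k_pr), length(k_pr) == 1L, is.finite(k_pr), k_pr > 0)
  structure(list(k_pr = k_pr), class = "sensor_char")
}

#' Readout-circuit configuration
#'
#' Parameters of the non-inverting amplifier and ADC stage. The amplifier
#' output is \eqn{V_{out} = (R_x + R_f)/R_x \cdot V_{ref}} and the ADC code
#' is \eqn{D = 2^m V_{out} / V_{adc\_ref}}.
#'
#' @param v_ref Amplifier reference voltage (V).
#' @param v_adc_ref ADC reference voltage (V); must be >= `v_ref`.
#' @param r_f Feedback resistor (ohm).
#' @param r_0 Charging resistor used to stabilise the ADC input (ohm);
#'   documentation only, it does not enter the ideal output equation.
#' @param m ADC resolution in bits.
#' @return An object of class `circuit_config`.
#' @export
circuit_config <- function(v_ref = 0.5, v_adc_ref = 5, r_f = 1e4,
                           r_0 = 1000, m = 10L) {
  stopifnot(v_ref > 0, v_adc_ref >= v_ref, r_f > 0, m >= 1)
  structure(list(v_ref = v_ref, v_adc_ref = v_adc_ref, r_f = r_f,
                 r_0 = r_0, m = as.integer(m)),
            class = "circuit_config")
}

#' Sensor resistance under load
#'
#' @param p Pressure(s) in kPa, non-negative.
#' @param char A [sensor_char()].
#' @return Resistance in ohm; `Inf` (open circuit) where `p == 0`.
#' @export
#' @examples
#' resistance_from_pressure(1, sensor_char(k_pr = 100))  # 100 ohm
resistance_from_pressure <- function(p, char = sensor_char()) {
  if (!is.numeric(p) || any(!is.finite(p)))
    stop("pressure must be finite numeric")
  if (any(p < 0)) stop("pressure must be non-negative")
  ifelse(p > 0, char$k_pr / p, Inf)
}

#' Ideal ADC output for a loaded cell
#'
#' Computes \eqn{D = 2^m (k_{pr} + p R_f)/k_{pr} \cdot V_{ref}/V_{adc\_ref}},
#' truncated (floored) to an integer code and clipped to `[0, 2^m]`. The
#' zero-load baseline is the code corresponding to `v_ref` alone.
#'
#' @inheritParams resistance_from_pressure
#' @param cfg A [circuit_config()].
#' @return Integer ADC counts, same length as `p`.
#' @export
#' @examples
#' adc_output(0)  # zero-load baseline: floor(1024 * 0.1) = 102
adc_output <- function(p, char = sensor_char(), cfg = circuit_config()) {
  if (!is.numeric(p) || any(!is.finite(p)))
    stop("pressure must be finite numeric")
  if (any(p < 0)) stop("pressure must be non-negative")
  d <- 2^cfg$m * ((char$k_pr + p * cfg$r_f) / char$k_pr) *
    cfg$v_ref / cfg$v_adc_ref
  as.integer(pmin(pmax(floor(d), 0), 2^cfg$m))
}

# ADC code from an effective sensed resistance (ohm), used by the
# crosstalk scan; Inf resistance gives the zero-load baseline.
adc_from_resistance <- function(r_eff, cfg = circuit_config()) {
  v_out <- ifelse(is.finite(r_eff), (r_eff + cfg$r_f) / r_eff, 1) * cfg$v_ref
  as.integer(pmin(pmax(floor(2^cfg$m * v_out / cfg$v_adc_ref), 0), 2^cfg$m))
}

# Effective resistance seen when reading cell (r, c) of a row/column
# addressed resistive array whose unselected channels float. Exact nodal
# analysis: selected row at 1 V, selected column at 0 V, KCL at every
# floating row/column node. R is the full resistance matrix (ohm).
scan_effective_resistance <- function(R, r, c) {
  nr <- nrow(R); nc <- ncol(R)
  g <- 1 / R
  fr <- setdiff(seq_len(nr), r)   # floating rows
  fc <- setdiff(seq_len(nc), c)   # floating columns
  nun <- length(fr) + length(fc)
  if (nun == 0L) return(R[r, c])
  A <- matrix(0, nun, nun)
  b <- numeric(nun)
  # unknowns: potentials of floating rows then floating columns
  for (ii in seq_along(fr)) {
    i <- fr[ii]
    A[ii, ii] <- sum(g[i, ])
    for (jj in seq_along(fc)) A[ii, length(fr) + jj] <- -g[i, fc[jj]]
    # selected column is at 0; no source term from it
  }
  for (jj in seq_along(fc)) {
    j <- fc[jj]
    row <- length(fr) + jj
    A[row, row] <- sum(g[, j])
    for (ii in seq_along(fr)) A[row, ii] <- -g[fr[ii], j]
    b[row] <- g[r, j] * 1   # driven row at 1 V
  }
  v <- solve(A, b)
  v_rows <- v[seq_along(fr)]
  # current collected at the selected (grounded) column
  i_col <- g[r, c] * 1 + sum(g[fr, c] * v_rows)
  1 / i_col
}

#' Scan an 8x8 pressure state through the readout electronics
#'
#' With `crosstalk_elimination = TRUE` the drive scheme grounds unselected
#' rows and pulls unselected columns to the reference voltage, so every
#' current path except the selected cell's is cut and each code equals the
#' ideal [adc_output()] of that cell's own pressure, bit for bit. With the
#' scheme off, unselected channels float and sneak paths through neighbouring
#' row/column nodes perturb the reading; the perturbation is computed by
#' exact nodal analysis of the resistive network.
#'
#' @param pressure_grid 8x8 non-negative matrix of pressures (kPa).
#' @param char,cfg Sensor and circuit parameters.
#' @param crosstalk_elimination Logical; apply the elimination drive scheme.
#' @param r_open Finite resistance (ohm) of an unloaded cell, standing in
#'   for the open circuit so the nodal solver stays well posed; the 1 Mohm
#'   default is typical of an unloaded piezoresistive film and is what lets
#'   sneak currents flow when the elimination scheme is off.
#' @return 8x8 integer matrix of ADC counts.
#' @export
simulate_scan <- function(pressure_grid, char = sensor_char(),
                          cfg = circuit_config(),
                          crosstalk_elimination = TRUE, r_open = 1e6) {
  if (!is.matrix(pressure_grid) || !all(dim(pressure_grid) == c(8L, 8L)))
    stop("pressure_grid must be an 8x8 matrix")
  if (any(!is.finite(pressure_grid)) || any(pressure_grid < 0))
    stop("pressure_grid entries must be finite and non-negative")
  if (crosstalk_elimination) {
    counts <- adc_output(as.vector(pressure_grid), char, cfg)
    return(matrix(counts, 8L, 8L))
  }
  R <- char$k_pr / pressure_grid
  R[!is.finite(R) | R > r_open] <- r_open
  out <- matrix(0L, 8L, 8L)
  for (r in 1:8) for (c in 1:8) {
    out[r, c] <- adc_from_resistance(scan_effective_resistance(R, r, c), cfg)
  }
  out
}

#' Convert a mass load to pressure on one sensor cell
#'
#' @param kg Mass in kilograms.
#' @param cell_area Sensing area of one cell in m^2 (default 2.5 cm^2).
#' @return Pressure in kPa.
#' @export
kg_to_kpa <- function(kg, cell_area = 2.5e-4) {
  kg * 9.80665 / cell_area / 1000
}

#' Least-squares calibration of one sensor cell
#'
#' Ordinary least-squares fit of ADC counts on applied load, as used when
#' each cell is loaded with standard weights stepped 0 to 11 kg and back.
#' Both passes of such a protocol are fitted as one line.
#'
#' @param loads Applied loads (kg), length >= 2 with at least two distinct
#'   values.
#' @param counts ADC counts observed at each load.
#' @return A `calibration_line`: `slope` (counts/kg), `intercept` (counts),
#'   `r_squared`. A perfect fit through constant counts reports r^2 = 1.
#' @export
calibrate_cell <- function(loads, counts) {
  if (length(loads) != length(counts) || length(loads) < 2L)
    stop("loads and counts must be equal-length sequences of length >= 2")
  if (length(unique(loads)) < 2L)
    stop("degenerate calibration: all load values identical")
  x <- as.numeric(loads); y <- as.numeric(counts)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= 0) 1 else max(0, min(1, 1 - rss / tss))
  structure(list(slope = slope, intercept = intercept, r_squared = r2),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Sensor calibration: counts = %.4f * load(kg) + %.4f  (r^2 = %.6f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
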