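# The reduced splanchnic circuit: a 12 V aortic source drives two parallel
# arterial branches — the celiac artery (CA) with a series stenosis
# potentiometer, and the pancreaticoduodenal (PDA) block, a fixed PDA
# resistor in parallel with an aneurysm/collateral potentiometer — feeding a
# common pancreas+liver load to ground.
#
# Topology (node A = aorta, node B = common distal bed):
#   src(+) -> A
#   A --[stenosis pot]--[3.3k CA]--> B            (CA flow)
#   A --[3.3k PDA  ||  aneurysm pot]--> B         (PDA flow = block total)
#   B --[12k pancreas+liver]--> ground = src(-)
#
# "PDA flow" is the total current entering the block (resistor + aneurysm
# path): at the normal state this reads 0.455 mA, whereas the PDA resistor
# alone would read 0.427 mA.

#' Parameters of the reduced splanchnic circuit
#'
#' Defaults are the study's component values: a 12 V source (120 mmHg on the
#' analog scale), 3.3 kOhm for each of the CA and PDA (two vessel segments of
#' ~1.3 kOhm, rounded up to the nearest stock resistor), a 12 kOhm
#' pancreas+liver load, and 0-50 kOhm potentiometers for the stenosis and the
#' aneurysm.
#'
#' @param source_voltage Source voltage in volts, > 0.
#' @param r_ca,r_pda CA and PDA branch resistances in ohms, > 0.
#' @param r_pancreas_liver Common load resistance in ohms, > 0.
#' @param pot_min,pot_max Potentiometer travel in ohms, `0 <= pot_min <= pot_max`.
#' @return An object of class `splanchnic_params`.
#' @export
splanchnic_params <- function(source_voltage = 12,
                              r_ca = 3300, r_pda = 3300,
                              r_pancreas_liver = 12000,
                              pot_min = 0, pot_max = 50000) {
  vals <- c(source_voltage, r_ca, r_pda, r_pancreas_liver, pot_max)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("source_voltage, resistances and pot_max must all be > 0", call. = FALSE)
  if (!is.finite(pot_min) || pot_min < 0 || pot_min > pot_max)
    stop("need 0 <= pot_min <= pot_max", call. = FALSE)
  structure(list(source_voltage = source_voltage, r_ca = r_ca, r_pda = r_pda,
                 r_pancreas_liver = r_pancreas_liver,
                 pot_min = pot_min, pot_max = pot_max),
            class = "splanchnic_params")
}

#' @export
print.splanchnic_params <- function(x, ...) {
  cat("<splanchnic_params> ", x$source_voltage, " V source; CA ", x$r_ca,
      " ohm; PDA ", x$r_pda, " ohm; pancreas+liver ", x$r_pancreas_liver,
      " ohm; pots [", x$pot_min, ", ", x$pot_max, "] ohm\n", sep = "")
  invisible(x)
}

#' Potentiometer state of the reduced circuit
#'
#' @param r_stenosis Stenosis (series, CA) potentiometer value in ohms.
#' @param r_aneurysm Aneurysm (parallel, PDA) potentiometer value in ohms.
#' @param params A [splanchnic_params()] whose potentiometer range bounds the
#'   values.
#' @return An object of class `model_state`.
#' @export
model_state <- function(r_stenosis, r_aneurysm, params = splanchnic_params()) {
  stopifnot(inherits(params, "splanchnic_params"))
  for (v in c(r_stenosis = r_stenosis, r_aneurysm = r_aneurysm))
    if (!is.finite(v) || v < params$pot_min || v > params$pot_max)
      stop("potentiometer value ", v, " outside [", params$pot_min, ", ",
           params$pot_max, "] ohm", call. = FALSE)
  structure(list(r_stenosis = r_stenosis, r_aneurysm = r_aneurysm),
            class = "model_state")
}

#' Build the reduced splanchnic circuit
#'
#' Assembles the two-branch current-divider circuit described above as a
#' [circuit()]: stenosis potentiometer in series with the CA resistor on one
#' branch, the PDA resistor in parallel with the aneurysm potentiometer on
#' the other, a common pancreas+liver load to ground. CA flow is the current
#' through the `"ca"` element; PDA flow is the total current entering the PDA
#' block, available as the current through the `"load"` element minus the CA
#' current, or directly via [steady_flows()].
#'
#' @param params A [splanchnic_params()].
#' @param state A [model_state()] (or a 2-element numeric
#'   `c(r_stenosis, r_aneurysm)`).
#' @return A [circuit()] with elements `src`, `pot_stenosis`, `ca`, `pda`,
#'   `pot_aneurysm`, `load`; nodes `aorta`, `ca_mid`, `bed`, `gnd`.
#' @export
build_reduced_circuit <- function(params = splanchnic_params(),
                                  state = model_state(0, params$pot_max, params)) {
  stopifnot(inherits(params, "splanchnic_params"))
  if (is.numeric(state) && length(state) == 2L)
    state <- model_state(state[1], state[2], params)
  stopifnot(inherits(state, "model_state"))
  model_state(state$r_stenosis, state$r_aneurysm, params)  # range re-check
  circuit(list(
    voltage_source("src", "aorta", "gnd", params$source_voltage),
    potentiometer("pot_stenosis", "aorta", "ca_mid", state$r_stenosis,
                  params$pot_min, params$pot_max),
    resistor("ca", "ca_mid", "bed", params$r_ca),
    resistor("pda", "aorta", "bed", params$r_pda),
    potentiometer("pot_aneurysm", "aorta", "bed", state$r_aneurysm,
                  params$pot_min, params$pot_max),
    resistor("load", "bed", "gnd", params$r_pancreas_liver)
  ), ground = "gnd")
}

#' Closed-form steady CA and PDA flows
#'
#' Series/parallel reduction of the reduced circuit, used both as the fast
#' evaluation path for scenario sweeps and as the analytic oracle against the
#' nodal solver:
#' `R_block = r_pda * r_a / (r_pda + r_a)` (0 when the aneurysm pot is 0),
#' `R_ca = r_ca + r_s`, total current `V / (r_load + R_ca || R_block)`, split
#' by the current divider. Currents are unsigned magnitudes, matching the
#' flow-tracing measurands.
#'
#' @param params A [splanchnic_params()].
#' @param state A [model_state()] or `c(r_stenosis, r_aneurysm)`.
#' @return An object of class `flow_pair`: list with `i_ca`, `i_pda`,
#'   `i_total` in milliamperes (`i_ca + i_pda == i_total`).
#' @examples
#' steady_flows(state = c(0, 50000))       # normal: 0.427 / 0.455 mA
#' steady_flows(state = c(50000, 0))       # full steal: 0.000 / 1.000 mA
#' @export
steady_flows <- function(params = splanchnic_params(),
                         state = model_state(0, params$pot_max, params)) {
  stopifnot(inherits(params, "splanchnic_params"))
  if (is.numeric(state) && length(state) == 2L)
    state <- model_state(state[1], state[2], params)
  r_s <- state$r_stenosis; r_a <- state$r_aneurysm
  model_state(r_s, r_a, params)
  r_block <- if (r_a == 0) 0 else params$r_pda * r_a / (params$r_pda + r_a)
  r_ca <- params$r_ca + r_s
  r_par <- if (r_block == 0) 0 else r_ca * r_block / (r_ca + r_block)
  i_total <- params$source_voltage / (params$r_pancreas_liver + r_par) * 1000
  i_ca <- if (r_block == 0) 0 else i_total * r_block / (r_ca + r_block)
  structure(list(i_ca = i_ca, i_pda = i_total - i_ca, i_total = i_total),
            class = "flow_pair")
}

#' @export
print.flow_pair <- function(x, ...) {
  cat(sprintf("<flow_pair> CA %.3f mA (%d mL/min) | PDA %.3f mA (%d mL/min) | total %.3f mA\n",
              x$i_ca, round(x$i_ca * 1000), x$i_pda, round(x$i_pda * 1000),
              x$i_total))
  invisible(x)
}

#' CA and PDA flows from the nodal solver
#'
#' Solves [build_reduced_circuit()] with [solve_dc()] and extracts the same
#' `flow_pair` as [steady_flows()]: CA flow from the CA branch, PDA flow as
#' the load current minus the CA current (total current entering the PDA
#' block). The two routes agree to solver precision and are cross-checked in
#' the test suite.
#'
#' @inheritParams steady_flows
#' @return A `flow_pair`.
#' @export
solved_flows <- function(params = splanchnic_params(),
                         state = model_state(0, params$pot_max, params)) {
  sol <- solve_dc(build_reduced_circuit(params, state))
  i_total <- abs(branch_current(sol, "load"))
  i_ca <- abs(branch_current(sol, "ca"))
  structure(list(i_ca = i_ca, i_pda = i_total - i_ca, i_total = i_total),
            class = "flow_pair")
}

#' Component-value derivation from physiological inputs
#'
#' Reproduces the arithmetic that sizes the circuit: each arterial segment is
#' taken as `r_vessel_unit` (1.3 kOhm, i.e. 1.3 mmHg min/L on the analog
#' scale), two segments in series make the ideal CA/PDA value, rounded up to
#' the nearest stock resistor; the voltage drop across the (paralleled)
#' CA/PDA pair at the portal flow then fixes the pancreas+liver load as the
#' remainder of the source voltage over the portal current.
#'
#' @param portal_flow Portal flow in L/min (default 0.86).
#' @param source_voltage Source voltage in volts (default 12, i.e. 120 mmHg).
#' @param r_vessel_unit Single-segment resistance in ohms (default 1300).
#' @param r_stock Stock resistor chosen for CA and PDA in ohms (default 3300).
#' @param f A [conversion_factors()] object.
#' @return List with `r_ca_pda_ideal` (ohms), `r_ca_pda` (ohms),
#'   `v_drop_ca_pda` (volts), `r_pancreas_liver` (ohms), and
#'   `portal_resistance` for a 10 mmHg portal gradient (ohms).
#' @export
derive_parameters <- function(portal_flow = 0.86, source_voltage = 12,
                              r_vessel_unit = 1300, r_stock = 3300,
                              f = conversion_factors()) {
  i_portal_mA <- flow_to_current(portal_flow, f)
  v_drop <- (r_stock / 2) * i_portal_mA * 1e-3
  list(r_ca_pda_ideal = 2 * r_vessel_unit,
       r_ca_pda = r_stock,
       v_drop_ca_pda = v_drop,
       r_pancreas_liver = (source_voltage - v_drop) / (i_portal_mA * 1e-3),
       portal_resistance = hemo_resistance_to_ohms(10, portal_flow, f))
}

# ---- full splanchnic network ------------------------------------------------

#' Edge template of the full splanchnic network
#'
#' The schematic splanchnic graph before reduction: the aorta feeds the
#' celiac (CA), superior mesenteric (SMA) and inferior mesenteric (IMA)
#' trunks; the pancreaticoduodenal arcade (PDA) bridges the celiac and SMA
#' territories and the arc of Riolan (AoR) the SMA and IMA territories; all
#' beds drain through the splenic (SV), superior mesenteric (SMV) and
#' inferior mesenteric (IMV) veins into the portal vein (PV) and the liver,
#' except the proper hepatic artery (PHA) which reaches the liver directly;
#' the hepatic vein (HV) returns to the inferior vena cava. No physiological
#' resistance values are shipped — every edge must be priced by the user.
#'
#' @return A data.frame with columns `name`, `from`, `to` (11 edges).
#' @export
splanchnic_edges <- function() {
  data.frame(
    name = c("CA", "SMA", "IMA", "PDA", "AoR", "PHA",
             "SV", "SMV", "IMV", "PV", "HV"),
    from = c("aorta", "aorta", "aorta", "sma", "ima", "celiac",
             "celiac", "sma", "ima", "portal", "liver"),
    to = c("celiac", "sma", "ima", "celiac", "sma", "liver",
           "portal", "portal", "portal", "liver", "ivc"),
    stringsAsFactors = FALSE)
}

#' Build the full splanchnic network from a resistance table
#'
#' @param resistance_table Named numeric vector (or list) giving a positive
#'   resistance in ohms for every edge of [splanchnic_edges()].
#' @param source_voltage Aorta-to-IVC source voltage in volts.
#' @return A [circuit()] over the full splanchnic graph with a `src` source
#'   from `aorta` to the grounded `ivc` node.
#' @examples
#' edges <- splanchnic_edges()
#' tab <- stats::setNames(rep(1000, nrow(edges)), edges$name)
#' ckt <- build_full_network(tab)
#' equivalent_resistance(ckt, "aorta", "ivc")
#' @export
build_full_network <- function(resistance_table, source_voltage = 12) {
  edges <- splanchnic_edges()
  resistance_table <- unlist(resistance_table)
  missing <- setdiff(edges$name, names(resistance_table))
  if (length(missing))
    stop("resistance_table is missing edges: ",
         paste(missing, collapse = ", "), call. = FALSE)
  vals <- resistance_table[edges$name]
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all edge resistances must be finite and > 0 ohm", call. = FALSE)
  els <- c(
    list(voltage_source("src", "aorta", "ivc", source_voltage)),
    lapply(seq_len(nrow(edges)), function(i)
      resistor(edges$name[i], edges$from[i], edges$to[i], vals[[i]])))
  circuit(els, ground = "ivc")
}

# ---- config loading ---------------------------------------------------------

#' Read parameters and state from a JSON config file
#'
#' The document may contain a `parameters` object (fields as in
#' [splanchnic_params()]), a `state` object (fields as in [model_state()]),
#' or both; absent fields fall back to the defaults.
#'
#' @param path Path to a JSON file.
#' @return List with `params` ([splanchnic_params()]) and `state`
#'   ([model_state()] or `NULL` when the file has no state).
#' @export
read_model_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  params <- do.call(splanchnic_params, as.list(doc$parameters))
  state <- NULL
  if (!is.null(doc$state))
    state <- model_state(doc$state$r_stenosis, doc$state$r_aneurysm, params)
  list(params = params, state = state)
}
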