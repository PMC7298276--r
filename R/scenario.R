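# Quasi-static scenario simulation: the circuit has no reactive elements, so
# each instant is an independent steady-state solve and a time course is just
# a sweep of the two potentiometer signals. The two built-in 7 s scenarios
# are the stenosis-first and aneurysm-first disease timelines; each
# manipulation is a linear 1 s ramp.

ZONE_LABELS <- c("normal", "stenosis_only", "aneurysm_only",
                 "preop", "postop", "transition")

#' Piecewise-linear resistance signal
#'
#' A signal defined by breakpoints `(time, resistance)`: linear interpolation
#' between breakpoints, constant extrapolation beyond the first and last.
#'
#' @param times Breakpoint times in seconds, strictly increasing.
#' @param resistances Resistance at each breakpoint, in ohms, >= 0.
#' @return An object of class `pw_signal`.
#' @export
pw_signal <- function(times, resistances) {
  stopifnot(is.numeric(times), is.numeric(resistances),
            length(times) == length(resistances), length(times) >= 1L)
  if (any(diff(times) <= 0))
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(resistances)) || any(resistances < 0))
    stop("resistances must be finite and >= 0 ohm", call. = FALSE)
  structure(list(times = as.numeric(times),
                 resistances = as.numeric(resistances)),
            class = "pw_signal")
}

#' Evaluate a piecewise-linear signal
#'
#' @param signal A [pw_signal()].
#' @param t Times in seconds (vectorised).
#' @return Resistance in ohms at each `t`.
#' @export
eval_signal <- function(signal, t) {
  stopifnot(inherits(signal, "pw_signal"))
  if (length(signal$times) == 1L) return(rep(signal$resistances, length(t)))
  stats::approx(signal$times, signal$resistances, xout = t, rule = 2)$y
}

#' Define a scenario
#'
#' A scenario couples the two potentiometer signals with a zone partition of
#' the timeline. Zones are half-open intervals `[start, end)` (the final
#' sample belongs to the last zone), must tile `[0, duration]` without
#' overlap, and carry one of the labels `normal`, `stenosis_only`,
#' `aneurysm_only`, `preop`, `postop`, `transition`.
#'
#' @param name Scenario name.
#' @param duration Total duration in seconds, > 0.
#' @param stenosis_signal,aneurysm_signal [pw_signal()]s for the stenosis and
#'   aneurysm potentiometers.
#' @param zones data.frame with columns `start`, `end`, `label`.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, duration, stenosis_signal, aneurysm_signal, zones) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(stenosis_signal, "pw_signal"),
            inherits(aneurysm_signal, "pw_signal"),
            is.data.frame(zones),
            all(c("start", "end", "label") %in% names(zones)))
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0 s", call. = FALSE)
  zones <- zones[order(zones$start), c("start", "end", "label")]
  if (!all(zones$label %in% ZONE_LABELS))
    stop("unknown zone labels: ",
         paste(setdiff(zones$label, ZONE_LABELS), collapse = ", "), call. = FALSE)
  ok <- isTRUE(all.equal(zones$start[1], 0)) &&
    isTRUE(all.equal(zones$end[nrow(zones)], duration)) &&
    (nrow(zones) == 1L ||
       isTRUE(all.equal(zones$end[-nrow(zones)], zones$start[-1])))
  if (!ok)
    stop("zones must tile [0, duration] without gaps or overlap", call. = FALSE)
  structure(list(name = name, duration = duration,
                 stenosis_signal = stenosis_signal,
                 aneurysm_signal = aneurysm_signal, zones = zones),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> '", x$name, "', ", x$duration, " s, ",
      nrow(x$zones), " zones\n", sep = "")
  print(x$zones, row.names = FALSE)
  invisible(x)
}

#' Built-in stenosis-first and aneurysm-first scenarios
#'
#' Both 7 s timelines start at the normal state (stenosis pot 0 ohm, aneurysm
#' pot 50 kOhm) and end at the postoperative state (50 kOhm, 50 kOhm); every
#' manipulation is a linear 1 s ramp and every hold lasts 1 s.
#'
#' Scenario 1 (stenosis first): hold normal; ramp stenosis 0 -> 50 k;
#' hold stenosis-only; ramp aneurysm 50 k -> 0; hold preop (full steal);
#' ramp aneurysm 0 -> 50 k (aneurysm correction); hold postop.
#'
#' Scenario 2 (aneurysm first): hold normal; ramp aneurysm 50 k -> 0;
#' hold aneurysm-only; ramp stenosis 0 -> 50 k; hold preop;
#' ramp aneurysm 0 -> 50 k; hold postop.
#'
#' @param which 1 (stenosis-first) or 2 (aneurysm-first).
#' @param params A [splanchnic_params()] supplying the potentiometer range.
#' @return A [scenario()].
#' @export
builtin_scenario <- function(which, params = splanchnic_params()) {
  if (!(length(which) == 1L && which %in% c(1, 2)))
    stop("'which' must be 1 or 2", call. = FALSE)
  lo <- params$pot_min; hi <- params$pot_max
  if (which == 1) {
    sten <- pw_signal(c(0, 1, 2), c(lo, lo, hi))
    aneu <- pw_signal(c(0, 3, 4, 5, 6), c(hi, hi, lo, lo, hi))
    mid <- "stenosis_only"
    name <- "stenosis-first"
  } else {
    sten <- pw_signal(c(0, 3, 4), c(lo, lo, hi))
    aneu <- pw_signal(c(0, 1, 2, 5, 6), c(hi, hi, lo, lo, hi))
    mid <- "aneurysm_only"
    name <- "aneurysm-first"
  }
  zones <- data.frame(
    start = 0:6, end = 1:7,
    label = c("normal", "transition", mid, "transition", "preop",
              "transition", "postop"),
    stringsAsFactors = FALSE)
  scenario(name, 7, sten, aneu, zones)
}

zone_label_at <- function(zones, t, duration) {
  lab <- character(length(t))
  for (i in seq_len(nrow(zones)))
    lab[t >= zones$start[i] & t < zones$end[i]] <- zones$label[i]
  lab[t >= duration - 1e-12] <- zones$label[nrow(zones)]
  lab
}

# vectorised closed-form divider currents (mA)
divider_currents <- function(params, r_s, r_a) {
  r_block <- ifelse(r_a == 0, 0, params$r_pda * r_a / (params$r_pda + r_a))
  r_ca <- params$r_ca + r_s
  r_par <- ifelse(r_block == 0, 0, r_ca * r_block / (r_ca + r_block))
  i_total <- params$source_voltage / (params$r_pancreas_liver + r_par) * 1000
  i_ca <- ifelse(r_block == 0, 0, i_total * r_block / (r_ca + r_block))
  list(i_ca = i_ca, i_pda = i_total - i_ca, i_total = i_total)
}

#' Run a scenario as a quasi-static sweep
#'
#' Samples both potentiometer signals on a uniform grid and solves the
#' steady-state divider at every sample. The circuit is purely resistive, so
#' each sample is an exact steady state; `dt` only controls tracing
#' resolution, and hold-zone values are independent of it.
#'
#' @param scn A [scenario()].
#' @param params A [splanchnic_params()].
#' @param dt Sampling step in seconds, `0 < dt <= 0.1`. Default 0.001.
#' @return A `flow_trace`: data.frame with columns `time_s`,
#'   `r_stenosis_ohm`, `r_aneurysm_ohm`, `i_ca_mA`, `i_pda_mA`,
#'   `q_ca_mL_min`, `q_pda_mL_min`, `zone`.
#' @examples
#' tr <- run_scenario(builtin_scenario(1), dt = 0.01)
#' tr[tr$time_s == 0.5, ]  # normal zone: 0.427 / 0.455 mA
#' @export
run_scenario <- function(scn, params = splanchnic_params(), dt = 0.001) {
  stopifnot(inherits(scn, "scenario"), inherits(params, "splanchnic_params"))
  if (!is.finite(dt) || dt <= 0 || dt > 0.1)
    stop("dt must satisfy 0 < dt <= 0.1 s", call. = FALSE)
  t <- seq(0, scn$duration, by = dt)
  r_s <- eval_signal(scn$stenosis_signal, t)
  r_a <- eval_signal(scn$aneurysm_signal, t)
  cur <- divider_currents(params, r_s, r_a)
  trace <- data.frame(
    time_s = t, r_stenosis_ohm = r_s, r_aneurysm_ohm = r_a,
    i_ca_mA = cur$i_ca, i_pda_mA = cur$i_pda,
    q_ca_mL_min = current_to_flow(cur$i_ca) * 1000,
    q_pda_mL_min = current_to_flow(cur$i_pda) * 1000,
    zone = zone_label_at(scn$zones, t, scn$duration),
    stringsAsFactors = FALSE)
  structure(trace, class = c("flow_trace", "data.frame"),
            scenario_name = scn$name, dt = dt, params = params)
}

#' Run both built-in scenarios on one 14 s timeline
#'
#' Concatenates the stenosis-first trace with the aneurysm-first trace
#' offset by +7 s, mirroring the published timeline in which the two
#' chronologies are shown back to back.
#'
#' @param params A [splanchnic_params()].
#' @param dt Sampling step in seconds.
#' @return A `flow_trace` spanning 0-14 s.
#' @export
run_combined <- function(params = splanchnic_params(), dt = 0.001) {
  tr1 <- run_scenario(builtin_scenario(1, params), params, dt)
  tr2 <- run_scenario(builtin_scenario(2, params), params, dt)
  tr2$time_s <- tr2$time_s + 7
  out <- rbind(as.data.frame(tr1), as.data.frame(tr2))
  structure(out, class = c("flow_trace", "data.frame"),
            scenario_name = "combined", dt = dt, params = params)
}

#' Summarize a trace zone by zone
#'
#' Each zone is summarised at its midpoint sample (the nearest grid time to
#' `(start + end) / 2`); for hold zones this equals the analytic steady flow
#' at the zone's constant state. Two qualitative flags are derived:
#' `steal_flag` is `TRUE` when any non-transition zone has CA flow below
#' 0.0005 mA (i.e. 0.000 mA at reporting precision), and
#' `reconstitution_flag` is the result of [detect_reconstitution()].
#'
#' @param trace A `flow_trace` from [run_scenario()].
#' @param scn The [scenario()] the trace was generated from.
#' @return An object of class `scenario_summary`: list with `zones`
#'   (data.frame: `label`, `start`, `end`, `r_stenosis_ohm`,
#'   `r_aneurysm_ohm`, `i_ca_mA`, `i_pda_mA`, `q_ca_mL_min`,
#'   `q_pda_mL_min`), `steal_flag`, `reconstitution_flag` and the scenario
#'   name.
#' @export
summarize_scenario <- function(trace, scn) {
  stopifnot(inherits(trace, "flow_trace"), inherits(scn, "scenario"))
  if (!identical(attr(trace, "scenario_name"), scn$name))
    stop("trace was not generated from this scenario ('",
         attr(trace, "scenario_name"), "' vs '", scn$name, "')", call. = FALSE)
  if (max(trace$time_s) < scn$duration - 1e-9)
    stop("trace does not cover the scenario duration", call. = FALSE)
  rows <- lapply(seq_len(nrow(scn$zones)), function(i) {
    tm <- (scn$zones$start[i] + scn$zones$end[i]) / 2
    k <- which.min(abs(trace$time_s - tm))
    data.frame(label = scn$zones$label[i],
               start = scn$zones$start[i], end = scn$zones$end[i],
               r_stenosis_ohm = trace$r_stenosis_ohm[k],
               r_aneurysm_ohm = trace$r_aneurysm_ohm[k],
               i_ca_mA = trace$i_ca_mA[k], i_pda_mA = trace$i_pda_mA[k],
               q_ca_mL_min = trace$q_ca_mL_min[k],
               q_pda_mL_min = trace$q_pda_mL_min[k],
               stringsAsFactors = FALSE)
  })
  zones <- do.call(rbind, rows)
  hold <- zones[zones$label != "transition", ]
  out <- structure(list(name = scn$name, zones = zones,
                        steal_flag = any(hold$i_ca_mA < 0.0005)),
                   class = "scenario_summary")
  out$reconstitution_flag <- detect_reconstitution(out)
  out
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("<scenario_summary> '", x$name, "'\n", sep = "")
  z <- x$zones
  for (i in seq_len(nrow(z)))
    cat(sprintf("  [%4.1f, %4.1f) %-14s CA %6.3f mA (%4.0f mL/min)  PDA %6.3f mA (%4.0f mL/min)\n",
                z$start[i], z$end[i], z$label[i],
                z$i_ca_mA[i], round(z$q_ca_mL_min[i]),
                z$i_pda_mA[i], round(z$q_pda_mL_min[i])))
  cat("  steal: ", x$steal_flag,
      " | reconstitution: ", x$reconstitution_flag, "\n", sep = "")
  invisible(x)
}

summary_zone <- function(summary, label) {
  z <- summary$zones[summary$zones$label == label, , drop = FALSE]
  if (nrow(z) == 0L)
    stop("summary has no '", label, "' zone", call. = FALSE)
  z[1L, ]
}

#' Detect postoperative reconstitution of the celiac flow
#'
#' Reconstitution is the clinical hallmark of the modelled case: after
#' ablation of the aneurysm/collateral path (with the stenosis left in situ)
#' the previously collapsed CA flow reappears — small, but not zero, and
#' below its normal value. Testably: preoperative CA flow <= 0.0005 mA,
#' postoperative CA flow > 0.0005 mA, and postoperative CA flow below the
#' normal-zone value.
#'
#' @param summary A `scenario_summary` containing `normal`, `preop` and
#'   `postop` zones.
#' @return `TRUE` or `FALSE`.
#' @export
detect_reconstitution <- function(summary) {
  stopifnot(inherits(summary, "scenario_summary"))
  labs <- summary$zones$label
  if (!all(c("preop", "postop") %in% labs)) return(FALSE)
  pre <- summary_zone(summary, "preop")
  post <- summary_zone(summary, "postop")
  nrm <- if ("normal" %in% labs) summary_zone(summary, "normal") else NULL
  post$i_ca_mA > 0.0005 && pre$i_ca_mA <= 0.0005 &&
    (is.null(nrm) || post$i_ca_mA < nrm$i_ca_mA)
}

#' Are two scenarios clinically equivalent?
#'
#' The bidirectional-causality claim, stated testably: the normal,
#' preoperative and postoperative steady flows are the same whichever
#' condition developed first — steady flows are functions of the
#' potentiometer state alone, not of the path taken to reach it.
#'
#' @param s1,s2 `scenario_summary` objects, each with `normal`, `preop` and
#'   `postop` zones.
#' @param tol Agreement tolerance in milliamperes.
#' @return `TRUE` iff CA and PDA flows agree in all three labelled zones.
#' @export
scenario_equivalence <- function(s1, s2, tol = 1e-6) {
  stopifnot(inherits(s1, "scenario_summary"), inherits(s2, "scenario_summary"))
  for (lab in c("normal", "preop", "postop")) {
    z1 <- summary_zone(s1, lab)
    z2 <- summary_zone(s2, lab)
    if (abs(z1$i_ca_mA - z2$i_ca_mA) >= tol ||
        abs(z1$i_pda_mA - z2$i_pda_mA) >= tol) return(FALSE)
  }
  TRUE
}

#' Qualitative LED-brightness class of a flow
#'
#' On the breadboard realisation each flow drives an LED, and the clinical
#' states are read off as brightness classes. Classification is by the ratio
#' to the normal-state current: `off` below 0.02, `dim` below 0.5, `normal`
#' up to 1.1, `bright` above. The thresholds are presentation heuristics of
#' this package, not measured LED characteristics.
#'
#' @param i Current magnitude in milliamperes, >= 0.
#' @param i_normal Normal-state current in milliamperes, > 0.
#' @return One of `"off"`, `"dim"`, `"normal"`, `"bright"` (vectorised over
#'   `i`).
#' @examples
#' classify_brightness(0.760, 0.455)  # "bright"
#' @export
classify_brightness <- function(i, i_normal) {
  if (!is.finite(i_normal) || i_normal <= 0)
    stop("i_normal must be > 0 mA", call. = FALSE)
  if (any(!is.finite(i)) || any(i < 0))
    stop("current magnitude must be finite and >= 0 mA", call. = FALSE)
  r <- i / i_normal
  ifelse(r < 0.02, "off",
         ifelse(r < 0.5, "dim",
                ifelse(r <= 1.1, "normal", "bright")))
}

# ---- scenario serialization -------------------------------------------------

#' Write a scenario to JSON
#'
#' @param scn A [scenario()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when writing to a file).
#' @export
scenario_to_json <- function(scn, path = NULL) {
  stopifnot(inherits(scn, "scenario"))
  doc <- list(
    name = scn$name, duration = scn$duration,
    stenosis_signal = list(times = scn$stenosis_signal$times,
                           resistances = scn$stenosis_signal$resistances),
    aneurysm_signal = list(times = scn$aneurysm_signal$times,
                           resistances = scn$aneurysm_signal$resistances),
    zones = scn$zones)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                          dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' Read a scenario from JSON
#'
#' @param path_or_text File path or JSON string from [scenario_to_json()].
#' @return A [scenario()].
#' @export
scenario_from_json <- function(path_or_text) {
  doc <- jsonlite::fromJSON(path_or_text, simplifyVector = TRUE)
  scenario(doc$name, doc$duration,
           pw_signal(doc$stenosis_signal$times, doc$stenosis_signal$resistances),
           pw_signal(doc$aneurysm_signal$times, doc$aneurysm_signal$resistances),
           as.data.frame(doc$zones))
}

#' Plot a flow trace
#'
#' Four stacked panels mirroring the flow-monitor layout: the two
#' potentiometer resistances and the two flows against time.
#'
#' @param x A `flow_trace`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.flow_trace <- function(x, ...) {
  old <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4.5, 1, 1))
  on.exit(graphics::par(old))
  panels <- list(
    list(y = x$r_stenosis_ohm / 1000, ylab = "stenosis pot (kOhm)"),
    list(y = x$r_aneurysm_ohm / 1000, ylab = "aneurysm pot (kOhm)"),
    list(y = x$i_ca_mA, ylab = "CA flow (mA)"),
    list(y = x$i_pda_mA, ylab = "PDA flow (mA)"))
  for (p in panels)
    graphics::plot(x$time_s, p$y, type = "l", xlab = "", ylab = p$ylab)
  invisible(x)
}
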