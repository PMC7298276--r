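test_that("piecewise-linear signals interpolate and clamp correctly", {
  s <- pw_signal(c(1, 2), c(0, 50000))
  expect_equal(eval_signal(s, c(0, 1, 1.5, 2, 10)),
               c(0, 0, 25000, 50000, 50000))
  expect_equal(eval_signal(pw_signal(3, 700), c(0, 5)), c(700, 700))
  expect_error(pw_signal(c(1, 1), c(0, 0)), "strictly increasing")
  expect_error(pw_signal(1, -5), ">= 0")
})

test_that("built-in scenarios hold the documented states in each zone", {
  s1 <- builtin_scenario(1)
  s2 <- builtin_scenario(2)
  state_at <- function(s, t) c(eval_signal(s$stenosis_signal, t),
                               eval_signal(s$aneurysm_signal, t))
  # both chronologies start at the normal state (0 ohm, 50 kOhm)
  expect_equal(state_at(s1, 0.5), c(0, 50000))
  expect_equal(state_at(s2, 0.5), c(0, 50000))
  # scenario 1 preop hold: severe stenosis with full-blown aneurysm
  expect_equal(state_at(s1, 4.5), c(50000, 0))
  # scenario 2 mid hold: aneurysm without stenosis (t = 9.5 on the combined axis)
  expect_equal(state_at(s2, 2.5), c(0, 0))
  # both end at the postoperative state
  expect_equal(state_at(s1, 6.5), c(50000, 50000))
  expect_equal(state_at(s2, 6.5), c(50000, 50000))
  expect_equal(s1$zones$label[s1$zones$start == 2], "stenosis_only")
  expect_equal(s2$zones$label[s2$zones$start == 2], "aneurysm_only")
  expect_error(builtin_scenario(3), "1 or 2")
})

test_that("traces carry the expected flows at hold and ramp samples", {
  tr <- run_scenario(builtin_scenario(1), dt = 0.01)
  at <- function(t) tr[which.min(abs(tr$time_s - t)), ]
  expect_equal(round(at(0.5)$i_ca_mA, 3), 0.427)
  expect_equal(round(at(6.5)$i_ca_mA, 3), 0.044)  # reconstitution, not zero
  expect_equal(at(6.5)$q_ca_mL_min, at(6.5)$i_ca_mA * 1000)
  # ramp midpoint t = 1.5 s: (25 kOhm, 50 kOhm) by independent hand reduction
  mid <- at(1.5)
  expect_equal(mid$r_stenosis_ohm, 25000)
  expect_equal(mid$i_ca_mA, unname(hand_flows(25000, 50000)["i_ca"]),
               tolerance = 1e-12)
  expect_equal(round(mid$i_ca_mA, 4), 0.0800)
  # conservation: the two branches carry the whole load current at every sample
  tot_ref <- vapply(seq_len(nrow(tr)), function(k)
    unname(hand_flows(tr$r_stenosis_ohm[k], tr$r_aneurysm_ohm[k])["i_total"]),
    numeric(1))
  expect_lt(max(abs(tr$i_ca_mA + tr$i_pda_mA - tot_ref)), 1e-9)
  expect_error(run_scenario(builtin_scenario(1), dt = 0), "dt")
  expect_error(run_scenario(builtin_scenario(1), dt = 0.5), "dt")
})

test_that("CA and PDA tracings are mirror images on every ramp", {
  for (which in 1:2) {
    tr <- run_scenario(builtin_scenario(which), dt = 0.01)
    d_ca <- diff(tr$i_ca_mA)
    d_pda <- diff(tr$i_pda_mA)
    moving <- abs(d_ca) > 1e-12
    expect_true(any(moving))
    expect_true(all(sign(d_ca[moving]) == -sign(d_pda[moving])))
  }
})

test_that("hold-zone flows are steady and independent of the path taken", {
  s1 <- builtin_scenario(1); s2 <- builtin_scenario(2)
  tr1 <- run_scenario(s1, dt = 0.005); tr2 <- run_scenario(s2, dt = 0.005)
  for (tr in list(tr1, tr2)) {
    scn <- if (identical(attr(tr, "scenario_name"), s1$name)) s1 else s2
    for (i in which(scn$zones$label != "transition")) {
      idx <- tr$time_s >= scn$zones$start[i] & tr$time_s < scn$zones$end[i]
      mid_state <- c(tr$r_stenosis_ohm[idx][1], tr$r_aneurysm_ohm[idx][1])
      ref <- steady_flows(state = mid_state)$i_ca
      expect_lt(max(abs(tr$i_ca_mA[idx] - ref)), 1e-9)
    }
  }
  # preop state reached stenosis-first or aneurysm-first gives identical flows
  sm1 <- summarize_scenario(tr1, s1); sm2 <- summarize_scenario(tr2, s2)
  pre1 <- sm1$zones[sm1$zones$label == "preop", ]
  pre2 <- sm2$zones[sm2$zones$label == "preop", ]
  expect_identical(pre1$i_ca_mA, pre2$i_ca_mA)
  expect_identical(pre1$i_pda_mA, pre2$i_pda_mA)
})

test_that("summaries match the analytic steady flows and refine under dt", {
  scn <- builtin_scenario(1)
  sm <- summarize_scenario(run_scenario(scn, dt = 0.001), scn)
  expect_equal(round(sm$zones$i_ca_mA[sm$zones$label == "preop"], 3), 0.000)
  expect_equal(round(sm$zones$i_pda_mA[sm$zones$label == "preop"], 3), 1.000)
  expect_equal(round(sm$zones$i_ca_mA[sm$zones$label == "postop"], 3), 0.044)
  expect_true(sm$steal_flag)
  expect_true(sm$reconstitution_flag)
  # halving dt changes no hold-zone summary value
  sm2 <- summarize_scenario(run_scenario(scn, dt = 0.0005), scn)
  hold <- sm$zones$label != "transition"
  expect_equal(sm2$zones$i_ca_mA[hold], sm$zones$i_ca_mA[hold],
               tolerance = 1e-12)
  expect_equal(sm2$zones$i_pda_mA[hold], sm$zones$i_pda_mA[hold],
               tolerance = 1e-12)
  # a trace from a different scenario is rejected
  expect_error(summarize_scenario(run_scenario(builtin_scenario(2), dt = 0.01),
                                  scn), "not generated")
})

test_that("scenario 2 postop shows the same reconstituted flows as scenario 1", {
  scn <- builtin_scenario(2)
  sm <- summarize_scenario(run_scenario(scn, dt = 0.001), scn)
  post <- sm$zones[sm$zones$label == "postop", ]
  expect_equal(round(post$i_ca_mA, 3), 0.044)
  expect_equal(round(post$i_pda_mA, 3), 0.760)
  expect_true(sm$reconstitution_flag)
})

test_that("the two chronologies are clinically equivalent; a different pot range is not", {
  summarize_builtin <- function(which, params = splanchnic_params()) {
    scn <- builtin_scenario(which, params)
    summarize_scenario(run_scenario(scn, params, dt = 0.001), scn)
  }
  sm1 <- summarize_builtin(1); sm2 <- summarize_builtin(2)
  expect_true(scenario_equivalence(sm1, sm2))
  expect_true(scenario_equivalence(sm1, sm1))  # reflexivity
  p25 <- splanchnic_params(pot_max = 25000)
  expect_false(scenario_equivalence(sm1, summarize_builtin(1, p25)))
})

test_that("reconstitution requires a collapsed preop CA that reappears below normal", {
  expect_true({
    scn <- builtin_scenario(1)
    summarize_scenario(run_scenario(scn, dt = 0.001), scn)$reconstitution_flag
  })
  # if the stenosis is also corrected postop, flows resume normal: no flag
  lo <- 0; hi <- 50000
  sten <- pw_signal(c(0, 1, 2, 5, 6), c(lo, lo, hi, hi, lo))
  aneu <- pw_signal(c(0, 3, 4, 5, 6), c(hi, hi, lo, lo, hi))
  zones <- data.frame(start = 0:6, end = 1:7,
                      label = c("normal", "transition", "stenosis_only",
                                "transition", "preop", "transition", "postop"))
  both_fixed <- scenario("both-corrected", 7, sten, aneu, zones)
  sm <- summarize_scenario(run_scenario(both_fixed, dt = 0.001), both_fixed)
  expect_equal(round(sm$zones$i_ca_mA[sm$zones$label == "postop"], 3), 0.427)
  expect_false(sm$reconstitution_flag)
  # an all-normal scenario has no steal and no reconstitution
  flat <- scenario("flat", 2, pw_signal(0, 0), pw_signal(0, 50000),
                   data.frame(start = 0, end = 2, label = "normal"))
  smf <- summarize_scenario(run_scenario(flat, dt = 0.01), flat)
  expect_equal(round(smf$zones$i_ca_mA, 3), 0.427)
  expect_false(smf$steal_flag)
  expect_false(smf$reconstitution_flag)
})

test_that("LED brightness classes reflect the flow ratio to normal", {
  expect_equal(classify_brightness(0.000, 0.427), "off")
  expect_equal(classify_brightness(0.044, 0.427), "dim")
  expect_equal(classify_brightness(0.427, 0.427), "normal")
  expect_equal(classify_brightness(0.760, 0.455), "bright")
  expect_equal(classify_brightness(c(0, 0.1, 0.42, 1), 0.427),
               c("off", "dim", "normal", "bright"))
  expect_error(classify_brightness(-0.1, 0.427), ">= 0")
  expect_error(classify_brightness(0.1, 0), "> 0")
})

test_that("the combined timeline offsets the aneurysm-first run by 7 s", {
  tr <- run_combined(dt = 0.01)
  expect_equal(max(tr$time_s), 14)
  at <- function(t) tr[which.min(abs(tr$time_s - t)), ][1, ]
  # 9-10 s window: aneurysm without stenosis
  expect_equal(at(9.5)$r_stenosis_ohm, 0)
  expect_equal(at(9.5)$r_aneurysm_ohm, 0)
  expect_equal(round(at(9.5)$i_ca_mA, 3), 0.000)
  expect_equal(at(9.5)$zone, "aneurysm_only")
  # matched zones on the two halves carry identical flows
  expect_equal(at(4.5)$i_ca_mA, at(11.5)$i_ca_mA)
  expect_equal(at(6.5)$i_pda_mA, at(13.5)$i_pda_mA)
})

test_that("scenarios round-trip through JSON", {
  scn <- builtin_scenario(2)
  back <- scenario_from_json(scenario_to_json(scn))
  expect_equal(back, scn)
  path <- withr::local_tempfile(fileext = ".json")
  scenario_to_json(scn, path)
  expect_equal(scenario_from_json(path), scn)
})

test_that("malformed zone partitions are rejected", {
  sig <- pw_signal(0, 0)
  good <- data.frame(start = c(0, 1), end = c(1, 2),
                     label = c("normal", "postop"))
  expect_s3_class(scenario("ok", 2, sig, sig, good), "scenario")
  gap <- data.frame(start = c(0, 1.5), end = c(1, 2),
                    label = c("normal", "postop"))
  expect_error(scenario("bad", 2, sig, sig, gap), "tile")
  expect_error(scenario("bad", 2, sig, sig,
                        data.frame(start = 0, end = 2, label = "weird")),
               "unknown zone label")
})
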