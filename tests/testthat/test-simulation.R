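test_that("the protocol has four contiguous phases with exact boundaries", {
  pr <- build_protocol(0.8, 0.3)
  expect_equal(nrow(pr), 4)
  expect_equal(attr(pr, "duration"), 20)
  expect_equal(pr$t_start, c(0, 5, 10, 15))
  expect_equal(pr$t_end, c(5, 10, 15, 20))
  expect_equal(pr$t_external, c(0.8, 0, 0, 0))
  expect_equal(pr$u_voluntary, c(0, 0, 0.3, 0))
  # all-rest protocol
  pr0 <- build_protocol(0, 0)
  expect_true(all(pr0$t_external == 0) && all(pr0$u_voluntary == 0))
})

test_that("zero gains and zero inputs hold the joint exactly at neutral", {
  p <- get_preset("wrist")
  e <- reflex_entry()
  res <- simulate_condition(p, reflex_config(e, e),
                            protocol = build_protocol(0, 0))
  expect_true(all(res$data$theta == 0))
  expect_true(all(res$data$omega == 0))
})

test_that("simulation is deterministic with an exact time grid", {
  p <- get_preset("wrist")
  prot <- build_protocol(0.2, 0.1, phase_dur = 1)
  r1 <- simulate_condition(p, protocol = prot)
  r2 <- simulate_condition(p, protocol = prot)
  expect_identical(r1$data, r2$data)
  dt <- r1$meta$dt
  expect_equal(r1$data$t, dt * (0:(nrow(r1$data) - 1)))
  expect_true(r1$meta$deterministic)
})

test_that("delayed feedback reads the pathway signal exactly tau in the past", {
  p <- get_preset("wrist")
  # flexor with a force pathway only (its recorded drive must then equal
  # k_f * force(t - tau_f) / f_max once t > tau_f, and the rest-history
  # value before that); the extensor keeps the reference pathways so the
  # joint stays stable under the torque and voluntary inputs
  ef <- reflex_entry(k_f = 0.8, tau_f = 0.03, tau_p = 0.03, tau_v = 0.03)
  cfg <- reflex_config(ef, p$reflex$extensor)
  res <- simulate_condition(p, cfg,
                            protocol = build_protocol(0.3, 0.2, phase_dur = 1))
  expect_false(res$meta$unstable)
  d <- res$data
  expect_gt(max(d$f_flex), 1)  # the flexor is loaded during the run
  dsteps <- as.integer(round(0.03 / res$meta$dt))
  k <- (dsteps + 1):nrow(d)
  expect_equal(d$u_reflex_flex[k],
               0.8 * d$f_flex[k - dsteps] / p$flexor$f_max, tolerance = 1e-12)
  rest_drive <- d$u_reflex_flex[1]
  expect_true(all(abs(d$u_reflex_flex[1:dsteps] - rest_drive) < 1e-9))
})

test_that("the reference run returns to neutral after each phase", {
  for (nm in c("wrist", "shoulder")) {
    ref <- get_battery(nm)$reference
    expect_false(ref$meta$unstable)
    expect_lt(abs(wmean(ref, 9.999, 10)), 0.01)
    expect_lt(abs(wmean(ref, 19.999, 20)), 0.01)
  }
})

test_that("halving the step changes the reference end state only marginally", {
  p <- get_preset("wrist")
  r1 <- get_battery("wrist")$reference
  r2 <- simulate_condition(p, settings = simulation_settings(dt = r1$meta$dt / 2))
  expect_lt(abs(r1$data$theta[nrow(r1$data)] - r2$data$theta[nrow(r2$data)]),
            1e-4)
})

test_that("the battery yields the reference plus nine labelled conditions", {
  bat <- get_battery("wrist")
  expect_length(bat, 10)
  labels <- as.vector(outer(c("increased_sensitivity", "imbalanced_sensitivity",
                              "imbalanced_offset"),
                            c("position", "velocity", "force"), paste, sep = "_"))
  expect_setequal(names(bat), c("reference", labels))
  for (lbl in names(bat)) expect_identical(bat[[lbl]]$meta$label, lbl)
})

test_that("unit sensitivity magnitude reproduces the reference trajectory", {
  p <- get_preset("wrist")
  prot <- build_protocol(p$protocol$t_force, p$protocol$u_voluntary,
                         phase_dur = 0.5)
  bat <- run_battery(p, magnitude_sens = 1, magnitude_offset = 1e-9,
                     protocol = prot)
  for (lbl in grep("sensitivity", names(bat), value = TRUE))
    expect_equal(bat[[lbl]]$data$theta, bat$reference$data$theta)
})

test_that("instability is flagged in metadata rather than thrown", {
  p <- get_preset("wrist")
  e <- reflex_entry(e_f = 1)  # saturating tonic drive on both muscles
  strong <- apply_scenario(p$reflex, scenario_spec("imbalanced_offset", "force", 5))
  res <- simulate_condition(p, strong,
                            settings = simulation_settings(theta_bound = 0.2))
  expect_true(res$meta$unstable)
  expect_true(anyNA(res$data$theta))
})

test_that("too coarse or incommensurate steps are rejected", {
  p <- get_preset("wrist")
  expect_error(simulate_condition(p, settings = simulation_settings(dt = 0.01)),
               "quarter")
  expect_error(simulate_condition(p, settings = simulation_settings(dt = 7e-4)),
               "integer multiples")
})
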