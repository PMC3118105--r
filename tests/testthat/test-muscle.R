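mp <- muscle_params(f_max = 150, l_ce_opt = 0.06, l_se_slack = 0.2,
                    tau_act = 0.04, tau_deact = 0.06, w_fl = 0.4)

test_that("activation dynamics follow first-order kinetics", {
  expect_equal(activation_rate(0.5, 0.5, mp), 0)
  expect_equal(activation_rate(1, 0, mp), 1 / 0.04)
  # deactivation uses the slower time constant
  expect_equal(activation_rate(0, 1, mp), -1 / 0.06)
  expect_error(activation_rate(1.2, 0, mp), "\\[0, 1\\]")

  # step response matches the closed-form exponential a(t) = 1 - exp(-t/tau)
  # (midpoint-rule integration at dt = 1e-5 so the discretization error sits
  # well below the 1e-6 comparison tolerance)
  dt <- 1e-5
  a <- 0
  for (i in seq_len(round(0.04 / dt))) {
    k1 <- activation_rate(1, a, mp)
    a <- a + dt * activation_rate(1, a + dt / 2 * k1, mp)
  }
  expect_equal(a, 1 - exp(-1), tolerance = 1e-6)
})

test_that("force-length is unimodal, symmetric and decays in the tails", {
  expect_equal(force_length(mp$l_ce_opt, mp), 1)
  expect_equal(force_length(mp$l_ce_opt * (1 - mp$w_fl), mp),
               force_length(mp$l_ce_opt * (1 + mp$w_fl), mp))
  expect_lt(force_length(1e-6, mp), 0.05)
  expect_lt(force_length(3 * mp$l_ce_opt, mp), 0.05)
  expect_true(all(force_length(seq(0.01, 0.2, by = 0.01), mp) >= 0))
})

test_that("force-velocity matches the Hill hyperbola and its inverse", {
  vm <- mp$v_max * mp$l_ce_opt
  expect_equal(force_velocity(0, mp), 1)
  expect_equal(force_velocity(-vm, mp), 0)
  # midpoint of the concentric branch, a_hill = 0.25:
  # (vm - vm/2) / (vm + (vm/2)/0.25) = 1/6
  expect_equal(force_velocity(-vm / 2, mp), 1 / 6)
  # monotone increasing
  v <- seq(-vm, vm, length.out = 200)
  expect_true(all(diff(force_velocity(v, mp)) > 0))
  # eccentric plateau bounds the factor
  expect_lt(force_velocity(100, mp), 1.3)
  # inverse recovers velocity across both branches
  for (phi in c(0.05, 0.3, 0.9, 1, 1.1, 1.25))
    expect_equal(force_velocity(crpsdystonia:::fv_inverse(phi, mp), mp), phi,
                 tolerance = 1e-10)
})

test_that("series-elastic element is slack below rest length", {
  expect_equal(se_force(mp$l_se_slack, mp), 0)
  expect_equal(se_force(0.9 * mp$l_se_slack, mp), 0)
  expect_equal(se_force(mp$l_se_slack * (1 + 0.04), mp), mp$f_max)
  l <- seq(0.19, 0.22, length.out = 50)
  expect_true(all(diff(se_force(l, mp)) >= 0))
})

test_that("muscle force is zero at slack and settles to f_max isometrically", {
  st <- muscle_state(a = 0, l_ce = mp$l_ce_opt)
  out <- muscle_force(st, mp, mp$l_ce_opt + mp$l_se_slack)
  expect_equal(out$force, 0)

  # full activation, musculotendon length chosen so the CE settles at its
  # optimum while the tendon carries f_max: integrate dl_ce/dt = v_ce
  l_mt <- mp$l_ce_opt + mp$l_se_slack * 1.04
  a <- 1; l_ce <- mp$l_ce_opt * 0.9; dt <- 1e-4
  for (i in seq_len(30000)) {
    out <- muscle_force(list(a = a, l_ce = l_ce), mp, l_mt)
    l_ce <- l_ce + dt * out$v_ce
  }
  expect_equal(out$force, mp$f_max, tolerance = 5e-3)
  expect_equal(l_ce, mp$l_ce_opt, tolerance = 1e-3)
})

test_that("muscle force is non-negative over random admissible states", {
  set.seed(101)
  forces <- vapply(seq_len(1000), function(i) {
    st <- list(a = runif(1), l_ce = runif(1, 0.4, 1.6) * mp$l_ce_opt)
    l_mt <- runif(1, 0.9, 1.1) * (mp$l_ce_opt + mp$l_se_slack)
    muscle_force(st, mp, l_mt)$force
  }, numeric(1))
  expect_gte(min(forces), 0)
})

test_that("joint acceleration balances muscle torques, damping and load", {
  jp <- joint_params(inertia = 0.005, b_passive = 0)
  expect_equal(joint_acceleration(0, 0, 0, 0, jp, 0.02), 0)
  expect_equal(joint_acceleration(0, 80, 80, 0, jp, 0.02), 0)  # co-contraction
  expect_equal(joint_acceleration(0, 100, 0, 0, jp, 0.02), 400)
  jp2 <- joint_params(inertia = 0.005, b_passive = 0.1)
  expect_equal(joint_acceleration(2, 0, 0, 0, jp2, 0.02), -0.1 * 2 / 0.005)
  expect_error(joint_acceleration(0, -1, 0, 0, jp, 0.02), ">= 0")
})

test_that("antagonist musculotendon length changes are equal and opposite", {
  p <- get_preset("wrist")
  th <- seq(-0.5, 0.5, by = 0.1)
  dflex <- musculotendon_length(th, p$flexor) - musculotendon_length(0, p$flexor)
  dext <- musculotendon_length(th, p$extensor) - musculotendon_length(0, p$extensor)
  expect_equal(dflex, -dext)
  # flexor lengthens as the joint extends
  expect_true(all(diff(musculotendon_length(th, p$flexor)) < 0))
})

test_that("a perturbed joint is passively bounded and reflexively restored", {
  p <- get_preset("wrist")
  pulse <- structure(
    data.frame(t_start = c(0, 0.2), t_end = c(0.2, 6),
               t_external = c(0.05, 0), u_voluntary = 0),
    class = c("input_protocol", "data.frame"), duration = 6)

  # passive pair (zero reflex gains): tone yields, so the deflection settles
  # at a finite angle without runaway -- neutral, not asymptotic, stability
  e <- reflex_entry()
  passive <- simulate_condition(p, reflex_config(e, e), protocol = pulse)
  expect_false(passive$meta$unstable)
  dp <- passive$data
  expect_lt(max(abs(dp$theta)), 0.5)
  expect_lt(abs(dp$omega[nrow(dp)]), 1e-3)

  # with the reference reflexes the joint returns to the neutral posture
  reflexive <- simulate_condition(p, p$reflex, protocol = pulse)
  dr <- reflexive$data
  expect_gt(max(abs(dr$theta)), 0.02)
  expect_lt(abs(dr$theta[nrow(dr)]), 0.01)
})
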