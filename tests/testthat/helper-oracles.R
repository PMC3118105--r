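# Independent oracles.
#
# euler_oracle(): plain fixed-step forward-Euler integration of the model
# equations, written directly from their mathematical definition (scalar
# arithmetic, no use of the package's integrator or its inlined core).
# Slow but simple; at dt = 1e-5 its own error is ~1e-4 rad, an order of
# magnitude below the fidelity tolerance it checks.
#
# fisher_oracle(): two-sided Fisher exact p for a 2x2 table by explicit
# enumeration of all tables with the observed margins, with probabilities
# from binomial coefficients (no dhyper).

euler_oracle <- function(preset, dt = 1e-5, duration = 20,
                         record_every = as.integer(round(1e-3 / dt))) {
  mf <- preset$flexor; me <- preset$extensor; jp <- preset$joint
  rf <- preset$reflex$flexor; re <- preset$reflex$extensor
  tF <- preset$protocol$t_force; uv <- preset$protocol$u_voluntary
  f_ecc <- 1.3; eps_ref <- 0.04; a_min <- 0.005; fl_min <- 1e-3

  sef <- function(lse, m) {
    eps <- (lse - m$l_se_slack) / m$l_se_slack
    if (eps <= 0) 0
    else m$f_max * (exp(m$k_se_shape * eps / eps_ref) - 1) / (exp(m$k_se_shape) - 1)
  }
  flf <- function(lce, m) exp(-((lce / m$l_ce_opt - 1) / m$w_fl)^2)
  vinv <- function(phi, m) {
    vm <- m$v_max * m$l_ce_opt; a <- m$a_hill
    b <- (f_ecc - 1) * vm * a / (1 + a)
    phi <- min(max(phi, 0), f_ecc - 0.01)
    if (phi <= 1) vm * (phi - 1) / (1 + phi / a)
    else b * ((f_ecc - 1) / (f_ecc - phi) - 1)
  }
  resteq <- function(m, e) {
    l0 <- m$l_ce_opt + m$l_se_slack
    es <- e$e_p + e$e_v + e$e_f
    g <- function(l) {
      f <- sef(l0 - l, m)
      u <- min(max(es + e$k_f * f / m$f_max, 0), 1)
      f - max(u, a_min) * m$f_max * flf(l, m)
    }
    l <- stats::uniroot(g, c(0.5 * m$l_ce_opt, m$l_ce_opt), tol = 1e-12)$root
    f <- sef(l0 - l, m)
    list(l = l, a = max(min(max(es + e$k_f * f / m$f_max, 0), 1), a_min), f = f)
  }
  qf <- resteq(mf, rf); qe <- resteq(me, re)
  n <- as.integer(round(duration / dt))
  dl <- as.integer(round(c(rf$tau_p, rf$tau_v, rf$tau_f,
                           re$tau_p, re$tau_v, re$tau_f) / dt))
  spf <- numeric(n + 1); svf <- numeric(n + 1); sff <- numeric(n + 1)
  spe <- numeric(n + 1); sve <- numeric(n + 1); sfe <- numeric(n + 1)
  threc <- numeric(n %/% record_every + 1L)
  th <- 0; om <- 0; af <- qf$a; lf <- qf$l; ae <- qe$a; le <- qe$l
  l0f <- mf$l_ce_opt + mf$l_se_slack; l0e <- me$l_ce_opt + me$l_se_slack
  rsf <- qf$f / mf$f_max; rse <- qe$f / me$f_max
  irec <- 0L
  for (k in 1:(n + 1)) {
    t <- (k - 1) * dt
    Ff <- sef(l0f - mf$r * th - lf, mf)
    vF <- vinv(Ff / (max(af, a_min) * mf$f_max * max(flf(lf, mf), fl_min)), mf)
    Fe <- sef(l0e + me$r * th - le, me)
    vE <- vinv(Fe / (max(ae, a_min) * me$f_max * max(flf(le, me), fl_min)), me)
    spf[k] <- max((lf - qf$l) / mf$l_ce_opt, 0)
    svf[k] <- max(vF / mf$l_ce_opt, 0)
    sff[k] <- Ff / mf$f_max
    spe[k] <- max((le - qe$l) / me$l_ce_opt, 0)
    sve[k] <- max(vE / me$l_ce_opt, 0)
    sfe[k] <- Fe / me$f_max
    if ((k - 1) %% record_every == 0L) {
      irec <- irec + 1L
      threc[irec] <- th
    }
    if (k > n) break
    urf <- rf$k_p * (if (k > dl[1]) spf[k - dl[1]] else 0) + rf$e_p +
      rf$k_v * (if (k > dl[2]) svf[k - dl[2]] else 0) + rf$e_v +
      rf$k_f * (if (k > dl[3]) sff[k - dl[3]] else rsf) + rf$e_f
    ure <- re$k_p * (if (k > dl[4]) spe[k - dl[4]] else 0) + re$e_p +
      re$k_v * (if (k > dl[5]) sve[k - dl[5]] else 0) + re$e_v +
      re$k_f * (if (k > dl[6]) sfe[k - dl[6]] else rse) + re$e_f
    text <- if (t < 5) tF else 0
    uvol <- if (t >= 10 && t < 15) uv else 0
    uf <- min(max(uvol + urf, 0), 1); ue <- min(max(ure, 0), 1)
    alpha <- (mf$r * Ff - me$r * Fe - jp$b_passive * om + text) / jp$inertia
    th <- th + dt * om
    om <- om + dt * alpha
    af <- min(max(af + dt * (uf - af) / (if (uf > af) mf$tau_act else mf$tau_deact), 0), 1)
    ae <- min(max(ae + dt * (ue - ae) / (if (ue > ae) me$tau_act else me$tau_deact), 0), 1)
    lf <- lf + dt * vF
    le <- le + dt * vE
  }
  list(t = seq(0, duration, by = dt * record_every), theta = threc)
}

fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  dens <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) / choose(m + n, k)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}
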