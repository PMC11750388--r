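test_that("fitness rates match their defining expressions", {
  fr <- fitness_rates(ref_state, baseline)
  expect_equal(fr$rHH, 0.015 * 1250 - 0.645)   # 18.105
  expect_equal(fr$rHL, 0.006 * 1250)
  expect_equal(fr$rLL, 0.006 * 1250 - 0.87)
  expect_equal(fr$rLH, 0.015 * 1250)
  # no susceptibles of a type: within-type rate is pure loss, cross rate is 0
  st0 <- c(sH = 0, sL = 0, iH = 1, iL = 1, epsH = 0.25, epsL = 0.25)
  fr0 <- fitness_rates(st0, baseline)
  expect_equal(fr0$rHH, -0.645)
  expect_equal(fr0$rLH, 0)
  expect_equal(fr0$rHL, 0)
})

test_that("evo_rhs reproduces hand-computed trait derivatives", {
  d <- evo_rhs(ref_state, baseline)
  expect_equal(d[["epsH"]], 24.9)   # 1*(0.01*0.5*2*1250 - 0.1) + 12.5
  expect_equal(d[["epsL"]], 24.0)
  # zero variance and equal traits: no trait motion at all
  p0 <- model_params(varH = 0, varL = 0)
  d0 <- evo_rhs(ref_state, p0)
  expect_equal(unname(d0[c("epsH", "epsL")]), c(0, 0))
  # no susceptibles: only the virulence cost remains
  st <- c(sH = 0, sL = 0, iH = 1, iL = 1, epsH = 0.25, epsL = 0.25)
  ds <- evo_rhs(st, baseline)
  expect_equal(ds[["epsH"]], -baseline$yH)
  expect_equal(ds[["epsL"]], -baseline$yL)
})

test_that("nonpositive traits are a domain error", {
  bad <- ref_state
  bad[["epsH"]] <- 0
  expect_error(evo_rhs(bad, baseline), "positive")
})

test_that("with the between-type terms inactive, the sign of trait change follows the fitness gradient", {
  # iL = 0 silences the mixing term in the high-yield trait equation, so
  # d(epsH)/dt must carry the sign of rho*x*epsH^(x-1)*sH - yH
  for (case in list(list(sH = 1250, eps = 0.25, sign = 1),
                    list(sH = 1, eps = 0.25, sign = -1),
                    list(sH = 8, eps = 0.25, sign = -1),
                    list(sH = 8, eps = 0.0025, sign = 1))) {
    st <- c(sH = case$sH, sL = 0, iH = 1, iL = 0,
            epsH = case$eps, epsL = case$eps)
    grad <- baseline$rho * baseline$x * case$eps^(baseline$x - 1) * case$sH -
      baseline$yH
    expect_equal(sign(grad), case$sign)
    expect_equal(sign(evo_rhs(st, baseline)[["epsH"]]), case$sign)
  }
})

test_that("zero variance with equal traits reduces exactly to the fixed-trait model", {
  pars <- model_params(varH = 0, varL = 0)
  init <- evo_init(pars, epsH0 = 0.25)
  evo <- simulate_evo(pars, init = init, t_end = 400, n = 201)
  epi <- simulate_epi(pars, 0.25, t_end = 400, n = 201)
  expect_equal(evo$epsH, rep(0.25, 201), tolerance = 1e-10)
  expect_equal(evo$epsL, rep(0.25, 201), tolerance = 1e-10)
  for (v in c("sH", "sL", "iH", "iL")) {
    expect_equal(evo[[v]], epi[[v]], tolerance = 1e-6)
  }
})

test_that("relabeling the host types swaps the trajectory components exactly", {
  pars <- model_params(p = 0.3)
  init <- evo_init(pars, iH0 = 0.1, iL0 = 0.05, epsH0 = 0.3, epsL0 = 0.2)
  a <- simulate_evo(pars, init = init, t_end = 150, n = 151)
  b <- simulate_evo(swap_types(pars), init = swap_state(init),
                    t_end = 150, n = 151)
  expect_equal(a$sH, b$sL, tolerance = 1e-8)
  expect_equal(a$iH, b$iL, tolerance = 1e-8)
  expect_equal(a$epsH, b$epsL, tolerance = 1e-7)
  expect_equal(a$epsL, b$epsH, tolerance = 1e-7)
})

test_that("traits surge while susceptibles are abundant, then relax to equilibrium", {
  traj <- simulate_evo(baseline, t_end = 500, n = 2001)
  # early phase (resolved on its own fine grid): both traits climb and track
  # each other closely
  early <- simulate_evo(baseline, t_end = 0.2, n = 41)
  expect_true(all(diff(early$epsH) > 0))
  expect_true(all(abs(early$epsH - early$epsL) / early$epsH < 0.05))
  # the surge peaks early, while susceptible hosts are still being depleted,
  # and the trait settles below that peak once susceptibles are rare
  k_peak <- which.max(traj$epsH)
  expect_lt(traj$time[k_peak], 5)
  expect_lt(tail(traj$epsH, 1), traj$epsH[k_peak])
  expect_gt(tail(traj$epsH, 1), 0.25)   # but well above its starting value
  expect_true(all(traj$epsH > 0 & traj$epsL > 0))
  # trait values diverge between host types as equilibrium is approached
  expect_lt(abs(early$epsH[5] - early$epsL[5]),
            abs(tail(traj$epsH, 1) - tail(traj$epsL, 1)))
})

test_that("equilibrium trait divergence grows with the virulence gap", {
  gaps <- c(0.3, 0.6, 1)
  div <- vapply(gaps, function(yL) {
    eq <- evo_equilibrium(model_params(yL = yL))
    abs(eq$state[["epsH"]] - eq$state[["epsL"]])
  }, numeric(1))
  expect_true(all(diff(div) > 0))
})

test_that("joint equilibrium agrees with long-time integration", {
  eq <- evo_equilibrium(baseline)
  expect_lt(eq$residual, 1e-8)
  traj <- simulate_evo(baseline, t_end = 4000, n = 41)
  final <- unlist(tail(traj, 1)[c("sH", "sL", "iH", "iL", "epsH", "epsL")])
  expect_equal(unname(eq$state[names(final)]), unname(final),
               tolerance = 1e-4)
})

test_that("zero-variance joint equilibrium equals the fixed-trait equilibrium", {
  pars <- model_params(varH = 0, varL = 0)
  eq <- evo_equilibrium(pars, init = evo_init(pars, epsH0 = 0.25))
  ref <- endemic_equilibrium(pars, 0.25)
  expect_equal(eq$state, ref$state, tolerance = 1e-10)
  expect_equal(unname(eq$state[c("epsH", "epsL")]), c(0.25, 0.25))
})

test_that("symmetric host types evolve identical traits at equilibrium", {
  eq <- evo_equilibrium(identical_hosts)
  expect_equal(eq$state[["epsH"]], eq$state[["epsL"]], tolerance = 1e-8)
})

test_that("tolerance halving leaves the coupled final state unchanged", {
  a <- simulate_evo(baseline, t_end = 200, n = 5)
  b <- simulate_evo(baseline, t_end = 200, n = 5, rtol = 5e-9, atol = 5e-11)
  fa <- unlist(tail(a, 1))
  fb <- unlist(tail(b, 1))
  expect_equal(fa, fb, tolerance = 1e-6)
})
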