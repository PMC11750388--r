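test_that("run_scenario pairs with/without-adaptation runs", {
  both <- run_scenario("baseline", evolution = "both", t_end = 400, n = 201)
  on <- both$on; off <- both$off
  # adaptation maintains lower equilibrium host densities
  for (v in c("sH", "sL", "iH", "iL")) {
    expect_lt(on$equilibrium$state[[v]], off$equilibrium$state[[v]])
  }
  # low-yield infections stay rarer than high-yield ones after transients
  late <- on$trajectory[on$trajectory$time > 100, ]
  expect_true(all(late$iL < late$iH))
  expect_true(all(c("Re", "vmr", "vmr_defined") %in% names(on$trajectory)))
})

test_that("identical host types at p = 0.5 keep susceptible densities equal", {
  run <- run_scenario(identical_hosts, evolution = "off", t_end = 200, n = 101)
  expect_equal(run$trajectory$sH, run$trajectory$sL, tolerance = 1e-10)
})

test_that("host-composition scan hits zero dispersion at both extremes", {
  sc <- scan_host_composition("baseline", p_grid = c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(sc$vmr[sc$p == 0], 0, tolerance = 1e-10)
  expect_equal(sc$vmr[sc$p == 1], 0, tolerance = 1e-10)
  expect_true(all(sc$vmr[sc$p %in% c(0.25, 0.5, 0.75)] > 0))
  expect_equal(sc$pct_sL, sc$p, tolerance = 0.05)
})

test_that("identical host types give zero dispersion at every composition", {
  sc <- scan_host_composition(identical_hosts, p_grid = c(0.2, 0.5, 0.8))
  expect_true(all(abs(sc$vmr) < 1e-10))
})

test_that("quality-gap grid is zero on the no-gap boundary and increases with the gap", {
  # no-gap boundary: identical host types make both vmrs zero cell-wise
  z <- scan_quality_grid(identical_hosts, p_grid = c(0.3, 0.7),
                         axis = "yL", values = identical_hosts$yH)
  expect_true(all(abs(z$delta_vmr) < 1e-10))
  qg <- scan_quality_grid(p_grid = c(0.25, 0.5, 0.75), axis = "yL",
                          values = c(0.5, 1))
  for (v in unique(qg$value)) {      # increasing in p at each gap size
    expect_true(all(diff(qg$delta_vmr[qg$value == v]) > 0))
  }
  for (p in unique(qg$p)) {          # increasing in the virulence gap
    expect_true(all(diff(qg$delta_vmr[qg$p == p]) > 0))
  }
})

test_that("variance scan: zero variance reduces to the fixed-trait epidemic", {
  sv <- scan_variance("baseline", var_grid = c(0, 1), t_end = 30, n = 1201)
  r0 <- sv[sv$var == 0, ]
  expect_equal(r0$epsH_eq, 0.25)
  expect_equal(r0$epsL_eq, 0.25)
  fixed <- annotate_dispersion(simulate_epi(baseline, 0.25, t_end = 30, n = 1201))
  expect_equal(r0$vmr_early_peak,
               fixed$vmr[which.min(abs(fixed$time - r0$t_peak))],
               tolerance = 1e-8)
  # higher variance accelerates adaptation and boosts the early dispersion peak
  r1 <- sv[sv$var == 1, ]
  expect_lt(r1$t_half_epsH, ifelse(r0$t_half_epsH == 0, Inf, r0$t_half_epsH))
  expect_gt(r1$vmr_early_peak, r0$vmr_early_peak)
})

test_that("adaptation speed rises and low-yield traits fall as variance grows", {
  sv <- scan_variance("baseline", var_grid = c(0.5, 1, 4), t_end = 30, n = 1201)
  expect_true(all(diff(sv$t_half_epsH) < 0))
  expect_lt(sv$epsL_eq[sv$var == 4], sv$epsL_eq[sv$var == 1])
})

test_that("scans are deterministic", {
  a <- scan_host_composition("baseline", p_grid = c(0.3, 0.6))
  b <- scan_host_composition("baseline", p_grid = c(0.3, 0.6))
  expect_identical(a, b)
})

test_that("equilibrium objects expose tidy and glance methods", {
  eq <- endemic_equilibrium(baseline, 0.25)
  td <- tidy(eq)
  expect_setequal(td$term, c("sH", "sL", "iH", "iL", "epsH", "epsL"))
  gl <- glance(eq)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("Re", "vmr", "disease_free", "residual") %in% names(gl)))
  expect_equal(gl$Re, 1, tolerance = 1e-8)   # any endemic equilibrium has Re = 1
})

test_that("trajectory autoplot and scan plots build without error", {
  traj <- annotate_dispersion(simulate_evo(baseline, t_end = 20, n = 41))
  expect_s3_class(autoplot(traj), "ggplot")
  sc <- scan_host_composition("baseline", p_grid = c(0.3, 0.7))
  expect_s3_class(plot_composition_scan(sc), "ggplot")
  qg <- scan_quality_grid(p_grid = c(0.4), axis = "cH", values = c(0.2, 0.5))
  expect_s3_class(plot_quality_grid(qg), "ggplot")
})

test_that("the command-line interface runs its subcommands end to end", {
  out_csv <- withr::local_tempfile(fileext = ".csv")
  expect_equal(cli_main(c("simulate", "--preset", "baseline",
                          "--evolution", "on", "--t-end", "50",
                          "--log-level", "quiet", "--out", out_csv)), 0L)
  df <- utils::read.csv(out_csv)
  expect_true(all(c("time", "sH", "sL", "iH", "iL", "epsH", "epsL",
                    "Re", "ReH_pop", "ReL_pop", "varRe", "vmr") %in% names(df)))
  out_scan <- withr::local_tempfile(fileext = ".csv")
  expect_equal(cli_main(c("scan-composition", "--preset", "baseline",
                          "--p-grid", "0,0.5,1", "--log-level", "quiet",
                          "--out", out_scan)), 0L)
  sc <- utils::read.csv(out_scan)
  expect_equal(nrow(sc), 3)
  expect_equal(sc$vmr[sc$p == 0], 0, tolerance = 1e-10)
  out_json <- withr::local_tempfile(fileext = ".json")
  expect_equal(cli_main(c("validate-price", "--preset", "baseline",
                          "--log-level", "quiet", "--out", out_json)), 0L)
  rep <- jsonlite::read_json(out_json)
  expect_true(rep$max_rel_err_epsH < 0.05)
  # usage errors exit nonzero
  expect_equal(suppressMessages(cli_main(c("simulate", "--preset", "nope"))), 1L)
  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 1L)
})

test_that("a YAML config feeds the CLI the same model as the preset", {
  cfg <- withr::local_tempfile(fileext = ".yml")
  write_params_config(preset_params("baseline"), cfg)
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  expect_equal(cli_main(c("simulate", "--config", cfg, "--t-end", "20",
                          "--log-level", "quiet", "--out", out1)), 0L)
  expect_equal(cli_main(c("simulate", "--preset", "baseline", "--t-end", "20",
                          "--log-level", "quiet", "--out", out2)), 0L)
  expect_identical(readLines(out1), readLines(out2))
})
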