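test_that("joints reconstructed from marginals preserve the margins", {
  j <- joint_from_marginals(0.45, 0.30, "fixed_cell_shift", delta = 0.015)
  expect_equal(unname(unclass(j)), c(0.15, 0.30, 0.15, 0.40))
  expect_equal(unname(unclass(joint_from_marginals(1, 0))), c(0, 1, 0, 0))
  ind <- joint_from_marginals(0.60, 0.40, "independence")
  expect_equal(unname(unclass(ind)), c(0.24, 0.36, 0.16, 0.24))
  expect_equal(marginal_rates(ind), c(efficacy = 0.60, toxicity = 0.40))
  # infeasible shift is clipped with a warning, margins still recovered
  expect_warning(cl <- joint_from_marginals(0.80, 0.25, "fixed_cell_shift", delta = 0.06),
                 "clipped")
  expect_equal(marginal_rates(cl), c(efficacy = 0.80, toxicity = 0.25))
  expect_gte(min(cl), 0)
  expect_error(joint_from_marginals(1.2, 0.5), "\\[0, 1\\]")
})

test_that("fixture joints reproduce every printed marginal pair and hypothesis", {
  ux <- load_fixture("uncontrolled_main")
  expect_equal(unname(unclass(ux$design$prior)), c(0.15, 0.30, 0.15, 0.40))
  expect_equal(ux$design$phi_eff, 0.45)
  expect_equal(ux$design$phi_tox, 0.30)
  expect_equal(ux$delta, 0.015)
  # scenario 2: LFC with arm A at the promising hypothesis
  m2 <- lapply(ux$scenarios$scenario_2$arms, marginal_rates)
  expect_equal(unname(m2[[1]]), c(0.60, 0.20))
  expect_equal(unname(m2[[2]]), c(0.45, 0.30))
  expect_identical(ux$scenarios$scenario_2$arms[[1]], ux$H1)
  expect_identical(ux$scenarios$scenario_1$arms[[3]], ux$H0)
  expect_equal(ux$scenarios$scenario_2$truth,
               c("admissible", "inadmissible", "inadmissible"))
  expect_true(all(ux$scenarios$scenario_1$truth == "inadmissible"))

  cx <- load_fixture("controlled_main")
  expect_equal(unname(unclass(cx$design$prior)), c(0.30, 0.30, 0.10, 0.30))
  expect_equal(unname(marginal_rates(cx$scenarios$scenario_1$control)), c(0.60, 0.40))
  expect_identical(cx$scenarios$scenario_2$arms[[1]], cx$H1)

  # every reconstructed joint must hit its printed (efficacy, toxicity) pair
  for (fx in list(ux, cx)) {
    for (sc in fx$scenarios) {
      for (arm in c(sc$arms, if (!is.null(sc$control)) list(sc$control))) {
        m <- marginal_rates(arm)
        expect_true(all(m >= 0 & m <= 1))
        expect_equal(sum(unclass(arm)), 1, tolerance = 1e-12)
        # margins are multiples of 0.05 in the published scenario grid
        expect_equal(m, round(m / 0.05) * 0.05, tolerance = 1e-9)
      }
    }
  }

  az <- load_fixture("aza_plus")
  expect_equal(unname(unclass(az$design$prior)), c(0.15, 0.25, 0.15, 0.45))
  expect_equal(az$design$K, 2)
  expect_true(az$design$controlled)
  expect_equal(az$design$schedule, c(20L, 40L, 60L, 80L))
  expect_equal(az$design$threshold$lambda, 0.63)
  expect_equal(az$problem$fwer_target, 0.15)
  expect_equal(unname(unclass(az$H1)), c(0.15, 0.40, 0.05, 0.40))
  expect_error(load_fixture("nope"))
})

test_that("run configurations parse and round-trip semantically", {
  cfg <- read_run_config(system.file("extdata", "simulate-example.yaml",
                                     package = "bop2mams"))
  expect_s3_class(cfg$design, "design_spec")
  expect_equal(cfg$design$K, 3)
  expect_equal(cfg$design$threshold$lambda, 0.63)
  expect_equal(cfg$scenario$truth, c("admissible", "inadmissible", "inadmissible"))
  expect_equal(cfg$seed, 42)

  # margins-with-delta arms resolve through the fixed-cell-shift rule
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "design:", "  K: 1", "  n_max: 4", "  schedule: [2, 4]",
    "  phi_eff: 0.45", "  phi_tox: 0.30",
    "  prior: [0.15, 0.30, 0.15, 0.40]",
    "threshold: {family: constant, eps: 0.9}",
    "scenario:",
    "  arms:", "    - {eff: 0.45, tox: 0.30, delta: 0.015}",
    "  truth: [inadmissible]",
    "replicates: 10", "seed: 1"), f)
  cfg2 <- read_run_config(f)
  expect_equal(unname(unclass(cfg2$scenario$arms[[1]])), c(0.15, 0.30, 0.15, 0.40))

  cal <- read_run_config(system.file("extdata", "calibrate-example.yaml",
                                     package = "bop2mams"))
  expect_s3_class(cal$problem, "calibration_problem")
  expect_equal(cal$problem$fwer_target, 0.10)
  expect_equal(cal$family, "multi_arm")
  expect_error(read_run_config(tempfile()), "not found")
})

test_that("the CLI simulates deterministically and degrades gracefully", {
  cfgf <- tempfile(fileext = ".yaml")
  writeLines(c(
    "design:", "  K: 2", "  n_max: 8", "  schedule: [4, 8]",
    "  phi_eff: 0.45", "  phi_tox: 0.30",
    "  prior: [0.15, 0.30, 0.15, 0.40]",
    "threshold: {family: multi_arm, lambda: 0.63, gamma: 1.0}",
    "scenario:",
    "  label: demo",
    "  arms:",
    "    - joint: [0.15, 0.30, 0.15, 0.40]",
    "    - joint: [0.15, 0.30, 0.15, 0.40]",
    "  truth: [inadmissible, inadmissible]",
    "replicates: 50", "seed: 7"), cfgf)
  d1 <- file.path(tempdir(), "cli1"); d2 <- file.path(tempdir(), "cli2")
  expect_equal(suppressMessages(bop2_cli(c("simulate", "--config", cfgf, "--out", d1))), 0L)
  expect_equal(suppressMessages(bop2_cli(c("simulate", "--config", cfgf, "--out", d2))), 0L)
  expect_identical(readLines(file.path(d1, "oc_demo.csv")),
                   readLines(file.path(d2, "oc_demo.csv")))
  expect_identical(readLines(file.path(d1, "oc_demo.json")),
                   readLines(file.path(d2, "oc_demo.json")))

  # oc-table over the results, and over an empty directory
  out <- tempfile(fileext = ".csv")
  expect_equal(suppressMessages(bop2_cli(c("oc-table", "--dir", d1, "--out", out))), 0L)
  expect_equal(utils::read.csv(out)$scenario, c("demo", "demo"))
  emptyd <- file.path(tempdir(), "cli-empty"); dir.create(emptyd, showWarnings = FALSE)
  expect_equal(suppressMessages(bop2_cli(c("oc-table", "--dir", emptyd, "--out", out))), 0L)
  expect_equal(nrow(utils::read.csv(out)), 0)

  # infeasible calibration exits nonzero with the diagnostic
  calf <- tempfile(fileext = ".yaml")
  writeLines(c(
    "design:", "  K: 2", "  n_max: 4", "  schedule: [2, 4]",
    "  phi_eff: 0.45", "  phi_tox: 0.30",
    "  prior: [0.15, 0.30, 0.15, 0.40]",
    "calibration:",
    "  family: multi_arm",
    "  H0: [0.15, 0.30, 0.15, 0.40]",
    "  H1: [0.18, 0.42, 0.02, 0.38]",
    "  fwer_target: 0.001",
    "  lambda_grid: [0.05]", "  gamma_grid: [1.0]",
    "  R_cal: 500", "  seed: 1"), calf)
  expect_equal(suppressMessages(bop2_cli(c("calibrate", "--config", calf))), 1L)
  expect_equal(suppressMessages(bop2_cli(c("bogus"))), 1L)
})
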