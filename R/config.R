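# YAML run configurations and the command-line interface.
#
# A run configuration fully describes a simulation or calibration run. Two
# shapes are accepted: an explicit design/scenario description, or a
# `fixture:` reference to one of the built-in configurations. All file
# paths inside a config are resolved relative to the config file.

parse_threshold <- function(x) {
  if (is.null(x)) return(NULL)
  threshold_spec(family = x$family, lambda = x$lambda, gamma = x$gamma,
                 eps = x$eps, K = x$K)
}

parse_arm <- function(x, delta_default = 0) {
  if (!is.null(x$joint)) return(outcome_probs(as.numeric(x$joint)))
  if (is.null(x$eff) || is.null(x$tox))
    stopf("scenario arm needs either 'joint: [4 cells]' or 'eff:'/'tox:' margins")
  joint_from_marginals(x$eff, x$tox, "fixed_cell_shift",
                       delta = if (is.null(x$delta)) delta_default else x$delta)
}

#' Read a run configuration
#'
#' Parses a YAML configuration into the package's design, scenario, accrual
#' and calibration objects. See `system.file("extdata", package =
#' "bop2mams")` for annotated examples of both the simulation and the
#' calibration shape; `fixture: <name>` (with optional `scenario:` label)
#' pulls a built-in fixture instead of an explicit design block.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with components `design`,
#'   `scenario`, `plan`, `replicates`, `seed`, and (calibration configs)
#'   `problem` and `family`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  out <- list(replicates = raw$replicates, seed = raw$seed)
  if (!is.null(raw$fixture)) {
    fx <- load_fixture(raw$fixture)
    out$design <- fx$design
    if (!is.null(raw$threshold)) out$design$threshold <- parse_threshold(raw$threshold)
    if (!is.null(raw$single_threshold))
      out$design$single_threshold <- parse_threshold(raw$single_threshold)
    if (!is.null(raw$scenario)) {
      if (!raw$scenario %in% names(fx$scenarios))
        stopf("fixture '%s' has no scenario '%s'", raw$fixture, raw$scenario)
      out$scenario <- fx$scenarios[[raw$scenario]]
    }
    out$problem <- fx$problem
  } else {
    d <- raw$design
    if (is.null(d)) stopf("config must contain a 'design' or 'fixture' block")
    # YAML 1.1 reads a bare key `N` as boolean; the canonical key is n_max
    n_max <- d$n_max %||% d$N %||% d[["FALSE"]]
    out$design <- design_spec(K = d$K, N = n_max, schedule = unlist(d$schedule),
                              controlled = isTRUE(d$controlled),
                              phi_eff = d$phi_eff, phi_tox = d$phi_tox,
                              prior = as.numeric(unlist(d$prior)),
                              threshold = parse_threshold(raw$threshold),
                              single_threshold = parse_threshold(raw$single_threshold))
    if (!is.null(raw$scenario)) {
      s <- raw$scenario
      out$scenario <- trial_scenario(
        arms = lapply(s$arms, parse_arm),
        control = if (!is.null(s$control)) parse_arm(s$control),
        truth = unlist(s$truth), label = s$label)
    }
  }
  if (!is.null(raw$calibration)) {
    cb <- raw$calibration
    grid_or <- function(x, default) if (is.null(x)) default else as.numeric(unlist(x))
    out$problem <- calibration_problem(
      design = out$design,
      H0 = outcome_probs(as.numeric(unlist(cb$H0))),
      H1 = outcome_probs(as.numeric(unlist(cb$H1))),
      H01 = if (!is.null(cb$H01)) outcome_probs(as.numeric(unlist(cb$H01))),
      H02 = if (!is.null(cb$H02)) outcome_probs(as.numeric(unlist(cb$H02))),
      fwer_target = cb$fwer_target,
      arm_alpha_target = cb$arm_alpha_target,
      lambda_grid = grid_or(cb$lambda_grid, seq(0.01, 0.99, by = 0.01)),
      gamma_grid = grid_or(cb$gamma_grid, seq(0.05, 1, by = 0.05)),
      eps_grid = grid_or(cb$eps_grid, seq(0.500, 0.995, by = 0.005)),
      R_cal = if (is.null(cb$R_cal)) 10000 else cb$R_cal,
      seed = if (is.null(cb$seed)) 1 else cb$seed)
    out$family <- if (is.null(cb$family)) "multi_arm" else cb$family
  }
  a <- raw$accrual
  out$plan <- if (is.null(a)) accrual_plan("planned") else
    accrual_plan(a$mode, psi = if (is.null(a$psi)) 1 else a$psi,
                 u = if (is.null(a$u)) 0L else a$u, reduced_N = a$reduced_N)
  class(out) <- "run_config"
  out
}

cli_usage <- function() {
  cat("usage: bop2mams <command> [options]\n",
      "commands:\n",
      "  simulate  --config <yaml> [--reps N] [--seed S] --out <dir>\n",
      "  calibrate --config <yaml> [--out <json>]\n",
      "  oc-table  --dir <dir> [--out <csv>]\n", sep = "")
}

cli_opt <- function(args, name, default = NULL) {
  i <- which(args == name)
  if (length(i) == 0) return(default)
  if (i[1] == length(args)) stopf("missing value for %s", name)
  args[i[1] + 1L]
}

#' Command-line interface
#'
#' Subcommands: `simulate` (run replicated trials for a config, write the
#' operating-characteristics table as CSV and JSON), `calibrate` (grid
#' search for a calibration config, write the chosen parameters and the
#' full audit grid as JSON), `oc-table` (combine `oc_*.csv` result files
#' from a directory into one table). Runs are reproducible: the seed,
#' replicate counts and package version are logged into the outputs.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly (0 on success).
#' @export
bop2_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) { cli_usage(); return(invisible(1L)) }
    cmd <- args[1]
    args <- args[-1]
    switch(cmd,
      simulate = {
        cfg <- read_run_config(cli_opt(args, "--config") %||% stopf("--config is required"))
        if (is.null(cfg$scenario)) stopf("simulate requires a scenario in the config")
        reps <- as.integer(cli_opt(args, "--reps", cfg$replicates %||% 1000))
        seed <- as.integer(cli_opt(args, "--seed", cfg$seed %||% stopf("a seed is required")))
        out_dir <- cli_opt(args, "--out", ".")
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        oc <- estimate_oc(cfg$design, cfg$scenario, cfg$plan, R = reps, seed = seed)
        tab <- oc_table(list(oc))
        lab <- cfg$scenario$label %||% "scenario"
        utils::write.csv(tab, file.path(out_dir, paste0("oc_", lab, ".csv")),
                         row.names = FALSE)
        meta <- list(seed = seed, replicates = reps, scenario = lab,
                     package_version = as.character(utils::packageVersion("bop2mams")),
                     fwer = oc$fwer, power = oc$power,
                     correct_selection_pct = oc$correct_selection_pct)
        jsonlite::write_json(meta, file.path(out_dir, paste0("oc_", lab, ".json")),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        message(sprintf("simulate: %d replicates of '%s' written to %s", reps, lab, out_dir))
        0L
      },
      calibrate = {
        cfg <- read_run_config(cli_opt(args, "--config") %||% stopf("--config is required"))
        if (is.null(cfg$problem)) stopf("calibrate requires a 'calibration' block or fixture")
        res <- calibrate(cfg$problem, cfg$family %||% "multi_arm")
        print(res)
        out <- cli_opt(args, "--out")
        if (!is.null(out)) {
          payload <- list(family = res$family, lambda = res$lambda, gamma = res$gamma,
                          eps = res$eps, fwer = res$fwer, power = res$power,
                          fwer_target = res$fwer_target, R_cal = res$R_cal,
                          seed = cfg$problem$seed,
                          package_version = as.character(utils::packageVersion("bop2mams")),
                          grid = res$grid)
          jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                               dataframe = "rows", pretty = TRUE)
          message("calibrate: result written to ", out)
        }
        0L
      },
      `oc-table` = {
        dir <- cli_opt(args, "--dir") %||% stopf("--dir is required")
        files <- sort(list.files(dir, pattern = "^oc_.*\\.csv$", full.names = TRUE))
        tab <- if (length(files)) do.call(rbind, lapply(files, utils::read.csv)) else
          oc_table(list())
        out <- cli_opt(args, "--out")
        if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE) else
          print(tab, row.names = FALSE)
        0L
      },
      { cli_usage(); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
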