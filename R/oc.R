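# Operating characteristics over replicated trials.

#' Estimate operating characteristics by simulation
#'
#' Replicates the trial `R` times under one scenario and aggregates the
#' design's performance metrics: per arm, the percentage of replicates
#' declaring the arm promising (efficacy and no toxicity, "ENT"), the
#' percentage stopping the arm before the terminal analysis ("ES") with the
#' rule responsible, and the mean sample size; per trial, the family-wise
#' error rate (at least one truly inadmissible arm declared promising),
#' power (the promising rate of the single admissible arm, least-favourable-
#' configuration labelling) and the correct-selection percentage (every
#' arm's declaration matches its truth label). Monte Carlo standard errors
#' `sqrt(p (1 - p) / R)` accompany every proportion.
#'
#' @param design A [design_spec()] with a threshold.
#' @param scenario A [trial_scenario()].
#' @param plan An [accrual_plan()].
#' @param truth_labels Per-arm `"admissible"` / `"inadmissible"` labels;
#'   defaults to the scenario's own labels.
#' @param R Number of replicates.
#' @param seed Integer seed.
#' @param trial_log Optional path; when given, a per-trial CSV log is
#'   written (one row per arm per replicate: trial, arm, stop_look,
#'   stop_reason, promising, sample_size).
#' @return An object of class `bop2_oc`.
#' @export
estimate_oc <- function(design, scenario, plan = accrual_plan("planned"),
                        truth_labels = scenario$truth, R = 10000, seed = NULL,
                        trial_log = NULL) {
  if (R < 1) stopf("R must be at least 1")
  if (length(scenario$arms) != design$K)
    stopf("scenario has %d arms but design has K = %d", length(scenario$arms), design$K)
  if (!is.null(truth_labels)) {
    truth_labels <- match.arg(truth_labels, c("admissible", "inadmissible"),
                              several.ok = TRUE)
    if (length(truth_labels) != design$K)
      stopf("truth_labels must have one entry per experimental arm")
  }
  if (!is.null(seed)) set.seed(seed)
  K <- design$K
  if (plan$mode == "imbalanced") {
    # per-replicate random schedules: loop the single-trial simulator
    promising <- matrix(FALSE, R, K)
    stop_look <- matrix(NA_integer_, R, K)
    fut <- tox <- matrix(FALSE, R, K)
    ss <- matrix(0L, R, K)
    for (r in seq_len(R)) {
      tr <- run_trial(design, scenario, plan)
      promising[r, ] <- tr$arms$promising
      stop_look[r, ] <- tr$arms$stop_look
      fut[r, ] <- tr$arms$stop_reason %in% c("futility", "both")
      tox[r, ] <- tr$arms$stop_reason %in% c("toxicity", "both")
      ss[r, ] <- tr$arms$sample_size
    }
  } else {
    cnt <- sim_counts(design, scenario, plan, R)
    mon <- monitor_arrays(design, cnt)
    dec <- apply_decisions(mon, design, N_anchor = plan_anchor(design, plan))
    promising <- dec$promising
    stop_look <- dec$stop_look
    early <- !is.na(stop_look)
    fut <- dec$fut_fired & early
    tox <- dec$tox_fired & early
    ss <- sample_sizes(stop_look, mon$n)
  }
  if (!is.null(trial_log)) {
    reason <- matrix("none", R, K)
    early <- !is.na(stop_look)
    reason[early & fut & !tox] <- "futility"
    reason[early & tox & !fut] <- "toxicity"
    reason[early & fut & tox] <- "both"
    utils::write.csv(data.frame(
      trial = rep(seq_len(R), K), arm = rep(seq_len(K), each = R),
      stop_look = as.vector(stop_look), stop_reason = as.vector(reason),
      promising = as.vector(promising), sample_size = as.vector(ss)),
      trial_log, row.names = FALSE)
  }
  pct <- function(x) 100 * mean(x)
  se_pct <- function(x) 100 * sqrt(mean(x) * (1 - mean(x)) / R)
  arms <- data.frame(
    arm = seq_len(K),
    ent_pct = apply(promising, 2, pct),
    ent_se = apply(promising, 2, se_pct),
    es_pct = apply(!is.na(stop_look), 2, pct),
    es_se = apply(!is.na(stop_look), 2, se_pct),
    es_futility_pct = apply(fut & !tox, 2, pct),
    es_toxicity_pct = apply(tox & !fut, 2, pct),
    es_both_pct = apply(fut & tox, 2, pct),
    mean_ss = colMeans(ss)
  )
  fwer <- power <- correct <- NA_real_
  fwer_se <- power_se <- correct_se <- NA_real_
  if (!is.null(truth_labels)) {
    inad <- truth_labels == "inadmissible"
    if (any(inad)) {
      fp <- rowSums(promising[, inad, drop = FALSE]) > 0
      fwer <- pct(fp); fwer_se <- se_pct(fp)
    }
    if (sum(!inad) == 1L) {
      pw <- promising[, !inad]
      power <- pct(pw); power_se <- se_pct(pw)
    }
    ok <- rowSums(promising == matrix(!inad, R, K, byrow = TRUE)) == K
    correct <- pct(ok); correct_se <- se_pct(ok)
  }
  structure(list(arms = arms, fwer = fwer, fwer_se = fwer_se,
                 power = power, power_se = power_se,
                 correct_selection_pct = correct, correct_selection_se = correct_se,
                 n_replicates = R, truth = truth_labels,
                 label = scenario$label),
            class = "bop2_oc")
}

#' @export
print.bop2_oc <- function(x, digits = 2, ...) {
  cat(sprintf("Operating characteristics%s (%d replicates)\n",
              if (is.null(x$label)) "" else paste0(" for scenario '", x$label, "'"),
              x$n_replicates))
  df <- x$arms
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  if (!is.na(x$fwer)) cat(sprintf("FWER: %.*f%% (MC SE %.*f)\n", digits, x$fwer, digits, x$fwer_se))
  if (!is.na(x$power)) cat(sprintf("Power: %.*f%% (MC SE %.*f)\n", digits, x$power, digits, x$power_se))
  if (!is.na(x$correct_selection_pct))
    cat(sprintf("Correct selection: %.*f%%\n", digits, x$correct_selection_pct))
  invisible(x)
}

#' Tabulate operating characteristics across scenarios
#'
#' Flattens a list of [estimate_oc()] results into one data frame, one row
#' per (scenario, arm), with the trial-level metrics repeated on each row of
#' the scenario. Percentages are reported to 2 decimals. The layout
#' round-trips through CSV.
#'
#' @param ocs List of `bop2_oc` objects.
#' @param labels Optional scenario labels (defaults to the objects' own or
#'   their position).
#' @param file Optional path; when given the table is also written as CSV.
#' @return A data frame.
#' @export
oc_table <- function(ocs, labels = NULL, file = NULL) {
  cols <- c("scenario", "arm", "ent_pct", "ent_se", "es_pct", "es_se",
            "es_futility_pct", "es_toxicity_pct", "es_both_pct", "mean_ss",
            "fwer", "power", "correct_selection_pct", "n_replicates")
  if (length(ocs) == 0) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                                dimnames = list(NULL, cols)))
  } else {
    if (is.null(labels))
      labels <- vapply(seq_along(ocs), function(i) {
        if (!is.null(ocs[[i]]$label)) ocs[[i]]$label else as.character(i)
      }, character(1))
    rows <- lapply(seq_along(ocs), function(i) {
      x <- ocs[[i]]
      df <- x$arms
      df$scenario <- labels[i]
      df$fwer <- round(x$fwer, 2)
      df$power <- round(x$power, 2)
      df$correct_selection_pct <- round(x$correct_selection_pct, 2)
      df$n_replicates <- x$n_replicates
      num <- vapply(df, is.numeric, logical(1)) & names(df) != "arm"
      df[num] <- lapply(df[num], round, 2)
      df[cols]
    })
    out <- do.call(rbind, rows)
  }
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
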