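# Scenario grid and simulation orchestration.

#' The canonical 30-scenario grid
#'
#' Ten ordered triples of preceding-study sample sizes (three equal, seven
#' unequal, each size in \{200, 500, 2000\}) crossed with three selection
#' variants: univariable selection at `alpha_in` 0.05 (`_a`) and 0.2
#' (`_b`) and backward elimination with the AIC (`_c`).
#'
#' @return A tibble with 30 rows and columns `scenario`, `n1`, `n2`,
#'   `n3`, `method`, `alpha_in` (`NA` for backward elimination).
#' @export
build_scenario_grid <- function() {
  triples <- rbind(
    c(200, 200, 200), c(500, 500, 500), c(2000, 2000, 2000),
    c(200, 200, 500), c(200, 500, 500), c(200, 500, 2000),
    c(200, 200, 2000), c(500, 500, 2000), c(200, 2000, 2000),
    c(500, 2000, 2000)
  )
  variants <- tibble(
    letter = c("a", "b", "c"),
    method = c("univariable", "univariable", "backward"),
    alpha_in = c(0.05, 0.2, NA_real_)
  )
  grid <- tidyr::crossing(
    tibble(block = seq_len(nrow(triples)),
           n1 = triples[, 1], n2 = triples[, 2], n3 = triples[, 3]),
    variants
  )
  grid <- dplyr::arrange(grid, .data$block,
                         match(.data$letter, c("a", "b", "c")))
  tibble(
    scenario = paste0("S", grid$block, "_", grid$letter),
    n1 = grid$n1, n2 = grid$n2, n3 = grid$n3,
    method = grid$method, alpha_in = grid$alpha_in
  )
}

#' Simulation run configuration
#'
#' @param scenarios Tibble of scenarios (rows of [build_scenario_grid()])
#'   or a character vector of scenario labels to pick from the canonical
#'   grid.
#' @param n_replications Replications per scenario (the emulated study
#'   uses 10,000; desk-scale runs of 500-1,000 give usable Monte Carlo
#'   error, which the output reports).
#' @param master_seed Master seed; every replication's stream is derived
#'   from `(master_seed, scenario label, replication index)` only, so any
#'   subset of scenarios reruns identically.
#' @param n_current,n_validation Sample sizes of the current and
#'   validation datasets used for the MSPE.
#' @param generator The [generator_spec()] to simulate from.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(scenarios = build_scenario_grid(),
                       n_replications = 10000,
                       master_seed = 29112018,
                       n_current = 500,
                       n_validation = 500,
                       generator = default_generator()) {
  if (is.character(scenarios)) {
    grid <- build_scenario_grid()
    miss <- setdiff(scenarios, grid$scenario)
    if (length(miss) > 0) {
      abort(paste0("unknown scenario label(s): ", paste(miss, collapse = ", ")))
    }
    scenarios <- grid[match(scenarios, grid$scenario), ]
  }
  stopifnot(n_replications >= 1, n_current > 25, n_validation >= 1)
  structure(
    list(scenarios = scenarios,
         n_replications = as.integer(n_replications),
         master_seed = as.integer(master_seed),
         n_current = as.integer(n_current),
         n_validation = as.integer(n_validation),
         generator = generator),
    class = "run_config"
  )
}

# Stable numeric key for a scenario label: canonical labels map to their
# grid position, anything else to a string hash.  Keeps replication
# streams independent of which subset of scenarios is run.
scenario_key <- function(id) {
  m <- regmatches(id, regexec("^S([0-9]+)_([abc])$", id))[[1]]
  if (length(m) == 3) {
    (as.integer(m[2]) - 1) * 3 + match(m[3], c("a", "b", "c"))
  } else {
    sum(utf8ToInt(id) * seq_along(utf8ToInt(id)) * 131) %% 1000003
  }
}

# Deterministic per-replication seed in [1, 2^31 - 2]; all arithmetic
# stays below 2^53 so it is exact in doubles.
replication_seed <- function(master_seed, scenario, rep_index) {
  p <- 2147483647
  x <- master_seed %% p
  x <- (x * 48271 + scenario_key(scenario) * 69621) %% p
  x <- (x * 48271 + rep_index) %% p
  as.integer(x + 1)
}

# One full replication on the fast matrix path.  Draw order within the
# seeded stream: study 1, study 2, study 3, current, validation.
core_replication <- function(cs, n_sizes, method, alpha_in,
                             n_current, n_validation, seed) {
  set.seed(seed)
  p <- length(cs$vars)
  masks <- matrix(FALSE, nrow = 3, ncol = p)
  for (i in 1:3) {
    X <- gen_x(cs, n_sizes[i])
    y <- gen_y(cs, X)
    masks[i, ] <- if (method == "univariable") {
      univariable_screen(X, y, alpha_in)$selected
    } else {
      backward_screen(X, y)$selected
    }
  }
  votes <- colSums(masks)
  Xc <- gen_x(cs, n_current)
  yc <- gen_y(cs, Xc)
  Xv <- gen_x(cs, n_validation)
  yv <- gen_y(cs, Xv)
  rules <- lapply(1:3, function(m) {
    mask <- votes >= m
    score <- score_mask(mask, cs)
    score$mspe <- mspe_mask(mask, Xc, yc, Xv, yv)
    list(mask = mask, score = score)
  })
  list(votes = votes, rules = rules)
}

#' Run a single replication of a scenario
#'
#' Generates the three preceding studies, applies the scenario's
#' selection method in each, combines the selections under rules 1-3 and
#' scores every rule's known-predictor set (including the MSPE on a fresh
#' current/validation pair shared across the three rules).  Deterministic
#' given `(master_seed, scenario, rep_index)`.
#'
#' @param scenario A scenario label (e.g. `"S3_c"`) or a one-row scenario
#'   tibble.
#' @param rep_index Replication index (1-based).
#' @param config A [run_config()].
#'
#' @return A tibble with three rows (rules 1-3): scoring flags, error
#'   counts, `mspe`, and a `known_vars` list-column with the known
#'   predictor names.
#' @export
run_replication <- function(scenario, rep_index, config = run_config()) {
  if (is.character(scenario)) {
    scenario <- run_config(scenarios = scenario)$scenarios
  }
  stopifnot(nrow(scenario) == 1, rep_index >= 1)
  cs <- compile_spec(config$generator)
  seed <- replication_seed(config$master_seed, scenario$scenario,
                           as.integer(rep_index))
  res <- core_replication(cs, c(scenario$n1, scenario$n2, scenario$n3),
                          scenario$method, scenario$alpha_in,
                          config$n_current, config$n_validation, seed)
  dplyr::bind_rows(lapply(1:3, function(m) {
    row <- res$rules[[m]]$score
    row$scenario <- scenario$scenario
    row$method <- scenario$method
    row$alpha_in <- scenario$alpha_in
    row$rule <- m
    row$rep_index <- as.integer(rep_index)
    row$known_vars <- list(cs$vars[res$rules[[m]]$mask])
    row[, c("scenario", "method", "alpha_in", "rule", "rep_index",
            "exact_match", "superset_of_truth", "superset_of_top5",
            "n_false_positives", "n_false_negatives", "mspe",
            "known_vars")]
  }))
}

# Run all replications of one scenario, accumulating plain counters.
run_scenario_internal <- function(scen, config, cs) {
  n_rep <- config$n_replications
  p <- length(cs$vars)
  n_sizes <- c(scen$n1, scen$n2, scen$n3)
  counts <- list(
    exact = numeric(3), superset = numeric(3), top5 = numeric(3),
    fp = numeric(3), fn = numeric(3),
    mspe_sum = numeric(3), mspe_sq = numeric(3),
    incl = matrix(0, nrow = 3, ncol = p)
  )
  for (r in seq_len(n_rep)) {
    seed <- replication_seed(config$master_seed, scen$scenario, r)
    res <- core_replication(cs, n_sizes, scen$method, scen$alpha_in,
                            config$n_current, config$n_validation, seed)
    for (m in 1:3) {
      sc <- res$rules[[m]]$score
      counts$exact[m] <- counts$exact[m] + sc$exact_match
      counts$superset[m] <- counts$superset[m] + sc$superset_of_truth
      counts$top5[m] <- counts$top5[m] + sc$superset_of_top5
      counts$fp[m] <- counts$fp[m] + sc$n_false_positives
      counts$fn[m] <- counts$fn[m] + sc$n_false_negatives
      counts$mspe_sum[m] <- counts$mspe_sum[m] + sc$mspe
      counts$mspe_sq[m] <- counts$mspe_sq[m] + sc$mspe^2
      counts$incl[m, ] <- counts$incl[m, ] + res$rules[[m]]$mask
    }
  }
  n_none <- length(cs$none_idx)
  n_true <- length(cs$true_idx)
  rate_se <- function(p) sqrt(p * (1 - p) / n_rep)
  msf <- counts$exact / n_rep
  tpr <- counts$superset / n_rep
  dmsf <- counts$top5 / n_rep
  mspe <- counts$mspe_sum / n_rep
  mspe_var <- pmax(counts$mspe_sq / n_rep - mspe^2, 0) * n_rep / (n_rep - 1)
  summary <- tibble(
    scenario = scen$scenario, method = scen$method,
    alpha_in = scen$alpha_in, rule = 1:3,
    n_replications = n_rep,
    msf = msf, tpr = tpr, dmsf = dmsf,
    fpr = counts$fp / (n_rep * n_none),
    fnr = counts$fn / (n_rep * n_true),
    mspe = mspe,
    msf_se = rate_se(msf), tpr_se = rate_se(tpr), dmsf_se = rate_se(dmsf),
    mspe_se = if (n_rep > 1) sqrt(mspe_var / n_rep) else NA_real_
  )
  inclusion <- tibble(
    scenario = scen$scenario, method = scen$method,
    alpha_in = scen$alpha_in,
    rule = rep(1:3, each = p),
    variable = rep(cs$vars, times = 3),
    role = rep(ifelse(seq_len(p) %in% cs$true_idx, "true predictor",
                      "non-predictor"), times = 3),
    frequency = as.vector(t(counts$incl)) / n_rep
  )
  list(summary = summary, inclusion = inclusion)
}

#' Run the simulation study
#'
#' Loops over the configured scenarios and replications, aggregates the
#' six performance indicators per (scenario, rule) cell together with
#' Monte Carlo standard errors, and collects per-variable inclusion
#' frequencies.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, `summary.csv`,
#'   `inclusion.csv` and `meta.yaml` are written there.
#' @param verbose Print per-scenario progress to stderr.
#'
#' @return A `sim_results` object: list with tibbles `summary` (one row
#'   per scenario x rule) and `inclusion` (long per-variable
#'   frequencies), plus `meta` (seed, replication count, generator hash,
#'   package version).
#' @export
run_study <- function(config = run_config(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE)) {
    abort(paste0("cannot create output directory: ", out_dir))
  }
  cs <- compile_spec(config$generator)
  pieces <- lapply(seq_len(nrow(config$scenarios)), function(i) {
    scen <- config$scenarios[i, ]
    if (verbose) {
      message(sprintf("[%s] scenario %s (%d replications)",
                      format(Sys.time(), "%H:%M:%S"), scen$scenario,
                      config$n_replications))
    }
    tryCatch(
      run_scenario_internal(scen, config, cs),
      error = function(e) {
        abort(paste0("scenario ", scen$scenario, " failed: ",
                     conditionMessage(e)), parent = e)
      }
    )
  })
  results <- structure(
    list(
      summary = dplyr::bind_rows(lapply(pieces, `[[`, "summary")),
      inclusion = dplyr::bind_rows(lapply(pieces, `[[`, "inclusion")),
      meta = list(
        master_seed = config$master_seed,
        n_replications = config$n_replications,
        n_current = config$n_current,
        n_validation = config$n_validation,
        generator_hash = rlang::hash(config$generator),
        package_version = as.character(packageVersion("priorsim")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    class = "sim_results"
  )
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

#' @export
print.sim_results <- function(x, ...) {
  cat("<sim_results> ", length(unique(x$summary$scenario)),
      " scenario(s) x 3 rules, ", x$meta$n_replications,
      " replications (seed ", x$meta$master_seed, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname tidy.prs_ols
#' @export
tidy.sim_results <- function(x, ...) {
  x$summary
}

#' @rdname tidy.prs_ols
#' @export
glance.sim_results <- function(x, ...) {
  tibble(
    n_scenarios = length(unique(x$summary$scenario)),
    n_replications = x$meta$n_replications,
    master_seed = x$meta$master_seed,
    package_version = x$meta$package_version
  )
}

#' Write simulation results to CSV
#'
#' Writes `summary.csv` (one row per scenario x rule with the six
#' indicators and their Monte Carlo standard errors), `inclusion.csv`
#' (long-format per-variable inclusion frequencies) and `meta.yaml`.
#'
#' @param results A `sim_results` object.
#' @param dir Output directory (created if missing).
#' @return `results`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort(paste0("cannot create output directory: ", dir))
  }
  readr::write_csv(results$summary, file.path(dir, "summary.csv"))
  readr::write_csv(results$inclusion, file.path(dir, "inclusion.csv"))
  yaml::write_yaml(results$meta, file.path(dir, "meta.yaml"))
  invisible(results)
}
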