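#' Pipeline configuration
#'
#' Assembles the configuration for the end-to-end synthetic workflow:
#' generate a batch of channel conformers (open pores with varying degrees
#' of lumen obstruction), screen them by a fast conductance estimate below a
#' threshold, verify the screened conformers with Brownian-dynamics
#' permeation runs, fit and classify their conducting regimes, and report.
#'
#' @param base_spec A [channel_spec()] used as the open-state template.
#' @param obstruction_fractions Numeric vector, one blocked-area fraction
#'   per conformer in the batch.
#' @param thresholds List with `screen_nS`, `sigma_nS`, `r2`, `band`.
#' @param verify List controlling the verification runs: `n_max` (how many
#'   screened conformers get a BD run), `duration`, `dt` (ns).
#' @param renorm Diffusion renormalization factor applied to verified
#'   currents.
#' @param seed Master seed; all stage seeds derive from it.
#' @param structural Logical: also compute toy-ensemble structural metrics
#'   (ellipticity, PCA landscape) for the verified conformers.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(base_spec = channel_spec(),
                            obstruction_fractions = c(rep(0.5, 3), rep(0.1, 7)),
                            thresholds = list(screen_nS = 2.5, sigma_nS = 2.3,
                                              r2 = 0.99, band = c(0.40, 0.60)),
                            verify = list(n_max = 2, duration = 60, dt = 0.01),
                            renorm = 1,
                            seed = 1L,
                            structural = FALSE) {
  th <- utils::modifyList(list(screen_nS = 2.5, sigma_nS = 2.3, r2 = 0.99,
                               band = c(0.40, 0.60)), thresholds)
  if (th$screen_nS <= 0 || th$sigma_nS <= 0) stop("thresholds must be positive")
  if (th$band[1] >= th$band[2]) stop("band must be an ordered interval")
  structure(
    list(base_spec = base_spec,
         obstruction_fractions = obstruction_fractions,
         thresholds = th, verify = verify, renorm = renorm,
         seed = as.integer(seed), structural = structural),
    class = "pipeline_config"
  )
}

#' Run the end-to-end synthetic pipeline
#'
#' Stages: (1) synthesize conformer specs from the obstruction fractions;
#' (2) screen by fast closed-form conductance below `screen_nS`; (3) verify
#' up to `verify$n_max` screened conformers by BD permeation runs; (4) fit
#' and classify their conducting regimes against the open-state reference;
#' (5) optional structural metrics on matched toy ensembles; (6) assemble
#' the report. Deterministic given the config (including its seed); any
#' stage failure yields a partial report with per-stage status.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_report`: `stages` (status per stage),
#'   `screening` (summary + table), `verification` (per-conformer
#'   conductance, ratio, classification), `open_reference_nS`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  report <- list(config_hash = config_hash(config))
  fail <- function(stage, e) {
    stages[[stage]] <<- paste("failed:", conditionMessage(e))
  }

  # stage 1: synthesize conformer batch
  specs <- tryCatch({
    out <- lapply(config$obstruction_fractions, function(f) {
      s <- config$base_spec
      s$obstruction_fraction <- f
      s
    })
    stages$synthesize <- "ok"
    out
  }, error = function(e) { fail("synthesize", e); NULL })
  if (is.null(specs)) return(new_run_report(report, stages))
  open_ref <- analytic_pore_conductance(config$base_spec)
  report$open_reference_nS <- open_ref

  # stage 2: fast conductance screening
  screening <- tryCatch({
    est <- data.frame(
      conformer = seq_along(specs),
      obstruction_fraction = config$obstruction_fractions,
      conductance = vapply(specs, analytic_pore_conductance, numeric(1))
    )
    scr <- screen_conformers(est, threshold_nS = config$thresholds$screen_nS,
                             open_reference_nS = open_ref)
    stages$screen <- "ok"
    c(scr, list(table = est))
  }, error = function(e) { fail("screen", e); NULL })
  report$screening <- screening
  if (is.null(screening)) return(new_run_report(report, stages))

  # stage 3-4: BD verification + regime classification
  verification <- tryCatch({
    picks <- utils::head(screening$selected$conformer, config$verify$n_max)
    rows <- lapply(picks, function(i) {
      traj <- simulate_pore_bd(specs[[i]], duration = config$verify$duration,
                               dt = config$verify$dt,
                               seed = child_seed(config$seed, 3L, i))
      ev <- detect_crossings(traj)
      qs <- cumulative_charge(ev)
      fit <- regime_fit(qs, voltage = specs[[i]]$voltage, renorm = config$renorm)
      cls <- classify_state(fit, open_ref,
                            thresholds = list(sigma = config$thresholds$sigma_nS,
                                              r2 = config$thresholds$r2,
                                              band = config$thresholds$band))
      data.frame(conformer = i,
                 conductance = fit$segments$conductance[nrow(fit$segments)],
                 current_ratio = current_ratio(ev),
                 n_events = nrow(ev),
                 model = fit$model, state = cls$label)
    })
    stages$verify <- "ok"
    if (length(rows)) do.call(rbind, rows) else NULL
  }, error = function(e) { fail("verify", e); NULL })
  report$verification <- verification

  # stage 5: structural metrics on toy ensembles
  if (isTRUE(config$structural) && !is.null(verification)) {
    report$structural <- tryCatch({
      mk <- function(placement, cond, seed) {
        make_toy_ensemble(toy_ensemble_spec(n_frames = 20,
                                            placement = placement,
                                            seed = seed), condition = cond)
      }
      open_e <- mk("vertical", "open", child_seed(config$seed, 5L, 1L))
      closed_e <- mk("horizontal-mid-pore", "closed",
                     child_seed(config$seed, 5L, 2L))
      land <- pca_landscape(list(superpose(open_e), superpose(closed_e)))
      stages$structural <- "ok"
      list(ellipticity_open = mean(ellipticity_series(open_e)),
           ellipticity_closed = mean(ellipticity_series(closed_e)),
           pc_variance = land$explained[1:2])
    }, error = function(e) { fail("structural", e); NULL })
  }

  stages$report <- "ok"
  new_run_report(report, stages)
}

new_run_report <- function(report, stages) {
  report$stages <- stages
  class(report) <- "run_report"
  report
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "base_spec")]), tmp)
  cat(deparse(unclass(config$base_spec)), file = tmp, append = TRUE)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline report (config", substr(x$config_hash, 1, 8), ")\n")
  for (s in names(x$stages)) cat("  stage", s, ":", x$stages[[s]], "\n")
  if (!is.null(x$screening)) {
    cat(sprintf("  screening: %d / %d conformers below %.2f nS (%d%% of open %.2f nS)\n",
                x$screening$summary$n_selected, x$screening$summary$n_total,
                x$screening$summary$threshold_nS,
                x$screening$summary$percent_of_open, x$open_reference_nS))
  }
  if (!is.null(x$verification)) {
    cat("  verification:\n")
    print(x$verification, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
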