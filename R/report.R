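# Reporting layer: one entry point that ties a configuration to a full run
# and emits the published table shapes as delimited text and JSON, with a
# run manifest for reproducibility.  Reporting conventions: GBP to whole
# pounds, life years and QALYs to 2 decimal places, death fractions to
# whole percent; machine-readable JSON keeps full precision.

round_tidy_cea <- function(td) {
  rnd <- function(metric, v) {
    dplyr::case_when(
      metric == "deaths" ~ round(100 * v),
      metric %in% c("ly", "qaly") ~ round(v, 2),
      TRUE ~ round(v))
  }
  dplyr::mutate(td,
                dplyr::across(c("mm", "lvad", "incremental"),
                              ~ rnd(.data$metric, .x)))
}

#' Run a full analysis and write report files
#'
#' Loads (or accepts) a parameter set, optionally applies a named scenario,
#' runs the deterministic model over each horizon, and writes per-horizon
#' cost-effectiveness tables, the shortfall/severity table, the cohort
#' traces, and optionally the one-way sensitivity (tornado), PSA and CEAC
#' outputs, plus a run manifest.  Logging goes to standard error; results
#' only to files.
#'
#' @param output_dir Directory for report files (created if missing).
#' @param config Path to a YAML configuration, or `NULL` to use `params`.
#' @param params Parameter set used when `config` is `NULL`; defaults to
#'   the packaged calibrated synthetic set.
#' @param scenario Scenario name (`"base"`, `"btt"`, `"intermacs1"`, ...).
#' @param horizons Months per horizon; `Inf` is the lifetime horizon.
#' @param genpop_qalys General-population remaining QALYs for the shortfall
#'   analysis.
#' @param seed Seed used for the PSA (and recorded in the manifest).
#' @param psa_n PSA draws; 0 skips the PSA/CEAC.
#' @param owsa_ranges Ranges tibble for [run_owsa()], or `NULL` to skip.
#' @param wtp_max,wtp_step CEAC willingness-to-pay grid settings.
#' @param life_table Life table; `NULL` uses the packaged synthetic table.
#' @return Invisibly, a list with the `lvad_cea_run`, optional `psa`,
#'   `ceac` and `tornado`, and the manifest.
#' @export
#' @examples
#' \donttest{
#' out <- run_analysis(tempfile("report"), horizons = c(24, Inf))
#' names(out)
#' }
run_analysis <- function(output_dir, config = NULL, params = NULL,
                         scenario = "base", horizons = c(24, 60, Inf),
                         genpop_qalys = 10.84, seed = 1L, psa_n = 0,
                         owsa_ranges = NULL, wtp_max = 100000, wtp_step = 1000,
                         life_table = NULL) {
  t0 <- Sys.time()
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  params <- if (!is.null(config)) load_parameters(config) else
    (params %||% default_parameters())
  life_table <- life_table %||% default_life_table()
  params <- apply_scenario(params, scenario)
  message(sprintf("running scenario '%s' over %d horizon(s)", scenario,
                  length(horizons)))

  snapshot <- file.path(output_dir, "config_used.yaml")
  write_parameters(params, snapshot)

  cea <- run_cea(params, horizons = horizons, genpop_qalys = genpop_qalys,
                 life_table = life_table)
  td <- tidy(cea)
  for (nm in names(cea$horizons)) {
    sub <- round_tidy_cea(dplyr::filter(td, .data$horizon == nm))
    write.csv(sub, file.path(output_dir, paste0("cea_", nm, ".csv")),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(dplyr::filter(td, .data$horizon == nm),
                         file.path(output_dir, paste0("cea_", nm, ".json")),
                         dataframe = "rows", na = "null", digits = NA)
  }
  if (!is.null(cea$shortfall)) {
    sf <- dplyr::mutate(cea$shortfall,
                        dplyr::across(c("comparator_qalys", "genpop_qalys",
                                        "absolute", "proportional"), ~ round(.x, 2)),
                        dplyr::across(c("icer_per_qaly", "weighted_icer"), round))
    write.csv(sf, file.path(output_dir, "shortfall.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(cea$shortfall, file.path(output_dir, "shortfall.json"),
                         dataframe = "rows", na = "null", digits = NA)
  }
  for (arm in c("LVAD", "MM")) {
    write_trace(run_cohort(params, arm, max(vapply(horizons, resolve_horizon,
                                                   integer(1), params = params)),
                           life_table),
                file.path(output_dir, paste0("trace_", tolower(arm), ".csv")))
  }

  tornado <- NULL
  if (!is.null(owsa_ranges)) {
    message("one-way sensitivity analysis over ", nrow(owsa_ranges), " parameters")
    tornado <- run_owsa(params, owsa_ranges, life_table = life_table)
    write_tornado(tornado, file.path(output_dir, "tornado.csv"))
  }
  psa <- NULL
  ceac <- NULL
  if (psa_n > 0) {
    message("probabilistic sensitivity analysis: ", psa_n, " draws, seed ", seed)
    psa <- run_psa(params, n = psa_n, seed = seed, life_table = life_table)
    write.csv(psa$summary, file.path(output_dir, "psa_summary.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(glance(psa), file.path(output_dir, "psa_summary.json"),
                         dataframe = "rows", na = "null", digits = NA)
    ceac <- compute_ceac(psa, seq(0, wtp_max, by = wtp_step))
    write_ceac(ceac, file.path(output_dir, "ceac.csv"))
  }

  manifest <- list(
    config_checksum = unname(tools::md5sum(snapshot)),
    seed = seed, scenario = scenario,
    horizons = vapply(horizons, resolve_horizon, integer(1), params = params),
    package_version = as.character(packageVersion("lvadcea")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cea = cea, psa = psa, ceac = ceac, tornado = tornado,
                 manifest = manifest))
}
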