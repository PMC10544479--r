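## Report generation: machine-readable CSV/JSON outputs for every analysis
## stage, a collated markdown report, and a run manifest with checksums.

write_csv_out <- function(df, path) {
  write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

#' Write a run manifest
#'
#' Records the run's provenance: timestamp, package version, seed, source
#' configuration and an MD5 checksum for every produced file. Re-running with
#' the manifest's config and seed reproduces all stochastic outputs exactly.
#'
#' @param out_dir directory holding the outputs.
#' @param files character vector of output file paths.
#' @param seed integer seed used for the run (or `NA`).
#' @param config path of the parameter file used (or `NA`).
#' @return path of the written `manifest.json`, invisibly.
#' @export
write_run_manifest <- function(out_dir, files, seed = NA, config = NA) {
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(packageVersion("abxcea")),
    seed = seed,
    config = config,
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Verify a run manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_run_manifest()].
#' @return `TRUE` if every listed output exists and matches its checksum,
#'   otherwise an error naming the first mismatch.
#' @export
verify_run_manifest <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  for (o in m$outputs) {
    f <- file.path(dir, o$file)
    if (!file.exists(f)) stop("manifest output missing: ", o$file, call. = FALSE)
    if (!identical(unname(tools::md5sum(f)), o$md5)) {
      stop("checksum mismatch for ", o$file, call. = FALSE)
    }
  }
  TRUE
}

#' Run the full analysis and write a report
#'
#' Evaluates the decision model, ranks strategies (both the frontier and the
#' all-strategies view), runs the tornado and the probabilistic sensitivity
#' analysis with CE-plane and acceptability-curve summaries, and writes
#' everything under `out_dir` as CSVs plus a collated markdown report and a
#' checksummed manifest. Human-readable tables round euros and QALDs to 2
#' decimals and probabilities to 4; the CSVs keep full precision.
#'
#' @param params a validated `cea_parameters` object.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the PSA.
#' @param iterations PSA iterations (default from the parameter set).
#' @param config optional path of the parameter file, recorded in the
#'   manifest.
#' @return invisibly, a named list of all result objects.
#' @export
run_report <- function(params, out_dir, seed = 1L, iterations = NULL,
                       config = NA) {
  stopifnot(inherits(params, "cea_parameters"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtp <- params$settings$wtp_per_qald

  results <- evaluate_strategies(params)
  cea <- rank_strategies(results, wtp)
  torn <- run_tornado(params)
  psa <- run_psa(params, iterations = iterations, seed = seed)
  pair <- attr(torn, "pair")
  plane <- ce_plane_summary(psa, pair, wtp)
  grid <- seq(0, params$settings$wtp_grid_max %||% (2 * wtp),
              length.out = params$settings$wtp_grid_points %||% 41)
  curve <- ceac(psa, grid)

  files <- c(
    write_csv_out(results, file.path(out_dir, "strategy_results.csv")),
    write_csv_out(cea, file.path(out_dir, "cea_table_all.csv")),
    write_csv_out(frontier(cea), file.path(out_dir, "cea_table_frontier.csv")),
    write_csv_out(torn, file.path(out_dir, "tornado.csv")),
    write_csv_out(psa, file.path(out_dir, "psa_iterations.csv")),
    write_csv_out(curve, file.path(out_dir, "ceac.csv"))
  )
  plane_df <- data.frame(quadrant = names(plane$quadrants),
                         proportion = as.numeric(plane$quadrants))
  files <- c(files, write_csv_out(plane_df, file.path(out_dir, "ce_plane.csv")))

  report <- file.path(out_dir, "report.md")
  writeLines(render_report_md(results, cea, torn, plane, curve, wtp, pair),
             report)
  files <- c(files, report)
  write_run_manifest(out_dir, files, seed = seed, config = config)

  invisible(list(results = results, cea = cea, tornado = torn, psa = psa,
                 plane = plane, ceac = curve))
}

render_report_md <- function(results, cea, torn, plane, curve, wtp, pair) {
  fmt2 <- function(x) formatC(x, format = "f", digits = 2)
  fmt4 <- function(x) formatC(x, format = "f", digits = 4)
  lines <- c(
    "# Cost-effectiveness report",
    "",
    sprintf("Willingness to pay: %.1f euros/QALD.", wtp),
    "",
    "## Expected cost and effectiveness per strategy",
    "",
    "| Strategy | Cost (euros) | Effectiveness (QALDs) |",
    "|---|---|---|",
    sprintf("| %s | %s | %s |", results$strategy,
            fmt2(results$cost_total), fmt2(results$effect_qald)),
    "",
    "## Incremental analysis (all strategies, ascending cost)",
    "",
    "| Strategy | Cost | Incr. cost | Effect | Incr. effect | ICER | NMB | Status |",
    "|---|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s | %s | %s | %s |",
            cea$strategy, fmt2(cea$cost), fmt2(cea$incr_cost),
            fmt2(cea$effect), fmt2(cea$incr_effect), fmt2(cea$icer),
            fmt2(cea$nmb), cea$status),
    "",
    sprintf("## One-way sensitivity of the %s vs %s ICER", pair[1], pair[2]),
    "",
    "| Parameter | Direction | Low ICER | High ICER |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %s |", torn$parameter, torn$direction,
            fmt2(torn$low_icer), fmt2(torn$high_icer)),
    "",
    "## Probabilistic sensitivity analysis",
    "",
    sprintf("%s vs %s over %d iterations: quadrant shares I %s, II %s, III %s, IV %s;",
            pair[1], pair[2], plane$n,
            fmt4(plane$quadrants[["I"]]), fmt4(plane$quadrants[["II"]]),
            fmt4(plane$quadrants[["III"]]), fmt4(plane$quadrants[["IV"]])),
    sprintf("acceptable at WTP in %s of iterations.", fmt4(plane$prop_acceptable)),
    "",
    sprintf("Acceptability at WTP %.1f: %s.", wtp,
            paste(sprintf("%s %s",
                          setdiff(names(curve), "wtp"),
                          fmt4(as.numeric(curve[which.min(abs(curve$wtp - wtp)),
                                                setdiff(names(curve), "wtp")]))),
                  collapse = ", "))
  )
  lines
}
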