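#' @title End-to-end pipeline orchestration
#' @name cli_pipeline
#' @description
#' `run_all()` drives the full analysis: read (or simulate) records,
#' resolve taxa, split into per-(study, habitat) networks, compute metrics,
#' run the domestic-host removal null model, draw rarefaction curves, and
#' fit the habitat/latitude models. Every stage writes a CSV into the
#' output directory and a YAML manifest captures the configuration and
#' seeds, so a rerun with the same config reproduces the outputs exactly.
NULL

#' Build a run configuration
#'
#' @param records_path CSV of blood-meal records, or `NULL` to simulate.
#' @param sympatry_path optional sympatry-table CSV.
#' @param domestic_path optional domestic-host list file.
#' @param out_dir output directory (created if missing).
#' @param ie_mode IE denominator mode.
#' @param n_reps null-model replicates.
#' @param seed integer seed used for simulation and the null model.
#' @param rarefaction_knots grid knots per rarefaction curve.
#' @param simulate_scenario a `synthetic_config` used when `records_path`
#'   is `NULL` (default [default_scenario()] under `seed`).
#' @param skip_rarefaction,skip_null_model,skip_glm optionally skip stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(records_path = NULL, sympatry_path = NULL,
                       domestic_path = NULL, out_dir = tempfile("bmn_run_"),
                       ie_mode = "realized_links", n_reps = 100L,
                       seed = 1L, rarefaction_knots = 40L,
                       simulate_scenario = NULL,
                       skip_rarefaction = FALSE, skip_null_model = FALSE,
                       skip_glm = FALSE) {
  structure(list(records_path = records_path, sympatry_path = sympatry_path,
                 domestic_path = domestic_path, out_dir = out_dir,
                 ie_mode = ie_mode, n_reps = as.integer(n_reps),
                 seed = as.integer(seed),
                 rarefaction_knots = as.integer(rarefaction_knots),
                 simulate_scenario = simulate_scenario,
                 skip_rarefaction = isTRUE(skip_rarefaction),
                 skip_null_model = isTRUE(skip_null_model),
                 skip_glm = isTRUE(skip_glm)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(y), allowed)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' Network inventory summary
#'
#' The headline description of a compiled network set: number of networks
#' per habitat, links per habitat, total blood meals, size of the
#' aggregated global network, per-habitat mean interaction evenness (both
#' denominator modes) and overall mean H2'.
#'
#' @param networks a `network_set`.
#' @param metrics optional precomputed [summarise_networks()] table for the
#'   default (realized-links) mode.
#' @return list of named summary values.
#' @export
reproduce_inventory <- function(networks, metrics = NULL) {
  nets <- networks$networks
  if (is.null(metrics)) metrics <- summarise_networks(networks)
  metrics_cells <- summarise_networks(networks, ie_mode = "all_cells",
                                      h2 = FALSE)
  agg <- aggregate_global(networks)
  habs <- vapply(nets, `[[`, character(1), "habitat")
  links <- vapply(nets, function(n) sum(n$weights > 0), numeric(1))
  per_hab <- function(x, f) vapply(split(x, habs), f, numeric(1))
  list(
    n_networks = length(nets),
    networks_per_habitat = table(factor(habs, levels = HABITAT_LEVELS)),
    links_per_habitat = per_hab(links, sum),
    total_bloodmeals = sum(vapply(nets, function(n) sum(n$weights),
                                  numeric(1))),
    aggregated_hosts = ncol(agg$weights),
    aggregated_diptera = nrow(agg$weights),
    aggregated_links = sum(agg$weights > 0),
    mean_ie_realized_links = vapply(
      split(metrics$IE, metrics$habitat),
      function(x) mean(x, na.rm = TRUE), numeric(1)),
    mean_ie_all_cells = vapply(
      split(metrics_cells$IE, metrics_cells$habitat),
      function(x) mean(x, na.rm = TRUE), numeric(1)),
    mean_h2prime = mean(metrics$H2prime[!grepl("h2_degenerate",
                                               metrics$flags)], na.rm = TRUE))
}

#' Run the full pipeline
#'
#' Executes records -> networks -> metrics -> null model -> rarefaction ->
#' models, writing each stage's CSV plus `manifest.yaml` into
#' `config$out_dir`. A stage failure keeps earlier outputs on disk and is
#' re-raised with the stage name.
#'
#' @param config a `run_config`.
#' @return (invisibly) list with all stage results: `records`,
#'   `resolution_log`, `networks`, `metrics`, `inventory`, `null_results`,
#'   `null_summary`, `rarefaction`, `glm` (term tables, Tukey contrasts,
#'   richness models), `manifest`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage ", sQuote(name), " failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  path <- function(f) file.path(config$out_dir, f)

  out$records <- stage("records_io", {
    if (!is.null(config$records_path)) {
      rec <- read_records(config$records_path)
    } else {
      scenario <- config$simulate_scenario
      if (is.null(scenario)) scenario <- default_scenario(config$seed)
      sim <- generate_dataset(scenario)
      out$truth <- sim$truth
      rec <- sim$records
    }
    sym <- if (!is.null(config$sympatry_path))
      read_sympatry(config$sympatry_path) else NULL
    res <- resolve_taxa(rec, sym)
    out$resolution_log <- res$log
    write_records(res$records, path("records_resolved.csv"))
    res$records
  })

  out$networks <- stage("network_build", {
    ns <- split_networks(out$records)
    utils::write.csv(do.call(rbind, lapply(ns$networks, edge_list)),
                     path("edges.csv"), row.names = FALSE)
    ns
  })

  out$metrics <- stage("metrics", {
    met <- summarise_networks(out$networks, ie_mode = config$ie_mode)
    utils::write.csv(met, path("metrics.csv"), row.names = FALSE)
    met
  })
  out$inventory <- reproduce_inventory(out$networks, out$metrics)

  if (!config$skip_null_model) {
    out$null_results <- stage("null_model", {
      domestic <- if (!is.null(config$domestic_path))
        read_domestic_hosts(config$domestic_path) else default_domestic_hosts()
      res <- run_null_models(out$networks, domestic,
                             n_reps = config$n_reps, seed = config$seed,
                             ie_mode = config$ie_mode)
      utils::write.csv(null_model_table(res), path("nullmodel.csv"),
                       row.names = FALSE)
      res
    })
    out$null_summary <- summarise_null_by_habitat(out$null_results)
    utils::write.csv(out$null_summary, path("nullmodel_habitat.csv"),
                     row.names = FALSE)
  }

  if (!config$skip_rarefaction) {
    out$rarefaction <- stage("rarefaction", {
      rt <- rarefaction_table(out$networks,
                              n_knots = config$rarefaction_knots)
      utils::write.csv(rt, path("rarefaction.csv"), row.names = FALSE)
      rt
    })
  }

  if (!config$skip_glm) {
    out$glm <- stage("glm_stage", {
      tbl <- metrics_table(out$metrics)
      terms_ie <- term_table(tbl, "IE")
      terms_h2 <- term_table(tbl, "H2prime")
      terms_ie$response <- "IE"
      terms_h2$response <- "H2prime"
      terms <- rbind(terms_ie, terms_h2)
      utils::write.csv(terms, path("glm_terms.csv"), row.names = FALSE)
      tukey <- tukey_habitat(tbl, "IE")
      utils::write.csv(tukey, path("tukey_ie.csv"), row.names = FALSE)
      rich <- lapply(c("host_richness", "diptera_richness"), function(r) {
        fit <- richness_latitude_model(tbl, r)
        cbind(response = r, attr(fit, "latitude_test"))
      })
      rich <- do.call(rbind, rich)
      utils::write.csv(rich, path("richness_latitude.csv"),
                       row.names = FALSE)
      list(table = tbl, terms = terms, tukey = tukey,
           richness_latitude = rich)
    })
  }

  out$manifest <- list(
    package = "bloodmealnets",
    version = as.character(utils::packageVersion("bloodmealnets")),
    seed = config$seed,
    ie_mode = config$ie_mode,
    n_reps = config$n_reps,
    records_path = if (is.null(config$records_path)) "simulated"
                   else config$records_path,
    n_networks = length(out$networks$networks),
    total_bloodmeals = out$inventory$total_bloodmeals,
    stages_skipped = c(rarefaction = config$skip_rarefaction,
                       null_model = config$skip_null_model,
                       glm = config$skip_glm))
  yaml::write_yaml(out$manifest, path("manifest.yaml"))
  invisible(out)
}
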