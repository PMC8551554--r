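#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline], with every
#' stage's parameters at its documented default. Any element can be
#' overridden via `...` (named, possibly nested lists are merged shallowly
#' per section). A YAML file with the same structure can be loaded with
#' [load_pipeline_config].
#'
#' @param output_dir Where stage outputs and the manifest are written.
#' @param ... Section overrides, e.g. `simulate = list(n_hc = 12)`.
#' @return Named configuration list.
#' @export
pipeline_config <- function(output_dir = tempfile("eegsourcenet_"), ...) {
  cfg <- list(
    output_dir = output_dir,
    seed = 1,
    simulate = list(n_hc = 12, n_pd = 12, duration = 60, fs = 250,
                    n_regions = 68, n_sensors = 96, sensor_noise_sd = 0.1,
                    kappa_off = 5, kappa_on = 0),
    preprocess = list(f_lo = 1, f_hi = 30, epoch_s = 2, p2p_limit = 150),
    inverse = list(lambda2 = 1 / 9, depth_gamma = 0.8),
    bands = names(canonical_bands()),
    connectivity = list(measure = "plv", epoch_scheme = "epochs"),
    graph = list(grid = seq(0.05, 0.5, by = 0.05)),
    stats = list(n_perm_psd = 1000, n_perm_nbs = 1000, edge_alpha = 0.05,
                 component_alpha = 0.01, fdr_q = 0.05))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose sections mirror [pipeline_config].
#' @return Configuration list (defaults filled in for missing entries).
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> inverse -> spectral -> connectivity ->
#' graph metrics -> group statistics on a synthetic cohort, writing TSV/JSON
#' outputs and a reproducibility manifest (seed, config, package version)
#' under `config$output_dir`. Fully deterministic for a fixed config.
#'
#' @param config List from [pipeline_config] (or [load_pipeline_config]).
#' @param keep_data Also return the intermediate per-subject objects
#'   (memory-heavy; default FALSE).
#' @return List with `psd_tests`, `graph_tests`, `nbs_off_on`,
#'   `edge_summary`, `manifest_file` and (optionally) `data`.
#' @export
run_pipeline <- function(config = pipeline_config(), keep_data = FALSE) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- config$simulate
  specs <- stage("simulate", default_study_specs(
    duration = sim$duration, fs = sim$fs, n_regions = sim$n_regions,
    seed = config$seed, kappa_off = sim$kappa_off, kappa_on = sim$kappa_on))
  lf <- make_toy_lead_field(sim$n_sensors, sim$n_regions,
                            seed = derive_seed(config$seed, "leadfield"))
  study <- stage("simulate", simulate_group_study(
    specs$hc, specs$pd_off, specs$pd_on, n_hc = sim$n_hc, n_pd = sim$n_pd,
    lead_field = lf, sensor_noise_sd = sim$sensor_noise_sd))

  op <- compute_wmne_operator(lf, inverse_spec(config$inverse$lambda2,
                                               config$inverse$depth_gamma))
  labels <- if (sim$n_regions == 68) dk_region_labels() else
    sprintf("region%02d", seq_len(sim$n_regions))

  to_sources <- function(rec) {
    pp <- config$preprocess
    ep <- preprocess_recording(rec, pp$f_lo, pp$f_hi, pp$epoch_s, pp$p2p_limit)
    clean <- epochs_to_recording(ep)
    vts <- apply_inverse(op, clean)
    parcellate(vts, labels, region_order = labels, fs = rec$fs)
  }
  src <- stage("preprocess+inverse", list(
    hc = lapply(study$hc, to_sources),
    pd_off = lapply(study$pd_off, to_sources),
    pd_on = lapply(study$pd_on, to_sources)))

  ## spectral group tests: independent HC vs PD-OFF, paired OFF vs ON
  st <- config$stats
  psd_tests <- stage("spectral", {
    summ <- lapply(src, cohort_band_summary)
    rows <- list()
    for (bn in config$bands) {
      hcp <- summ$hc$power[summ$hc$band == bn]
      offp <- summ$pd_off$power[summ$pd_off$band == bn]
      onp <- summ$pd_on$power[summ$pd_on$band == bn]
      rows[[length(rows) + 1L]] <- data.frame(
        band = bn,
        p_hc_vs_off = permutation_test(hcp, offp, n_perm = st$n_perm_psd,
                                       seed = derive_seed(config$seed, paste0("psd-i-", bn)))$p,
        p_off_vs_on = permutation_test(offp, onp, paired = TRUE,
                                       n_perm = st$n_perm_psd,
                                       seed = derive_seed(config$seed, paste0("psd-p-", bn)))$p,
        power_ratio_off_hc = mean(offp) / mean(hcp))
    }
    do.call(rbind, rows)
  })

  ## graph metrics and group tests
  graph_tests <- stage("graphmetrics", {
    sweep_arm <- function(arm) {
      do.call(rbind, lapply(seq_along(src[[arm]]), function(s) {
        out <- do.call(rbind, lapply(config$bands, function(bn) {
          cmat <- connectivity_matrix(src[[arm]][[s]], bn,
                                      measure = config$connectivity$measure,
                                      epoch_scheme = config$connectivity$epoch_scheme)
          d <- graph_metric_sweep(cmat, grid = config$graph$grid)
          d$band <- bn
          d
        }))
        out$subject <- s
        out
      }))
    }
    sw <- list(hc = sweep_arm("hc"), pd_off = sweep_arm("pd_off"),
               pd_on = sweep_arm("pd_on"))
    utils::write.table(
      do.call(rbind, lapply(names(sw), function(a) cbind(arm = a, sw[[a]]))),
      file.path(config$output_dir, "graph_metrics.tsv"),
      sep = "\t", row.names = FALSE)
    list(hc_vs_off = graph_metric_group_test(sw$hc, sw$pd_off, q = st$fdr_q),
         off_vs_on = graph_metric_group_test(sw$pd_off, sw$pd_on,
                                             paired = TRUE, q = st$fdr_q))
  })

  ## edgewise NBS: paired OFF vs ON per band
  nbs_off_on <- stage("netstats", {
    res <- list()
    for (bn in config$bands) {
      cm_off <- lapply(src$pd_off, connectivity_matrix, band = bn,
                       measure = config$connectivity$measure,
                       epoch_scheme = config$connectivity$epoch_scheme)
      cm_on <- lapply(src$pd_on, connectivity_matrix, band = bn,
                      measure = config$connectivity$measure,
                      epoch_scheme = config$connectivity$epoch_scheme)
      res[[bn]] <- nbs(cm_off, cm_on, stat_spec(
        n_perm_psd = st$n_perm_psd, n_perm_nbs = st$n_perm_nbs,
        edge_alpha = st$edge_alpha, component_alpha = st$component_alpha,
        paired = TRUE, seed = derive_seed(config$seed, paste0("nbs-", bn))))
    }
    res
  })
  edge_summary <- tryCatch(
    edge_count_summary(nbs_edge_table(nbs_off_on,
                                      alpha = st$component_alpha)),
    error = function(e) NULL)

  manifest <- list(
    package_version = as.character(utils::packageVersion("eegsourcenet")),
    seed = config$seed, config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  manifest_file <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(psd_tests = psd_tests,
         planted_edges = specs$planted_edges,
         nbs_significant = lapply(nbs_off_on, function(r)
           list(increase = r$increase$p_values, decrease = r$decrease$p_values))),
    file.path(config$output_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")

  out <- list(psd_tests = psd_tests, graph_tests = graph_tests,
              nbs_off_on = nbs_off_on, edge_summary = edge_summary,
              planted_edges = specs$planted_edges,
              manifest_file = manifest_file)
  if (keep_data) out$data <- list(study = study, sources = src)
  out
}
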