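#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run so that the configuration
#' echoed into the output manifest suffices to reproduce the run.
#'
#' @param samples Path to `samples.csv`.
#' @param traits Path to `traits.csv`.
#' @param out_dir Output directory.
#' @param bin_width_velocity,bin_width_depth Bin widths (m/s, m);
#'   default 0.05.
#' @param substrate_levels Substrate category codes.
#' @param ffg_threshold FFG membership threshold (1-10); default 3.
#' @param groups Organism groups to analyse; default
#'   [analysis_groups()].
#' @param strategy Campaign combination strategy,
#'   `"envelope_fill"` (default) or `"pointwise_max"`.
#' @param fill_threshold Plateau anchor threshold for `envelope_fill`;
#'   default 0.8.
#' @param permutations ANOSIM permutations; default 999.
#' @param seed Integer seed for the run's RNG.
#' @param normalize_k Normalize K components by their dataset maxima
#'   before weighting; default `FALSE`.
#' @return List of class `hsc_config`.
#' @export
run_config <- function(samples, traits, out_dir,
                       bin_width_velocity = 0.05, bin_width_depth = 0.05,
                       substrate_levels = substrate_codes(),
                       ffg_threshold = 3, groups = analysis_groups(),
                       strategy = "envelope_fill", fill_threshold = 0.8,
                       permutations = 999, seed = 1,
                       normalize_k = FALSE) {
  structure(list(samples = samples, traits = traits, out_dir = out_dir,
                 bin_width_velocity = bin_width_velocity,
                 bin_width_depth = bin_width_depth,
                 substrate_levels = substrate_levels,
                 ffg_threshold = ffg_threshold, groups = groups,
                 strategy = strategy, fill_threshold = fill_threshold,
                 permutations = permutations, seed = seed,
                 normalize_k = normalize_k),
            class = "hsc_config")
}

#' Run the habitat-suitability pipeline end-to-end
#'
#' In order: (1) ANOSIM pre-check of between-campaign differences in
#' community structure (Bray-Curtis on ln(1+count)-transformed
#' counts) -> `anosim.json`; (2) per-campaign and combined curve sets
#' for every group x parameter -> `curves.csv`; (3) final combined
#' HSCs -> `hsc.csv`; (4) K coefficients -> `krecords.csv` and the
#' binned K upper envelope against the community SI-HUC ->
#' `k_envelope.csv`; (5) a machine-readable manifest (configuration
#' echo, seed, package version, collected warnings) ->
#' `manifest.json`. Output is deterministic given the configuration.
#'
#' @param config An `hsc_config` object (see [run_config()]).
#' @return Invisibly, a list with the in-memory results (`anosim`,
#'   `curvesets`, `finals`, `krecords`, `warnings`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hsc_config"))
  warnings_log <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }, message = function(m) {
      warnings_log <<- c(warnings_log, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  }
  stage <- function(name, expr) {
    tryCatch(collect(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- stage("read", read_dataset(config$samples, config$traits,
                                        config$substrate_levels))
  membership <- stage("ffg", assign_ffg(dataset$traits,
                                        config$ffg_threshold))

  # ANOSIM pooling pre-check across campaigns
  res_anosim <- NULL
  campaigns <- sort(unique(dataset$env$campaign_id))
  if (length(campaigns) >= 2) {
    res_anosim <- stage("anosim", {
      d <- bray_curtis(log_density_transform(dataset$comm))
      anosim_test(d, dataset$env$campaign_id,
                  permutations = config$permutations, seed = config$seed)
    })
    write_anosim(res_anosim, file.path(config$out_dir, "anosim.json"))
  }

  # shared bin schemes over the full dataset
  bins <- list(
    velocity = default_bins("velocity", values = dataset$env$velocity,
                            width = config$bin_width_velocity),
    depth = default_bins("depth", values = dataset$env$depth,
                         width = config$bin_width_depth),
    substrate = default_bins("substrate",
                             categories = config$substrate_levels))

  scopes <- c(as.list(campaigns), "combined")
  curvesets <- list()
  finals <- list()
  curve_rows <- list()
  final_rows <- list()
  for (group in config$groups) {
    for (param in names(bins)) {
      sets <- list()
      for (scope in scopes) {
        cs <- tryCatch(
          stage(paste("curves", group, param, scope, sep = "/"),
                suitability_curves(dataset, membership, group, param,
                                   bins = bins[[param]], campaign = scope)),
          error = function(e) {
            warnings_log <<- c(warnings_log, conditionMessage(e))
            NULL
          })
        if (is.null(cs)) next
        sets[[as.character(scope)]] <- cs
        curve_rows[[length(curve_rows) + 1]] <- as.data.frame(cs)
      }
      curvesets[[paste(group, param, sep = ".")]] <- sets
      per_campaign <- sets[setdiff(names(sets), "combined")]
      if (length(per_campaign)) {
        strat <- if (bins[[param]]$kind == "categorical") "pointwise_max"
                 else config$strategy
        fin <- stage(paste("combine", group, param, sep = "/"),
                     combine_campaigns(per_campaign, strategy = strat,
                                       fill_threshold = config$fill_threshold))
        finals[[paste(group, param, sep = ".")]] <- fin
        final_rows[[length(final_rows) + 1]] <- as.data.frame(fin)
      }
    }
  }
  write_curve_csv <- function(rows, path) {
    df <- do.call(rbind, lapply(rows, function(r) {
      for (col in c("bin_lo", "bin_hi", "category"))
        if (!(col %in% names(r))) r[[col]] <- NA
      r
    }))
    utils::write.csv(df, path, row.names = FALSE)
  }
  write_curve_csv(curve_rows, file.path(config$out_dir, "curves.csv"))
  write_curve_csv(final_rows, file.path(config$out_dir, "hsc.csv"))

  krecords <- stage("kparam", k_coefficients(dataset, config$normalize_k))
  utils::write.csv(as.data.frame(krecords),
                   file.path(config$out_dir, "krecords.csv"),
                   row.names = FALSE)
  kenv_rows <- list()
  for (param in names(bins)) {
    cs <- curvesets[[paste("COMMUNITY", param, sep = ".")]][["combined"]]
    if (is.null(cs)) next
    env <- stage(paste("k_envelope", param, sep = "/"),
                 k_upper_envelope(krecords, dataset, bins[[param]],
                                  si_huc = cs$si_huc))
    kenv_rows[[param]] <- data.frame(
      parameter = param, bin = bins[[param]]$labels,
      k_envelope = env$envelope, si_huc = cs$si_huc,
      abs_diff = env$abs_diff, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, kenv_rows),
                   file.path(config$out_dir, "k_envelope.csv"),
                   row.names = FALSE)

  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("hscurves")),
    n_samples = nrow(dataset$env),
    n_taxa = ncol(dataset$comm),
    campaigns = campaigns,
    empty_membership_taxa = attr(membership, "empty"),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(anosim = res_anosim, curvesets = curvesets, finals = finals,
                 krecords = krecords, warnings = warnings_log))
}
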