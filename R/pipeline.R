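#' Validate a pipeline run configuration
#'
#' Checks the configuration document for [run_pipeline()]: required keys
#' present, no unknown keys, basic type sanity. Errors name the path of
#' the offending key (e.g. `config$doses`).
#'
#' @param config a named list (typically from a JSON file).
#' @return the validated config, with defaults filled in.
#' @export
validate_config <- function(config) {
  known <- c("rates", "doses", "n_block_modes", "conc_ACh", "n_cells",
             "n_events", "seed", "amplitudes", "noise_sd", "sample_rate",
             "filter_cutoff", "td_ms", "tau_crit_ms", "free", "n_starts",
             "voltages", "vsens_block", "render")
  required <- c("rates", "doses")
  if (is.null(names(config)) && length(config))
    stop("config must be a named list")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste0("config$", unknown, collapse = ", "))
  for (k in required)
    if (is.null(config[[k]]))
      stop("missing required key: config$", k)
  if (!length(config$doses)) stop("config$doses is empty")
  defaults <- list(n_block_modes = 1, conc_ACh = 100, n_cells = 3,
                   n_events = 3000, seed = 1,
                   amplitudes = c(closed = 0, open = 7), noise_sd = 1,
                   sample_rate = 25000, filter_cutoff = 10000,
                   td_ms = 0.2, tau_crit_ms = 50, free = NULL,
                   n_starts = 3, voltages = 0, vsens_block = 0,
                   render = TRUE)
  utils::modifyList(defaults, config)
}

# Stable hash of the configuration for provenance stamping.
.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full simulate-idealize-fit-summarize pipeline
#'
#' Orchestrates the dose-dependence analysis chain on synthetic data:
#' generate recordings for every (cell, dose), idealize the traces by SKM,
#' impose the dead time, fit the blockade rate constants per dataset by
#' MIL (gating/desensitization rates held at the generating values, the
#' blockade rates free), and summarize blocking/unblocking kinetics across
#' doses. Stage outputs land under `out_dir` together with a manifest;
#' identical config and seed reproduce identical outputs. With
#' `resume = TRUE`, stages whose outputs already exist are skipped.
#'
#' @param config a configuration list, see [validate_config()]; may also
#'   be a path to a JSON config file.
#' @param out_dir output directory.
#' @param seed optional master-seed override.
#' @param resume skip stages whose outputs are already on disk.
#' @return the `blockade_summary`, invisibly; side effect: files in
#'   `out_dir` (`manifest.json`, per-dataset DWT files, `rates.csv`,
#'   `summary.json`), all stamped with the config hash.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, resume = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config)
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  hash <- .config_hash(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_file <- function(f) file.path(out_dir, f)
  manifest <- list(config_hash = hash, seed = cfg$seed, stages = list(),
                   version = as.character(utils::packageVersion("scblock")))
  flush_manifest <- function()
    jsonlite::write_json(manifest, stage_file("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_stage <- function(name, expr) {
    manifest$stages[[name]] <<- "running"; flush_manifest()
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- paste("failed:", conditionMessage(e))
      flush_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- "done"; flush_manifest()
    res
  }

  # simulate
  exp_cfg <- cfg[intersect(names(cfg),
                           c("rates", "doses", "n_block_modes", "conc_ACh",
                             "n_cells", "n_events", "seed", "amplitudes",
                             "noise_sd", "sample_rate", "filter_cutoff",
                             "voltages", "vsens_block", "render"))]
  sim <- run_stage("simulate", synth_experiment(exp_cfg))

  # idealize
  td <- cfg$td_ms / 1000
  ideal_path <- stage_file("idealized.dwt")
  ideal <- if (resume && file.exists(ideal_path)) {
    segs <- read_dwt(ideal_path)
    names(segs) <- names(sim$datasets)
    segs
  } else run_stage("idealize", {
    out <- lapply(sim$datasets, function(ds) {
      ev <- if (!is.null(ds$trace)) skm_idealize(ds$trace)
            else aggregate_classes(ds$dwells)
      impose_dead_time(ev, td)
    })
    write_dwt(out, ideal_path)
    out
  })

  # fit (blockade rates per dataset at non-zero dose)
  free <- cfg$free
  if (is.null(free))
    free <- if (cfg$n_block_modes == 1) c("kB_on", "kB_off")
            else c("kB_on_fast", "kB_off_fast", "kB_on_slow", "kB_off_slow")
  scheme <- build_blockade_scheme(cfg$rates, cfg$n_block_modes,
                                  vsens_block = cfg$vsens_block)
  fits <- run_stage("fit", {
    idx <- which(sim$manifest$dose > 0)
    lapply(idx, function(i) {
      id <- sim$manifest$id[i]
      f <- fit_mil(scheme,
                   list(list(dwells = ideal[[id]],
                             cond = sim$datasets[[id]]$cond)),
                   free = free, n_starts = cfg$n_starts, dead_time = td)
      list(id = id, cell = sim$manifest$cell[i],
           dose = sim$manifest$dose[i], fit = f)
    })
  })

  # analyze
  summary_out <- run_stage("analyze", {
    rf <- blockade_rate_frame(lapply(fits, `[[`, "fit"),
                              cells = vapply(fits, `[[`, 0, "cell"),
                              doses = vapply(fits, `[[`, 0, "dose"))
    rates_csv <- stage_file("rates.csv")
    con <- file(rates_csv, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    utils::write.csv(rf, con, row.names = FALSE)
    close(con)
    bs <- blocking_kinetics(rf)
    js <- list(config_hash = hash, seed = cfg$seed,
               summary = lapply(bs, function(s)
                 s[setdiff(names(s), "per_dose")]),
               per_dose = lapply(bs, `[[`, "per_dose"))
    jsonlite::write_json(js, stage_file("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    bs
  })
  invisible(summary_out)
}
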