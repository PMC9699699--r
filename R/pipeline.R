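#' Run the full analysis pipeline from a config
#'
#' Orchestrates \code{simulate -> analyze -> report} from a single
#' structured configuration (YAML file or nested list). Every stage output
#' is a pure function of config + seed: running the same config twice
#' produces byte-identical metric tables. With \code{resume: true} a stage
#' whose outputs already exist is skipped.
#'
#' Config schema (version 1; unknown keys are errors):
#' \preformatted{
#' version: 1
#' seed: 7
#' out_dir: runs/demo
#' stages: [simulate, analyze, report]
#' simulate:
#'   stages: [DIV3, DIV14, DIV28]   # default: all seven
#'   conditions: [healthy, toxic]
#'   n_cells: 10
#'   duration_s: 300
#'   fs: 5
#'   n_images: 3
#' params:
#'   r: 0.7            # neuropil ratio (applied when neuropil traces exist)
#'   k: 3              # event threshold, SD multiples
#'   cutoff: 0.8       # N/C classification cutoff
#'   n_rest: 5         # F0 rest-window width
#'   smooth_window: 3
#'   band_edges_mHz: [0, 10, 100, 300]
#' resume: false
#' timestamps: false   # keep reports byte-identical by default
#' }
#'
#' @param config path to a YAML file or a nested list.
#' @return (invisibly) a \code{run_report}: list with the per-view metric
#'   table, per-image morphometry table, profile tables, comparisons and a
#'   provenance block.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(provenance = list(config = cfg, seed = cfg$seed,
                                   package_version =
                                     as.character(utils::packageVersion("catrace"))))
  if (isTRUE(cfg$timestamps)) report$provenance$timestamp <- format(Sys.time())
  if ("simulate" %in% cfg$stages) .pipeline_simulate(cfg)
  if ("analyze" %in% cfg$stages) report <- .pipeline_analyze(cfg, report)
  if ("report" %in% cfg$stages) report <- .pipeline_report(cfg, report)
  class(report) <- "run_report"
  invisible(report)
}

.config_defaults <- function() {
  list(version = 1, seed = 1, out_dir = "catrace_run",
       stages = c("simulate", "analyze", "report"),
       simulate = list(stages = paste0("DIV", c(3, 6, 10, 14, 17, 21, 28)),
                       conditions = c("healthy", "toxic"),
                       n_cells = 10, duration_s = 300, fs = 5, n_images = 3),
       params = list(r = 0.7, k = 3, cutoff = 0.8, n_rest = 5,
                     smooth_window = 3, band_edges_mHz = c(0, 10, 100, 300)),
       resume = FALSE, timestamps = FALSE)
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML path or a list")
  defaults <- .config_defaults()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in c("simulate", "params")) {
    bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(bad)) stop("unknown ", blk, " key(s): ",
                          paste(bad, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("invalid parameter: seed")
  }
  with(cfg$params, {
    if (r < 0 || r > 1) stop("invalid parameter: r")
    if (k <= 0) stop("invalid parameter: k")
    if (cutoff < 0) stop("invalid parameter: cutoff")
  })
  bad_stage <- setdiff(cfg$stages, c("simulate", "analyze", "report"))
  if (length(bad_stage)) stop("unknown stage(s): ",
                              paste(bad_stage, collapse = ", "))
  cfg
}

.view_seed <- function(seed, i_stage, i_cond) {
  (seed * 7919 + i_stage * 101 + i_cond) %% 2147483647
}

.sim_grid <- function(cfg) {
  expand.grid(stage = cfg$simulate$stages, cond = cfg$simulate$conditions,
              stringsAsFactors = FALSE)
}

.pipeline_simulate <- function(cfg) {
  presets <- build_stage_presets()
  mpresets <- build_morph_presets()
  grid <- .sim_grid(cfg)
  sim_dir <- file.path(cfg$out_dir, "simulated")
  dir.create(sim_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(grid))) {
    stage <- grid$stage[i]; cond <- grid$cond[i]
    stem <- file.path(sim_dir, paste0(stage, "_", cond))
    trace_file <- paste0(stem, "_traces.csv")
    if (isTRUE(cfg$resume) && file.exists(trace_file)) next
    vseed <- .view_seed(cfg$seed, match(stage, cfg$simulate$stages),
                        match(cond, cfg$simulate$conditions))
    view <- simulate_view(get_preset(presets, stage, cond),
                          n_cells = cfg$simulate$n_cells,
                          duration_s = cfg$simulate$duration_s,
                          fs = cfg$simulate$fs, seed = vseed)
    write_traces_csv(view, trace_file)
    truth <- do.call(rbind, lapply(seq_along(view$truth_events), function(ci) {
      ev <- view$truth_events[[ci]]
      if (!nrow(ev)) return(NULL)
      data.frame(cell = paste0("cell", ci), ev)
    }))
    if (is.null(truth)) truth <- data.frame(cell = character(0),
                                            time = numeric(0),
                                            amplitude = numeric(0))
    utils::write.csv(truth, paste0(stem, "_truth.csv"), row.names = FALSE)
    for (j in seq_len(cfg$simulate$n_images)) {
      img <- render_neuron_image(get_preset(mpresets, stage, cond),
                                 seed = vseed + j)
      write_image_tiff(img, paste0(stem, "_img", j, ".tif"))
      utils::write.csv(
        data.frame(truth_length = img$truth_length,
                   truth_soma_area = img$truth_soma_area,
                   truth_nc_ratio = img$truth_nc_ratio,
                   pixel_size = img$pixel_size,
                   center_row = img$soma_center[1],
                   center_col = img$soma_center[2]),
        paste0(stem, "_img", j, "_truth.csv"), row.names = FALSE)
    }
  }
  invisible(NULL)
}

.pipeline_analyze <- function(cfg, report) {
  grid <- .sim_grid(cfg)
  sim_dir <- file.path(cfg$out_dir, "simulated")
  p <- cfg$params
  view_rows <- list(); morph_rows <- list()
  for (i in seq_len(nrow(grid))) {
    stage <- grid$stage[i]; cond <- grid$cond[i]
    div <- as.integer(sub("DIV", "", stage))
    stem <- file.path(sim_dir, paste0(stage, "_", cond))
    tr <- read_traces_csv(paste0(stem, "_traces.csv"))
    dffs <- list(); tabs <- list()
    for (ci in seq_len(nrow(tr$traces))) {
      x <- tr$traces[ci, ] - tr$background
      dff <- to_dff(x, background = 0,
                    f0 = compute_f0(x, n_rest = p$n_rest), fs = tr$fs)
      tab <- detect_events(dff, k = p$k, smooth_window = p$smooth_window)
      tabs[[ci]] <- waveform_metrics(dff, tab)
      dffs[[ci]] <- dff
    }
    names(tabs) <- rownames(tr$traces)
    write_events_csv(tabs, paste0(stem, "_events.csv"))
    freq <- vapply(tabs, event_frequency_mHz, numeric(1))
    amp <- unlist(lapply(tabs, `[[`, "amplitude"))
    fwhm <- unlist(lapply(tabs, `[[`, "fwhm"))
    sync <- view_synchrony(do.call(rbind, lapply(dffs, `[[`, "values")))
    bf <- band_fractions(view_spectrum(dffs, fs = tr$fs),
                         edges_mHz = p$band_edges_mHz)
    view_rows[[i]] <- data.frame(
      div = div, condition = cond,
      frequency_mHz = mean(freq),
      amplitude = if (length(amp)) mean(amp, na.rm = TRUE) else NA_real_,
      fwhm = if (length(fwhm)) mean(fwhm, na.rm = TRUE) else NA_real_,
      synchrony = sync$mean_coefficient,
      ultra_slow_pct = bf[[1]], slow_pct = bf[[2]], fast_pct = bf[[3]])
    for (j in seq_len(cfg$simulate$n_images)) {
      img_px <- read_image_tiff(paste0(stem, "_img", j, ".tif"))
      masks <- lapply(c("nucleus", "cytosol", "soma", "neurites", "background"),
                      function(nm) read_image_tiff(
                        paste0(stem, "_img", j, "_mask_", nm, ".tif")) > 0.5)
      names(masks) <- c("nucleus", "cytosol", "soma", "neurites", "background")
      truth <- utils::read.csv(paste0(stem, "_img", j, "_truth.csv"))
      ncr <- nc_ratio_and_class(img_px, masks$nucleus, masks$cytosol,
                                cutoff = p$cutoff)
      morph_rows[[length(morph_rows) + 1]] <- data.frame(
        div = div, condition = cond, image = j,
        nc_ratio = ncr$nc_ratio, nuclear_class = ncr$nuclear_class,
        soma_area = soma_area(masks$soma, truth$pixel_size),
        neurite_length = total_neurite_length(masks$neurites,
                                              truth$pixel_size),
        contrast = image_contrast(mean(img_px[masks$soma]),
                                  mean(img_px[masks$background])))
    }
  }
  report$view_metrics <- do.call(rbind, view_rows)
  report$morphometry <- do.call(rbind, morph_rows)
  utils::write.csv(report$view_metrics,
                   file.path(cfg$out_dir, "view_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$morphometry,
                   file.path(cfg$out_dir, "morphometry.csv"),
                   row.names = FALSE)
  report
}

.pipeline_report <- function(cfg, report) {
  if (is.null(report$view_metrics)) {
    vm_file <- file.path(cfg$out_dir, "view_metrics.csv")
    if (!file.exists(vm_file)) stop("missing upstream output: ", vm_file)
    report$view_metrics <- utils::read.csv(vm_file)
    report$morphometry <- utils::read.csv(file.path(cfg$out_dir,
                                                    "morphometry.csv"))
  }
  vm <- report$view_metrics; mo <- report$morphometry
  profiles <- list()
  for (cond in unique(vm$condition)) {
    for (metric in c("frequency_mHz", "amplitude", "fwhm", "synchrony")) {
      prof <- stage_profiles(vm[vm$condition == cond, ], value_col = metric,
                             metric_name = paste0(metric, ":", cond))
      profiles[[paste0(metric, ":", cond)]] <- prof
    }
    for (metric in c("soma_area", "neurite_length", "nc_ratio")) {
      prof <- stage_profiles(mo[mo$condition == cond, ], value_col = metric,
                             metric_name = paste0(metric, ":", cond))
      profiles[[paste0(metric, ":", cond)]] <- prof
    }
  }
  report$profiles <- profiles
  prof_tab <- do.call(rbind, lapply(names(profiles), function(nm) {
    data.frame(metric = nm, as.data.frame(profiles[[nm]]))
  }))
  utils::write.csv(prof_tab, file.path(cfg$out_dir, "stage_profiles.csv"),
                   row.names = FALSE)
  # growth rates for the morphological profiles
  rates <- lapply(profiles[grep("^(soma_area|neurite_length)", names(profiles))],
                  function(p) if (nrow(p) >= 2) growth_rates(p) else NULL)
  rate_tab <- do.call(rbind, lapply(names(rates), function(nm) {
    if (is.null(rates[[nm]])) return(NULL)
    data.frame(metric = nm, rates[[nm]])
  }))
  if (!is.null(rate_tab)) {
    utils::write.csv(rate_tab, file.path(cfg$out_dir, "growth_rates.csv"),
                     row.names = FALSE)
  }
  report$growth_rates <- rates
  # healthy functional-vs-structural profile correlations
  ph <- profiles[paste0(c("amplitude", "frequency_mHz", "neurite_length"),
                        ":healthy")]
  if (all(!vapply(ph, is.null, logical(1))) &&
      nrow(ph[[1]]) >= 3 && identical(ph[[1]]$div, ph[[3]]$div)) {
    report$correlations <- list(
      amplitude_vs_length = profile_correlation(ph[[3]], ph[[1]]),
      frequency_vs_length = profile_correlation(ph[[3]], ph[[2]]))
  }
  # healthy-vs-toxic comparison at the last shared stage
  comps <- list()
  if (length(unique(vm$condition)) == 2) {
    last_div <- max(vm$div)
    for (metric in c("frequency_mHz", "amplitude", "fwhm", "synchrony")) {
      gr <- split(vm[vm$div == last_div, metric],
                  vm[vm$div == last_div, "condition"])
      if (all(vapply(gr, length, integer(1)) >= 2)) {
        comps[[metric]] <- group_compare(gr)
      }
    }
    gr <- split(mo[mo$div == last_div, "soma_area"],
                mo[mo$div == last_div, "condition"])
    if (all(vapply(gr, length, integer(1)) >= 2)) {
      comps$soma_area <- group_compare(gr)
    }
  }
  report$comparisons <- comps
  .write_report_md(cfg, report)
  report
}

.write_report_md <- function(cfg, report) {
  lines <- c("# catrace run report", "",
             "## Provenance", "",
             paste0("- seed: ", cfg$seed),
             paste0("- package version: ",
                    report$provenance$package_version),
             paste0("- stages: ", paste(cfg$stages, collapse = ", ")),
             paste0("- conditions: ",
                    paste(cfg$simulate$conditions, collapse = ", ")))
  if (!is.null(report$provenance$timestamp)) {
    lines <- c(lines, paste0("- timestamp: ", report$provenance$timestamp))
  }
  if (!is.null(report$view_metrics)) {
    lines <- c(lines, "", "## Per-view metrics (head)", "",
               utils::capture.output(print(utils::head(report$view_metrics))))
  }
  if (length(report$comparisons)) {
    lines <- c(lines, "", "## Healthy vs toxic (last stage)", "")
    for (nm in names(report$comparisons)) {
      cc <- report$comparisons[[nm]]
      lines <- c(lines, sprintf("- %s: t = %.3f, p = %.3g %s", nm,
                                cc$statistic, cc$p_value, cc$stars))
    }
  }
  writeLines(lines, file.path(cfg$out_dir, "report.md"))
  invisible(NULL)
}
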