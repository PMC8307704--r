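#' Pipeline run configuration
#'
#' Single configuration object for an end-to-end run: synthetic section
#' phantom -> fiber metrics, synthetic morphometry table -> healing indices
#' and group statistics, synthetic scar time-series -> planimetry summary
#' and day-3 area comparison. All randomness derives from the single `seed`.
#'
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @param box_side side of the flanking analysis boxes in pixels (500 in the
#'   standard full-resolution layout; the default demo scale is smaller so a
#'   complete run takes seconds).
#' @param scar_kappa,flank_kappa orientation concentrations of the simulated
#'   scar and flanking regions.
#' @param target_density simulated collagen fraction.
#' @param ratio_threshold,window_radius_px,local_radius_px fiber-analysis
#'   parameters ([fiber_params()]); the local variance radius defaults to the
#'   standard 50 px.
#' @param n_per_group animals per group in the simulated morphometry table.
#' @param alpha significance threshold of the statistical pipeline.
#' @param write_heatmaps write local-variance and density heatmap PNGs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("scarkit_run_"),
                            box_side = 150, scar_kappa = 0, flank_kappa = 5,
                            target_density = 0.6, ratio_threshold = 1,
                            window_radius_px = 8, local_radius_px = 50,
                            n_per_group = 9, alpha = 0.05,
                            write_heatmaps = FALSE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 box_side = box_side, scar_kappa = scar_kappa,
                 flank_kappa = flank_kappa, target_density = target_density,
                 ratio_threshold = ratio_threshold,
                 window_radius_px = window_radius_px,
                 local_radius_px = local_radius_px,
                 n_per_group = as.integer(n_per_group), alpha = alpha,
                 write_heatmaps = write_heatmaps),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Demo five-region layout scaled to the configured box side (internal).
demo_layout <- function(side) {
  gap <- ceiling(side / 5)
  xs <- gap + (0:4) * (side + gap)  # LD LP S RP RD left-to-right
  region_layout(
    scar = region_box(xs[3], gap, side),
    LD = c(xs[1], gap), LP = c(xs[2], gap),
    RP = c(xs[4], gap), RD = c(xs[5], gap),
    box_side = side)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> fiber analysis -> morphometry -> planimetry -> group
#' statistics and writes per-stage outputs (CSV tables, JSON statistics, an
#' optional heatmap PNG pair, and a log with the configuration hash) into
#' `config$out_dir`. Deterministic per seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`fiber_metrics`,
#'   `index_summary`, `morpho_stats`, `planimetry_summary`, `area_day3`) and
#'   the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  log <- function(stage, msg)
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%H:%M:%S"), stage, msg),
        file = log_path, append = TRUE)
  cat(sprintf("config md5 %s\n", unname(tools::md5sum(tf))), file = log_path)
  unlink(tf)

  ## fiber stage -------------------------------------------------------
  t0 <- proc.time()[3]
  layout <- demo_layout(config$box_side)
  mk_spec <- function(kappa, mean_deg, seed_off)
    phantom_spec(image_height_px = max(64, config$box_side),
                 image_width_px = max(64, config$box_side),
                 n_fibers = 4000, kappa = kappa,
                 mean_orientation_deg = mean_deg,
                 target_density = config$target_density,
                 fiber_length_px = max(20, round(config$box_side / 8)),
                 seed = config$seed + seed_off)
  specs <- list(S = mk_spec(config$scar_kappa, 90, 11),
                LD = mk_spec(config$flank_kappa, 0, 12),
                LP = mk_spec(config$flank_kappa, 0, 13),
                RP = mk_spec(config$flank_kappa, 0, 14),
                RD = mk_spec(config$flank_kappa, 0, 15))
  sec <- generate_section_phantom(specs, layout)
  params <- fiber_params(config$ratio_threshold, config$window_radius_px,
                         config$local_radius_px)
  metrics <- analyze_section(sec$image, layout, params)
  utils::write.csv(metrics, file.path(config$out_dir, "fiber_metrics.csv"),
                   row.names = FALSE)
  if (config$write_heatmaps) {
    cmap <- segment_collagen(sec$image, config$ratio_threshold)
    field <- estimate_orientation_field(cmap, config$window_radius_px)
    loc <- local_directional_variance(field, config$local_radius_px)
    m <- loc$map; m[is.na(m)] <- 0
    png::writePNG(m, file.path(config$out_dir, "local_variance_heatmap.png"))
    png::writePNG(cmap$weight, file.path(config$out_dir, "density_heatmap.png"))
  }
  log("fibers", sprintf("5 regions analyzed in %.1fs", proc.time()[3] - t0))

  ## morphometry stage -------------------------------------------------
  t0 <- proc.time()[3]
  tab <- generate_morphometry_table(
    morphometry_sim_spec(n_per_group = config$n_per_group,
                         seed = config$seed + 20))
  idx <- index_table(tab)
  utils::write.csv(idx$summary,
                   file.path(config$out_dir, "index_summary.csv"),
                   row.names = FALSE)
  morpho_stats <- lapply(measurement_vars(), function(v) {
    lapply(split(tab, tab$day), function(dd) {
      et <- data.frame(value = dd[[v]], group = dd$group, endpoint = v,
                       day = dd$day[1])
      unclass(run_endpoint(et, config$alpha))
    })
  })
  names(morpho_stats) <- measurement_vars()
  jsonlite::write_json(morpho_stats,
                       file.path(config$out_dir, "morphometry_stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log("morphometry", sprintf("%d endpoints in %.1fs", length(morpho_stats),
                             proc.time()[3] - t0))

  ## planimetry stage --------------------------------------------------
  t0 <- proc.time()[3]
  ts <- generate_scar_timeseries(seed = config$seed + 30)
  summ <- build_timeseries(ts)
  utils::write.csv(summ, file.path(config$out_dir, "planimetry_summary.csv"),
                   row.names = FALSE)
  d3 <- ts[ts$day == 3, ]
  area_day3 <- run_endpoint(data.frame(value = d3$area_mm2, group = d3$group,
                                       endpoint = "area_mm2", day = 3),
                            config$alpha)
  jsonlite::write_json(unclass(area_day3),
                       file.path(config$out_dir, "area_day3_stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log("planimetry", sprintf("%d records in %.1fs", nrow(ts),
                            proc.time()[3] - t0))

  invisible(list(fiber_metrics = metrics, index_summary = idx$summary,
                 morpho_stats = morpho_stats, planimetry_summary = summ,
                 area_day3 = area_day3, out_dir = config$out_dir))
}
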