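#' Read a pipeline run configuration
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return Named list (validated lazily by [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
}

#' Validate a run configuration before any computation
#'
#' Collects every schema violation into a single error so a bad config fails
#' fast and completely.
#'
#' @param config Named list (see [run_pipeline()]).
#' @return `config`, invisibly, on success.
#' @export
validate_run_config <- function(config) {
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(is.list(config), "config must be a list")
  need(is.numeric(config$pixel_size_um %||% NA) &&
         isTRUE(config$pixel_size_um > 0),
       "pixel_size_um missing or not a positive number")
  need(is.numeric(config$seed %||% NA) && is.finite(config$seed %||% NA),
       "seed missing")
  need(is.character(config$out_dir %||% NA) && nzchar(config$out_dir %||% ""),
       "out_dir missing")
  stages <- config$stages %||% character()
  known <- c("synth", "quantify", "motility", "wound", "report")
  need(length(stages) > 0, "stages missing or empty")
  bad <- setdiff(stages, known)
  need(length(bad) == 0, paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  if ("quantify" %in% stages)
    need(is.list(config$phantoms$conditions %||% NULL),
         "quantify stage needs phantoms$conditions")
  if ("motility" %in% stages)
    need(is.list(config$tracks$conditions %||% NULL),
         "motility stage needs tracks$conditions")
  if ("wound" %in% stages)
    need(is.numeric(config$wound$width_um %||% NA),
         "wound stage needs wound$width_um")
  if (length(problems))
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(config)
}

#' Run the full quantification pipeline from a configuration
#'
#' Orchestrates synthetic-data generation, segmentation + intensity
#' quantification, motility analytics, wound-healing analysis and group
#' reporting, writing one CSV/JSON per product into `out_dir`. Every random
#' decision consumes a seed derived from `config$seed`, so a rerun of the
#' same configuration reproduces every output byte for byte. Failures on
#' individual cells are logged and skipped; their count is reported in the
#' run metadata.
#'
#' @param config Configuration list or path to a YAML/JSON file. Required
#'   fields: `pixel_size_um`, `seed`, `out_dir`, `stages` (subset of
#'   `synth`, `quantify`, `motility`, `wound`, `report`). Stage blocks:
#'   `phantoms` (`n_per_condition`, `noise_sd_frac`, `conditions`, each a
#'   list with `enrichment_fold` and `nc_ratio`), `segmentation` (`offset`,
#'   `ring_thickness_um`, `box_size_um`, `nucleus_dilation_um`), `tracks`
#'   (`conditions`, each a trajectory model spec), `wound` (`width_um`,
#'   `closure_rate_um_per_h`, `timepoints_h`), `report` (`control`).
#' @return Invisibly, a list with the in-memory results and the paths of all
#'   files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  px <- config$pixel_size_um
  seed0 <- as.integer(config$seed)
  paths <- character()
  results <- list()
  skipped <- 0L

  if (any(c("synth", "quantify") %in% stages) &&
      !is.null(config$phantoms$conditions)) {
    seg <- config$segmentation %||% list()
    box_px <- max(2L, round((seg$box_size_um %||% 3.88) / px))
    conds <- names(config$phantoms$conditions)
    n_rep <- config$phantoms$n_per_condition %||% 3L
    recs <- list()
    for (ci in seq_along(conds)) {
      cp <- config$phantoms$conditions[[ci]]
      for (rep_i in seq_len(n_rep)) {
        cell_seed <- seed0 + 101L * ci + rep_i
        rec <- tryCatch({
          spec <- cell_phantom_spec(
            image_size_px = config$phantoms$image_size_px %||% 160,
            pixel_size_um = px,
            enrichment_fold = cp$enrichment_fold %||% 1,
            nc_ratio = cp$nc_ratio %||% 1,
            n_protrusions = cp$n_protrusions %||% 0,
            noise = list(type = "gaussian",
                         sd_frac = config$phantoms$noise_sd_frac %||% 0.05),
            seed = cell_seed)
          ph <- make_cell_image(spec)
          quantify_cell(ph$stack, seg, box_px, seed = cell_seed,
                        cell_id = sprintf("%s_%02d", conds[ci], rep_i),
                        condition = conds[ci])
        }, error = function(e) {
          message("run_pipeline: skipping cell ", conds[ci], "_", rep_i, ": ",
                  conditionMessage(e))
          skipped <<- skipped + 1L
          NULL
        })
        if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
      }
    }
    records <- do.call(rbind, recs)
    if ("quantify" %in% stages && !is.null(records)) {
      ctrl <- config$report$control %||% conds[1]
      records <- do.call(rbind, lapply(split(records, records$region),
        function(d) normalize_to_control(d, ctrl)))
      records <- records[order(records$region, records$condition,
                               records$cell_id), , drop = FALSE]
      rownames(records) <- NULL
      p <- file.path(out_dir, "quant_records.csv")
      write_records(records, p)
      paths <- c(paths, p)
      results$records <- records
    }
  }

  if ("motility" %in% stages) {
    conds <- names(config$tracks$conditions)
    all_tracks <- list(); speed_rows <- list(); msd_rows <- list()
    fits <- list()
    for (ci in seq_along(conds)) {
      tc <- config$tracks$conditions[[ci]]
      tracks <- if (!is.null(tc$path)) read_tracks(tc$path)
      else {
        spec <- trajectory_spec(
          model = tc$model, n_tracks = tc$n_tracks %||% 40,
          dt_h = tc$dt_h %||% (1 / 6), duration_h = tc$duration_h %||% 16,
          D_um2_h = tc$D_um2_h, speed_um_h = tc$speed_um_h,
          persistence = tc$persistence, S0_um_h = tc$S0_um_h,
          S_inf_um_h = tc$S_inf_um_h, half_life_h = tc$half_life_h,
          speed_cv = tc$speed_cv %||% 0, seed = seed0 + 977L * ci)
        simulate_tracks(spec)$tracks
      }
      all_tracks[[conds[ci]]] <- tracks
      speed_rows[[ci]] <- data.frame(
        condition = conds[ci],
        track_id = vapply(tracks, `[[`, character(1), "track_id"),
        speed_um_h = vapply(tracks, average_speed, numeric(1)),
        stringsAsFactors = FALSE)
      m <- msd(tracks)
      msd_rows[[ci]] <- cbind(condition = conds[ci], as.data.frame(m))
      fit <- fit_msd_linear(m)
      cls <- classify_motion(m)
      fits[[conds[ci]]] <- list(slope_um2_h = fit$slope,
                                intercept_um2 = fit$intercept,
                                r_squared = fit$r_squared,
                                alpha = cls$alpha, class = cls$class)
    }
    speeds <- do.call(rbind, speed_rows)
    p1 <- file.path(out_dir, "speeds.csv"); write_records(speeds, p1)
    p2 <- file.path(out_dir, "msd.csv")
    write_records(do.call(rbind, msd_rows), p2)
    p3 <- file.path(out_dir, "msd_fits.json")
    jsonlite::write_json(fits, p3, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p1, p2, p3)
    results$speeds <- speeds
    results$msd_fits <- fits
    results$tracks <- all_tracks
  }

  if ("wound" %in% stages) {
    wc <- config$wound
    series <- make_wound_series(
      width_um = wc$width_um,
      closure_rate_um_per_h = wc$closure_rate_um_per_h %||% 0,
      timepoints_h = wc$timepoints_h %||% c(0, 6, 12, 18, 24),
      pixel_size_um = wc$pixel_size_um %||% 1, seed = seed0 + 4999L)
    wp <- list(pixel_size_um = wc$pixel_size_um %||% 1)
    areas <- vapply(series$frames, function(f) wound_area(f, wp)$area_um2,
                    numeric(1))
    ws <- residual_series(areas, series$timepoints_h)
    p <- file.path(out_dir, "wound_series.csv")
    write_records(as.data.frame(ws), p)
    paths <- c(paths, p)
    results$wound <- ws
  }

  if ("report" %in% stages) {
    ctrl <- config$report$control %||% NULL
    if (!is.null(results$speeds)) {
      sm <- summarize_groups(results$speeds$speed_um_h,
                             results$speeds$condition)
      p <- file.path(out_dir, "speed_summary.csv"); write_records(sm, p)
      paths <- c(paths, p)
      results$speed_summary <- sm
      if (!is.null(ctrl) && length(unique(results$speeds$condition)) >= 2 &&
          all(table(results$speeds$condition) >= 2)) {
        cmp <- compare_groups(results$speeds$speed_um_h,
                              results$speeds$condition, control = ctrl)
        p <- file.path(out_dir, "speed_comparisons.csv")
        write_records(cmp$posthoc, p)
        paths <- c(paths, p)
        results$speed_comparison <- cmp
      }
    }
    if (!is.null(results$records)) {
      cortex <- results$records[results$records$region == "cortex_random", ]
      if (nrow(cortex)) {
        sm <- summarize_groups(cortex$fold, cortex$condition)
        p <- file.path(out_dir, "cortex_fold_summary.csv")
        write_records(sm, p)
        paths <- c(paths, p)
        results$cortex_summary <- sm
      }
    }
  }

  meta <- list(package = "cellquant",
               version = as.character(utils::packageVersion("cellquant")),
               seed = seed0, skipped_cells = skipped,
               stages = stages, config = config)
  pm <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, pm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, pm)
  invisible(c(results, list(paths = paths, skipped_cells = skipped)))
}

# Segment one phantom stack and emit its quantification records.
quantify_cell <- function(stack, seg, box_px, seed, cell_id, condition) {
  actin <- project(stack, "actin", "average")
  dapi <- project(stack, "dapi", "average")
  poi <- project(stack, "poi", "max")
  pcnt <- project(stack, "pcnt", "max")
  sp <- list(offset = seg$offset %||% 0.05, window_px = seg$window_px)
  cell <- segment_cell(actin, sp)
  nuc <- segment_nucleus(dapi, cell, sp)
  ring <- cortical_ring(cell, seg$ring_thickness_um %||% 2,
                        stack$pixel_size_um)
  boxes <- select_random_boxes(ring, nuc, box_px, n = 2,
                               dilation_um = seg$nucleus_dilation_um %||% 2,
                               pixel_size_um = stack$pixel_size_um,
                               seed = seed)
  region <- apply_protrusion_boxes(ring, boxes)
  cmask <- centrosome_mask(pcnt)
  data.frame(
    cell_id = cell_id, condition = condition, batch = "run1",
    region = c("cortex_random", "nucleus", "whole_cell", "centrosome"),
    value = c(mean_intensity(region, poi),
              nc_ratio(nuc, cell, poi),
              mean_intensity(cell, poi),
              centrosome_total_intensity(cmask, poi)),
    stringsAsFactors = FALSE)
}
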