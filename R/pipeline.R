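# Per-cell orchestration of the full analysis chain and batch experiments.
#
# One cropped stack = one cell. The chain: background subtraction on both
# channels -> synapse-plane detection (structural channel) -> intensity
# masking -> COF / axial distance / axial dispersion (reporter channel) ->
# footprint segmentation + g(r) + g_ave at the synapse plane. A failure of
# the clustering stage flags that field; it does not abort the cell.

#' Analysis configuration
#'
#' @param detection A [synapse_detection_params()].
#' @param reporter_rule A [threshold_rule()] for the reporter-channel mask.
#'   The default (95th percentile of nonzero voxels) is stricter than the
#'   detection mask: in a single-cell crop, background voxels outnumber
#'   reporter-signal voxels severalfold and the localization metrics weight
#'   every masked voxel, so the cut sits above the background noise tail
#'   under a shot-noise camera model.
#' @param segmentation A [segmentation_params()].
#' @param bin_width g(r) radial bin width, um (NULL: one pixel pitch).
#' @param r_max g_ave cutoff radius, um (conventionally 0.25 or 0.5).
#' @param reporter,structural Channel names.
#' @return Object of class `analysis_config` carrying a parameter hash.
#' @export
analysis_config <- function(detection = synapse_detection_params(),
                            reporter_rule = threshold_rule(p = 95),
                            segmentation = segmentation_params(),
                            bin_width = NULL, r_max = 0.5,
                            reporter = "reporter", structural = "structural") {
  cfg <- list(detection = detection, reporter_rule = reporter_rule,
              segmentation = segmentation, bin_width = bin_width, r_max = r_max,
              reporter = reporter, structural = structural)
  cfg$param_hash <- rlang::hash(cfg[setdiff(names(cfg), "param_hash")])
  structure(cfg, class = "analysis_config")
}

empty_report_row <- function(cell_id, condition, status, hash) {
  tibble::tibble(
    cell_id = cell_id, condition = condition, status = status,
    synapse_plane = NA_integer_, synapse_z_um = NA_real_,
    cof_x_um = NA_real_, cof_y_um = NA_real_, cof_z_um = NA_real_,
    cof_distance_um = NA_real_, axial_dispersion_um = NA_real_,
    n_voxels = NA_integer_, g_ave = NA_real_, param_hash = hash
  )
}

#' Analyze one cell stack
#'
#' @param stack A two-channel [voxel_stack()] (one cropped cell).
#' @param config An [analysis_config()].
#' @param cell_id,condition Identifiers carried into the report.
#' @return One-row tibble (a cell report). `status` is `"ok"`,
#'   `"no-synapse"`, `"no-signal"`, or `"ok-no-clustering"`; numeric fields
#'   of failed stages are NA.
#' @export
analyze_cell <- function(stack, config = analysis_config(),
                         cell_id = "cell", condition = NA_character_) {
  row <- empty_report_row(cell_id, condition, "ok", config$param_hash)

  bg_s <- estimate_background(stack, config$structural)
  bg_r <- estimate_background(stack, config$reporter)
  stack <- subtract_background(stack, bg_s, config$structural)
  stack <- subtract_background(stack, bg_r, config$reporter)

  synapse <- tryCatch(
    detect_synapse_plane(stack, config$detection),
    synloc_no_synapse = function(e) NULL,
    synloc_synapse_above_stack = function(e) NULL
  )
  if (is.null(synapse)) {
    row$status <- "no-synapse"
    return(row)
  }
  row$synapse_plane <- synapse$plane_index
  row$synapse_z_um <- synapse$plane_z_um

  mask <- sufficient_intensity_mask(stack, config$reporter, config$reporter_rule)
  metrics <- tryCatch(
    localization_metrics(stack, config$reporter, mask, synapse),
    synloc_no_signal = function(e) NULL
  )
  if (is.null(metrics)) {
    row$status <- "no-signal"
    return(row)
  }
  row$cof_x_um <- metrics$cof$x
  row$cof_y_um <- metrics$cof$y
  row$cof_z_um <- metrics$cof$z
  row$cof_distance_um <- metrics$cof_distance_um
  row$axial_dispersion_um <- metrics$axial_dispersion_um
  row$n_voxels <- metrics$n_voxels

  g_ave <- tryCatch({
    k <- synapse$plane_index
    struct_plane <- channel_data(stack, config$structural)[k, , ]
    rep_plane <- channel_data(stack, config$reporter)[k, , ]
    fp <- segment_synapse_mask(struct_plane, config$segmentation,
                               pixel_size = stack$geometry$dx)
    corr <- pair_autocorrelation(rep_plane, fp, bin_width = config$bin_width,
                                 pixel_size = stack$geometry$dx)
    clustering_coefficient(corr, config$r_max)$g_ave
  }, error = function(e) NA_real_)
  if (is.na(g_ave)) row$status <- "ok-no-clustering"
  row$g_ave <- g_ave
  row
}

#' Analyze a batch of cells and compare conditions
#'
#' @param cells Either a list of `list(stack = , condition = , cell_id = )`
#'   entries, or a data frame manifest with columns `path`, `condition` (and
#'   optionally `cell_id`), whose TIFFs are read with the supplied geometry.
#' @param config An [analysis_config()].
#' @param geometry A [voxel_geometry()] (manifest input only).
#' @param channel_names Channel labels for manifest TIFFs
#'   (default reporter, structural).
#' @return List with `reports` (per-cell tibble; unreadable or failed cells
#'   keep a row with a reason status) and `comparisons` (per-metric pooled
#'   two-tailed t between the two conditions, when exactly two conditions
#'   have usable cells).
#' @export
run_batch <- function(cells, config = analysis_config(), geometry = NULL,
                      channel_names = c("reporter", "structural")) {
  if (is.data.frame(cells)) {
    if (is.null(geometry)) stop("manifest input needs a geometry", call. = FALSE)
    entries <- lapply(seq_len(nrow(cells)), function(i) {
      id <- if ("cell_id" %in% names(cells)) cells$cell_id[i] else basename(cells$path[i])
      stk <- tryCatch(
        read_tiff_stack(cells$path[i], geometry, n_channels = length(channel_names),
                        channel_names = channel_names),
        error = function(e) e
      )
      list(stack = stk, condition = cells$condition[i], cell_id = id)
    })
  } else {
    entries <- cells
  }
  if (!length(entries)) stop("empty batch", call. = FALSE)

  reports <- lapply(entries, function(e) {
    id <- if (is.null(e$cell_id)) "cell" else e$cell_id
    if (inherits(e$stack, "error") || !inherits(e$stack, "voxel_stack")) {
      message(sprintf("skipping cell '%s': unreadable stack", id))
      return(empty_report_row(id, e$condition, "unreadable", config$param_hash))
    }
    analyze_cell(e$stack, config, cell_id = id, condition = e$condition)
  })
  reports <- do.call(rbind, reports)

  usable <- reports[reports$status %in% c("ok", "ok-no-clustering"), ]
  if (!nrow(usable)) {
    stop(sprintf("all cells failed: %s",
                 paste(unique(reports$status), collapse = ", ")), call. = FALSE)
  }
  comparisons <- NULL
  conds <- unique(usable$condition)
  if (length(conds) == 2L) {
    cmp_metric <- function(metric) {
      a <- usable[[metric]][usable$condition == conds[1]]
      b <- usable[[metric]][usable$condition == conds[2]]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      tt <- two_sample_t(a, b)
      tibble::tibble(metric = metric, condition_a = conds[1], condition_b = conds[2],
                     mean_a = tt$group_means[1], mean_b = tt$group_means[2],
                     t_stat = tt$t_stat, df = tt$df, p_two_tailed = tt$p_two_tailed)
    }
    comparisons <- do.call(rbind, Filter(Negate(is.null),
      lapply(c("cof_distance_um", "axial_dispersion_um"), cmp_metric)))
  }
  list(reports = reports, comparisons = comparisons)
}
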