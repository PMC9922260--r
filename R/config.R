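#' Pipeline configuration
#'
#' One flat bag of every fixed constant the pipeline uses.  Thresholds stated
#' in micrometres are applied in micrometres and converted to pixels at use
#' through each image's pixel size; thresholds stated in pixels (rolling-ball
#' radius, Niblack window, segment-link distance, nucleus areas) are applied in
#' pixels and are therefore resolution-dependent.
#'
#' @param ... Named overrides of the defaults listed below.
#'
#' @section Defaults:
#' \describe{
#'   \item{cell segmentation}{`gaussian_sigma_px = 3`, `otsu_fraction = 0.4`,
#'     `area_inflation_um2 = 63.353` (subtracted from the measured cell area
#'     before computing the corrected radius R), QC window
#'     `cell_area_min_um2 = 1700` to `cell_area_max_um2 = 2000` (inclusive).}
#'   \item{annuli}{`annulus_width_um = 4`, `annulus_step_um = 2`,
#'     `n_annuli = 8`, `report_annulus = "6-10"` (or `"8-12"`).}
#'   \item{fibre binarisation}{`rollingball_radius_px = 30`,
#'     `niblack_window_px = 15`, `niblack_k = -0.3`, `niblack_offset = -0.01`,
#'     segment linking `link_max_angle_deg = 30`, `link_max_dist_px = 30`,
#'     tilt exclusion `theta_r_max_deg = 68`.}
#'   \item{microculture}{`wiener_culture_px = 20`, `entropy_px = 3`,
#'     `opening_px = 9`, bounding-box QC `bbox_width_min_um = 225`,
#'     `bbox_width_max_um = 375`, `bbox_height_min_um = 550`,
#'     `bbox_cover_min = 0.80`, `roi_um = c(200, 500)`,
#'     `director_window_um = 60`, `director_overlap = 0.70`.}
#'   \item{nuclei}{`wiener_nuclei_px = 9`, `nick_k = -0.2`,
#'     `nick_window_px = 51`, `nucleus_area_min_px = 500`,
#'     `nucleus_area_max_px = 10000`, `min_nuclei = 50`.}
#'   \item{alignment and statistics}{`mrl_cutoff_nuclei = 0.35`,
#'     `mrl_cutoff_director = 0.5`, `hist_bin_deg = 5`, `hist_bin_sf_deg = 2`,
#'     `bimodal_alpha = 0.05`.}
#' }
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    gaussian_sigma_px = 3,
    otsu_fraction = 0.4,
    area_inflation_um2 = 63.353,
    cell_area_min_um2 = 1700,
    cell_area_max_um2 = 2000,
    annulus_width_um = 4,
    annulus_step_um = 2,
    n_annuli = 8,
    rollingball_radius_px = 30,
    niblack_window_px = 15,
    niblack_k = -0.3,
    niblack_offset = -0.01,
    link_max_angle_deg = 30,
    link_max_dist_px = 30,
    theta_r_max_deg = 68,
    min_clip_px = 7,
    min_segment_px = 15,
    report_annulus = "6-10",
    wiener_culture_px = 20,
    entropy_px = 3,
    opening_px = 9,
    bbox_width_min_um = 225,
    bbox_width_max_um = 375,
    bbox_height_min_um = 550,
    bbox_cover_min = 0.80,
    roi_um = c(200, 500),
    director_window_um = 60,
    director_overlap = 0.70,
    wiener_nuclei_px = 9,
    nick_k = -0.2,
    nick_window_px = 51,
    nucleus_area_min_px = 500,
    nucleus_area_max_px = 10000,
    min_nuclei = 50,
    mrl_cutoff_nuclei = 0.35,
    mrl_cutoff_director = 0.5,
    hist_bin_deg = 5,
    hist_bin_sf_deg = 2,
    bimodal_alpha = 0.05
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("gaussian_sigma_px", "otsu_fraction", "annulus_width_um",
           "annulus_step_um", "n_annuli", "rollingball_radius_px",
           "niblack_window_px", "link_max_angle_deg", "link_max_dist_px",
           "theta_r_max_deg", "wiener_culture_px", "entropy_px", "opening_px",
           "bbox_width_min_um", "bbox_width_max_um", "bbox_height_min_um",
           "director_window_um", "wiener_nuclei_px", "nick_window_px",
           "nucleus_area_min_px", "nucleus_area_max_px", "min_nuclei",
           "hist_bin_deg", "hist_bin_sf_deg", "cell_area_min_um2",
           "cell_area_max_um2", "area_inflation_um2")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || any(cfg[[k]] <= 0))
      stop("config key '", k, "' must be strictly positive")
  }
  if (!(cfg$director_overlap > 0 && cfg$director_overlap < 1))
    stop("director_overlap must lie strictly between 0 and 1")
  if (cfg$cell_area_min_um2 >= cfg$cell_area_max_um2)
    stop("cell_area_min_um2 must be below cell_area_max_um2")
  if (!cfg$report_annulus %in% c("6-10", "8-12"))
    stop("report_annulus must be \"6-10\" or \"8-12\"")
  if (length(cfg$roi_um) != 2 || any(cfg$roi_um <= 0))
    stop("roi_um must be two positive numbers (width, height)")
  invisible(cfg)
}

# annulus index (0-based) corresponding to the configured report annulus
report_annulus_index <- function(cfg) {
  switch(cfg$report_annulus, "6-10" = 3L, "8-12" = 4L,
         stop("bad report_annulus"))
}

#' Write a pipeline configuration to a YAML file
#' @param cfg A [pipeline_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the package defaults; absent keys keep
#' their defaults.
#' @param path YAML file path.
#' @return A [pipeline_config()] object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$roi_um)) vals$roi_um <- as.numeric(unlist(vals$roi_um))
  do.call(pipeline_config, vals)
}
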