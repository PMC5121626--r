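#' NIfTI and configuration I/O
#'
#' Thin wrappers around RNifti keeping header geometry intact on round
#' trips, plus the YAML run-configuration and the pipeline driver used by
#' the command-line interface. Voxel indices are 0-based on disk (NIfTI
#' convention) and 1-based inside R; affines are passed through untouched.
#'
#' @name cli_io
NULL

# NIfTI writers drop trailing singleton dimensions; restore them so shape
# checks compare like with like.
pad_dim <- function(img, rank) {
  d <- dim(img) %||% length(img)
  if (length(d) < rank) dim(img) <- c(d, rep(1L, rank - length(d)))
  img
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @param allow_nonfinite Keep non-finite voxels (default FALSE: they are
#'   rejected with a count).
#' @return A list with `img` (numeric array) and `header` (the `niftiImage`
#'   carrying the original header/affine).
#' @export
read_volume <- function(path, allow_nonfinite = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such volume: %s", path),
                               call. = FALSE)
  nim <- RNifti::readNifti(path)
  img <- as.array(nim)
  nbad <- sum(!is.finite(img))
  if (nbad > 0 && !allow_nonfinite)
    stop(sprintf("%s contains %d non-finite voxels", path, nbad),
         call. = FALSE)
  list(img = img, header = nim)
}

#' Write a NIfTI volume
#'
#' @param img Numeric array.
#' @param path Output path.
#' @param template Optional `niftiImage` (or header list) whose geometry is
#'   copied.
#' @param pixdim Voxel dimensions when no template is given.
#' @param description Free-text stored in the header description field
#'   (e.g. units).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path, template = NULL, pixdim = NULL,
                         description = NULL) {
  nim <- if (!is.null(template)) RNifti::asNifti(img, reference = template)
         else RNifti::asNifti(img)
  if (!is.null(pixdim)) RNifti::pixdim(nim) <- pixdim
  if (!is.null(description))
    nim <- RNifti::asNifti(nim, descrip = substr(description, 1, 79))
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read / write a run configuration
#'
#' Run configurations are YAML files collecting physics constants, sequence
#' parameters, thresholds, the ratio convention and seeds, so that a run can
#' be reproduced from the file written next to its outputs.
#'
#' @param path YAML path.
#' @return A named list (class `mrvf_config`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "mrvf_config")
}

#' @rdname read_config
#' @param config A named list / `mrvf_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

default_config <- function() {
  structure(list(
    physics = unclass(physics_constants()),
    sequence = list(n_echoes = 32L, delta_te = 3.3, se_time = 60,
                    n_fid = 8L, tr = 4000, dt = 0.5),
    ratio = "post-pre",
    r2_threshold = 0.8,
    n_drop = 8L,
    smooth = TRUE,
    seed = 1L), class = "mrvf_config")
}

config_physics <- function(cfg)
  do.call(physics_constants, cfg$physics %||% list())

config_sequence <- function(cfg)
  do.call(sequence_params, cfg$sequence %||% list())

#' Run the matching pipeline from files
#'
#' Reads co-registered pre/post GESFIDE volumes (and an optional ADC map),
#' checks shapes before any computation, matches against a dictionary and
#' writes the parametric maps (`bvf.nii.gz`, `radius.nii.gz`,
#' `sto2.nii.gz`, `orientation.nii.gz`, `r2.nii.gz`,
#' `excluded.nii.gz`) plus a JSON manifest to `out_dir`.
#'
#' @param pre_path,post_path 4D NIfTI paths.
#' @param dict_path Dictionary RDS path ([save_dictionary()]).
#' @param adc_path Optional ADC NIfTI path.
#' @param out_dir Output directory (created).
#' @param roi_path Optional ROI label NIfTI; when given a JSON ROI report is
#'   written too.
#' @param config Optional `mrvf_config` overriding thresholds/conventions.
#' @return The `mrvf_maps`, invisibly.
#' @export
run_match_pipeline <- function(pre_path, post_path, dict_path,
                               adc_path = NULL, out_dir, roi_path = NULL,
                               config = default_config()) {
  t0 <- Sys.time()
  pre <- read_volume(pre_path); post <- read_volume(post_path)
  pre$img <- pad_dim(pre$img, 4L); post$img <- pad_dim(post$img, 4L)
  if (!identical(dim(pre$img), dim(post$img)))
    stop(sprintf("shape mismatch: %s is %s but %s is %s", pre_path,
                 paste(dim(pre$img), collapse = "x"), post_path,
                 paste(dim(post$img), collapse = "x")), call. = FALSE)
  adc <- NULL
  if (!is.null(adc_path)) {
    adc <- read_volume(adc_path)
    adc$img <- pad_dim(adc$img, 3L)
    if (!identical(dim(adc$img), dim(pre$img)[1:3]))
      stop(sprintf("shape mismatch: ADC map %s is %s, expected %s", adc_path,
                   paste(dim(adc$img), collapse = "x"),
                   paste(dim(pre$img)[1:3], collapse = "x")), call. = FALSE)
  }
  dict <- load_dictionary(dict_path)
  message(sprintf("[match] inputs read (%.1fs)",
                  as.numeric(Sys.time() - t0, units = "secs")))
  maps <- match_volume(pre$img, post$img, if (!is.null(adc)) adc$img,
                       dict, r2_threshold = config$r2_threshold %||% 0.8,
                       smooth = isTRUE(config$smooth %||% TRUE),
                       n_drop = config$n_drop)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("bvf", "radius", "sto2", "orientation", "r2")) {
    m <- maps[[nm]]
    m[!is.finite(m)] <- 0
    write_volume(m, file.path(out_dir, paste0(nm, ".nii.gz")),
                 template = pre$header)
  }
  write_volume(maps$excluded + 0, file.path(out_dir, "excluded.nii.gz"),
               template = pre$header)
  manifest <- list(pre = pre_path, post = post_path, adc = adc_path,
                   dict = dict_path, r2_threshold = config$r2_threshold,
                   ratio = dict$manifest$ratio,
                   elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(roi_path)) {
    roi <- pad_dim(read_volume(roi_path)$img, 3L)
    rep <- roi_report(maps, array(as.integer(round(roi)), dim(roi)))
    jsonlite::write_json(rep, file.path(out_dir, "roi_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  message(sprintf("[match] maps written to %s (%.1fs total)", out_dir,
                  as.numeric(Sys.time() - t0, units = "secs")))
  invisible(maps)
}

#' Run the steady-state pipeline from files
#'
#' @param pre_path,post_path 4D NIfTI paths.
#' @param adc_path ADC NIfTI path.
#' @param out_dir Output directory.
#' @param echo_times Echo times (ms) of the 4D volumes.
#' @param config Optional `mrvf_config`.
#' @return The `mrvf_ss_maps`, invisibly.
#' @export
run_steadystate_pipeline <- function(pre_path, post_path, adc_path, out_dir,
                                     echo_times = sequence_params()$echo_times,
                                     config = default_config()) {
  pre <- read_volume(pre_path); post <- read_volume(post_path)
  adc <- read_volume(adc_path)
  pre$img <- pad_dim(pre$img, 4L); post$img <- pad_dim(post$img, 4L)
  adc$img <- pad_dim(adc$img, 3L)
  if (!identical(dim(pre$img), dim(post$img)))
    stop("shape mismatch between pre and post volumes", call. = FALSE)
  maps <- steadystate_maps(pre$img, post$img, echo_times, adc$img,
                           physics = config_physics(config),
                           se_time = config$sequence$se_time %||% 60)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("delta_r2", "delta_r2_star", "bvf_ss", "vsi")) {
    m <- maps[[nm]]
    m[!is.finite(m)] <- 0
    write_volume(m, file.path(out_dir, paste0(nm, ".nii.gz")),
                 template = pre$header)
  }
  write_volume(maps$excluded + 0, file.path(out_dir, "excluded.nii.gz"),
               template = pre$header)
  invisible(maps)
}
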