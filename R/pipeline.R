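#' Run the full lumen quantification pipeline from a configuration
#'
#' Chains the package's stages — phantom generation or volume input,
#' optional segmentation, centerline fitting, cross-section profiling,
#' optional shrinkage against a second profile, and optional joint-histogram
#' analysis — and writes every product plus a manifest (parameters, package
#' version, md5 content hashes) to an output directory.
#'
#' The configuration is a named list or a YAML file with (all optional
#' unless noted):
#' \describe{
#'   \item{`output_dir`}{required output directory.}
#'   \item{`phantom`}{a preset name from [phantom_preset()]; generates the
#'     input mask in place of `mask`/`volume`.}
#'   \item{`mask`}{path of a binary lumen volume readable by
#'     [read_volume()].}
#'   \item{`volume`}{path of a grayscale volume; requires `segmentation`
#'     with `seeds` and `tolerance` (plus `median_kernel`,
#'     `opening_radius`).}
#'   \item{`voxel_length`}{micrometers per voxel (required for TIFF input).}
#'   \item{`centerline`}{list of [centerline_fit()] arguments
#'     (`beta`, `sigma`, `mu`, `max_iter`).}
#'   \item{`shrinkage_against`}{path of a previously written profile CSV to
#'     compare against; optional `offset_mm` fixes the alignment.}
#'   \item{`histogram_pair`}{list with `a`, `b` volume paths and optional
#'     `bins`, `prefilter_a` sigma.}
#'   \item{`seed`}{integer seed fixed for reproducibility.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return the output directory, invisibly; products on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config must name an 'output_dir'")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  products <- character(0)

  # ---- input mask -----------------------------------------------------
  if (!is.null(config$phantom)) {
    ph <- phantom_preset(config$phantom,
                         voxel_length = config$voxel_length %||% 1)
    mask <- ph$mask
    gt_path <- file.path(out_dir, "ground_truth.csv")
    write_ground_truth(ph$truth, gt_path)
    products <- c(products, gt_path)
  } else if (!is.null(config$mask)) {
    mask <- binarize(read_volume(config$mask,
                                 voxel_length = config$voxel_length), 0.5)
  } else if (!is.null(config$volume)) {
    seg <- config$segmentation
    if (is.null(seg$seeds))
      stop("grayscale input requires segmentation seeds")
    v <- read_volume(config$volume, voxel_length = config$voxel_length)
    params <- segmentation_params(
      median_kernel = seg$median_kernel %||% 15L,
      grow_tolerance = seg$tolerance %||% 0.5,
      seeds = matrix(unlist(seg$seeds), ncol = 3L, byrow = TRUE),
      opening_radius = seg$opening_radius %||% 0L)
    mask <- segment_lumen(v, params)
    mask_path <- file.path(out_dir, "mask")
    write_volume(mask, mask_path, "tiff-stack")
    products <- c(products, list.files(mask_path, full.names = TRUE))
  } else {
    stop("config must provide one of 'phantom', 'mask' or 'volume'")
  }

  # ---- centerline ------------------------------------------------------
  cl <- config$centerline %||% list()
  fit <- centerline_fit(mask,
                        beta = cl$beta %||% 0.5,
                        sigma = cl$sigma %||% 20,
                        mu = cl$mu %||% 0.3,
                        max_iter = cl$max_iter %||% 100L)
  cl_path <- file.path(out_dir, "centerline.csv")
  rho_path <- file.path(out_dir, "residuals.csv")
  write_centerline(fit, cl_path, rho_path)
  products <- c(products, cl_path, rho_path)

  # ---- area profile ----------------------------------------------------
  prof <- area_profile(mask, fit, allow_unconverged = TRUE)
  prof_path <- file.path(out_dir, "area_profile.csv")
  write_profile(prof, prof_path)
  products <- c(products, prof_path)

  # ---- optional shrinkage ---------------------------------------------
  if (!is.null(config$shrinkage_against)) {
    other <- utils::read.csv(config$shrinkage_against)
    other <- structure(other,
                       class = c("cross_section_profile", "data.frame"))
    shr <- shrinkage_profile(other, prof,
                             offset = config$offset_mm)
    shr_path <- file.path(out_dir, "shrinkage.csv")
    write_profile(shr, shr_path)
    products <- c(products, shr_path)
  }

  # ---- optional joint histogram ---------------------------------------
  hp <- config$histogram_pair
  if (!is.null(hp)) {
    va <- read_volume(hp$a, voxel_length = config$voxel_length)
    vb <- read_volume(hp$b, voxel_length = config$voxel_length)
    if (!is.null(hp$prefilter_a)) va <- gaussian_prefilter(va, hp$prefilter_a)
    jh <- joint_histogram(va, vb, n_bins = hp$bins %||% 256L)
    jh_path <- file.path(out_dir, "joint_histogram.csv")
    idx <- which(jh$counts > 0, arr.ind = TRUE)
    utils::write.csv(data.frame(bin_a = idx[, 1L], bin_b = idx[, 2L],
                                count = jh$counts[idx]),
                     jh_path, row.names = FALSE)
    products <- c(products, jh_path)
    for (nm in c("a", "b")) {
      v <- if (nm == "a") va else vb
      hist1 <- intensity_histogram(v, n_bins = hp$bins %||% 256L)
      gfit <- fit_multi_gaussian(hist1, n_components = 4L)
      fit_path <- file.path(out_dir, sprintf("gaussian_fit_%s.csv", nm))
      utils::write.csv(cbind(component = seq_len(4L), gfit$components),
                       fit_path, row.names = FALSE)
      products <- c(products, fit_path)
    }
  }

  # ---- manifest --------------------------------------------------------
  manifest <- c(
    sprintf("lumenline %s", as.character(utils::packageVersion("lumenline"))),
    sprintf("generated %s", "run"),
    "parameters:",
    utils::capture.output(utils::str(config, give.attr = FALSE)),
    "products (md5):",
    sprintf("  %s  %s", tools::md5sum(products), basename(products)))
  writeLines(manifest, file.path(out_dir, "MANIFEST.txt"))
  invisible(out_dir)
}
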