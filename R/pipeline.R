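#' Pipeline configuration
#'
#' Collects every tunable parameter of the three pipeline steps. All values
#' have the defaults used throughout the package; a resolved copy is written
#' next to each run's outputs so any artifact set is regenerable from its
#' directory alone.
#'
#' @param k_mip MIP clustering classes (default 5).
#' @param p quadrangle coverage proportion (default 0.75).
#' @param top_m_mip brightest clusters counted as bone (default 1).
#' @param use_quadrangle apply the spatial threshold (default TRUE).
#' @param n_control_points odd spline control-point count (default 7).
#' @param step_px arc-length spacing of normal lines (default 1; use 10 to
#'   process sparse sections and interpolate intermediate columns).
#' @param half_length_px half-length of each normal line (default 20).
#' @param k_section per-section clustering classes (default 4; 2 suits
#'   closed-bite scans where teeth and jaw merge).
#' @param degree long-axis polynomial degree (default 5).
#' @param min_area section speckle filter, px (default 10).
#' @param k_neighbors normal-estimation neighbourhood (default 9).
#' @param reference_row development reference row (default "mid").
#' @param n_slices slab thickness for the thickened radiograph; 1 disables
#'   it (default 1).
#' @param baseline also render the cylinder baseline (default FALSE).
#' @param z_band optional MIP z-crop fractions, length 2.
#' @param window optional display window `c(width, level)` for 8-bit
#'   overlay output.
#' @param clahe also write a contrast-equalised 8-bit PNG of each
#'   radiograph (EBImage CLAHE; display only, never used in pipeline math
#'   or validation). Default FALSE.
#' @param seed RNG seed for all clustering (default 0).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(k_mip = 5, p = 0.75, top_m_mip = 1,
                            use_quadrangle = TRUE, n_control_points = 7,
                            step_px = 1, half_length_px = 20,
                            k_section = 4, degree = 5, min_area = 10,
                            k_neighbors = 9, reference_row = "mid",
                            n_slices = 1, baseline = FALSE, z_band = NULL,
                            window = NULL, clahe = FALSE, seed = 0) {
  cfg <- list(k_mip = k_mip, p = p, top_m_mip = top_m_mip,
              use_quadrangle = use_quadrangle,
              n_control_points = n_control_points, step_px = step_px,
              half_length_px = half_length_px, k_section = k_section,
              degree = degree, min_area = min_area,
              k_neighbors = k_neighbors, reference_row = reference_row,
              n_slices = n_slices, baseline = baseline, z_band = z_band,
              window = window, clahe = clahe, seed = seed)
  stopifnot(cfg$k_mip >= 2, cfg$p > 0, cfg$p < 1,
            cfg$n_control_points %% 2 == 1, cfg$step_px > 0,
            cfg$degree >= 1, cfg$degree <= 7,
            cfg$n_slices %% 2 == 1)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full panoramic synthesis pipeline
#'
#' Step 1 creates the dental arch curve from the axial MIP; step 2 extracts
#' the 3D panoramic curved surface through the tooth long axes; step 3
#' develops the surface into the panoramic radiograph(s). When `out_dir` is
#' given, writes: the MIP with the arch curve burnt in (`mip_overlay.png`),
#' the control points (`arch_curve.json`), the surface mesh
#' (`surface.ply`), the single-slice radiograph
#' (`panoramic_single.tif` + sidecar), optionally the thickened and
#' cylinder-baseline radiographs, the resolved config
#' (`config_resolved.yaml`) and a structured timing log (`log.json`).
#'
#' @param vol a [cbct_volume] or a path accepted by [load_volume].
#' @param cfg a [pipeline_config].
#' @param out_dir optional output directory (created if missing).
#' @return list: `curve`, `arch` (full step-1 output), `surface`, `dev`,
#'   `single` (developed image), `thickened` (or NULL), `cylinder` (or
#'   NULL), `mip`, `log` (per-step wall seconds).
#' @export
run_pipeline <- function(vol, cfg = pipeline_config(), out_dir = NULL) {
  if (is.character(vol)) vol <- load_volume(vol)
  stopifnot(inherits(vol, "cbct_volume"), inherits(cfg, "pipeline_config"))
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  mip <- mip_axial(vol, z_band = cfg$z_band)
  arch <- create_arch_curve(mip, k = cfg$k_mip, p = cfg$p,
                            n_control_points = cfg$n_control_points,
                            seed = cfg$seed, top_m = cfg$top_m_mip,
                            use_quadrangle = cfg$use_quadrangle)
  log$step1_arch_curve_s <- tic() - t0
  t0 <- tic()
  lines <- sample_perpendicular_lines(arch$curve, step_px = cfg$step_px,
                                      half_length_px = cfg$half_length_px)
  surf <- extract_panoramic_surface(vol, lines, k_section = cfg$k_section,
                                    seed = cfg$seed, degree = cfg$degree,
                                    min_area = cfg$min_area,
                                    k_neighbors = cfg$k_neighbors)
  log$step2_surface_s <- tic() - t0
  log$n_sections <- nrow(lines$foot)
  log$n_fallback_sections <- attr(surf, "n_fallback")
  t0 <- tic()
  dev <- develop_surface(surf, reference_row = cfg$reference_row)
  single <- render_single_slice(vol, surf, dev)
  thick <- if (cfg$n_slices > 1)
    render_thickened(vol, surf, dev, n_slices = cfg$n_slices) else NULL
  cyl <- if (isTRUE(cfg$baseline))
    render_cylinder_baseline(vol, arch$curve, n_slices = 1) else NULL
  log$step3_synthesis_s <- tic() - t0
  out <- list(curve = arch$curve, arch = arch, surface = surf, dev = dev,
              single = single, thickened = thick, cylinder = cyl,
              mip = mip, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ## MIP overlay: burn the curve into the MIP at max intensity
    ov <- mip$data
    u <- seq(0, nrow(arch$curve$control_points) - 1, length.out = 4001L)
    pc <- round(eval_arch_curve(arch$curve, u)) + 1L
    keep <- pc[, 1] >= 1 & pc[, 1] <= nrow(ov) &
            pc[, 2] >= 1 & pc[, 2] <= ncol(ov)
    ov[pc[keep, , drop = FALSE]] <- max(ov)
    ov_img <- cbct_image(ov, spacing = mip$spacing, provenance = "mip")
    if (!is.null(cfg$window))
      ov_img <- apply_window(ov_img, cfg$window[1], cfg$window[2])
    save_image(ov_img, file.path(out_dir, "mip_overlay.png"), bit_depth = 8)
    jsonlite::write_json(
      list(control_points = arch$curve$control_points,
           tangents = arch$curve$tangents,
           parabola = list(coef = arch$parabola$coef,
                           angle = arch$parabola$angle,
                           center = arch$parabola$center)),
      file.path(out_dir, "arch_curve.json"), digits = NA, matrix = "rowmajor")
    write_surface_ply(surf, file.path(out_dir, "surface.ply"))
    save_image(as_cbct_image(single),
               file.path(out_dir, "panoramic_single.tif"), bit_depth = 16)
    if (!is.null(thick))
      save_image(as_cbct_image(thick),
                 file.path(out_dir, "panoramic_thickened.tif"),
                 bit_depth = 16)
    if (!is.null(cyl))
      save_image(as_cbct_image(cyl),
                 file.path(out_dir, "panoramic_cylinder.tif"),
                 bit_depth = 16)
    if (isTRUE(cfg$clahe)) {
      for (nm in c("single", "thickened", "cylinder")) {
        im <- out[[nm]]
        if (is.null(im)) next
        ## EBImage images share this package's (x, y) index order; CLAHE
        ## needs dimensions divisible by the tile grid, so pad by edge
        ## replication and crop back
        sc <- (im$data - min(im$data)) / max(1e-12, diff(range(im$data)))
        d0 <- dim(sc)
        dpad <- ceiling(d0 / 4) * 4
        sc <- sc[c(seq_len(d0[1]), rep(d0[1], dpad[1] - d0[1])),
                 c(seq_len(d0[2]), rep(d0[2], dpad[2] - d0[2]))]
        eq <- EBImage::clahe(EBImage::Image(sc), nx = 4, ny = 4)
        save_image(cbct_image(EBImage::imageData(eq)[seq_len(d0[1]),
                                                     seq_len(d0[2])],
                              provenance = "panoramic"),
                   file.path(out_dir, paste0("panoramic_", nm, "_clahe.png")),
                   bit_depth = 8)
      }
    }
    write_pipeline_config(cfg, file.path(out_dir, "config_resolved.yaml"))
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Generate a phantom and write its volume and ground truth to files
#'
#' @param cfg a [phantom_config].
#' @param out_dir output directory; writes `phantom.nii.gz` and
#'   `truth.json`.
#' @return list with `volume_path`, `truth_path`, and the in-memory
#'   `volume` / `truth`.
#' @export
write_phantom <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- generate_phantom(cfg)
  vp <- file.path(out_dir, "phantom.nii.gz")
  tp <- file.path(out_dir, "truth.json")
  write_volume(ph$volume, vp)
  write_phantom_truth(ph$truth, tp)
  list(volume_path = vp, truth_path = tp,
       volume = ph$volume, truth = ph$truth)
}
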