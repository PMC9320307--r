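#' Pipeline configuration
#'
#' Bundles the per-stage settings of the full labeling pipeline
#' (enhance -> register -> fuse -> segment -> export) together with the
#' input/output directories. Series are discovered in `pet_dir` / `ct_dir`
#' and paired by the numeric suffix of their file names (natural order); an
#' optional `points_dir` may hold one `points_<index>.csv` landmark file per
#' pair, refining the automatic outer-frame pre-alignment.
#'
#' @param enhance an [enhance_config()].
#' @param wavelet a [wavelet_config()].
#' @param weights a [fusion_weights()] (default 40% PET / 60% CT).
#' @param grow a [grow_config()].
#' @param paths named list with `pet_dir`, `ct_dir`, `out_dir` and optional
#'   `points_dir`.
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(enhance = enhance_config(),
                            wavelet = wavelet_config(),
                            weights = fusion_weights(),
                            grow = grow_config(),
                            paths = list(pet_dir = ".", ct_dir = ".",
                                         out_dir = "."),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(inherits(enhance, "enhance_config"),
            inherits(wavelet, "wavelet_config"),
            inherits(weights, "fusion_weights"),
            inherits(grow, "grow_config"))
  structure(list(enhance = enhance, wavelet = wavelet, weights = weights,
                 grow = grow, paths = paths, log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()]: `enhance: {target_size, pet_min}`,
#' `wavelet: {wavelet_name, levels, soft_threshold, extension_mode}`,
#' `weights: {pet_pct, ct_pct}`, `grow: {search_halfwidth,
#' threshold_increase, max_radius}`, `paths: {pet_dir, ct_dir, points_dir,
#' out_dir}`, `log_level`. Missing keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(node, make) if (is.null(node)) make() else do.call(make, node)
  pipeline_config(enhance = take(y$enhance, enhance_config),
                  wavelet = take(y$wavelet, wavelet_config),
                  weights = take(y$weights, fusion_weights),
                  grow = take(y$grow, grow_config),
                  paths = if (is.null(y$paths)) list(pet_dir = ".", ct_dir = ".",
                                                     out_dir = ".") else y$paths,
                  log_level = if (is.null(y$log_level)) "info" else y$log_level)
}

# numbered-series discovery: trailing integer of the file stem
series_index <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(stem, regexpr("[0-9]+$", stem))
  if (length(m) == 0L) NA_integer_ else as.integer(m)
}

discover_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.(png|tif|tiff|dcm)$",
                      ignore.case = TRUE, full.names = TRUE)
  idx <- vapply(files, series_index, integer(1))
  files <- files[!is.na(idx)]; idx <- idx[!is.na(idx)]
  files[order(idx)]
}

#' Run the full labeling pipeline over a numbered PET/CT series
#'
#' For every discovered PET/CT pair: enlarge and enhance the PET, register it
#' to the CT (outer-frame pre-alignment, refined by a landmark least-squares
#' fit when a `points_<index>.csv` file is present), resample it into CT
#' space, fuse the pair in the wavelet domain, and for every click on that
#' pair refine the seed, grow the lesion region, trace its polygon and
#' bounding box and emit one label record. Writes `labels.json`, a fused
#' grayscale and pseudocolor PNG per pair, and a `run_log.txt` recording
#' every parameter. Deterministic: rerunning with identical inputs gives
#' bit-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param clicks data frame with columns `index`, `x`, `y` and optionally
#'   `label`: one professional's click per lesion, in CT/fused coordinates.
#' @return (invisibly) list with `records` (the [label_record()]s) and
#'   `outputs` (paths written).
#' @export
run_pipeline <- function(cfg, clicks = data.frame(index = integer(),
                                                  x = numeric(), y = numeric())) {
  p <- cfg$paths
  out_dir <- p$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (cfg$log_level != "quiet") message(line)
  }
  note("pipeline: weights PET %g%% / CT %g%%, wavelet %s x%d levels (%s), %s",
       cfg$weights$pet_pct, cfg$weights$ct_pct, cfg$wavelet$wavelet_name,
       cfg$wavelet$levels, cfg$wavelet$extension_mode,
       if (identical(cfg$enhance$pet_min, "auto")) "PETmin auto"
       else sprintf("PETmin %g", cfg$enhance$pet_min))
  note("grow: halfwidth %d, threshold increase %g, max radius %d",
       cfg$grow$search_halfwidth, cfg$grow$threshold_increase,
       cfg$grow$max_radius)

  pets <- discover_series(p$pet_dir)
  cts <- discover_series(p$ct_dir)
  pet_idx <- vapply(pets, series_index, integer(1))
  ct_idx <- vapply(cts, series_index, integer(1))
  all_idx <- sort(union(pet_idx, ct_idx))
  for (i in all_idx) {
    if (!(i %in% pet_idx) || !(i %in% ct_idx))
      pc_stop(sprintf("missing partner image for series index %d", i),
              "pairing_error")
  }
  if (!is.data.frame(clicks)) clicks <- as.data.frame(clicks)
  if (is.null(clicks$label)) clicks$label <- rep("", nrow(clicks))

  records <- list()
  outputs <- character(0)
  for (i in all_idx) {
    pet <- read_gray_image(pets[match(i, pet_idx)], "PET")
    ct <- read_gray_image(cts[match(i, ct_idx)], "CT")
    csize <- image_size(ct)
    enh_cfg <- enhance_config(csize, cfg$enhance$pet_min)
    enhanced <- enhance_pet(pet, enh_cfg)
    pre <- frame_prealign(enhanced, ct)
    pts_file <- if (!is.null(p$points_dir))
      file.path(p$points_dir, sprintf("points_%d.csv", i)) else ""
    if (nzchar(pts_file) && file.exists(pts_file)) {
      pts <- read_control_points(pts_file)
      # fit in pre-aligned coordinates, then compose with the pre-alignment
      pre_src <- affine_apply(pre, pts$source)
      fit <- fit_affine(control_points(pre_src, pts$target))
      total <- affine_compose(fit$params, pre)
      note("pair %d: landmark fit RMS %.4g px over pre-alignment", i, fit$rms)
    } else {
      total <- pre
      note("pair %d: outer-frame pre-alignment only", i)
    }
    registered <- apply_affine(enhanced, total, csize)
    fused <- fuse_images(registered, ct, cfg$weights, cfg$wavelet)
    fg <- file.path(out_dir, sprintf("fused_%03d.png", i))
    fc <- file.path(out_dir, sprintf("fused_%03d_color.png", i))
    write_gray_image(fused, fg)
    write_rgb_image(pseudocolor(fused), fc)
    outputs <- c(outputs, fg, fc)

    these <- clicks[clicks$index == i, , drop = FALSE]
    lesion_id <- 0L
    for (ci in seq_len(nrow(these))) {
      sd <- refine_seed(registered, c(these$x[ci], these$y[ci]), cfg$grow)
      region <- region_grow(registered, sd$seed, sd$value_min, cfg$grow)
      region <- map_region_to_ct(region, identity_affine())
      lesion_id <- lesion_id + 1L
      records[[length(records) + 1L]] <-
        label_record(image_id = tools::file_path_sans_ext(
                       basename(cts[match(i, ct_idx)])),
                     lesion_id = lesion_id,
                     polygon = region$boundary,
                     bbox = region$bbox,
                     seed = sd$seed,
                     label_text = these$label[ci],
                     suv_class = "unknown",
                     image_size = csize)
      note("pair %d: click (%g, %g) -> seed (%d, %d), %d px region",
           i, these$x[ci], these$y[ci], sd$seed[1], sd$seed[2],
           nrow(region$members))
    }
  }
  skipped <- setdiff(unique(clicks$index), all_idx)
  for (s in skipped) {
    warning(sprintf("click refers to series index %s with no image pair; skipped", s))
    note("warning: click on missing pair index %s skipped", s)
  }
  labels_path <- file.path(out_dir, "labels.json")
  export_labels(records, labels_path)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(records = records,
                 outputs = c(outputs, labels_path,
                             file.path(out_dir, "run_log.txt"))))
}

#' Fuse one pair at several PET:CT ratios
#'
#' Convenience sweep for choosing the blending ratio visually: fuses the same
#' registered pair at each listed ratio. The default list is the five ratios
#' conventionally inspected (30:70, 40:60, 50:50, 60:40, 70:30).
#'
#' @param pet,ct registered same-size [gray_image()]s.
#' @param ratios list of [fusion_weights()].
#' @param cfg a [wavelet_config()].
#' @return named list of fused [gray_image()]s, names like `"40:60"`.
#' @export
sweep_ratios <- function(pet, ct,
                         ratios = lapply(c(30, 40, 50, 60, 70),
                                         function(a) fusion_weights(a, 100 - a)),
                         cfg = wavelet_config()) {
  out <- lapply(ratios, function(w) fuse_images(pet, ct, w, cfg))
  names(out) <- vapply(ratios,
                       function(w) sprintf("%g:%g", w$pet_pct, w$ct_pct),
                       character(1))
  out
}
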