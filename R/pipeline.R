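pipeline_defaults <- list(
  schema_version = 1L,
  segmentation = list(rel_threshold = 0.20, connectivity = 8L,
                      mode = "slice", band = "symmetric"),
  coil = list(width_m = 0.14, height_m = 0.106, current_A = 240,
              n_segments = NULL, warp = FALSE, curvature_radius_mm = 90,
              standoff_mm = 0, center_mm = NULL),
  dose = list(threshold_mT = 1.0),
  seeds = list(units = "index"),
  rng_seed = 1L
)

known_keys <- list(
  top = c("schema_version", "inputs", "phantom", "cohort_fixture", "seeds",
          "segmentation", "coil", "dose", "output_dir", "rng_seed"),
  inputs = c("dwi", "flair"),
  phantom = c("pre", "post"),
  seeds = c("dwi", "flair", "units"),
  segmentation = c("rel_threshold", "connectivity", "mode", "band"),
  coil = c("width_m", "height_m", "current_A", "n_segments", "warp",
           "curvature_radius_mm", "standoff_mm", "center_mm"),
  dose = c("threshold_mT")
)

config_error <- function(...) {
  stop(structure(class = c("elfdose_config_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

check_keys <- function(block, where) {
  extra <- setdiff(names(block), known_keys[[where]])
  if (length(extra))
    config_error("unknown config key%s in `%s`: %s",
                 if (length(extra) > 1) "s" else "", where,
                 paste(extra, collapse = ", "))
}

fill_defaults <- function(block, defaults) {
  for (k in names(defaults))
    if (is.null(block[[k]])) block[k] <- defaults[k]
  block
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or an equivalent nested list, checks it against
#' the schema, rejects unknown keys and contradictory settings, and fills
#' defaults (relative threshold 0.20, 14 x 10.6 cm coil at 240 A, dose
#' threshold 1 mT). Exactly one input source must be present: real NIfTI
#' `inputs`, a `phantom` block (pre/post specifications), or
#' `cohort_fixture: true`. Real inputs additionally require explicit seeds
#' for both volumes.
#'
#' @param raw Path to a YAML config or a named list.
#' @return A validated object of class `pipeline_config`.
#' @export
validate_config <- function(raw) {
  cfg <- if (is.character(raw) && length(raw) == 1L) {
    if (!file.exists(raw)) config_error("config file not found: %s", raw)
    yaml::read_yaml(raw)
  } else if (is.list(raw)) raw
  else config_error("config must be a YAML path or a list")

  check_keys(cfg, "top")
  modes <- c(inputs = !is.null(cfg$inputs), phantom = !is.null(cfg$phantom),
             cohort_fixture = isTRUE(cfg$cohort_fixture))
  if (sum(modes) != 1L)
    config_error(
      "exactly one of `inputs`, `phantom`, `cohort_fixture` must be given (found %d)",
      sum(modes))
  for (blk in c("inputs", "phantom", "seeds", "segmentation", "coil",
                "dose"))
    if (!is.null(cfg[[blk]])) check_keys(cfg[[blk]], blk)

  cfg$segmentation <- fill_defaults(cfg$segmentation,
                                    pipeline_defaults$segmentation)
  cfg$coil <- fill_defaults(cfg$coil, pipeline_defaults$coil)
  cfg$dose <- fill_defaults(cfg$dose, pipeline_defaults$dose)
  cfg$seeds <- fill_defaults(cfg$seeds, pipeline_defaults$seeds)
  if (is.null(cfg$rng_seed)) cfg$rng_seed <- pipeline_defaults$rng_seed
  if (is.null(cfg$schema_version))
    cfg$schema_version <- pipeline_defaults$schema_version
  if (cfg$schema_version != 1L)
    config_error("unsupported schema_version: %s", cfg$schema_version)

  if (cfg$coil$current_A <= 0) config_error("coil current must be > 0")
  if (cfg$coil$width_m <= 0 || cfg$coil$height_m <= 0)
    config_error("coil dimensions must be > 0")
  if (cfg$segmentation$rel_threshold <= 0)
    config_error("segmentation rel_threshold must be > 0")
  if (cfg$dose$threshold_mT <= 0) config_error("dose threshold must be > 0")
  if (is.null(cfg$coil$n_segments))
    cfg$coil$n_segments <- if (isTRUE(cfg$coil$warp)) 720L else 4L

  if (modes[["inputs"]]) {
    for (side in c("dwi", "flair")) {
      p <- cfg$inputs[[side]]
      if (is.null(p)) config_error("inputs must name both `dwi` and `flair`")
      if (!file.exists(p)) config_error("input file not found: %s", p)
      if (is.null(cfg$seeds[[side]]))
        config_error("real inputs require seeds for `%s`", side)
    }
  }
  if (modes[["phantom"]]) {
    for (side in c("pre", "post"))
      if (is.null(cfg$phantom[[side]]))
        config_error("phantom block must contain `pre` and `post` specs")
  }
  if (is.null(cfg$output_dir)) config_error("`output_dir` is required")
  structure(cfg, class = "pipeline_config")
}

as_seed_matrix <- function(seeds, volume, units) {
  if (identical(units, "mm")) seeds_from_mm(seeds, volume)
  else normalize_seeds(seeds)
}

build_coil_from_config <- function(coil_cfg) {
  coil <- make_rect_coil(coil_cfg$width_m, coil_cfg$height_m,
                         coil_cfg$current_A, coil_cfg$n_segments)
  if (isTRUE(coil_cfg$warp))
    coil <- warp_coil(coil, head_model(coil_cfg$curvature_radius_mm,
                                       coil_cfg$standoff_mm))
  coil
}

#' Run the full analysis pipeline
#'
#' Executes segment -> volumetrics -> field -> dose -> report on the
#' configured input source and writes the artifact bundle into
#' `output_dir`: lesion mask NIfTIs, a |B| field map NIfTI (mT), a
#' volumetrics CSV, a dose CSV, the coil vertex list, and a JSON run
#' manifest echoing the config, the package version and output checksums.
#' In cohort-fixture mode the published six-patient table is summarized
#' instead of segmenting images. Identical config and seed give
#' byte-identical outputs; any stage failure removes the partial outputs
#' and reports the stage name.
#'
#' @param config A [pipeline_config][validate_config] (or anything
#'   `validate_config()` accepts).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(path) { written[[length(written) + 1L]] <<- path; path }
  log_stage <- function(name, t0, extra = "") {
    if (!quiet)
      message(sprintf("[%s] done in %.2fs%s", name,
                      as.numeric(Sys.time()) - t0,
                      if (nzchar(extra)) paste0(" | ", extra) else ""))
  }
  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(force(expr), error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_stage(name, t0)
    res
  }
  set.seed(config$rng_seed)
  paths <- list()
  input_hashes <- list()

  if (isTRUE(config$cohort_fixture)) {
    report <- stage("report", {
      rep <- summarize_cohort(make_cohort_fixture())
      paths$cohort_report <- note(file.path(out_dir, "cohort_report.csv"))
      write_cohort_report(rep, paths$cohort_report)
      paths$cohort_groups <- note(file.path(out_dir, "cohort_groups.csv"))
      utils::write.csv(rep$groups, paths$cohort_groups, row.names = FALSE,
                       quote = FALSE)
      rep
    })
  } else {
    if (!is.null(config$phantom)) {
      vols <- stage("phantom", {
        spec_pre <- do.call(phantom_spec, config$phantom$pre)
        spec_post <- do.call(phantom_spec, config$phantom$post)
        make_phantom_pair(spec_pre, spec_post)
      })
      dwi <- vols$dwi; flair <- vols$flair
      seeds_dwi <- if (!is.null(config$seeds$dwi))
        as_seed_matrix(config$seeds$dwi, dwi, config$seeds$units)
      else seeds_from_mask(vols$truth_pre, dwi)
      seeds_flair <- if (!is.null(config$seeds$flair))
        as_seed_matrix(config$seeds$flair, flair, config$seeds$units)
      else seeds_from_mask(vols$truth_post, flair)
      input_hashes <- list(phantom_pre_seed = config$phantom$pre$rng_seed,
                           phantom_post_seed = config$phantom$post$rng_seed)
    } else {
      dwi <- stage("load", read_volume_nifti(config$inputs$dwi, "dwi"))
      flair <- read_volume_nifti(config$inputs$flair, "flair")
      seeds_dwi <- as_seed_matrix(config$seeds$dwi, dwi, config$seeds$units)
      seeds_flair <- as_seed_matrix(config$seeds$flair, flair,
                                    config$seeds$units)
      input_hashes <- as.list(tools::md5sum(c(config$inputs$dwi,
                                              config$inputs$flair)))
    }

    seg <- config$segmentation
    masks <- stage("segment", {
      m_pre <- region_grow(dwi, seeds_dwi, seg$rel_threshold,
                           seg$connectivity, seg$mode, seg$band)
      m_post <- region_grow(flair, seeds_flair, seg$rel_threshold,
                            seg$connectivity, seg$mode, seg$band)
      paths$mask_dwi <- note(file.path(out_dir, "mask_dwi.nii"))
      write_nifti(m_pre, paths$mask_dwi)
      paths$mask_flair <- note(file.path(out_dir, "mask_flair.nii"))
      write_nifti(m_post, paths$mask_flair)
      list(pre = m_pre, post = m_post)
    })

    volumetrics <- stage("volumetrics", {
      v_pre <- lesion_volume(masks$pre)
      v_post <- lesion_volume(masks$post)
      mm <- mismatch(v_pre, v_post)
      df <- data.frame(dwi_pre_cm3 = v_pre, flair_post_cm3 = v_post,
                       mismatch_cm3 = round_half_out(mm),
                       flair_dwi_rate = round_half_out(
                         flair_dwi_rate(v_pre, v_post)),
                       evolution = classify_evolution(mm))
      paths$volumetrics <- note(file.path(out_dir, "volumetrics.csv"))
      utils::write.csv(df, paths$volumetrics, row.names = FALSE,
                       quote = FALSE)
      df
    })

    coil <- build_coil_from_config(config$coil)
    center_mm <- config$coil$center_mm
    if (is.null(center_mm)) {
      # default placement: on the pre-lesion's in-plane axis, 5 mm below
      # the first slice (outside the volume, clear of the 1 mm guard)
      ctr <- colMeans(voxel_centers_mm(dim(masks$pre$data),
                                       masks$pre$spacing_mm,
                                       masks$pre$origin_mm,
                                       subset = masks$pre$data))
      center_mm <- c(ctr[1], ctr[2], -5)
    }
    field <- stage("field", {
      f <- field_on_grid(coil, dwi, center_mm)
      bmag <- image_volume(array(field_magnitude_mT(f),
                                 dim = dim(dwi$data)),
                           dwi$spacing_mm, dwi$origin_mm, "dwi")
      paths$field_map <- note(file.path(out_dir, "bmag_mT.nii"))
      write_nifti(bmag, paths$field_map)
      paths$coil_vertices <- note(file.path(out_dir, "coil_vertices.txt"))
      write_coil_vertices(coil, paths$coil_vertices)
      f
    })

    stage("dose", {
      doses <- list(
        dwi_pre = lesion_field_stats(field, masks$pre,
                                     config$dose$threshold_mT, center_mm),
        flair_post = lesion_field_stats(field, masks$post,
                                        config$dose$threshold_mT,
                                        center_mm))
      paths$dose <- note(file.path(out_dir, "dose.csv"))
      utils::write.csv(dose_report(doses), paths$dose, row.names = FALSE,
                       quote = FALSE)
      doses
    })
  }

  stage("manifest", {
    paths$manifest <- note(file.path(out_dir, "manifest.json"))
    manifest <- list(
      package = "elfdose",
      version = as.character(utils::packageVersion("elfdose")),
      rng_seed = config$rng_seed,
      config = unclass(config),
      input_hashes = input_hashes,
      outputs = as.list(tools::md5sum(
        setdiff(unlist(paths), paths$manifest))))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    NULL
  })
  invisible(paths)
}
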