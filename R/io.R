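# NIfTI and table I/O. All volumes travel as NIfTI-1 through RNifti; region
# and cohort tables are plain TSV. Grids are index-addressed: inputs must
# already share one voxel grid (no world-space resampling here).

#' Read a NIfTI volume
#'
#' 3D files come back as a [masked_volume] (mask all-`TRUE` unless `mask` is
#' given), 4D files as a [bold_series] with the repetition time taken from the
#' header. Voxel sizes are populated from the header `pixdim`.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param mask optional 3D logical array to attach to a 3D volume.
#' @return A `masked_volume` or `bold_series`.
#' @export
read_volume <- function(path, mask = NULL) {
  if (!file.exists(path))
    stop_nc(sprintf("file not found: %s", path), "nc_io_error")
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop_nc(
                    sprintf("malformed NIfTI file %s: %s", path, conditionMessage(e)),
                    "nc_format_error"))
  nd <- length(dim(img))
  pd <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim(img))
  if (nd == 3L) {
    masked_volume(arr, mask = mask, voxel_size_mm = pd[1:3])
  } else if (nd == 4L) {
    tr <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else 1
    bold_series(arr, tr_s = tr, voxel_size_mm = pd[1:3])
  } else {
    stop_nc(sprintf("expected a 3D or 4D volume, got %dD", nd),
            "nc_dimension_error")
  }
}

#' Write a volume to NIfTI-1
#'
#' @param vol a [masked_volume], [bold_series], [atlas_parcellation], or bare
#'   3D/4D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param tr_s repetition time stored in the 4th `pixdim` slot for 4D data.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, tr_s = NULL) {
  if (inherits(vol, "masked_volume")) {
    arr <- vol$data; vox <- vol$voxel_size_mm
  } else if (inherits(vol, "bold_series")) {
    arr <- vol$data; vox <- vol$voxel_size_mm; tr_s <- vol$tr_s
  } else if (inherits(vol, "atlas_parcellation")) {
    arr <- vol$labels; vox <- c(3, 3, 3)
  } else {
    arr <- as.array(vol); vox <- c(3, 3, 3)
  }
  img <- RNifti::asNifti(arr)
  pd <- if (length(dim(arr)) == 4L) c(vox, if (is.null(tr_s)) 1 else tr_s) else vox
  RNifti::pixdim(img) <- pd
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop_nc(sprintf("cannot write %s", path), "nc_io_error")
  invisible(path)
}

#' Write / read a region table
#' @param regions data.frame with `id`, `name`, `is_hub`.
#' @param path TSV path.
#' @return `path` / a data.frame.
#' @export
write_regions <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$is_hub <- as.logical(df$is_hub)
  df
}

#' Map a total Fazekas score to its severity group
#'
#' The total score is the sum of the deep (0-3) and periventricular (0-3)
#' visual ratings; totals of 1-2 define the mild, 3-4 the moderate, and 5-6
#' the severe white-matter-hyperintensity group.
#'
#' @param fazekas_total integer vector of total scores, 1-6.
#' @return factor with levels `mild`, `moderate`, `severe`.
#' @export
fazekas_group <- function(fazekas_total) {
  if (any(fazekas_total < 1 | fazekas_total > 6))
    stop_nc("total Fazekas score must lie in 1-6", "nc_validation_error")
  cut(fazekas_total, breaks = c(0, 2, 4, 6),
      labels = c("mild", "moderate", "severe"))
}

wmh_groups <- function() c("mild", "moderate", "severe")

validate_cohort_df <- function(df) {
  need <- c("id", "fazekas_total", "group", "age", "sex", "education_years")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_nc(paste("cohort table missing columns:", paste(miss, collapse = ", ")),
            "nc_validation_error")
  if (anyDuplicated(df$id))
    stop_nc("subject ids are not unique", "nc_duplicate_id_error")
  expected <- as.character(fazekas_group(df$fazekas_total))
  bad <- which(as.character(df$group) != expected)
  if (length(bad))
    stop_nc(sprintf(
      "Fazekas/group mismatch for subject(s) %s (e.g. total %d labeled '%s', expected '%s')",
      paste(df$id[bad], collapse = ", "), df$fazekas_total[bad[1]],
      df$group[bad[1]], expected[bad[1]]), "nc_group_mismatch_error")
  if (!all(df$sex %in% c("M", "F")))
    stop_nc("sex must be 'M' or 'F'", "nc_validation_error")
  invisible(df)
}

#' Load and validate a cohort from a config file
#'
#' The config (YAML or JSON) names the cohort table, the gray-matter mask,
#' the atlas, and optional per-subject volume path templates in which `{id}`
#' is replaced by the subject id:
#' \preformatted{
#' cohort: cohort.tsv
#' mask: mask.nii.gz
#' atlas: atlas.nii.gz
#' regions: regions.tsv
#' volumes:
#'   bold: "{id}_bold.nii.gz"
#'   cbf:  "{id}_cbf.nii.gz"
#' }
#' All relative paths resolve against the config file's directory. Every
#' invariant is checked eagerly: unique subject ids, Fazekas/group
#' consistency, referenced files exist, and every referenced volume shares the
#' mask's grid (a mismatch names the offending subject).
#'
#' @param config_path path to the YAML/JSON config.
#' @return Object of class `cohort_table`: a list with `subjects`
#'   (data.frame), `mask`, `atlas`, and `paths` (per-subject named paths).
#' @export
load_cohort <- function(config_path) {
  cfg <- read_config(config_path)
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  df <- read.delim(resolve(cfg$cohort), stringsAsFactors = FALSE)
  validate_cohort_df(df)
  mask_vol <- read_volume(resolve(cfg$mask))
  mask <- mask_vol$data > 0.5
  atlas <- NULL
  if (!is.null(cfg$atlas)) {
    av <- read_volume(resolve(cfg$atlas))
    regions <- read_regions(resolve(cfg$regions))
    atlas <- atlas_parcellation(av$data, regions)
    if (!identical(dim(atlas$labels), dim(mask)))
      stop_nc("atlas grid differs from the mask grid", "nc_grid_mismatch_error")
  }
  paths <- list()
  for (kind in names(cfg$volumes)) {
    tmpl <- cfg$volumes[[kind]]
    p <- vapply(df$id, function(id) resolve(gsub("{id}", id, tmpl, fixed = TRUE)),
                character(1))
    for (i in seq_along(p)) {
      if (!file.exists(p[i]))
        stop_nc(sprintf("missing %s volume for subject %s: %s",
                        kind, df$id[i], p[i]), "nc_io_error")
      hdr <- RNifti::niftiHeader(p[i])
      d <- hdr$dim[2:4]
      if (!identical(as.integer(d), as.integer(dim(mask))))
        stop_nc(sprintf("grid mismatch for subject %s (%s volume %s vs mask %s)",
                        df$id[i], kind, paste(d, collapse = "x"),
                        paste(dim(mask), collapse = "x")),
                "nc_grid_mismatch_error")
    }
    paths[[kind]] <- p
  }
  nc_log("load_cohort", n_subjects = nrow(df), grid = dim(mask))
  structure(list(subjects = df, mask = mask, atlas = atlas, paths = paths,
                 voxel_size_mm = mask_vol$voxel_size_mm),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table: %d subjects (%s)>\n", nrow(x$subjects),
              paste(sprintf("%s=%d", wmh_groups(),
                            table(factor(x$subjects$group, wmh_groups()))),
                    collapse = ", ")))
  invisible(x)
}

read_config <- function(path) {
  if (!file.exists(path))
    stop_nc(sprintf("config not found: %s", path), "nc_io_error")
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
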