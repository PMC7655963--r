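#' Write a BOLD series to a NIfTI file
#'
#' Stores the 4-D array with the affine in the sform/qform and the repetition
#' time in the fourth pixdim slot.
#'
#' @param series a [bold_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  img <- RNifti::`sform<-`(img, structure(series$affine, code = 2L))
  hdr <- RNifti::niftiHeader(img)
  hdr$pixdim[2:4] <- sqrt(colSums(series$affine[1:3, 1:3]^2))
  hdr$pixdim[5] <- series$tr
  RNifti::writeNifti(RNifti::asNifti(series$data, reference = hdr), path)
  invisible(path)
}

#' Read a BOLD series from a NIfTI file
#'
#' @param path NIfTI path.
#' @param tr repetition time override (s); default taken from the file's
#'   fourth pixdim.
#' @return A [bold_series()].
#' @export
read_bold_nifti <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("expected a 4-D NIfTI: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else 2.5
  }
  bold_series(array(as.numeric(img), dim(img)), aff, tr)
}

#' Write a 3-D map to NIfTI
#'
#' @param values 3-D numeric or logical array.
#' @param affine 4x4 voxel-to-world transform.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(values, affine, path) {
  img <- RNifti::asNifti(array(as.numeric(values), dim(values)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D map from NIfTI
#'
#' @param path NIfTI path.
#' @return List with `values` (3-D array) and `affine`.
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3-D NIfTI: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(values = array(as.numeric(img), dim(img)), affine = aff)
}

#' Write a motion trace as 6-column whitespace-delimited text
#'
#' SPM realignment dialect: three translations (mm) then three rotations
#' (radians), one row per volume, no header.
#'
#' @param trace a [motion_trace()].
#' @param path output path (conventionally `rp_*.txt`).
#' @return `path`, invisibly.
#' @export
write_motion_txt <- function(trace, path) {
  utils::write.table(format(unclass(trace), scientific = TRUE, digits = 8),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a 6-column motion-parameter text file
#'
#' @param path text file with one row per volume and 6 whitespace-delimited
#'   columns.
#' @return A [motion_trace()].
#' @export
read_motion_txt <- function(path) {
  motion_trace(as.matrix(utils::read.table(path)))
}

#' Write a synthetic cohort to disk
#'
#' Emits the on-disk layout consumed by the pipeline: per-subject 4-D BOLD
#' NIfTIs and motion text files, the gray-matter probability NIfTI, one
#' binary NIfTI per RSN template (with a label manifest), the covariate table
#' as CSV (`subject_id`, `age`, `sex`, `acer_total`), and the ground truth as
#' a JSON sidecar.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "templates"), showWarnings = FALSE)
  ids <- cohort$covariates$subject_id
  for (s in seq_along(cohort$bold)) {
    write_bold_nifti(cohort$bold[[s]],
                     file.path(dir, sprintf("%s_bold.nii.gz", ids[s])))
    write_motion_txt(cohort$motion[[s]],
                     file.path(dir, sprintf("rp_%s.txt", ids[s])))
  }
  write_map_nifti(cohort$gm_prob$map, cohort$gm_prob$affine,
                  file.path(dir, "gm_probability.nii.gz"))
  manifest <- data.frame(label = names(cohort$templates),
                         file = sprintf("templates/%s.nii.gz",
                                        names(cohort$templates)))
  for (nm in names(cohort$templates)) {
    tp <- cohort$templates[[nm]]
    write_map_nifti(tp$mask, tp$affine,
                    file.path(dir, "templates", sprintf("%s.nii.gz", nm)))
  }
  utils::write.csv(manifest, file.path(dir, "templates", "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(grid_shape = dim(truth$network_assignment),
         network_assignment = as.integer(truth$network_assignment),
         hub_voxels = which(truth$hub_mask),
         subject_ages = truth$subject_ages,
         subject_sex = truth$subject_sex,
         true_acer = truth$true_acer),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Read a covariate table
#'
#' @param path CSV with columns `subject_id`, `age`, `sex`, `acer_total`.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  cov <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "acer_total")
  if (!all(need %in% names(cov)))
    stop("covariate table must contain columns: ", paste(need, collapse = ", "))
  cov
}

#' Write a per-subject quality-control table
#'
#' @param screening data.frame from [screen_subjects()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_csv <- function(screening, path) {
  utils::write.csv(screening, path, row.names = FALSE)
  invisible(path)
}

#' Write a cluster table as CSV
#'
#' @param table a `cluster_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Write an ICC map with its JSON sidecar
#'
#' Writes the 3-D map as NIfTI plus a JSON sidecar recording the mode, the
#' distance threshold, the denominator convention, whether the map is
#' standardized, and the linear indices of any zero-variance voxels.
#'
#' @param map an `icc_map`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_icc_nifti <- function(map, prefix) {
  write_map_nifti(map$values, map$affine, paste0(prefix, ".nii.gz"))
  jsonlite::write_json(
    list(mode = map$mode, d_thr_mm = map$d_thr_mm,
         denominator = map$denominator, standardized = map$standardized,
         zero_variance_voxels = which(map$zero_variance)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
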