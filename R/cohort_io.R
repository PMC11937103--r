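# Cohort persistence: NIfTI volumes (via RNifti), visits/subjects CSV.

#' Write a cohort to disk
#'
#' Writes `mri_<id>.nii.gz` and `pet_<id>.nii.gz` per subject plus
#' `visits.csv` and `subjects.csv`. The write is atomic at the level of
#' precondition checks: duplicate subject ids abort before any file is
#' created.
#'
#' @param cohort a `pd_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, a data.frame manifest of written files.
#' @export
write_cohort <- function(cohort, dir) {
  assert_that(inherits(cohort, "pd_cohort"), "`cohort` must be a pd_cohort")
  ids <- cohort$subjects$subject_id
  assert_that(!anyDuplicated(ids), "duplicate subject ids; nothing written")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(dir) && file.access(dir, 2) == 0,
              sprintf("directory '%s' is not writable", dir))

  files <- character(0)
  for (id in ids) {
    vp <- cohort$volumes[[id]]
    fm <- file.path(dir, sprintf("mri_%s.nii.gz", id))
    fp <- file.path(dir, sprintf("pet_%s.nii.gz", id))
    RNifti::writeNifti(RNifti::asNifti(vp$mri, datatype = "double"), fm)
    RNifti::writeNifti(RNifti::asNifti(vp$pet, datatype = "double"), fp)
    files <- c(files, fm, fp)
  }
  fv <- file.path(dir, "visits.csv")
  fs <- file.path(dir, "subjects.csv")
  utils::write.csv(cohort$visits, fv, row.names = FALSE)
  utils::write.csv(cohort$subjects, fs, row.names = FALSE)
  files <- c(files, fv, fs)
  invisible(data.frame(file = files, stringsAsFactors = FALSE))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `subjects.csv`, `visits.csv` and the
#'   per-subject NIfTI pairs.
#' @param load_volumes read the NIfTI volumes (set `FALSE` for table-only use).
#' @return a `pd_cohort` (with `config = NULL`; generator truth lives in the
#'   `sim_` columns of `subjects`).
#' @export
read_cohort <- function(dir, load_volumes = TRUE) {
  fs <- file.path(dir, "subjects.csv")
  fv <- file.path(dir, "visits.csv")
  assert_that(file.exists(fs) && file.exists(fv),
              sprintf("'%s' does not contain subjects.csv/visits.csv", dir))
  subjects <- utils::read.csv(fs, stringsAsFactors = FALSE)
  visits <- utils::read.csv(fv, stringsAsFactors = FALSE)
  volumes <- NULL
  if (load_volumes) {
    volumes <- lapply(subjects$subject_id, function(id) {
      mri <- RNifti::readNifti(file.path(dir, sprintf("mri_%s.nii.gz", id)))
      pet <- RNifti::readNifti(file.path(dir, sprintf("pet_%s.nii.gz", id)))
      structure(list(mri = unclass(as.array(mri)),
                     pet = unclass(as.array(pet)),
                     shape = dim(mri),
                     voxel_spacing = c(1, 1, 1),
                     affine = diag(4)),
                class = "pd_volume_pair")
    })
    names(volumes) <- subjects$subject_id
  }
  structure(list(subjects = subjects, visits = visits, volumes = volumes,
                 config = NULL, seed = NA_integer_),
            class = "pd_cohort")
}
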