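## Shared I/O: NIfTI volumes with JSON timing sidecars, CSV tables, YAML
## configuration, and the volume-normalization arithmetic.

#' Write / read a dynamic series as NIfTI plus JSON sidecar
#'
#' The 4D signal array is stored as NIfTI-1 with the per-volume acquisition
#' times, sequence tag and baseline count in a JSON sidecar
#' (`{"times_s": [...], "sequence": "fast|slow", "baseline_count": n}`)
#' next to the image.
#'
#' @param series a [dynamicSeries()].
#' @param path output image path (`.nii` or `.nii.gz`); the sidecar replaces
#'   the image extension with `.json`.
#' @return `writeDynamicSeries` returns `path` invisibly;
#'   `readDynamicSeries` returns a [dynamicSeries()].
#' @export
writeDynamicSeries <- function(series, path) {
  RNifti::writeNifti(series@data, path)
  jsonlite::write_json(
    list(times_s = series@times, sequence = series@sequenceTag,
         baseline_count = series@baselineCount),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDynamicSeries
#' @export
readDynamicSeries <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  dynamicSeries(array(as.numeric(img), dim = dim(img)),
                side$times_s, side$sequence, side$baseline_count)
}

sidecarPath <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write / read a 3D map (T1, labels, Ki, ...) as NIfTI
#'
#' @param map 3D numeric or integer array.
#' @param path image path (`.nii` or `.nii.gz`).
#' @return `writeVolume` returns `path` invisibly; `readVolume` a 3D array.
#' @export
writeVolume <- function(map, path) {
  RNifti::writeNifti(map, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Read a simulated acquisition directory
#'
#' Counterpart of the files written by [runPipeline()]'s simulate stage:
#' fast/slow dynamic series with sidecars, T1 map and label mask.
#'
#' @param dir directory containing `fast.nii.gz`, `slow.nii.gz`,
#'   `t1.nii.gz`, `labels.nii.gz` and the JSON sidecars.
#' @return A list with `fast`, `slow`, `t1`, `labels`.
#' @export
readAcquisition <- function(dir) {
  list(fast = readDynamicSeries(file.path(dir, "fast.nii.gz")),
       slow = readDynamicSeries(file.path(dir, "slow.nii.gz")),
       t1 = readVolume(file.path(dir, "t1.nii.gz")),
       labels = round(readVolume(file.path(dir, "labels.nii.gz"))))
}

#' Regional volumes normalized to the intracranial volume
#'
#' Computes per-region voxel counts and millilitre volumes, and the
#' relative brain and WMH volumes (structure volume divided by intracranial
#' volume), the normalization used before any between-patient comparison of
#' volumes.
#'
#' @param labels 3D integer label array.
#' @param icvMask logical/0-1 3D array of the intracranial volume; defaults
#'   to all non-background voxels.
#' @param voxelDims voxel edge lengths (mm), length 3.
#' @return A list with `regionVoxels`, `regionML`, `icvVoxels`,
#'   `relativeBrainVolume`, `relativeWmhVolume`.
#' @export
computeRelativeVolumes <- function(labels, icvMask = NULL,
                                   voxelDims = c(1, 1, 1)) {
  if (is.null(icvMask)) icvMask <- labels != 0L
  nIcv <- sum(as.logical(icvMask))
  if (nIcv == 0L) stop("intracranial mask is empty")
  codes <- regionCodes()
  vmm3 <- prod(voxelDims)
  regionVoxels <- vapply(codes, function(cd) sum(labels == cd), numeric(1))
  brain <- sum(regionVoxels[tissueRegions()])
  list(regionVoxels = regionVoxels,
       regionML = regionVoxels * vmm3 / 1e3,
       icvVoxels = nIcv,
       relativeBrainVolume = brain / nIcv,
       relativeWmhVolume = regionVoxels[["WMH"]] / nIcv)
}

#' Structure volume relative to the intracranial volume
#'
#' The elementary normalization: `structure / icv`, dimensionless in
#' `[0, 1]` when the structure lies inside the intracranial volume.
#'
#' @param structure,icv volumes in any common unit (voxels, mL).
#' @return Relative volume.
#' @export
relativeVolume <- function(structure, icv) {
  if (icv <= 0) stop("intracranial volume must be positive")
  structure / icv
}

#' Cohort attrition arithmetic
#'
#' Number of patients remaining in an analysis after sequential losses
#' (unusable data, deaths, declined follow-up, ...).
#'
#' @param enrolled number enrolled at baseline.
#' @param losses numeric vector of patients lost, by cause.
#' @return Number analysed.
#' @export
attritionCount <- function(enrolled, losses) {
  if (any(losses < 0) || enrolled < sum(losses))
    stop("losses must be non-negative and not exceed enrolment")
  enrolled - sum(losses)
}

#' Percentage of a count within a group
#'
#' @param count numerator count.
#' @param total group size.
#' @return `100 * count / total`.
#' @export
percentOf <- function(count, total) {
  if (total <= 0) stop("total must be positive")
  100 * count / total
}
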