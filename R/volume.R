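# Core containers: volume_image and region_mask_set.
#
# Axis convention throughout: x = left-right (dim 1), y = anterior-posterior
# (dim 2), z = dorsal-ventral (dim 3). Coronal slices are fixed-y planes.
# Bregma-referenced coordinates: bregma_mm = (y_index - bregma_index) * dy.

#' Construct a volume image
#'
#' A light S3 wrapper around a 3D scalar array carrying voxel spacing and the
#' subject / session metadata the pipeline propagates into its record tables.
#'
#' @param data 3D numeric array (x = left-right, y = anterior-posterior,
#'   z = dorsal-ventral).
#' @param voxel_size_mm numeric triple (mm per voxel along x, y, z).
#' @param subject_id,group,session metadata carried into SUV records.
#' @param bregma_index y index of the bregma plane (may be fractional);
#'   `NA` if unknown.
#' @return object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size_mm = c(1, 1, 1), subject_id = NA_character_,
                         group = NA_character_, session = NA_character_,
                         bregma_index = NA_real_) {
  assert_that(is.array(data) && length(dim(data)) == 3,
              "volume_image() requires a 3D array")
  assert_that(all(is.finite(data)), "voxel values must be finite")
  assert_that(length(voxel_size_mm) == 3 && all(voxel_size_mm > 0),
              "voxel_size_mm must be 3 positive numbers")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 subject_id = subject_id, group = group, session = session,
                 bregma_index = bregma_index),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image %s  subject=%s session=%s  voxel=%.2fx%.2fx%.2f mm>\n",
              paste(dim(x$data), collapse = "x"), x$subject_id, x$session,
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Distance from bregma of a coronal slice
#' @param vol a `volume_image`
#' @param slice_index y index (1-based)
#' @return signed distance in mm (positive = anterior), `NA` if the volume has
#'   no bregma reference.
#' @export
bregma_mm <- function(vol, slice_index) {
  (slice_index - vol$bregma_index) * vol$voxel_size_mm[2]
}

#' Construct a region mask set
#'
#' Named brain regions mapped to per-coronal-slice, per-hemisphere voxel masks.
#' Each mask object is stored as linear voxel indices into the template grid.
#' Midline regions (e.g. prefrontal PLC / ILC analysed as one object per
#' slice) carry hemisphere `"BOTH"`.
#'
#' @param brain_mask logical 3D array.
#' @param objects list of mask objects, each a list with elements `region`
#'   (character), `slice` (integer y index), `hemisphere` (`"L"`, `"R"` or
#'   `"BOTH"`) and `idx` (integer voxel indices into the grid).
#' @return object of class `region_mask_set`.
#' @export
region_mask_set <- function(brain_mask, objects) {
  assert_that(is.logical(brain_mask) && length(dim(brain_mask)) == 3,
              "brain_mask must be a logical 3D array")
  assert_that(length(objects) > 0, "mask set needs at least one object")
  brain_idx <- which(brain_mask)
  seen <- character(0)
  all_idx <- integer(0)
  for (ob in objects) {
    assert_that(all(c("region", "slice", "hemisphere", "idx") %in% names(ob)),
                "each mask object needs region, slice, hemisphere, idx")
    assert_that(ob$hemisphere %in% c("L", "R", "BOTH"),
                sprintf("bad hemisphere '%s' in region %s", ob$hemisphere, ob$region))
    assert_that(length(ob$idx) > 0,
                sprintf("empty mask object: region %s slice %d (%s)",
                        ob$region, ob$slice, ob$hemisphere),
                "betapet_mask_error")
    assert_that(all(ob$idx %in% brain_idx),
                sprintf("region %s slice %d extends outside the brain mask",
                        ob$region, ob$slice),
                "betapet_mask_error")
    key <- paste(ob$region, ob$slice, ob$hemisphere)
    assert_that(!key %in% seen,
                sprintf("duplicate mask object: %s", key), "betapet_mask_error")
    seen <- c(seen, key)
    all_idx <- c(all_idx, ob$idx)
  }
  assert_that(!anyDuplicated(all_idx),
              "region masks overlap; objects must be mutually disjoint",
              "betapet_mask_error")
  structure(list(brain_mask = brain_mask, objects = objects),
            class = "region_mask_set")
}

#' @export
print.region_mask_set <- function(x, ...) {
  regs <- vapply(x$objects, function(o) o$region, character(1))
  cat(sprintf("<region_mask_set  %d regions, %d mask objects, %d brain voxels>\n",
              length(unique(regs)), length(x$objects), sum(x$brain_mask)))
  invisible(x)
}

#' Region names present in a mask set
#' @param masks a `region_mask_set`
#' @return character vector in first-appearance order
#' @export
mask_regions <- function(masks) {
  unique(vapply(masks$objects, function(o) o$region, character(1)))
}

#' Build a region mask set from a label volume
#'
#' Accepts the one-file dialect: a single integer label volume (region id per
#' voxel, 0 = background). Objects are split per coronal slice and, unless the
#' region is listed in `both_regions`, per hemisphere at the midline plane.
#'
#' @param labels integer 3D array of region ids (0 = none).
#' @param brain_mask logical 3D array.
#' @param region_names named character vector mapping id (as name) to region
#'   name, e.g. `c("1" = "BA", "2" = "PLC")`.
#' @param both_regions regions analysed as one object per slice (midline
#'   structures); default follows the prefrontal convention.
#' @param midline_index hemisphere boundary: x indices `<= midline_index` are
#'   left. Defaults to `floor(nx / 2)`.
#' @return a `region_mask_set`
#' @export
mask_set_from_labels <- function(labels, brain_mask, region_names,
                                 both_regions = c("PLC", "ILC"),
                                 midline_index = NULL) {
  dims <- dim(labels)
  assert_that(identical(dims, dim(brain_mask)),
              "labels and brain_mask must share a grid")
  midline_index <- midline_index %||% floor(dims[1] / 2)
  coords <- function(idx) arrayInd(idx, dims)
  objects <- list()
  for (id in names(region_names)) {
    reg <- region_names[[id]]
    idx <- which(labels == as.integer(id))
    if (length(idx) == 0) next
    xy <- coords(idx)
    for (s in sort(unique(xy[, 2]))) {
      in_slice <- idx[xy[, 2] == s]
      xs <- xy[xy[, 2] == s, 1]
      if (reg %in% both_regions) {
        objects[[length(objects) + 1]] <-
          list(region = reg, slice = as.integer(s), hemisphere = "BOTH",
               idx = in_slice)
      } else {
        for (h in c("L", "R")) {
          sel <- if (h == "L") xs <= midline_index else xs > midline_index
          if (any(sel)) {
            objects[[length(objects) + 1]] <-
              list(region = reg, slice = as.integer(s), hemisphere = h,
                   idx = in_slice[sel])
          }
        }
      }
    }
  }
  region_mask_set(brain_mask, objects)
}

#' Flatten a mask set back to a label volume
#' @param masks a `region_mask_set`
#' @return list with integer array `labels` and named map `region_ids`
#' @export
mask_set_to_labels <- function(masks) {
  labels <- array(0L, dim = dim(masks$brain_mask))
  regs <- mask_regions(masks)
  ids <- stats::setNames(seq_along(regs), regs)
  for (ob in masks$objects) labels[ob$idx] <- ids[[ob$region]]
  list(labels = labels, region_ids = ids)
}
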