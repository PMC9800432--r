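#' Region-of-interest map
#'
#' Five regions of interest on the reconstruction grid and their grouping
#' into anatomical regions: ROIs 1 and 2 (left/right frontal white matter)
#' combine to FWM, ROIs 3 and 4 (left/right corticospinal tract) to CST,
#' ROIs 1-4 to WM, and ROI 5 is the grey-matter region GM. ROI values are
#' voxel means; region values are arithmetic means of their constituent
#' ROI values, which also performs the left/right hemisphere averaging.
#'
#' @param rois named list (`"1"` ... `"5"`) of integer matrices with
#'   columns (row, col): the voxels belonging to each ROI.
#' @param regions named list mapping region name to the ROI indices it
#'   averages; must contain `FWM`, `CST`, `WM` and `GM`.
#' @param recon_matrix reconstruction grid size used for bounds checking.
#' @return An object of class `mrs_roi_map`.
#' @export
roi_map <- function(rois, regions, recon_matrix = c(32L, 32L)) {
  required <- c("FWM", "CST", "WM", "GM")
  missing <- setdiff(required, names(regions))
  if (length(missing)) {
    stop("region definitions lack: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rois <- lapply(rois, function(v) matrix(as.integer(v), ncol = 2))
  for (nm in names(rois)) {
    v <- rois[[nm]]
    if (!nrow(v)) stop("ROI ", nm, " has no voxels", call. = FALSE)
    if (any(v < 1L) || any(v[, 1] > recon_matrix[1]) || any(v[, 2] > recon_matrix[2])) {
      stop("ROI ", nm, " has voxels outside the reconstruction grid", call. = FALSE)
    }
  }
  for (nm in names(regions)) {
    bad <- setdiff(as.character(regions[[nm]]), names(rois))
    if (length(bad)) {
      stop("region ", nm, " references undefined ROI(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(
    list(rois = rois, regions = regions, recon_matrix = as.integer(recon_matrix)),
    class = "mrs_roi_map"
  )
}

#' Default five-ROI map
#'
#' One voxel per ROI on the 32 x 32 reconstruction grid: two frontal
#' white-matter voxels (ROI 1 left, ROI 2 right), two voxels on the
#' left/right corticospinal tract in the supraventricular white matter
#' (ROIs 3 and 4), and one parasagittal grey-matter voxel (ROI 5).
#'
#' @param recon_matrix reconstruction grid size.
#' @return An [roi_map()].
#' @export
default_roi_map <- function(recon_matrix = c(32L, 32L)) {
  r <- recon_matrix
  mid <- floor(r / 2)
  v <- function(row, col) matrix(c(row, col), ncol = 2)
  roi_map(
    rois = list(
      "1" = v(mid[1] - 4, mid[2] - 3),
      "2" = v(mid[1] - 4, mid[2] + 3),
      "3" = v(mid[1] + 3, mid[2] - 3),
      "4" = v(mid[1] + 3, mid[2] + 3),
      "5" = v(mid[1] - 6, mid[2])
    ),
    regions = list(FWM = c(1, 2), CST = c(3, 4), WM = 1:4, GM = 5),
    recon_matrix = r
  )
}

# All distinct voxels referenced by a roi map, as an integer matrix.
roi_voxels <- function(map) {
  unique(do.call(rbind, map$rois))
}

#' Aggregate per-voxel interval ratios into ROI and region values
#'
#' Averages voxel ratios within each ROI, then averages ROI values into the
#' region scheme of the map (`FWM = mean(ROI1, ROI2)`,
#' `CST = mean(ROI3, ROI4)`, `WM = mean(ROI1..4)`, `GM = ROI5` by default).
#'
#' @param voxel_ratios data frame with columns `row`, `col`, `ioi`,
#'   `ratio`: the Cr2-normalized ratios of every processed voxel.
#' @param map an [roi_map()].
#' @param scan_id identifier stamped on the output records.
#' @return A tidy ratio table: data frame with columns `scan_id`, `region`,
#'   `ioi`, `ratio`, with ROI-level means in `attr(, "roi_values")`.
#' @export
aggregate_regions <- function(voxel_ratios, map, scan_id = "scan") {
  stopifnot(inherits(map, "mrs_roi_map"))
  iois <- unique(voxel_ratios$ioi)
  key <- paste(voxel_ratios$row, voxel_ratios$col)
  roi_vals <- matrix(NA_real_, length(map$rois), length(iois),
    dimnames = list(names(map$rois), iois)
  )
  for (nm in names(map$rois)) {
    vox <- map$rois[[nm]]
    vkeys <- paste(vox[, 1], vox[, 2])
    present <- vkeys %in% key
    if (!all(present)) {
      stop(
        sprintf(
          "ROI %s is missing ratios for voxel(s): %s", nm,
          paste(vkeys[!present], collapse = "; ")
        ),
        call. = FALSE
      )
    }
    sub <- voxel_ratios[key %in% vkeys, ]
    roi_vals[nm, ] <- tapply(sub$ratio, factor(sub$ioi, levels = iois), mean)
  }
  out <- do.call(rbind, lapply(names(map$regions), function(reg) {
    members <- as.character(map$regions[[reg]])
    data.frame(
      scan_id = scan_id, region = reg, ioi = iois,
      ratio = colMeans(roi_vals[members, , drop = FALSE]),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  attr(out, "roi_values") <- roi_vals
  out
}
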