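# Box-counting fractal dimension of 3D binary regions.
#
# FD is estimated as the slope of log N(s) versus log(1/s), where N(s) is
# the number of non-overlapping axis-aligned boxes of edge length s (voxels)
# that contain at least one foreground voxel. The box grid is anchored at
# the origin of the region's bounding box, which makes the count
# deterministic and translation-invariant.

#' Box-counting curve for a binary mask
#'
#' Counts, for each box edge length `s`, the non-overlapping grid boxes of
#' edge `s` voxels that contain at least one foreground voxel. The grid is
#' anchored at the origin of the mask's bounding box; partial boxes at the
#' far edges count when they contain any foreground voxel.
#'
#' @param mask a [binary_mask()] or 3D logical array with >= 1 `TRUE` voxel.
#' @param sizes strictly decreasing positive integer box edge lengths; none
#'   may exceed the smallest dimension of the foreground bounding box.
#' @return An object of class `box_count_curve` with elements `sizes` and
#'   `counts`.
#' @seealso [default_sizes()], [fit_fd()]
#' @export
box_count <- function(mask, sizes) {
  arr <- if (inherits(mask, "binary_mask")) mask$data else mask
  if (!is.logical(arr)) stop("`mask` must be logical")
  if (!any(arr)) stop("mask is empty: box counting requires >= 1 foreground voxel")
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || any(sizes < 1L)) stop("box sizes must be positive integers")
  if (length(sizes) > 1L && any(diff(sizes) >= 0L)) {
    stop("box sizes must be strictly decreasing")
  }
  min_dim <- min(dim(arr))
  if (any(sizes > min_dim)) {
    bad <- sizes[sizes > min_dim][1L]
    stop("box size ", bad, " exceeds the smallest mask dimension (",
         min_dim, ")")
  }
  cropped <- crop_to_bbox(arr)
  idx0 <- which(cropped, arr.ind = TRUE) - 1L  # 0-based voxel coordinates
  d <- dim(cropped)
  counts <- vapply(sizes, function(s) {
    box <- idx0 %/% s
    nb <- ceiling(d / s)
    key <- box[, 1L] + nb[1L] * (box[, 2L] + nb[2L] * box[, 3L])
    length(unique(key))
  }, integer(1))
  new_box_count_curve(sizes, counts, dims = d)
}

new_box_count_curve <- function(sizes, counts, dims = NULL) {
  stopifnot(length(sizes) == length(counts), all(counts >= 1L))
  structure(list(sizes = as.integer(sizes), counts = as.integer(counts),
                 dims = dims),
            class = "box_count_curve")
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat("<box_count_curve> ", length(x$sizes), " scales\n", sep = "")
  print(data.frame(size = x$sizes, count = x$counts), row.names = FALSE)
  invisible(x)
}

#' Default box-size schedule for a mask
#'
#' Starts at the smallest dimension of the foreground bounding box and
#' floor-halves down to 1 voxel, dropping duplicates. At least three sizes
#' are required for a fractal-dimension fit.
#'
#' @param mask a [binary_mask()] or 3D logical array, non-empty.
#' @return Integer vector of strictly decreasing box edge lengths.
#' @export
default_sizes <- function(mask) {
  arr <- if (inherits(mask, "binary_mask")) mask$data else mask
  if (!any(arr)) stop("mask is empty")
  s <- min(dim(crop_to_bbox(arr)))
  sizes <- integer(0)
  while (s >= 1L) {
    sizes <- c(sizes, s)
    if (s == 1L) break
    s <- s %/% 2L
  }
  sizes <- unique(sizes)
  if (length(sizes) < 3L) {
    stop("bounding box too small: only ", length(sizes),
         " box sizes available, need >= 3; pad or reject this region")
  }
  sizes
}

#' Fit the fractal dimension from a box-counting curve
#'
#' Ordinary least-squares fit of log N(s) on log(1/s); the slope is the FD
#' estimate. Valid 3D inputs give FD in \[0, 3\]; out-of-range fits are kept
#' but flagged with a warning.
#'
#' @param curve a `box_count_curve` with >= 3 points.
#' @param mode provenance tag, `"mask"` (filled region) or `"boundary"`.
#' @return An object of class `fd_result`: `fd`, `fit_r2`, `curve`, `mode`,
#'   `in_range`.
#' @export
fit_fd <- function(curve, mode = c("mask", "boundary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "box_count_curve"))
  if (length(curve$sizes) < 3L) stop("need >= 3 (size, count) pairs for a fit")
  x <- log(1 / curve$sizes)
  y <- log(curve$counts)
  if (max(x) - min(x) < .Machine$double.eps * 10) {
    stop("zero variance in log(1/s): sizes are degenerate")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2L])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  in_range <- slope >= -1e-6 && slope <= 3 + 1e-6
  if (!in_range) {
    warning("fitted fd = ", format(slope), " outside [0, 3]; flagged")
  }
  structure(list(fd = slope, fit_r2 = r2, curve = curve, mode = mode,
                 in_range = in_range),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("<fd_result> fd = %.4f (R^2 = %.6f, %d sizes, mode = %s)\n",
              x$fd, x$fit_r2, length(x$curve$sizes), x$mode))
  invisible(x)
}

#' Fractal dimension of one labelled region
#'
#' Extracts the binary mask of `label`, crops it to its bounding box, and
#' runs [box_count()] with [default_sizes()] followed by [fit_fd()]. In
#' `"boundary"` mode the mask is first reduced to its 6-connectivity
#' boundary (mask minus its one-voxel erosion), so the FD describes surface
#' rather than bulk complexity.
#'
#' A warning is emitted when voxel spacing anisotropy exceeds 20% since FD
#' is computed in voxel units; see [resample_isotropic()].
#'
#' @param volume a [label_volume()].
#' @param label integer region label present in the volume.
#' @param mode `"mask"` (default, count filled voxels) or `"boundary"`.
#' @return An [fit_fd()] result.
#' @export
region_fd <- function(volume, label, mode = c("mask", "boundary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "label_volume"))
  present <- setdiff(sort(unique(as.vector(volume$data))), 0L)
  if (!label %in% present) {
    stop("label ", label, " not present; available labels: ",
         paste(present, collapse = ", "))
  }
  if (max(volume$spacing) / min(volume$spacing) > 1.2) {
    warning("voxel spacing anisotropy exceeds 20%; FD is computed in voxel ",
            "units (consider resample_isotropic())")
  }
  arr <- crop_to_bbox(volume$data == label)
  if (mode == "boundary") arr <- boundary_voxels(arr)
  sizes <- default_sizes(arr)
  fit_fd(box_count(arr, sizes), mode = mode)
}

#' Resample a label volume to isotropic voxels
#'
#' Nearest-neighbour resampling to a cubic voxel of edge `min(spacing)`,
#' for inputs acquired with anisotropic voxels.
#'
#' @param volume a [label_volume()].
#' @return A [label_volume()] with isotropic spacing.
#' @export
resample_isotropic <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  sp <- volume$spacing
  target <- min(sp)
  if (max(sp) / target <= 1 + 1e-9) return(volume)
  d <- dim(volume$data)
  new_d <- pmax(1L, as.integer(round(d * sp / target)))
  grid <- lapply(seq_len(3), function(a) {
    pmin(d[a], pmax(1L, as.integer(ceiling((seq_len(new_d[a]) - 0.5) *
                                             target / sp[a]))))
  })
  label_volume(volume$data[grid[[1]], grid[[2]], grid[[3]], drop = FALSE],
               spacing = rep(target, 3), region_names = volume$region_names)
}

#' Regional FD table for a cohort of labelled volumes
#'
#' Computes per-subject, per-region FD. Regions that cannot support a fit
#' (bounding box too small for three box sizes) are recorded as missing
#' with the reason, not dropped silently.
#'
#' @param volumes named list of [label_volume()] objects; names are subject
#'   ids (duplicates are an error).
#' @param mode `"mask"` or `"boundary"`, applied to every region.
#' @return A data frame with columns `subject_id`, `region`, `fd`,
#'   `fit_r2`, `n_sizes`, `mode`; skipped regions carry `NA` fd and the
#'   attribute `missing` lists them with reasons.
#' @export
extract_cohort_fd <- function(volumes, mode = c("mask", "boundary")) {
  mode <- match.arg(mode)
  if (is.null(names(volumes)) || any(!nzchar(names(volumes)))) {
    stop("`volumes` must be a named list (names are subject ids)")
  }
  if (anyDuplicated(names(volumes))) {
    stop("duplicate subject ids: ",
         paste(unique(names(volumes)[duplicated(names(volumes))]), collapse = ", "))
  }
  rows <- list()
  missing <- list()
  for (sid in names(volumes)) {
    vol <- volumes[[sid]]
    labs <- setdiff(sort(unique(as.vector(vol$data))), 0L)
    if (length(labs) == 0L) stop("subject ", sid, " has no non-background label")
    for (lab in labs) {
      region <- region_label_name(vol, lab)
      res <- tryCatch(region_fd(vol, lab, mode = mode), error = identity)
      if (inherits(res, "error")) {
        missing[[length(missing) + 1L]] <- data.frame(
          subject_id = sid, region = region, reason = conditionMessage(res))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, region = region, fd = NA_real_, fit_r2 = NA_real_,
          n_sizes = NA_integer_, mode = mode)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, region = region, fd = res$fd, fit_r2 = res$fit_r2,
          n_sizes = length(res$curve$sizes), mode = mode)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  missing_df <- if (length(missing)) do.call(rbind, missing) else
    data.frame(subject_id = character(), region = character(), reason = character())
  if (nrow(missing_df)) {
    message(nrow(missing_df), " region(s) skipped; see attr(, 'missing')")
  }
  structure(out, missing = missing_df)
}

region_label_name <- function(volume, label) {
  nm <- volume$region_names
  key <- as.character(label)
  if (!is.null(nm) && key %in% names(nm)) nm[[key]] else sprintf("region_%03d", label)
}

#' Write / read a regional FD table as TSV
#'
#' @param fd_table data frame from [extract_cohort_fd()].
#' @param path TSV path.
#' @return `path` (write) or the table (read).
#' @export
write_fd_table <- function(fd_table, path) {
  utils::write.table(fd_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fd_table
#' @export
read_fd_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
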