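#' Displacement magnitude map
#'
#' Per-voxel Euclidean norm |u(x)| of a displacement field, in mm (the
#' quantity rendered as a heat map under the arrow plots).
#'
#' @param f a \code{displacement_field}.
#' @return a \code{volume_grid} of magnitudes.
#' @export
magnitude_map <- function(f) {
  stopifnot(inherits(f, "displacement_field"))
  mag <- sqrt(f$vectors[, , , 1]^2 + f$vectors[, , , 2]^2 + f$vectors[, , , 3]^2)
  volume_grid(mag, f$spacing, f$origin)
}

#' Slice specification for displacement renderings
#'
#' @param plane one of "axial" (fixed z), "coronal" (fixed y) or "sagittal"
#'   (fixed x; the median plane).
#' @param index 0-based slice index along the fixed axis.
#' @param stride arrow subsampling stride in voxels (>= 1).
#' @param mag_range optional length-2 colour range for the magnitude heat
#'   map (mm); defaults to the slice's own range.
#' @return object of class \code{slice_spec}.
#' @export
slice_spec <- function(plane = c("coronal", "axial", "sagittal"), index,
                       stride = 4, mag_range = NULL) {
  plane <- match.arg(plane)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  structure(list(plane = plane, index = as.integer(index),
                 stride = as.integer(stride), mag_range = mag_range),
            class = "slice_spec")
}

slice_axis <- function(plane) switch(plane, sagittal = 1L, coronal = 2L, axial = 3L)

#' Arrow (quiver) plot of a displacement field on a slice
#'
#' Renders stride-subsampled in-mask displacement vectors as arrows over the
#' displacement-magnitude heat map for one orthogonal slice, and writes the
#' numbers behind the figure (voxel indices, physical coordinates, label,
#' in-plane vector components, magnitude) to a CSV so that analyses and
#' tests assert on data, never on rendered pixels. Output is deterministic
#' for fixed inputs.
#'
#' @param f \code{displacement_field}.
#' @param labels \code{label_volume} on the same grid; arrows are drawn at
#'   voxels with nonzero label.
#' @param s a [slice_spec()].
#' @param out_path figure file (.png or .pdf decides the device); NULL to
#'   skip rendering.
#' @param export_csv CSV path for the sampled vectors; NULL to skip.
#' @return invisibly, the data.frame of sampled arrows.
#' @export
arrow_plot <- function(f, labels, s, out_path = NULL, export_csv = NULL) {
  stopifnot(inherits(f, "displacement_field"), inherits(s, "slice_spec"))
  stop_if_grid_mismatch(f, labels, "field and labels")
  dm <- dim(f$vectors)[1:3]
  ax <- slice_axis(s$plane)
  if (s$index < 0 || s$index >= dm[ax])
    stop("slice index ", s$index, " out of range for ", s$plane,
         " plane (0..", dm[ax] - 1, ")", call. = FALSE)
  inplane <- setdiff(1:3, ax)

  idx <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  idx[[ax]] <- s$index + 1L
  mag <- magnitude_map(f)$values[idx[[1]], idx[[2]], idx[[3]]]
  lab_slice <- labels$values[idx[[1]], idx[[2]], idx[[3]]]
  u1 <- f$vectors[, , , inplane[1]][idx[[1]], idx[[2]], idx[[3]]]
  u2 <- f$vectors[, , , inplane[2]][idx[[1]], idx[[2]], idx[[3]]]

  n1 <- dm[inplane[1]]; n2 <- dm[inplane[2]]
  keep1 <- seq(1, n1, by = s$stride); keep2 <- seq(1, n2, by = s$stride)
  grid <- expand.grid(i = keep1, j = keep2)
  sel <- lab_slice[cbind(grid$i, grid$j)] != 0L
  grid <- grid[sel, , drop = FALSE]

  id_by_num <- stats::setNames(names(labels$label_dict), labels$label_dict)
  arrows_df <- data.frame(
    plane = s$plane, slice_index = s$index,
    vox1 = grid$i - 1L, vox2 = grid$j - 1L,
    mm1 = f$origin[inplane[1]] + (grid$i - 1) * f$spacing[inplane[1]],
    mm2 = f$origin[inplane[2]] + (grid$j - 1) * f$spacing[inplane[2]],
    label = unname(id_by_num[as.character(lab_slice[cbind(grid$i, grid$j)])]),
    u_inplane1 = u1[cbind(grid$i, grid$j)],
    u_inplane2 = u2[cbind(grid$i, grid$j)],
    magnitude_mm = mag[cbind(grid$i, grid$j)],
    stringsAsFactors = FALSE
  )

  if (!is.null(export_csv)) utils::write.csv(arrows_df, export_csv, row.names = FALSE)
  if (!is.null(out_path)) {
    ext <- tolower(tools::file_ext(out_path))
    if (ext == "pdf") grDevices::pdf(out_path, width = 6, height = 6)
    else grDevices::png(out_path, width = 720, height = 720, type = "cairo")
    on.exit(grDevices::dev.off(), add = TRUE)
    zl <- if (is.null(s$mag_range)) range(mag) else s$mag_range
    if (diff(zl) == 0) zl <- zl + c(0, 1e-6)
    x_mm <- f$origin[inplane[1]] + (seq_len(n1) - 1) * f$spacing[inplane[1]]
    y_mm <- f$origin[inplane[2]] + (seq_len(n2) - 1) * f$spacing[inplane[2]]
    graphics::image(x_mm, y_mm, mag, zlim = zl, useRaster = TRUE, asp = 1,
                    col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                    xlab = paste0("axis ", inplane[1], " (mm)"),
                    ylab = paste0("axis ", inplane[2], " (mm)"),
                    main = sprintf("displacement, %s slice %d", s$plane, s$index))
    nonzero <- sqrt(arrows_df$u_inplane1^2 + arrows_df$u_inplane2^2) > 1e-9
    if (any(nonzero)) {
      a <- arrows_df[nonzero, , drop = FALSE]
      graphics::arrows(a$mm1, a$mm2, a$mm1 + a$u_inplane1, a$mm2 + a$u_inplane2,
                       length = 0.04, col = "black")
    }
  }
  invisible(arrows_df)
}
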