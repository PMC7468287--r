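#' Jacobian-determinant growth maps
#'
#' The Jacobian determinant of a deformation is the determinant of the
#' matrix of first-order partial derivatives of the transformation
#' x -> x + u(x); it is the local volume-change factor, with values greater
#' than 1 representing expansion and smaller than 1 contraction. To compare
#' growth between regions of a globally growing brain, raw maps are
#' normalized for global volume change by dividing by the scalar object
#' volume ratio R, so a normalized value of 0.95 under 9\% global growth
#' still corresponds to +3.5\% absolute local growth.
#'
#' @param f a \code{displacement_field}.
#' @return \code{jacobian_determinant} returns a \code{jacobian_map} (a
#'   \code{volume_grid} with fields \code{kind} = "raw" or "normalized" and
#'   \code{global_ratio}). Derivatives use central finite differences in
#'   physical mm, one-sided at the grid boundary.
#' @export
jacobian_determinant <- function(f) {
  stopifnot(inherits(f, "displacement_field"))
  dm <- dim(f$vectors)[1:3]
  if (any(dm < 3)) stop("grid must have at least 3 voxels per axis", call. = FALSE)
  g <- vector("list", 9)  # g[[3*(j-1)+i]] = d u_i / d x_j
  for (i in 1:3) for (j in 1:3)
    g[[3 * (j - 1) + i]] <- fd_axis(f$vectors[, , , i], j, f$spacing[j])
  a11 <- 1 + g[[1]]; a21 <- g[[2]];     a31 <- g[[3]]
  a12 <- g[[4]];     a22 <- 1 + g[[5]]; a32 <- g[[6]]
  a13 <- g[[7]];     a23 <- g[[8]];     a33 <- 1 + g[[9]]
  J <- a11 * (a22 * a33 - a23 * a32) -
       a12 * (a21 * a33 - a23 * a31) +
       a13 * (a21 * a32 - a22 * a31)
  structure(list(values = J, spacing = f$spacing, origin = f$origin,
                 kind = "raw", global_ratio = NA_real_),
            class = c("jacobian_map", "volume_grid"))
}

#' @export
print.jacobian_map <- function(x, ...) {
  cat("<jacobian_map:", x$kind, "> ", paste(dim(x$values), collapse = " x "),
      " voxels, range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]",
      if (x$kind == "normalized") paste0(", global ratio ", signif(x$global_ratio, 5)),
      "\n", sep = "")
  invisible(x)
}

object_mask <- function(labels) labels$values != 0L

#' Global volume-change ratio between two segmentations
#'
#' R = (object-mask volume of target) / (object-mask volume of source),
#' volumes measured as voxel count times voxel volume. Used to correct
#' Jacobian maps for global scaling.
#'
#' @param source_labels,target_labels \code{label_volume}s (any nonzero
#'   label counts as object).
#' @return scalar ratio R.
#' @export
global_growth <- function(source_labels, target_labels) {
  vs <- sum(object_mask(source_labels)) * prod(source_labels$spacing)
  vt <- sum(object_mask(target_labels)) * prod(target_labels$spacing)
  if (vs == 0 || vt == 0) stop("object mask is empty", call. = FALSE)
  vt / vs
}

#' Global ratio from the Jacobian map itself
#'
#' Alternative global-scaling estimate: the mean raw Jacobian over the
#' source object mask (the factor by which the mask volume grows under the
#' field). Provided as a cross-check on [global_growth()].
#'
#' @param j raw \code{jacobian_map}.
#' @param source_labels source segmentation.
#' @return scalar ratio.
#' @export
global_growth_from_jacobian <- function(j, source_labels) {
  m <- object_mask(source_labels)
  if (!any(m)) stop("object mask is empty", call. = FALSE)
  mean(j$values[m])
}

#' @rdname jacobian_determinant
#' @param j a raw \code{jacobian_map}.
#' @param R positive global volume ratio (see [global_growth()]).
#' @export
normalize_jacobian <- function(j, R) {
  stopifnot(inherits(j, "jacobian_map"))
  if (!is.finite(R) || R <= 0) stop("global ratio R must be positive", call. = FALSE)
  j$values <- j$values / R
  j$kind <- "normalized"
  j$global_ratio <- R
  j
}

#' Absolute local growth from a normalized Jacobian
#'
#' Back-composes the global growth into a normalized Jacobian value:
#' \code{(j_norm * (1 + g) - 1) * 100} percent. For example, a normalized
#' Jacobian of 0.95 under 9\% global volume growth is an absolute local
#' growth of 3.5\% (3.55\% unrounded); a normalized Jacobian of 1.1 with no
#' global growth reads as a 10\% local expansion.
#'
#' @param j_norm normalized Jacobian value(s), > 0.
#' @param g fractional global volume growth (> -1), e.g. 0.09 for 9\%.
#' @param digits decimals to round the percentage to (default 1, use NA for
#'   no rounding).
#' @return growth percentage(s).
#' @export
absolute_growth <- function(j_norm, g, digits = 1) {
  if (any(j_norm <= 0)) stop("j_norm must be positive", call. = FALSE)
  if (any(g <= -1)) stop("g must be > -1", call. = FALSE)
  pct <- (j_norm * (1 + g) - 1) * 100
  if (!is.na(digits)) {
    # snap to 12 significant digits first: the subtraction amplifies binary
    # representation noise (e.g. 3.55 computes as 3.5500000000000009), which
    # would otherwise flip decimal ties the wrong way when reporting
    pct <- round(signif(pct, 12), digits)
  }
  pct
}

#' Region-wise growth summary
#'
#' Per-label statistics of a Jacobian map over a segmentation: mean and
#' median Jacobian, region volume in mm^3, and mean absolute growth percent
#' (via [absolute_growth()] using the map's recorded global ratio, or g = 0
#' for raw maps). Grid-boundary voxels are excluded from the statistics
#' because one-sided derivatives there are less accurate.
#'
#' @param j a \code{jacobian_map}.
#' @param labels a \code{label_volume} on the same grid.
#' @return data.frame sorted by mean Jacobian, descending; labels absent
#'   from the volume appear with zero volume and a \code{present} flag.
#' @export
region_growth_summary <- function(j, labels) {
  stop_if_grid_mismatch(j, labels, "Jacobian map and labels")
  dm <- dim(j$values)
  interior <- array(FALSE, dm)
  interior[2:(dm[1] - 1), 2:(dm[2] - 1), 2:(dm[3] - 1)] <- TRUE
  g <- if (j$kind == "normalized") j$global_ratio - 1 else 0
  voxvol <- prod(labels$spacing)
  fg <- labels$label_dict[labels$label_dict != 0L]
  rows <- lapply(names(fg), function(nm) {
    sel_all <- labels$values == fg[[nm]]
    sel <- sel_all & interior
    if (!any(sel)) {
      data.frame(label = nm, mean_jacobian = NA_real_, median_jacobian = NA_real_,
                 volume_mm3 = sum(sel_all) * voxvol, mean_absolute_growth_pct = NA_real_,
                 present = any(sel_all), stringsAsFactors = FALSE)
    } else {
      v <- j$values[sel]
      data.frame(label = nm, mean_jacobian = mean(v), median_jacobian = stats::median(v),
                 volume_mm3 = sum(sel_all) * voxvol,
                 mean_absolute_growth_pct = absolute_growth(mean(v), g),
                 present = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_jacobian, out$label, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
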