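#' Volume grids, label volumes and displacement fields
#'
#' The imaging side of the package works on three light-weight S3 containers:
#' \code{volume_grid} (a 3D scalar lattice with physical spacing and origin),
#' \code{label_volume} (an integer lattice on the same grid plus a name-to-id
#' dictionary, background = 0) and \code{displacement_field} (a per-voxel
#' 3-vector in mm, mapping source coordinates to target via x + u(x)).
#'
#' Conventions: voxel indices are 0-based; physical coordinates are
#' \code{origin + index * spacing} along each axis (a fixed right-handed
#' axis order); all displacements and derivatives are in physical mm, so
#' anisotropic voxels are handled correctly.
#'
#' @param values 3D numeric array of intensities.
#' @param spacing positive numeric length-3, voxel size in mm per axis.
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return \code{volume_grid} returns an object of class \code{volume_grid}.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3)
    stop("volume values must be a 3D array, got ", length(dim(values)), "D", call. = FALSE)
  if (any(dim(values) < 2)) stop("each axis needs at least 2 voxels", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers", call. = FALSE)
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers", call. = FALSE)
  if (any(!is.finite(values))) stop("volume values must be finite", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @rdname volume_grid
#' @param labels 3D integer array of label ids (0 = background).
#' @param label_dict named integer vector mapping region names to ids;
#'   must cover every nonzero id present in \code{labels}.
#' @export
label_volume <- function(labels, label_dict, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3)
    stop("label array must be 3D", call. = FALSE)
  storage.mode(labels) <- "integer"
  label_dict <- vapply(label_dict, as.integer, integer(1))
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, label_dict)
  if (length(missing) > 0)
    stop("label ids present in volume but absent from label_dict: ",
         paste(missing, collapse = ", "), call. = FALSE)
  g <- volume_grid(labels + 0, spacing, origin)   # reuse metadata validation
  structure(list(values = labels, label_dict = label_dict,
                 spacing = g$spacing, origin = g$origin),
            class = "label_volume")
}

#' @rdname volume_grid
#' @param vectors 4D numeric array \code{[nx, ny, nz, 3]}: the displacement
#'   u(x) in mm; component order follows the axis order of the grid.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(vectors)) != 4 || dim(vectors)[4] != 3)
    stop("displacement field must be an [nx,ny,nz,3] array", call. = FALSE)
  if (any(!is.finite(vectors))) stop("displacement vectors must be finite", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  structure(list(vectors = vectors, spacing = spacing, origin = origin),
            class = "displacement_field")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, labels: ", paste(names(x$label_dict), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$vectors, ncol = 3)^2))
  cat("<displacement_field> ", paste(dim(x$vectors)[1:3], collapse = " x "),
      " voxels, |u| max ", signif(max(mag), 4), " mm\n", sep = "")
  invisible(x)
}

grids_compatible <- function(a, b) {
  da <- if (!is.null(a$vectors)) dim(a$vectors)[1:3] else dim(a$values)
  db <- if (!is.null(b$vectors)) dim(b$vectors)[1:3] else dim(b$values)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) < 1e-6) &&
    all(abs(a$origin - b$origin) < 1e-6)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!grids_compatible(a, b))
    stop(what, " are on different grids (shape, spacing or origin differ)", call. = FALSE)
  invisible(TRUE)
}

nifti_xform <- function(spacing, origin) {
  m <- diag(4)
  m[1, 1] <- spacing[1]; m[2, 2] <- spacing[2]; m[3, 3] <- spacing[3]
  m[1:3, 4] <- origin
  structure(m, code = 2L)
}

#' Read and write volumes, label images and displacement fields as NIfTI-1
#'
#' Scalar volumes and label images are stored as 3D NIfTI; displacement
#' fields use the NIfTI vector convention (5D, size 3 along the 5th
#' dimension, components in mm in grid-axis order). Round-trips preserve
#' values exactly and spacing/origin to better than 1e-6.
#'
#' @param path file path (.nii or .nii.gz).
#' @param v,f,l object to write.
#' @return \code{read_volume} a \code{volume_grid}; \code{read_field} a
#'   \code{displacement_field}; \code{read_labels} a \code{label_volume}.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3D volume, got ", length(d), "D: ", path, call. = FALSE)
  meta <- nifti_grid_meta(img)
  volume_grid(array(as.numeric(img), dim = d), meta$spacing, meta$origin)
}

nifti_grid_meta <- function(img) {
  x <- RNifti::xform(img)
  spacing <- sqrt(colSums(x[1:3, 1:3]^2))
  list(spacing = as.numeric(spacing), origin = as.numeric(x[1:3, 4]))
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_grid") || inherits(v, "label_volume"))
  img <- RNifti::asNifti(v$values + 0)
  img <- RNifti::`sform<-`(img, nifti_xform(v$spacing, v$origin))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param label_dict dictionary to attach to the integer image read from disk.
#' @export
read_labels <- function(path, label_dict) {
  g <- read_volume(path)
  lab <- g$values
  storage.mode(lab) <- "integer"
  label_volume(lab, label_dict, g$spacing, g$origin)
}

#' @rdname read_volume
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!(length(d) == 5 && d[4] == 1))
    stop("expected a 5D vector NIfTI (nx, ny, nz, 1, 3): ", path, call. = FALSE)
  if (d[5] != 3)
    stop("displacement field must have 3 components per voxel, found ", d[5],
         ": ", path, call. = FALSE)
  meta <- nifti_grid_meta(img)
  vec <- array(as.numeric(img), dim = c(d[1:3], 3))
  displacement_field(vec, meta$spacing, meta$origin)
}

#' @rdname read_volume
#' @export
write_field <- function(f, path) {
  stopifnot(inherits(f, "displacement_field"))
  d <- dim(f$vectors)
  arr <- array(f$vectors, dim = c(d[1:3], 1, 3))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, nifti_xform(f$spacing, f$origin))
  RNifti::writeNifti(img, path)
  invisible(path)
}

LAYERS <- c("SG", "MZ", "CP", "SP")

#' Read a layered regional expression table
#'
#' Expects a TSV with header columns \code{gene_id}, \code{specimen_id},
#' \code{region}, \code{layer}, \code{value}: one linear-scale intensity per
#' gene, specimen, region and cortical layer (SG, MZ, CP, SP). Duplicate
#' keys and negative values are integrity errors, not warnings.
#'
#' @param path TSV file path.
#' @return data.frame of class \code{expression_table}.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_expression_table(df)
}

#' @rdname read_expression
#' @param df data.frame with the expression columns, validated in place.
#' @export
as_expression_table <- function(df) {
  need <- c("gene_id", "specimen_id", "region", "layer", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("expression table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!df$layer %in% LAYERS))
    stop("layer values must be one of ", paste(LAYERS, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$value)) || any(df$value < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  key <- paste(df$gene_id, df$specimen_id, df$region, df$layer, sep = "\r")
  if (anyDuplicated(key) > 0)
    stop("duplicate (gene, specimen, region, layer) rows in expression table",
         call. = FALSE)
  class(df) <- c("expression_table", "data.frame")
  df
}

#' @rdname read_expression
#' @param t expression table to write.
#' @export
write_expression <- function(t, path) {
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-layer fold-change contrast report
#'
#' One CSV row per selected or ranked gene with columns \code{layer},
#' \code{gene_id}, \code{fold_change}, \code{rank}, sorted by layer (SG, MZ,
#' CP, SP order) then descending fold change. An empty selection yields a
#' header-only CSV.
#'
#' @param result a \code{contrast_result} from [contrast_report()].
#' @param path output CSV path.
#' @param selected_only write only the selected (top-percentile) genes
#'   (default) or all ranked genes.
#' @export
write_contrast_report <- function(result, path, selected_only = TRUE) {
  stopifnot(inherits(result, "contrast_result"))
  rows <- do.call(rbind, lapply(result$layers, function(b) {
    d <- b$table
    if (selected_only) d <- d[d$selected, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(layer = b$layer, gene_id = d$gene_id,
               fold_change = d$fold_change, rank = d$rank,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(layer = character(), gene_id = character(),
                       fold_change = numeric(), rank = integer())
  rows$layer <- factor(rows$layer, levels = LAYERS)
  rows <- rows[order(rows$layer, -rows$fold_change, rows$gene_id), , drop = FALSE]
  rows$layer <- as.character(rows$layer)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read and write affine transforms as plain-text matrix files
#'
#' The file holds 12 whitespace-separated numbers: the 3x3 linear part in
#' row-major order followed by the 3-vector translation (mm), acting on
#' physical coordinates.
#'
#' @param a an \code{affine_transform}.
#' @param path file path.
#' @export
write_affine <- function(a, path) {
  stopifnot(inherits(a, "affine_transform"))
  writeLines(paste(format(c(t(a$linear), a$translation), digits = 17),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  v <- scan(path, quiet = TRUE)
  if (length(v) != 12) stop("affine file must contain 12 numbers", call. = FALSE)
  affine_transform(matrix(v[1:9], 3, 3, byrow = TRUE), v[10:12])
}
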