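#' Specification for a growing-brain phantom
#'
#' The phantom emulates the lateral surface of one fetal hemisphere across a
#' series of weekly timepoints: an ellipsoidal "hemisphere" carrying a
#' lateral wedge-shaped indentation (the open Sylvian fissure) between a
#' frontal/parietal opercular shell above and a temporal opercular shell
#' below, with the insula at the indentation floor. Growth from one week to
#' the next is the exponential of an analytic stationary velocity field:
#' a global radial expansion term (fractional volume growth
#' \code{global_growth_per_week}), an extra opercular expansion term, and an
#' opercular convergence term that pushes the frontal shell inferiorly and
#' the temporal shell superiorly toward the fissure plane, with magnitude
#' decaying smoothly away from the plane. The deformation is therefore
#' diffeomorphic by construction and known in closed form, which makes it a
#' ground-truth oracle for registration and Jacobian analysis.
#'
#' @param grid_shape integer length-3, voxels per axis (>= 16 each).
#' @param spacing_mm positive length-3 voxel size in mm.
#' @param n_weeks number of timepoints (>= 2).
#' @param global_growth_per_week fractional volume growth per week (g > -1);
#'   0.06 means +6\% volume per week.
#' @param opercular_excess_growth extra fractional volume growth of the
#'   opercular shell per week.
#' @param convergence_amplitude_mm peak opercular closing displacement per
#'   week, in mm (>= 0).
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (intensities are on a 0..1 scale).
#' @param seed RNG seed; all randomness is reproducible from it.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48),
                         spacing_mm = c(1, 1, 1),
                         n_weeks = 3,
                         global_growth_per_week = 0.06,
                         opercular_excess_growth = 0.03,
                         convergence_amplitude_mm = 1.2,
                         noise_sd = 0.002,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 16))
    stop("grid_shape must be 3 integers, each >= 16", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive numbers", call. = FALSE)
  if (n_weeks < 2) stop("n_weeks must be >= 2", call. = FALSE)
  if (global_growth_per_week <= -1) stop("global_growth_per_week must be > -1", call. = FALSE)
  if (convergence_amplitude_mm < 0) stop("convergence_amplitude_mm must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 n_weeks = as.integer(n_weeks),
                 global_growth_per_week = global_growth_per_week,
                 opercular_excess_growth = opercular_excess_growth,
                 convergence_amplitude_mm = convergence_amplitude_mm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", paste(x$grid_shape, collapse = "x"), " voxels, ",
      x$n_weeks, " weeks, g = ", x$global_growth_per_week,
      ", opercular excess = ", x$opercular_excess_growth,
      ", convergence = ", x$convergence_amplitude_mm, " mm\n", sep = "")
  invisible(x)
}

PHANTOM_LABELS <- c(background = 0L, interior = 1L, insula = 2L,
                    frontal_operculum = 3L, parietal_operculum = 4L,
                    temporal_operculum = 5L)

sigmoid <- function(t) 1 / (1 + exp(-t))

# Geometry parameters derived from a spec: ellipsoid semi-axes, wedge shape,
# fissure plane. All in physical mm unless suffixed _n (normalized).
phantom_geometry <- function(spec) {
  half <- (spec$grid_shape - 1) * spec$spacing_mm / 2
  centre <- half            # origin at 0, so the centre is half the extent
  semi <- c(0.55, 0.64, 0.55) * half
  list(centre = centre, semi = semi,
       wedge_q1 = 0.45,      # lateral (normalized) coordinate where the fissure opens
       wedge_halfwidth_n = 2.5 / semi[3],   # max half-width of the wedge, normalized z
       shell_e = 0.55,       # e >= shell_e is the cortical shell
       conv_scale_mm = 4)    # decay scale of the convergence term
}

# Week-0 anatomy as analytic functions of physical points (n x 3 matrix).
# Returns integer labels per PHANTOM_LABELS.
phantom_label_fun <- function(pts, geo) {
  q1 <- (pts[, 1] - geo$centre[1]) / geo$semi[1]
  q2 <- (pts[, 2] - geo$centre[2]) / geo$semi[2]
  q3 <- (pts[, 3] - geo$centre[3]) / geo$semi[3]
  e <- q1^2 + q2^2 + q3^2
  wz <- pmax(0, geo$wedge_halfwidth_n * (q1 - geo$wedge_q1) / (1 - geo$wedge_q1))
  in_wedge <- q1 > geo$wedge_q1 & abs(q3) < wz
  object <- e <= 1 & !in_wedge
  lab <- integer(length(e))
  lab[object] <- PHANTOM_LABELS[["interior"]]
  insula <- object & q1 > 0.22 & q1 <= geo$wedge_q1 &
    abs(q3) <= 1.3 * geo$wedge_halfwidth_n
  lab[insula] <- PHANTOM_LABELS[["insula"]]
  shell <- object & e >= geo$shell_e & q1 > 0.15 & !insula
  upper <- shell & q3 >= 0
  lab[upper & q2 >= 0] <- PHANTOM_LABELS[["frontal_operculum"]]
  lab[upper & q2 < 0] <- PHANTOM_LABELS[["parietal_operculum"]]
  lab[shell & q3 < 0] <- PHANTOM_LABELS[["temporal_operculum"]]
  lab
}

# Smooth week-0 intensity: bright cortical ribbon over a dimmer interior,
# zero background (the open wedge is background, giving the fissure its
# edge). A fixed sum of smooth sinusoidal "tissue texture" components rides
# on top; it moves with the anatomy (it is evaluated at material points), so
# intensity gradients exist throughout the object and registration can
# observe interior growth, as in textured T2-weighted tissue.
phantom_intensity_fun <- function(pts, geo) {
  q1 <- (pts[, 1] - geo$centre[1]) / geo$semi[1]
  q2 <- (pts[, 2] - geo$centre[2]) / geo$semi[2]
  q3 <- (pts[, 3] - geo$centre[3]) / geo$semi[3]
  e <- q1^2 + q2^2 + q3^2
  wz <- pmax(0, geo$wedge_halfwidth_n * (q1 - geo$wedge_q1) / (1 - geo$wedge_q1))
  ribbon <- exp(-((e - 0.78) / 0.18)^2)
  # texture wavelengths ~7-10 mm: resolvable at 1 mm voxels, smooth for demons
  tex <- sin(0.80 * pts[, 1] + 1.3) * sin(0.67 * pts[, 2] + 0.4) +
         sin(0.59 * pts[, 2] + 2.1) * sin(0.88 * pts[, 3] + 0.9) +
         sin(0.73 * pts[, 3] + 0.2) * sin(0.64 * pts[, 1] + 2.6)
  # soft (partial-volume-like) object and fissure edges, ~1.5 mm transition
  obj_soft <- sigmoid((1 - e) / 0.06)
  wedge_soft <- sigmoid((q1 - geo$wedge_q1) / 0.03) *
    sigmoid((wz - abs(q3)) * geo$semi[3] / 1.0)
  obj_soft * (1 - wedge_soft) * (0.40 + 0.45 * ribbon + 0.15 * tex)
}

# Analytic stationary velocity at physical points (mm/week). Three terms:
# radial expansion, opercular excess expansion and opercular convergence.
phantom_velocity_fun <- function(pts, spec, geo) {
  d1 <- pts[, 1] - geo$centre[1]
  d2 <- pts[, 2] - geo$centre[2]
  d3 <- pts[, 3] - geo$centre[3]
  q1 <- d1 / geo$semi[1]
  e <- q1^2 + (d2 / geo$semi[2])^2 + (d3 / geo$semi[3])^2
  a <- log1p(spec$global_growth_per_week) / 3
  v <- cbind(a * d1, a * d2, a * d3)
  if (spec$opercular_excess_growth != 0) {
    b <- log1p(spec$opercular_excess_growth) / 3
    w_op <- sigmoid((q1 - 0.30) / 0.08) * sigmoid((e - geo$shell_e) / 0.08)
    v <- v + b * w_op * cbind(d1, d2, d3)
  }
  if (spec$convergence_amplitude_mm > 0) {
    s0 <- geo$conv_scale_mm
    s <- abs(d3)
    f <- (s / s0) * exp(1 - s / s0)
    w_lat <- sigmoid((q1 - 0.35) / 0.10)
    v[, 3] <- v[, 3] - spec$convergence_amplitude_mm * sign(d3) * f * w_lat
  }
  v
}

#' Generate a growing-brain phantom series with ground-truth deformations
#'
#' Produces, per week, an intensity \code{volume_grid} and a
#' \code{label_volume} (labels background, interior, insula,
#' frontal/parietal/temporal operculum), and per consecutive week pair the
#' ground-truth \code{displacement_field} (mapping week k to week k+1 via
#' x + u(x), so Jacobian > 1 encodes growth). The field is the exponential
#' of the analytic stationary velocity, computed by scaling-and-squaring,
#' and is numerically verified to be diffeomorphic (min Jacobian > 0);
#' specs whose convergence amplitude folds the field are rejected.
#'
#' Week-k anatomy is rendered by evaluating the analytic week-0 label and
#' intensity functions at backward-mapped points (the exponential of
#' \code{-k v}), so no cumulative resampling error enters the series.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class \code{growth_series}: lists \code{volumes},
#'   \code{labels} (length \code{n_weeks}), \code{true_fields} (length
#'   \code{n_weeks - 1}), plus the spec and label dictionary.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  dm <- spec$grid_shape
  sp <- spec$spacing_mm
  base <- grid_index_points(dm)
  pts_mm <- sweep(base, 2, sp, "*")   # origin at 0

  vel <- phantom_velocity_fun(pts_mm, spec, geo)
  vel_arr <- array(vel, dim = c(dm, 3))

  # ground-truth pair field: exp(v); identical for every pair since v is
  # stationary and the series is its flow
  u_pair <- exp_velocity_arr(vel_arr, sp, min_squarings = 6L, base = base)
  field <- displacement_field(u_pair, sp, c(0, 0, 0))
  jmin <- min(jacobian_determinant(field)$values)
  if (jmin <= 0)
    stop("phantom spec is non-physical: the analytic deformation folds ",
         "(min Jacobian = ", signif(jmin, 3), "); reduce convergence_amplitude_mm",
         call. = FALSE)

  volumes <- vector("list", spec$n_weeks)
  labels <- vector("list", spec$n_weeks)
  noise <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_weeks), function(i)
      if (spec$noise_sd > 0) stats::rnorm(nrow(base), 0, spec$noise_sd) else 0)
  })
  for (k in seq_len(spec$n_weeks) - 1L) {
    if (k == 0) {
      mapped <- pts_mm
    } else {
      u_back <- exp_velocity_arr(-k * vel_arr, sp, min_squarings = 6L, base = base)
      mapped <- pts_mm + matrix(u_back, ncol = 3)
    }
    ints <- phantom_intensity_fun(mapped, geo) + noise[[k + 1L]]
    labs <- phantom_label_fun(mapped, geo)
    volumes[[k + 1L]] <- volume_grid(array(ints, dim = dm), sp)
    labels[[k + 1L]] <- label_volume(array(labs, dim = dm),
                                     PHANTOM_LABELS, sp)
  }
  true_fields <- rep(list(field), spec$n_weeks - 1L)
  structure(list(volumes = volumes, labels = labels, true_fields = true_fields,
                 spec = spec, label_dict = PHANTOM_LABELS),
            class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  cat("<growth_series> ", length(x$volumes), " weeks, ",
      paste(dim(x$volumes[[1]]$values), collapse = "x"), " voxels\n", sep = "")
  invisible(x)
}

#' Write a phantom series to disk
#'
#' Writes per-week NIfTI intensity and label images, per-pair ground-truth
#' displacement fields, and the spec as YAML.
#'
#' @param series a \code{growth_series}.
#' @param dir output directory (created if needed).
#' @return invisibly, a character vector of the files written.
#' @export
write_phantom <- function(series, dir) {
  stopifnot(inherits(series, "growth_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (k in seq_along(series$volumes)) {
    fv <- file.path(dir, sprintf("week%02d_intensity.nii.gz", k - 1))
    fl <- file.path(dir, sprintf("week%02d_labels.nii.gz", k - 1))
    write_volume(series$volumes[[k]], fv)
    write_volume(series$labels[[k]], fl)
    files <- c(files, fv, fl)
  }
  for (k in seq_along(series$true_fields)) {
    ff <- file.path(dir, sprintf("pair%02d_true_field.nii.gz", k - 1))
    write_field(series$true_fields[[k]], ff)
    files <- c(files, ff)
  }
  fs <- file.path(dir, "phantom_spec.yaml")
  yaml::write_yaml(unclass(series$spec), fs)
  files <- c(files, fs)
  invisible(files)
}
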