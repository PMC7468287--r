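#' Affine transforms acting on physical coordinates
#'
#' @param linear 3x3 matrix (must be invertible).
#' @param translation length-3 vector in mm.
#' @return object of class \code{affine_transform}.
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  if (abs(det(linear)) <= 1e-8)
    stop("affine linear part is singular", call. = FALSE)
  structure(list(linear = linear, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> det =", signif(det(x$linear), 5),
      ", translation =", paste(signif(x$translation, 4), collapse = ", "), "mm\n")
  invisible(x)
}

#' Registration parameters
#'
#' Defaults follow common demons practice: a 3-level multi-resolution
#' pyramid (downsampling by 2), (100, 50, 25) iterations coarse to fine,
#' update-field smoothing of 1 voxel and velocity-field smoothing of 1.5
#' voxels. The similarity metric is the mean-squared intensity difference.
#' The algorithm is fully deterministic; \code{seed} is reserved for future
#' stochastic sampling options.
#'
#' @param levels maximum pyramid levels (>= 1); levels whose grid would fall
#'   below 16 voxels on any axis are not built, because neither the demons
#'   force stencil nor the fissure geometry is meaningful there.
#' @param iterations iterations per level, coarse to fine; aligned to the
#'   fine end when fewer levels are built than entries given.
#' @param force intensity force: classic \code{"demons"} (normalized SSD
#'   gradient) or plain \code{"ssd"} gradient descent.
#' @param sigma_update_vox Gaussian smoothing of each update, in voxels.
#' @param sigma_velocity_vox Gaussian smoothing of the accumulated velocity,
#'   in voxels.
#' @param symmetric estimate velocities in both directions (moving to fixed
#'   and fixed to moving) and antisymmetrize them; roughly doubles runtime
#'   but removes most of the bias in the recovered Jacobian, in the spirit
#'   of symmetric normalization.
#' @param step step size multiplying the force (> 0); adapted internally by
#'   a monotone accept/halve rule.
#' @param tol relative MSE improvement below which a level stops.
#' @param min_squarings minimum scaling-and-squaring steps used to
#'   exponentiate the velocity.
#' @param seed reserved; the default algorithm is deterministic.
#' @return object of class \code{registration_params}.
#' @export
registration_params <- function(levels = 3, iterations = c(200, 100, 60),
                                force = c("demons", "ssd"),
                                sigma_update_vox = 2.5, sigma_velocity_vox = 1.5,
                                symmetric = TRUE,
                                step = 1, tol = 1e-7, min_squarings = 6L,
                                seed = NULL) {
  force <- match.arg(force)
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  if (sigma_update_vox < 0 || sigma_velocity_vox < 0)
    stop("smoothing sigmas must be >= 0", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  structure(list(levels = as.integer(levels),
                 iterations = as.integer(iterations),
                 force = force,
                 sigma_update_vox = sigma_update_vox,
                 sigma_velocity_vox = sigma_velocity_vox,
                 symmetric = isTRUE(symmetric),
                 step = step, tol = tol,
                 min_squarings = as.integer(min_squarings), seed = seed),
            class = "registration_params")
}

# Anti-aliased downsampling by 2 along each axis; keeps the origin (samples
# at even indices of the finer grid).
downsample_volume <- function(values, spacing) {
  sm <- gauss_smooth3(values, c(1, 1, 1))
  dm <- dim(values)
  idx <- lapply(dm, function(n) seq(1, n, by = 2))
  list(values = sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       spacing = spacing * 2)
}

mse_between <- function(a, b) mean((a - b)^2)

#' Affine registration by multi-resolution least squares
#'
#' Estimates the 12-parameter affine transform (acting on physical
#' coordinates, parameterized about the volume centre) that minimizes the
#' mean-squared intensity difference between the transformed moving image
#' and the fixed image, by BFGS with analytic gradients on a coarse-to-fine
#' pyramid. The returned residual MSE never exceeds the initial MSE (the
#' identity is kept if no improvement is found); non-convergence yields a
#' warning status, never a silent failure.
#'
#' @param moving,fixed \code{volume_grid}s with overlapping fields of view.
#' @param params a [registration_params()] (only \code{levels} and
#'   \code{iterations} are used here).
#' @return list of class \code{affine_fit}: \code{transform}
#'   (an \code{affine_transform} mapping fixed-space points into
#'   moving-image space for resampling), \code{initial_mse},
#'   \code{final_mse}, \code{converged}.
#' @export
affine_register <- function(moving, fixed, params = registration_params()) {
  stopifnot(inherits(moving, "volume_grid"), inherits(fixed, "volume_grid"))
  centre <- fixed$origin + (dim(fixed$values) - 1) * fixed$spacing / 2
  theta <- c(rep(0, 9), rep(0, 3))   # vec(M), t ; map y = c + (I+M)(x-c) + t

  mov <- list(values = moving$values, spacing = moving$spacing)
  fix <- list(values = fixed$values, spacing = fixed$spacing)
  pyr_m <- list(mov); pyr_f <- list(fix)
  for (l in seq_len(params$levels - 1)) {
    if (any(dim(pyr_m[[1]]$values) < 16)) break
    pyr_m <- c(list(downsample_volume(pyr_m[[1]]$values, pyr_m[[1]]$spacing)), pyr_m)
    pyr_f <- c(list(downsample_volume(pyr_f[[1]]$values, pyr_f[[1]]$spacing)), pyr_f)
  }
  converged <- TRUE
  for (l in seq_along(pyr_f)) {
    fx <- pyr_f[[l]]; mv <- pyr_m[[l]]
    dm <- dim(fx$values)
    pts <- sweep(grid_index_points(dm), 2, fx$spacing, "*")
    pts <- sweep(pts, 2, fixed$origin, "+")
    xc <- sweep(pts, 2, centre, "-")
    gm <- lapply(1:3, function(ax) fd_axis(mv$values, ax, mv$spacing[ax]))
    mo <- moving$origin; msp <- mv$spacing
    fvec <- as.vector(fx$values)
    map_pts <- function(th) {
      M <- matrix(th[1:9], 3, 3)
      sweep(xc %*% t(diag(3) + M), 2, centre + th[10:12], "+")
    }
    objective <- function(th) {
      y <- map_pts(th)
      yv <- sweep(sweep(y, 2, mo, "-"), 2, msp, "/")
      w <- interp3(mv$values, yv, mode = "fill", fill = 0)
      mean((w - fvec)^2)
    }
    gradient <- function(th) {
      y <- map_pts(th)
      yv <- sweep(sweep(y, 2, mo, "-"), 2, msp, "/")
      w <- interp3(mv$values, yv, mode = "fill", fill = 0)
      r <- w - fvec
      G <- vapply(1:3, function(k) interp3(gm[[k]], yv, mode = "fill", fill = 0),
                  numeric(length(r)))
      n <- length(r)
      gM <- crossprod(G * (2 * r / n), xc)      # 3x3: d MSE / d M
      gt <- colSums(G * (2 * r / n))
      c(as.vector(gM), gt)
    }
    it <- max(params$iterations[min(l, length(params$iterations))], 20L)
    opt <- stats::optim(theta, objective, gradient, method = "BFGS",
                        control = list(maxit = it,
                                       parscale = c(rep(0.05, 9), rep(1, 3)),
                                       reltol = params$tol))
    if (opt$convergence != 0 && l == length(pyr_f)) converged <- FALSE
    if (opt$value <= objective(theta)) theta <- opt$par
  }
  # final MSE at full resolution
  dm <- dim(fixed$values)
  final <- local({
    pts <- sweep(grid_index_points(dm), 2, fixed$spacing, "*")
    pts <- sweep(pts, 2, fixed$origin, "+")
    xc <- sweep(pts, 2, centre, "-")
    M <- matrix(theta[1:9], 3, 3)
    y <- sweep(xc %*% t(diag(3) + M), 2, centre + theta[10:12], "+")
    yv <- sweep(sweep(y, 2, moving$origin, "-"), 2, moving$spacing, "/")
    w <- interp3(moving$values, yv, mode = "fill", fill = 0)
    mean((w - as.vector(fixed$values))^2)
  })
  init <- mse_between(moving$values, fixed$values)
  if (final > init) {   # never return worse than identity
    theta <- rep(0, 12); final <- init; converged <- FALSE
  }
  if (!converged)
    warning("affine registration did not fully converge; returning best transform")
  M <- matrix(theta[1:9], 3, 3)
  L <- diag(3) + M
  structure(list(transform = affine_transform(L, centre + theta[10:12] - L %*% centre),
                 initial_mse = init, final_mse = final, converged = converged),
            class = "affine_fit")
}

#' Apply an affine transform to a volume by resampling
#'
#' Resamples \code{v} at \code{A x + t} for every physical grid point x of
#' the output grid (the grid of \code{v} itself), i.e. the transform maps
#' output-space coordinates into the input image.
#'
#' @param v \code{volume_grid} to resample.
#' @param a \code{affine_transform}.
#' @param interpolation "linear" or "nearest".
#' @return resampled \code{volume_grid}.
#' @export
apply_affine <- function(v, a, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dm <- dim(v$values)
  pts <- sweep(grid_index_points(dm), 2, v$spacing, "*")
  pts <- sweep(pts, 2, v$origin, "+")
  y <- sweep(pts %*% t(a$linear), 2, a$translation, "+")
  yv <- sweep(sweep(y, 2, v$origin, "-"), 2, v$spacing, "/")
  vals <- if (interpolation == "linear") interp3(v$values, yv, fill = 0)
          else interp3_nearest(v$values, yv, fill = 0)
  volume_grid(array(vals, dm), v$spacing, v$origin)
}

# One demons level. Returns updated velocity (mm) and the accepted MSE trace.
demons_level <- function(mov_vals, fix_vals, spacing, v, params) {
  dm <- dim(fix_vals)
  base <- grid_index_points(dm)
  fvec <- as.vector(fix_vals)
  kappa2 <- mean(spacing)^2
  n <- length(fvec)

  eval_mse <- function(vel) {
    u <- exp_velocity_arr(vel, spacing, params$min_squarings, base = base)
    pts <- base
    for (k in 1:3) pts[, k] <- pts[, k] + u[(k - 1) * n + seq_len(n)] / spacing[k]
    w <- interp3(mov_vals, pts, fill = 0)
    list(mse = mean((w - fvec)^2), warped = w, u = u)
  }

  cur <- eval_mse(v)
  trace <- cur$mse
  step <- params$step
  for (it in seq_len(params$iterations_level)) {
    warped <- array(cur$warped, dm)
    G <- lapply(1:3, function(ax) as.vector(fd_axis(warped, ax, spacing[ax])))
    r <- cur$warped - fvec
    if (params$force == "demons") {
      denom <- G[[1]]^2 + G[[2]]^2 + G[[3]]^2 + r^2 / kappa2
      scale <- ifelse(denom > 1e-12, -r / denom, 0)
    } else {
      gn <- sqrt(G[[1]]^2 + G[[2]]^2 + G[[3]]^2)
      scale <- -r / (mean(gn^2) + 1e-12)
    }
    d <- array(c(scale * G[[1]], scale * G[[2]], scale * G[[3]]), dim = c(dm, 3))
    d <- gauss_smooth_vec(d, params$sigma_update_vox)
    accepted <- FALSE
    for (try in 1:6) {
      cand <- gauss_smooth_vec(v + step * d, params$sigma_velocity_vox)
      res <- eval_mse(cand)
      if (res$mse <= cur$mse) {
        rel <- (cur$mse - res$mse) / max(cur$mse, 1e-30)
        v <- cand; cur <- res; trace <- c(trace, res$mse)
        step <- min(step * 1.2, 4 * params$step)
        accepted <- TRUE
        if (rel < params$tol) return(list(v = v, trace = trace))
        break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  list(v = v, trace = trace)
}

#' Diffeomorphic registration by stationary-velocity log-demons
#'
#' Estimates a diffeomorphic transform mapping the moving image onto the
#' fixed image with a multi-resolution log-demons scheme: at each iteration
#' an intensity force is computed, smoothed, accumulated into a stationary
#' velocity field, the velocity is smoothed, and the displacement is
#' obtained by exponentiating the velocity with scaling-and-squaring. A
#' monotone accept/halve step rule makes the per-level MSE trace
#' non-increasing. The returned field is verified to have strictly positive
#' Jacobian everywhere (hard error otherwise) and a final MSE no larger
#' than the initial MSE.
#'
#' @param moving,fixed \code{volume_grid}s on the same grid (affine
#'   pre-alignment, when needed, is a separate step).
#' @param params a [registration_params()].
#' @return list of class \code{diffeo_fit}: \code{field} (a
#'   \code{displacement_field}; x is a fixed-frame coordinate and x + u(x)
#'   the corresponding moving-frame point, so registering the later week as
#'   moving onto the earlier week as fixed makes Jacobian > 1 encode
#'   growth), \code{velocity}, \code{initial_mse}, \code{final_mse},
#'   \code{mse_trace} (per level and direction), \code{min_jacobian}.
#' @export
diffeo_register <- function(moving, fixed, params = registration_params()) {
  stopifnot(inherits(moving, "volume_grid"), inherits(fixed, "volume_grid"))
  stop_if_grid_mismatch(moving, fixed, "moving and fixed images")
  fwd <- demons_multires(moving$values, fixed$values, fixed$spacing, params)
  if (params$symmetric) {
    bwd <- demons_multires(fixed$values, moving$values, fixed$spacing, params)
    v <- (fwd$v - bwd$v) / 2
    traces <- list(forward = fwd$traces, backward = bwd$traces)
  } else {
    v <- fwd$v
    traces <- list(forward = fwd$traces)
  }
  u <- exp_velocity_arr(v, fixed$spacing, params$min_squarings)
  field <- displacement_field(u, fixed$spacing, fixed$origin)
  jmin <- min(jacobian_determinant(field)$values)
  if (jmin <= 0)
    stop("diffeomorphism contract broken: returned field has min Jacobian ",
         signif(jmin, 3), call. = FALSE)
  init <- mse_between(moving$values, fixed$values)
  warped <- warp_volume(volume_grid(moving$values, fixed$spacing, fixed$origin), field)
  final <- mse_between(warped$values, fixed$values)
  if (final > init)
    stop("registration increased the similarity objective; this should be impossible",
         call. = FALSE)
  structure(list(field = field,
                 velocity = displacement_field(v, fixed$spacing, fixed$origin),
                 initial_mse = init, final_mse = final,
                 mse_trace = traces, min_jacobian = jmin),
            class = "diffeo_fit")
}

# One-directional multi-resolution stationary-velocity demons; returns the
# velocity (mm, on the full grid) and per-level accepted-MSE traces.
demons_multires <- function(mov_vals, fix_vals, spacing, params) {
  pyr_m <- list(list(values = mov_vals, spacing = spacing))
  pyr_f <- list(list(values = fix_vals, spacing = spacing))
  for (l in seq_len(params$levels - 1)) {
    if (any(dim(pyr_m[[1]]$values) < 32)) break   # halving would go below 16
    pyr_m <- c(list(downsample_volume(pyr_m[[1]]$values, pyr_m[[1]]$spacing)), pyr_m)
    pyr_f <- c(list(downsample_volume(pyr_f[[1]]$values, pyr_f[[1]]$spacing)), pyr_f)
  }
  nl <- length(pyr_f)
  iters <- rep(params$iterations, length.out = max(nl, length(params$iterations)))
  iters <- utils::tail(iters, nl)   # finest level always gets the last entry
  v <- NULL
  traces <- vector("list", nl)
  for (l in seq_len(nl)) {
    fx <- pyr_f[[l]]; mv <- pyr_m[[l]]
    dm <- dim(fx$values)
    if (is.null(v)) {
      v <- array(0, dim = c(dm, 3))
    } else {
      # upsample velocity (mm values carry over; sample the coarse field at
      # fine grid positions)
      vold <- v
      v <- array(0, dim = c(dm, 3))
      ratio <- fx$spacing / pyr_f[[l - 1]]$spacing
      pts <- grid_index_points(dm)
      pts <- sweep(pts, 2, ratio, "*")
      for (k in 1:3) v[, , , k] <- interp3(vold[, , , k], pts, mode = "clamp")
    }
    p <- params
    p$iterations_level <- iters[l]
    res <- demons_level(mv$values, fx$values, fx$spacing, v, p)
    v <- res$v
    traces[[l]] <- res$trace
  }
  list(v = v, traces = traces)
}

#' @export
print.diffeo_fit <- function(x, ...) {
  cat("<diffeo_fit> MSE ", signif(x$initial_mse, 4), " -> ", signif(x$final_mse, 4),
      " (", round(100 * (1 - x$final_mse / x$initial_mse)), "% reduction), min J ",
      signif(x$min_jacobian, 3), "\n", sep = "")
  invisible(x)
}

#' Warp a volume or label image through a displacement field
#'
#' Resamples \code{v} at x + u(x). Out-of-domain samples take the
#' background value 0; nearest-neighbour mode preserves the input label
#' set and is the mode used for segmentations.
#'
#' @param v \code{volume_grid} or \code{label_volume}.
#' @param f \code{displacement_field} on the same grid.
#' @param interpolation "linear" or "nearest".
#' @return warped object of the same class as \code{v}.
#' @export
warp_volume <- function(v, f, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stop_if_grid_mismatch(v, f, "volume and field")
  dm <- dim(v$values)
  base <- grid_index_points(dm)
  n <- nrow(base)
  pts <- base
  for (k in 1:3) pts[, k] <- pts[, k] + f$vectors[(k - 1) * n + seq_len(n)] / f$spacing[k]
  vals <- if (interpolation == "linear") interp3(v$values + 0, pts, fill = 0)
          else interp3_nearest(v$values, pts, fill = 0)
  if (inherits(v, "label_volume")) {
    label_volume(array(as.integer(vals), dm), v$label_dict, v$spacing, v$origin)
  } else {
    volume_grid(array(vals, dm), v$spacing, v$origin)
  }
}

#' Approximate inverse of a displacement field
#'
#' Fixed-point iteration: u_inv(x) <- -u(x + u_inv(x)). Adequate for the
#' smooth, moderate-magnitude fields produced here.
#'
#' @param f \code{displacement_field}.
#' @param n_iter fixed-point iterations.
#' @return \code{displacement_field} approximating the inverse.
#' @export
invert_field <- function(f, n_iter = 20) {
  dm <- dim(f$vectors)[1:3]
  base <- grid_index_points(dm)
  n <- nrow(base)
  uinv <- array(0, dim = dim(f$vectors))
  for (i in seq_len(n_iter)) {
    pts <- base
    for (k in 1:3) pts[, k] <- pts[, k] + uinv[(k - 1) * n + seq_len(n)] / f$spacing[k]
    for (k in 1:3) uinv[, , , k] <- -interp3(f$vectors[, , , k], pts, mode = "clamp")
  }
  displacement_field(uinv, f$spacing, f$origin)
}
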