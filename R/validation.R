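#' Multiclass Dice overlap between two segmentations
#'
#' For each label L, Dice = 2 |A_L intersect B_L| / (|A_L| + |B_L|). Labels
#' absent from both inputs are excluded; a label present in only one scores
#' 0. The macro average is the unweighted mean over foreground labels
#' present in either input (background never enters the average: its
#' overlap would inflate scores meaninglessly); a voxel-weighted average is
#' also reported.
#'
#' @param a,b \code{label_volume}s on identical grids.
#' @return object of class \code{dice_report}: data.frame \code{per_label}
#'   (label, dice, voxels_a, voxels_b), \code{macro_dice},
#'   \code{weighted_dice}.
#' @export
multiclass_dice <- function(a, b) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  stop_if_grid_mismatch(a, b, "label volumes")
  dict <- a$label_dict[a$label_dict != 0L]
  rows <- lapply(names(dict), function(nm) {
    id <- dict[[nm]]
    na <- sum(a$values == id); nb <- sum(b$values == id)
    if (na == 0 && nb == 0) return(NULL)
    inter <- sum(a$values == id & b$values == id)
    data.frame(label = nm, dice = 2 * inter / (na + nb),
               voxels_a = na, voxels_b = nb, stringsAsFactors = FALSE)
  })
  per_label <- do.call(rbind, rows)
  if (is.null(per_label))
    stop("no foreground label present in either input", call. = FALSE)
  structure(list(per_label = per_label,
                 macro_dice = mean(per_label$dice),
                 weighted_dice = sum(per_label$dice * (per_label$voxels_a + per_label$voxels_b)) /
                   sum(per_label$voxels_a + per_label$voxels_b)),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat("<dice_report> macro Dice", round(x$macro_dice, 4), "\n")
  print(x$per_label, row.names = FALSE)
  invisible(x)
}

#' Validate week-pair registrations by warped-segmentation overlap
#'
#' For each consecutive pair (k, k+1), warps the later week's segmentation
#' back to the earlier week with nearest-neighbour interpolation through the
#' pair's displacement field (which maps week-k coordinates to week-k+1
#' points) and scores it against the week-k segmentation with
#' [multiclass_dice()].
#'
#' @param series a \code{growth_series} (or any list with a \code{labels}
#'   list of \code{label_volume}s).
#' @param fields list of \code{displacement_field}s, one per consecutive
#'   pair, in order.
#' @return data.frame with one row per pair (pair index, macro and weighted
#'   Dice) and the full \code{dice_report}s as an attribute
#'   \code{"reports"}.
#' @export
validate_registration <- function(series, fields) {
  n_pairs <- length(series$labels) - 1
  if (length(fields) != n_pairs)
    stop("need exactly one displacement field per consecutive week pair (",
         n_pairs, "), got ", length(fields), call. = FALSE)
  reports <- vector("list", n_pairs)
  rows <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    warped <- warp_volume(series$labels[[k + 1]], fields[[k]], "nearest")
    rep_k <- multiclass_dice(series$labels[[k]], warped)
    reports[[k]] <- rep_k
    rows[[k]] <- data.frame(pair = k, macro_dice = rep_k$macro_dice,
                            weighted_dice = rep_k$weighted_dice)
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
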