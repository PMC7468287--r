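#' Region-set configuration for the opercula-versus-insula contrast
#'
#' @param target_structures structure names pooled as the high-growth
#'   (opercular) target set.
#' @param contrast_structures structure names pooled as the contrast
#'   (insular) set; must be disjoint from the targets.
#' @param layers ordered layer names (default SG, MZ, CP, SP, superficial
#'   to deep).
#' @return object of class \code{region_set_config}.
#' @export
region_set_config <- function(target_structures = default_target_structures(),
                              contrast_structures = default_contrast_structures(),
                              layers = LAYERS) {
  if (length(target_structures) == 0 || length(contrast_structures) == 0)
    stop("target and contrast sets must be nonempty", call. = FALSE)
  if (length(intersect(target_structures, contrast_structures)) > 0)
    stop("target and contrast sets must be disjoint", call. = FALSE)
  structure(list(target_structures = target_structures,
                 contrast_structures = contrast_structures, layers = layers),
            class = "region_set_config")
}

#' Aggregate expression per gene for one layer
#'
#' Unweighted arithmetic mean on the linear scale across specimens and
#' constituent structures, separately for the target and contrast sets.
#' Genes missing from one set in this layer are dropped (and counted):
#' a fold change needs both sides.
#'
#' @param t an \code{expression_table}.
#' @param cfg a [region_set_config()].
#' @param layer single layer name present in the table.
#' @return data.frame (gene_id, target_mean, contrast_mean, n_target,
#'   n_contrast) with attributes \code{n_dropped} (genes lacking one side)
#'   and \code{expected_samples} per side.
#' @export
aggregate_expression <- function(t, cfg, layer) {
  if (!layer %in% t$layer)
    stop("layer ", layer, " not present in the expression table", call. = FALSE)
  d <- t[t$layer == layer, , drop = FALSE]
  d_t <- d[d$region %in% cfg$target_structures, , drop = FALSE]
  d_c <- d[d$region %in% cfg$contrast_structures, , drop = FALSE]
  if (nrow(d_t) == 0 || nrow(d_c) == 0)
    stop("layer ", layer, " has no samples in the ",
         if (nrow(d_t) == 0) "target" else "contrast", " set", call. = FALSE)
  mt <- tapply(d_t$value, d_t$gene_id, mean)
  nt <- tapply(d_t$value, d_t$gene_id, length)
  mc <- tapply(d_c$value, d_c$gene_id, mean)
  nc <- tapply(d_c$value, d_c$gene_id, length)
  common <- intersect(names(mt), names(mc))
  dropped <- length(union(names(mt), names(mc))) - length(common)
  out <- data.frame(gene_id = common,
                    target_mean = as.numeric(mt[common]),
                    contrast_mean = as.numeric(mc[common]),
                    n_target = as.integer(nt[common]),
                    n_contrast = as.integer(nc[common]),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- dropped
  attr(out, "expected_samples") <- c(
    target = length(cfg$target_structures) * length(unique(d$specimen_id)),
    contrast = length(cfg$contrast_structures) * length(unique(d$specimen_id)))
  out
}

#' Fold change with a pseudocount guard
#'
#' (target_mean + eps) / (contrast_mean + eps). The linear-scale
#' pseudocount (default 0.5) prevents infinite folds on zero contrast
#' means without materially shifting large folds.
#'
#' @param target_mean,contrast_mean non-negative mean intensities.
#' @param eps pseudocount on the linear intensity scale.
#' @return fold change(s), > 0.
#' @export
fold_change <- function(target_mean, contrast_mean, eps = 0.5) {
  if (any(target_mean < 0) || any(contrast_mean < 0))
    stop("means must be non-negative", call. = FALSE)
  (target_mean + eps) / (contrast_mean + eps)
}

#' Select the top expression-fold percentile of genes
#'
#' Rank-based percentile semantics: the 99.9th percentile of G genes keeps
#' the \code{n_sel = max(1, round(G * (1 - percentile/100)))} genes with the
#' largest fold changes, which for 35,000 genes selects the top 35.
#' Boundary ties are broken by lexicographic gene id, so the selection is
#' deterministic; the reported rank is dense in the fold value (equal folds
#' share a rank).
#'
#' @param folds named numeric vector of fold changes (names = gene ids).
#' @param percentile selection percentile (default 99.9).
#' @return list: \code{table} (gene_id, fold_change, rank, selected, sorted
#'   by descending fold then gene id), \code{n_selected},
#'   \code{cutoff_fold} (smallest selected fold).
#' @export
select_top_percentile <- function(folds, percentile = 99.9) {
  if (length(folds) < 1) stop("need at least one gene", call. = FALSE)
  if (is.null(names(folds))) stop("folds must be named by gene id", call. = FALSE)
  G <- length(folds)
  n_sel <- max(1L, as.integer(round(G * (1 - percentile / 100))))
  ord <- order(-folds, names(folds), method = "radix")
  f_sorted <- folds[ord]
  tab <- data.frame(gene_id = names(f_sorted), fold_change = as.numeric(f_sorted),
                    rank = cumsum(!duplicated(as.numeric(f_sorted))),
                    selected = seq_len(G) <= n_sel,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, n_selected = n_sel,
       cutoff_fold = as.numeric(f_sorted[n_sel]))
}

#' Layered opercula-versus-insula contrast report
#'
#' Runs aggregate, fold change and top-percentile selection for every layer
#' (SG, MZ, CP, SP order); layers with an empty target or contrast side are
#' skipped with a warning rather than failing the whole report.
#'
#' @param t an \code{expression_table}.
#' @param cfg a [region_set_config()].
#' @param percentile selection percentile (default 99.9, the top 0.1\%).
#' @param eps fold-change pseudocount (default 0.5).
#' @return object of class \code{contrast_result}: \code{layers} (one block
#'   per layer: layer, table, n_selected, cutoff_fold, n_dropped) and
#'   \code{cutoffs} (data.frame layer, cutoff_fold, n_selected).
#' @export
contrast_report <- function(t, cfg = region_set_config(), percentile = 99.9,
                            eps = 0.5) {
  stopifnot(inherits(t, "expression_table"), inherits(cfg, "region_set_config"))
  layers_present <- intersect(cfg$layers, unique(t$layer))
  if (length(layers_present) == 0)
    stop("expression table covers none of the configured layers", call. = FALSE)
  blocks <- list()
  for (layer in layers_present) {
    agg <- tryCatch(aggregate_expression(t, cfg, layer), error = function(e) e)
    if (inherits(agg, "error")) {
      warning("skipping layer ", layer, ": ", conditionMessage(agg))
      next
    }
    folds <- stats::setNames(fold_change(agg$target_mean, agg$contrast_mean, eps),
                             agg$gene_id)
    sel <- select_top_percentile(folds, percentile)
    means <- agg[match(sel$table$gene_id, agg$gene_id), ]
    sel$table$target_mean <- means$target_mean
    sel$table$contrast_mean <- means$contrast_mean
    blocks[[layer]] <- list(layer = layer, table = sel$table,
                            n_selected = sel$n_selected,
                            cutoff_fold = sel$cutoff_fold,
                            n_dropped = attr(agg, "n_dropped"))
  }
  if (length(blocks) == 0)
    stop("no layer could be contrasted", call. = FALSE)
  cutoffs <- data.frame(layer = vapply(blocks, `[[`, "", "layer"),
                        cutoff_fold = vapply(blocks, `[[`, 0, "cutoff_fold"),
                        n_selected = vapply(blocks, function(b) as.integer(b$n_selected), 0L),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(layers = blocks, cutoffs = cutoffs,
                 percentile = percentile, eps = eps),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("<contrast_result> top ", 100 - x$percentile, "% per layer\n", sep = "")
  print(x$cutoffs, row.names = FALSE)
  invisible(x)
}
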