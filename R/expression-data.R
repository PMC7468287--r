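#' Default opercular (target) and insular (contrast) structure sets
#'
#' The target set lists the opercular cortical structures bordering the
#' Sylvian fissure as sampled by prenatal LMD microarray atlases; the
#' contrast set is the insular cortex (dysgranular and granular divisions),
#' the low-growth region at the fissure floor.
#'
#' @return character vector of structure names.
#' @export
default_target_structures <- function() c(
  "frontopolar cortex", "ventrolateral prefrontal cortex",
  "orbital frontal cortex", "primary motor cortex",
  "primary somatosensory cortex", "inferior parietal cortex",
  "parainsular temporal cortex", "lateral temporooccipital cortex",
  "superior temporal cortex"
)

#' @rdname default_target_structures
#' @export
default_contrast_structures <- function() c(
  "dysgranular insular cortex", "granular insular cortex"
)

#' Specification for a synthetic layered expression table
#'
#' Emulates a two-specimen prenatal microarray profile: ~35,000 genes, each
#' measured per specimen, per cortical structure and per transient cortical
#' layer (SG, MZ, CP, SP), with log-normal baseline intensities and a known
#' set of genes planted with multiplicative opercular overexpression in an
#' assigned layer. The planted truth is returned alongside the table so
#' recovery can be scored exactly.
#'
#' @param n_genes number of genes (default 35,000).
#' @param n_specimens number of specimens (default 2).
#' @param layers layer names, default SG, MZ, CP, SP.
#' @param target_regions,contrast_regions structure names receiving /
#'   not receiving the planted overexpression.
#' @param planted_gene_count planted genes per layer (scalar or per-layer).
#' @param planted_fold_range length-2 range of planted fold increases
#'   (> 1), drawn uniformly.
#' @param baseline_log_mean,baseline_log_sd log-scale mean and sd of
#'   per-gene baseline intensity.
#' @param noise_log_sd log-scale sd of per-sample noise around the gene
#'   baseline.
#' @param seed RNG seed.
#' @return object of class \code{expression_spec}.
#' @export
expression_spec <- function(n_genes = 35000, n_specimens = 2, layers = LAYERS,
                            target_regions = default_target_structures(),
                            contrast_regions = default_contrast_structures(),
                            planted_gene_count = 40,
                            planted_fold_range = c(15, 40),
                            baseline_log_mean = 3, baseline_log_sd = 1,
                            noise_log_sd = 0.5, seed = 1L) {
  planted_gene_count <- rep(as.integer(planted_gene_count), length.out = length(layers))
  if (any(planted_gene_count > n_genes))
    stop("planted_gene_count cannot exceed n_genes", call. = FALSE)
  if (any(planted_fold_range <= 1) && any(planted_gene_count > 0))
    stop("planted folds must be > 1", call. = FALSE)
  if (length(intersect(target_regions, contrast_regions)) > 0)
    stop("target and contrast regions must be disjoint", call. = FALSE)
  if (length(target_regions) == 0 || length(contrast_regions) == 0)
    stop("target and contrast region sets must be nonempty", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), n_specimens = as.integer(n_specimens),
                 layers = layers, target_regions = target_regions,
                 contrast_regions = contrast_regions,
                 planted_gene_count = planted_gene_count,
                 planted_fold_range = as.numeric(planted_fold_range),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 noise_log_sd = noise_log_sd, seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate a synthetic layered expression table with planted signal
#'
#' Values are strictly positive: \code{exp(mu_gene + noise)} with per-gene
#' baselines \code{mu_gene ~ N(baseline_log_mean, baseline_log_sd)} and
#' per-sample noise \code{N(0, noise_log_sd)}. Each layer's planted genes
#' get their fold multiplier applied in target-region samples only.
#'
#' @param spec an [expression_spec()].
#' @return list of class \code{expression_set}: \code{table} (an
#'   \code{expression_table}) and \code{truth} (data.frame gene_id, layer,
#'   planted_fold).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  genes <- sprintf("g%06d", seq_len(spec$n_genes))
  specimens <- sprintf("specimen%02d", seq_len(spec$n_specimens))
  regions <- c(spec$target_regions, spec$contrast_regions)
  ng <- spec$n_genes; ns <- spec$n_specimens; nr <- length(regions); nl <- length(spec$layers)
  n <- ng * ns * nr * nl

  out <- with_seed(spec$seed, {
    mu <- stats::rnorm(ng, spec$baseline_log_mean, spec$baseline_log_sd)
    logv <- rep(mu, times = ns * nr * nl) +
      stats::rnorm(n, 0, spec$noise_log_sd)
    # plant per-layer overexpression in target regions
    mult <- rep(1, n)
    truth <- NULL
    gene_idx <- rep(seq_len(ng), times = ns * nr * nl)
    region_idx <- rep(rep(seq_len(nr), each = ng * ns), times = nl)
    layer_idx <- rep(seq_len(nl), each = ng * ns * nr)
    target_region <- region_idx <= length(spec$target_regions)
    for (l in seq_len(nl)) {
      cnt <- spec$planted_gene_count[l]
      if (cnt == 0) next
      planted <- sample.int(ng, cnt)
      folds <- stats::runif(cnt, spec$planted_fold_range[1], spec$planted_fold_range[2])
      fold_by_gene <- rep(1, ng)
      fold_by_gene[planted] <- folds
      rows <- layer_idx == l & target_region
      mult[rows] <- fold_by_gene[gene_idx[rows]]
      truth <- rbind(truth, data.frame(gene_id = genes[planted],
                                       layer = spec$layers[l],
                                       planted_fold = folds,
                                       stringsAsFactors = FALSE))
    }
    list(values = exp(logv) * mult, truth = truth,
         gene_idx = gene_idx, region_idx = region_idx, layer_idx = layer_idx,
         spec_idx = rep(rep(seq_len(ns), each = ng), times = nr * nl))
  })

  df <- data.frame(gene_id = genes[out$gene_idx],
                   specimen_id = specimens[out$spec_idx],
                   region = regions[out$region_idx],
                   layer = spec$layers[out$layer_idx],
                   value = out$values,
                   stringsAsFactors = FALSE)
  truth <- out$truth
  if (is.null(truth))
    truth <- data.frame(gene_id = character(), layer = character(),
                        planted_fold = numeric(), stringsAsFactors = FALSE)
  structure(list(table = as_expression_table(df), truth = truth, spec = spec),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set> ", nrow(x$table), " rows (", x$spec$n_genes, " genes, ",
      x$spec$n_specimens, " specimens), ", nrow(x$truth), " planted gene-layer signals\n",
      sep = "")
  invisible(x)
}
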