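#' Pipeline configuration
#'
#' One configuration object drives both analysis arms: the imaging arm
#' (phantom or user-supplied volumes, registered pairwise, turned into
#' Jacobian growth maps, displacement renderings and overlap validation)
#' and the transcriptome arm (synthetic or user-supplied expression table,
#' turned into a layered opercula-versus-insula contrast report). Every
#' convention the analysis depends on (normalization mode, fold-change
#' pseudocount, percentile rule, field direction) is an explicit named key
#' so it can be flipped and audited rather than buried in code.
#'
#' Exactly one input source per arm: the imaging arm reads
#' \code{volume_paths}/\code{label_paths} if given, otherwise generates a
#' phantom; the transcriptome arm reads \code{expression_path} if given,
#' otherwise generates a synthetic table.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; defaults for the phantom and expression
#'   generators derive from it unless overridden.
#' @param phantom named list of [phantom_spec()] overrides.
#' @param volume_paths,label_paths optional equal-length vectors (>= 2) of
#'   per-week intensity and label NIfTI paths, ordered by week.
#' @param label_dict name -> integer id map, required with
#'   \code{label_paths}.
#' @param registration named list of [registration_params()] overrides.
#' @param run_affine if TRUE, affinely pre-align each moving week before
#'   the diffeomorphic stage (the Jacobian then measures only the residual
#'   nonlinear shape change, with the global affine component removed).
#' @param normalization \code{"mask_volume"} (global ratio = target/source
#'   object-mask volume) or \code{"jacobian_mean"} (global ratio = mean raw
#'   Jacobian over the source mask).
#' @param arrow_plane,arrow_index,arrow_stride slice used for the
#'   displacement arrow rendering; \code{arrow_index = NULL} takes the
#'   middle slice.
#' @param expression named list of [expression_spec()] overrides.
#' @param expression_path optional TSV expression table to analyse instead
#'   of generating one.
#' @param target_structures,contrast_structures structure sets for the
#'   contrast (defaults: opercular cortices versus insular cortices).
#' @param percentile,eps selection percentile and fold-change pseudocount.
#' @return object of class \code{pipeline_config}.
#' @seealso [read_pipeline_config()] to build one from a YAML file.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            phantom = list(),
                            volume_paths = NULL, label_paths = NULL,
                            label_dict = NULL,
                            registration = list(),
                            run_affine = FALSE,
                            normalization = c("mask_volume", "jacobian_mean"),
                            arrow_plane = "sagittal", arrow_index = NULL,
                            arrow_stride = 4,
                            expression = list(),
                            expression_path = NULL,
                            target_structures = default_target_structures(),
                            contrast_structures = default_contrast_structures(),
                            percentile = 99.9, eps = 0.5) {
  normalization <- match.arg(normalization)
  seed <- as.integer(seed)
  if (!is.null(volume_paths)) {
    if (is.null(label_paths) || length(label_paths) != length(volume_paths))
      stop("label_paths must accompany volume_paths, one per week", call. = FALSE)
    if (length(volume_paths) < 2)
      stop("need at least two weeks of volumes", call. = FALSE)
    if (is.null(label_dict))
      stop("label_dict is required with user-supplied label volumes", call. = FALSE)
    if (length(phantom) > 0)
      stop("give either volume_paths or phantom overrides, not both ",
           "(exactly one input source per arm)", call. = FALSE)
  }
  if (!is.null(expression_path) && length(expression) > 0)
    stop("give either expression_path or expression overrides, not both ",
         "(exactly one input source per arm)", call. = FALSE)
  if (!"seed" %in% names(phantom)) phantom$seed <- seed
  if (!"seed" %in% names(expression)) expression$seed <- seed
  structure(list(
    out_dir = out_dir, seed = seed,
    phantom = do.call(phantom_spec, phantom),
    volume_paths = volume_paths, label_paths = label_paths,
    label_dict = label_dict,
    registration = do.call(registration_params, registration),
    run_affine = isTRUE(run_affine),
    normalization = normalization,
    arrow_plane = arrow_plane, arrow_index = arrow_index,
    arrow_stride = as.integer(arrow_stride),
    expression = do.call(expression_spec, expression),
    expression_path = expression_path,
    regions = region_set_config(target_structures, contrast_structures),
    percentile = percentile, eps = eps
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()] one-to-one;
#' \code{phantom}, \code{registration} and \code{expression} are nested
#' mappings of generator/parameter overrides.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(raw$label_dict))
    raw$label_dict <- unlist(raw$label_dict)
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> out_dir:", x$out_dir, " seed:", x$seed, "\n",
      " imaging input:",
      if (is.null(x$volume_paths)) "generated phantom" else
        paste(length(x$volume_paths), "user volumes"),
      "| normalization:", x$normalization,
      "| affine prealignment:", x$run_affine, "\n",
      " expression input:",
      if (is.null(x$expression_path)) "generated table" else x$expression_path,
      "| percentile:", x$percentile, "| eps:", x$eps, "\n")
  invisible(x)
}

# Append a line to the log file and echo it to stderr. Lines carry no
# timestamps so logs are bit-identical across reruns of the same seed.
pipeline_logger <- function(log_path) {
  cat("", file = log_path)
  function(...) {
    line <- paste0(...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
}

# Run one pipeline stage; any error halts with the stage name (and pair
# index when applicable), keeping partial outputs on disk.
run_stage <- function(stage, pair, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline failed at stage '", stage, "'",
         if (!is.na(pair)) paste0(" (pair ", pair, ")"), ": ",
         conditionMessage(e), call. = FALSE)
  })
}

manifest_entry <- function(paths, out_dir) {
  sums <- unname(tools::md5sum(paths))
  lapply(seq_along(paths), function(i) list(
    path = sub(paste0("^", out_dir, "/?"), "", paths[i]),
    md5 = sums[i]))
}

#' Run the imaging growth-mapping pipeline
#'
#' End to end: input weeks (generated phantom or user volumes) -> optional
#' affine pre-alignment -> diffeomorphic registration of each consecutive
#' pair (moving = later week onto fixed = earlier week, so the recovered
#' field maps earlier-week coordinates forward and its Jacobian reads
#' growth as values > 1) -> raw and normalized Jacobian maps -> region
#' growth summaries -> displacement magnitude maps and arrow renderings ->
#' warped-segmentation Dice validation -> a JSON manifest listing every
#' artifact with its MD5 checksum. Fully deterministic for a fixed config
#' and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the manifest list (also written to
#'   \code{manifest_growth.json}).
#' @export
run_growth_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- pipeline_logger(file.path(cfg$out_dir, "growth_pipeline.log"))
  log("growth pipeline: seed ", cfg$seed,
      "; normalization ", cfg$normalization,
      "; field direction: x + u(x) maps week k to week k+1 (J > 1 = growth)",
      "; affine prealignment ", cfg$run_affine)
  artifacts <- character(0)

  series <- run_stage("input", NA, {
    if (is.null(cfg$volume_paths)) {
      log("generating phantom: grid ",
          paste(cfg$phantom$grid_shape, collapse = "x"),
          ", ", cfg$phantom$n_weeks, " weeks, global growth ",
          cfg$phantom$global_growth_per_week, "/week")
      s <- generate_phantom(cfg$phantom)
      artifacts <- c(artifacts, write_phantom(s, file.path(cfg$out_dir, "phantom")))
      s
    } else {
      log("reading ", length(cfg$volume_paths), " user volume/label pairs")
      vols <- lapply(cfg$volume_paths, read_volume)
      labs <- lapply(cfg$label_paths, read_labels, label_dict = cfg$label_dict)
      for (k in seq_along(vols)) stop_if_grid_mismatch(vols[[k]], labs[[k]], "week inputs")
      list(volumes = vols, labels = labs, label_dict = cfg$label_dict)
    }
  })

  n_pairs <- length(series$volumes) - 1
  fields <- vector("list", n_pairs)
  pair_rows <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    fixed <- series$volumes[[k]]; moving <- series$volumes[[k + 1]]
    tag <- sprintf("pair%02d", k - 1)

    if (cfg$run_affine) {
      a <- run_stage("affine", k, affine_register(moving, fixed, cfg$registration))
      moving <- apply_affine(moving, a$transform)
      p_aff <- file.path(cfg$out_dir, paste0(tag, "_affine.txt"))
      write_affine(a$transform, p_aff)
      artifacts <- c(artifacts, p_aff)
      log(tag, ": affine MSE ", signif(a$initial_mse, 4), " -> ",
          signif(a$final_mse, 4))
    }

    fit <- run_stage("registration", k,
                     diffeo_register(moving, fixed, cfg$registration))
    log(tag, ": diffeo MSE ", signif(fit$initial_mse, 4), " -> ",
        signif(fit$final_mse, 4), " (reduction ",
        round(100 * (1 - fit$final_mse / fit$initial_mse), 1),
        "%), min J ", signif(fit$min_jacobian, 4))
    fields[[k]] <- fit$field
    p_field <- file.path(cfg$out_dir, paste0(tag, "_field.nii.gz"))
    write_field(fit$field, p_field)

    maps <- run_stage("growth_maps", k, {
      j <- jacobian_determinant(fit$field)
      R <- if (cfg$normalization == "mask_volume")
        global_growth(series$labels[[k]], series$labels[[k + 1]])
      else global_growth_from_jacobian(j, series$labels[[k]])
      jn <- normalize_jacobian(j, R)
      p_raw <- file.path(cfg$out_dir, paste0(tag, "_jacobian_raw.nii.gz"))
      p_norm <- file.path(cfg$out_dir, paste0(tag, "_jacobian_norm.nii.gz"))
      write_volume(j, p_raw); write_volume(jn, p_norm)
      summ <- region_growth_summary(jn, series$labels[[k]])
      p_sum <- file.path(cfg$out_dir, paste0(tag, "_region_growth.csv"))
      utils::write.csv(summ, p_sum, row.names = FALSE)
      list(R = R, paths = c(p_raw, p_norm, p_sum), summary = summ)
    })
    log(tag, ": global volume ratio R = ", signif(maps$R, 6),
        "; top region by mean normalized J: ", maps$summary$label[1])

    disp <- run_stage("displacement_maps", k, {
      p_mag <- file.path(cfg$out_dir, paste0(tag, "_magnitude.nii.gz"))
      write_volume(magnitude_map(fit$field), p_mag)
      dm <- dim(fit$field$vectors)[1:3]
      ax <- slice_axis(cfg$arrow_plane)
      idx <- if (is.null(cfg$arrow_index)) dm[ax] %/% 2L else cfg$arrow_index
      s <- slice_spec(cfg$arrow_plane, idx, cfg$arrow_stride)
      p_png <- file.path(cfg$out_dir, paste0(tag, "_arrows.png"))
      p_csv <- file.path(cfg$out_dir, paste0(tag, "_arrows.csv"))
      arrow_plot(fit$field, series$labels[[k]], s, p_png, p_csv)
      c(p_mag, p_png, p_csv)
    })
    artifacts <- c(artifacts, p_field, maps$paths, disp)
    pair_rows[[k]] <- list(pair = k, global_ratio = maps$R,
                           initial_mse = fit$initial_mse,
                           final_mse = fit$final_mse,
                           min_jacobian = fit$min_jacobian)
  }

  dice <- run_stage("validation", NA, validate_registration(series, fields))
  p_dice <- file.path(cfg$out_dir, "dice_validation.csv")
  utils::write.csv(dice, p_dice, row.names = FALSE)
  artifacts <- c(artifacts, p_dice)
  for (k in seq_len(n_pairs))
    log(sprintf("pair%02d", k - 1), ": macro Dice ", round(dice$macro_dice[k], 4))

  manifest <- list(
    pipeline = "growth",
    package_version = as.character(utils::packageVersion("morphogrowth")),
    seed = cfg$seed,
    settings = list(normalization = cfg$normalization,
                    field_direction = "x + u(x) maps week k to week k+1",
                    run_affine = cfg$run_affine,
                    arrow_plane = cfg$arrow_plane,
                    arrow_stride = cfg$arrow_stride),
    pairs = pair_rows,
    dice = lapply(seq_len(nrow(dice)), function(i) as.list(dice[i, ])),
    artifacts = manifest_entry(artifacts, cfg$out_dir))
  p_man <- file.path(cfg$out_dir, "manifest_growth.json")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log("manifest: ", p_man, " (", length(artifacts), " artifacts)")
  invisible(manifest)
}

#' Run the transcriptome contrast pipeline
#'
#' End to end: expression table (generated with planted truth, or read from
#' TSV) -> layered opercula-versus-insula fold-change contrast -> one CSV
#' of selected genes per layer, a combined report, a cutoff summary, and a
#' JSON manifest with checksums. Deterministic for a fixed config and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the manifest list (also written to
#'   \code{manifest_contrast.json}).
#' @export
run_contrast_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- pipeline_logger(file.path(cfg$out_dir, "contrast_pipeline.log"))
  log("contrast pipeline: seed ", cfg$seed, "; percentile ", cfg$percentile,
      " (rank-based top ", 100 - cfg$percentile, "% per layer, ties broken ",
      "by gene id); fold-change pseudocount eps = ", cfg$eps,
      "; aggregation: linear-scale mean over specimens and structures")
  artifacts <- character(0)

  tbl <- run_stage("input", NA, {
    if (is.null(cfg$expression_path)) {
      log("generating expression: ", cfg$expression$n_genes, " genes, ",
          cfg$expression$n_specimens, " specimens, ",
          sum(cfg$expression$planted_gene_count), " planted gene-layer signals")
      es <- generate_expression(cfg$expression)
      p_truth <- file.path(cfg$out_dir, "planted_truth.csv")
      utils::write.csv(es$truth, p_truth, row.names = FALSE)
      artifacts <- c(artifacts, p_truth)
      es$table
    } else {
      log("reading expression table ", cfg$expression_path)
      read_expression(cfg$expression_path)
    }
  })

  res <- run_stage("contrast", NA,
                   contrast_report(tbl, cfg$regions, cfg$percentile, cfg$eps))

  out_paths <- run_stage("report", NA, {
    paths <- character(0)
    for (b in res$layers) {
      p <- file.path(cfg$out_dir, paste0("contrast_", b$layer, ".csv"))
      utils::write.csv(b$table[b$table$selected, , drop = FALSE], p,
                       row.names = FALSE)
      paths <- c(paths, p)
      log("layer ", b$layer, ": n_selected ", b$n_selected,
          ", cutoff fold ", signif(b$cutoff_fold, 5))
    }
    p_all <- file.path(cfg$out_dir, "contrast_selected.csv")
    write_contrast_report(res, p_all)
    p_cut <- file.path(cfg$out_dir, "contrast_cutoffs.csv")
    utils::write.csv(res$cutoffs, p_cut, row.names = FALSE)
    c(paths, p_all, p_cut)
  })
  artifacts <- c(artifacts, out_paths)

  manifest <- list(
    pipeline = "contrast",
    package_version = as.character(utils::packageVersion("morphogrowth")),
    seed = cfg$seed,
    settings = list(percentile = cfg$percentile, eps = cfg$eps,
                    aggregation = "linear-scale mean over specimens and structures",
                    tie_break = "lexicographic gene id",
                    target_structures = cfg$regions$target_structures,
                    contrast_structures = cfg$regions$contrast_structures),
    cutoffs = lapply(seq_len(nrow(res$cutoffs)),
                     function(i) as.list(res$cutoffs[i, ])),
    artifacts = manifest_entry(artifacts, cfg$out_dir))
  p_man <- file.path(cfg$out_dir, "manifest_contrast.json")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log("manifest: ", p_man, " (", length(artifacts), " artifacts)")
  invisible(manifest)
}
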