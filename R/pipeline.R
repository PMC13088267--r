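# End-to-end experiments: synthesize sections, extract CIELAB clouds,
# compute separation metrics and agreement/classifier statistics, and
# write machine-readable reports.

#' Experiment configuration
#'
#' Serializable configuration for the end-to-end experiments. Defaults are
#' the package's desk-scale experiment settings; the per-operation
#' protocol defaults (81-px regions, 64^3 grids) remain available by
#' overriding `region_px` and `gridsize`.
#'
#' @param section_width,section_height synthetic section size (px).
#' @param n_regions regions (clouds) per condition (default 5, giving the
#'   5 x 5 = 25-pair comparison).
#' @param region_px cloud region edge (px).
#' @param gridsize KDE grid nodes per axis.
#' @param bandwidth per-axis KDE bandwidth, or NULL for Scott's rule.
#' @param cavity_nm slide cavity thickness (nm).
#' @param ri_healthy,ri_cancer class RI models `c(mean, sd)`.
#' @param thickness_um thickness model (um): `c(mean, sd)` for
#'   `thickness_dist = "normal"`, `c(min, max)` for `"uniform"`.
#' @param thickness_dist thickness distribution form.
#' @param smooth_sigma_px spatial correlation length of the fields (px).
#' @param noise_sd sensor noise sd (sRGB units).
#' @param n_tiles_per_class,tile_px,n_subjects screening-experiment tile
#'   settings.
#' @param classifier `"centroid"` or `"logistic"`.
#' @param threshold decision threshold on the classifier score.
#' @param seed default seed.
#' @param out_dir output directory for reports, or NULL to skip writing.
#' @param dry_run validate the configuration and return without computing.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(section_width = 160, section_height = 120,
                       n_regions = 5, region_px = 27,
                       gridsize = 32, bandwidth = NULL,
                       cavity_nm = 243,
                       ri_healthy = c(1.27, 0.02), ri_cancer = c(1.37, 0.02),
                       thickness_um = c(0.5, 0.02),
                       thickness_dist = "normal", smooth_sigma_px = 1.5,
                       noise_sd = 0.01,
                       n_tiles_per_class = 40, tile_px = 20, n_subjects = 2,
                       classifier = "centroid", threshold = 0.5,
                       seed = 1, out_dir = NULL, dry_run = FALSE) {
  cfg <- list(section_width = section_width, section_height = section_height,
              n_regions = n_regions, region_px = region_px,
              gridsize = gridsize, bandwidth = bandwidth,
              cavity_nm = cavity_nm,
              ri_healthy = ri_healthy, ri_cancer = ri_cancer,
              thickness_um = thickness_um,
              thickness_dist = thickness_dist,
              smooth_sigma_px = smooth_sigma_px, noise_sd = noise_sd,
              n_tiles_per_class = n_tiles_per_class, tile_px = tile_px,
              n_subjects = n_subjects, classifier = classifier,
              threshold = threshold, seed = seed, out_dir = out_dir,
              dry_run = dry_run)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$n_regions >= 1, cfg$region_px >= 3, cfg$gridsize >= 8,
            cfg$cavity_nm > 0, cfg$tile_px >= 4, cfg$n_subjects >= 1,
            cfg$threshold > 0, cfg$threshold < 1)
  if (cfg$region_px > min(cfg$section_width / 2, cfg$section_height))
    stop("region_px too large for the section geometry")
  invisible(cfg)
}

#' Read / write a run configuration as JSON
#'
#' The JSON round-trips: `read_run_config(write_run_config(cfg, f))`
#' parses back equal to `cfg`.
#'
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

section_spec_from_config <- function(cfg, mode) {
  section_spec(width = cfg$section_width, height = cfg$section_height,
               ri_healthy = cfg$ri_healthy, ri_cancer = cfg$ri_cancer,
               thickness_um = cfg$thickness_um,
               thickness_dist = cfg$thickness_dist,
               smooth_sigma_px = cfg$smooth_sigma_px,
               noise_sd = cfg$noise_sd, mode = mode,
               slide = slide_config(cavity_nm = cfg$cavity_nm))
}

# Render one section per mode from the same seed and extract the
# healthy/cancer clouds.
clouds_for_mode <- function(spec, cfg, lut, seed) {
  sec <- render_section(spec, lut = lut, seed = seed)
  regions <- lapply(1:2, function(cls)
    sample_regions(spec$region_map, cls, cfg$n_regions, cfg$region_px,
                   seed = seed + 7919L * cls))
  lapply(regions, function(rs)
    lapply(rs, function(p) extract_lab_cloud(sec$rgb, p, cfg$region_px)))
}

#' Run the healthy-vs-cancer color separation experiment
#'
#' Synthesizes a tissue section, renders it under both the NOS slide
#' forward model and the weak-contrast glass proxy, samples
#' `n_regions` + `n_regions` non-overlapping class-pure regions, extracts
#' CIELAB clouds, computes the pairwise KDE-IoU (plus Frobenius and
#' Chamfer) per rendering mode, and tests the two IoU sets against each
#' other with a two-sided independent-samples t-test.
#'
#' @param cfg a [run_config()].
#' @param luts optional named list of prebuilt LUTs (`nos`, `glass`) for
#'   reuse across seeds.
#' @return Object of class `nos_report` with elements `config`, `seed`,
#'   `nos` and `glass` (each a `group_iou`), `t_test`, `timings_s`; or the
#'   validated config invisibly when `dry_run` is set.
#' @export
run_comparison_experiment <- function(cfg = run_config(), luts = NULL) {
  validate_run_config(cfg)
  if (isTRUE(cfg$dry_run)) return(invisible(cfg))
  t0 <- proc.time()[["elapsed"]]
  specs <- list(nos = section_spec_from_config(cfg, "nos"),
                glass = section_spec_from_config(cfg, "glass"))
  if (is.null(luts))
    luts <- lapply(specs, build_color_lut)
  t_lut <- proc.time()[["elapsed"]]
  comps <- lapply(names(specs), function(mode) {
    cl <- clouds_for_mode(specs[[mode]], cfg, luts[[mode]], cfg$seed)
    group_iou_comparison(cl[[1]], cl[[2]], bandwidth = cfg$bandwidth,
                         gridsize = cfg$gridsize,
                         labels = c("healthy", "cancerous"),
                         extra_metrics = TRUE)
  })
  names(comps) <- names(specs)
  t_metrics <- proc.time()[["elapsed"]]
  tt <- compare_group_iou(comps$glass, comps$nos)
  report <- structure(list(
    kind = "comparison",
    version = as.character(utils::packageVersion("noscolor")),
    config = cfg, seed = cfg$seed,
    nos = comps$nos, glass = comps$glass,
    mean_iou = c(nos = comps$nos$mean_iou, glass = comps$glass$mean_iou),
    t_test = list(statistic = unname(tt$statistic),
                  p_value = tt$p.value, df = unname(tt$parameter)),
    timings_s = c(lut = t_lut - t0, metrics = t_metrics - t_lut)),
    class = "nos_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Sign-test ordering experiment across seeds
#'
#' Repeats the comparison experiment over `n_seeds` seeds (LUTs built
#' once) and counts the seeds where the NOS-slide mean healthy-vs-cancer
#' IoU is lower than the glass-mode one, with an exact binomial sign
#' test against 1/2.
#'
#' @param cfg a [run_config()]; its `seed` is the base seed.
#' @param n_seeds number of replicate seeds (default 20).
#' @return List with the per-seed mean IoUs, `n_nos_lower`, and the sign
#'   test p-value.
#' @export
ordering_experiment <- function(cfg = run_config(), n_seeds = 20) {
  validate_run_config(cfg)
  specs <- list(nos = section_spec_from_config(cfg, "nos"),
                glass = section_spec_from_config(cfg, "glass"))
  luts <- lapply(specs, build_color_lut)
  res <- vapply(seq_len(n_seeds), function(k) {
    cfg_k <- cfg; cfg_k$seed <- cfg$seed + k - 1L; cfg_k$out_dir <- NULL
    means <- vapply(names(specs), function(mode) {
      cl <- clouds_for_mode(specs[[mode]], cfg_k, luts[[mode]], cfg_k$seed)
      group_iou_comparison(cl[[1]], cl[[2]], bandwidth = cfg$bandwidth,
                           gridsize = cfg$gridsize)$mean_iou
    }, numeric(1))
    means
  }, numeric(2))
  n_lower <- sum(res["nos", ] < res["glass", ])
  bt <- stats::binom.test(n_lower, n_seeds, p = 0.5,
                          alternative = "greater")
  list(iou_nos = unname(res["nos", ]), iou_glass = unname(res["glass", ]),
       n_seeds = n_seeds, n_nos_lower = n_lower, p_value = bt$p.value)
}

#' Run the tile screening experiment
#'
#' Generates labeled tiles with a subject-level train/test split, scores
#' the held-out tiles with the baseline color-feature classifier and
#' reports the full evaluation suite: confusion matrix at the decision
#' threshold, accuracy/precision/recall/F1, Cohen's kappa and consistency
#' rate against truth, and the ROC curve with its AUC.
#'
#' @param cfg a [run_config()].
#' @param shuffle_labels permute the training labels first (null
#'   control; expected AUC 0.5).
#' @return Object of class `nos_report` with the metric suite.
#' @export
run_screening_experiment <- function(cfg = run_config(), shuffle_labels = FALSE) {
  validate_run_config(cfg)
  if (isTRUE(cfg$dry_run)) return(invisible(cfg))
  t0 <- proc.time()[["elapsed"]]
  spec <- section_spec_from_config(cfg, "nos")
  lut <- build_color_lut(spec)
  ds <- make_labeled_tiles(spec, n_per_class = cfg$n_tiles_per_class,
                           tile_px = cfg$tile_px,
                           n_subjects = cfg$n_subjects,
                           seed = cfg$seed, lut = lut)
  train_labels <- ds$train$labels
  if (shuffle_labels)
    train_labels <- with_seed(cfg$seed + 99L,
                              sample(train_labels, length(train_labels)))
  scores <- baseline_tile_classifier(ds$train$tiles, train_labels,
                                     ds$test$tiles, method = cfg$classifier)
  truth <- ds$test$labels
  pred <- factor(ifelse(scores >= cfg$threshold, "cancerous", "healthy"),
                 levels = levels(truth))
  cm <- confusion_matrix(as.character(pred), as.character(truth),
                         labels = levels(truth))
  ev <- binary_metrics(TP = sum(pred == "cancerous" & truth == "cancerous"),
                       FP = sum(pred == "cancerous" & truth == "healthy"),
                       TN = sum(pred == "healthy" & truth == "healthy"),
                       FN = sum(pred == "healthy" & truth == "cancerous"))
  roc <- roc_curve(scores, truth == "cancerous")
  kap <- tryCatch(cohens_kappa(cm), error = function(e) NULL)
  report <- structure(list(
    kind = "screening",
    version = as.character(utils::packageVersion("noscolor")),
    config = cfg, seed = cfg$seed,
    confusion = cm, metrics = ev,
    kappa = kap, consistency = consistency_rate(cm),
    roc = roc, auc = auc(roc), scores = scores,
    truth = truth,
    timings_s = c(total = proc.time()[["elapsed"]] - t0)),
    class = "nos_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.nos_report <- function(x, ...) {
  cat(sprintf("<nos_report> %s experiment, seed %d\n", x$kind, x$seed))
  if (x$kind == "comparison") {
    cat(sprintf("  mean healthy-vs-cancer IoU: NOS %.4f, glass %.4f\n",
                x$mean_iou[["nos"]], x$mean_iou[["glass"]]))
    cat(sprintf("  two-sided t-test (glass vs NOS): t = %.3f, p = %.3g\n",
                x$t_test$statistic, x$t_test$p_value))
  } else {
    cat(sprintf(
      "  accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | AUC %.3f\n",
      x$metrics$accuracy, x$metrics$precision, x$metrics$recall,
      x$metrics$f1, x$auc))
    if (!is.null(x$kappa))
      cat(sprintf("  kappa %.3f, consistency %.3f\n",
                  x$kappa$kappa, x$consistency))
  }
  invisible(x)
}

# Write a report to out_dir: JSON summary + CSV metric tables.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(out_dir, paste0(report$kind, "_seed", report$seed))
  if (report$kind == "comparison") {
    for (mode in c("nos", "glass")) {
      g <- report[[mode]]
      pairs <- expand.grid(i = seq_len(nrow(g$iou_matrix)),
                           j = seq_len(ncol(g$iou_matrix)))
      utils::write.csv(data.frame(
        mode = mode, healthy = pairs$i, cancerous = pairs$j,
        iou = g$iou_matrix[as.matrix(pairs)],
        frobenius = g$frobenius_matrix[as.matrix(pairs)],
        chamfer = g$chamfer_matrix[as.matrix(pairs)]),
        paste0(base, "_", mode, "_pairs.csv"), row.names = FALSE)
    }
    summary <- list(kind = report$kind, version = report$version,
                    seed = report$seed, config = unclass(report$config),
                    mean_iou = as.list(report$mean_iou),
                    t_test = report$t_test)
  } else {
    utils::write.csv(data.frame(score = report$scores,
                                truth = as.character(report$truth)),
                     paste0(base, "_scores.csv"), row.names = FALSE)
    summary <- list(kind = report$kind, version = report$version,
                    seed = report$seed, config = unclass(report$config),
                    accuracy = report$metrics$accuracy,
                    precision = report$metrics$precision,
                    recall = report$metrics$recall,
                    f1 = report$metrics$f1,
                    kappa = if (!is.null(report$kappa)) report$kappa$kappa,
                    consistency = report$consistency,
                    auc = report$auc,
                    confusion = unclass(report$confusion))
  }
  jsonlite::write_json(summary, paste0(base, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(base)
}
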