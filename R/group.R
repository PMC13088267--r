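#' Pairwise KDE-IoU between two groups of point clouds
#'
#' Estimates every cloud's density on one shared grid spanning all clouds
#' and computes all pairwise KDE-IoU values between the two groups (5 + 5
#' clouds give the 5 x 5 = 25-pair protocol). Optionally also computes the
#' pairwise Frobenius norms and Chamfer distances.
#'
#' @param group_a,group_b lists of [lab_cloud()]s (non-empty).
#' @param bandwidth per-axis KDE bandwidth; default: largest Scott's-rule
#'   bandwidth over all clouds (shared, so densities are comparable).
#' @param gridsize grid nodes per axis (default 64).
#' @param padding grid padding in bandwidth units (default 3).
#' @param labels length-2 character labels for the two groups.
#' @param extra_metrics also compute pairwise `frobenius` and `chamfer`
#'   (default FALSE; the Chamfer pass is the expensive part).
#' @return Object of class `group_iou`: list with `iou_matrix`
#'   (length(group_a) x length(group_b)), `mean_iou`, `labels`, the KDE
#'   settings, and optionally `frobenius_matrix` / `chamfer_matrix`.
#' @export
group_iou_comparison <- function(group_a, group_b, bandwidth = NULL,
                                 gridsize = 64, padding = 3,
                                 labels = c("A", "B"),
                                 extra_metrics = FALSE) {
  if (inherits(group_a, "lab_cloud")) group_a <- list(group_a)
  if (inherits(group_b, "lab_cloud")) group_b <- list(group_b)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  clouds <- c(group_a, group_b)
  if (is.null(bandwidth)) {
    bws <- sapply(clouds, scott_bandwidth)
    bandwidth <- apply(matrix(bws, nrow = 3), 1, max)
  }
  bandwidth <- rep_len(bandwidth, 3)
  axes <- kde_axes(clouds, bandwidth, gridsize, padding)
  dens_a <- lapply(group_a, kde_density, bandwidth = bandwidth, axes = axes)
  dens_b <- lapply(group_b, kde_density, bandwidth = bandwidth, axes = axes)
  na <- length(group_a); nb <- length(group_b)
  iou <- matrix(NA_real_, na, nb,
                dimnames = list(paste0(labels[1], seq_len(na)),
                                paste0(labels[2], seq_len(nb))))
  frob <- if (extra_metrics) iou else NULL
  cham <- if (extra_metrics) iou else NULL
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    iou[i, j] <- kde_iou(dens_a[[i]], dens_b[[j]])
    if (extra_metrics) {
      frob[i, j] <- frobenius_diff(dens_a[[i]], dens_b[[j]])
      cham[i, j] <- chamfer_distance(group_a[[i]], group_b[[j]])$rescaled
    }
  }
  structure(list(iou_matrix = iou, mean_iou = mean(iou),
                 frobenius_matrix = frob, chamfer_matrix = cham,
                 labels = labels, bandwidth = bandwidth,
                 gridsize = gridsize, padding = padding),
            class = "group_iou")
}

#' @export
print.group_iou <- function(x, ...) {
  cat(sprintf("<group_iou> %s vs %s: %d x %d pairs, mean IoU %.4f\n",
              x$labels[1], x$labels[2],
              nrow(x$iou_matrix), ncol(x$iou_matrix), x$mean_iou))
  invisible(x)
}

#' Compare two group IoU distributions
#'
#' Two-sided independent-samples (Student's, pooled-variance) t-test on the
#' two sets of pairwise IoU values, e.g. NOS-slide versus glass-slide
#' healthy-vs-cancer IoUs.
#'
#' @param comp_a,comp_b `group_iou` objects (or numeric vectors of IoU
#'   values).
#' @return The `htest` from [stats::t.test()] (two-sided, `var.equal =
#'   TRUE`).
#' @export
compare_group_iou <- function(comp_a, comp_b) {
  va <- if (inherits(comp_a, "group_iou")) as.vector(comp_a$iou_matrix) else as.numeric(comp_a)
  vb <- if (inherits(comp_b, "group_iou")) as.vector(comp_b$iou_matrix) else as.numeric(comp_b)
  stats::t.test(va, vb, alternative = "two.sided", var.equal = TRUE)
}
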