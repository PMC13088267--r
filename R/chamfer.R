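#' Chamfer distance between two point clouds
#'
#' Symmetric average nearest-neighbor distance between two point sets.
#' Each axis is first linearly normalized to \[0, 1\] over the joint
#' extent of both clouds so all dimensions contribute equally; axes with
#' zero joint range are dropped from the normalization (recorded in the
#' result). For each point the Euclidean distance to its nearest neighbor
#' in the other cloud is found (exact, ties broken by first index); the
#' two directional (optionally weighted) means are averaged; and the
#' normalized scalar is rescaled back to the original units by the
#' root-mean-square of the kept per-axis ranges. With that convention two
#' single-point clouds give exactly their Euclidean distance.
#'
#' @param a,b [lab_cloud()]s or numeric matrices with matching columns.
#' @param weights_a,weights_b optional non-negative per-point weights for
#'   the a-to-b and b-to-a directional means (default uniform).
#' @return Object of class `chamfer_dist`: list with `rescaled` (original
#'   units; what `as.numeric()` returns), `normalized` (unit-cube value),
#'   `dropped_axes` and the per-axis `ranges`.
#' @export
chamfer_distance <- function(a, b, weights_a = NULL, weights_b = NULL) {
  A <- as.matrix(a); B <- as.matrix(b)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty point cloud")
  if (ncol(A) != ncol(B)) stop("clouds must have the same dimensionality")
  wa <- check_weights(weights_a, nrow(A)); wb <- check_weights(weights_b, nrow(B))
  lo <- pmin(apply(A, 2, min), apply(B, 2, min))
  hi <- pmax(apply(A, 2, max), apply(B, 2, max))
  ranges <- hi - lo
  keep <- ranges > 0
  dropped <- colnames(A)[!keep]
  if (!any(keep)) {
    # all points of both clouds coincide
    out <- list(rescaled = 0, normalized = 0,
                dropped_axes = dropped, ranges = ranges)
    return(structure(out, class = "chamfer_dist"))
  }
  An <- sweep(sweep(A[, keep, drop = FALSE], 2, lo[keep]), 2, ranges[keep], "/")
  Bn <- sweep(sweep(B[, keep, drop = FALSE], 2, lo[keep]), 2, ranges[keep], "/")
  d_ab <- nn_distances(An, Bn)
  d_ba <- nn_distances(Bn, An)
  normalized <- (sum(wa * d_ab) / sum(wa) + sum(wb * d_ba) / sum(wb)) / 2
  scale <- sqrt(mean(ranges[keep]^2))
  structure(list(rescaled = normalized * scale, normalized = normalized,
                 dropped_axes = dropped, ranges = ranges),
            class = "chamfer_dist")
}

check_weights <- function(w, n) {
  if (is.null(w)) return(rep(1, n))
  w <- as.numeric(w)
  if (length(w) != n) stop("weights length must match cloud size")
  if (any(!is.finite(w)) || any(w < 0) || sum(w) == 0)
    stop("weights must be non-negative with positive sum")
  w
}

# Exact nearest-neighbor distance from each row of X to the rows of Y,
# chunked so the cross-distance block stays small.
nn_distances <- function(X, Y, chunk = 512L) {
  ny2 <- rowSums(Y^2)
  out <- numeric(nrow(X))
  for (s in seq(1, nrow(X), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(X))
    Xc <- X[idx, , drop = FALSE]
    d2 <- outer(rowSums(Xc^2), ny2, "+") - 2 * Xc %*% t(Y)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' @export
print.chamfer_dist <- function(x, ...) {
  cat(sprintf("<chamfer_dist> %.6g (normalized %.6g)%s\n",
              x$rescaled, x$normalized,
              if (length(x$dropped_axes))
                paste0(" [degenerate axes dropped: ",
                       paste(x$dropped_axes, collapse = ", "), "]") else ""))
  invisible(x)
}

#' @export
as.double.chamfer_dist <- function(x, ...) x$rescaled
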