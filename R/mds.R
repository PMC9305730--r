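#' MDS network layout of a polychoric correlation matrix
#'
#' Embeds the items in the plane by classical (Torgerson) multidimensional
#' scaling of the dissimilarity `d_ij = sqrt(2 * (1 - r_ij))`, so that more
#' strongly associated items lie closer together. The embedding is
#' deterministic up to rigid motion; a fixed sign convention (the coordinate
#' of largest magnitude on each axis is made positive) pins the reflection.
#' Negative eigenvalues of the double-centred matrix are truncated with a
#' warning rather than failing.
#'
#' @param r A `polychoric_matrix` or a plain correlation matrix.
#' @param edge_threshold Minimum correlation for a pair to appear in the edge
#'   list (display only; default 0.3).
#' @return Object of class `network_layout`: list with `coordinates` (Jx2
#'   matrix) and `edge_list` (`data.frame` of item pairs and weights).
#' @export
mds_layout <- function(r, edge_threshold = 0.3) {
  if (inherits(r, "polychoric_matrix")) r <- r$r_pc
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (max(abs(r - t(r))) > 1e-8 || any(abs(diag(r) - 1) > 1e-8)) {
    stop("mds_layout expects a symmetric correlation matrix with unit diagonal")
  }
  j <- nrow(r)
  labels <- rownames(r) %||% paste0("item_", seq_len(j))
  d <- sqrt(pmax(2 * (1 - r), 0))
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = min(2, j - 1), eig = TRUE)
  )
  if (any(fit$eig < -1e-8)) {
    warning("double-centred matrix not positive semi-definite; ",
            "negative eigenvalues truncated")
  }
  coords <- fit$points
  if (is.null(coords) || length(coords) == 0) {
    coords <- matrix(0, j, 2)
  }
  if (ncol(coords) < 2) {
    coords <- cbind(coords, matrix(0, j, 2 - ncol(coords)))
  }
  # sign convention: largest-magnitude coordinate on each axis is positive
  for (ax in 1:2) {
    i_max <- which.max(abs(coords[, ax]))
    if (length(i_max) && coords[i_max, ax] < 0) coords[, ax] <- -coords[, ax]
  }
  rownames(coords) <- labels
  colnames(coords) <- c("x", "y")
  pairs <- which(upper.tri(r) & r >= edge_threshold, arr.ind = TRUE)
  edge_list <- data.frame(
    item1 = labels[pairs[, 1]],
    item2 = labels[pairs[, 2]],
    weight = r[pairs],
    stringsAsFactors = FALSE
  )
  structure(list(coordinates = coords, edge_list = edge_list,
                 eig = fit$eig),
            class = "network_layout")
}

#' @export
print.network_layout <- function(x, ...) {
  cat(sprintf("<network_layout> %d nodes, %d edges\n",
              nrow(x$coordinates), nrow(x$edge_list)))
  invisible(x)
}
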