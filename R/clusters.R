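# Connected-component extraction on thresholded statistic maps.

neighbour_offsets <- function(connectivity = c(26L, 18L, 6L)) {
  connectivity <- as.integer(connectivity[1])
  if (!connectivity %in% c(6L, 18L, 26L))
    abort("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  g[keep, , drop = FALSE]
}

# Label connected components among `idx` (1-based linear indices into an
# array of dimension `dim`). Returns a list of integer vectors, one per
# component. Flood fill over a rank lookup array; independent of the order
# in which voxels are supplied.
label_components <- function(idx, dim, connectivity = 26L) {
  if (length(idx) == 0) return(list())
  idx <- sort(as.integer(idx))
  offs <- neighbour_offsets(connectivity)
  pos <- integer(prod(dim))
  pos[idx] <- seq_along(idx)
  coords <- lin_to_coord(idx, dim)
  visited <- logical(length(idx))
  out <- list()
  for (s in seq_along(idx)) {
    if (visited[s]) next
    stack <- s
    visited[s] <- TRUE
    comp <- integer(0)
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, cur)
      nc <- offs + rep(coords[cur, ], each = nrow(offs))
      ok <- nc[, 1] >= 1 & nc[, 1] <= dim[1] &
        nc[, 2] >= 1 & nc[, 2] <= dim[2] &
        nc[, 3] >= 1 & nc[, 3] <= dim[3]
      if (any(ok)) {
        hits <- pos[coord_to_lin(nc[ok, , drop = FALSE], dim)]
        hits <- hits[hits > 0]
        hits <- hits[!visited[hits]]
        if (length(hits) > 0) {
          visited[hits] <- TRUE
          stack <- c(stack, hits)
        }
      }
    }
    out[[length(out) + 1]] <- idx[comp]
  }
  out
}

max_cluster_size <- function(idx, dim, connectivity = 26L) {
  comps <- label_components(idx, dim, connectivity)
  if (length(comps) == 0) 0L else max(lengths(comps))
}

#' Extract supra-threshold clusters from a statistic map
#'
#' Connected components of `{v : t(v) >= t_threshold}` under the given
#' connectivity. The cluster peak is the voxel with maximal t; ties are
#' broken by the smallest linear index (x fastest). Clusters are returned
#' sorted by descending peak t.
#'
#' @param map a `stat_map` from [contrast_map()], or a 3-D numeric array
#'   (then `df` must be given for z-scores).
#' @param t_threshold finite cluster-forming threshold on t.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param df degrees of freedom when `map` is a bare array.
#' @return a tibble with one row per cluster: `size`, 0-based peak
#'   coordinates `peak_x/y/z`, `peak_t`, `peak_z`, the internal 1-based
#'   linear `peak_idx`, and a `voxels` list-column of linear indices.
#' @export
extract_clusters <- function(map, t_threshold, connectivity = 26L, df = NULL) {
  if (inherits(map, "stat_map")) {
    tarr <- map$t; df <- map$df
  } else {
    tarr <- map
    if (is.null(df)) abort("df required when map is a bare array")
  }
  stopifnot(is.finite(t_threshold))
  dim3 <- dim(tarr)
  idx <- which(tarr >= t_threshold)
  comps <- label_components(idx, dim3, connectivity)
  if (length(comps) == 0) {
    return(tibble::tibble(
      size = integer(0), peak_x = integer(0), peak_y = integer(0),
      peak_z = integer(0), peak_t = numeric(0), peak_z_score = numeric(0),
      peak_idx = integer(0), voxels = list()
    ))
  }
  rows <- purrr::map(comps, function(vx) {
    tv <- tarr[vx]
    best <- vx[tv == max(tv)]
    peak <- min(best) # tie rule: smallest linear index
    xyz <- lin_to_coord(peak, dim3)[1, ]
    tibble::tibble(
      size = length(vx),
      peak_x = xyz[1] - 1L, peak_y = xyz[2] - 1L, peak_z = xyz[3] - 1L,
      peak_t = tarr[peak], peak_z_score = t_to_z(tarr[peak], df),
      peak_idx = as.integer(peak), voxels = list(sort(vx))
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$peak_t, out$peak_idx), ]
}
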