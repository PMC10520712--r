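#' Spatial weights from an adjacency edge list
#'
#' Builds the binary geographical adjacency matrix W: `W[i, j] = 1` when
#' regions i and j share an edge, 0 otherwise, zero diagonal. Regions with no
#' neighbours (islands) are kept as all-zero rows and reported.
#'
#' @param map a [region_map()].
#' @return An object of class `spatial_weights`: list with `W` (dense named
#'   matrix), `standardized` flag, `region_order`, `islands`.
#' @export
weights_from_edges <- function(map) {
  stopifnot(inherits(map, "region_map"))
  ids <- map$region_ids
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- map$edges
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  if (anyDuplicated(key)) {
    warn_gc("%d duplicate edge(s) collapsed", sum(duplicated(key)))
    e <- e[!duplicated(key), , drop = FALSE]
  }
  W[cbind(e$from, e$to)] <- 1
  W[cbind(e$to, e$from)] <- 1
  new_spatial_weights(W, standardized = FALSE)
}

new_spatial_weights <- function(W, standardized) {
  islands <- rownames(W)[rowSums(W) == 0]
  structure(list(W = W, standardized = standardized,
                 region_order = rownames(W), islands = islands),
            class = "spatial_weights")
}

as_weights_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$W else as.matrix(W)
}

#' Row-standardize a spatial weights matrix
#'
#' Divides each nonzero row by its sum so rows sum to one; island rows (all
#' zero) are preserved and reported with a warning. Row standardization is the
#' convention assumed by the spatial panel estimators in this package: it
#' bounds the admissible spatial parameter above by 1 and makes spillovers
#' interpretable as neighbourhood averages.
#'
#' @param W a `spatial_weights` object.
#' @return A `spatial_weights` object with `standardized = TRUE`.
#' @export
row_standardize <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  m <- W$W
  rs <- rowSums(m)
  if (any(rs == 0)) {
    warn_gc("island region(s) with no neighbours kept as zero rows: %s",
            paste(rownames(m)[rs == 0], collapse = ", "))
  }
  nz <- rs > 0
  m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  new_spatial_weights(m, standardized = TRUE)
}

#' Principal submatrix of a spatial weights object
#'
#' Restricts W to a subset of regions (used for regional-heterogeneity runs).
#' If the input was row-standardized the subset is re-standardized from the
#' underlying nonzero pattern; regions that lose all neighbours become
#' islands and are reported.
#'
#' @param W a `spatial_weights` object.
#' @param regions nonempty character vector of region labels to keep, in the
#'   desired order.
#' @return A `spatial_weights` object over `regions`.
#' @export
subset_weights <- function(W, regions) {
  stopifnot(inherits(W, "spatial_weights"))
  regions <- as.character(regions)
  if (!length(regions)) stop_gc("empty region subset")
  unknown <- setdiff(regions, W$region_order)
  if (length(unknown)) stop_gc("unknown region(s): %s", paste(unknown, collapse = ", "))
  m <- W$W[regions, regions, drop = FALSE]
  out <- new_spatial_weights(m, standardized = FALSE)
  if (W$standardized) out <- suppressWarnings(row_standardize(out))
  if (length(out$islands)) {
    warn_gc("subsetting created island(s): %s", paste(out$islands, collapse = ", "))
  }
  out
}

# Real eigenvalues of W. Row-standardized matrices derived from a symmetric
# binary matrix are similar to a symmetric matrix, so the spectrum is real;
# a small imaginary residue from the general solver is tolerated and dropped.
weights_eigen <- function(W) {
  m <- as_weights_matrix(W)
  ev <- eigen(m, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-7 * max(1, max(abs(ev)))) {
    stop_gc("spatial weights have genuinely complex eigenvalues; expected a symmetric-similar matrix")
  }
  sort(Re(ev))
}

# Admissible interval for the spatial autoregressive parameter:
# (1/omega_min, 1/omega_max) with omega the eigenvalues of W.
rho_interval <- function(W, ev = NULL) {
  ev <- ev %||% weights_eigen(W)
  c(1 / min(ev), 1 / max(ev))
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d regions, %s, %d island(s)\n",
              length(x$region_order),
              if (x$standardized) "row-standardized" else "binary/raw",
              length(x$islands)))
  invisible(x)
}

#' Read an adjacency edge list from CSV
#'
#' Expects a header and two columns (`from`, `to` region labels).
#'
#' @param path CSV file path.
#' @return data.frame with columns `from` and `to`.
#' @export
read_edge_list <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(e) < 2L) stop_gc("edge list must have two columns")
  data.frame(from = as.character(e[[1L]]), to = as.character(e[[2L]]),
             stringsAsFactors = FALSE)
}

#' Write a spatial weights matrix as dense CSV
#'
#' First column holds the region labels; remaining columns are the weights in
#' region order.
#'
#' @param W a `spatial_weights` object.
#' @param path output CSV path.
#' @export
write_weights_csv <- function(W, path) {
  stopifnot(inherits(W, "spatial_weights"))
  df <- data.frame(region = W$region_order, W$W, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
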