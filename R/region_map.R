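#' Region map: labelled regions, adjacency edges and a regional grouping
#'
#' A `region_map` records the spatial skeleton of a study: an ordered set of
#' region labels, an undirected adjacency edge list (regions sharing a border),
#' and a grouping of regions into macro-regions (e.g. east / central / west).
#'
#' @param region_ids character vector of unique region labels; the order is
#'   kept and used everywhere downstream.
#' @param edges two-column data.frame or matrix of region-id pairs; undirected,
#'   no self-loops.
#' @param groups named character vector mapping every region id to a group
#'   label, or `NULL` for a single group `"all"`.
#' @return An object of class `region_map` with elements `region_ids`,
#'   `edges` (data.frame with columns `from`, `to`) and `groups`.
#' @export
region_map <- function(region_ids, edges, groups = NULL) {
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids)) stop_gc("duplicate region ids")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop_gc("edges must have two columns")
  edges <- data.frame(from = as.character(edges[[1L]]),
                      to   = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  unknown <- setdiff(c(edges$from, edges$to), region_ids)
  if (length(unknown)) {
    stop_gc("edge endpoint(s) not in region set: %s",
            paste(unknown, collapse = ", "))
  }
  if (any(edges$from == edges$to)) stop_gc("self-loop edges are not allowed")
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(region_ids)), region_ids)
  }
  if (!setequal(names(groups), region_ids)) {
    stop_gc("groups must assign exactly one group to every region")
  }
  structure(list(region_ids = region_ids,
                 edges = edges,
                 groups = groups[region_ids]),
            class = "region_map")
}

#' Rook-adjacency lattice region map
#'
#' Builds a `rows` x `cols` grid of regions with rook (edge-sharing)
#' adjacency, a stand-in for province contiguity when no real border data are
#' used. Regions are labelled row-major (`R01`, `R02`, ...) and grouped into
#' east / central / west bands by column, mimicking the coast-to-interior
#' gradient of a national panel.
#'
#' @param rows,cols grid dimensions; `rows * cols >= 4`.
#' @param group_split fractions of columns assigned to the east, central and
#'   west bands, in order; must sum to 1.
#' @return A [region_map()].
#' @examples
#' m <- make_lattice_map(5, 6)
#' length(m$region_ids)  # 30
#' nrow(m$edges)         # 49 rook edges
#' @export
make_lattice_map <- function(rows, cols, group_split = c(east = 1/3, central = 1/3, west = 1/3)) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L || rows * cols < 4L) {
    stop_gc("degenerate grid: need rows*cols >= 4 (got %dx%d)", rows, cols)
  }
  if (abs(sum(group_split) - 1) > 1e-8) stop_gc("group_split fractions must sum to 1")
  if (length(group_split) != 3L) stop_gc("group_split must give three fractions")
  n <- rows * cols
  ids <- sprintf("R%02d", seq_len(n))
  idx <- function(r, c) (r - 1L) * cols + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) { from <- c(from, idx(r, c)); to <- c(to, idx(r, c + 1L)) }
      if (r < rows) { from <- c(from, idx(r, c)); to <- c(to, idx(r + 1L, c)) }
    }
  }
  grp_names <- names(group_split) %||% c("east", "central", "west")
  cuts <- round(cumsum(group_split) * cols)
  col_group <- character(cols)
  prev <- 0
  for (g in seq_along(cuts)) {
    take <- seq_len(cols) > prev & seq_len(cols) <= cuts[g]
    col_group[take] <- grp_names[g]
    prev <- cuts[g]
  }
  col_group[col_group == ""] <- grp_names[length(grp_names)]
  groups <- stats::setNames(
    col_group[((seq_len(n) - 1L) %% cols) + 1L], ids)
  region_map(ids, data.frame(from = ids[from], to = ids[to]), groups)
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map: %d regions, %d edges, groups: %s\n",
              length(x$region_ids), nrow(x$edges),
              paste(sprintf("%s (%d)", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}
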