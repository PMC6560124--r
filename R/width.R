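# Sulcal width: for each vertex of the boundary edge loop, find the nearest
# loop vertex that is not a loop neighbour (candidate on the opposite bank),
# refine by walking up to walk_steps positions along the loop, and take the
# median of the resulting bridge distances.

#' Options controlling the width estimator
#'
#' @param walk_steps Maximum number of loop positions the refinement walk
#'   moves away from the initially nearest vertex, in each direction
#'   (default 4, i.e. up to 9 candidates are examined per source vertex).
#' @param exclusion_window Number of cyclic loop positions on each side of a
#'   source vertex excluded from its nearest-vertex search (default 5).
#'   "Not neighbouring in the loop" is formalised as this window; choose it
#'   so that `exclusion_window * mesh spacing` exceeds the widest sulcus you
#'   expect, otherwise the nearest admissible candidate can lie on the same
#'   bank.
#' @param min_loop_size Minimum loop length worth estimating; shorter loops
#'   yield a width failure.  Default `2 * exclusion_window + 2`.
#' @return A list of class `width_options`.
#' @export
width_options <- function(walk_steps = 4L, exclusion_window = 5L,
                          min_loop_size = 2L * exclusion_window + 2L) {
  walk_steps <- as.integer(walk_steps)
  exclusion_window <- as.integer(exclusion_window)
  min_loop_size <- as.integer(min_loop_size)
  stopifnot(walk_steps >= 0L, exclusion_window >= 1L, min_loop_size >= 3L)
  structure(list(walk_steps = walk_steps,
                 exclusion_window = exclusion_window,
                 min_loop_size = min_loop_size),
            class = "width_options")
}

# cyclic distance between loop positions i and j on a loop of length n
cyclic_dist <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

# distances from loop position i to every loop position (coords: n x 3)
dist_from <- function(coords, i) {
  d <- coords - matrix(coords[i, ], nrow(coords), 3L, byrow = TRUE)
  sqrt(rowSums(d * d))
}

#' Nearest admissible loop vertex on the opposite bank
#'
#' Returns the loop position minimising the Euclidean distance to position
#' `i` over all positions whose cyclic loop-distance from `i` exceeds the
#' exclusion window.  Ties are broken toward the smaller cyclic
#' loop-distance, then the smaller vertex index.
#'
#' @param loop A `sulc_loop` from [get_edge_loop()].
#' @param mesh The parent [fs_surface()].
#' @param i Loop position (1-based).
#' @param opts A [width_options()].
#' @return Loop position (1-based), or `NA_integer_` if no admissible
#'   candidate exists.
#' @export
nearest_opposite_vertex <- function(loop, mesh, i, opts = width_options()) {
  coords <- mesh$vertices[as.integer(loop), , drop = FALSE]
  n <- nrow(coords)
  cd <- cyclic_dist(i, seq_len(n), n)
  cand <- which(cd > opts$exclusion_window)
  if (length(cand) == 0L) return(NA_integer_)
  d <- dist_from(coords, i)[cand]
  ord <- order(d, cd[cand], as.integer(loop)[cand])
  cand[ord[1L]]
}

#' Refine a bridge match by walking along the loop
#'
#' Examines every loop position within `walk_steps` cyclic steps of the
#' initial match `j0` (both directions, still excluding the window around
#' `i`) and returns the position minimising the distance to vertex `i`.
#' With `walk_steps = 0` this is the identity.
#'
#' @inheritParams nearest_opposite_vertex
#' @param j0 Initial match position from [nearest_opposite_vertex()].
#' @return List with `position` and `distance` (mm).
#' @export
walk_refine <- function(loop, mesh, i, j0, opts = width_options()) {
  coords <- mesh$vertices[as.integer(loop), , drop = FALSE]
  n <- nrow(coords)
  steps <- -opts$walk_steps:opts$walk_steps
  cand <- unique(((j0 - 1L + steps) %% n) + 1L)
  cd <- cyclic_dist(i, cand, n)
  cand <- cand[cd > opts$exclusion_window]
  d <- dist_from(coords, i)[cand]
  ord <- order(d, cyclic_dist(i, cand, n), as.integer(loop)[cand])
  list(position = cand[ord[1L]], distance = d[ord[1L]])
}

#' Estimate sulcal width from a boundary edge loop
#'
#' Every loop vertex contributes one bridge: the distance to its refined
#' nearest-opposite match.  The sulcal width is the median of these bridge
#' distances (even count: mean of the two central values).  Robustness to
#' the short-end bridges at the sulcus extremities is delegated entirely to
#' the median.
#'
#' @param region The `sulc_region` the loop belongs to.
#' @param loop A `sulc_loop`, or a `sulc_loop_failure` (propagated).
#' @param opts A [width_options()].
#' @return A list of class `sulc_width`: `width` (mm), `bridges` (tibble
#'   with one row per loop vertex: `position`, `vertex`, `matched_position`,
#'   `matched_vertex`, `distance`), `n_bridges`; or a `sulc_measure_failure`
#'   when the loop failed or is shorter than `min_loop_size`.
#' @export
compute_width <- function(region, loop, opts = width_options()) {
  if (is_loop_failure(loop)) {
    return(measure_failure("width", loop$reason, region$label_name))
  }
  stopifnot(inherits(loop, "sulc_loop"))
  n <- length(loop)
  if (n < opts$min_loop_size) {
    return(measure_failure("width", "loop-too-short", region$label_name,
                           loop_size = n))
  }
  mesh <- region$mesh
  ids <- as.integer(loop)
  coords <- mesh$vertices[ids, , drop = FALSE]
  pos <- seq_len(n)
  matched <- integer(n)
  dist <- numeric(n)
  for (i in pos) {
    j0 <- nearest_opposite_vertex(loop, mesh, i, opts)
    if (is.na(j0)) {
      return(measure_failure("width", "no-admissible-candidates",
                             region$label_name, loop_size = n))
    }
    w <- walk_refine(loop, mesh, i, j0, opts)
    matched[i] <- w$position
    dist[i] <- w$distance
  }
  bridges <- tibble::tibble(
    position = pos, vertex = ids,
    matched_position = matched, matched_vertex = ids[matched],
    distance = dist)
  structure(list(width = stats::median(dist),
                 bridges = bridges,
                 n_bridges = n,
                 label_name = region$label_name),
            class = "sulc_width")
}

measure_failure <- function(metric, reason, label_name, ...) {
  structure(list(metric = metric, reason = reason,
                 label_name = label_name, ...),
            class = "sulc_measure_failure")
}

#' Test whether a measurement failed
#' @param x Result of [compute_width()] or [compute_depth()].
#' @return `TRUE` for a `sulc_measure_failure`.
#' @export
is_measure_failure <- function(x) inherits(x, "sulc_measure_failure")

#' @export
print.sulc_width <- function(x, ...) {
  cat(sprintf("<sulc_width '%s': %.3f mm over %d bridges>\n",
              x$label_name, x$width, x$n_bridges))
  invisible(x)
}

#' @export
print.sulc_measure_failure <- function(x, ...) {
  cat(sprintf("<sulc_measure_failure '%s' (%s): %s>\n",
              x$label_name, x$metric, x$reason))
  invisible(x)
}
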