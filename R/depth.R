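# Sulcal depth: the fundus is the n_fundus region vertices most extreme in
# the sulcal map; depth is the median Euclidean distance from those vertices
# to the smoothed enclosing (outer) surface.  Straight-line distance
# underestimates the true along-wall depth of curved sulci by construction.

#' Options controlling the depth estimator
#'
#' @param n_fundus Number of deepest vertices defining the fundus
#'   (default 100); regions with fewer vertices use all of them and flag the
#'   shortfall.
#' @param fundus_direction Which extreme of the sulcal map marks the fundus:
#'   `"low"` (default; fundus carries the lowest overlay values) or
#'   `"high"` for toolchains with the opposite sign convention.
#' @param distance_mode `"point-to-triangle"` (default; exact distance to
#'   the outer mesh's triangles) or `"point-to-vertex"` (distance to its
#'   vertices only, always an overestimate, kept for comparison).
#' @return A list of class `depth_options`.
#' @export
depth_options <- function(n_fundus = 100L,
                          fundus_direction = c("low", "high"),
                          distance_mode = c("point-to-triangle",
                                            "point-to-vertex")) {
  n_fundus <- as.integer(n_fundus)
  stopifnot(n_fundus >= 1L)
  structure(list(n_fundus = n_fundus,
                 fundus_direction = match.arg(fundus_direction),
                 distance_mode = match.arg(distance_mode)),
            class = "depth_options")
}

#' Select the fundus vertices of a sulcus region
#'
#' Picks the `n_fundus` region vertices most extreme in the sulcal map
#' (lowest values by default).  Ties at the cutoff are broken toward the
#' smaller vertex index.  A region smaller than `n_fundus` contributes all
#' its vertices, with `shortfall = TRUE`.
#'
#' @param region A `sulc_region`.
#' @param sulcmap Numeric per-vertex overlay for the parent mesh (from
#'   [read_overlay()]).
#' @param opts A [depth_options()].
#' @return Tibble with columns `vertex` and `value`, plus attribute
#'   `shortfall`.
#' @export
select_fundus <- function(region, sulcmap, opts = depth_options()) {
  stopifnot(inherits(region, "sulc_region"))
  if (region$absent) {
    stop("cannot select a fundus in an empty region", call. = FALSE)
  }
  if (length(sulcmap) != nrow(region$mesh$vertices)) {
    stop("overlay length does not match the parent mesh", call. = FALSE)
  }
  ids <- region$vertex_ids
  vals <- sulcmap[ids]
  key <- if (opts$fundus_direction == "low") vals else -vals
  ord <- order(key, ids)
  n_take <- min(opts$n_fundus, length(ids))
  sel <- ord[seq_len(n_take)]
  out <- tibble::tibble(vertex = ids[sel], value = vals[sel])
  attr(out, "shortfall") <- n_take < opts$n_fundus
  out
}

#' Exact distances from points to a triangle mesh
#'
#' Minimum Euclidean distance from each query point to the surface, taking
#' the exact point-to-triangle distance over all faces (interior projection,
#' edge, or vertex case), or the vertex-only distance in
#' `"point-to-vertex"` mode.  Point-to-triangle distance is never larger
#' than point-to-vertex distance.
#'
#' @param points Numeric k x 3 matrix (or length-3 vector) of query points (mm).
#' @param outer An [fs_surface()], typically `?h.pial-outer-smoothed`.
#' @param opts A [depth_options()] (only `distance_mode` is used).
#' @return Numeric vector of k distances (mm).
#' @export
point_to_surface_distance <- function(points, outer, opts = depth_options()) {
  stopifnot(inherits(outer, "fs_surface"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  if (opts$distance_mode == "point-to-vertex") {
    v <- outer$vertices
    return(vapply(seq_len(nrow(points)), function(k) {
      d <- v - matrix(points[k, ], nrow(v), 3L, byrow = TRUE)
      sqrt(min(rowSums(d * d)))
    }, numeric(1L)))
  }
  dist_points_to_triangles(points, outer$vertices, outer$faces)
}

# Exact point-to-triangle distance, vectorised over all triangles per query
# point (Ericson's region classification of the barycentric projection).
dist_points_to_triangles <- function(points, vertices, faces) {
  A <- vertices[faces[, 1L], , drop = FALSE]
  B <- vertices[faces[, 2L], , drop = FALSE]
  C <- vertices[faces[, 3L], , drop = FALSE]
  ab <- B - A; ac <- C - A
  m <- nrow(faces)
  out <- numeric(nrow(points))
  for (k in seq_len(nrow(points))) {
    p <- matrix(points[k, ], m, 3L, byrow = TRUE)
    ap <- p - A
    d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
    bp <- p - B
    d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
    cp <- p - C
    d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

    close <- matrix(NA_real_, m, 3L)
    done <- rep(FALSE, m)

    take <- function(mask, pts) {
      mask <- mask & !done
      close[mask, ] <<- pts[mask, , drop = FALSE]
      done <<- done | mask
    }
    take(d1 <= 0 & d2 <= 0, A)                                   # vertex A
    take(d3 >= 0 & d4 <= d3, B)                                  # vertex B
    take(d6 >= 0 & d5 <= d6, C)                                  # vertex C
    vc <- d1 * d4 - d3 * d2
    vv <- d1 / (d1 - d3)
    take(vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * vv)               # edge AB
    vb <- d5 * d2 - d1 * d6
    ww <- d2 / (d2 - d6)
    take(vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * ww)               # edge AC
    va <- d3 * d6 - d5 * d4
    wbc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
         B + (C - B) * wbc)                                      # edge BC
    denom <- va + vb + vc
    vin <- vb / denom; win <- vc / denom
    take(!done, A + ab * vin + ac * win)                         # interior

    dd <- close - p
    # na.rm guards geometrically degenerate (zero-area) triangles
    out[k] <- sqrt(min(rowSums(dd * dd), na.rm = TRUE))
  }
  out
}

#' Estimate sulcal depth
#'
#' Depth is the median of the fundus vertices' Euclidean distances to the
#' smoothed enclosing surface.  As a guard against a silently inverted
#' overlay sign convention, the selected fundus set is checked to lie
#' farther (on average) from the outer surface than a sample of the
#' region's remaining vertices; a warning is raised otherwise.
#'
#' @param region A `sulc_region`.
#' @param sulcmap Per-vertex overlay for the parent mesh.
#' @param outer The outer smoothed surface, an [fs_surface()].
#' @param opts A [depth_options()].
#' @return A list of class `sulc_depth`: `depth` (mm), `fundus` (tibble
#'   `vertex`, `value`, `distance`), `n_fundus`, `shortfall`; or a
#'   `sulc_measure_failure` for an empty region.
#' @export
compute_depth <- function(region, sulcmap, outer, opts = depth_options()) {
  stopifnot(inherits(region, "sulc_region"))
  if (region$absent) {
    return(measure_failure("depth", "label-absent", region$label_name))
  }
  fundus <- select_fundus(region, sulcmap, opts)
  pts <- region$mesh$vertices[fundus$vertex, , drop = FALSE]
  d <- point_to_surface_distance(pts, outer, opts)
  fundus$distance <- d

  rest <- setdiff(region$vertex_ids, fundus$vertex)
  if (length(rest) > 0L) {
    if (length(rest) > 200L) {
      rest <- rest[round(seq(1L, length(rest), length.out = 200L))]
    }
    d_rest <- point_to_surface_distance(
      region$mesh$vertices[rest, , drop = FALSE], outer, opts)
    if (mean(d) <= mean(d_rest)) {
      warning(sprintf(
        paste0("fundus of '%s' is not farther from the outer surface than ",
               "the rest of the region; check the overlay sign convention ",
               "(fundus_direction)"), region$label_name), call. = FALSE)
    }
  }
  structure(list(depth = stats::median(d),
                 fundus = fundus,
                 n_fundus = nrow(fundus),
                 shortfall = isTRUE(attr(fundus, "shortfall")),
                 label_name = region$label_name),
            class = "sulc_depth")
}

#' @export
print.sulc_depth <- function(x, ...) {
  cat(sprintf("<sulc_depth '%s': %.3f mm over %d fundus vertices%s>\n",
              x$label_name, x$depth, x$n_fundus,
              if (x$shortfall) " (shortfall)" else ""))
  invisible(x)
}
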