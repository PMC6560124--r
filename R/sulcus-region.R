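# Isolating one labelled sulcus as a submesh and extracting its boundary
# edge loop.  Failure to produce a single closed loop is a *value* (class
# sulc_loop_failure), never an error: the cohort pipeline counts failures.

#' Names of the sulci supported for measurement
#'
#' The eight Destrieux-atlas sulci for which width/depth estimation is
#' validated, plus (optionally) the experimental set — superior and inferior
#' temporal and intraparietal sulci — whose parcellations frequently split
#' into discontinuous patches and therefore fail edge-loop extraction at an
#' unacceptable rate.
#'
#' @param experimental If `TRUE`, append the experimental sulci.
#' @return A tibble with columns `name` (FreeSurfer v6.0 Destrieux label),
#'   `description`, and `status` (`"supported"` or `"experimental"`).
#' @export
supported_sulci <- function(experimental = FALSE) {
  core <- tibble::tibble(
    name = c("S_central", "S_postcentral", "S_front_sup", "S_front_inf",
             "S_parieto_occipital", "S_oc-temp_med&Lingual",
             "S_oc_middle&Lunatus", "S_cingul-Marginalis"),
    description = c("central", "post-central", "superior frontal",
                    "inferior frontal", "parieto-occipital",
                    "occipito-temporal", "middle occipital and lunate",
                    "marginal part of the cingulate"),
    status = "supported")
  if (!experimental) return(core)
  extra <- tibble::tibble(
    name = c("S_temporal_sup", "S_temporal_inf", "S_intrapariet&P_trans"),
    description = c("superior temporal", "inferior temporal", "intraparietal"),
    status = "experimental")
  dplyr::bind_rows(core, extra)
}

#' Isolate one labelled sulcus as a submesh
#'
#' A face belongs to the sulcus when all three of its vertices carry the
#' target label (the conservative membership rule: the resulting region
#' boundary lies between labels).  A label that exists in the annotation
#' table but covers no faces yields an empty region flagged `absent`, not an
#' error.
#'
#' @param mesh An [fs_surface()].
#' @param annot An [fs_annotation()] with one label per mesh vertex.
#' @param label_name Destrieux name, e.g. `"S_central"`.
#' @return A `sulc_region`: list with `mesh`, `face_ids` (parent face
#'   indices), `vertex_ids` (sorted parent vertex indices used by those
#'   faces), `label_name`, `absent` flag.
#' @export
isolate_sulcus <- function(mesh, annot, label_name) {
  stopifnot(inherits(mesh, "fs_surface"), inherits(annot, "fs_annotation"))
  if (length(annot$labels) != nrow(mesh$vertices)) {
    stop("annotation and mesh vertex counts differ", call. = FALSE)
  }
  hit <- annot$table$name == label_name
  if (!any(hit)) {
    stop(sprintf("unknown sulcus label '%s'; available: %s", label_name,
                 paste(annot$table$name, collapse = ", ")), call. = FALSE)
  }
  code <- annot$table$code[hit][1L]
  on_label <- annot$labels == code
  f <- mesh$faces
  member <- on_label[f[, 1L]] & on_label[f[, 2L]] & on_label[f[, 3L]]
  face_ids <- which(member)
  structure(list(mesh = mesh,
                 face_ids = face_ids,
                 vertex_ids = sort(unique(as.integer(f[face_ids, ]))),
                 label_name = label_name,
                 absent = length(face_ids) == 0L),
            class = "sulc_region")
}

#' @export
print.sulc_region <- function(x, ...) {
  cat(sprintf("<sulc_region '%s': %d faces, %d vertices%s>\n", x$label_name,
              length(x$face_ids), length(x$vertex_ids),
              if (x$absent) " (absent)" else ""))
  invisible(x)
}

# sorted undirected edge list (m*3 x 2) for a set of faces
region_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

#' Boundary edges of a sulcus region
#'
#' The region boundary is the set of mesh edges incident to exactly one face
#' of the region.  This brute-force definition is the reference against
#' which loop extraction is validated.
#'
#' @param region A `sulc_region` from [isolate_sulcus()].
#' @return Integer k x 2 matrix of vertex-index pairs (each row sorted).
#' @export
boundary_edges <- function(region) {
  stopifnot(inherits(region, "sulc_region"))
  if (region$absent) stop("region is empty (label absent on surface)", call. = FALSE)
  e <- region_edges(region$mesh$faces[region$face_ids, , drop = FALSE])
  key <- paste(e[, 1L], e[, 2L])
  tab <- table(key)
  single <- names(tab)[tab == 1L]
  e[match(single, key), , drop = FALSE]
}

#' Edge-connected components of a sulcus region
#'
#' Two faces are connected when they share an edge (sharing only a vertex
#' does not connect them).  Parcellations split into several patches show up
#' here as `n_components > 1` and cannot yield a single boundary loop.
#'
#' @param region A `sulc_region`.
#' @return List with `n_components` and `component` (one id per region face,
#'   parallel to `region$face_ids`).
#' @export
connected_components <- function(region) {
  stopifnot(inherits(region, "sulc_region"))
  if (region$absent) stop("region is empty (label absent on surface)", call. = FALSE)
  nf <- length(region$face_ids)
  e <- region_edges(region$mesh$faces[region$face_ids, , drop = FALSE])
  key <- paste(e[, 1L], e[, 2L])
  face_of_edge <- rep(seq_len(nf), 3L)
  # pair up the faces sharing each interior edge
  ord <- order(key)
  key_s <- key[ord]; face_s <- face_of_edge[ord]
  same <- which(key_s[-1L] == key_s[-length(key_s)])
  g <- igraph::make_graph(rbind(face_s[same], face_s[same + 1L]),
                          n = nf, directed = FALSE)
  comp <- igraph::components(g)
  list(n_components = as.integer(comp$no),
       component = as.integer(comp$membership[seq_len(nf)]))
}

#' Extract the closed boundary edge loop of a sulcus region
#'
#' Chains the region's boundary edges into a single contiguous cyclic loop
#' of vertices — the mid-level contour between the sulcus and its adjacent
#' gyri that the width estimator bridges across.  Chaining starts at the
#' smallest boundary vertex index and prefers the smaller-index neighbour,
#' so the result is deterministic.
#'
#' Failure is returned as a value of class `sulc_loop_failure` with a
#' machine-readable `reason`:
#' \describe{
#'   \item{`discontinuous-region`}{the label comprises two or more
#'     edge-disconnected patches;}
#'   \item{`non-manifold-boundary`}{some boundary vertex touches more than
#'     two boundary edges (pinch point);}
#'   \item{`multiple-loops`}{the boundary splits into several closed loops
#'     (e.g. an annular region).}
#' }
#'
#' @param region A `sulc_region`.
#' @return A `sulc_loop` (integer vector of parent vertex indices in cyclic
#'   order, with attributes) or a `sulc_loop_failure`.
#' @export
get_edge_loop <- function(region) {
  stopifnot(inherits(region, "sulc_region"))
  if (region$absent) {
    return(loop_failure("label-absent", region$label_name))
  }
  cc <- connected_components(region)
  if (cc$n_components > 1L) {
    return(loop_failure("discontinuous-region", region$label_name,
                        n_components = cc$n_components))
  }
  be <- boundary_edges(region)
  if (nrow(be) < 3L) {
    return(loop_failure("non-manifold-boundary", region$label_name))
  }
  verts <- sort(unique(as.integer(be)))
  deg <- tabulate(match(as.integer(be), verts), nbins = length(verts))
  if (any(deg != 2L)) {
    return(loop_failure("non-manifold-boundary", region$label_name,
                        bad_vertices = verts[deg != 2L]))
  }
  # adjacency: each boundary vertex has exactly two boundary neighbours
  idx <- match(as.integer(be), verts)
  m1 <- matrix(idx, ncol = 2L)
  nbr <- matrix(NA_integer_, length(verts), 2L)
  slot <- integer(length(verts))
  for (r in seq_len(nrow(m1))) {
    a <- m1[r, 1L]; b <- m1[r, 2L]
    slot[a] <- slot[a] + 1L; nbr[a, slot[a]] <- b
    slot[b] <- slot[b] + 1L; nbr[b, slot[b]] <- a
  }
  start <- 1L  # verts is sorted, so verts[1] is the smallest vertex index
  loop_local <- integer(length(verts))
  loop_local[1L] <- start
  prev <- 0L; cur <- start
  for (k in seq_len(length(verts) - 1L)) {
    nxt <- nbr[cur, ]
    nxt <- nxt[nxt != prev]
    if (length(nxt) > 1L) nxt <- min(nxt)  # first step: prefer smaller index
    loop_local[k + 1L] <- nxt
    prev <- cur; cur <- nxt
  }
  # closedness: the walk must return to start and consume every vertex once
  last_nbrs <- nbr[cur, ]
  closed <- start %in% last_nbrs
  if (!closed || anyDuplicated(loop_local) > 0L) {
    return(loop_failure("multiple-loops", region$label_name))
  }
  structure(verts[loop_local],
            class = "sulc_loop",
            label_name = region$label_name)
}

loop_failure <- function(reason, label_name, ...) {
  structure(list(reason = reason, label_name = label_name, ...),
            class = "sulc_loop_failure")
}

#' Test whether a loop extraction failed
#' @param x Result of [get_edge_loop()].
#' @return `TRUE` for a `sulc_loop_failure`.
#' @export
is_loop_failure <- function(x) inherits(x, "sulc_loop_failure")

#' @export
print.sulc_loop <- function(x, ...) {
  cat(sprintf("<sulc_loop '%s': %d vertices>\n",
              attr(x, "label_name"), length(x)))
  invisible(x)
}

#' @export
print.sulc_loop_failure <- function(x, ...) {
  cat(sprintf("<sulc_loop_failure '%s': %s>\n", x$label_name, x$reason))
  invisible(x)
}
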