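# Shared fixtures and independent oracles.  Oracles are deliberately naive
# (explicit loops, separate formulations) so they stay independent of the
# implementation paths they check.

# n x n flat unit-spacing grid plate at z = 0
grid_plate <- function(n, z = 0) {
  xs <- seq(0, n - 1)
  v <- cbind(rep(xs, each = n), rep(xs, n), z)
  vid <- function(ix, iy) (ix - 1L) * n + iy
  ix <- rep(seq_len(n - 1L), each = n - 1L)
  iy <- rep(seq_len(n - 1L), n - 1L)
  f <- rbind(cbind(vid(ix, iy), vid(ix + 1L, iy), vid(ix + 1L, iy + 1L)),
             cbind(vid(ix, iy), vid(ix + 1L, iy + 1L), vid(ix, iy + 1L)))
  list(surf = fs_surface(v, f), n = n, vid = vid)
}

# build a sulc_region directly from a face subset (bypasses annotation)
region_from_faces <- function(surf, face_ids, label_name = "S_central") {
  structure(list(mesh = surf, face_ids = as.integer(face_ids),
                 vertex_ids = sort(unique(as.integer(
                   surf$faces[face_ids, , drop = FALSE]))),
                 label_name = label_name,
                 absent = length(face_ids) == 0L),
            class = "sulc_region")
}

# annotation labelling exactly the given vertices with label_name
annot_for <- function(surf, labelled_vertices, label_name = "S_central") {
  tab <- annot_table(c("Unknown", label_name))
  labels <- rep(0L, nrow(surf$vertices))
  labels[labelled_vertices] <- tab$code[2L]
  fs_annotation(labels, tab)
}

# canonical sortable representation of an undirected edge set
edge_key <- function(e) {
  k <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  sort(k)
}

# edges of a cyclic vertex loop
loop_edges <- function(loop) {
  v <- as.integer(loop)
  cbind(v, c(v[-1L], v[1L]))
}

# --- width oracle: naive double-loop over the definition ------------------
# For loop position i: initial match = Euclidean-nearest position whose
# cyclic distance exceeds `window` (ties: smaller cyclic distance, then
# smaller vertex id); final match = nearest among positions within `walk`
# cyclic steps of the initial match, still outside the window.
brute_force_bridges <- function(coords, ids, window, walk) {
  n <- nrow(coords)
  cyc <- function(a, b) min(abs(a - b), n - abs(a - b))
  out <- numeric(n)
  for (i in seq_len(n)) {
    best_j <- NA; best <- c(Inf, Inf, Inf)
    for (j in seq_len(n)) {
      if (cyc(i, j) <= window) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      key <- c(d, cyc(i, j), ids[j])
      if (is.na(best_j) ||
          (key[1] < best[1]) ||
          (key[1] == best[1] && key[2] < best[2]) ||
          (key[1] == best[1] && key[2] == best[2] && key[3] < best[3])) {
        best <- key; best_j <- j
      }
    }
    if (is.na(best_j)) return(NULL)
    refined <- c(Inf, Inf, Inf); got <- FALSE
    for (j in seq_len(n)) {
      along <- min(abs(j - best_j), n - abs(j - best_j))
      if (along > walk) next
      if (cyc(i, j) <= window) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      key <- c(d, cyc(i, j), ids[j])
      if (!got ||
          (key[1] < refined[1]) ||
          (key[1] == refined[1] && key[2] < refined[2]) ||
          (key[1] == refined[1] && key[2] == refined[2] &&
             key[3] < refined[3])) {
        refined <- key; got <- TRUE
      }
    }
    out[i] <- refined[1]
  }
  out
}

# wrap a bare coordinate loop as a mesh + region + loop for compute_width
loop_fixture <- function(coords) {
  n <- nrow(coords)
  # any valid mesh containing these vertices will do; faces are unused by
  # the width computation itself
  faces <- cbind(seq_len(n), (seq_len(n) %% n) + 1L,
                 ((seq_len(n) + 1L) %% n) + 1L)
  faces <- faces[faces[, 1] != faces[, 3] & faces[, 2] != faces[, 3], ,
                 drop = FALSE]
  surf <- fs_surface(coords, faces[1:max(1, nrow(faces)), , drop = FALSE])
  loop <- structure(seq_len(n), class = "sulc_loop", label_name = "fixture")
  region <- region_from_faces(surf, 1L, "fixture")
  list(surf = surf, region = region, loop = loop)
}

# --- point-to-triangle oracle: constrained projection, per face -----------
# Independent formulation: unconstrained barycentric solve via the normal
# equations, then candidate set = {interior solution if feasible, the three
# clamped edge projections, the three vertices}.
pt_tri_oracle_one <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    w <- v - u
    t <- sum((p - u) * w) / sum(w * w)
    t <- min(1, max(0, t))
    sqrt(sum((p - (u + t * w))^2))
  }
  cand <- c(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, a, c),
            sqrt(sum((p - a)^2)), sqrt(sum((p - b)^2)), sqrt(sum((p - c)^2)))
  e1 <- b - a; e2 <- c - a
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- c(sum(e1 * (p - a)), sum(e2 * (p - a)))
  if (abs(det(G)) > 1e-14) {
    st <- solve(G, rhs)
    if (st[1] >= 0 && st[2] >= 0 && st[1] + st[2] <= 1) {
      cand <- c(cand, sqrt(sum((p - (a + st[1] * e1 + st[2] * e2))^2)))
    }
  }
  min(cand)
}

pt_mesh_oracle <- function(p, surf) {
  d <- Inf
  for (r in seq_len(nrow(surf$faces))) {
    f <- surf$faces[r, ]
    d <- min(d, pt_tri_oracle_one(p, surf$vertices[f[1], ],
                                  surf$vertices[f[2], ],
                                  surf$vertices[f[3], ]))
  }
  d
}

# --- one-way ANOVA identity, computed directly ----------------------------
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  subj_means <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((m - subj_means)^2) / (n * (k - 1))
  list(msb = msb, msw = msw,
       icc = (msb - msw) / (msb + (k - 1) * msw))
}

# random rectangular label patch (optionally with a hole or a second patch)
# on a grid plate; returns a sulc_region
random_patch_region <- function(seed) {
  set.seed(seed)
  g <- grid_plate(12L)
  x0 <- sample(1:4, 1); x1 <- sample(7:11, 1)
  y0 <- sample(1:4, 1); y1 <- sample(7:11, 1)
  lab <- rep(FALSE, 12L * 12L)
  for (ix in x0:x1) for (iy in y0:y1) lab[g$vid(ix, iy)] <- TRUE
  style <- sample(c("solid", "hole", "two"), 1)
  if (style == "hole" && x1 - x0 >= 4 && y1 - y0 >= 4) {
    for (ix in (x0 + 2):(x1 - 2)) for (iy in (y0 + 2):(y1 - 2)) {
      lab[g$vid(ix, iy)] <- FALSE
    }
  }
  if (style == "two") {
    lab[] <- FALSE
    for (ix in x0:min(x0 + 2, 11)) for (iy in y0:min(y0 + 2, 11)) {
      lab[g$vid(ix, iy)] <- TRUE
    }
    for (ix in max(x1 - 1, 1):x1) for (iy in max(y1 - 1, 1):y1) {
      lab[g$vid(ix, iy)] <- TRUE
    }
  }
  f <- g$surf$faces
  member <- lab[f[, 1]] & lab[f[, 2]] & lab[f[, 3]]
  region_from_faces(g$surf, which(member))
}

# 3-vector cross product
crossprod_3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
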