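# Synthetic FreeSurfer subjects with analytically known sulcal geometry.
#
# A subject is a flat cortical "plate" carrying one U-shaped fold (a box
# canyon): two walls separated by true_width descending true_depth below the
# plate plane, joined by a floor.  The fold is embedded in a regular grid
# swept along the sulcus length, so the true width (rim separation), true
# depth (floor-to-plate distance) and the boundary edge loop are all exact.
# The outer smoothed surface is the plate's plane, exactly what the
# gyrification hull is for a single open fold.

#' Specification of one synthetic box-canyon sulcus
#'
#' @param true_width Rim-to-rim separation of the fold mouth (mm).
#' @param true_depth Along-wall depth of the fold (mm).  With
#'   `fundus_curvature = 0` the walls are straight and this equals the
#'   vertical floor-to-plate distance; with curvature it is the arc length
#'   of the curved wall (the geodesic fundus depth), which exceeds the
#'   vertical drop.
#' @param length Extent of the fold along the sulcus axis (mm).
#' @param mesh_spacing Target grid spacing (mm).
#' @param wall_tilt Outward tilt of straight walls, degrees from vertical
#'   (0 = parallel walls; ignored when `fundus_curvature > 0`).
#' @param fundus_curvature Curvature (1/mm) of the wall profile; positive
#'   values bend the trench into a hook so that the Euclidean depth to the
#'   plate underestimates the along-wall depth.  Must satisfy
#'   `fundus_curvature * true_depth < pi/2`.
#' @param noise_sd Standard deviation of i.i.d. Gaussian jitter added to
#'   every vertex coordinate (mm).  Labels are assigned by construction, so
#'   jitter never moves a vertex across the label boundary.
#' @param margin Flat plate margin on each side of the fold mouth (mm).
#' @param seed Integer seed making the subject deterministic.
#' @return A validated list of class `sulcus_spec`.
#' @export
sulcus_spec <- function(true_width = 3, true_depth = 10, length = 60,
                        mesh_spacing = 0.5, wall_tilt = 0,
                        fundus_curvature = 0, noise_sd = 0,
                        margin = 5, seed = 1L) {
  stopifnot(true_width > 0, true_depth > 0, length > 0, mesh_spacing > 0,
            noise_sd >= 0, margin > 0, fundus_curvature >= 0)
  if (fundus_curvature > 0 && fundus_curvature * true_depth >= pi / 2) {
    stop("fundus_curvature * true_depth must be < pi/2", call. = FALSE)
  }
  structure(list(true_width = true_width, true_depth = true_depth,
                 length = length, mesh_spacing = mesh_spacing,
                 wall_tilt = wall_tilt, fundus_curvature = fundus_curvature,
                 noise_sd = noise_sd, margin = margin,
                 seed = as.integer(seed)),
            class = "sulcus_spec")
}

# Cross-section profile of the folded plate: (x, z) sample points at
# ~spacing arclength steps — left plate, left wall down, floor, right wall
# up, right plate — plus the u-indices of the two rim points and the
# achieved vertical drop of the floor below the plate plane.
fold_profile <- function(spec) {
  h <- spec$mesh_spacing
  W <- spec$true_width
  seg <- function(from, to) {
    # straight segment sampled at ~h spacing, excluding the start point
    len <- sqrt(sum((to - from)^2))
    n <- max(1L, round(len / h))
    t <- seq_len(n) / n
    cbind(from[1] + t * (to[1] - from[1]), from[2] + t * (to[2] - from[2]))
  }
  # wall offsets from the rim, top (excluded) to bottom, at ~h arc steps
  n_wall <- max(2L, round(spec$true_depth / h))
  s <- seq_len(n_wall) / n_wall * spec$true_depth
  if (spec$fundus_curvature > 0) {
    # both walls follow the same circular arc (a leaning trench): wall
    # separation stays W everywhere, arc length = true_depth
    kap <- spec$fundus_curvature
    dxL <- (1 - cos(kap * s)) / kap
    dz <- -sin(kap * s) / kap
    dxR <- dxL
  } else {
    tilt <- spec$wall_tilt * pi / 180
    dxL <- -s * sin(tilt)          # left wall leans outward (-x)
    dz <- -s * cos(tilt)
    dxR <- -dxL                    # mirrored right wall
  }
  drop <- -dz[n_wall]
  left_edge <- c(-W / 2 - spec$margin, 0)
  rim_l <- c(-W / 2, 0)
  left_plate <- rbind(left_edge, seg(left_edge, rim_l))
  rim_l_idx <- nrow(left_plate)
  left_wall <- cbind(rim_l[1] + dxL, dz)
  bottom_l <- left_wall[n_wall, ]
  bottom_r <- c(W / 2 + dxR[n_wall], dz[n_wall])
  floor_pts <- seg(bottom_l, bottom_r)
  # right wall from just above its bottom point back up to the right rim
  up <- rev(seq_len(n_wall - 1L))
  right_wall <- rbind(cbind(W / 2 + dxR[up], dz[up]), c(W / 2, 0))
  pts <- rbind(left_plate, left_wall, floor_pts, right_wall)
  rim_r_idx <- nrow(pts)
  right_edge <- c(W / 2 + spec$margin, 0)
  pts <- rbind(pts, seg(c(W / 2, 0), right_edge))
  list(pts = pts, rim_l = rim_l_idx, rim_r = rim_r_idx, drop = drop)
}

# Build the full fold geometry: vertices, faces, per-vertex label flag,
# overlay values, ground-truth loop and face ids.
build_fold_geometry <- function(spec, label_name = "S_central",
                                sulc_sign = c("fundus-low", "fundus-high")) {
  sulc_sign <- match.arg(sulc_sign)
  prof <- fold_profile(spec)
  pts <- prof$pts
  nu <- nrow(pts)
  ny <- max(2L, round(spec$length / spec$mesh_spacing)) + 1L
  y <- seq(0, spec$length, length.out = ny)
  vid <- function(iu, iy) (iu - 1L) * ny + iy
  vertices <- cbind(rep(pts[, 1], each = ny),
                    rep(y, nu),
                    rep(pts[, 2], each = ny))
  # faces: two triangles per grid quad, consistent diagonal
  iu <- rep(seq_len(nu - 1L), each = ny - 1L)
  iy <- rep(seq_len(ny - 1L), nu - 1L)
  a <- vid(iu, iy); b <- vid(iu + 1L, iy)
  c2 <- vid(iu + 1L, iy + 1L); d <- vid(iu, iy + 1L)
  faces <- rbind(cbind(a, b, c2), cbind(a, c2, d))
  # faces are ordered: quad q = (iu, iy) owns rows q and q + nquad
  labelled_u <- seq(prof$rim_l, prof$rim_r)
  label_flag <- rep(FALSE, nu * ny)
  for (u in labelled_u) label_flag[vid(u, seq_len(ny))] <- TRUE
  quad_in <- iu >= prof$rim_l & (iu + 1L) <= prof$rim_r
  interior_faces <- c(which(quad_in), which(quad_in) + length(iu))
  # ground-truth boundary loop: perimeter of the labelled sub-grid, cyclic
  loop <- c(vid(prof$rim_l, seq_len(ny)),
            vid(seq(prof$rim_l + 1L, prof$rim_r), ny),
            vid(prof$rim_r, seq(ny - 1L, 1L)),
            vid(seq(prof$rim_r - 1L, prof$rim_l + 1L), 1L))
  overlay <- vertices[, 3]
  if (sulc_sign == "fundus-high") overlay <- -overlay
  if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed, {
      vertices <- vertices +
        matrix(stats::rnorm(length(vertices), 0, spec$noise_sd),
               ncol = 3L)
    })
  }
  ord_key <- if (sulc_sign == "fundus-high") -overlay else overlay
  deepest <- order(ord_key, seq_along(overlay))
  list(vertices = vertices, faces = faces, label_flag = label_flag,
       overlay = overlay, loop = as.integer(loop),
       interior_faces = sort(as.integer(interior_faces)),
       deepest = deepest, drop = prof$drop,
       geodesic_depth = spec$true_depth,
       label_name = label_name, sulc_sign = sulc_sign)
}

# outer smoothed surface: a coarse flat plate at z = 0 covering the fold's
# xy footprint with margin
build_outer_plate <- function(vertices, spacing) {
  xr <- range(vertices[, 1]) + c(-2, 2)
  yr <- range(vertices[, 2]) + c(-2, 2)
  xs <- seq(xr[1], xr[2], length.out = max(2L, ceiling(diff(xr) / spacing) + 1L))
  ys <- seq(yr[1], yr[2], length.out = max(2L, ceiling(diff(yr) / spacing) + 1L))
  nx <- length(xs); nyy <- length(ys)
  v <- cbind(rep(xs, each = nyy), rep(ys, nx), 0)
  vid <- function(ix, iy) (ix - 1L) * nyy + iy
  ix <- rep(seq_len(nx - 1L), each = nyy - 1L)
  iy <- rep(seq_len(nyy - 1L), nx - 1L)
  f <- rbind(cbind(vid(ix, iy), vid(ix + 1L, iy), vid(ix + 1L, iy + 1L)),
             cbind(vid(ix, iy), vid(ix + 1L, iy + 1L), vid(ix, iy + 1L)))
  fs_surface(v, f)
}

destrieux_subset_table <- function() {
  nms <- c("Unknown", supported_sulci(experimental = TRUE)$name)
  annot_table(nms)
}

#' Generate a synthetic box-canyon FreeSurfer subject
#'
#' Writes a complete single-hemisphere subject in FreeSurfer layout —
#' `surf/<hemi>.pial`, `surf/<hemi>.pial-outer-smoothed`,
#' `surf/<hemi>.sulc`, `label/<hemi>.aparc.a2009s.annot` — whose sulcal
#' geometry is known exactly, plus a `ground_truth.json` record.  The files
#' round-trip through the package's own readers and are valid FreeSurfer
#' binaries.  Deterministic given the spec's seed.
#'
#' @param spec A [sulcus_spec()].
#' @param subject_dir Directory to create (the subject directory).
#' @param hemi Hemisphere prefix, `"lh"` or `"rh"`.
#' @param label_name Destrieux name given to the fold (default
#'   `"S_central"`).
#' @param sulc_sign Overlay sign convention: `"fundus-low"` (default; the
#'   fundus carries the lowest overlay values) or `"fundus-high"`.
#' @return Invisibly, the ground-truth list: `true_width`, `true_depth`
#'   (vertical drop), `geodesic_depth`, `interior_faces`, `loop`,
#'   `deepest100`, `label_name`, `n_vertices`, plus the file paths.
#' @export
make_box_sulcus <- function(spec, subject_dir, hemi = "lh",
                            label_name = "S_central",
                            sulc_sign = c("fundus-low", "fundus-high")) {
  stopifnot(inherits(spec, "sulcus_spec"))
  sulc_sign <- match.arg(sulc_sign)
  geo <- build_fold_geometry(spec, label_name, sulc_sign)
  surf <- fs_surface(geo$vertices, geo$faces)
  tab <- destrieux_subset_table()
  code <- tab$code[tab$name == label_name]
  if (length(code) != 1L) {
    stop(sprintf("label '%s' is not in the synthetic annotation table",
                 label_name), call. = FALSE)
  }
  labels <- ifelse(geo$label_flag, code, tab$code[tab$name == "Unknown"])
  annot <- fs_annotation(labels, tab)
  outer <- build_outer_plate(geo$vertices, spacing = 4 * spec$mesh_spacing)

  dir.create(file.path(subject_dir, "surf"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(subject_dir, "label"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list(
    pial = file.path(subject_dir, "surf", paste0(hemi, ".pial")),
    outer = file.path(subject_dir, "surf",
                      paste0(hemi, ".pial-outer-smoothed")),
    sulc = file.path(subject_dir, "surf", paste0(hemi, ".sulc")),
    annot = file.path(subject_dir, "label",
                      paste0(hemi, ".aparc.a2009s.annot")))
  write_surface(surf, paths$pial)
  write_surface(outer, paths$outer)
  write_overlay(geo$overlay, paths$sulc, n_faces = nrow(geo$faces))
  write_annotation(annot, paths$annot)

  truth <- list(true_width = spec$true_width,
                true_depth = geo$drop,
                geodesic_depth = geo$geodesic_depth,
                label_name = label_name,
                hemi = hemi,
                n_vertices = nrow(geo$vertices),
                interior_faces = geo$interior_faces,
                loop = geo$loop,
                deepest100 = geo$deepest[seq_len(min(100L,
                                                     length(geo$deepest)))],
                sulc_sign = sulc_sign,
                spec = unclass(spec))
  jsonlite::write_json(truth, file.path(subject_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(truth, list(paths = paths)))
}

#' Generate the failure-mode test subjects
#'
#' Emits three subjects exercising the pipeline's failure semantics:
#' \describe{
#'   \item{`split_label`}{the target label covers two edge-disconnected
#'     patches (a second labelled patch on the flat plate), so loop
#'     extraction reports `discontinuous-region`;}
#'   \item{`annulus`}{the label forms a ring on the plate, one connected
#'     component with two boundary loops, so loop extraction reports
#'     `multiple-loops`;}
#'   \item{`undersized`}{a fold with fewer vertices than the default
#'     fundus size, so depth is computed over all available vertices with
#'     the shortfall flagged.}
#' }
#'
#' @param parent_dir Directory in which the three subject directories are
#'   created.
#' @param hemi Hemisphere prefix.
#' @param label_name Destrieux name carrying the defect.
#' @return Invisibly, a named list of subject directories.
#' @export
make_failure_fixtures <- function(parent_dir, hemi = "lh",
                                  label_name = "S_central") {
  tab <- destrieux_subset_table()
  code <- tab$code[tab$name == label_name]
  unknown <- tab$code[tab$name == "Unknown"]
  dirs <- list()

  emit <- function(name, surf, labels, overlay) {
    d <- file.path(parent_dir, name)
    dir.create(file.path(d, "surf"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(d, "label"), recursive = TRUE, showWarnings = FALSE)
    write_surface(surf, file.path(d, "surf", paste0(hemi, ".pial")))
    write_surface(build_outer_plate(surf$vertices, 2),
                  file.path(d, "surf", paste0(hemi, ".pial-outer-smoothed")))
    write_overlay(overlay, file.path(d, "surf", paste0(hemi, ".sulc")),
                  n_faces = nrow(surf$faces))
    write_annotation(fs_annotation(labels, tab),
                     file.path(d, "label",
                               paste0(hemi, ".aparc.a2009s.annot")))
    d
  }

  # flat grid helper: n x n plate at unit spacing, z = 0
  grid_plate <- function(n) {
    xs <- seq(0, n - 1)
    v <- cbind(rep(xs, each = n), rep(xs, n), 0)
    vid <- function(ix, iy) (ix - 1L) * n + iy
    ix <- rep(seq_len(n - 1L), each = n - 1L)
    iy <- rep(seq_len(n - 1L), n - 1L)
    f <- rbind(cbind(vid(ix, iy), vid(ix + 1L, iy), vid(ix + 1L, iy + 1L)),
               cbind(vid(ix, iy), vid(ix + 1L, iy + 1L), vid(ix, iy + 1L)))
    list(surf = fs_surface(v, f), n = n, vid = vid)
  }

  # (a) split label: two disjoint square patches on a 15x15 plate
  g <- grid_plate(15L)
  lab <- rep(unknown, 15L * 15L)
  for (ix in 2:5) for (iy in 2:5) lab[g$vid(ix, iy)] <- code
  for (ix in 10:13) for (iy in 10:13) lab[g$vid(ix, iy)] <- code
  dirs$split_label <- emit("split_label", g$surf, lab,
                           -as.numeric(lab == code))

  # (b) annulus: ring-shaped patch (square annulus, hole in the middle)
  g <- grid_plate(15L)
  lab <- rep(unknown, 15L * 15L)
  for (ix in 3:12) for (iy in 3:12) {
    if (ix <= 5 || ix >= 10 || iy <= 5 || iy >= 10) lab[g$vid(ix, iy)] <- code
  }
  dirs$annulus <- emit("annulus", g$surf, lab, -as.numeric(lab == code))

  # (c) undersized: a genuine small fold with < 100 region vertices
  spec <- sulcus_spec(true_width = 2, true_depth = 3, length = 4,
                      mesh_spacing = 1, margin = 3, seed = 7L)
  d <- file.path(parent_dir, "undersized")
  make_box_sulcus(spec, d, hemi = hemi, label_name = label_name)
  dirs$undersized <- d

  invisible(dirs)
}

#' Default cohort effect model
#'
#' Linear age trends plus between- and within-subject Gaussian noise for
#' the synthetic cohort.  The defaults are calibrated so that, over ages
#' uniform on 20-80 years (sd 17.32), the generating age-width correlation
#' is +0.5 and the generating age-depth correlation is -0.5:
#' `slope * sd(age) = sqrt(sd_between^2 + sd_within^2) / sqrt(3)`.
#'
#' @param width,depth Named numeric vectors with elements `base` (mm at the
#'   mean age), `slope` (mm/year), `sd_between` (mm), `sd_within` (mm).
#' @return List of class `effect_model`.
#' @export
effect_model <- function(width = c(base = 3, slope = 0.01,
                                   sd_between = 0.2828427, sd_within = 0.1),
                         depth = c(base = 10, slope = -0.02,
                                   sd_between = 0.5656854, sd_within = 0.2)) {
  need <- c("base", "slope", "sd_between", "sd_within")
  stopifnot(all(need %in% names(width)), all(need %in% names(depth)))
  structure(list(width = width, depth = depth), class = "effect_model")
}

#' Generating age correlation implied by an effect model
#'
#' `r = slope * sd(age) / sqrt(slope^2 var(age) + sd_between^2 +
#' sd_within^2)` — the population correlation between age and a single
#' session's true measure under the cohort generator.
#'
#' @param model An [effect_model()].
#' @param metric `"width"` or `"depth"`.
#' @param age_range Two-element age range (years), uniform.
#' @return Numeric correlation.
#' @export
generating_correlation <- function(model, metric = c("width", "depth"),
                                   age_range = c(20, 80)) {
  metric <- match.arg(metric)
  p <- model[[metric]]
  sd_age <- diff(age_range) / sqrt(12)
  num <- p[["slope"]] * sd_age
  num / sqrt(num^2 + p[["sd_between"]]^2 + p[["sd_within"]]^2)
}

#' Generate a synthetic cohort with known age trends
#'
#' Samples ages uniformly, draws each subject's true width/depth from the
#' effect model's linear age trend plus between-subject noise, adds
#' within-subject (session) noise, and — optionally — emits one synthetic
#' subject directory per subject and session.  Deterministic given `seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param parent_dir Directory for subject folders (required when
#'   `write_subjects = TRUE`).
#' @param age_range Uniform age range in years.
#' @param model An [effect_model()].
#' @param n_sessions Sessions per subject (test-retest uses >= 2).
#' @param seed Integer seed.
#' @param write_subjects If `TRUE` (default), emit FreeSurfer-layout
#'   subjects named `sub<ID>_ses<K>`; if `FALSE`, return only the truth
#'   table (useful for value-level simulation studies).
#' @param mesh_spacing,length,margin Geometry parameters passed to each
#'   subject's [sulcus_spec()].
#' @param label_name Destrieux name for the generated fold.
#' @param hemi Hemisphere prefix.
#' @return A tibble (the truth table): `subject`, `session`, `age`,
#'   `true_width`, `true_depth`, and `dir` when subjects were written.
#'   Covariate columns `thickness` and `ventricle` carry age-related
#'   nuisance measures for partial-correlation exercises.
#' @export
make_cohort <- function(n_subjects, parent_dir = NULL,
                        age_range = c(20, 80), model = effect_model(),
                        n_sessions = 1L, seed = 1L, write_subjects = TRUE,
                        mesh_spacing = 1, length = 30, margin = 4,
                        label_name = "S_central", hemi = "lh") {
  stopifnot(n_subjects >= 2L, n_sessions >= 1L)
  if (write_subjects && is.null(parent_dir)) {
    stop("parent_dir is required when write_subjects = TRUE", call. = FALSE)
  }
  truth <- withr::with_seed(as.integer(seed), {
    age <- stats::runif(n_subjects, age_range[1], age_range[2])
    age_c <- age - mean(age_range)
    w <- model$width; d <- model$depth
    width_s <- w[["base"]] + w[["slope"]] * age_c +
      stats::rnorm(n_subjects, 0, w[["sd_between"]])
    depth_s <- d[["base"]] + d[["slope"]] * age_c +
      stats::rnorm(n_subjects, 0, d[["sd_between"]])
    # age-related nuisance covariates (atrophy proxies)
    thickness <- 2.8 - 0.005 * age_c + stats::rnorm(n_subjects, 0, 0.08)
    ventricle <- 1500 + 15 * age_c + stats::rnorm(n_subjects, 0, 250)
    tidyr::expand_grid(subject = sprintf("sub%03d", seq_len(n_subjects)),
                       session = seq_len(n_sessions)) |>
      dplyr::mutate(
        age = rep(age, each = n_sessions),
        thickness = rep(thickness, each = n_sessions),
        ventricle = rep(ventricle, each = n_sessions),
        true_width = pmax(mesh_spacing,
                          rep(width_s, each = n_sessions) +
                            stats::rnorm(dplyr::n(), 0, w[["sd_within"]])),
        true_depth = pmax(2 * mesh_spacing,
                          rep(depth_s, each = n_sessions) +
                            stats::rnorm(dplyr::n(), 0, d[["sd_within"]])))
  })
  if (!write_subjects) return(truth)
  dirs <- character(nrow(truth))
  for (r in seq_len(nrow(truth))) {
    dname <- sprintf("%s_ses%d", truth$subject[r], truth$session[r])
    dirs[r] <- file.path(parent_dir, dname)
    spec <- sulcus_spec(true_width = truth$true_width[r],
                        true_depth = truth$true_depth[r],
                        length = length, mesh_spacing = mesh_spacing,
                        margin = margin,
                        seed = as.integer(seed) + r)
    make_box_sulcus(spec, dirs[r], hemi = hemi, label_name = label_name)
  }
  truth$dir <- dirs
  truth
}
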