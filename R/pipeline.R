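# Batch orchestration over a FreeSurfer subjects directory.  Measurement
# failures are per-measure values in the output table; only missing input
# files abort a subject, and no single subject can abort a cohort run.

subject_paths <- function(subjects_dir, subject, hemi) {
  base <- file.path(subjects_dir, subject)
  list(pial = file.path(base, "surf", paste0(hemi, ".pial")),
       outer = file.path(base, "surf", paste0(hemi, ".pial-outer-smoothed")),
       sulc = file.path(base, "surf", paste0(hemi, ".sulc")),
       annot = file.path(base, "label", paste0(hemi, ".aparc.a2009s.annot")))
}

#' Measure the requested sulci of one subject
#'
#' Runs the full per-sulcus procedure for every requested (hemisphere,
#' sulcus) pair: read the pial surface, annotation, sulcal map and outer
#' smoothed surface; isolate the sulcus; extract the boundary edge loop;
#' estimate width and depth.  Per-measure failures (discontinuous label,
#' multiple boundary loops, short loop, absent label) are rows with
#' `status != "ok"` and an `NA` value — the run continues.
#'
#' By default depth is still computed when the width edge loop fails (the
#' fundus-to-outer-surface distance does not need the loop); `strict = TRUE`
#' fails both together, matching a per-sulcus exclusion policy.
#'
#' @param subjects_dir FreeSurfer subjects directory.
#' @param subject Subject identifier (directory name).
#' @param hemi Character vector of hemispheres, subset of `c("lh", "rh")`.
#' @param sulci Character vector of Destrieux sulcus names; defaults to the
#'   eight supported sulci.  Experimental names (temporal, intraparietal)
#'   require `experimental = TRUE` and emit a warning.
#' @param width_opts A [width_options()].
#' @param depth_opts A [depth_options()].
#' @param strict If `TRUE`, a width (loop) failure also fails depth.
#' @param experimental Allow the experimental sulci.
#' @param allow_largest_component If `TRUE`, a discontinuous label is
#'   measured on its largest edge-connected component instead of failing;
#'   the measure is flagged `largest-component` in `flags`.  Off by
#'   default: a non-loopable parcellation is a failed estimate.
#' @return A tibble with one row per (hemi, sulcus, metric): columns
#'   `subject`, `hemi`, `sulcus`, `metric` (`"width"`/`"depth"`), `value`
#'   (mm, `NA` on failure), `status` (`"ok"` or the failure reason), `n`
#'   (bridges or fundus vertices), `flags`.
#' @export
run_subject <- function(subjects_dir, subject, hemi = "lh",
                        sulci = supported_sulci()$name,
                        width_opts = width_options(),
                        depth_opts = depth_options(),
                        strict = FALSE, experimental = FALSE,
                        allow_largest_component = FALSE) {
  registry <- supported_sulci(experimental = TRUE)
  unknown <- setdiff(sulci, registry$name)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown sulcus name(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  exp_requested <- intersect(
    sulci, registry$name[registry$status == "experimental"])
  if (length(exp_requested) > 0L) {
    if (!experimental) {
      stop(sprintf(
        paste0("sulci %s are experimental (width estimation fails at an ",
               "unacceptable rate); pass experimental = TRUE to measure them"),
        paste(exp_requested, collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("measuring experimental sulci: %s",
                    paste(exp_requested, collapse = ", ")), call. = FALSE)
  }

  rows <- list()
  for (h in hemi) {
    paths <- subject_paths(subjects_dir, subject, h)
    missing <- !vapply(paths, file.exists, logical(1L))
    if (any(missing)) {
      msg <- sprintf("subject '%s' (%s): missing required file(s): %s",
                     subject, h,
                     paste(unlist(paths[missing]), collapse = ", "))
      if (missing[["outer"]]) {
        msg <- paste0(msg, " (the outer smoothed surface is produced by ",
                      "FreeSurfer's gyrification analysis; run it first)")
      }
      stop(msg, call. = FALSE)
    }
    mesh <- read_surface(paths$pial)
    annot <- read_annotation(paths$annot)
    sulcmap <- read_overlay(paths$sulc, expected_n = nrow(mesh$vertices))
    outer <- read_surface(paths$outer)

    for (sname in sulci) {
      rows[[length(rows) + 1L]] <-
        measure_one_sulcus(mesh, annot, sulcmap, outer, sname, subject, h,
                           width_opts, depth_opts, strict,
                           allow_largest_component)
    }
  }
  dplyr::bind_rows(rows)
}

measure_one_sulcus <- function(mesh, annot, sulcmap, outer, sname, subject,
                               h, width_opts, depth_opts, strict,
                               allow_largest_component) {
  row <- function(metric, value, status, n, flags = "") {
    tibble::tibble(subject = subject, hemi = h, sulcus = sname,
                   metric = metric, value = value, status = status,
                   n = as.integer(n), flags = flags)
  }
  if (!sname %in% annot$table$name) {
    return(dplyr::bind_rows(row("width", NA_real_, "label-missing-from-table", 0L),
                            row("depth", NA_real_, "label-missing-from-table", 0L)))
  }
  region <- isolate_sulcus(mesh, annot, sname)
  if (region$absent) {
    return(dplyr::bind_rows(row("width", NA_real_, "label-absent", 0L),
                            row("depth", NA_real_, "label-absent", 0L)))
  }
  flags <- character(0)
  loop <- get_edge_loop(region)
  if (is_loop_failure(loop) && loop$reason == "discontinuous-region" &&
      allow_largest_component) {
    cc <- connected_components(region)
    keep <- which(cc$component ==
                    which.max(tabulate(cc$component, cc$n_components)))
    region <- structure(
      list(mesh = region$mesh, face_ids = region$face_ids[keep],
           vertex_ids = sort(unique(as.integer(
             region$mesh$faces[region$face_ids[keep], ]))),
           label_name = region$label_name, absent = FALSE),
      class = "sulc_region")
    loop <- get_edge_loop(region)
    flags <- "largest-component"
  }
  w <- compute_width(region, loop, width_opts)
  if (is_measure_failure(w)) {
    wrow <- row("width", NA_real_, w$reason, 0L, paste(flags, collapse = ";"))
  } else {
    wrow <- row("width", w$width, "ok", w$n_bridges,
                paste(flags, collapse = ";"))
  }
  if (strict && is_measure_failure(w)) {
    drow <- row("depth", NA_real_, paste0("strict-width-", w$reason), 0L,
                paste(flags, collapse = ";"))
  } else {
    dep <- compute_depth(region, sulcmap, outer, depth_opts)
    if (is_measure_failure(dep)) {
      drow <- row("depth", NA_real_, dep$reason, 0L,
                  paste(flags, collapse = ";"))
    } else {
      dflags <- c(flags, if (dep$shortfall) "fundus-shortfall")
      drow <- row("depth", dep$depth, "ok", dep$n_fundus,
                  paste(dflags, collapse = ";"))
    }
  }
  dplyr::bind_rows(wrow, drow)
}

#' Discover subject directories in a subjects directory
#'
#' A subject is any directory directly under `subjects_dir` containing a
#' `surf/` subdirectory.
#'
#' @param subjects_dir FreeSurfer subjects directory.
#' @return Character vector of subject ids, sorted.
#' @export
discover_subjects <- function(subjects_dir) {
  cand <- list.dirs(subjects_dir, recursive = FALSE, full.names = FALSE)
  sort(cand[dir.exists(file.path(subjects_dir, cand, "surf"))])
}

#' Measure a cohort of subjects
#'
#' Runs [run_subject()] over every subject, isolating crashes: a subject
#' whose inputs are missing or unreadable is recorded in `errors` and
#' skipped; the run continues.  The long measurement table is canonical
#' (failures carry a reason, never a sentinel number); the wide table and
#' QC report are derived via [summarize_cohort()].
#'
#' @inheritParams run_subject
#' @param subjects Character vector of subject ids, or `NULL` to
#'   auto-discover.
#' @param mean_requires_complete Passed to [summarize_cohort()].
#' @return A list of class `sulc_cohort`: `measures` (long tibble),
#'   `summary` (a `cohort_summary`: wide table + QC), `errors` (tibble
#'   `subject`, `message`), `config` (all resolved options, for the QC
#'   report's configuration echo).
#' @export
run_cohort <- function(subjects_dir, subjects = NULL, hemi = "lh",
                       sulci = supported_sulci()$name,
                       width_opts = width_options(),
                       depth_opts = depth_options(),
                       strict = FALSE, experimental = FALSE,
                       allow_largest_component = FALSE,
                       mean_requires_complete = TRUE) {
  if (is.null(subjects)) subjects <- discover_subjects(subjects_dir)
  if (length(subjects) == 0L) {
    stop("no subjects to process (empty subject list)", call. = FALSE)
  }
  measures <- list()
  errors <- list()
  for (s in subjects) {
    res <- tryCatch(
      run_subject(subjects_dir, s, hemi = hemi, sulci = sulci,
                  width_opts = width_opts, depth_opts = depth_opts,
                  strict = strict, experimental = experimental,
                  allow_largest_component = allow_largest_component),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        tibble::tibble(subject = s, message = conditionMessage(res))
    } else {
      measures[[length(measures) + 1L]] <- res
    }
  }
  measures <- dplyr::bind_rows(measures)
  errors <- if (length(errors) > 0L) dplyr::bind_rows(errors) else
    tibble::tibble(subject = character(0), message = character(0))
  summary <- if (nrow(measures) > 0L) {
    summarize_cohort(measures, mean_requires_complete = mean_requires_complete)
  } else NULL
  config <- list(subjects_dir = subjects_dir, subjects = subjects,
                 hemi = hemi, sulci = sulci,
                 width_opts = unclass(width_opts),
                 depth_opts = unclass(depth_opts),
                 strict = strict, experimental = experimental,
                 allow_largest_component = allow_largest_component,
                 mean_requires_complete = mean_requires_complete)
  structure(list(measures = measures, summary = summary, errors = errors,
                 config = config),
            class = "sulc_cohort")
}

#' @export
print.sulc_cohort <- function(x, ...) {
  cat(sprintf("<sulc_cohort: %d measures, %d subject errors>\n",
              nrow(x$measures), nrow(x$errors)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Write cohort results to disk
#'
#' Emits the canonical long CSV, the derived wide CSV, and a JSON QC report
#' containing per-sulcus failure rates, flags, subject errors, and the
#' fully resolved configuration (every default materialised) for
#' reproducibility.
#'
#' @param cohort A `sulc_cohort` from [run_cohort()].
#' @param out_prefix Path prefix; writes `<prefix>_long.csv`,
#'   `<prefix>_wide.csv`, `<prefix>_qc.json`.
#' @return Invisibly, the three paths.
#' @export
write_cohort_results <- function(cohort, out_prefix) {
  stopifnot(inherits(cohort, "sulc_cohort"))
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(long = paste0(out_prefix, "_long.csv"),
             wide = paste0(out_prefix, "_wide.csv"),
             qc = paste0(out_prefix, "_qc.json"))
  utils::write.csv(cohort$measures, paths[["long"]], row.names = FALSE)
  if (!is.null(cohort$summary)) {
    utils::write.csv(cohort$summary$wide, paths[["wide"]], row.names = FALSE)
  }
  qc <- list(qc = if (is.null(cohort$summary)) NULL else cohort$summary$qc,
             flagged_sulci = if (is.null(cohort$summary)) character(0) else
               cohort$summary$flagged_sulci,
             errors = cohort$errors,
             config = cohort$config)
  jsonlite::write_json(qc, paths[["qc"]], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}
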