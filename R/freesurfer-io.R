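# FreeSurfer binary file I/O: triangle surfaces, annotations, scalar overlays.
# All multi-byte fields in these formats are big-endian.  Vertex indices are
# 0-based on disk and 1-based inside R.

TRIANGLE_MAGIC <- 16777214L  # 0xFFFFFE, current binary triangle surface
QUAD_MAGIC     <- 16777215L  # 0xFFFFFF, legacy quad surface (rejected)
NEW_CURV_MAGIC <- 16777215L  # same 3 bytes open the "new" curv dialect

read_int3 <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) return(NA_integer_)
  b[1L] * 65536L + b[2L] * 256L + b[3L]
}

write_int3 <- function(con, x) {
  b <- c(x %/% 65536L, (x %/% 256L) %% 256L, x %% 256L)
  writeBin(as.integer(b), con, size = 1L)
}

stop_format <- function(path, offset, msg) {
  stop(sprintf("FreeSurfer format error in '%s' at byte offset %d: %s",
               path, offset, msg), call. = FALSE)
}

#' Read a FreeSurfer binary triangle surface
#'
#' Reads the binary triangle-surface format used for `?h.pial`,
#' `?h.white`, `?h.pial-outer-smoothed` and friends.  Coordinates are
#' returned exactly as stored (surface RAS, millimetres); no transform is
#' applied.  Only the current triangle dialect is supported; legacy quad
#' files are rejected with an explicit message.
#'
#' @param path Path to the surface file.
#' @return An object of class `fs_surface`: a list with `vertices`
#'   (numeric n x 3 matrix, mm) and `faces` (integer m x 3 matrix of
#'   1-based vertex indices).
#' @seealso [write_surface()], [read_annotation()], [read_overlay()]
#' @export
#' @examples
#' surf <- fs_surface(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE),
#'                    matrix(c(1, 2, 3), 1))
#' f <- tempfile(fileext = ".pial")
#' write_surface(surf, f)
#' identical(read_surface(f)$vertices, surf$vertices)
read_surface <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("surface file does not exist: '%s'", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (is.na(magic)) stop_format(path, 0L, "file truncated before magic number")
  if (magic == QUAD_MAGIC) {
    stop_format(path, 0L,
                "legacy quad-surface magic found; only the binary triangle dialect is supported")
  }
  if (magic != TRIANGLE_MAGIC) {
    stop_format(path, 0L,
                sprintf("not a triangle surface (magic %d, expected %d)",
                        magic, TRIANGLE_MAGIC))
  }
  # comment string terminated by "\n\n"
  comment_bytes <- raw(0)
  prev_nl <- FALSE
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) {
      stop_format(path, 3L + length(comment_bytes),
                  "file truncated inside header comment")
    }
    if (b == as.raw(10L)) {
      if (prev_nl) break
      prev_nl <- TRUE
    } else {
      prev_nl <- FALSE
    }
    comment_bytes <- c(comment_bytes, b)
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L || any(counts < 0L)) {
    stop_format(path, 3L + length(comment_bytes) + 2L,
                "truncated or negative vertex/face counts")
  }
  nv <- counts[1L]; nf <- counts[2L]
  verts <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  if (length(verts) < 3L * nv) {
    stop_format(path, NA_integer_, "file truncated inside vertex block")
  }
  faces <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(faces) < 3L * nf) {
    stop_format(path, NA_integer_, "file truncated inside face block")
  }
  fs_surface(matrix(verts, ncol = 3L, byrow = TRUE),
             matrix(faces + 1L, ncol = 3L, byrow = TRUE))
}

#' Construct and validate a surface mesh
#'
#' @param vertices Numeric n x 3 matrix of coordinates (mm, surface RAS).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @return An `fs_surface` object.
#' @export
fs_surface <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || nrow(vertices) < 3L) {
    stop("vertices must be an n x 3 matrix with n >= 3", call. = FALSE)
  }
  if (ncol(faces) != 3L || nrow(faces) < 1L) {
    stop("faces must be an m x 3 matrix with m >= 1", call. = FALSE)
  }
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range [1, n_vertices]", call. = FALSE)
  }
  if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
          faces[, 1L] == faces[, 3L])) {
    stop("faces must reference three distinct vertices", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "fs_surface")
}

#' @export
print.fs_surface <- function(x, ...) {
  cat(sprintf("<fs_surface: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Write a FreeSurfer binary triangle surface
#'
#' @param surface An [fs_surface()] object (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  surface <- fs_surface(surface$vertices, surface$faces)
  con <- file(path, "wb")
  on.exit(close(con))
  write_int3(con, TRIANGLE_MAGIC)
  writeBin(charToRaw("created by sulcmorph\n\n"), con)
  writeBin(as.integer(c(nrow(surface$vertices), nrow(surface$faces))),
           con, size = 4L, endian = "big")
  writeBin(as.numeric(t(surface$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(surface$faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Construct and validate a parcellation annotation
#'
#' An annotation assigns one label per mesh vertex plus a colour/name table.
#' The label stored per vertex is the packed RGB code FreeSurfer uses
#' (`r + 256 g + 65536 b`); `0` means "no label".
#'
#' @param labels Integer vector, one packed label code per vertex.
#' @param table Data frame with columns `name`, `r`, `g`, `b` (0-255) and the
#'   derived `code`; built with [annot_table()].
#' @return An `fs_annotation` object.
#' @export
fs_annotation <- function(labels, table) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("labels must be non-empty", call. = FALSE)
  stopifnot(is.data.frame(table),
            all(c("name", "r", "g", "b", "code") %in% names(table)))
  present <- setdiff(unique(labels), 0L)
  missing <- setdiff(present, table$code)
  if (length(missing) > 0L) {
    stop(sprintf("label codes present on vertices but absent from table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(list(labels = labels, table = tibble::as_tibble(table)),
            class = "fs_annotation")
}

#' Build an annotation name/colour table
#'
#' @param names Character vector of structure names.
#' @param colors Optional m x 3 integer matrix of RGB values (0-255); chosen
#'   automatically (distinct per name) when omitted.
#' @return A tibble with columns `name`, `r`, `g`, `b`, `code`.
#' @export
annot_table <- function(names, colors = NULL) {
  n <- length(names)
  if (is.null(colors)) {
    # distinct low-collision colours; code = r + 256 g + 65536 b must be unique
    idx <- seq_len(n)
    colors <- cbind((idx * 37L) %% 256L, (idx * 111L) %% 256L,
                    (idx * 173L + 20L) %% 256L)
  }
  colors <- matrix(as.integer(colors), ncol = 3L)
  code <- colors[, 1L] + 256L * colors[, 2L] + 65536L * colors[, 3L]
  if (anyDuplicated(code)) stop("annotation colours must be distinct", call. = FALSE)
  tibble::tibble(name = as.character(names),
                 r = colors[, 1L], g = colors[, 2L], b = colors[, 3L],
                 code = code)
}

#' @export
print.fs_annotation <- function(x, ...) {
  cat(sprintf("<fs_annotation: %d vertices, %d named labels>\n",
              length(x$labels), nrow(x$table)))
  invisible(x)
}

#' Read a FreeSurfer annotation file
#'
#' Reads `?h.aparc.a2009s.annot`-style files, including the embedded
#' (version-2) colour table, which is required: without it, sulcus lookup by
#' Destrieux name is impossible.  Vertices carrying an unknown or zero label
#' are mapped to the no-label code `0`.
#'
#' @param path Path to the `.annot` file.
#' @return An [fs_annotation()] object.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file does not exist: '%s'", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(nv) == 0L || nv <= 0L) {
    stop_format(path, 0L, "invalid vertex count")
  }
  pairs <- readBin(con, "integer", n = 2L * nv, size = 4L, endian = "big")
  if (length(pairs) < 2L * nv) {
    stop_format(path, 4L, "truncated vertex/label block")
  }
  pairs <- matrix(pairs, ncol = 2L, byrow = TRUE)
  labels <- integer(nv)
  labels[pairs[, 1L] + 1L] <- pairs[, 2L]
  has_ctab <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(has_ctab) == 0L || has_ctab != 1L) {
    stop_format(path, 4L + 8L * nv,
                "missing colour table; name-based sulcus lookup is impossible")
  }
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(version) == 0L || version >= 0L) {
    stop_format(path, NA_integer_,
                "old-format colour table not supported (expect version -2)")
  }
  if (version != -2L) {
    stop_format(path, NA_integer_,
                sprintf("unsupported colour table version %d", version))
  }
  n_entries <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  fn_len <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  readBin(con, "raw", n = fn_len)  # embedded original-filename string; unused
  n_read <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(n_read) == 0L || n_read != n_entries) {
    stop_format(path, NA_integer_, "colour table entry count mismatch")
  }
  nm <- character(n_entries); rgbt <- matrix(0L, n_entries, 4L)
  for (k in seq_len(n_entries)) {
    readBin(con, "integer", n = 1L, size = 4L, endian = "big")  # structure id
    len <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    raw_name <- readBin(con, "raw", n = len)
    nm[k] <- rawToChar(raw_name[raw_name != as.raw(0L)])
    rgbt[k, ] <- readBin(con, "integer", n = 4L, size = 4L, endian = "big")
  }
  tab <- tibble::tibble(name = nm, r = rgbt[, 1L], g = rgbt[, 2L],
                        b = rgbt[, 3L],
                        code = rgbt[, 1L] + 256L * rgbt[, 2L] + 65536L * rgbt[, 3L])
  # vertices whose code is 0 or matches an "Unknown" entry carry no label
  unknown_codes <- c(0L, tab$code[tolower(tab$name) %in% c("unknown", "none")])
  labels[labels %in% unknown_codes] <- 0L
  known <- labels %in% c(0L, tab$code)
  labels[!known] <- 0L
  fs_annotation(labels, tab)
}

#' Write a FreeSurfer annotation file
#'
#' Emits the version-2 colour-table dialect that `read_annotation()` (and
#' FreeSurfer itself) consumes.
#'
#' @param annot An [fs_annotation()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path) {
  annot <- fs_annotation(annot$labels, annot$table)
  con <- file(path, "wb")
  on.exit(close(con))
  nv <- length(annot$labels)
  writeBin(as.integer(nv), con, size = 4L, endian = "big")
  inter <- integer(2L * nv)
  inter[seq(1L, 2L * nv, by = 2L)] <- seq_len(nv) - 1L
  inter[seq(2L, 2L * nv, by = 2L)] <- annot$labels
  writeBin(inter, con, size = 4L, endian = "big")
  writeBin(1L, con, size = 4L, endian = "big")        # colour table present
  writeBin(-2L, con, size = 4L, endian = "big")       # ctab version 2
  tab <- annot$table
  writeBin(as.integer(nrow(tab)), con, size = 4L, endian = "big")
  fname <- "sulcmorph.ctab"
  writeBin(as.integer(nchar(fname) + 1L), con, size = 4L, endian = "big")
  writeBin(c(charToRaw(fname), as.raw(0L)), con)
  writeBin(as.integer(nrow(tab)), con, size = 4L, endian = "big")
  for (k in seq_len(nrow(tab))) {
    writeBin(as.integer(k - 1L), con, size = 4L, endian = "big")
    writeBin(as.integer(nchar(tab$name[k]) + 1L), con, size = 4L, endian = "big")
    writeBin(c(charToRaw(tab$name[k]), as.raw(0L)), con)
    writeBin(as.integer(c(tab$r[k], tab$g[k], tab$b[k], 0L)),
             con, size = 4L, endian = "big")
  }
  invisible(path)
}

#' Read a FreeSurfer per-vertex scalar overlay
#'
#' Reads the "new" binary curv-family dialect used for `?h.sulc` and
#' `?h.curv`: one finite float per vertex, in the surface file's vertex
#' order.  The legacy (old-curv) dialect is rejected.
#'
#' @param path Path to the overlay file.
#' @param expected_n Optional vertex count to validate against (e.g. the
#'   companion surface's); a mismatch is a consistency error.
#' @return Numeric vector of per-vertex values.
#' @export
read_overlay <- function(path, expected_n = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("overlay file does not exist: '%s'", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (is.na(magic) || magic != NEW_CURV_MAGIC) {
    stop_format(path, 0L,
                sprintf("not a new-format scalar overlay (magic %s)", magic))
  }
  hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
  if (length(hdr) < 3L) stop_format(path, 3L, "truncated overlay header")
  nv <- hdr[1L]; vals_per <- hdr[3L]
  if (vals_per != 1L) {
    stop_format(path, 11L, sprintf("expected 1 value per vertex, found %d", vals_per))
  }
  vals <- readBin(con, "numeric", n = nv, size = 4L, endian = "big")
  if (length(vals) < nv) stop_format(path, 15L, "truncated overlay data")
  if (any(!is.finite(vals))) {
    stop_format(path, NA_integer_, "overlay contains non-finite values")
  }
  if (!is.null(expected_n) && nv != expected_n) {
    stop(sprintf("overlay '%s' has %d values but %d were expected from the surface",
                 path, nv, expected_n), call. = FALSE)
  }
  vals
}

#' Write a FreeSurfer per-vertex scalar overlay
#'
#' @param values Numeric vector of finite per-vertex values.
#' @param path Output path.
#' @param n_faces Face count written into the header (informational in this
#'   dialect); defaults to 0.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(values, path, n_faces = 0L) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("overlay must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("overlay values must be finite", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  write_int3(con, NEW_CURV_MAGIC)
  writeBin(as.integer(c(length(values), n_faces, 1L)), con,
           size = 4L, endian = "big")
  writeBin(values, con, size = 4L, endian = "big")
  invisible(path)
}
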