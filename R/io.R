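# Readers and writers for the exchange formats the pipeline consumes:
# two-file STL (one tooth per file, ASCII or binary) and single-file ASCII PLY
# with an integer `label` vertex property. Units are assumed to be mm.

is_binary_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80)
  if (length(head80) < 80) return(FALSE)
  nfac <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(nfac) != 1 || is.na(nfac) || nfac < 0) return(FALSE)
  isTRUE(file.size(path) == 84 + 50 * as.numeric(nfac))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nfac <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (nfac < 1) stopf("STL file '%s' contains no facets", path)
  rec <- readBin(con, "raw", 50 * nfac)
  if (length(rec) < 50 * nfac) stopf("truncated binary STL '%s'", path)
  rec <- matrix(rec, nrow = 50)
  vals <- readBin(as.vector(rec[1:48, ]), "numeric", size = 4,
                  n = 12L * nfac, endian = "little")
  vals <- matrix(vals, nrow = 12)           # per facet: normal + 3 vertices
  v <- rbind(t(vals[4:6, , drop = FALSE]),
             t(vals[7:9, , drop = FALSE]),
             t(vals[10:12, , drop = FALSE]))
  faces <- cbind(seq_len(nfac), seq_len(nfac) + nfac, seq_len(nfac) + 2L * nfac)
  list(vertices = v, faces = faces)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (!length(vl)) stopf("STL file '%s' contains no facets", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  }))
  if (nrow(v) %% 3 != 0 || any(!is.finite(v))) {
    stopf("malformed ASCII STL '%s'", path)
  }
  nfac <- nrow(v) %/% 3
  idx <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  list(vertices = v, faces = idx)
}

#' Read a triangle mesh from an STL file
#'
#' Auto-detects binary versus ASCII layout.
#'
#' @param path path to the STL file.
#' @return A list of class `tri_mesh` with `vertices` (V x 3) and `faces`
#'   (F x 3 vertex indices).
#' @export
read_stl_mesh <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  mesh <- if (is_binary_stl(path)) read_stl_binary(path) else
    read_stl_ascii(path)
  structure(mesh, class = "tri_mesh")
}

#' Read a segmented tooth pair into a labelled point cloud
#'
#' Two-file STL input assigns labels 1 and 2 in argument order (mesh vertices
#' become the cloud, deduplicated); PLY input reads per-vertex integer labels
#' from a `label` property.
#'
#' @param path one PLY path, or a character vector of two STL paths.
#' @param format `"auto"` (default, by extension), `"stl"` or `"ply"`.
#' @return A [labeled_cloud()].
#' @export
read_model <- function(path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path[1], ignore.case = TRUE)) "ply" else
      "stl"
  }
  if (format == "ply") {
    if (length(path) != 1) stopf("PLY input takes a single file")
    return(read_ply(path))
  }
  if (length(path) != 2) {
    stopf("STL input takes two files, one tooth each")
  }
  clouds <- lapply(path, function(p) {
    m <- read_stl_mesh(p)
    unique(m$vertices)
  })
  labeled_cloud(do.call(rbind, clouds),
                rep(1:2, vapply(clouds, nrow, integer(1))))
}

#' Write a labelled cloud as an ASCII PLY file with a label property
#'
#' @param cloud a [labeled_cloud()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  if (!inherits(cloud, "labeled_cloud")) stopf("expected a labeled_cloud")
  n <- nrow(cloud$points)
  header <- c("ply", "format ascii 1.0",
              "comment proxigap labelled tooth pair (units mm)",
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              "property int label", "end_header")
  body <- sprintf("%.6f %.6f %.6f %d",
                  cloud$points[, 1], cloud$points[, 2], cloud$points[, 3],
                  cloud$labels)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ASCII PLY point cloud with a label property
#'
#' @param path path to the PLY file.
#' @return A [labeled_cloud()].
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || tolower(trimws(txt[1])) != "ply") {
    stopf("not a PLY file: %s", path)
  }
  endh <- match("end_header", trimws(txt))
  if (is.na(endh)) stopf("malformed PLY (no end_header): %s", path)
  header <- trimws(txt[seq_len(endh)])
  ev <- grep("^element vertex ", header, value = TRUE)
  if (!length(ev)) stopf("malformed PLY (no vertex element): %s", path)
  n <- as.integer(strsplit(ev[1], "\\s+")[[1]][3])
  props <- sub("^property\\s+\\S+\\s+", "",
               grep("^property ", header, value = TRUE))
  need <- c("x", "y", "z", "label")
  if (!all(need %in% props)) {
    stopf("PLY must carry x, y, z and an integer label property")
  }
  rows <- strsplit(trimws(txt[endh + seq_len(n)]), "\\s+")
  m <- do.call(rbind, lapply(rows, as.numeric))
  if (is.null(m) || nrow(m) != n || ncol(m) < length(props)) {
    stopf("malformed PLY vertex block: %s", path)
  }
  labeled_cloud(m[, match(c("x", "y", "z"), props), drop = FALSE],
                as.integer(m[, match("label", props)]))
}

#' Write one tooth of a pair (or any point set) as an ASCII STL point mesh
#'
#' Each point becomes a degenerate-free micro-triangle so that standard mesh
#' tools can display the cloud; primarily a debugging aid and round-trip
#' surface for the tests.
#'
#' @param points numeric matrix of 3D points.
#' @param path output path.
#' @param scale micro-triangle edge scale in mm.
#' @return `path`, invisibly.
#' @export
write_stl_points <- function(points, path, scale = 0.01) {
  points <- as.matrix(points)
  n <- nrow(points)
  v1 <- sprintf("vertex %.6f %.6f %.6f", points[, 1], points[, 2], points[, 3])
  v2 <- sprintf("vertex %.6f %.6f %.6f", points[, 1] + scale, points[, 2],
                points[, 3])
  v3 <- sprintf("vertex %.6f %.6f %.6f", points[, 1], points[, 2] + scale,
                points[, 3])
  block <- rbind("facet normal 0 0 1", "outer loop", v1, v2, v3,
                 "endloop", "endfacet")
  writeLines(c("solid proxigap", as.vector(block), "endsolid proxigap"), path)
  invisible(path)
}
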