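#' Load a triangle mesh from an STL file
#'
#' Reads binary or ASCII STL (auto-detected), welds duplicated facet corners
#' and builds edge adjacency.  STL carries no connectivity, so welding is
#' required before any adjacency-based operation.
#'
#' @param path STL file path.
#' @param weld_tolerance vertex merge tolerance in mm (default 1e-6).
#' @param mirror if TRUE the mesh is mirrored about the sagittal plane on
#'   load (left-hip inputs).
#' @return A [trimesh].
#' @export
load_mesh <- function(path, weld_tolerance = 1e-6, mirror = FALSE) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  is_ascii <- length(raw) >= 6 &&
    identical(rawToChar(raw[1:5]), "solid") &&
    # binary STLs may also start with "solid"; check the facet payload size
    !(length(raw) >= 84 &&
        length(raw) == 84 + 50 * readBin(raw[81:84], "integer", size = 4,
                                         endian = "little"))
  tri <- if (is_ascii) .read_stl_ascii(path) else .read_stl_binary(raw, path)
  if (nrow(tri) == 0L) stop("mesh has zero faces: ", path)
  faces <- matrix(seq_len(nrow(tri)), ncol = 3L, byrow = TRUE)
  mesh <- trimesh(tri, faces, weld_tolerance = weld_tolerance)
  if (mirror) mesh <- mirror_mesh(mesh)
  mesh
}

.read_stl_binary <- function(raw, path) {
  if (length(raw) < 84) stop("unreadable STL file: ", path)
  n <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  if (length(raw) < 84 + 50 * n) stop("truncated binary STL: ", path)
  # each 50-byte record: 12 floats (normal + 3 vertices) + uint16 attribute
  rec <- 84 + rep((seq_len(n) - 1L) * 50L, each = 48L) + seq_len(48L)
  vals <- readBin(raw[rec], "numeric", n = 12L * n, size = 4,
                  endian = "little")
  vals <- matrix(vals, ncol = 12L, byrow = TRUE)[, 4:12, drop = FALSE]
  matrix(t(vals), ncol = 3L, byrow = TRUE)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("unreadable ASCII STL file: ", path)
  nums <- vapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4]), numeric(3))
  t(nums)
}

#' Write a mesh as binary STL
#' @param mesh a [trimesh].
#' @param path output file.
#' @param mirror mirror back about the sagittal plane before writing.
#' @export
write_stl <- function(mesh, path, mirror = FALSE) {
  stopifnot(inherits(mesh, "trimesh"))
  if (mirror) mesh <- mirror_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  block <- cbind(nrm, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(block[i, ]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Severity colour palette
#'
#' Named RGB palette for the four impingement severity bands plus the
#' non-impinged colour.  Band order is most to least severe.
#' @param colors character vector of band colour names (defaults
#'   red/yellow/green/blue as in the standard representation).
#' @param non_impinged name of the non-impinged colour (default grey).
#' @return Named list mapping colour name -> integer RGB triple (0-255).
#' @export
default_palette <- function(colors = c("red", "yellow", "green", "blue"),
                            non_impinged = "grey") {
  base <- list(red = c(255L, 0L, 0L), yellow = c(255L, 255L, 0L),
               green = c(0L, 255L, 0L), blue = c(0L, 0L, 255L),
               grey = c(128L, 128L, 128L))
  out <- lapply(c(colors, non_impinged), function(nm) {
    if (!is.null(base[[nm]])) base[[nm]]
    else as.integer(grDevices::col2rgb(nm)[, 1])
  })
  names(out) <- c(colors, non_impinged)
  out
}

#' Write a colour-annotated mesh as binary PLY
#'
#' Writes binary little-endian PLY with double-precision vertices and
#' per-face uchar red/green/blue properties (STL cannot carry colour).
#' Reloading with [read_ply()] reproduces topology and colours exactly.
#'
#' @param mesh a [trimesh].
#' @param colors character vector, one colour name per face (entries must be
#'   names of `palette`), or `NULL` for all non-impinged.
#' @param path output file.
#' @param palette named list of RGB triples, see [default_palette()].
#' @param mirror mirror back about the sagittal plane before writing.
#' @export
save_colored_mesh <- function(mesh, colors, path,
                              palette = default_palette(), mirror = FALSE) {
  stopifnot(inherits(mesh, "trimesh"))
  m <- nrow(mesh$faces)
  if (is.null(colors)) colors <- rep(names(palette)[length(palette)], m)
  if (length(colors) != m)
    stop("colors must assign exactly one colour to each of the ", m, " faces")
  if (anyNA(colors)) stop("colors contains missing values")
  bad <- setdiff(unique(colors), names(palette))
  if (length(bad)) stop("colour(s) not in palette: ", paste(bad, collapse = ", "))
  if (mirror) mesh <- mirror_mesh(mesh)
  rgb <- t(vapply(palette, identity, integer(3)))[colors, , drop = FALSE]
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           "comment impingemap face-coloured mesh",
           paste("element vertex", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           paste("element face", m),
           "property list uchar int vertex_indices",
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
  # fixed 16-byte face record: count(1) + 3 x int32 + rgb(3)
  frec <- raw(16L * m)
  idx0 <- (seq_len(m) - 1L) * 16L
  frec[idx0 + 1L] <- as.raw(3L)
  fb <- writeBin(as.integer(t(mesh$faces - 1L)), raw(), size = 4,
                 endian = "little")
  frec[rep(idx0, each = 12L) + rep(2:13, m)] <- fb
  frec[rep(idx0, each = 3L) + rep(14:16, m)] <- as.raw(t(rgb))
  writeBin(frec, con)
  invisible(path)
}

#' Read a face-coloured binary PLY written by [save_colored_mesh()]
#'
#' @param path PLY file path.
#' @param weld_tolerance vertex merge tolerance (mm).
#' @return A [trimesh] with attribute `"face_rgb"` (m x 3 integer matrix).
#' @export
read_ply <- function(path, weld_tolerance = 1e-6) {
  raw <- readBin(path, "raw", n = file.size(path))
  # locate end_header
  txt_end <- .find_bytes(raw, charToRaw("end_header\n"))
  if (is.na(txt_end)) stop("unreadable PLY file: ", path)
  hdr <- strsplit(rawToChar(raw[seq_len(txt_end - 1L)]), "\n")[[1]]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  if (!any(grepl("binary_little_endian", hdr)))
    stop("only binary little-endian PLY is supported")
  off <- txt_end + attr(txt_end, "len") - 1L
  vbytes <- raw[off + seq_len(8L * 3L * nv)]
  verts <- matrix(readBin(vbytes, "numeric", n = 3L * nv, size = 8,
                          endian = "little"), ncol = 3L, byrow = TRUE)
  off <- off + 24L * nv
  frec <- raw[off + seq_len(16L * nf)]
  idx0 <- (seq_len(nf) - 1L) * 16L
  cnt <- as.integer(frec[idx0 + 1L])
  if (any(cnt != 3L)) stop("non-triangular face in PLY")
  fb <- frec[rep(idx0, each = 12L) + rep(2:13, nf)]
  faces <- matrix(readBin(fb, "integer", n = 3L * nf, size = 4,
                          endian = "little"), ncol = 3L, byrow = TRUE) + 1L
  rgb <- matrix(as.integer(frec[rep(idx0, each = 3L) + rep(14:16, nf)]),
                ncol = 3L, byrow = TRUE)
  mesh <- trimesh(verts, faces, weld_tolerance = weld_tolerance)
  attr(mesh, "face_rgb") <- rgb
  mesh
}

.find_bytes <- function(raw, pat) {
  n <- length(pat)
  hits <- which(raw == pat[1])
  for (h in hits) {
    if (h + n - 1L <= length(raw) && all(raw[h:(h + n - 1L)] == pat)) {
      out <- h
      attr(out, "len") <- n
      return(out)
    }
  }
  NA_integer_
}
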