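# ---- point_cloud class ------------------------------------------------------

#' Construct a point cloud
#'
#' @param points n x 3 numeric matrix of world coordinates in metres.
#' @param color optional n x 3 matrix of 0-255 RGB values.
#' @param label optional provenance label.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, color = NULL, label = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("points must have 3 columns")
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  if (any(!is.finite(pts))) stop("point coordinates must all be finite")
  structure(list(points = pts, color = color, label = label),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s\n", nrow(x$points),
              if (is.null(x$label)) "" else paste0(" (", x$label, ")")))
  invisible(x)
}

as_point_matrix <- function(x) {
  if (inherits(x, "point_cloud")) x$points else {
    m <- as.matrix(x); dimnames(m) <- NULL; storage.mode(m) <- "double"; m
  }
}

sniff_format <- function(path, format = NULL) {
  if (!is.null(format)) return(toupper(format))
  switch(tolower(tools::file_ext(path)),
         ply = "PLY", pcd = "PCD", xyz = "XYZ", txt = "XYZ",
         stop("cannot infer cloud format from extension of ", path))
}

#' Read a point cloud from PLY, PCD or XYZ
#'
#' Supports ASCII and binary-little-endian PLY (scalar vertex properties),
#' PCD v0.7 ASCII, and whitespace-delimited XYZ.  Units are taken as stored.
#'
#' @param path file to read.
#' @param format one of `"PLY"`, `"PCD"`, `"XYZ"`; inferred from the
#'   extension when omitted.
#' @return a `point_cloud`.
#' @export
read_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- sniff_format(path, format)
  cl <- switch(fmt,
    XYZ = read_xyz(path),
    PLY = read_ply(path),
    PCD = read_pcd(path),
    stop("unsupported format: ", fmt))
  if (nrow(cl$points) == 0L) stop("empty cloud in ", path)
  cl
}

#' Write a point cloud
#'
#' @param cloud a `point_cloud`.
#' @param path destination.
#' @param format `"PLY"`, `"PCD"` or `"XYZ"` (inferred from extension when
#'   omitted).
#' @param binary write binary-little-endian PLY instead of ASCII.
#' @export
write_cloud <- function(cloud, path, format = NULL, binary = FALSE) {
  pts <- as_point_matrix(cloud)
  fmt <- sniff_format(path, format)
  switch(fmt,
    XYZ = utils::write.table(pts, path, row.names = FALSE, col.names = FALSE),
    PLY = write_ply(pts, path, binary),
    PCD = write_pcd(pts, path),
    stop("unsupported format: ", fmt))
  invisible(path)
}

read_xyz <- function(path) {
  m <- tryCatch(as.matrix(utils::read.table(path)),
                error = function(e) stop("malformed XYZ file ", path, ": ",
                                         conditionMessage(e)))
  if (ncol(m) < 3L) stop("malformed XYZ file ", path, ": fewer than 3 columns")
  point_cloud(m[, 1:3, drop = FALSE], label = basename(path))
}

write_pcd <- function(pts, path) {
  n <- nrow(pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# .PCD v0.7 - Point Cloud Data file format",
    "VERSION 0.7", "FIELDS x y z", "SIZE 4 4 4", "TYPE F F F",
    "COUNT 1 1 1", paste("WIDTH", n), "HEIGHT 1",
    "VIEWPOINT 0 0 0 1 0 0 0", paste("POINTS", n), "DATA ascii"), con)
  utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
}

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  di <- grep("^DATA\\b", lines)
  if (length(di) != 1L) stop("malformed PCD file ", path, ": no DATA line")
  hdr <- lines[seq_len(di)]
  get <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), hdr, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    strsplit(trimws(sub(paste0("^", key), "", ln[1])), "\\s+")[[1]]
  }
  if (!identical(tolower(get("DATA")), "ascii"))
    stop("only ASCII PCD is supported (", path, ")")
  fields <- get("FIELDS")
  xi <- match(c("x", "y", "z"), fields)
  if (any(is.na(xi))) stop("PCD file ", path, " lacks x/y/z fields")
  body <- lines[-seq_len(di)]
  body <- body[nzchar(trimws(body))]
  m <- tryCatch(
    matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
           ncol = length(fields), byrow = TRUE),
    warning = function(w) stop("malformed PCD body in ", path),
    error = function(e) stop("malformed PCD body in ", path))
  npt <- as.integer(get("POINTS")[1])
  if (!is.na(npt) && npt != nrow(m))
    stop("PCD file ", path, ": POINTS=", npt, " but ", nrow(m), " records")
  point_cloud(m[, xi, drop = FALSE], label = basename(path))
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

write_ply <- function(pts, path, binary = FALSE) {
  n <- nrow(pts)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           paste("element vertex", n),
           "property double x", "property double y", "property double z",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(pts)), con, size = 8, endian = "little")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
  }
}

read_ply <- function(path) {
  all_raw <- readBin(path, "raw", n = file.info(path)$size)
  marker <- charToRaw("end_header\n")
  pos <- grepRaw("end_header\n", all_raw, fixed = TRUE)
  if (length(pos) == 0L) stop("malformed PLY ", path, ": no end_header")
  pos <- pos[1]
  hdr <- strsplit(rawToChar(all_raw[seq_len(pos - 1L)]), "\r?\n")[[1]]
  body_raw <- all_raw[(pos + length(marker) - 1L + 1L):length(all_raw)]
  if (!identical(trimws(hdr[1]), "ply")) stop("malformed PLY ", path, ": bad magic")
  fmt <- grep("^format", hdr, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format line: ", fmt)
  # vertex element and its scalar properties (must come first among elements)
  el <- grep("^element", hdr)
  if (length(el) == 0L) stop("malformed PLY ", path, ": no element")
  first_el <- strsplit(trimws(hdr[el[1]]), "\\s+")[[1]]
  if (first_el[2] != "vertex")
    stop("PLY ", path, ": first element must be vertex")
  nvert <- as.integer(first_el[3])
  pend <- if (length(el) > 1L) el[2] - 1L else length(hdr)
  props <- hdr[(el[1] + 1L):pend]
  props <- props[grepl("^property", props)]
  ptok <- lapply(strsplit(trimws(props), "\\s+"), function(x) x[-1])
  if (any(vapply(ptok, function(x) x[1] == "list", logical(1))))
    stop("PLY ", path, ": list properties on vertex element unsupported")
  types <- vapply(ptok, `[`, "", 1L)
  names_ <- vapply(ptok, function(x) x[length(x)], "")
  xi <- match(c("x", "y", "z"), names_)
  if (any(is.na(xi))) stop("PLY ", path, " lacks x/y/z vertex properties")
  if (binary) {
    sizes <- ply_type_size[types]
    if (any(is.na(sizes))) stop("PLY ", path, ": unknown property type")
    raw <- body_raw
    if (length(raw) < sum(sizes) * nvert)
      stop("malformed PLY ", path, ": truncated at byte ",
           length(raw), " of vertex data")
    offs <- cumsum(c(0L, sizes))
    stride <- sum(sizes)
    read_col <- function(j) {
      b <- outer(seq_len(sizes[j]) + offs[j], (seq_len(nvert) - 1L) * stride, "+")
      col_raw <- raw[as.vector(b)]
      what <- if (types[j] %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      readBin(col_raw, what, n = nvert, size = sizes[j], endian = "little",
              signed = !(types[j] %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    m <- cbind(read_col(xi[1]), read_col(xi[2]), read_col(xi[3]))
  } else {
    body <- strsplit(rawToChar(body_raw), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))][seq_len(min(nvert, 1e9))]
    body <- body[!is.na(body)]
    if (length(body) < nvert)
      stop("malformed PLY ", path, ": expected ", nvert, " vertex lines, got ",
           length(body))
    vals <- strsplit(trimws(body), "\\s+")
    m0 <- matrix(as.numeric(unlist(vals)), ncol = length(types), byrow = TRUE)
    m <- m0[, xi, drop = FALSE]
  }
  point_cloud(m, label = basename(path))
}

# ---- orientation and scaling ------------------------------------------------

#' Orient a cloud by principal component analysis
#'
#' Rigidly rotates the cloud (about its centroid, which is moved to the
#' origin) so that the largest-eigenvalue eigenvector of the centered
#' covariance maps to +z: the cloud's longest axis becomes vertical,
#' reducing the void voxel space.  The rotation is proper (det = +1) and the
#' eigenvector sign is fixed so the oriented cloud has non-negative skewness
#' along +z.
#'
#' @param cloud a `point_cloud`.
#' @return the oriented `point_cloud`; the 3 x 3 rotation applied is
#'   attached as attribute `"rotation"`.
#' @export
orient_by_pca <- function(cloud) {
  pts <- as_point_matrix(cloud)
  if (nrow(pts) < 3L) stop("degenerate geometry: need at least 3 points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  cv <- crossprod(X) / (nrow(X) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] <= 0 || eg$values[2] <= 1e-12 * eg$values[1])
    stop("degenerate geometry: points are collinear or coincident")
  # columns: PC1, PC2, PC3 -> target axes z, x, y
  V <- eg$vectors[, c(2, 3, 1)]
  if (det(V) < 0) V[, 2] <- -V[, 2]        # keep proper rotation
  Y <- X %*% V
  sk <- mean(Y[, 3]^3)
  if (sk < 0) {                             # flip z; flip y too to stay proper
    Y[, 2:3] <- -Y[, 2:3]
    V[, 2:3] <- -V[, 2:3]
  }
  out <- point_cloud(Y, color = cloud$color, label = cloud$label)
  attr(out, "rotation") <- t(V)
  out
}

#' Uniformly scale a cloud by a reference length
#'
#' Multiplies all coordinates by `reference_length_measured /
#' reference_length_in_cloud`, the single-factor reduction of scaling a
#' photogrammetric model to tape/laser measurements.
#'
#' @param cloud a `point_cloud`.
#' @param reference_length_measured physically measured length (metres).
#' @param reference_length_in_cloud the same length measured in the cloud.
#' @return the scaled `point_cloud`.
#' @export
apply_scale <- function(cloud, reference_length_measured, reference_length_in_cloud) {
  if (reference_length_measured <= 0 || reference_length_in_cloud <= 0)
    stop("reference lengths must be positive")
  s <- reference_length_measured / reference_length_in_cloud
  point_cloud(as_point_matrix(cloud) * s, color = cloud$color, label = cloud$label)
}
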