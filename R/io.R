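#' Read an STL surface (binary or ASCII)
#'
#' Auto-detects dialect: a file whose size equals the 84-byte binary header
#' plus 50 bytes per declared triangle is read as binary, otherwise as
#' ASCII.  Vertices are deduplicated by exact coordinate match; normals are
#' not taken from the file (compute them with [compute_vertex_normals()],
#' which also fixes the inward orientation).
#'
#' @param path path to an STL file.
#' @param units `"m"` (default) or `"mm"`; with `"mm"` coordinates are
#'   converted to metres on load.
#' @return a [tri_surface] (no normals).
#' @export
read_stl <- function(path, units = c("m", "mm")) {
  units <- match.arg(units)
  size <- file.size(path)
  if (is.na(size) || size < 15)
    stop("not an STL file (too short): ", path)
  con <- file(path, "rb")
  head5 <- rawToChar(readBin(con, "raw", 5))
  close(con)
  is_binary <- !identical(head5, "solid")
  if (is_binary && size < 84)
    stop("not an STL file (no 'solid' header and too short for binary): ",
         path)
  if (!is_binary && size >= 84) {
    # "solid"-prefixed files can still be binary; trust the byte layout
    con <- file(path, "rb")
    seek(con, 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  surf <- if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
  if (units == "mm") surf$vertices <- surf$vertices * 1e-3
  dedup_vertices(surf)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(ntri) || is.na(ntri) || ntri < 0)
    stop("binary STL: unreadable triangle count at byte offset 80: ", path)
  expected <- 84 + 50 * as.numeric(ntri)
  if (file.size(path) != expected)
    stop(sprintf(
      "binary STL triangle count mismatch at byte offset 80: header declares %d triangles (expected file size %d, got %d)",
      ntri, expected, file.size(path)))
  # records interleave 12 float32 with a uint16 attribute; unpack from raw
  raw <- readBin(con, "raw", 50 * ntri)
  m <- matrix(raw, nrow = 50)
  tri <- vapply(seq_len(ntri), function(i)
    readBin(m[1:48, i], "numeric", 12, size = 4, endian = "little"),
    numeric(12))
  tri <- t(tri)  # ntri x 12: normal, v1, v2, v3
  verts <- matrix(0, 3 * ntri, 3)
  verts[seq(1, 3 * ntri, 3), ] <- tri[, 4:6, drop = FALSE]
  verts[seq(2, 3 * ntri, 3), ] <- tri[, 7:9, drop = FALSE]
  verts[seq(3, 3 * ntri, 3), ] <- tri[, 10:12, drop = FALSE]
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  tri_surface(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lt <- trimws(lines)
  if (!length(lt) || !startsWith(lt[1], "solid"))
    stop("ASCII STL must start with 'solid' at byte offset 0: ", path)
  vl <- grep("^vertex[[:space:]]", lt)
  if (length(vl) %% 3 != 0)
    stop(sprintf(
      "ASCII STL vertex count %d is not a multiple of 3 (near line %d)",
      length(vl), if (length(vl)) vl[length(vl)] else 1))
  if (!any(startsWith(lt, "endsolid")))
    stop("ASCII STL missing 'endsolid' terminator: ", path)
  toks <- strsplit(lt[vl], "[[:space:]]+")
  verts <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (any(!is.finite(verts)))
    stop("ASCII STL has non-numeric vertex coordinates")
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  tri_surface(verts, faces)
}

#' Write an STL surface
#'
#' @param surface a [tri_surface].
#' @param path output path.
#' @param dialect `"binary"` (little-endian, 80-byte header, uint32 count,
#'   50-byte triangle records) or `"ascii"` (coordinates at full double
#'   precision, so ASCII round-trips are bit-exact; binary STL stores
#'   float32 by format definition).
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  fn <- face_normals_raw(surface)
  len <- sqrt(rowSums(fn^2))
  fn <- fn / ifelse(len > 0, len, 1)
  v <- surface$vertices
  f <- surface$faces
  ntri <- nrow(f)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(formatC("aneuflow binary STL", width = -80))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(ntri), con, size = 4, endian = "little")
    for (i in seq_len(ntri)) {
      writeBin(c(fn[i, ], t(v[f[i, ], , drop = FALSE])), con,
               size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    num <- function(x) sprintf("%.17g", x)
    out <- character(2 + 7 * ntri)
    out[1] <- "solid aneuflow"
    k <- 2
    for (i in seq_len(ntri)) {
      out[k] <- paste("facet normal", num(fn[i, 1]), num(fn[i, 2]), num(fn[i, 3]))
      out[k + 1] <- "  outer loop"
      for (j in 1:3)
        out[k + 1 + j] <- paste("    vertex", num(v[f[i, j], 1]),
                                num(v[f[i, j], 2]), num(v[f[i, j], 3]))
      out[k + 5] <- "  endloop"
      out[k + 6] <- "endfacet"
      k <- k + 7
    }
    out[k] <- "endsolid aneuflow"
    writeLines(out, path)
  }
  invisible(path)
}

#' Read a gridded velocity field
#'
#' Accepts either a VTK legacy structured-points file (ASCII) carrying a
#' 3-component `VECTORS` array and an optional 0/1 `SCALARS mask`, or the
#' package CSV dialect with header row `i,j,k,x,y,z,ux,uy,uz,mask`
#' (0-based indices, x fastest).  A file without a mask yields an all-true
#' mask.
#'
#' @param path input path.
#' @param units `"m"` (default) or `"mm"`; with `"mm"` origin and spacing
#'   are converted to metres on load (velocities are taken as given).
#' @return a [velocity_field].
#' @export
read_velocity_grid <- function(path, units = c("m", "mm")) {
  units <- match.arg(units)
  first <- readLines(path, n = 1, warn = FALSE)
  field <- if (startsWith(first, "# vtk")) read_grid_vtk(path)
           else read_grid_csv(path)
  if (units == "mm") {
    field$spacing <- field$spacing * 1e-3
    field$origin <- field$origin * 1e-3
  }
  field
}

read_grid_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    i <- grep(paste0("^", key, "\\b"), lines)
    if (!length(i)) stop("VTK file missing ", key, " line: ", path)
    list(i = i[1], v = strsplit(trimws(lines[i[1]]), "[[:space:]]+")[[1]][-1])
  }
  if (!any(grepl("^DATASET STRUCTURED_POINTS", lines)))
    stop("only VTK legacy STRUCTURED_POINTS is supported: ", path)
  dims <- as.integer(grab("DIMENSIONS")$v)
  origin <- as.numeric(grab("ORIGIN")$v)
  spacing <- as.numeric(grab("SPACING")$v)
  npt <- as.integer(grab("POINT_DATA")$v[1])
  if (npt != prod(dims))
    stop(sprintf("VTK POINT_DATA count %d does not match DIMENSIONS product %d",
                 npt, prod(dims)))
  vec <- grep("^VECTORS[[:space:]]", lines)
  if (!length(vec)) stop("VTK file has no VECTORS array: ", path)
  nums <- function(from, n_values) {
    vals <- scan(text = lines[seq(from, length(lines))], what = double(),
                 n = n_values, quiet = TRUE)
    if (length(vals) < n_values)
      stop("VTK payload truncated: expected ", n_values, " values")
    vals
  }
  uv <- nums(vec[1] + 1, 3 * npt)
  u <- aperm(array(uv, c(3, dims)), c(2, 3, 4, 1))
  mask <- NULL
  sc <- grep("^SCALARS[[:space:]]+mask\\b", lines)
  if (length(sc)) {
    mv <- nums(sc[1] + 2, npt)  # skip LOOKUP_TABLE line
    mask <- array(mv != 0, dims)
  }
  velocity_field(u, spacing, origin, mask)
}

read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("i", "j", "k", "x", "y", "z", "ux", "uy", "uz")
  if (!all(need %in% names(df)))
    stop("CSV grid dialect needs columns i,j,k,x,y,z,ux,uy,uz[,mask]: ", path)
  dims <- c(max(df$i), max(df$j), max(df$k)) + 1L
  if (nrow(df) != prod(dims))
    stop(sprintf("CSV grid has %d rows but index range implies %d voxels",
                 nrow(df), prod(dims)))
  lin <- df$i + dims[1] * (df$j + dims[2] * df$k) + 1L
  if (anyDuplicated(lin)) stop("CSV grid has duplicate (i,j,k) rows")
  origin <- c(df$x[which(lin == 1)], df$y[which(lin == 1)], df$z[which(lin == 1)])
  spacing <- numeric(3)
  for (ax in 1:3) {
    col <- c("x", "y", "z")[ax]
    if (dims[ax] > 1) {
      nb <- which(lin == 1 + c(1, dims[1], dims[1] * dims[2])[ax])
      spacing[ax] <- df[[col]][nb] - origin[ax]
    } else spacing[ax] <- 1
  }
  u <- array(NA_real_, c(dims, 3))
  for (c3 in 1:3) {
    a <- array(NA_real_, dims)
    a[lin] <- df[[c("ux", "uy", "uz")[c3]]]
    u[, , , c3] <- a
  }
  mask <- if ("mask" %in% names(df)) {
    a <- array(TRUE, dims); a[lin] <- df$mask != 0; a
  } else NULL
  velocity_field(u, spacing, origin, mask)
}

#' Write a gridded velocity field
#'
#' @param field a [velocity_field].
#' @param path output path; extension `.csv` selects the CSV dialect,
#'   anything else the VTK legacy structured-points dialect.  Doubles are
#'   written at full precision (`%.17g`), so round-trips are bit-exact.
#' @return `path`, invisibly.
#' @export
write_velocity_grid <- function(field, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    write_grid_csv(field, path)
  else write_grid_vtk(field, path)
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

write_grid_vtk <- function(field, path) {
  d <- field$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "aneuflow structured velocity field",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", d[1], d[2], d[3]),
    paste("ORIGIN", fmt17(field$origin[1]), fmt17(field$origin[2]), fmt17(field$origin[3])),
    paste("SPACING", fmt17(field$spacing[1]), fmt17(field$spacing[2]), fmt17(field$spacing[3])),
    paste("POINT_DATA", prod(d)),
    "VECTORS velocity double"
  ), con)
  um <- cbind(as.vector(field$u[, , , 1]), as.vector(field$u[, , , 2]),
              as.vector(field$u[, , , 3]))
  writeLines(paste(fmt17(um[, 1]), fmt17(um[, 2]), fmt17(um[, 3])), con)
  writeLines(c("SCALARS mask int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(field$mask)), con)
}

write_grid_csv <- function(field, path) {
  d <- field$dims
  idx <- arrayInd(seq_len(prod(d)), d) - 1L
  xyz <- voxel_centers(field)
  df <- data.frame(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    x = fmt17(xyz[, 1]), y = fmt17(xyz[, 2]), z = fmt17(xyz[, 3]),
    ux = fmt17(as.vector(field$u[, , , 1])),
    uy = fmt17(as.vector(field$u[, , , 2])),
    uz = fmt17(as.vector(field$u[, , , 3])),
    mask = as.integer(field$mask)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a table of results as CSV
#'
#' Plain CSV with header row, comma separator and `.` decimal mark.  An
#' empty data frame yields a header-only file.
#'
#' @param rows a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}

#' Write per-voxel scalar arrays in the VTK dialect
#'
#' Emits the geometry of `field` as a legacy structured-points file whose
#' point data are the given scalar arrays (plus the lumen mask), e.g. the
#' Q-criterion for iso-surface inspection in ParaView.
#'
#' @param field a [velocity_field] supplying grid geometry and mask.
#' @param scalars named list of numeric arrays of `field$dims`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scalars_vtk <- function(field, scalars, path) {
  stopifnot(is.list(scalars), length(names(scalars)) == length(scalars))
  d <- field$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "aneuflow scalar fields",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", d[1], d[2], d[3]),
    paste("ORIGIN", fmt17(field$origin[1]), fmt17(field$origin[2]), fmt17(field$origin[3])),
    paste("SPACING", fmt17(field$spacing[1]), fmt17(field$spacing[2]), fmt17(field$spacing[3])),
    paste("POINT_DATA", prod(d))
  ), con)
  for (nm in names(scalars)) {
    a <- scalars[[nm]]
    a[!is.finite(a)] <- 0
    writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
    writeLines(fmt17(as.vector(a)), con)
  }
  writeLines(c("SCALARS mask int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(field$mask)), con)
  invisible(path)
}
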