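# Surface geometry I/O: FreeSurfer binary triangle files and GIFTI
# (.surf.gii / .func.gii). Vertex indices are converted between the
# package's 1-based convention and the 0-based on-disk convention here
# and nowhere else.

FS_TRIANGLE_MAGIC <- c(0xFFL, 0xFFL, 0xFEL)

guess_hemisphere <- function(path) {
  b <- tolower(basename(path))
  if (grepl("^lh\\.|[._-]lh[._-]|\\.l\\.", b)) return("left")
  if (grepl("^rh\\.|[._-]rh[._-]|\\.r\\.", b)) return("right")
  "none"
}

#' Read a surface mesh from file
#'
#' @param path file path.
#' @param format `"freesurfer"` (binary triangle file), `"gifti"`
#'   (`.surf.gii`), or `"auto"` (by extension: `.gii` is GIFTI,
#'   anything else FreeSurfer).
#' @param hemisphere hemisphere tag; `"auto"` guesses from the filename
#'   (`lh.*` / `rh.*`), falling back to `"none"`.
#' @return a `triangle_mesh`.
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "gifti"),
                         hemisphere = "auto") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "freesurfer"
  if (identical(hemisphere, "auto")) hemisphere <- guess_hemisphere(path)
  switch(format,
         freesurfer = read_fs_surface(path, hemisphere),
         gifti = read_gifti_surface(path, hemisphere))
}

#' Write a surface mesh to file
#'
#' @param mesh a `triangle_mesh`.
#' @param path destination path.
#' @param format `"freesurfer"`, `"gifti"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, format = c("auto", "freesurfer", "gifti")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "freesurfer"
  switch(format,
         freesurfer = write_fs_surface(mesh, path),
         gifti = write_gifti_surface(mesh, path))
  invisible(path)
}

read_fs_surface <- function(path, hemisphere) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  if (length(magic) < 3 || !all(magic == FS_TRIANGLE_MAGIC))
    stop("not a FreeSurfer binary triangle surface (bad magic): ", path)
  # comment line terminated by "\n\n"
  comment <- raw(0)
  repeat {
    ch <- readBin(con, "raw", n = 1)
    if (length(ch) == 0) stop("truncated FreeSurfer surface (unterminated header): ", path)
    comment <- c(comment, ch)
    nc <- length(comment)
    if (nc >= 2 && comment[nc] == as.raw(10) && comment[nc - 1] == as.raw(10)) break
    if (nc > 10000) stop("malformed FreeSurfer surface header (comment too long): ", path)
  }
  counts <- readBin(con, "integer", n = 2, size = 4, endian = "big")
  if (length(counts) < 2) stop("truncated FreeSurfer surface (missing counts): ", path)
  nv <- counts[1]; nf <- counts[2]
  if (nv <= 0 || nf <= 0) stop("empty mesh in ", path, " (vertices=", nv, ", faces=", nf, ")")
  verts <- readBin(con, "numeric", n = 3 * nv, size = 4, endian = "big")
  faces <- readBin(con, "integer", n = 3 * nf, size = 4, endian = "big")
  if (length(verts) < 3 * nv) stop("truncated FreeSurfer surface (vertex block): ", path)
  if (length(faces) < 3 * nf) stop("truncated FreeSurfer surface (face block): ", path)
  triangle_mesh(matrix(verts, ncol = 3, byrow = TRUE),
                matrix(faces, ncol = 3, byrow = TRUE) + 1L,
                hemisphere = hemisphere)
}

write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xFF, 0xFF, 0xFE)), con)
  writeBin(charToRaw("created by surfReHo\n\n"), con)
  writeBin(c(n_vertices(mesh), nrow(mesh$triangles)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$triangles - 1L)), con, size = 4, endian = "big")
}

# ---- GIFTI ------------------------------------------------------------------

gifti_decode_data <- function(da, path) {
  enc <- xml2::xml_attr(da, "Encoding")
  dt <- xml2::xml_attr(da, "DataType")
  dims <- vapply(paste0("Dim", 0:5), function(a)
    suppressWarnings(as.integer(xml2::xml_attr(da, a))), 1L)
  dims <- dims[!is.na(dims)]
  node <- xml2::xml_find_first(da, ".//Data")
  if (inherits(node, "xml_missing")) stop("GIFTI DataArray without <Data>: ", path)
  txt <- xml2::xml_text(node)
  n <- prod(dims)
  vals <- switch(enc,
    "ASCII" = as.numeric(strsplit(trimws(txt), "\\s+")[[1]]),
    "Base64Binary" = ,
    "GZipBase64Binary" = {
      bytes <- jsonlite::base64_dec(gsub("\\s", "", txt))
      if (enc == "GZipBase64Binary") bytes <- memDecompress(bytes, type = "gzip")
      switch(dt,
        "NIFTI_TYPE_FLOAT32" = readBin(bytes, "numeric", n = n, size = 4, endian = "little"),
        "NIFTI_TYPE_FLOAT64" = readBin(bytes, "numeric", n = n, size = 8, endian = "little"),
        "NIFTI_TYPE_INT32" = readBin(bytes, "integer", n = n, size = 4, endian = "little"),
        stop("unsupported GIFTI DataType '", dt, "' in ", path))
    },
    stop("unsupported GIFTI Encoding '", enc, "' in ", path))
  if (length(vals) != n)
    stop("GIFTI data length ", length(vals), " != product of Dims ", n, " in ", path)
  order <- xml2::xml_attr(da, "ArrayIndexingOrder")
  if (length(dims) == 2L) {
    m <- if (identical(order, "ColumnMajorOrder"))
      matrix(vals, nrow = dims[1]) else matrix(vals, nrow = dims[1], byrow = TRUE)
    m
  } else matrix(vals, ncol = 1)
}

read_gifti_surface <- function(path, hemisphere) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed GIFTI XML in ", path, ": ",
                                           conditionMessage(e)))
  das <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(das, "Intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) != 1L || length(it) != 1L)
    stop("GIFTI surface must contain exactly one POINTSET and one TRIANGLE DataArray: ", path)
  verts <- gifti_decode_data(das[[ip]], path)
  faces <- gifti_decode_data(das[[it]], path)
  triangle_mesh(verts, faces + 1L, hemisphere = hemisphere)
}

gifti_data_array_xml <- function(values_rowmajor, intent, datatype, dims) {
  dimattr <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims), collapse = " ")
  sprintf(paste0(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
    'Dimensionality="%d" %s Encoding="ASCII" Endian="LittleEndian" ',
    'ExternalFileName="" ExternalFileOffset="">\n<Data>%s</Data>\n</DataArray>'),
    intent, datatype, length(dims), dimattr,
    paste(values_rowmajor, collapse = " "))
}

write_gifti_xml <- function(arrays, path) {
  body <- paste(arrays, collapse = "\n")
  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" ',
    'Version="1.0" NumberOfDataArrays="%d">\n%s\n</GIFTI>\n'),
    length(arrays), body)
  writeLines(xml, path)
  invisible(path)
}

write_gifti_surface <- function(mesh, path) {
  va <- gifti_data_array_xml(format(as.numeric(t(mesh$vertices)), digits = 9, trim = TRUE),
                             "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                             c(n_vertices(mesh), 3L))
  fa <- gifti_data_array_xml(as.integer(t(mesh$triangles - 1L)),
                             "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                             c(nrow(mesh$triangles), 3L))
  write_gifti_xml(c(va, fa), path)
}

#' Write per-vertex functional data as GIFTI
#'
#' Writes a `surface_timeseries` (one DataArray per volume) or a
#' `surface_map` (a single DataArray; masked-out vertices written as NaN)
#' to a `.func.gii` file with ASCII encoding.
#'
#' @param x `surface_timeseries` or `surface_map`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_gifti_func <- function(x, path) {
  if (inherits(x, "surface_timeseries")) {
    arrays <- lapply(seq_len(ncol(x$data)), function(j)
      gifti_data_array_xml(format(x$data[, j], digits = 9, trim = TRUE),
                           "NIFTI_INTENT_TIME_SERIES", "NIFTI_TYPE_FLOAT32",
                           nrow(x$data)))
  } else if (inherits(x, "surface_map")) {
    arrays <- list(gifti_data_array_xml(
      format(x$values, digits = 9, trim = TRUE),
      "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32", length(x$values)))
  } else stop("x must be a surface_timeseries or surface_map")
  write_gifti_xml(arrays, path)
}

#' Read per-vertex functional data from GIFTI
#'
#' @param path a `.func.gii` path.
#' @return numeric V x T matrix (T = number of DataArrays).
#' @export
read_gifti_func <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed GIFTI XML in ", path, ": ",
                                           conditionMessage(e)))
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(das) == 0) stop("no DataArray in ", path)
  cols <- lapply(das, gifti_decode_data, path = path)
  do.call(cbind, lapply(cols, as.numeric))
}

# ---- plain-text maps --------------------------------------------------------

#' Write a surface map as TSV
#'
#' Two columns: `vertex` (in the chosen index base) and `value`
#' (NA for masked-out vertices).
#'
#' @param map a `surface_map`.
#' @param path destination path.
#' @param index_base 0 or 1; base of the written vertex indices.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path, index_base = 0L) {
  stopifnot(index_base %in% c(0L, 1L))
  df <- data.frame(vertex = seq_along(map$values) - 1L + as.integer(index_base),
                   value = map$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a surface map from TSV
#'
#' @param path TSV with `vertex` and `value` columns.
#' @param mesh the mesh the map belongs to.
#' @param index_base base of the stored vertex indices (0 or 1).
#' @return a `surface_map`; NA values become masked-out vertices.
#' @export
read_map_tsv <- function(path, mesh, index_base = 0L) {
  df <- utils::read.delim(path)
  if (!all(c("vertex", "value") %in% names(df)))
    stop("map TSV must have 'vertex' and 'value' columns: ", path)
  v <- n_vertices(mesh)
  idx <- df$vertex + 1L - as.integer(index_base)
  if (any(idx < 1L | idx > v)) stop("vertex index out of range in ", path)
  vals <- rep(NA_real_, v)
  vals[idx] <- df$value
  keep <- !is.na(vals)
  if (!any(keep)) stop("map in ", path, " has no finite values")
  surface_map(vals, mesh, cortex_mask(keep, mesh))
}
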