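# File I/O: NIfTI volumes (RNifti), GIFTI surfaces and per-vertex scalar
# maps (minimal ASCII-encoding reader/writer over xml2), MatrixMarket
# matrices, TSV tables, YAML configuration and JSON.

#' @importClassesFrom Matrix Matrix
NULL

#' Read and write NIfTI volumes
#'
#' @param volume numeric or logical 3-D array.
#' @param path file path (`.nii` / `.nii.gz`).
#' @param voxelSize isotropic voxel edge length in mm.
#' @return `readVolume()` returns the array with a `"voxelSize"` attribute.
#' @export
writeVolume <- function(volume, path, voxelSize = 1) {
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- rep(voxelSize, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxelSize") <- RNifti::pixdim(img)[1L]
  out
}

.giftiDataArray <- function(root, intent, datatype, x, dims) {
  da <- xml2::xml_add_child(root, "DataArray",
    Intent = intent, DataType = datatype, ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)), Encoding = "ASCII",
    Endian = "LittleEndian", ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", i - 1L), as.character(dims[i]))
  xml2::xml_add_child(da, "Data", paste(x, collapse = " "))
  invisible(da)
}

#' Read and write GIFTI surfaces and scalar maps
#'
#' Minimal GIFTI (.gii) support sufficient for the package's artifacts:
#' ASCII-encoded data arrays, a pointset + triangle pair for surfaces and a
#' single array for per-vertex scalar maps.
#'
#' @param surface a [SurfaceMesh-class].
#' @param path file path (`.surf.gii` / `.func.gii`).
#' @return `readGiftiSurface()` returns a [SurfaceMesh-class];
#'   `readGiftiScalar()` a numeric vector.
#' @export
writeGiftiSurface <- function(surface, path) {
  root <- xml2::xml_new_root("GIFTI", Version = "1.0",
                             NumberOfDataArrays = "2")
  v <- t(surface@vertices)  # row-major: vertex rows
  .giftiDataArray(root, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                  format(as.vector(v), digits = 10, trim = TRUE),
                  c(nrow(surface@vertices), 3L))
  f <- t(surface@faces - 1L)  # GIFTI triangles are 0-based
  .giftiDataArray(root, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                  as.vector(f), c(nrow(surface@faces), 3L))
  xml2::write_xml(root, path)
  invisible(path)
}

.readGiftiArrays <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  lapply(das, function(da) {
    enc <- xml2::xml_attr(da, "Encoding")
    if (!identical(enc, "ASCII"))
      .stopf("%s: only ASCII-encoded GIFTI data arrays are supported", path)
    dims <- as.integer(vapply(seq_len(as.integer(xml2::xml_attr(da, "Dimensionality"))),
      function(i) xml2::xml_attr(da, paste0("Dim", i - 1L)), character(1)))
    raw <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
    vals <- as.numeric(strsplit(trimws(raw), "\\s+")[[1L]])
    if (length(vals) != prod(dims))
      .stopf("%s: data length %d does not match Dim attributes", path, length(vals))
    list(intent = xml2::xml_attr(da, "Intent"), dims = dims, values = vals)
  })
}

#' @rdname writeGiftiSurface
#' @export
readGiftiSurface <- function(path) {
  arrays <- .readGiftiArrays(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  pi_ <- match("NIFTI_INTENT_POINTSET", intents)
  ti <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (is.na(pi_) || is.na(ti)) .stopf("%s: not a surface GIFTI file", path)
  v <- matrix(arrays[[pi_]]$values, ncol = 3L, byrow = TRUE)
  f <- matrix(as.integer(arrays[[ti]]$values), ncol = 3L, byrow = TRUE) + 1L
  new("SurfaceMesh", vertices = v, faces = f)
}

#' @rdname writeGiftiSurface
#' @param values numeric per-vertex map.
#' @export
writeGiftiScalar <- function(values, path) {
  root <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "1")
  .giftiDataArray(root, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                  format(as.numeric(values), digits = 10, trim = TRUE),
                  length(values))
  xml2::write_xml(root, path)
  invisible(path)
}

#' @rdname writeGiftiSurface
#' @export
readGiftiScalar <- function(path) {
  arrays <- .readGiftiArrays(path)
  arrays[[1L]]$values
}

#' Read and write sparse matrices in MatrixMarket format
#'
#' @param m a matrix or sparse [Matrix::Matrix].
#' @param path `.mtx` file path.
#' @return `readSparseMatrix()` returns a sparse Matrix.
#' @export
writeSparseMatrix <- function(m, path) {
  Matrix::writeMM(methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"), path)
  invisible(path)
}

#' @rdname writeSparseMatrix
#' @export
readSparseMatrix <- function(path) Matrix::readMM(path)

#' Read and write TSV tables
#'
#' @param df data.frame.
#' @param path `.tsv` path.
#' @return `readTsv()` returns a data.frame.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) utils::read.delim(path, check.names = FALSE)

#' Write a blueprint as TSV
#'
#' One row per vertex: `vertex`, `zero` flag, then one normalized column per
#' tract.
#'
#' @param bp a [Blueprint-class].
#' @param path `.tsv` path.
#' @return `readBlueprint()` reconstructs the [Blueprint-class] (the raw
#'   matrix is not stored and is set to the normalized one).
#' @export
writeBlueprint <- function(bp, path) {
  df <- data.frame(vertex = bp@vertexIds, zero = as.integer(bp@zeroRows))
  for (j in seq_along(bp@tractNames)) df[[bp@tractNames[j]]] <- bp@matrix[, j]
  writeTsv(df, path)
}

#' @rdname writeBlueprint
#' @export
readBlueprint <- function(path) {
  df <- readTsv(path)
  tn <- setdiff(names(df), c("vertex", "zero"))
  m <- as.matrix(df[, tn, drop = FALSE])
  dimnames(m) <- NULL
  new("Blueprint", matrix = m, raw = m, tractNames = tn,
      vertexIds = as.integer(df$vertex), zeroRows = df$zero > 0)
}
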