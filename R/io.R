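#' Write a mesh as a legacy VTK unstructured grid
#'
#' Plain-text legacy VTK: points, tetrahedral cells, the tissue region
#' as cell data (integer codes; the level names are embedded in the
#' title line) and any number of nodal fields as point data. Node
#' indices are converted to VTK's 0-based convention on output.
#'
#' @param mesh a [tet_mesh()].
#' @param path output file.
#' @param point_data named list of numeric nodal vectors.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  levels <- unique(mesh$region)
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("tet_mesh regions=", paste(levels, collapse = "|")),
               "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  n <- nrow(mesh$nodes); nt <- nrow(mesh$tets)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(apply(format(mesh$nodes, digits = 17, trim = TRUE,
                          scientific = FALSE), 1L, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", nt, 5L * nt), con)
  writeLines(paste(4L, mesh$tets[, 1L] - 1L, mesh$tets[, 2L] - 1L,
                   mesh$tets[, 3L] - 1L, mesh$tets[, 4L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(as.character(rep(10L, nt)), con)
  writeLines(sprintf("CELL_DATA %d", nt), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$region, levels) - 1L), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (length(v) != n) stop("point data '", nm, "' has wrong length")
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(v, digits = 17, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a legacy VTK unstructured grid written by [write_vtk_mesh()]
#'
#' @param path input file.
#' @return list with `mesh` (a [tet_mesh()]) and `point_data` (named
#'   list of nodal vectors, possibly empty).
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  title <- lines[2L]
  levels <- if (grepl("regions=", title))
    strsplit(sub(".*regions=", "", title), "|", fixed = TRUE)[[1L]] else NULL
  tok_at <- function(pat) grep(pat, lines)[1L]

  ip <- tok_at("^POINTS ")
  n <- as.integer(strsplit(lines[ip], " +")[[1L]][2L])
  nodes <- matrix(scan(text = lines[(ip + 1L):(ip + n)], quiet = TRUE),
                  ncol = 3L, byrow = TRUE)

  ic <- tok_at("^CELLS ")
  nt <- as.integer(strsplit(lines[ic], " +")[[1L]][2L])
  cell_rows <- matrix(scan(text = lines[(ic + 1L):(ic + nt)], quiet = TRUE),
                      ncol = 5L, byrow = TRUE)
  if (any(cell_rows[, 1L] != 4L)) stop("non-tetrahedral cell in VTK file")
  tets <- cell_rows[, 2:5, drop = FALSE] + 1L

  region <- NULL
  ird <- grep("^SCALARS region ", lines)
  if (length(ird)) {
    codes <- as.integer(scan(text = lines[(ird[1L] + 2L):(ird[1L] + 1L + nt)],
                             quiet = TRUE))
    region <- if (!is.null(levels)) levels[codes + 1L] else as.character(codes)
  }
  mesh <- tet_mesh(nodes, tets, region = region)

  point_data <- list()
  ipd <- grep("^POINT_DATA ", lines)
  if (length(ipd)) {
    scalar_rows <- grep("^SCALARS ", lines)
    scalar_rows <- scalar_rows[scalar_rows > ipd[1L]]
    for (sr in scalar_rows) {
      nm <- strsplit(lines[sr], " +")[[1L]][2L]
      point_data[[nm]] <- scan(text = lines[(sr + 2L):(sr + 1L + n)],
                               quiet = TRUE)
    }
  }
  list(mesh = mesh, point_data = point_data)
}

#' Export a system matrix as Matrix Market plus a JSON sidecar
#'
#' The matrix goes to `<path>` in MatrixMarket coordinate format; the
#' boundary/candidate node index maps go to `<path>.json` so the
#' columns can be tied back to mesh nodes when reloading.
#'
#' @param sysmat a [build_system_matrix()] result.
#' @param path output `.mtx` file.
#' @return `path`, invisibly.
#' @export
write_system_matrix <- function(sysmat, path) {
  Matrix::writeMM(Matrix::Matrix(sysmat$A, sparse = TRUE), path)
  jsonlite::write_json(
    list(row_nodes = sysmat$row_nodes, col_nodes = sysmat$col_nodes),
    paste0(path, ".json"))
  invisible(path)
}

#' Read a system matrix written by [write_system_matrix()]
#' @param path the `.mtx` file.
#' @return a `system_matrix` object.
#' @export
read_system_matrix <- function(path) {
  A <- as.matrix(Matrix::readMM(path))
  storage.mode(A) <- "double"
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(A = A, row_nodes = as.integer(side$row_nodes),
                 col_nodes = as.integer(side$col_nodes)),
            class = "system_matrix")
}
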