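# Legacy ASCII VTK export of meshes and solutions (unstructured grid of
# VTK_HEXAHEDRON cells, optional per-element scalar field), plus a matching
# reader used for round-trip checks. Force traces go through write_trace().

#' Export a hex mesh (and optional cell field) to legacy VTK
#'
#' @param mesh A [build_mesh()] result.
#' @param path Output file path (conventionally `.vtk`).
#' @param cell_field Optional numeric vector, one value per element, written
#'   as a `CELL_DATA` scalar.
#' @param field_name Name of the scalar field.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, cell_field = NULL,
                        field_name = "shear_strain") {
  stopifnot(inherits(mesh, "hex_mesh"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "viscofit specimen mesh",
    "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", nrow(mesh$nodes))
  ), con)
  writeLines(apply(format(mesh$nodes, digits = 17, scientific = TRUE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  ne <- mesh$n_elements
  writeLines(sprintf("CELLS %d %d", ne, 9L * ne), con)
  writeLines(apply(cbind(8L, mesh$elements - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  if (!is.null(cell_field)) {
    stopifnot(length(cell_field) == ne)
    writeLines(c(
      sprintf("CELL_DATA %d", ne),
      sprintf("SCALARS %s double 1", field_name),
      "LOOKUP_TABLE default"
    ), con)
    writeLines(format(cell_field, digits = 17, scientific = TRUE, trim = TRUE),
               con)
  }
  invisible(path)
}

#' Export an FE solution: VTK with peak strain field plus force-trace CSV
#'
#' @param solution A [solve_shear()] result.
#' @param vtk_path Path for the VTK file (peak centroid engineering shear
#'   strain as cell data).
#' @param force_csv_path Optional path for the reaction force trace CSV
#'   (`time_s,force_n`).
#' @return `vtk_path`, invisibly.
#' @export
export_solution <- function(solution, vtk_path, force_csv_path = NULL) {
  stopifnot(inherits(solution, "fe_solution"))
  export_mesh(solution$mesh, vtk_path,
              cell_field = solution$element_strains_at_peak)
  if (!is.null(force_csv_path)) write_trace(solution$force_trace, force_csv_path)
  invisible(vtk_path)
}

#' Read a legacy VTK unstructured hex mesh written by [export_mesh()]
#'
#' @param path VTK file path.
#' @return List with `nodes`, `elements` (1-based), and `cell_field`
#'   (or `NULL`).
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  p_at <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[p_at], "\\s+")[[1]][2])
  nodes <- matrix(
    as.numeric(unlist(strsplit(trimws(lines[(p_at + 1L):(p_at + np)]), "\\s+"))),
    ncol = 3L, byrow = TRUE
  )
  c_at <- grep("^CELLS", lines)[1]
  ne <- as.integer(strsplit(lines[c_at], "\\s+")[[1]][2])
  cell_rows <- lapply(strsplit(trimws(lines[(c_at + 1L):(c_at + ne)]), "\\s+"),
                      as.integer)
  elements <- do.call(rbind, lapply(cell_rows, function(r) r[-1L] + 1L))
  field <- NULL
  s_at <- grep("^SCALARS", lines)
  if (length(s_at)) {
    start <- s_at[1] + 2L  # skip LOOKUP_TABLE line
    field <- as.numeric(lines[start:(start + ne - 1L)])
  }
  list(nodes = nodes, elements = elements, cell_field = field)
}
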