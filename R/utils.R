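#' Export a mesh with fields to ASCII VTU
#'
#' Minimal VTK unstructured-grid writer (tetrahedra, inline ASCII) for
#' inspecting simulation fields in ParaView.
#'
#' @param mesh a `gm_mesh`.
#' @param file output path (.vtu).
#' @param point_data named list of per-node vectors.
#' @param cell_data named list of per-element vectors.
#' @param u optional n x 3 displacement written as a vector field.
#' @return invisibly, `file`.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list(),
                      u = NULL) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) paste(formatC(x, format = "g", digits = 9), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n, '" NumberOfCells="', m, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(t(mesh$nodes)))
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(t(mesh$tets) - 1L, collapse = " "))
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(4L * seq_len(m), collapse = " "))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(10L, m), collapse = " "))
  w('</DataArray></Cells>')
  w('<PointData>')
  if (!is.null(u)) {
    w('<DataArray type="Float64" Name="u" NumberOfComponents="3" format="ascii">')
    w(num(t(u)))
    w('</DataArray>')
  }
  for (nm in names(point_data)) {
    w('<DataArray type="Float64" Name="', nm, '" format="ascii">')
    w(num(point_data[[nm]]))
    w('</DataArray>')
  }
  w('</PointData><CellData>')
  for (nm in names(cell_data)) {
    w('<DataArray type="Float64" Name="', nm, '" format="ascii">')
    w(num(cell_data[[nm]]))
    w('</DataArray>')
  }
  w('</CellData></Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}
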