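#' Export a mesh (and optional nodal fields) as legacy ASCII VTK
#'
#' Writes an unstructured-grid VTK file with quadratic-triangle cells
#' (VTK cell type 22), the element region tag as cell data, every boundary
#' node set as a 0/1 point-data mask, and any supplied nodal fields as
#' point data. The format is plain text and round-trips through
#' [read_mesh_vtk()] with tags preserved.
#'
#' @param mesh a `"bs_mesh"`.
#' @param path output file path (conventionally `.vtk`).
#' @param point_data named list of nodal vectors (e.g. `list(S = ..., P = ...)`).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list()) {
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# vtk DataFile Version 2.0",
    "biosensor unit-cell mesh (r z plane, axisymmetric)",
    "ASCII", "DATASET UNSTRUCTURED_GRID",
    paste("POINTS", nn, "double"))
  w(paste(format(mesh$nodes[, 1], digits = 17),
          format(mesh$nodes[, 2], digits = 17), "0"))
  w(paste("CELLS", ne, ne * 7))
  w(paste(6, apply(mesh$elems - 1L, 1, paste, collapse = " ")))
  w(paste("CELL_TYPES", ne))
  w(as.character(rep(22L, ne)))
  w(paste("CELL_DATA", ne),
    "SCALARS region int 1", "LOOKUP_TABLE default")
  w(as.character(mesh$region))
  w(paste("POINT_DATA", nn))
  for (nm in names(mesh$sets)) {
    mask <- integer(nn); mask[mesh$sets[[nm]]] <- 1L
    w(paste("SCALARS", paste0("set_", nm), "int 1"), "LOOKUP_TABLE default")
    w(as.character(mask))
  }
  for (nm in names(point_data)) {
    vals <- point_data[[nm]]
    stopifnot(length(vals) == nn)
    w(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default")
    w(format(vals, digits = 17))
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh_vtk()]
#'
#' Reconstructs the node coordinates, quadratic-triangle connectivity,
#' region tags and boundary node sets. The generating `geometry_spec` is
#' not stored in the file, so the returned mesh carries `spec = NULL`; any
#' additional point-data fields are returned in `$fields`.
#'
#' @param path a VTK file produced by [write_mesh_vtk()].
#' @return A `"bs_mesh"` (without `spec`).
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  find <- function(pat) grep(pat, lines, fixed = FALSE)[1]
  ip <- find("^POINTS")
  nn <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(lines[(ip + 1):(ip + nn)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  nodes <- pts[, 1:2, drop = FALSE]
  colnames(nodes) <- c("r", "z")
  ic <- find("^CELLS")
  ne <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  elems <- do.call(rbind, lapply(lines[(ic + 1):(ic + ne)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]][-1]) + 1L))
  scalar_after <- function(start, n, what) {
    idx <- grep(paste0("^SCALARS ", what, " "), lines)
    idx <- idx[idx > start][1]
    if (is.na(idx)) return(NULL)
    as.numeric(unlist(strsplit(trimws(lines[(idx + 2):(idx + 1 + n)]), "\\s+")))
  }
  icd <- find("^CELL_DATA")
  region <- as.integer(scalar_after(icd, ne, "region"))
  ipd <- find("^POINT_DATA")
  set_names <- sub("^SCALARS set_(\\S+) .*$", "\\1",
                   grep("^SCALARS set_", lines, value = TRUE))
  sets <- lapply(set_names, function(nm)
    which(scalar_after(ipd, nn, paste0("set_", nm)) == 1))
  names(sets) <- set_names
  field_names <- setdiff(
    sub("^SCALARS (\\S+) double.*$", "\\1",
        grep("^SCALARS \\S+ double", lines[ipd:length(lines)], value = TRUE)),
    character(0))
  fields <- lapply(field_names, function(nm) scalar_after(ipd, nn, nm))
  names(fields) <- field_names
  structure(list(nodes = nodes, elems = elems, region = region,
                 sets = sets, spec = NULL, fields = fields),
            class = "bs_mesh")
}

#' Write a current trace as CSV
#'
#' Two-column CSV (`t`, `i`) of the sampled dimensionless current.
#'
#' @param trace a `"current_trace"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(t = trace$times, i = trace$i_values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a current trace from CSV
#' @param path a CSV written by [write_trace_csv()].
#' @return A `"current_trace"` (unconverged; apply [steady_state_current()]).
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  current_trace(d$t, d$i)
}

# stable short hash of a configuration list (hex string)
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}
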