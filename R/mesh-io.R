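#' Write a skull mesh as a legacy VTK unstructured grid
#'
#' ASCII legacy VTK file with the tetrahedra, the region labels as cell
#' data, the base-set indicator as point data and, optionally, a nodal
#' displacement vector field.
#'
#' @param mesh A `skull_mesh`.
#' @param path Output file path (conventionally `.vtk`).
#' @param displacement Optional n x 3 displacement matrix.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, displacement = NULL) {
  stopifnot(inherits(mesh, "skull_mesh"))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "craniospring unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  utils::write.table(format(mesh$nodes, scientific = FALSE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS region int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$region)), con)
  writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS base int 1",
               "LOOKUP_TABLE default"), con)
  base <- integer(n)
  base[mesh$base_nodes] <- 1L
  writeLines(as.character(base), con)
  if (!is.null(displacement)) {
    stopifnot(nrow(displacement) == n, ncol(displacement) == 3)
    writeLines("VECTORS displacement float", con)
    utils::write.table(format(displacement, scientific = FALSE,
                              trim = TRUE), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a legacy VTK unstructured grid written by [write_vtk()]
#'
#' Minimal reader for the subset of the legacy format this package writes
#' (ASCII tetrahedral grids with region cell data and base point data).
#'
#' @param path File path.
#' @return A `skull_mesh` carrying nodes, elements, region labels and base
#'   set (generator bookkeeping such as notch pairs is not stored in VTK).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  grab <- function(tag) grep(tag, lines, fixed = TRUE)[1]
  ip <- grab("POINTS")
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  colnames(nodes) <- c("x", "y", "z")
  ic <- grab("CELLS")
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- matrix(scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE),
                  ncol = 5, byrow = TRUE)
  if (any(cells[, 1] != 4)) stop("only tetrahedral cells are supported")
  elems <- cells[, 2:5] + 1L
  storage.mode(elems) <- "integer"
  ir <- grab("SCALARS region")
  region_int <- as.integer(lines[(ir + 2):(ir + 1 + m)])
  lev <- c("frontal", "coronal_suture", "parietal", "lambdoid_suture",
           "occipital")
  ib <- grab("SCALARS base")
  base <- as.integer(lines[(ib + 2):(ib + 1 + n)])
  structure(list(nodes = nodes, elems = elems,
                 region = factor(lev[region_int], levels = lev),
                 elem_scale = rep(1, m),
                 base_nodes = which(base == 1L),
                 ref_plane = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                 outer_nodes = NULL, inner_nodes = NULL, outer_all = NULL,
                 notch_pairs = list(), cut_faces = list(), osteotomy = NULL),
            class = "skull_mesh")
}

#' Write the outer vault surface as an ASCII STL
#'
#' Triangulates the structured outer-surface grid (two triangles per quad)
#' and writes an ASCII STL of the outer surface only.
#'
#' @param mesh A `skull_mesh` with generator bookkeeping.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "skull_mesh"))
  if (is.null(mesh$node_grid)) stop("mesh lacks the structured surface grid")
  idx <- mesh$node_grid[, , 1]
  ni <- nrow(idx); nk <- ncol(idx)
  tri <- list()
  for (i in seq_len(ni - 1))
    for (k in seq_len(nk - 1)) {
      v <- c(idx[i, k], idx[i + 1, k], idx[i + 1, k + 1], idx[i, k + 1])
      tri[[length(tri) + 1]] <- v[c(1, 2, 3)]
      tri[[length(tri) + 1]] <- v[c(1, 3, 4)]
    }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid craniospring_outer", con)
  for (tr in tri) {
    p <- mesh$nodes[tr, , drop = FALSE]
    nrm <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
               (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
             (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
               (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
             (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
               (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    nl <- sqrt(sum(nrm^2))
    if (nl > 1e-12) nrm <- nrm / nl
    writeLines(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
               con)
    writeLines("    outer loop", con)
    for (j in 1:3)
      writeLines(sprintf("      vertex %g %g %g", p[j, 1], p[j, 2],
                         p[j, 3]), con)
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid craniospring_outer", con)
  invisible(path)
}
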