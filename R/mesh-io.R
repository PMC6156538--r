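#' Read and write tetrahedral meshes
#'
#' Two ASCII dialects are supported:
#' \itemize{
#'   \item \code{"vtk"}: legacy VTK unstructured grid (DATASET
#'     UNSTRUCTURED_GRID, cell type 10), 0-based connectivity in the file.
#'     Optional per-cell scalar/vector data can be attached on write via
#'     \code{cell_data}.
#'   \item \code{"dyna"}: LS-DYNA keyword deck with \code{*NODE} and
#'     \code{*ELEMENT_SOLID} cards, 1-based ids, comma- or
#'     whitespace-separated fields. Tet connectivity is stored in the
#'     8-node solid slots with nodes 5..8 repeating node 4, the usual
#'     degenerate-tet convention.
#' }
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param path file path.
#' @param dialect \code{"vtk"} or \code{"dyna"}.
#' @param cell_data optional named list of per-element vectors (scalars) or
#'   matrices (n_elem x k) written as CELL_DATA (VTK only).
#' @return \code{read_mesh} returns a \code{\link{tet_mesh}}.
#' @export
write_mesh <- function(mesh, path, dialect = c("vtk", "dyna"),
                       cell_data = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mesh, "tet_mesh"))
  if (dialect == "vtk") .write_vtk(mesh, path, cell_data)
  else .write_dyna(mesh, path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, dialect = c("vtk", "dyna")) {
  dialect <- match.arg(dialect)
  if (dialect == "vtk") .read_vtk(path) else .read_dyna(path)
}

.num_fmt <- function(x) formatC(x, format = "g", digits = 17)

.write_vtk <- function(mesh, path, cell_data = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  ne <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "fibremech tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(apply(mesh$nodes, 1L, function(r) paste(.num_fmt(r), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", ne, 5L * ne), con)
  writeLines(apply(mesh$elements - 1L, 1L, function(r)
    paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("10", ne), con)
  parts <- as.integer(factor(mesh$part_labels))
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS part int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(parts), con)
  if (!is.null(cell_data)) for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    if (is.matrix(v) && ncol(v) == 3L) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(apply(v, 1L, function(r) paste(.num_fmt(r), collapse = " ")), con)
    } else if (is.matrix(v) && ncol(v) == 9L) {
      writeLines(sprintf("TENSORS %s double", nm), con)
      writeLines(apply(v, 1L, function(r) paste(.num_fmt(r), collapse = " ")), con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(.num_fmt(as.numeric(v)), con)
    }
  }
}

.read_vtk <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("UNSTRUCTURED_GRID", lines)))
    stop("not a legacy VTK unstructured grid")
  toks <- function(s) strsplit(trimws(s), "[ \t]+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(toks(lines[ip])[2])
  pts_flat <- as.numeric(unlist(strsplit(trimws(
    paste(lines[(ip + 1):length(lines)][seq_len(.lines_for(lines, ip, 3L * np))],
          collapse = " ")), "[ \t]+")))[seq_len(3L * np)]
  nodes <- matrix(pts_flat, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  nc <- as.integer(toks(lines[ic])[2])
  cell_lines <- lines[(ic + 1):(ic + nc)]
  cells <- t(vapply(cell_lines, function(s) as.integer(toks(s)), integer(5)))
  if (any(cells[, 1] != 4L)) stop("mixed element types: only 4-node tets supported")
  it <- grep("^CELL_TYPES", lines)[1]
  types <- as.integer(lines[(it + 1):(it + nc)])
  if (any(types != 10L)) stop("mixed element types: only VTK cell type 10 supported")
  parts <- rep("part", nc)
  is_ <- grep("^SCALARS part", lines)
  if (length(is_)) parts <- as.character(lines[(is_[1] + 2):(is_[1] + 1 + nc)])
  tet_mesh(nodes, cells[, 2:5, drop = FALSE] + 1L, parts)
}

# number of lines needed to supply n whitespace tokens starting after line i0
.lines_for <- function(lines, i0, n) {
  cnt <- 0L; used <- 0L
  for (i in (i0 + 1):length(lines)) {
    used <- used + 1L
    cnt <- cnt + length(strsplit(trimws(lines[i]), "[ \t]+")[[1]])
    if (cnt >= n) break
  }
  used
}

.write_dyna <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("*KEYWORD", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%8d%16.8f%16.8f%16.8f", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT_SOLID", con)
  pid <- as.integer(factor(mesh$part_labels))
  e <- mesh$elements
  writeLines(sprintf("%8d%8d%8d%8d%8d%8d%8d%8d%8d%8d",
                     seq_len(nrow(e)), pid, e[, 1], e[, 2], e[, 3], e[, 4],
                     e[, 4], e[, 4], e[, 4], e[, 4]), con)
  writeLines("*END", con)
}

.read_dyna <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\$", lines)]
  kw <- grep("^\\*", lines)
  get_block <- function(name) {
    i <- which(toupper(lines[kw]) == name)
    if (!length(i)) return(character(0))
    from <- kw[i[1]] + 1L
    nxt <- kw[kw > kw[i[1]]]
    to <- if (length(nxt)) nxt[1] - 1L else length(lines)
    lines[from:to]
  }
  parse_fixed_or_free <- function(s, widths) {
    if (grepl(",", s)) return(as.numeric(strsplit(s, ",")[[1]]))
    if (grepl("^\\s", s) || !grepl("  ", trimws(s))) {
      # try whitespace split first; fall back to fixed width
      tk <- strsplit(trimws(s), "[ \t]+")[[1]]
      if (length(tk) >= length(widths) || nchar(s) < sum(widths))
        return(as.numeric(tk))
    }
    starts <- cumsum(c(1L, widths[-length(widths)]))
    as.numeric(substring(s, starts, starts + widths - 1L))
  }
  nb <- get_block("*NODE")
  if (!length(nb)) stop("no *NODE block found")
  nd <- t(vapply(nb, function(s) parse_fixed_or_free(s, c(8L, 16L, 16L, 16L))[1:4],
                 numeric(4)))
  ord <- order(nd[, 1])
  nodes <- nd[ord, 2:4, drop = FALSE]
  id_map <- integer(max(nd[, 1])); id_map[nd[ord, 1]] <- seq_len(nrow(nodes))
  eb <- get_block("*ELEMENT_SOLID")
  if (!length(eb)) stop("no *ELEMENT_SOLID block found")
  em <- t(vapply(eb, function(s) parse_fixed_or_free(s, rep(8L, 10L))[1:10],
                 numeric(10)))
  conn <- em[, 3:6, drop = FALSE]
  n5to8 <- em[, 7:10, drop = FALSE]
  if (any(!is.na(n5to8) & n5to8 != 0 & n5to8 != em[, 6]))
    stop("mixed element types: only degenerate-tet 8-node solids supported")
  tet_mesh(nodes, matrix(id_map[conn], ncol = 4),
           part_labels = as.character(as.integer(em[, 2])))
}
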