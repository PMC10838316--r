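TISSUE_PHYS_TAGS <- c(skin = 1L, skull = 2L, csf = 3L, gray = 4L,
                      white = 5L, lesion = 6L)

#' Write a head model to a Gmsh MSH v4.1 file
#'
#' ASCII MSH v4.1 with one volume entity and one element block per tissue,
#' tissue labels as physical groups, and the head metadata (fiducials,
#' target, affected side, conductivities, construction parameters) in a
#' `$TdcsimMeta` JSON section that standard readers skip. Coordinates are
#' RAS millimetres, origin at the model centre.
#'
#' @param head a `head_model`.
#' @param path output path ending in `.msh`.
#' @return `invisible(path)`.
#' @export
write_head_msh <- function(head, path) {
  if (!grepl("\\.msh$", path, ignore.case = TRUE)) {
    stop("format error: MSH writer requires a .msh path")
  }
  mesh <- head$mesh
  present <- intersect(names(TISSUE_PHYS_TAGS), unique(mesh$labels))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  w("$PhysicalNames", as.character(length(present)))
  for (lab in present) {
    w(sprintf("3 %d \"%s\"", TISSUE_PHYS_TAGS[[lab]], lab))
  }
  w("$EndPhysicalNames")
  bb <- apply(mesh$nodes, 2L, range)
  w("$Entities", sprintf("0 0 0 %d", length(present)))
  for (lab in present) {
    tag <- TISSUE_PHYS_TAGS[[lab]]
    w(sprintf("%d %.9g %.9g %.9g %.9g %.9g %.9g 1 %d 0",
              tag, bb[1, 1], bb[1, 2], bb[1, 3], bb[2, 1], bb[2, 2], bb[2, 3],
              tag))
  }
  w("$EndEntities")
  n <- nrow(mesh$nodes)
  first_tag <- TISSUE_PHYS_TAGS[[present[1L]]]
  w("$Nodes", sprintf("1 %d 1 %d", n, n),
    sprintf("3 %d 0 %d", first_tag, n))
  w(as.character(seq_len(n)))
  w(sprintf("%.17g %.17g %.17g",
            mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]))
  w("$EndNodes")
  m <- nrow(mesh$tets)
  w("$Elements", sprintf("%d %d 1 %d", length(present), m, m))
  offset <- 0L
  for (lab in present) {
    rows <- which(mesh$labels == lab)
    w(sprintf("3 %d 4 %d", TISSUE_PHYS_TAGS[[lab]], length(rows)))
    w(sprintf("%d %d %d %d %d",
              offset + seq_along(rows),
              mesh$tets[rows, 1L], mesh$tets[rows, 2L],
              mesh$tets[rows, 3L], mesh$tets[rows, 4L]))
    offset <- offset + length(rows)
  }
  w("$EndElements")
  meta <- list(
    coordinate_convention = "RAS mm, origin at model centre",
    fiducials = apply(head$fiducials, 1L, as.numeric, simplify = FALSE),
    target = as.numeric(head$target),
    affected_side = head$affected_side,
    conductivities = as.list(head$conductivities),
    layer_radii = head$layer_radii,
    mesh_size = head$mesh_size,
    seed = head$seed
  )
  w("$TdcsimMeta", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
    "$EndTdcsimMeta")
  invisible(path)
}

#' Read a head model from a Gmsh MSH v4.1 file
#'
#' Parses the ASCII MSH v4.1 subset produced by [write_head_msh()]
#' (single node block, tetrahedral element blocks labeled by physical
#' group). The boundary surface is reconstructed from the tetrahedra.
#'
#' @param path a `.msh` file.
#' @return a `head_model`.
#' @export
read_head_msh <- function(path) {
  if (!grepl("\\.msh$", path, ignore.case = TRUE)) {
    stop("format error: MSH reader requires a .msh path")
  }
  lines <- readLines(path)
  section <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) {
      stop(sprintf("parse error: missing $%s section", name))
    }
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(section("MeshFormat")[1L], "\\s+")[[1L]]
  if (fmt[1L] != "4.1" || fmt[2L] != "0") {
    stop("parse error: expected ASCII MSH 4.1")
  }
  pn <- section("PhysicalNames")
  n_phys <- as.integer(pn[1L])
  phys <- list()
  for (i in seq_len(n_phys)) {
    parts <- strsplit(pn[1L + i], "\\s+")[[1L]]
    phys[[parts[2L]]] <- gsub("\"", "", paste(parts[-(1:2)], collapse = " "))
  }
  nd <- section("Nodes")
  hdr <- as.integer(strsplit(nd[1L], "\\s+")[[1L]])
  n_nodes <- hdr[2L]
  tags <- as.integer(nd[2L + seq_len(n_nodes)])
  coords <- do.call(rbind, lapply(
    nd[2L + n_nodes + seq_len(n_nodes)],
    function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1L]])
  ))
  nodes <- matrix(0, n_nodes, 3L)
  nodes[tags, ] <- coords
  el <- section("Elements")
  hdr <- as.integer(strsplit(el[1L], "\\s+")[[1L]])
  n_blocks <- hdr[1L]
  pos <- 2L
  tet_rows <- list()
  labels <- character(0)
  for (b in seq_len(n_blocks)) {
    bh <- as.integer(strsplit(el[pos - 1L + 1L], "\\s+")[[1L]])
    if (length(bh) != 4L) stop("parse error: malformed element block header")
    ent_tag <- bh[2L]; etype <- bh[3L]; n_el <- bh[4L]
    if (etype != 4L) stop("parse error: only tetrahedral blocks supported")
    block <- el[pos + seq_len(n_el)]
    conn <- do.call(rbind, lapply(block, function(s) {
      as.integer(strsplit(trimws(s), "\\s+")[[1L]])[-1L]
    }))
    tet_rows[[b]] <- conn
    lab <- phys[[as.character(ent_tag)]]
    if (is.null(lab)) stop("parse error: element block without physical name")
    labels <- c(labels, rep(lab, n_el))
    pos <- pos + n_el + 1L
  }
  tets <- do.call(rbind, tet_rows)
  meta_lines <- tryCatch(section("TdcsimMeta"), error = function(e) NULL)
  mesh <- tet_mesh(nodes, tets, boundary_from_tets(
    structure(list(tets = tets), class = "tet_mesh")), labels)
  if (is.null(meta_lines)) {
    stop("parse error: missing $TdcsimMeta head metadata")
  }
  meta <- jsonlite::fromJSON(paste(meta_lines, collapse = ""))
  fid <- do.call(rbind, meta$fiducials)
  structure(
    list(
      mesh = mesh,
      conductivities = unlist(meta$conductivities),
      fiducials = fid,
      target = as.numeric(meta$target),
      affected_side = meta$affected_side,
      layer_radii = as.numeric(meta$layer_radii),
      mesh_size = meta$mesh_size,
      seed = as.integer(meta$seed)
    ),
    class = "head_model"
  )
}

#' Round-trip a head model through an on-disk mesh file
#'
#' Writes then re-reads the model; the format is inferred from the path
#' extension (currently `.msh`). Node coordinates survive exactly for
#' the full double precision written.
#'
#' @param head a `head_model`.
#' @param path destination; extension selects the format.
#' @return the re-read `head_model`.
#' @export
mesh_io_roundtrip <- function(head, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext != "msh") {
    stop(sprintf("format error: unsupported mesh extension '.%s'", ext))
  }
  write_head_msh(head, path)
  read_head_msh(path)
}

#' Export a field solution to a legacy VTK unstructured grid
#'
#' ASCII legacy VTK with the tetrahedral mesh, the nodal potential as
#' point data and the element field vectors, magnitudes and tissue
#' labels as cell data; readable by standard VTK viewers.
#'
#' @param head a `head_model`.
#' @param solution a `field_solution` (optional; mesh-only export if NULL).
#' @param path output path ending in `.vtk`.
#' @return `invisible(path)`.
#' @export
write_field_vtk <- function(head, solution = NULL, path) {
  if (!grepl("\\.vtk$", path, ignore.case = TRUE)) {
    stop("format error: VTK writer requires a .vtk path")
  }
  mesh <- head$mesh
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  w("# vtk DataFile Version 3.0",
    "tdcsim head model (RAS mm, origin at model centre)",
    "ASCII", "DATASET UNSTRUCTURED_GRID")
  w(sprintf("POINTS %d double", n))
  w(sprintf("%.17g %.17g %.17g",
            mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]))
  w(sprintf("CELLS %d %d", m, 5L * m))
  w(sprintf("4 %d %d %d %d",
            mesh$tets[, 1L] - 1L, mesh$tets[, 2L] - 1L,
            mesh$tets[, 3L] - 1L, mesh$tets[, 4L] - 1L))
  w(sprintf("CELL_TYPES %d", m))
  w(rep("10", m))
  if (!is.null(solution)) {
    w(sprintf("POINT_DATA %d", n), "SCALARS potential double 1",
      "LOOKUP_TABLE default")
    w(sprintf("%.17g", solution$potential))
    w(sprintf("CELL_DATA %d", m), "VECTORS efield double")
    w(sprintf("%.17g %.17g %.17g",
              solution$field[, 1L], solution$field[, 2L], solution$field[, 3L]))
    w("SCALARS emagnitude double 1", "LOOKUP_TABLE default")
    w(sprintf("%.17g", solution$magnitude))
  }
  w(if (is.null(solution)) sprintf("CELL_DATA %d", m) else character(0))
  w("SCALARS tissue int 1", "LOOKUP_TABLE default")
  w(as.character(TISSUE_PHYS_TAGS[mesh$labels]))
  invisible(path)
}

#' Read a legacy VTK unstructured grid written by [write_field_vtk()]
#'
#' @param path a `.vtk` file.
#' @return list with `nodes`, `tets`, `point_data` (named list),
#'   `cell_data` (named list; vectors as matrices).
#' @export
read_field_vtk <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# vtk DataFile", lines[1L])) stop("parse error: not a VTK file")
  ip <- grep("^POINTS ", lines)[1L]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
  nodes <- do.call(rbind, lapply(lines[ip + seq_len(n)], function(s) {
    as.numeric(strsplit(trimws(s), "\\s+")[[1L]])
  }))
  ic <- grep("^CELLS ", lines)[1L]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1L]][2L])
  tets <- do.call(rbind, lapply(lines[ic + seq_len(m)], function(s) {
    as.integer(strsplit(trimws(s), "\\s+")[[1L]])[-1L] + 1L
  }))
  point_data <- list()
  cell_data <- list()
  i <- 1L
  mode <- ""
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^POINT_DATA", ln)) mode <- "point"
    if (grepl("^CELL_DATA", ln)) mode <- "cell"
    if (grepl("^SCALARS ", ln)) {
      name <- strsplit(ln, "\\s+")[[1L]][2L]
      sz <- if (mode == "point") n else m
      vals <- as.numeric(lines[i + 1L + seq_len(sz)])
      if (mode == "point") point_data[[name]] <- vals else {
        cell_data[[name]] <- vals
      }
      i <- i + 1L + sz
    } else if (grepl("^VECTORS ", ln)) {
      name <- strsplit(ln, "\\s+")[[1L]][2L]
      sz <- if (mode == "point") n else m
      vals <- do.call(rbind, lapply(lines[i + seq_len(sz)], function(s) {
        as.numeric(strsplit(trimws(s), "\\s+")[[1L]])
      }))
      if (mode == "point") point_data[[name]] <- vals else {
        cell_data[[name]] <- vals
      }
      i <- i + sz
    }
    i <- i + 1L
  }
  list(nodes = nodes, tets = tets, point_data = point_data,
       cell_data = cell_data)
}
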