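# On-disk formats: legacy-ASCII VTK unstructured grids for meshes with point
# and cell data, JSON for voxel tensor grids and run manifests, YAML for
# configuration. All numeric I/O is in mm / day / MPa.

#' Write a tetrahedral mesh with fields to a legacy-ASCII VTK file
#'
#' @param mesh A `gm_mesh` object.
#' @param path Output path (`.vtk`).
#' @param point_data Named list of nodal scalar fields (or M x k matrices for
#'   vectors, written as 3-component VECTORS when k = 3).
#' @param cell_data Named list of cellwise scalar fields or ne x 6 symmetric
#'   tensor fields (written as one scalar array per component).
#' @return The path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(),
                           cell_data = list()) {
  stopifnot(inherits(mesh, "gm_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  M <- nrow(mesh$nodes); ne <- nrow(mesh$tets)
  num <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(c("# vtk DataFile Version 3.0",
               "gliomech mesh (units: mm / day / MPa)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", M, "double")), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(paste("CELLS", ne, 5 * ne), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELL_TYPES", ne), con)
  writeLines(as.character(rep(10L, ne)), con)
  dump_fields <- function(fields, nrows) {
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.matrix(f) && ncol(f) == 3L) {
        writeLines(paste("VECTORS", nm, "double"), con)
        utils::write.table(f, con, row.names = FALSE, col.names = FALSE)
      } else if (is.matrix(f) && ncol(f) == 6L) {
        for (k in 1:6) {
          writeLines(c(paste("SCALARS", paste0(nm, "_", .TENSOR_COMP[k]),
                             "double 1"), "LOOKUP_TABLE default"), con)
          writeLines(num(f[, k]), con)
        }
      } else {
        writeLines(c(paste("SCALARS", nm, "double 1"),
                     "LOOKUP_TABLE default"), con)
        writeLines(num(as.numeric(f)), con)
      }
    }
  }
  if (length(point_data)) {
    writeLines(paste("POINT_DATA", M), con)
    dump_fields(point_data, M)
  }
  if (length(cell_data)) {
    writeLines(paste("CELL_DATA", ne), con)
    dump_fields(cell_data, ne)
  }
  invisible(path)
}

#' Read a legacy-ASCII VTK tetrahedral mesh with fields
#'
#' Supports the subset written by [write_mesh_vtk()]: POINTS, CELLS of
#' tetrahedra, SCALARS and VECTORS arrays in POINT_DATA / CELL_DATA sections,
#' then validates the mesh and fields (see [validate_inputs()]).
#'
#' @param path Path to a `.vtk` file.
#' @param validate Run input validation after reading.
#' @return List with `mesh`, `point_data`, `cell_data`.
#' @export
read_mesh_vtk <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", lines[1]))
    stop("unknown format: not a legacy VTK file: ", path)
  toks_at <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  scan_block <- function(start, count, ncol_) {
    vals <- scan(text = paste(lines[start:(start + count - 1)],
                              collapse = "\n"), quiet = TRUE)
    matrix(vals, ncol = ncol_, byrow = TRUE)
  }
  i <- grep("^POINTS", lines)[1]
  M <- as.integer(toks_at(i)[2])
  nodes <- scan_block(i + 1, M, 3)
  i <- grep("^CELLS", lines)[1]
  ne <- as.integer(toks_at(i)[2])
  cells <- scan_block(i + 1, ne, 5)
  if (any(cells[, 1] != 4)) stop("only tetrahedral cells are supported")
  tets <- matrix(as.integer(cells[, 2:5] + 1L), ncol = 4)
  mesh <- gm_mesh(nodes, tets)

  read_section <- function(tag, n) {
    out <- list()
    sec <- grep(paste0("^", tag), lines)
    if (!length(sec)) return(out)
    other <- setdiff(grep("^(POINT_DATA|CELL_DATA)", lines), sec[1])
    end <- if (length(other) && any(other > sec[1]))
      min(other[other > sec[1]]) else length(lines) + 1L
    j <- sec[1] + 1L
    while (j < end) {
      tk <- toks_at(j)
      if (length(tk) && tk[1] == "SCALARS") {
        out[[tk[2]]] <- as.numeric(scan(
          text = paste(lines[(j + 2):(j + 1 + n)], collapse = "\n"),
          quiet = TRUE))
        j <- j + 2L + n
      } else if (length(tk) && tk[1] == "VECTORS") {
        out[[tk[2]]] <- scan_block(j + 1, n, 3)
        j <- j + 1L + n
      } else j <- j + 1L
    }
    out
  }
  pd <- read_section("POINT_DATA", M)
  cd <- read_section("CELL_DATA", ne)
  # reassemble 6-component tensor fields split per component
  comp_suffix <- paste0("_", .TENSOR_COMP)
  base <- unique(sub("_(xx|xy|xz|yy|yz|zz)$", "",
                     grep("_(xx|xy|xz|yy|yz|zz)$", names(cd), value = TRUE)))
  for (b in base) {
    nms <- paste0(b, comp_suffix)
    if (all(nms %in% names(cd))) {
      cd[[b]] <- do.call(cbind, cd[nms])
      colnames(cd[[b]]) <- .TENSOR_COMP
      cd[nms] <- NULL
    }
  }
  out <- list(mesh = mesh, point_data = pd, cell_data = cd)
  if (validate) validate_inputs(out)
  out
}

#' Validate solver inputs
#'
#' Checks that the mesh has no inverted/degenerate tets (reported with the
#' cell index), that all fields are finite, that any field named `chi` lies
#' in `[0, 1]`, and that 6-component cell tensor fields are positive
#' semi-definite.
#'
#' @param x A list as returned by [read_mesh_vtk()], or a `gm_mesh`.
#' @return `TRUE` invisibly; errors describe the offending field/cell.
#' @export
validate_inputs <- function(x) {
  if (inherits(x, "gm_mesh")) x <- list(mesh = x, point_data = list(),
                                        cell_data = list())
  v <- .signed_volumes(x$mesh$nodes, x$mesh$tets)
  if (any(v <= 0))
    stop("inverted or degenerate tetrahedron at cell ", which(v <= 0)[1])
  for (nm in names(x$point_data)) {
    f <- x$point_data[[nm]]
    if (!all(is.finite(f))) stop("non-finite values in point field '", nm, "'")
    if (nm == "chi" && (any(f < 0) || any(f > 1)))
      stop("field 'chi' out of range [0, 1]")
  }
  for (nm in names(x$cell_data)) {
    f <- x$cell_data[[nm]]
    if (!all(is.finite(f))) stop("non-finite values in cell field '", nm, "'")
    if (is.matrix(f) && ncol(f) == 6L) {
      for (e in seq_len(nrow(f))) {
        ev <- eigen(vec_to_sym(f[e, ]), symmetric = TRUE, only.values = TRUE)
        if (min(ev$values) < -1e-10 * max(abs(ev$values), 1))
          stop("cell tensor field '", nm, "' not positive semi-definite ",
               "at cell ", e)
      }
    }
  }
  invisible(TRUE)
}

#' Read / write a voxel tensor grid as JSON
#'
#' The grid (see [make_synthetic_dti()]) is stored with its origin, spacing,
#' dimensions, component order (xx, xy, xz, yy, yz, zz; x varying fastest)
#' and units metadata.
#'
#' @param grid A voxel grid list.
#' @param path File path (`.json`).
#' @return `write_dti_json`: the path invisibly; `read_dti_json`: the grid.
#' @export
write_dti_json <- function(grid, path) {
  jsonlite::write_json(
    list(units = "mm^2/day; coordinates mm",
         component_order = .TENSOR_COMP,
         origin = grid$origin, spacing = grid$spacing, dim = grid$dim,
         mode = grid$mode,
         tensors = as.vector(grid$tensors)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dti_json
#' @export
read_dti_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tensors <- matrix(x$tensors, ncol = 6)
  colnames(tensors) <- .TENSOR_COMP
  list(origin = x$origin, spacing = x$spacing, dim = as.integer(x$dim),
       tensors = tensors, mode = x$mode %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a simulation configuration as YAML
#'
#' @param config A [simulation_config()] object.
#' @param path File path (`.yaml`).
#' @param overrides Named list applied on top of the file's keys
#'   (unknown keys are an error).
#' @return `write_config_yaml`: the path; `read_config_yaml`: a `gm_config`.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$material <- unclass(x$material)
  x$growth <- unclass(x$growth)
  x$permeability <- unclass(x$permeability)
  x$units <- "mm / day / MPa"
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path, overrides = list()) {
  x <- yaml::read_yaml(path)
  x$units <- NULL
  known <- names(formals(simulation_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  bad2 <- setdiff(names(overrides), known)
  if (length(bad2)) stop("unknown config keys: ", paste(bad2, collapse = ", "))
  x[names(overrides)] <- overrides
  if (!is.null(x$material)) x$material <- do.call(material_params, x$material)
  if (!is.null(x$growth)) x$growth <- do.call(growth_params, x$growth)
  if (!is.null(x$permeability))
    x$permeability <- do.call(permeability_params, x$permeability)
  do.call(simulation_config, x)
}

#' Write a run manifest
#'
#' Records the configuration echo, md5 checksums of the inputs and outputs,
#' the package version and the per-step solver log, as JSON next to the run
#' outputs. Reruns with identical inputs produce identical manifests apart
#' from the timestamp field.
#'
#' @param path Output path (`.json`).
#' @param config A `gm_config`.
#' @param inputs,outputs Character vectors of file paths to checksum.
#' @param log Per-step log data.frame from [run_simulation()].
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(),
                           outputs = character(), log = NULL) {
  checksum <- function(fs) {
    fs <- fs[file.exists(fs)]
    as.list(tools::md5sum(fs))
  }
  cfgfile <- tempfile(fileext = ".yaml")
  write_config_yaml(config, cfgfile)
  manifest <- list(
    package = "gliomech",
    version = as.character(utils::packageVersion("gliomech")),
    units = "mm / day / MPa",
    timestamp = format(Sys.time(), tz = "UTC"),
    config = yaml::read_yaml(cfgfile),
    input_checksums = checksum(inputs),
    output_checksums = checksum(outputs),
    step_log = log)
  unlink(cfgfile)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
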