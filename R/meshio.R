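# Mesh and solution I/O in legacy VTK ASCII (unstructured grid, cell type
# 22 = quadratic triangle).  Region labels are written as an integer cell
# array with the label legend embedded in the dataset title line; boundary
# tags are 0/1 point arrays.  Writing is fully deterministic, so
# write -> read -> write reproduces the file byte for byte.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a mesh as a legacy VTK file
#'
#' @param mesh a `region_mesh`.
#' @param path output path (conventionally `.vtk`).
#' @param point_data optional named list of per-node numeric vectors to
#'   attach (e.g. solution fields).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, point_data = NULL) {
  stopifnot(inherits(mesh, "region_mesh"))
  region_levels <- sort(unique(mesh$region))
  legend <- paste(sprintf("%s=%d", region_levels, seq_along(region_levels)),
                  collapse = ",")
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, open = "wb")  # binary mode: exact newline control
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con, sep = "\n")
  wl("# vtk DataFile Version 3.0")
  wl(paste0("implantFE region_mesh h=", .fmt_num(mesh$target_size),
            " regions:", legend))
  wl("ASCII", "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(paste(.fmt_num(mesh$nodes[, 1L]), .fmt_num(mesh$nodes[, 2L]), "0"))
  wl(sprintf("CELLS %d %d", m, 7L * m))
  el0 <- mesh$elements - 1L
  wl(paste(6L, el0[, 1L], el0[, 2L], el0[, 3L], el0[, 4L], el0[, 5L],
           el0[, 6L]))
  wl(sprintf("CELL_TYPES %d", m))
  wl(as.character(rep(22L, m)))
  wl(sprintf("CELL_DATA %d", m))
  wl("SCALARS region int 1", "LOOKUP_TABLE default")
  wl(as.character(match(mesh$region, region_levels)))
  tags <- mesh$tags
  n_arrays <- length(tags) + length(point_data)
  if (n_arrays > 0L) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(tags)) {
      wl(sprintf("SCALARS tag_%s int 1", nm), "LOOKUP_TABLE default")
      flag <- integer(n); flag[tags[[nm]]] <- 1L
      wl(as.character(flag))
    }
    for (nm in names(point_data)) {
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      wl(.fmt_num(rep_len(point_data[[nm]], n)))
    }
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' Restores nodes, connectivity, region labels and boundary tags, and
#' rebuilds the derived boundary-edge and interface structures; the
#' round-trip is lossless.
#'
#' @param path a VTK file produced by [write_mesh()].
#' @return a `region_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path)
  fail <- function(i, why) stop("malformed mesh file at line ", i, ": ", why)
  if (!startsWith(lines[1L], "# vtk DataFile")) fail(1L, "not a VTK file")
  title <- lines[2L]
  hm <- regmatches(title, regexec("h=([0-9.eE+-]+)", title))[[1L]]
  if (length(hm) < 2L) fail(2L, "missing mesh size in title")
  h <- as.numeric(hm[2L])
  lg <- regmatches(title, regexec("regions:([^ ]+)", title))[[1L]]
  if (length(lg) < 2L) fail(2L, "missing region legend in title")
  pairs <- strsplit(strsplit(lg[2L], ",")[[1L]], "=")
  region_levels <- vapply(pairs, `[`, "", 1L)
  codes <- as.integer(vapply(pairs, `[`, "", 2L))
  region_levels <- region_levels[order(codes)]

  i <- grep("^POINTS ", lines)[1L]
  if (is.na(i)) fail(0L, "POINTS section missing")
  n <- as.integer(strsplit(lines[i], " ")[[1L]][2L])
  pts <- do.call(rbind, strsplit(lines[(i + 1L):(i + n)], " "))
  nodes <- cbind(r = as.numeric(pts[, 1L]), z = as.numeric(pts[, 2L]))

  i <- grep("^CELLS ", lines)[1L]
  m <- as.integer(strsplit(lines[i], " ")[[1L]][2L])
  cl <- do.call(rbind, strsplit(lines[(i + 1L):(i + m)], " "))
  if (any(cl[, 1L] != "6")) fail(i, "only quadratic triangles supported")
  elements <- matrix(as.integer(cl[, 2:7]) + 1L, ncol = 6L)

  i <- grep("^SCALARS region ", lines)[1L]
  if (is.na(i)) fail(0L, "region cell data missing")
  reg_codes <- as.integer(lines[(i + 2L):(i + 1L + m)])
  if (any(reg_codes < 1L | reg_codes > length(region_levels)))
    fail(i, paste0("unknown region label code ",
                   reg_codes[which(reg_codes < 1L |
                                     reg_codes > length(region_levels))[1L]]))
  region <- region_levels[reg_codes]

  tag_heads <- grep("^SCALARS tag_", lines)
  tags <- list()
  for (th in tag_heads) {
    nm <- sub("^SCALARS tag_([^ ]+) .*$", "\\1", lines[th])
    flag <- as.integer(lines[(th + 2L):(th + 1L + n)])
    tags[[nm]] <- which(flag == 1L)
  }

  # rebuild edge bookkeeping from connectivity, then restore the tag node
  # sets exactly as read
  nv <- max(elements[, 1:3])
  ea <- cbind(elements[, 1L], elements[, 2L], elements[, 3L])
  eb <- cbind(elements[, 2L], elements[, 3L], elements[, 1L])
  key <- as.numeric(pmin(ea, eb)) * (nv + 1) + as.numeric(pmax(ea, eb))
  core <- list(nodes = nodes, elements = elements, region = region,
               edge_key = matrix(match(key, unique(key)), ncol = 3L),
               n_corner_nodes = nv)
  tag_defs <- lapply(tags, function(set) {
    in_set <- logical(nrow(nodes)); in_set[set] <- TRUE
    function(r, z) in_set
  })
  mesh <- .finalize_mesh(core, h, tag_defs)
  mesh$tags[names(tags)] <- tags
  mesh
}

#' Export a solution as a VTK file with field arrays
#'
#' Writes the mesh plus nodal displacement components, von Mises stress and
#' equivalent strain (region-maximum value at nodes shared by several
#' regions, since VTK point arrays hold one value per node).
#'
#' @param solution an `fe_solution`.
#' @param mesh the `region_mesh` it was solved on.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(solution, mesh, path) {
  stopifnot(inherits(solution, "fe_solution"))
  n <- nrow(mesh$nodes)
  vm <- numeric(n); eq <- numeric(n)
  agg <- solution$nodal
  o <- order(agg$node, agg$von_mises)  # last (max) wins below
  for (i in o) {
    vm[agg$node[i]] <- max(vm[agg$node[i]], agg$von_mises[i])
    eq[agg$node[i]] <- max(eq[agg$node[i]], agg$eq_strain[i])
  }
  write_mesh(mesh, path, point_data = list(
    u_r = solution$u[, 1L], u_z = solution$u[, 2L],
    von_mises = vm, eq_strain = eq))
}

#' Write a per-region field summary as CSV
#'
#' @param solution an `fe_solution`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_summary <- function(solution, path) {
  utils::write.csv(summary(solution), path, row.names = FALSE)
  invisible(path)
}
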