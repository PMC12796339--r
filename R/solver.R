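# Axisymmetric small-strain linear elasticity on quadratic-triangle meshes.
#
# Strain ordering throughout: (eps_rr, eps_zz, eps_tt, gamma_rz) with
# engineering shear; stresses (sig_rr, sig_zz, sig_tt, tau_rz) in MPa.
# Degrees of freedom are interleaved: node i owns dofs (2i-1, 2i) = (u_r,
# u_z).  Compression is negative internally; postprocessing reports
# magnitudes.  The assembled system is solved by direct sparse Cholesky
# factorization (Matrix), so results are deterministic for a fixed mesh.

# 4x4 isotropic elasticity matrix, axisymmetric, engineering shear
.elastic_D <- function(E, nu) {
  f <- E / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 4, 4)
  D[1, 1] <- D[2, 2] <- D[3, 3] <- f * (1 - nu)
  D[1, 2] <- D[2, 1] <- D[1, 3] <- D[3, 1] <- D[2, 3] <- D[3, 2] <- f * nu
  D[4, 4] <- f * (1 - 2 * nu) / 2
  D
}

# degree-5 symmetric Gauss rule on the unit triangle (barycentric, weights
# summing to one); interior points only, so the hoop term 1/r is never
# evaluated on the axis
.TRI_GAUSS <- local({
  a <- 0.059715871789770; b <- 0.470142064105115
  c <- 0.797426985353087; d <- 0.101286507323456
  w1 <- 0.225; w2 <- 0.132394152788506; w3 <- 0.125939180544827
  L <- rbind(c(1/3, 1/3, 1/3),
             c(a, b, b), c(b, a, b), c(b, b, a),
             c(c, d, d), c(d, c, d), c(d, d, c))
  list(L = L, w = c(w1, w2, w2, w2, w3, w3, w3))
})

# quadratic shape values and barycentric derivatives at one (L1,L2,L3)
.shape_quadratic <- function(L1, L2, L3) {
  N <- c(L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1),
         4 * L1 * L2, 4 * L2 * L3, 4 * L3 * L1)
  dL <- rbind(  # rows: d/dL1, d/dL2, d/dL3 for the 6 shape functions
    c(4 * L1 - 1, 0, 0, 4 * L2, 0, 4 * L3),
    c(0, 4 * L2 - 1, 0, 4 * L1, 4 * L3, 0),
    c(0, 0, 4 * L3 - 1, 0, 4 * L2, 4 * L1))
  list(N = N, dL = dL)
}

# per-element corner geometry for a subset of elements
.element_geometry <- function(mesh, idx) {
  el <- mesh$elements[idx, , drop = FALSE]
  r <- matrix(mesh$nodes[el[, 1:3], 1L], ncol = 3L)
  z <- matrix(mesh$nodes[el[, 1:3], 2L], ncol = 3L)
  b <- cbind(z[, 2L] - z[, 3L], z[, 3L] - z[, 1L], z[, 1L] - z[, 2L])
  cc <- cbind(r[, 3L] - r[, 2L], r[, 1L] - r[, 3L], r[, 2L] - r[, 1L])
  A <- 0.5 * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L])
  A <- 0.5 * ((r[, 2L] - r[, 1L]) * (z[, 3L] - z[, 1L]) -
                (r[, 3L] - r[, 1L]) * (z[, 2L] - z[, 1L]))
  list(el = el, r = r, z = z, b = b, cc = cc, A = A)
}

# B-matrix rows at one barycentric point for all elements of `geom`:
# list of four (n_el x 12) matrices (eps_rr, eps_zz, eps_tt, gamma_rz).
# Nodes with r below `axis_tol` get the axis limit eps_tt = eps_rr.
.b_rows_at <- function(geom, L, axis_tol = 0) {
  sh <- .shape_quadratic(L[1L], L[2L], L[3L])
  n_el <- nrow(geom$b)
  inv2A <- 1 / (2 * geom$A)
  rg <- geom$r %*% L
  Brr <- Bzz <- Btt <- matrix(0, n_el, 12L)
  Grz_r <- matrix(0, n_el, 12L)  # gamma row entries
  for (i in 1:6) {
    dNdr <- (sh$dL[1L, i] * geom$b[, 1L] + sh$dL[2L, i] * geom$b[, 2L] +
               sh$dL[3L, i] * geom$b[, 3L]) * inv2A
    dNdz <- (sh$dL[1L, i] * geom$cc[, 1L] + sh$dL[2L, i] * geom$cc[, 2L] +
               sh$dL[3L, i] * geom$cc[, 3L]) * inv2A
    cr <- 2L * i - 1L; cz <- 2L * i
    Brr[, cr] <- dNdr
    Bzz[, cz] <- dNdz
    Grz_r[, cr] <- dNdz
    Grz_r[, cz] <- dNdr
    if (axis_tol > 0) {
      on_axis <- rg[, 1L] < axis_tol
      Btt[, cr] <- ifelse(on_axis, dNdr, sh$N[i] / rg[, 1L])
    } else {
      Btt[, cr] <- sh$N[i] / rg[, 1L]
    }
  }
  list(Brr = Brr, Bzz = Bzz, Btt = Btt, Brz = Grz_r, rg = as.vector(rg))
}

# unit-modulus stiffness triplets for the elements of one region
.region_unit_stiffness <- function(mesh, region, nu) {
  idx <- which(mesh$region == region)
  if (length(idx) == 0L) stop("mesh has no elements in region '", region, "'")
  geom <- .element_geometry(mesh, idx)
  D <- .elastic_D(1, nu)
  n_el <- length(idx)
  Ke <- matrix(0, n_el, 144L)
  gauss <- .TRI_GAUSS
  for (g in seq_along(gauss$w)) {
    B <- .b_rows_at(geom, gauss$L[g, ])
    wg <- gauss$w[g] * geom$A * (2 * pi) * B$rg
    rows <- list(B$Brr, B$Bzz, B$Btt, B$Brz)
    DB <- vector("list", 4L)
    for (i in 1:4) {
      acc <- matrix(0, n_el, 12L)
      for (k in 1:4) if (D[i, k] != 0) acc <- acc + D[i, k] * rows[[k]]
      DB[[i]] <- acc
    }
    for (a in 1:12) {
      base_q <- (a - 1L) * 12L
      for (i in 1:4) {
        Bia <- rows[[i]][, a] * wg
        Ke[, (base_q + 1L):(base_q + 12L)] <-
          Ke[, (base_q + 1L):(base_q + 12L)] + Bia * DB[[i]]
      }
    }
  }
  edof <- matrix(0L, n_el, 12L)
  for (j in 1:6) {
    edof[, 2L * j - 1L] <- 2L * geom$el[, j] - 1L
    edof[, 2L * j] <- 2L * geom$el[, j]
  }
  ndof <- 2L * nrow(mesh$nodes)
  ii <- edof[, rep(1:12, each = 12L)]
  jj <- edof[, rep(1:12, times = 12L)]
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                       x = as.vector(Ke), dims = c(ndof, ndof))
}

#' Precompute unit-modulus region stiffness matrices
#'
#' The elasticity matrix is linear in Young's modulus at fixed Poisson
#' ratio, so the global stiffness is `sum_r E_r * K_r` over regions.  For a
#' design sweep where only the shell modulus changes across configurations,
#' computing the per-region `K_r` once per mesh removes almost all assembly
#' cost.
#'
#' @param mesh a `region_mesh`.
#' @param nus named numeric vector/list: Poisson ratio per region.
#' @return named list of sparse unit-modulus stiffness matrices.
#' @export
precompute_stiffness <- function(mesh, nus) {
  regions <- sort(unique(mesh$region))
  missing_nu <- setdiff(regions, names(nus))
  if (length(missing_nu) > 0L)
    stop("no Poisson ratio given for region(s): ",
         paste(missing_nu, collapse = ", "))
  out <- lapply(regions, function(rg)
    .region_unit_stiffness(mesh, rg, as.numeric(nus[[rg]])))
  names(out) <- regions
  out
}

#' Axial load case
#'
#' @param total_axial_force total compressive axial force in N (positive;
#'   applied downward as a uniform traction over the `load_tag` surface).
#' @param load_tag boundary tag carrying the traction.
#' @param fixed_tags tags whose nodes are fully fixed (both components).
#' @param roller_tags tags whose nodes are fixed axially only (u_z = 0).
#' @return an object of class `load_case`.
#' @export
#' @examples
#' load_case(250)  # the study's bite-force load case
load_case <- function(total_axial_force = 250, load_tag = "load_top",
                      fixed_tags = "fixed_lateral",
                      roller_tags = character(0)) {
  if (!is.numeric(total_axial_force) || length(total_axial_force) != 1L ||
      total_axial_force < 0)
    stop("total_axial_force must be a single non-negative force in N")
  structure(list(total_axial_force = total_axial_force, load_tag = load_tag,
                 fixed_tags = fixed_tags, roller_tags = roller_tags),
            class = "load_case")
}

# consistent nodal forces for a uniform axial traction over an edge set
.traction_forces <- function(mesh, edges, total_force) {
  ndof <- 2L * nrow(mesh$nodes)
  f <- numeric(ndof)
  if (nrow(edges) == 0L || total_force == 0) return(f)
  r1 <- mesh$nodes[edges[, 1L], 1L]; z1 <- mesh$nodes[edges[, 1L], 2L]
  r2 <- mesh$nodes[edges[, 2L], 1L]; z2 <- mesh$nodes[edges[, 2L], 2L]
  len <- sqrt((r2 - r1)^2 + (z2 - z1)^2)
  area <- 2 * pi * (r1 + r2) / 2 * len       # exact for straight edges
  t_z <- -total_force / sum(area)            # compression: downward
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5 / 9, 8 / 9, 5 / 9)
  for (g in 1:3) {
    xi <- gx[g]
    N <- c(xi * (xi - 1) / 2, xi * (xi + 1) / 2, 1 - xi^2)
    rgp <- r1 * (1 - xi) / 2 + r2 * (1 + xi) / 2
    w <- gw[g] * len / 2 * 2 * pi * rgp * t_z
    for (i in 1:3) {
      zdof <- 2L * edges[, i]
      f[zdof] <- f[zdof] + N[i] * w
    }
  }
  f
}

# collect constrained dofs (indices + prescribed values)
.dirichlet_dofs <- function(mesh, load, dirichlet = NULL) {
  idx <- integer(0); val <- numeric(0)
  add <- function(dofs, values) {
    idx <<- c(idx, dofs); val <<- c(val, values)
  }
  for (tg in load$fixed_tags) {
    nd <- mesh$tags[[tg]]
    if (is.null(nd)) stop("fixed tag '", tg, "' not present in the mesh")
    add(c(2L * nd - 1L, 2L * nd), numeric(2L * length(nd)))
  }
  for (tg in load$roller_tags) {
    nd <- mesh$tags[[tg]]
    if (is.null(nd)) stop("roller tag '", tg, "' not present in the mesh")
    add(2L * nd, numeric(length(nd)))
  }
  axis_nodes <- which(abs(mesh$nodes[, 1L]) < .COORD_TOL)
  add(2L * axis_nodes - 1L, numeric(length(axis_nodes)))
  if (!is.null(dirichlet)) {
    nd <- dirichlet$nodes
    if (!is.null(dirichlet$ur)) add(2L * nd - 1L, rep_len(dirichlet$ur,
                                                          length(nd)))
    if (!is.null(dirichlet$uz)) add(2L * nd, rep_len(dirichlet$uz,
                                                     length(nd)))
  }
  keep <- !duplicated(idx)
  list(idx = idx[keep], val = val[keep])
}

#' Assemble and solve the linear-elastic boundary-value problem
#'
#' Assembles the axisymmetric stiffness from per-region isotropic
#' materials, applies the axial load as a uniform traction over the load
#' tag (integrating exactly to the total force), fixes the constrained
#' tags, solves by sparse Cholesky factorization, and recovers nodal
#' strain/stress fields with region-wise nodal averaging (no averaging
#' across material boundaries, so interface discontinuities are kept).
#'
#' @param mesh a `region_mesh`.
#' @param materials named list of [isotropic_material()] per mesh region.
#' @param load a [load_case()].
#' @param stiffness optional precomputed list from [precompute_stiffness()]
#'   (Poisson ratios must match `materials`).
#' @param dirichlet optional list `(nodes, ur, uz)` of additional prescribed
#'   displacements (used e.g. by patch tests); `NULL` entries leave the
#'   component free.
#' @return an object of class `fe_solution`: displacements `u` (mm),
#'   region-wise nodal field table `nodal`, the axial equilibrium residual
#'   (N), and the load case.
#' @export
assemble_and_solve <- function(mesh, materials, load = load_case(),
                               stiffness = NULL, dirichlet = NULL) {
  stopifnot(inherits(mesh, "region_mesh"), inherits(load, "load_case"))
  regions <- sort(unique(mesh$region))
  missing_mat <- setdiff(regions, names(materials))
  if (length(missing_mat) > 0L)
    stop("no material given for region(s): ",
         paste(missing_mat, collapse = ", "))
  if (is.null(stiffness)) {
    nus <- lapply(materials, `[[`, "nu")
    stiffness <- precompute_stiffness(mesh, nus)
  }
  K <- NULL
  for (rg in regions) {
    Kr <- materials[[rg]]$E * stiffness[[rg]]
    K <- if (is.null(K)) Kr else K + Kr
  }
  edges <- mesh$edge_sets[[load$load_tag]]
  if (is.null(edges))
    stop("load tag '", load$load_tag, "' not present in the mesh")
  f <- .traction_forces(mesh, edges, load$total_axial_force)
  bc <- .dirichlet_dofs(mesh, load, dirichlet)
  ndof <- 2L * nrow(mesh$nodes)
  free <- setdiff(seq_len(ndof), bc$idx)
  u <- numeric(ndof)
  u[bc$idx] <- bc$val
  rhs <- f[free]
  if (any(bc$val != 0))
    rhs <- rhs - as.vector(K[free, bc$idx, drop = FALSE] %*% bc$val)
  if (length(free) > 0L) {
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    u[free] <- as.vector(Matrix::solve(Kff, rhs, sparse = TRUE))
  }
  # axial equilibrium audit: reactions at constrained z-dofs vs applied load
  resid_vec <- as.vector(K %*% u) - f
  zfixed <- bc$idx[bc$idx %% 2L == 0L]
  residual <- abs(sum(resid_vec[zfixed]) - load$total_axial_force)
  if (load$total_axial_force == 0) residual <- abs(sum(resid_vec[zfixed]))

  nodal <- .recover_fields(mesh, materials, u)
  structure(list(
    u = matrix(u, ncol = 2L, byrow = TRUE,
               dimnames = list(NULL, c("u_r", "u_z"))),
    nodal = nodal, residual = residual, load = load,
    materials = materials, target_size = mesh$target_size
  ), class = "fe_solution")
}

# nodal strain/stress recovery with region-wise averaging
.recover_fields <- function(mesh, materials, u) {
  # element-node barycentric coordinates (corners then midsides)
  pts <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5))
  regions <- sort(unique(mesh$region))
  out <- vector("list", length(regions))
  for (ri in seq_along(regions)) {
    rg <- regions[ri]
    idx <- which(mesh$region == rg)
    geom <- .element_geometry(mesh, idx)
    el <- geom$el
    edof <- matrix(0L, length(idx), 12L)
    for (j in 1:6) {
      edof[, 2L * j - 1L] <- 2L * el[, j] - 1L
      edof[, 2L * j] <- 2L * el[, j]
    }
    ue <- matrix(u[edof], ncol = 12L)
    nodes_acc <- integer(0)
    eps_acc <- NULL
    for (p in 1:6) {
      B <- .b_rows_at(geom, pts[p, ], axis_tol = .COORD_TOL)
      eps <- cbind(rowSums(B$Brr * ue), rowSums(B$Bzz * ue),
                   rowSums(B$Btt * ue), rowSums(B$Brz * ue))
      nodes_acc <- c(nodes_acc, el[, p])
      eps_acc <- rbind(eps_acc, eps)
    }
    avg <- rowsum(eps_acc, group = nodes_acc, reorder = TRUE)
    cnt <- as.vector(rowsum(rep(1, length(nodes_acc)), group = nodes_acc,
                            reorder = TRUE))
    avg <- avg / cnt
    nid <- as.integer(rownames(avg))
    D <- .elastic_D(materials[[rg]]$E, materials[[rg]]$nu)
    sig <- avg %*% t(D)
    nu <- materials[[rg]]$nu
    out[[ri]] <- data.frame(
      node = nid, region = rg,
      r = mesh$nodes[nid, 1L], z = mesh$nodes[nid, 2L],
      eps_rr = avg[, 1L], eps_zz = avg[, 2L], eps_tt = avg[, 3L],
      gamma_rz = avg[, 4L],
      sig_rr = sig[, 1L], sig_zz = sig[, 2L], sig_tt = sig[, 3L],
      tau_rz = sig[, 4L],
      von_mises = von_mises(sig),
      eq_strain = equivalent_strain(avg, nu))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' von Mises equivalent stress
#'
#' `sqrt(0.5 * ((s_rr - s_zz)^2 + (s_zz - s_tt)^2 + (s_tt - s_rr)^2)
#'  + 3 * tau_rz^2)` for the axisymmetric stress tensor.
#'
#' @param stress numeric vector of length 4 `(sig_rr, sig_zz, sig_tt,
#'   tau_rz)` or an n x 4 matrix of such rows, in MPa.
#' @return von Mises stress (MPa), one value per row.
#' @export
#' @examples
#' von_mises(c(0, -8.84, 0, 0))  # uniaxial: |sigma|
von_mises <- function(stress) {
  if (is.null(dim(stress))) stress <- matrix(stress, ncol = 4L)
  unname(sqrt(0.5 * ((stress[, 1L] - stress[, 2L])^2 +
                       (stress[, 2L] - stress[, 3L])^2 +
                       (stress[, 3L] - stress[, 1L])^2) +
                3 * stress[, 4L]^2))
}

#' Equivalent (von Mises type) elastic strain
#'
#' Scalarizes the strain tensor as
#' `1/(1 + nu) * sqrt(0.5 * ((e_rr - e_zz)^2 + (e_zz - e_tt)^2 +
#' (e_tt - e_rr)^2) + 0.75 * gamma_rz^2)`.
#' The `1/(1 + nu)` normalization (the material's own Poisson ratio as the
#' effective ratio) makes a uniaxial stress state return exactly its axial
#' strain magnitude, matching the convention of mainstream commercial FE
#' codes.  An alternative scalarization by maximum absolute principal
#' strain is available via `method = "max_principal"`.
#'
#' @param strain numeric vector of length 4 `(eps_rr, eps_zz, eps_tt,
#'   gamma_rz)` (engineering shear) or an n x 4 matrix.
#' @param nu Poisson ratio of the material the strain lives in.
#' @param method `"von_mises"` (default) or `"max_principal"`.
#' @return dimensionless equivalent strain, one value per row.
#' @export
#' @examples
#' equivalent_strain(c(-0.3e-3, 1e-3, -0.3e-3, 0), nu = 0.3)  # 1e-3
equivalent_strain <- function(strain, nu, method = c("von_mises",
                                                     "max_principal")) {
  method <- match.arg(method)
  if (is.null(dim(strain))) strain <- matrix(strain, ncol = 4L)
  if (method == "von_mises") {
    dev <- 0.5 * ((strain[, 1L] - strain[, 2L])^2 +
                    (strain[, 2L] - strain[, 3L])^2 +
                    (strain[, 3L] - strain[, 1L])^2) +
      0.75 * strain[, 4L]^2
    sqrt(dev) / (1 + nu)
  } else {
    # in-plane principal strains plus the hoop strain
    m <- (strain[, 1L] + strain[, 2L]) / 2
    rad <- sqrt(((strain[, 1L] - strain[, 2L]) / 2)^2 +
                  (strain[, 4L] / 2)^2)
    pmax(abs(m + rad), abs(m - rad), abs(strain[, 3L]))
  }
}

#' Axial equilibrium residual of a solved case
#'
#' Absolute difference between the total axial reaction at the constrained
#' boundaries and the applied axial load, in N; the pipeline treats
#' `residual <= 1e-6 * F` as equilibrium.
#'
#' @param solution an `fe_solution`.
#' @param load ignored; the solution carries its own load case.
#' @return residual force in N.
#' @export
reaction_check <- function(solution, load = NULL) {
  stopifnot(inherits(solution, "fe_solution"))
  solution$residual
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf(
    "<fe_solution> %d nodes, axial load %g N, equilibrium residual %.3g N\n",
    nrow(x$u), x$load$total_axial_force, x$residual))
  vm <- tapply(x$nodal$von_mises, x$nodal$region, max)
  cat("  max von Mises per region (MPa):\n")
  print(round(vm, 3))
  invisible(x)
}

#' @export
summary.fe_solution <- function(object, ...) {
  s <- do.call(rbind, lapply(split(object$nodal, object$nodal$region),
                             function(d) data.frame(
    region = d$region[1L],
    max_von_mises_MPa = max(d$von_mises),
    max_eq_strain_ue = max(d$eq_strain) * 1e6,
    max_displacement_mm = max(sqrt(object$u[d$node, 1L]^2 +
                                     object$u[d$node, 2L]^2)))))
  rownames(s) <- NULL
  s
}

#' Plot the von Mises field of a solution
#'
#' Flat-shaded triangle plot of the region-averaged nodal von Mises stress
#' (element means), on the r-z half-section.
#'
#' @param x an `fe_solution`.
#' @param mesh the `region_mesh` the solution was computed on.
#' @param field one of `"von_mises"` or `"eq_strain"`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the per-element plotted values.
#' @export
plot.fe_solution <- function(x, mesh, field = c("von_mises", "eq_strain"),
                             ...) {
  field <- match.arg(field)
  key <- paste(x$nodal$node, x$nodal$region)
  vals <- x$nodal[[field]]
  el <- mesh$elements
  elv <- matrix(vals[match(paste(el[, 1:3], rep(mesh$region, 3L)), key)],
                ncol = 3L)
  ev <- rowMeans(elv)
  pal <- grDevices::hcl.colors(64, "viridis")
  col <- pal[cut(ev, 64, labels = FALSE)]
  graphics::plot(NA, xlim = range(mesh$nodes[, 1L]),
                 ylim = range(mesh$nodes[, 2L]), asp = 1,
                 xlab = "r (mm)", ylab = "z (mm)", ...)
  for (e in seq_len(nrow(el)))
    graphics::polygon(mesh$nodes[el[e, 1:3], 1L],
                      mesh$nodes[el[e, 1:3], 2L],
                      col = col[e], border = NA)
  invisible(ev)
}
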