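# Axisymmetric elasticity solver: analytic oracles and invariances.

test_that("patch test: a uniform strain state is reproduced to machine precision", {
  # de-structure the grid so the test does not rely on mesh regularity
  # the axisymmetric uniform-strain state: u_r = a*r, u_z = b*z + c
  # (eps_rr = eps_tt = a, eps_zz = b; a uniform shear state is not an
  # equilibrium state in axisymmetry, so it is not part of the patch)
  mesh <- jitter_mesh(make_uniaxial_bar_fixture(3, 6, 0.75), amount = 0.2)
  expect_true(validate_mesh(mesh))
  a <- 2.3e-4; b <- -4.1e-4; cc <- 5e-4
  exact <- function(r, z) cbind(a * r, b * z + cc)
  bnd <- rect_boundary_nodes(mesh)
  ub <- exact(mesh$nodes[bnd, 1], mesh$nodes[bnd, 2])
  mats <- list(bar = isotropic_material("bar", 13000, 0.3))
  sol <- assemble_and_solve(
    mesh, mats, load_case(0, fixed_tags = character(0)),
    dirichlet = list(nodes = bnd, ur = ub[, 1], uz = ub[, 2]))
  ue <- exact(mesh$nodes[, 1], mesh$nodes[, 2])
  expect_lt(max(abs(sol$u - ue)), 1e-12 * max(abs(ue)))
  # recovered strains are the prescribed uniform state
  expect_equal(unique(round(sol$nodal$eps_rr, 12)), a)
  expect_equal(unique(round(sol$nodal$eps_tt, 12)), a)
  expect_equal(unique(round(sol$nodal$eps_zz, 12)), b)
  expect_equal(unique(round(sol$nodal$gamma_rz, 12)), 0)
})

test_that("uniaxial bar carries sigma_zz = -F/A uniformly", {
  mesh <- make_uniaxial_bar_fixture(3, 13, 1)
  mats <- list(bar = isotropic_material("bar", 120000, 0.3))
  lc <- load_case(250, fixed_tags = character(0),
                  roller_tags = "fixed_bottom")
  sol <- assemble_and_solve(mesh, mats, lc)
  s_exact <- -250 / (pi * 3^2)
  expect_lt(max(abs(sol$nodal$sig_zz / s_exact - 1)), 1e-3)
  expect_lt(max(abs(sol$nodal$von_mises / abs(s_exact) - 1)), 1e-3)
  expect_lt(reaction_check(sol), 1e-6 * 250)
  # equivalent strain equals the axial strain magnitude (uniaxial identity)
  expect_equal(max(sol$nodal$eq_strain), abs(s_exact) / 120000,
               tolerance = 1e-6)
})

test_that("zero load gives the zero solution and the response is linear", {
  mesh <- make_uniaxial_bar_fixture(2, 5, 0.5)
  mats <- list(bar = isotropic_material("bar", 50000, 0.25))
  lc0 <- load_case(0, fixed_tags = "fixed_bottom")
  expect_equal(max(abs(assemble_and_solve(mesh, mats, lc0)$u)), 0)
  s1 <- assemble_and_solve(mesh, mats,
                           load_case(100, fixed_tags = "fixed_bottom"))
  s2 <- assemble_and_solve(mesh, mats,
                           load_case(200, fixed_tags = "fixed_bottom"))
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-12)
  expect_equal(s2$nodal$von_mises, 2 * s1$nodal$von_mises,
               tolerance = 1e-10)
})

test_that("bonded concentric cylinders partition the load by axial stiffness", {
  E1 <- 120000; E2 <- 10000
  mesh <- make_concentric_cylinder_fixture(1, 3, 13, 0.5)
  mats <- list(core = isotropic_material("core", E1, 0.3),
               shell = isotropic_material("shell", E2, 0.3))
  lc <- load_case(250, fixed_tags = character(0),
                  roller_tags = "fixed_bottom")
  sol <- assemble_and_solve(mesh, mats, lc)
  A1 <- pi; A2 <- 8 * pi
  den <- E1 * A1 + E2 * A2
  # fully developed partition at the plane where plane sections are enforced
  bot <- sol$nodal[abs(sol$nodal$z) < 1e-9, ]
  s_core <- mean(bot$sig_zz[bot$region == "core"])
  s_shell <- mean(bot$sig_zz[bot$region == "shell"])
  expect_equal(s_core, -E1 * 250 / den, tolerance = 5e-3)
  expect_equal(s_shell, -E2 * 250 / den, tolerance = 5e-3)
  # equal axial strain in both materials there
  expect_equal(mean(bot$eps_zz[bot$region == "core"]),
               mean(bot$eps_zz[bot$region == "shell"]), tolerance = 1e-2)
  expect_lt(reaction_check(sol), 1e-6 * 250)
})

test_that("solution is invariant under node renumbering", {
  mesh <- make_concentric_cylinder_fixture(1, 3, 6, 1)
  mats <- list(core = isotropic_material("core", 100000, 0.3),
               shell = isotropic_material("shell", 5000, 0.3))
  lc <- load_case(100, fixed_tags = "fixed_bottom")
  s1 <- assemble_and_solve(mesh, mats, lc)
  pm <- permute_mesh_nodes(mesh, seed = 3)
  expect_true(validate_mesh(pm))
  s2 <- assemble_and_solve(pm, mats, lc)
  expect_equal(max(s2$nodal$von_mises), max(s1$nodal$von_mises),
               tolerance = 1e-9)
  expect_equal(sort(s2$nodal$eq_strain), sort(s1$nodal$eq_strain),
               tolerance = 1e-9)
})

test_that("von Mises matches the principal-stress formula", {
  expect_equal(von_mises(c(5, 5, 5, 0)), 0)
  expect_equal(von_mises(c(0, -8.842, 0, 0)), 8.842)
  # generic state cross-checked through an eigen-decomposition oracle
  s <- c(10, -5, 3, 4)
  full <- matrix(c(s[1], s[4], 0,
                   s[4], s[2], 0,
                   0, 0, s[3]), 3, 3)
  p <- eigen(full, symmetric = TRUE, only.values = TRUE)$values
  vm_oracle <- sqrt(0.5 * ((p[1] - p[2])^2 + (p[2] - p[3])^2 +
                             (p[3] - p[1])^2))
  expect_equal(von_mises(s), vm_oracle)
  # matrix input vectorizes
  expect_equal(von_mises(rbind(s, s)), rep(vm_oracle, 2))
})

test_that("equivalent strain honors its normalization and homogeneity", {
  expect_equal(equivalent_strain(c(1e-3, 1e-3, 1e-3, 0), 0.3), 0)
  # uniaxial stress state returns the axial strain
  eps <- 1e-3; nu <- 0.3
  uni <- c(-nu * eps, eps, -nu * eps, 0)
  expect_equal(equivalent_strain(uni, nu), eps)
  expect_equal(equivalent_strain(2 * uni, nu),
               2 * equivalent_strain(uni, nu))
  # alternative scalarization: max principal strain
  expect_equal(equivalent_strain(uni, nu, method = "max_principal"), eps)
  expect_gt(equivalent_strain(c(0, 0, 0, 2e-3), nu), 0)
})

test_that("missing materials and constraints are diagnosed", {
  mesh <- make_concentric_cylinder_fixture(1, 2, 4, 1)
  mats <- list(core = isotropic_material("core", 1000, 0.3))
  expect_error(assemble_and_solve(mesh, mats,
                                  load_case(10, fixed_tags = "fixed_bottom")),
               "shell")
  mats$shell <- isotropic_material("shell", 1000, 0.3)
  expect_error(assemble_and_solve(mesh, mats,
                                  load_case(10, fixed_tags = "nowhere")),
               "nowhere")
  expect_error(assemble_and_solve(mesh, mats,
                                  load_case(10, load_tag = "nope",
                                            fixed_tags = "fixed_bottom")),
               "nope")
})
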