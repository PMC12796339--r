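# Rule-of-mixtures homogenization of the porous HA/Ti shell.

test_that("dense Voigt/Reuss bounds reproduce the published design table", {
  # published values, verified self-consistent with the mixture rules
  expect_equal(voigt_modulus(composite_shell_spec(10, 90)), 115000)
  expect_equal(voigt_modulus(composite_shell_spec(50, 50)), 95000)
  expect_equal(reuss_modulus(composite_shell_spec(10, 90)), 112000,
               tolerance = 1e-3)
  expect_equal(reuss_modulus(composite_shell_spec(50, 50)), 88420,
               tolerance = 1e-3)
  # hand evaluation of the harmonic mean for 30HA70Ti:
  # 1/(0.3/70 + 0.7/120) GPa = 98.8235 GPa
  expect_equal(reuss_modulus(composite_shell_spec(30, 70)),
               1 / (0.3 / 70000 + 0.7 / 120000))
  expect_equal(reuss_modulus(composite_shell_spec(30, 70)), 98800,
               tolerance = 1e-3)
  # single-phase degeneracy
  expect_equal(voigt_modulus(composite_shell_spec(0, 100)), 120000)
  expect_equal(reuss_modulus(composite_shell_spec(100, 0)), 70000)
})

test_that("porous bounds follow the porosity-degraded mixture rules", {
  expect_equal(porous_upper_bound(composite_shell_spec(10, 90, 10)), 104200)
  # hand evaluation: 0.5*70 + 0.5*120*0.1 GPa = 41 GPa
  expect_equal(porous_upper_bound(composite_shell_spec(50, 50, 90)), 41000)
  expect_equal(porous_lower_bound(composite_shell_spec(10, 90, 10)), 102430,
               tolerance = 1e-3)
  expect_equal(porous_lower_bound(composite_shell_spec(50, 50, 90)), 20480,
               tolerance = 1e-3)
  # zero-porosity identity
  for (ha in c(10, 35, 50)) {
    spec <- composite_shell_spec(ha, 100 - ha, 0)
    expect_identical(porous_upper_bound(spec), voigt_modulus(spec))
    expect_identical(porous_lower_bound(spec), reuss_modulus(spec))
  }
})

test_that("composition validation names the offending field", {
  expect_error(composite_shell_spec(60, 50), "pct_Ti")
  expect_error(composite_shell_spec(-5, 105), "pct_HA")
  expect_error(composite_shell_spec(10, 90, 100), "pct_p")
  expect_error(composite_shell_spec(10, 90, -1), "pct_p")
  expect_error(isotropic_material("x", -1, 0.3), "E")
  expect_error(isotropic_material("x", 1000, 0.5), "nu")
  expect_error(shell_material(composite_shell_spec(10, 90), "sideways"),
               "arg")
})

test_that("bound ordering and monotonicity hold across the design space", {
  set.seed(7)
  for (i in 1:50) {
    ha <- runif(1, 1, 99)
    p <- runif(1, 1, 99)
    spec <- composite_shell_spec(ha, 100 - ha, p)
    expect_lt(reuss_modulus(spec), voigt_modulus(spec))
    expect_lt(porous_lower_bound(spec), porous_upper_bound(spec))
    # strictly decreasing in porosity
    spec2 <- composite_shell_spec(ha, 100 - ha, min(p + 1, 99.9))
    expect_lt(porous_upper_bound(spec2), porous_upper_bound(spec))
    expect_lt(porous_lower_bound(spec2), porous_lower_bound(spec))
    # Voigt decreasing in the softer phase's content
    spec3 <- composite_shell_spec(min(ha + 1, 100))
    expect_lt(voigt_modulus(spec3), voigt_modulus(composite_shell_spec(ha)))
  }
  # equal-phase degeneracy: all four bounds collapse to the common modulus
  spec <- composite_shell_spec(37, 63, 0)
  for (f in list(voigt_modulus, reuss_modulus, porous_upper_bound,
                 porous_lower_bound))
    expect_equal(f(spec, E_Ti = 90000, E_HA = 90000), 90000)
})

test_that("the material table covers the grid and flags inconsistent reference cells", {
  tab <- build_material_table()
  expect_equal(nrow(tab), 9L)
  expect_named(tab, c("composition_label", "pct_HA", "pct_Ti", "pct_p",
                      "Emax_porous_MPa", "Emin_porous_MPa",
                      "Emax_solid_MPa", "Emin_solid_MPa"))
  r1 <- tab[tab$composition_label == "10HA90Ti", ]
  expect_equal(r1$Emax_porous_MPa, 104200)
  expect_equal(r1$Emin_porous_MPa, 102439.02, tolerance = 1e-6)
  expect_equal(r1$Emax_solid_MPa, 115000)
  expect_equal(r1$Emin_solid_MPa, 112000, tolerance = 1e-3)
  # empty grid
  expect_equal(nrow(build_material_table(list())), 0L)
  # the published table's porous upper bounds of rows 2-9 and the dense
  # lower bound of row 2 are inconsistent with the mixture rules
  mism <- attr(tab, "reference_mismatch")
  expect_s3_class(mism, "data.frame")
  expect_equal(sum(mism$column == "Emax_porous_MPa"), 8L)
  expect_equal(sum(mism$column == "Emin_solid_MPa"), 1L)
  expect_equal(mism$composition_label[mism$column == "Emin_solid_MPa"],
               "15HA85Ti")
  expect_equal(nrow(mism), 9L)
})

test_that("unit flag and YAML constant overrides work", {
  spec <- composite_shell_spec(10, 90, 10)
  expect_equal(porous_upper_bound(spec, E_Ti = 120, E_HA = 70,
                                  units = "GPa"),
               porous_upper_bound(spec))
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nu_shell: 0.28", "E_trab: 1500"), cfg)
  const <- load_constants_config(cfg)
  expect_equal(const$nu_shell, 0.28)
  expect_equal(const$E_trab, 1500)
  expect_equal(const$E_cort, 13000)  # untouched default
  expect_error(material_constants(list(bogus = 1)), "unknown")
})

test_that("shell_material selects the requested branch", {
  spec <- composite_shell_spec(10, 90, 10)
  m <- shell_material(spec, "upper", porous = TRUE, nu_shell = 0.30)
  expect_equal(m$E, 104200)
  expect_equal(m$nu, 0.30)
  expect_equal(shell_material(spec, "upper", porous = FALSE)$E, 115000)
  expect_equal(shell_material(spec, "lower", porous = TRUE)$E,
               porous_lower_bound(spec))
  # porous branch at p = 0 is identical to the dense branch
  spec0 <- composite_shell_spec(25, 75, 0)
  expect_identical(shell_material(spec0, "upper", porous = TRUE),
                   shell_material(spec0, "upper", porous = FALSE))
})
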