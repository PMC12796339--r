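# Study enumeration, per-configuration runs, sweep mechanics, convergence
# protocol, optimal-design selection and reporting.

test_that("the design space enumerates to 108 bilayer + 1 conventional", {
  configs <- enumerate_configs()
  expect_length(configs, 109L)
  types <- vapply(configs, `[[`, "", "implant_type")
  expect_equal(sum(types == "bilayer"), 108L)
  expect_equal(sum(types == "conventional"), 1L)
  tls <- vapply(configs, function(cf) if (is.na(cf$T_L)) -1 else cf$T_L, 0)
  for (tl in c(1, 1.5, 2)) expect_equal(sum(tls == tl), 36L)
  ids <- vapply(configs, `[[`, "", "id")
  expect_false(anyDuplicated(ids) > 0)
  # deterministic ordering
  expect_identical(ids, vapply(enumerate_configs(), `[[`, "", "id"))
})

test_that("run_config fills a complete, deterministic result row", {
  h <- 1  # coarse: row mechanics, not field accuracy
  conv <- run_config(implant_config("conventional"), mesh_size = h)
  expect_true(is.na(conv$composition))
  expect_true(is.na(conv$max_vm_shell_MPa))
  expect_false(is.na(conv$max_vm_implant_MPa))
  expect_lt(conv$residual_N, 1e-6 * 250)
  conv2 <- run_config(implant_config("conventional"), mesh_size = h)
  expect_identical(conv, conv2)
  row <- run_config(small_bilayer_config(), mesh_size = h)
  expect_equal(row$shell_E_MPa, 104200)
  expect_equal(row$composition, "10HA90Ti")
  expect_equal(row$max_vm_implant_MPa,
               max(row$max_vm_shell_MPa, row$max_vm_core_MPa))
  expect_true(row$mechanostat_window %in%
                c("disuse", "adapted", "mild_overload",
                  "pathologic_overload"))
})

test_that("run_sweep reuses geometry, appends the reference and computes reductions", {
  subset <- list(
    small_bilayer_config(10, porous = TRUE, branch = "upper"),
    small_bilayer_config(10, porous = FALSE, branch = "upper"),
    small_bilayer_config(50, pct_p = 90, porous = TRUE, branch = "lower"))
  tab <- run_sweep(subset, mesh_size = 1)
  expect_s3_class(tab, "study_table")
  expect_equal(nrow(tab), 4L)  # conventional appended
  expect_equal(sum(tab$implant_type == "conventional"), 1L)
  ref <- tab$max_vm_implant_MPa[tab$implant_type == "conventional"]
  i <- which(tab$config_id == subset[[1]]$id)
  expect_equal(tab$stress_reduction_shell_pct[i],
               stress_reduction(ref, tab$max_vm_shell_MPa[i]))
  # subset rows agree with standalone runs of the same configuration
  solo <- run_config(subset[[1]], mesh_size = 1)
  expect_equal(tab$max_vm_shell_MPa[i], solo$max_vm_shell_MPa)
  expect_equal(tab$interfacial_strain_ue[i], solo$interfacial_strain_ue)
  # re-execution is bit-identical
  tab2 <- run_sweep(subset, mesh_size = 1)
  expect_identical(tab, tab2)
})

test_that("reports round-trip the table and summarize it coherently", {
  subset <- list(small_bilayer_config(10), small_bilayer_config(30, 50))
  tab <- run_sweep(subset, mesh_size = 1)
  out <- withr::local_tempdir()
  files <- report(tab, out, plot = TRUE)
  expect_true(file.exists(files$results))
  expect_true(file.exists(files$summary))
  expect_true(file.exists(files$plot))
  back <- read.csv(files$results, stringsAsFactors = FALSE)
  num <- vapply(tab, is.numeric, TRUE)
  for (cl in names(tab)[num])
    expect_equal(back[[cl]], tab[[cl]], tolerance = 1e-12, label = cl)
  smry <- jsonlite::read_json(files$summary)
  expect_named(smry, c("n_configurations", "n_bilayer",
                       "conventional_max_vm_MPa",
                       "conventional_interfacial_strain_ue",
                       "optimal_config", "optimal_rationale",
                       "stress_reduction_shell_pct_range",
                       "stress_reduction_core_pct_range",
                       "mechanostat_window_counts"),
               ignore.order = TRUE)
  expect_equal(sum(unlist(smry$mechanostat_window_counts)), nrow(tab))
  # regenerating the report from the same table is identical
  out2 <- withr::local_tempdir()
  files2 <- report(tab, out2, plot = FALSE)
  expect_identical(readLines(files$results), readLines(files2$results))
})

test_that("optimal-design selection applies the lexicographic rule", {
  mk <- function(id, T_L, ha, strain, red) data.frame(
    config_id = id, implant_type = "bilayer", T_L = T_L, pct_HA = ha,
    interfacial_strain_ue = strain, stress_reduction_shell_pct = red)
  tab <- rbind(
    mk("a_overloaded", 2, 10, 5200, 90),   # infeasible
    mk("b_desirable_lowred", 2, 20, 1800, 40),
    mk("c_desirable_highred", 1, 25, 1600, 70),
    mk("d_below_window_highred", 2, 10, 900, 95))
  tab$implant_type <- "bilayer"
  # desirable-window rows are preferred even over a higher reduction below
  # the window; among them the best reduction wins
  sel <- select_optimal(tab)
  expect_equal(sel$config_id, "c_desirable_highred")
  expect_true(any(grepl("desirable", sel$rationale)))
  # without the window preference, raw reduction wins
  sel2 <- select_optimal(tab, prefer_desirable = FALSE)
  expect_equal(sel2$config_id, "d_below_window_highred")
  # ties broken by thicker shell, then lower HA content
  tie <- rbind(mk("thin", 1, 10, 1700, 50), mk("thick", 2, 30, 1700, 50),
               mk("thick_lowHA", 2, 15, 1700, 50))
  expect_equal(select_optimal(tie)$config_id, "thick_lowHA")
  # empty feasible set is reported, not raised
  none <- mk("x", 2, 10, 6000, 80)
  sel3 <- select_optimal(none)
  expect_true(is.na(sel3$config_id))
  expect_true(any(grepl("no feasible", sel3$rationale)))
})

test_that("convergence protocol reports relative changes on a ladder", {
  expect_error(convergence_study(implant_config("conventional"),
                                 sizes = 1), "two sizes")
  expect_error(convergence_study(implant_config("conventional"),
                                 sizes = c(0.5, 1)), "decreasing")
  tab <- convergence_study(implant_config("conventional"), sizes = c(2, 1))
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$rel_change[1]))
  expect_gte(tab$rel_change[2], 0)
  expect_type(tab$converged, "logical")
})
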