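# Study orchestration: enumeration of the design space, per-configuration
# runs, mesh convergence protocol, optimal-design selection and reporting.

#' Enumerate the full study design space
#'
#' One conventional solid implant plus every combination of shell
#' thickness (1, 1.5, 2 mm), the nine-composition design grid, porosity
#' flag and modulus-bound branch: `1 + 3 * 9 * 2 * 2 = 109` configurations
#' in a fixed deterministic order (conventional first, then nested loops
#' thickness > composition > porosity > branch).
#'
#' @param grid composition grid, a list of [composite_shell_spec()].
#' @param thicknesses shell thickness values in mm.
#' @return list of [implant_config()] objects.
#' @export
#' @examples
#' length(enumerate_configs())  # 109
enumerate_configs <- function(grid = default_composition_grid(),
                              thicknesses = c(1, 1.5, 2)) {
  configs <- list(implant_config("conventional"))
  for (T_L in thicknesses)
    for (comp in grid)
      for (porous in c(FALSE, TRUE))
        for (branch in c("upper", "lower"))
          configs[[length(configs) + 1L]] <-
            implant_config("bilayer", T_L = T_L, composition = comp,
                           porous = porous, bound_branch = branch)
  configs
}

# region Poisson ratios of one configuration (for stiffness precomputation)
.region_nus <- function(config, constants) {
  nus <- list(cortical = constants$nu_bone, trabecular = constants$nu_bone,
              cap = constants$nu_cap)
  if (config$implant_type == "conventional") nus$implant <- constants$nu_core
  else {
    nus$core <- constants$nu_core
    nus$shell <- constants$nu_shell
  }
  nus
}

#' Run one study configuration
#'
#' Builds (or reuses) the mesh for the configuration's geometry, solves the
#' 250 N axial load case and reduces the solution to one study result row.
#'
#' @param config an [implant_config()].
#' @param bone a [bone_spec()].
#' @param mesh_size target element size in mm (production default 0.25).
#' @param load a [load_case()].
#' @param constants material constants from [material_constants()].
#' @param windows a [mechanostat_windows()].
#' @param mesh,stiffness optional precomputed `region_mesh` and
#'   [precompute_stiffness()] list for this geometry (reused across the
#'   sweep).
#' @return a one-row data.frame (`study_result_row`).
#' @export
run_config <- function(config, bone = bone_spec(), mesh_size = 0.25,
                       load = load_case(), constants = material_constants(),
                       windows = mechanostat_windows(),
                       mesh = NULL, stiffness = NULL) {
  stopifnot(inherits(config, "implant_config"))
  res <- tryCatch({
    if (is.null(mesh)) {
      geo <- build_assembly_geometry(config, bone)
      mesh <- generate_mesh(geo, mesh_size)
    }
    mats <- region_materials(config, constants)
    sol <- assemble_and_solve(mesh, mats, load, stiffness = stiffness)
    conventional <- config$implant_type == "conventional"
    vm_shell <- if (conventional) NA_real_
                else region_max_von_mises(sol, mesh, "shell")$value
    vm_core <- if (conventional) NA_real_
               else region_max_von_mises(sol, mesh, "core")$value
    vm_impl <- if (conventional)
      region_max_von_mises(sol, mesh, "implant")$value
    else max(vm_shell, vm_core)
    vm_bone <- max(region_max_von_mises(sol, mesh, "cortical")$value,
                   region_max_von_mises(sol, mesh, "trabecular")$value)
    istr <- interfacial_strain(sol, mesh)
    data.frame(
      config_id = config$id,
      implant_type = config$implant_type,
      T_L = config$T_L,
      composition = if (conventional) NA_character_
                    else composition_label(config$composition),
      pct_HA = if (conventional) NA_real_ else config$composition$pct_HA,
      pct_p = if (conventional) NA_real_ else config$composition$pct_p,
      porous = config$porous,
      bound_branch = config$bound_branch,
      shell_E_MPa = if (conventional) constants$E_core
                    else mats$shell$E,
      max_vm_shell_MPa = vm_shell,
      max_vm_core_MPa = vm_core,
      max_vm_implant_MPa = vm_impl,
      max_vm_bone_MPa = vm_bone,
      interfacial_strain_ue = istr$max_ue,
      interfacial_strain_p99_ue = istr$percentile_ue,
      mechanostat_window = as.character(
        classify_mechanostat(istr$max_ue, windows)),
      residual_N = sol$residual,
      mesh_size_mm = mesh$target_size,
      stringsAsFactors = FALSE)
  }, error = function(e) {
    stop("configuration '", config$id, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' Run the configuration sweep
#'
#' Executes every configuration, reusing one mesh and one set of
#' unit-modulus region stiffness matrices per distinct geometry (the
#' geometry depends only on implant type and shell thickness, and only the
#' shell modulus differs within a geometry group).  The conventional
#' reference is always solved at the same refinement level, and per-row
#' percent stress reductions are computed against its implant maximum.
#' Rows are independent, so the result is identical regardless of
#' execution order.
#'
#' @inheritParams run_config
#' @param configs list of configurations, e.g. [enumerate_configs()].
#' @param progress print per-geometry progress messages?
#' @return a `study_table` data.frame, one row per configuration (the
#'   conventional reference is appended if absent), with reduction columns
#'   `stress_reduction_shell_pct`, `stress_reduction_core_pct`,
#'   `stress_reduction_implant_pct`.
#' @export
run_sweep <- function(configs = enumerate_configs(), bone = bone_spec(),
                      mesh_size = 0.25, load = load_case(),
                      constants = material_constants(),
                      windows = mechanostat_windows(), progress = FALSE) {
  stopifnot(is.list(configs), length(configs) > 0L)
  if (!any(vapply(configs, function(cf) cf$implant_type, "") ==
             "conventional"))
    configs <- c(configs, list(implant_config("conventional")))
  geo_key <- vapply(configs, function(cf)
    if (cf$implant_type == "conventional") "conventional"
    else sprintf("bilayer_TL%g", cf$T_L), "")
  rows <- vector("list", length(configs))
  failures <- character(0)
  for (key in unique(geo_key)) {
    in_group <- which(geo_key == key)
    cf0 <- configs[[in_group[1L]]]
    if (progress)
      message("geometry ", key, ": meshing at h = ", mesh_size, " mm (",
              length(in_group), " configuration(s))")
    geo <- build_assembly_geometry(cf0, bone)
    mesh <- generate_mesh(geo, mesh_size)
    stiffness <- precompute_stiffness(mesh, .region_nus(cf0, constants))
    for (i in in_group) {
      rows[[i]] <- tryCatch(
        run_config(configs[[i]], bone, mesh_size, load, constants, windows,
                   mesh = mesh, stiffness = stiffness),
        error = function(e) {
          failures <<- c(failures, conditionMessage(e))
          NULL
        })
      if (progress && i == in_group[length(in_group)])
        message("geometry ", key, ": done")
    }
  }
  if (length(failures) > 0L)
    warning("failed configuration(s):\n", paste(failures, collapse = "\n"))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ref <- tab$max_vm_implant_MPa[tab$implant_type == "conventional"][1L]
  tab$stress_reduction_shell_pct <-
    ifelse(tab$implant_type == "bilayer",
           stress_reduction(ref, tab$max_vm_shell_MPa), NA_real_)
  tab$stress_reduction_core_pct <-
    ifelse(tab$implant_type == "bilayer",
           stress_reduction(ref, tab$max_vm_core_MPa), NA_real_)
  tab$stress_reduction_implant_pct <-
    ifelse(tab$implant_type == "bilayer",
           stress_reduction(ref, tab$max_vm_implant_MPa), NA_real_)
  class(tab) <- c("study_table", "data.frame")
  tab
}

#' Mesh-convergence protocol
#'
#' Solves one configuration on a ladder of decreasing element sizes and
#' reports the relative change of the implant's peak von Mises stress
#' between successive refinements; a level is flagged converged when the
#' change drops to `tol` or below (the usual 5% criterion by default).
#'
#' @inheritParams run_config
#' @param sizes strictly decreasing element sizes in mm (at least two).
#' @param tol relative-change tolerance.
#' @return data.frame with `size_mm`, `max_vm_implant_MPa`,
#'   `interfacial_strain_ue`, `rel_change` and `converged`.
#' @export
convergence_study <- function(config, sizes = c(1, 0.5, 0.25),
                              bone = bone_spec(), load = load_case(),
                              constants = material_constants(), tol = 0.05) {
  if (length(sizes) < 2L) stop("the size ladder needs at least two sizes")
  if (any(diff(sizes) >= 0)) stop("sizes must be strictly decreasing")
  rows <- lapply(sizes, function(h)
    run_config(config, bone, h, load, constants))
  vm <- vapply(rows, function(r) r$max_vm_implant_MPa, 0)
  ue <- vapply(rows, function(r) r$interfacial_strain_ue, 0)
  rel <- c(NA_real_, abs(diff(vm)) / utils::head(vm, -1L))
  data.frame(size_mm = sizes, max_vm_implant_MPa = vm,
             interfacial_strain_ue = ue, rel_change = rel,
             converged = !is.na(rel) & rel <= tol)
}

#' Select the preferred design from a study table
#'
#' Formalizes the study's qualitative preference as a configurable
#' lexicographic rule: (1) feasibility - interfacial strain below the
#' pathologic-overload threshold; (2) if any feasible row's strain lies in
#' the desirable window `[adapted_upper, desirable_upper)`, restrict to
#' those rows; (3) maximize the shell stress reduction; ties broken by
#' thicker shell, then lower HA content.
#'
#' @param table a `study_table` from [run_sweep()].
#' @param windows a [mechanostat_windows()].
#' @param prefer_desirable apply step (2)?
#' @param metric column maximized in step (3).
#' @return list with `config_id` (`NA` if no feasible row), the selected
#'   `row`, and a `rationale` character vector tracing the decision.
#' @export
select_optimal <- function(table, windows = mechanostat_windows(),
                           prefer_desirable = TRUE,
                           metric = "stress_reduction_shell_pct") {
  stopifnot(is.data.frame(table))
  cand <- table[table$implant_type == "bilayer", , drop = FALSE]
  rationale <- character(0)
  feasible <- cand[cand$interfacial_strain_ue <
                     windows$overload_threshold, , drop = FALSE]
  rationale <- c(rationale, sprintf(
    "%d of %d bilayer rows feasible (interfacial strain < %g ue)",
    nrow(feasible), nrow(cand), windows$overload_threshold))
  if (nrow(feasible) == 0L)
    return(list(config_id = NA_character_, row = NULL,
                rationale = c(rationale, "no feasible configuration")))
  if (prefer_desirable) {
    in_win <- feasible$interfacial_strain_ue >= windows$adapted_upper &
      feasible$interfacial_strain_ue < windows$desirable_upper
    if (any(in_win)) {
      feasible <- feasible[in_win, , drop = FALSE]
      rationale <- c(rationale, sprintf(
        "%d row(s) inside the desirable window [%g, %g) ue",
        nrow(feasible), windows$adapted_upper, windows$desirable_upper))
    } else {
      rationale <- c(rationale, "no row reaches the desirable window; all feasible rows kept")
    }
  }
  ord <- order(-feasible[[metric]], -feasible$T_L, feasible$pct_HA)
  best <- feasible[ord[1L], , drop = FALSE]
  rationale <- c(rationale, sprintf(
    "maximal %s = %.2f%% at %s", metric, best[[metric]], best$config_id))
  list(config_id = best$config_id, row = best, rationale = rationale)
}

#' Write study reports
#'
#' Writes the full result table as CSV, a JSON summary (selected optimum,
#' reduction ranges, mechanostat window counts) and, optionally, a PDF
#' strain-versus-configuration plot with the mechanostat thresholds
#' overlaid.
#'
#' @param table a `study_table`.
#' @param out_dir output directory (created if missing).
#' @param windows a [mechanostat_windows()].
#' @param plot write the strain plot?
#' @return named list of written file paths, invisibly.
#' @export
report <- function(table, out_dir, windows = mechanostat_windows(),
                   plot = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out_dir, "results.csv")
  utils::write.csv(table, csv, row.names = FALSE)
  bil <- table[table$implant_type == "bilayer", , drop = FALSE]
  rng <- function(x) if (all(is.na(x))) c(NA, NA) else range(x, na.rm = TRUE)
  opt <- select_optimal(table, windows)
  summary <- list(
    n_configurations = nrow(table),
    n_bilayer = nrow(bil),
    conventional_max_vm_MPa =
      table$max_vm_implant_MPa[table$implant_type == "conventional"][1L],
    conventional_interfacial_strain_ue =
      table$interfacial_strain_ue[table$implant_type == "conventional"][1L],
    optimal_config = opt$config_id,
    optimal_rationale = opt$rationale,
    stress_reduction_shell_pct_range = list(
      porous = rng(bil$stress_reduction_shell_pct[bil$porous]),
      non_porous = rng(bil$stress_reduction_shell_pct[!bil$porous])),
    stress_reduction_core_pct_range = list(
      porous = rng(bil$stress_reduction_core_pct[bil$porous]),
      non_porous = rng(bil$stress_reduction_core_pct[!bil$porous])),
    mechanostat_window_counts = as.list(table(table$mechanostat_window)))
  js <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files <- list(results = csv, summary = js)
  if (isTRUE(plot)) {
    pdf_path <- file.path(out_dir, "interfacial_strain.pdf")
    grDevices::pdf(pdf_path, width = 9, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_interfacial_strain(table, windows)
    files$plot <- pdf_path
  }
  invisible(files)
}

#' Strain-versus-configuration plot
#'
#' Interfacial microstrain of every bilayer configuration, grouped by shell
#' thickness and colored by porosity, with the mechanostat thresholds as
#' horizontal lines and the conventional implant's strain as a reference.
#'
#' @param table a `study_table`.
#' @param windows a [mechanostat_windows()].
#' @return invisibly, the plotted data.
#' @export
plot_interfacial_strain <- function(table,
                                    windows = mechanostat_windows()) {
  bil <- table[table$implant_type == "bilayer", , drop = FALSE]
  bil <- bil[order(bil$T_L, bil$pct_HA, bil$porous, bil$bound_branch), ]
  x <- seq_len(nrow(bil))
  col <- ifelse(bil$porous, "#D55E00", "#0072B2")
  pch <- ifelse(bil$bound_branch == "upper", 19, 1)
  ymax <- max(bil$interfacial_strain_ue, windows$overload_threshold) * 1.1
  graphics::plot(x, bil$interfacial_strain_ue, col = col, pch = pch,
                 ylim = c(0, ymax), xlab = "configuration",
                 ylab = "interfacial strain (microstrain)")
  th <- unlist(windows)
  graphics::abline(h = th, lty = 3, col = "grey40")
  graphics::mtext(names(th), side = 4, at = th, las = 2, cex = 0.6)
  conv <- table$interfacial_strain_ue[table$implant_type == "conventional"]
  if (length(conv) > 0L && is.finite(conv[1L]))
    graphics::abline(h = conv[1L], lty = 2, col = "grey10")
  brk <- which(diff(bil$T_L) != 0) + 0.5
  graphics::abline(v = brk, col = "grey80")
  graphics::legend("topleft", legend = c("porous", "dense", "upper bound",
                                         "lower bound"),
                   col = c("#D55E00", "#0072B2", "grey30", "grey30"),
                   pch = c(15, 15, 19, 1), bty = "n", cex = 0.8)
  invisible(bil)
}
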