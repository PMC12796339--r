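# Homogenized material model of the porous HA/Ti composite shell and the
# homogeneous isotropic materials of the bone-implant assembly.
#
# Internal unit system: mm - N - MPa.  All moduli are stored in MPa.

#' Default material constants of the bone-implant model
#'
#' Elastic constants for every homogeneous region of the assembly and for the
#' two phases of the composite shell, in the package's mm-N-MPa unit system:
#' cortical bone (E = 13000 MPa), trabecular bone (E = 1370 MPa), both with
#' Poisson ratio 0.30; ceramic cap (E = 68900 MPa, nu = 0.28); Ti6Al4V
#' core/conventional implant (E = 120000 MPa, nu = 0.35); shell phase moduli
#' E_Ti = 120000 MPa and E_HA = 70000 MPa.  The Poisson ratio of the
#' homogenized shell is not fixed by the mixture rule; the default 0.30 lies
#' between the titanium (0.35) and typical hydroxyapatite (~0.27) values and
#' can be overridden here or through a YAML configuration file.
#'
#' @param overrides named list (or NULL) of constants to override.
#' @return named list of material constants.
#' @seealso [load_constants_config()] to read overrides from a YAML file.
#' @export
#' @examples
#' material_constants()$E_cort
#' material_constants(list(nu_shell = 0.28))$nu_shell
material_constants <- function(overrides = NULL) {
  constants <- list(
    E_Ti = 120000, E_HA = 70000,
    E_cort = 13000, E_trab = 1370, nu_bone = 0.30,
    E_cap = 68900, nu_cap = 0.28,
    E_core = 120000, nu_core = 0.35,
    nu_shell = 0.30
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    unknown <- setdiff(names(overrides), names(constants))
    if (length(unknown) > 0L)
      stop("unknown material constant(s): ", paste(unknown, collapse = ", "))
    constants[names(overrides)] <- overrides
  }
  constants
}

#' Read material-constant overrides from a YAML configuration file
#'
#' The file may contain any subset of the names returned by
#' [material_constants()], e.g. `nu_shell: 0.28`.
#'
#' @param path path to a YAML file.
#' @return named list of constants with the file's overrides applied.
#' @export
load_constants_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  material_constants(yaml::read_yaml(path))
}

#' Isotropic linear-elastic material
#'
#' @param name label of the material/region.
#' @param E Young's modulus in MPa; must be positive.
#' @param nu Poisson ratio; must satisfy 0 <= nu < 0.5.
#' @return an object of class `isotropic_material`.
#' @export
#' @examples
#' isotropic_material("cortical", 13000, 0.30)
isotropic_material <- function(name, E, nu) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0)
    stop("E must be a positive finite number (MPa), got: ", format(E))
  if (!is.numeric(nu) || length(nu) != 1L || nu < 0 || nu >= 0.5)
    stop("nu must lie in [0, 0.5), got: ", format(nu))
  structure(list(name = name, E = E, nu = nu), class = "isotropic_material")
}

#' @export
print.isotropic_material <- function(x, ...) {
  cat(sprintf("<isotropic_material> %s: E = %g MPa, nu = %g\n",
              x$name, x$E, x$nu))
  invisible(x)
}

#' Composite shell composition
#'
#' A point of the shell design grid: hydroxyapatite and titanium volume
#' percentages (summing to 100) plus a porosity percentage.  Porosity 100%
#' is excluded because it annihilates the load-bearing Ti skeleton (the Ti
#' stiffness term of the porous Reuss bound diverges).
#'
#' @param pct_HA hydroxyapatite volume percent in \[0, 100\].
#' @param pct_Ti titanium volume percent in \[0, 100\]; `pct_HA + pct_Ti`
#'   must equal 100.
#' @param pct_p porosity percent in \[0, 100).
#' @return an object of class `composite_shell_spec`.
#' @export
#' @examples
#' composite_shell_spec(10, 90, 10)  # "10HA90Ti" at 10% porosity
composite_shell_spec <- function(pct_HA, pct_Ti = 100 - pct_HA, pct_p = 0) {
  for (nm in c("pct_HA", "pct_Ti", "pct_p")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("field ", nm, " must be a single finite number")
  }
  if (pct_HA < 0 || pct_HA > 100) stop("field pct_HA must lie in [0, 100]")
  if (pct_Ti < 0 || pct_Ti > 100) stop("field pct_Ti must lie in [0, 100]")
  if (abs(pct_HA + pct_Ti - 100) > 1e-9)
    stop("field pct_Ti invalid: pct_HA + pct_Ti must equal 100 (got ",
         pct_HA + pct_Ti, ")")
  if (pct_p < 0 || pct_p >= 100) stop("field pct_p must lie in [0, 100)")
  structure(list(pct_HA = pct_HA, pct_Ti = pct_Ti, pct_p = pct_p),
            class = "composite_shell_spec")
}

#' @export
print.composite_shell_spec <- function(x, ...) {
  cat(sprintf("<composite_shell_spec> %s, porosity %g%%\n",
              composition_label(x), x$pct_p))
  invisible(x)
}

#' Composition label in the "%HA%Ti" convention
#'
#' @param spec a [composite_shell_spec()].
#' @return character label, e.g. `"10HA90Ti"`.
#' @export
composition_label <- function(spec) {
  sprintf("%gHA%gTi", spec$pct_HA, spec$pct_Ti)
}

.as_MPa <- function(E, units) {
  units <- match.arg(units, c("MPa", "GPa"))
  if (units == "GPa") E * 1000 else E
}

#' Voigt (upper-bound) modulus of the dense HA/Ti composite
#'
#' Rule-of-mixtures arithmetic mean over volume fractions,
#' `E_max = E_Ti * V_Ti + E_HA * V_HA`.  Porosity is ignored (dense branch).
#'
#' @param spec a [composite_shell_spec()].
#' @param E_Ti,E_HA phase Young's moduli (MPa by default).
#' @param units `"MPa"` (default) or `"GPa"` for the phase moduli inputs;
#'   the return value is always MPa.
#' @return effective Young's modulus in MPa.
#' @export
#' @examples
#' voigt_modulus(composite_shell_spec(10, 90))  # 115000
voigt_modulus <- function(spec, E_Ti = 120000, E_HA = 70000, units = "MPa") {
  stopifnot(inherits(spec, "composite_shell_spec"))
  E_Ti <- .as_MPa(E_Ti, units); E_HA <- .as_MPa(E_HA, units)
  E_Ti * spec$pct_Ti / 100 + E_HA * spec$pct_HA / 100
}

#' Reuss (lower-bound) modulus of the dense HA/Ti composite
#'
#' Harmonic volume-fraction mean, `1/E_min = V_Ti/E_Ti + V_HA/E_HA`.
#'
#' @inheritParams voigt_modulus
#' @return effective Young's modulus in MPa.
#' @export
#' @examples
#' reuss_modulus(composite_shell_spec(10, 90))  # 112000
reuss_modulus <- function(spec, E_Ti = 120000, E_HA = 70000, units = "MPa") {
  stopifnot(inherits(spec, "composite_shell_spec"))
  E_Ti <- .as_MPa(E_Ti, units); E_HA <- .as_MPa(E_HA, units)
  1 / (spec$pct_Ti / 100 / E_Ti + spec$pct_HA / 100 / E_HA)
}

#' Porosity-adjusted Voigt bound of the porous HA/Ti composite
#'
#' Porosity degrades only the titanium skeleton term:
#' `E_max = V_HA * E_HA + V_Ti * E_Ti * (1 - p)` with fractions
#' `V = pct/100`, `p = pct_p/100`.  Reduces exactly to [voigt_modulus()]
#' at zero porosity.
#'
#' @inheritParams voigt_modulus
#' @return effective Young's modulus in MPa.
#' @export
#' @examples
#' porous_upper_bound(composite_shell_spec(10, 90, 10))  # 104200
porous_upper_bound <- function(spec, E_Ti = 120000, E_HA = 70000,
                               units = "MPa") {
  stopifnot(inherits(spec, "composite_shell_spec"))
  E_Ti <- .as_MPa(E_Ti, units); E_HA <- .as_MPa(E_HA, units)
  spec$pct_HA / 100 * E_HA +
    spec$pct_Ti / 100 * (E_Ti * (1 - spec$pct_p / 100))
}

#' Porosity-adjusted Reuss bound of the porous HA/Ti composite
#'
#' `E_min = ( V_HA / E_HA + V_Ti / (E_Ti * (1 - p)) )^-1`; the titanium term
#' diverges as porosity approaches 100%.  Reduces exactly to
#' [reuss_modulus()] at zero porosity.
#'
#' @inheritParams voigt_modulus
#' @return effective Young's modulus in MPa.
#' @export
#' @examples
#' porous_lower_bound(composite_shell_spec(50, 50, 90))  # ~20490
porous_lower_bound <- function(spec, E_Ti = 120000, E_HA = 70000,
                               units = "MPa") {
  stopifnot(inherits(spec, "composite_shell_spec"))
  E_Ti <- .as_MPa(E_Ti, units); E_HA <- .as_MPa(E_HA, units)
  1 / (spec$pct_HA / 100 / E_HA +
         spec$pct_Ti / 100 / (E_Ti * (1 - spec$pct_p / 100)))
}

#' Default shell design grid
#'
#' Nine compositions pairing HA content 10% to 50% in 5% steps (Ti 90% down
#' to 50%) row-wise with porosity 10% to 90% in 10% steps.
#'
#' @return list of nine [composite_shell_spec()] objects.
#' @export
default_composition_grid <- function() {
  pct_HA <- seq(10, 50, by = 5)
  pct_p <- seq(10, 90, by = 10)
  Map(function(ha, p) composite_shell_spec(ha, 100 - ha, p), pct_HA, pct_p)
}

# Published reference effective moduli (MPa) for the default design grid, as
# reported for this implant family.  Used only to cross-flag cells where the
# published table deviates from the mixture rules it states: the porous
# upper-bound column of rows 2-9 matches the rule evaluated with %p equal to
# the row's %HA rather than its printed %p, and row 2's dense lower bound
# ("10,830") is an evident typo for ~108,390.
.reference_shell_moduli <- data.frame(
  composition_label = c("10HA90Ti", "15HA85Ti", "20HA80Ti", "25HA75Ti",
                        "30HA70Ti", "35HA65Ti", "40HA60Ti", "45HA55Ti",
                        "50HA50Ti"),
  pct_p = seq(10, 90, by = 10),
  Emax_porous_MPa = c(104200, 97200, 90800, 85000, 79800, 75200, 71200,
                      67800, 65000),
  Emin_porous_MPa = c(102430, 90930, 80760, 71480, 62680, 53930, 44680,
                      34070, 20480),
  Emax_solid_MPa = c(115000, 112500, 110000, 107500, 105000, 102500, 100000,
                     97500, 95000),
  Emin_solid_MPa = c(112000, 10830, 105000, 101800, 98800, 96000, 93300,
                     90800, 88420)
)

#' Effective-modulus table for a grid of shell compositions
#'
#' Evaluates the four mixture-rule bounds (porous and dense Voigt/Reuss) for
#' every composition of the grid.  When `compare_reference = TRUE` (default
#' for the default grid) computed values are compared to the published
#' reference table for this design family at relative tolerance `tol`;
#' non-matching reference cells are reported in the `"reference_mismatch"`
#' attribute rather than being reproduced.
#'
#' @param grid list of [composite_shell_spec()] objects; defaults to
#'   [default_composition_grid()].
#' @param E_Ti,E_HA phase moduli in MPa.
#' @param compare_reference compare against the published reference values
#'   (only meaningful for the default grid).
#' @param tol relative tolerance used for the reference comparison.
#' @return data.frame with columns `composition_label`, `pct_HA`, `pct_Ti`,
#'   `pct_p`, `Emax_porous_MPa`, `Emin_porous_MPa`, `Emax_solid_MPa`,
#'   `Emin_solid_MPa`; attribute `reference_mismatch` (data.frame) lists
#'   reference cells whose printed value disagrees with the mixture rule.
#' @export
#' @examples
#' tab <- build_material_table()
#' tab[1, ]
#' attr(tab, "reference_mismatch")
build_material_table <- function(grid = default_composition_grid(),
                                 E_Ti = 120000, E_HA = 70000,
                                 compare_reference = missing(grid),
                                 tol = 1e-3) {
  stopifnot(is.list(grid))
  if (length(grid) == 0L) {
    out <- data.frame(composition_label = character(0), pct_HA = numeric(0),
                      pct_Ti = numeric(0), pct_p = numeric(0),
                      Emax_porous_MPa = numeric(0),
                      Emin_porous_MPa = numeric(0),
                      Emax_solid_MPa = numeric(0),
                      Emin_solid_MPa = numeric(0))
    return(out)
  }
  rows <- lapply(grid, function(spec) {
    stopifnot(inherits(spec, "composite_shell_spec"))
    data.frame(
      composition_label = composition_label(spec),
      pct_HA = spec$pct_HA, pct_Ti = spec$pct_Ti, pct_p = spec$pct_p,
      Emax_porous_MPa = porous_upper_bound(spec, E_Ti, E_HA),
      Emin_porous_MPa = porous_lower_bound(spec, E_Ti, E_HA),
      Emax_solid_MPa = voigt_modulus(spec, E_Ti, E_HA),
      Emin_solid_MPa = reuss_modulus(spec, E_Ti, E_HA)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (isTRUE(compare_reference)) {
    ref <- .reference_shell_moduli
    mism <- NULL
    cols <- c("Emax_porous_MPa", "Emin_porous_MPa",
              "Emax_solid_MPa", "Emin_solid_MPa")
    for (i in seq_len(nrow(out))) {
      j <- match(out$composition_label[i], ref$composition_label)
      if (is.na(j) || out$pct_p[i] != ref$pct_p[j]) next
      for (cl in cols) {
        rel <- abs(out[[cl]][i] - ref[[cl]][j]) / abs(out[[cl]][i])
        if (rel > tol) {
          mism <- rbind(mism, data.frame(
            composition_label = out$composition_label[i], column = cl,
            computed = out[[cl]][i], reference = ref[[cl]][j],
            rel_diff = rel))
        }
      }
    }
    attr(out, "reference_mismatch") <-
      if (is.null(mism)) {
        data.frame(composition_label = character(0), column = character(0),
                   computed = numeric(0), reference = numeric(0),
                   rel_diff = numeric(0))
      } else mism
  }
  out
}

#' Export a material table as CSV
#'
#' @param table data.frame from [build_material_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_material_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Solver material for the composite shell of one study configuration
#'
#' Maps a shell composition plus the modulus-bound branch and porosity flag
#' to the isotropic material handed to the elasticity solver.
#'
#' @param spec a [composite_shell_spec()].
#' @param bound_branch `"upper"` (Voigt-type) or `"lower"` (Reuss-type).
#' @param porous logical; use the porosity-adjusted bounds?
#' @param nu_shell Poisson ratio assigned to the homogenized shell.
#' @param E_Ti,E_HA phase moduli in MPa.
#' @return an [isotropic_material()] named `"shell"`.
#' @export
#' @examples
#' shell_material(composite_shell_spec(10, 90, 10), "upper", porous = TRUE)
shell_material <- function(spec, bound_branch = c("upper", "lower"),
                           porous = TRUE, nu_shell = 0.30,
                           E_Ti = 120000, E_HA = 70000) {
  bound_branch <- match.arg(bound_branch)
  E <- if (porous) {
    if (bound_branch == "upper") porous_upper_bound(spec, E_Ti, E_HA)
    else porous_lower_bound(spec, E_Ti, E_HA)
  } else {
    if (bound_branch == "upper") voigt_modulus(spec, E_Ti, E_HA)
    else reuss_modulus(spec, E_Ti, E_HA)
  }
  isotropic_material("shell", E, nu_shell)
}

#' Region materials for a study configuration
#'
#' Builds the region -> material map consumed by [assemble_and_solve()]:
#' cortical and trabecular bone, ceramic cap, and either the Ti6Al4V
#' conventional implant or the solid core plus homogenized shell.
#'
#' @param config an [implant_config()].
#' @param constants list from [material_constants()].
#' @return named list of [isotropic_material()] objects keyed by region.
#' @export
region_materials <- function(config, constants = material_constants()) {
  stopifnot(inherits(config, "implant_config"))
  mats <- list(
    cortical = isotropic_material("cortical", constants$E_cort,
                                  constants$nu_bone),
    trabecular = isotropic_material("trabecular", constants$E_trab,
                                    constants$nu_bone),
    cap = isotropic_material("cap", constants$E_cap, constants$nu_cap)
  )
  if (config$implant_type == "conventional") {
    mats$implant <- isotropic_material("implant", constants$E_core,
                                       constants$nu_core)
  } else {
    mats$core <- isotropic_material("core", constants$E_core,
                                    constants$nu_core)
    mats$shell <- shell_material(config$composition, config$bound_branch,
                                 config$porous, constants$nu_shell,
                                 constants$E_Ti, constants$E_HA)
  }
  mats
}
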