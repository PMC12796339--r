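# Parametric geometry of the idealized bone-implant assembly.
#
# The 3D assembly (rectangular mandibular block, helically threaded implant)
# is idealized as a 2D axisymmetric half-section in the r-z plane: the bone
# block becomes a cylinder of radius width/2, the helical thread becomes a
# stack of axisymmetric annular fins with a symmetric triangular profile.
# z points upward along the implant axis; the bone occupies z in [0, height]
# and the cap sits on top of the bone crest.

#' Implant configuration
#'
#' One point of the study design space: either the conventional solid
#' Ti6Al4V implant, or a bilayer implant whose outer shell of thickness
#' `T_L` is the homogenized porous HA/Ti composite.  The implant body is
#' 6 mm in diameter and 13 mm long, so the solid core diameter is
#' `6 - 2 * T_L` (2, 3, 4 mm for shells of 2, 1.5, 1 mm).
#'
#' @param implant_type `"bilayer"` or `"conventional"`.
#' @param T_L shell thickness in mm, one of 1, 1.5, 2 (bilayer only).
#' @param composition a [composite_shell_spec()] (bilayer only).
#' @param porous logical; porosity-adjusted shell moduli?
#' @param bound_branch `"upper"` or `"lower"` modulus bound branch.
#' @param diameter,length implant body diameter and length in mm.
#' @return an object of class `implant_config` with the derived
#'   `core_diameter` field and a deterministic `id` label.
#' @export
#' @examples
#' implant_config("bilayer", T_L = 2, composition = composite_shell_spec(10, 90, 10))
#' implant_config("conventional")
implant_config <- function(implant_type = c("bilayer", "conventional"),
                           T_L = NULL, composition = NULL, porous = FALSE,
                           bound_branch = c("upper", "lower"),
                           diameter = 6, length = 13) {
  implant_type <- match.arg(implant_type)
  bound_branch <- match.arg(bound_branch)
  stopifnot(diameter > 0, length > 0)
  if (implant_type == "conventional") {
    cfg <- list(implant_type = "conventional", T_L = NA_real_,
                core_diameter = diameter, composition = NULL,
                porous = FALSE, bound_branch = NA_character_,
                diameter = diameter, length = length,
                id = "conventional")
  } else {
    if (is.null(T_L) || !is.numeric(T_L) || length(T_L) != 1L)
      stop("bilayer implants need a single numeric shell thickness T_L")
    core_diameter <- diameter - 2 * T_L
    if (core_diameter <= 0)
      stop("shell thickness T_L = ", T_L,
           " mm leaves no core inside a ", diameter, " mm implant")
    if (is.null(composition) || !inherits(composition, "composite_shell_spec"))
      stop("bilayer implants need a composite_shell_spec composition")
    id <- sprintf("TL%g_%s_%s_%s", T_L, composition_label(composition),
                  if (porous) "porous" else "solid", bound_branch)
    cfg <- list(implant_type = "bilayer", T_L = T_L,
                core_diameter = core_diameter, composition = composition,
                porous = isTRUE(porous), bound_branch = bound_branch,
                diameter = diameter, length = length, id = id)
  }
  structure(cfg, class = "implant_config")
}

#' @export
print.implant_config <- function(x, ...) {
  if (x$implant_type == "conventional") {
    cat(sprintf("<implant_config> conventional solid implant, %g x %g mm\n",
                x$diameter, x$length))
  } else {
    cat(sprintf(
      "<implant_config> bilayer %s, T_L = %g mm (core %g mm), %s, %s bound\n",
      composition_label(x$composition), x$T_L, x$core_diameter,
      if (x$porous) sprintf("porous %g%%", x$composition$pct_p) else "dense",
      x$bound_branch))
  }
  invisible(x)
}

#' Bone segment and assembly dimensions
#'
#' Mandibular bone section 24.2 mm high and 16.3 mm wide with a 2 mm
#' cortical shell around a cancellous core; the implant carries a single
#' continuous triangular thread of 1 mm depth at 1 mm pitch, idealized here
#' as axisymmetric annular fins.  The ceramic cap (shape unspecified in the
#' source design; a cylinder by default) sits on the bone crest.  The
#' cortical band covers the crestal (top) and outer lateral surfaces;
#' whether it also covers the bottom is configurable, as is fixing the
#' bottom surface in the solver.
#'
#' @param height,width bone section height and width in mm.
#' @param cortical_thickness thickness of the cortical band in mm.
#' @param thread_depth,thread_pitch thread fin depth and axial pitch in mm.
#' @param cap_height,cap_diameter cap dimensions in mm.
#' @param cortical_bottom logical; cortical band on the bottom surface too?
#' @param threads logical; `FALSE` gives a smooth (thread-less) implant
#'   profile for convergence studies.
#' @return an object of class `bone_spec`.
#' @export
bone_spec <- function(height = 24.2, width = 16.3, cortical_thickness = 2,
                      thread_depth = 1, thread_pitch = 1,
                      cap_height = 2, cap_diameter = 6,
                      cortical_bottom = FALSE, threads = TRUE) {
  stopifnot(height > 0, width > 0, cortical_thickness > 0,
            thread_depth >= 0, thread_pitch > 0, cap_height >= 0,
            cap_diameter > 0)
  if (cortical_thickness >= width / 2)
    stop("cortical_thickness must be smaller than half the bone width")
  structure(list(height = height, width = width,
                 cortical_thickness = cortical_thickness,
                 thread_depth = thread_depth, thread_pitch = thread_pitch,
                 cap_height = cap_height, cap_diameter = cap_diameter,
                 cortical_bottom = isTRUE(cortical_bottom),
                 threads = isTRUE(threads)),
            class = "bone_spec")
}

#' Region-boundary description of the bone-implant assembly
#'
#' Decomposes the axisymmetric half-section into closed, non-overlapping
#' regions: implant core and shell (merged into one `implant` region for the
#' conventional design), thread fins on the shell's outer boundary, ceramic
#' cap on top, and cortical/trabecular bone.  The description carries a
#' point-classification function used by the mesh generator and analytic
#' region areas used for mesh-convergence checks.
#'
#' @param config an [implant_config()].
#' @param bone a [bone_spec()].
#' @return an object of class `assembly_geometry`: a list with the key radii
#'   and heights, `region_of(r, z)` (vectorized classifier returning region
#'   labels or `NA` outside the solid domain) and `areas` (named vector of
#'   analytic r-z section areas in mm^2).
#' @export
#' @examples
#' geo <- build_assembly_geometry(
#'   implant_config("bilayer", 2, composite_shell_spec(10, 90, 10)),
#'   bone_spec())
#' geo$areas
build_assembly_geometry <- function(config, bone = bone_spec()) {
  stopifnot(inherits(config, "implant_config"), inherits(bone, "bone_spec"))
  r_body <- config$diameter / 2
  r_core <- config$core_diameter / 2
  r_bone <- bone$width / 2
  r_cap <- bone$cap_diameter / 2
  z_top <- bone$height                      # bone crest
  z_bot <- bone$height - config$length      # implant apex
  z_cap <- z_top + bone$cap_height
  depth <- if (bone$threads) bone$thread_depth else 0
  pitch <- bone$thread_pitch
  r_crest <- r_body + depth                 # fin crest radius
  r_cort <- r_bone - bone$cortical_thickness
  z_cort <- z_top - bone$cortical_thickness
  if (z_bot <= 0)
    stop("implant of length ", config$length,
         " mm does not fit inside a bone of height ", bone$height, " mm")
  if (r_cap > r_bone)
    stop("cap of diameter ", bone$cap_diameter,
         " mm is wider than the bone section")
  if (r_crest > r_cort)
    stop("thread crest radius ", r_crest,
         " mm reaches into the lateral cortical band")
  n_fins <- if (depth > 0) floor(config$length / pitch + 1e-9) else 0L
  z_fin_top <- z_bot + n_fins * pitch
  conventional <- config$implant_type == "conventional"

  # radial extent of the implant (body + fin profile) at height z; 0 outside
  implant_radius <- function(z) {
    r <- ifelse(z >= z_bot & z <= z_top, r_body, 0)
    if (depth > 0) {
      t <- (z - z_bot) / pitch
      frac <- t - floor(t)
      fin <- r_body + depth * (1 - abs(2 * frac - 1))
      r <- ifelse(z >= z_bot & z < z_fin_top, pmax(r, fin), r)
    }
    r
  }

  region_of <- function(r, z) {
    n <- max(length(r), length(z))
    r <- rep_len(r, n); z <- rep_len(z, n)
    out <- rep(NA_character_, n)
    in_cap <- z > z_top & z <= z_cap & r <= r_cap
    out[in_cap] <- "cap"
    in_impl <- z >= z_bot & z <= z_top & r < implant_radius(z)
    if (conventional) {
      out[in_impl] <- "implant"
    } else {
      out[in_impl & r < r_core] <- "core"
      out[in_impl & r >= r_core] <- "shell"
    }
    in_bone <- is.na(out) & z >= 0 & z <= z_top & r <= r_bone
    cort <- in_bone & (r >= r_cort | z >= z_cort |
                         (bone$cortical_bottom & z <= bone$cortical_thickness))
    out[cort] <- "cortical"
    out[in_bone & is.na(out)] <- "trabecular"
    out
  }

  # analytic r-z section areas
  fin_area_total <- n_fins * 0.5 * pitch * depth
  body_area <- r_body * config$length
  impl_area <- body_area + fin_area_total
  cap_area <- r_cap * bone$cap_height
  # fins intersecting the crestal cortical band z in [z_cort, z_top]
  fin_area_in_crest <- 0
  if (depth > 0 && n_fins > 0) {
    for (i in seq_len(n_fins)) {
      z0 <- z_bot + (i - 1) * pitch
      fin_area_in_crest <- fin_area_in_crest +
        .triangle_band_overlap(z0, pitch, depth, z_cort, z_top)
    }
  }
  lateral_area <- bone$cortical_thickness * z_top
  crest_area <- (r_cort - r_body) * bone$cortical_thickness -
    fin_area_in_crest
  bottom_area <- if (bone$cortical_bottom)
    bone$cortical_thickness * (r_cort - 0) else 0
  # crestal band only spans r in [implant body, r_cort]; implant occupies the
  # rest of that band's inner radius range
  cort_area <- lateral_area + crest_area + bottom_area
  bone_area <- r_bone * z_top
  trab_area <- bone_area - impl_area - cort_area
  areas <- if (conventional) {
    c(implant = impl_area, cap = cap_area, cortical = cort_area,
      trabecular = trab_area)
  } else {
    core_area <- r_core * config$length
    c(core = core_area, shell = impl_area - core_area, cap = cap_area,
      cortical = cort_area, trabecular = trab_area)
  }

  structure(list(
    config = config, bone = bone,
    r_body = r_body, r_core = r_core, r_bone = r_bone, r_cap = r_cap,
    r_crest = r_crest, r_cort = r_cort,
    z_bot = z_bot, z_top = z_top, z_cap = z_cap, z_cort = z_cort,
    depth = depth, pitch = pitch, n_fins = n_fins, z_fin_top = z_fin_top,
    conventional = conventional,
    region_of = region_of, implant_radius = implant_radius, areas = areas
  ), class = "assembly_geometry")
}

# r-z area of one triangular fin (base [z0, z0+pitch] on the body, apex at
# depth) clipped to the axial band [za, zb]
.triangle_band_overlap <- function(z0, pitch, depth, za, zb) {
  f <- function(z) {  # fin width at height z
    t <- (z - z0) / pitch
    ifelse(t < 0 | t > 1, 0, depth * (1 - abs(2 * t - 1)))
  }
  lo <- max(za, z0); hi <- min(zb, z0 + pitch)
  if (hi <= lo) return(0)
  # piecewise linear; integrate exactly over sub-intervals split at the apex
  mid <- z0 + pitch / 2
  segs <- unique(pmin(pmax(c(lo, mid, hi), lo), hi))
  segs <- sort(segs)
  a <- 0
  for (i in seq_len(length(segs) - 1L)) {
    z1 <- segs[i]; z2 <- segs[i + 1L]
    a <- a + (f(z1) + f(z2)) / 2 * (z2 - z1)
  }
  a
}

#' @export
print.assembly_geometry <- function(x, ...) {
  cat(sprintf(
    "<assembly_geometry> %s implant in %g x %g mm bone section\n",
    x$config$implant_type, x$bone$width, x$bone$height))
  cat(sprintf("  implant: r = %g mm, z in [%g, %g] mm, %d thread fins\n",
              x$r_body, x$z_bot, x$z_top, x$n_fins))
  cat("  region areas (mm^2):\n")
  print(round(x$areas, 4))
  invisible(x)
}
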