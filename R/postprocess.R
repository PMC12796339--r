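# Reduction of solution fields to the study's outcome metrics: per-region
# peak von Mises stress, bone-side interfacial microstrain, Frost
# mechanostat classification, and percent stress reduction relative to the
# conventional implant.

#' Frost mechanostat strain windows
#'
#' Thresholds (in microstrain) separating the bone-adaptation windows:
#' disuse below `disuse_upper`, adapted/homeostatic up to `adapted_upper`,
#' mild overload up to `overload_threshold` (its lower part, up to
#' `desirable_upper`, is the most desirable window for peri-implant bone),
#' and pathologic overload above.  The disuse threshold is not part of the
#' study's reported windows; the conventional 100 microstrain default is
#' used and is configurable.
#'
#' @param disuse_upper,adapted_upper,desirable_upper,overload_threshold
#'   strictly increasing thresholds in microstrain.
#' @return an object of class `mechanostat_windows`.
#' @export
#' @examples
#' mechanostat_windows()
mechanostat_windows <- function(disuse_upper = 100, adapted_upper = 1500,
                                desirable_upper = 2500,
                                overload_threshold = 4000) {
  th <- c(disuse_upper, adapted_upper, desirable_upper, overload_threshold)
  if (any(!is.finite(th)) || any(diff(th) <= 0))
    stop("mechanostat thresholds must be finite and strictly increasing")
  structure(list(disuse_upper = disuse_upper, adapted_upper = adapted_upper,
                 desirable_upper = desirable_upper,
                 overload_threshold = overload_threshold),
            class = "mechanostat_windows")
}

#' Classify microstrain into mechanostat windows
#'
#' Intervals are half-open `[lower, upper)`: a strain exactly on a
#' threshold belongs to the upper window (so exactly 1500 microstrain is
#' `mild_overload`).
#'
#' @param strain microstrain values (non-negative), vectorized.
#' @param windows a [mechanostat_windows()].
#' @return character vector with levels `disuse`, `adapted`,
#'   `mild_overload`, `pathologic_overload`; the `"desirable"` attribute
#'   flags values inside the most desirable sub-window
#'   `[adapted_upper, desirable_upper)`.
#' @export
#' @examples
#' classify_mechanostat(c(1200, 1500, 4633))
classify_mechanostat <- function(strain, windows = mechanostat_windows()) {
  stopifnot(inherits(windows, "mechanostat_windows"))
  if (any(strain < 0)) stop("strain must be non-negative (microstrain)")
  out <- ifelse(strain < windows$disuse_upper, "disuse",
         ifelse(strain < windows$adapted_upper, "adapted",
         ifelse(strain < windows$overload_threshold, "mild_overload",
                "pathologic_overload")))
  attr(out, "desirable") <- strain >= windows$adapted_upper &
    strain < windows$desirable_upper
  out
}

#' Peak von Mises stress within one region
#'
#' Maximum of the region-averaged nodal von Mises stress over the region,
#' with the location of the maximum.
#'
#' @param solution an `fe_solution`.
#' @param mesh the `region_mesh` it was solved on (used for location only;
#'   may be `NULL`).
#' @param region region label.
#' @return list with `value` (MPa), `node`, and `location` `(r, z)` in mm.
#' @export
region_max_von_mises <- function(solution, mesh = NULL, region) {
  stopifnot(inherits(solution, "fe_solution"))
  d <- solution$nodal[solution$nodal$region == region, ]
  if (nrow(d) == 0L)
    stop("solution has no nodal values in region '", region, "'")
  i <- which.max(d$von_mises)
  list(value = d$von_mises[i], node = d$node[i],
       location = c(r = d$r[i], z = d$z[i]))
}

#' Bone-side interfacial equivalent strain
#'
#' Maximum equivalent strain over the bone side of the bone-implant
#' interface, in microstrain.  By default only the cancellous (trabecular)
#' side is considered, matching the study's definition of the interfacial
#' metric; include `"cortical"` in `bone_regions` for the crestal band as
#' well.  Because re-entrant thread-root corners are singular in linear
#' elasticity and the raw maximum is therefore mesh-sensitive, a high
#' percentile of the same nodal values is always co-reported.
#'
#' @param solution an `fe_solution`.
#' @param mesh the `region_mesh` carrying the `bone_implant_interface` tag.
#' @param bone_regions bone regions whose interface nodes are sampled.
#' @param percentile probability of the co-reported quantile.
#' @return list with `max_ue`, `percentile_ue`, `percentile`, `node` and
#'   `location` of the maximum.
#' @export
interfacial_strain <- function(solution, mesh,
                               bone_regions = "trabecular",
                               percentile = 0.99) {
  stopifnot(inherits(solution, "fe_solution"),
            inherits(mesh, "region_mesh"))
  nodes <- mesh$tags$bone_implant_interface
  if (is.null(nodes) || length(nodes) == 0L)
    stop("mesh has no bone_implant_interface tag")
  d <- solution$nodal[solution$nodal$node %in% nodes &
                        solution$nodal$region %in% bone_regions, ]
  if (nrow(d) == 0L)
    stop("no interface nodes border region(s): ",
         paste(bone_regions, collapse = ", "))
  ue <- d$eq_strain * 1e6
  i <- which.max(ue)
  list(max_ue = ue[i],
       percentile_ue = as.numeric(stats::quantile(ue, percentile)),
       percentile = percentile,
       node = d$node[i], location = c(r = d$r[i], z = d$z[i]))
}

#' Percent stress reduction relative to a reference design
#'
#' `100 * (reference - design) / reference`.
#'
#' @param reference_max reference peak stress in MPa (must be positive).
#' @param design_max design peak stress in MPa.
#' @return reduction in percent (negative if the design is worse).
#' @export
#' @examples
#' stress_reduction(83, 24.9)
stress_reduction <- function(reference_max, design_max) {
  if (any(!is.finite(reference_max)) || any(reference_max <= 0))
    stop("reference_max must be positive")
  100 * (reference_max - design_max) / reference_max
}
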