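#' Measure biparietal and occipitofrontal diameters
#'
#' BPD (skull width) and OFD (skull length) are the maximal mediolateral and
#' anteroposterior extents of the (optionally deformed) outer surface, taken
#' over points on or above the reference plane.  Extents are axis-aligned in
#' the fixed anatomical frame (+x anterior, +y left, +z superior); the skull
#' base is fully constrained during simulation, so no re-registration is
#' needed.
#'
#' @param mesh A `skull_mesh`.
#' @param displacement Optional n x 3 nodal displacement matrix (mm).
#' @return Named numeric vector `c(bpd_mm, ofd_mm)`.
#' @export
#' @examples
#' sk <- generate_skull(skull_params(mesh_size_mm = 16))
#' measure_bpd_ofd(sk)
measure_bpd_ofd <- function(mesh, displacement = NULL) {
  stopifnot(inherits(mesh, "skull_mesh"))
  if (!is.null(mesh$node_grid)) {
    e <- function(coord, sgn) .grid_extreme(mesh, displacement, coord, sgn)
    return(c(bpd_mm = e(2, 1) - e(2, -1), ofd_mm = e(1, 1) - e(1, -1)))
  }
  ids <- if (!is.null(mesh$outer_all)) mesh$outer_all else mesh$outer_nodes
  if (is.null(ids)) stop("mesh carries no outer surface")
  pts <- mesh$nodes[ids, , drop = FALSE]
  if (!is.null(displacement)) {
    stopifnot(nrow(displacement) == nrow(mesh$nodes))
    pts <- pts + displacement[ids, , drop = FALSE]
  }
  pp <- mesh$ref_plane$point
  nn <- mesh$ref_plane$normal
  above <- as.vector((pts - matrix(pp, nrow(pts), 3, byrow = TRUE)) %*%
                       nn) >= -1e-6
  pts <- pts[above, , drop = FALSE]
  if (nrow(pts) == 0) stop("no outer-surface points above the reference plane")
  c(bpd_mm = max(pts[, 2]) - min(pts[, 2]),
    ofd_mm = max(pts[, 1]) - min(pts[, 1]))
}

# sub-grid extremum of one deformed outer-surface coordinate: the discrete
# nodal maximum is refined by 1D parabolas along the two surface grid
# directions, so diameters evolve smoothly in time instead of jumping when
# the winning node changes
.grid_extreme <- function(mesh, displacement, coord, sgn) {
  g <- mesh$node_grid[, , 1]
  P <- mesh$nodes
  if (!is.null(displacement)) {
    stopifnot(nrow(displacement) == nrow(mesh$nodes))
    P <- P + displacement
  }
  above <- (P[, 3] - mesh$ref_plane$point[3]) >= -1e-6
  U <- matrix(sgn * P[g, coord], nrow(g), ncol(g))
  U[!above[g]] <- -Inf
  if (!any(is.finite(U)))
    stop("no outer-surface points above the reference plane")
  ij <- arrayInd(which.max(U), dim(U))
  i0 <- ij[1]; k0 <- ij[2]
  v <- U[i0, k0]
  para <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (!is.finite(vm) || !is.finite(vp) || den >= -1e-12) return(0)
    -(vp - vm)^2 / (8 * den)
  }
  dv <- 0
  if (i0 > 1 && i0 < nrow(U))
    dv <- dv + para(U[i0 - 1, k0], v, U[i0 + 1, k0])
  if (k0 > 1 && k0 < ncol(U))
    dv <- dv + para(U[i0, k0 - 1], v, U[i0, k0 + 1])
  sgn * (v + dv)
}

#' Cranial index and its change from baseline
#'
#' The cranial index is `CI = BPD / OFD`; the change is reported in
#' percentage points, `delta = 100 (CI(t) - CI(0))`, matching the clinical
#' convention of quoting CI as a percentage.
#'
#' @param bpd_mm,ofd_mm Current diameters (mm); `ofd_mm` must be positive.
#' @param baseline_ci Optional baseline CI (dimensionless) for the delta.
#' @return Tibble with `ci` (dimensionless), `ci_pct` and, when a baseline is
#'   given, `delta_ci_points`.
#' @export
#' @examples
#' compute_ci(108.3, 152.6)            # CI ~ 0.7097
#' compute_ci(113.5, 152.6, 0.7097)    # widened skull vs baseline
compute_ci <- function(bpd_mm, ofd_mm, baseline_ci = NULL) {
  if (any(ofd_mm <= 0)) stop("ofd_mm must be positive")
  if (any(bpd_mm <= 0)) stop("bpd_mm must be positive")
  ci <- bpd_mm / ofd_mm
  out <- tibble::tibble(ci = ci, ci_pct = 100 * ci)
  if (!is.null(baseline_ci))
    out$delta_ci_points <- 100 * (ci - baseline_ci)
  out
}

#' Craniometric time series of an expansion result
#'
#' Measures BPD, OFD, CI and the CI change (percentage points relative to
#' the undeformed state) at every recorded output time.
#'
#' @param result An `expansion_result` from [solve_expansion()].
#' @return Tibble with one row per time point: `time_s`, `bpd_mm`, `ofd_mm`,
#'   `ci`, `delta_ci_points`.
#' @export
cranial_measurements <- function(result) {
  stopifnot(inherits(result, "expansion_result"))
  mesh <- result$mesh
  base <- measure_bpd_ofd(mesh)
  ci0 <- base[["bpd_mm"]] / base[["ofd_mm"]]
  purrr::map_dfr(names(result$displacements), function(tn) {
    d <- measure_bpd_ofd(mesh, result$displacements[[tn]])
    tibble::tibble(time_s = as.numeric(tn),
                   bpd_mm = d[["bpd_mm"]], ofd_mm = d[["ofd_mm"]],
                   ci = d[["bpd_mm"]] / d[["ofd_mm"]],
                   delta_ci_points = 100 * (.data$ci - ci0))
  })
}

#' Normalize surgical parameters by skull dimensions
#'
#' Osteotomy distance is normalized by skull width, spring positions by skull
#' length: `LAT% = 100 LAT / BPD`, `A% = 100 A / OFD`, `B% = 100 B / OFD`;
#' the posterior spring position is `(A+B)% = A% + B%` and the combined
#' stiffness is `K_TOT = K_ANT + K_POST`.
#'
#' @param lat_mm,a_mm,b_mm Absolute surgical distances (mm).
#' @param bpd_mm,ofd_mm Skull dimensions (mm).
#' @param k_ant,k_post Spring stiffnesses (N/mm).
#' @return One-row tibble with `lat_pct`, `a_pct`, `b_pct`, `a_plus_b_pct`,
#'   `k_ant`, `k_post`, `k_tot`.
#' @export
#' @examples
#' normalize_surgical(18.3, 47.92, 26.2, 108.3, 152.6, 0.17, 0.68)
normalize_surgical <- function(lat_mm, a_mm, b_mm, bpd_mm, ofd_mm,
                               k_ant = NA_real_, k_post = NA_real_) {
  stopifnot(all(c(lat_mm, b_mm, bpd_mm, ofd_mm) > 0), a_mm >= 0)
  tibble::tibble(
    lat_pct = 100 * lat_mm / bpd_mm,
    a_pct = 100 * a_mm / ofd_mm,
    b_pct = 100 * b_mm / ofd_mm,
    a_plus_b_pct = .data$a_pct + .data$b_pct,
    k_ant = k_ant, k_post = k_post,
    k_tot = k_ant + k_post
  )
}

#' Invert the surgical-parameter normalization
#'
#' @param lat_pct,a_pct,b_pct Normalized parameters (percent).
#' @param bpd_mm,ofd_mm Skull dimensions (mm).
#' @return One-row tibble with `lat_mm`, `a_mm`, `b_mm`.
#' @export
denormalize_surgical <- function(lat_pct, a_pct, b_pct, bpd_mm, ofd_mm) {
  tibble::tibble(lat_mm = lat_pct * bpd_mm / 100,
                 a_mm = a_pct * ofd_mm / 100,
                 b_mm = b_pct * ofd_mm / 100)
}

#' Percent difference relative to a reference value
#'
#' `100 * (value - reference) / reference`; used e.g. to compare a template
#' skull dimension with its population average.
#'
#' @param value,reference Numeric.
#' @return Percent difference.
#' @export
percent_difference <- function(value, reference) {
  if (any(reference == 0)) stop("reference must be non-zero")
  100 * (value - reference) / reference
}
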