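#' Parameters of the synthetic scaphocephalic calvarium
#'
#' Constructs the parameter set for [generate_skull()].  The generator stands
#' in for a CT-derived population-average skull: a half-superellipsoid vault
#' shell with uniform thickness, two suture bands (coronal, lambdoid) defined
#' by inclined planes, and a fully constrained inferior border lying on the
#' reference (nasion--meatus analogue) plane.
#'
#' Defaults reproduce the population means of the study cohort: outer length
#' (occipitofrontal diameter, OFD) 152.6 mm, outer width (biparietal diameter,
#' BPD) 108.3 mm, shell thickness 2.02 mm, suture plane angles 81.5 deg
#' (coronal) and 70.9 deg (lambdoid) to the reference plane, 2 mm suture
#' width.  Scaphocephalic proportions require `ofd_mm > bpd_mm` (cranial
#' index below 1).
#'
#' @param ofd_mm Anteroposterior outer length of the vault (mm).
#' @param bpd_mm Mediolateral outer width (mm); must be less than `ofd_mm`.
#' @param height_mm Vault height above the reference plane (mm).  Not printed
#'   in the source population tables; the default 66 mm is a plausible
#'   vault height for a 5-month infant (about 0.43 of OFD).
#' @param thickness_mm Uniform shell thickness (mm).
#' @param alpha_deg Angle between the coronal-suture plane and the reference
#'   plane (degrees, in (0, 90)).
#' @param beta_deg Angle between the lambdoid-suture plane and the reference
#'   plane (degrees, in (0, 90)).
#' @param suture_width_mm Width of each suture band (mm).
#' @param mesh_size_mm Target element edge length (mm).
#' @param superellipse_exponent Exponent of the superellipsoid vault surface;
#'   2 gives an ellipsoid, larger values flatten the vertex.  Default 2.5.
#' @param eminence_frac Relative width bulge of the parietal eminence.  Real
#'   calvaria are widest at the parietal eminences, well above the
#'   nasion--meatus plane; the generator widens the wall by this fraction at
#'   the eminence height so the biparietal diameter is measured on free
#'   (unconstrained) bone rather than on the fixed base rim.  Default 0.05.
#' @param eminence_height_frac Height of the eminence bulge as a fraction of
#'   the vault height.  Default 0.3.
#' @param coronal_arc_frac,lambdoid_arc_frac Positions of the suture plane
#'   anchors, expressed as fractions of the front-to-back arc length of the
#'   midsagittal outer curve.  The defaults (0.30, 0.79) give a parietal arc
#'   long enough to accommodate the full surgical design space of spring
#'   positions.
#' @param suture_modulus_scale Stiffness multiplier applied to elements in
#'   the coronal and lambdoid suture bands.  Patent (unfused) sutures in a
#'   5-month infant are fibrous tissue, far more compliant than the
#'   surrounding bone; the default 0.1 keeps them an order of magnitude
#'   softer.  Set to 1 for bone-stiff sutures.
#' @param n_layers Number of element layers through the shell thickness
#'   (at least 2).
#' @return An object of class `skull_params`.
#' @export
#' @examples
#' p <- skull_params()
#' p$ofd_mm / p$bpd_mm   # scaphocephalic aspect ratio ~ 1.41
skull_params <- function(ofd_mm = 152.6,
                         bpd_mm = 108.3,
                         height_mm = 66,
                         thickness_mm = 2.02,
                         alpha_deg = 81.5,
                         beta_deg = 70.9,
                         suture_width_mm = 2,
                         mesh_size_mm = 9,
                         superellipse_exponent = 2.5,
                         eminence_frac = 0.05,
                         eminence_height_frac = 0.3,
                         coronal_arc_frac = 0.30,
                         lambdoid_arc_frac = 0.79,
                         suture_modulus_scale = 0.1,
                         n_layers = 2) {
  stopifnot(
    ofd_mm > 0, bpd_mm > 0, height_mm > 0,
    thickness_mm > 0, suture_width_mm > 0, mesh_size_mm > 0,
    superellipse_exponent >= 2, n_layers >= 2,
    suture_modulus_scale > 0, suture_modulus_scale <= 1,
    eminence_frac >= 0, eminence_frac < 0.2,
    eminence_height_frac > 0, eminence_height_frac < 1,
    0 < coronal_arc_frac, coronal_arc_frac < lambdoid_arc_frac,
    lambdoid_arc_frac < 1
  )
  if (ofd_mm <= bpd_mm)
    stop("ofd_mm must exceed bpd_mm (scaphocephalic proportions, CI < 1)")
  if (alpha_deg <= 0 || alpha_deg >= 90 || beta_deg <= 0 || beta_deg >= 90)
    stop("suture plane angles must lie strictly between 0 and 90 degrees")
  structure(
    list(ofd_mm = ofd_mm, bpd_mm = bpd_mm, height_mm = height_mm,
         thickness_mm = thickness_mm, alpha_deg = alpha_deg,
         beta_deg = beta_deg, suture_width_mm = suture_width_mm,
         mesh_size_mm = mesh_size_mm,
         superellipse_exponent = superellipse_exponent,
         eminence_frac = eminence_frac,
         eminence_height_frac = eminence_height_frac,
         coronal_arc_frac = coronal_arc_frac,
         lambdoid_arc_frac = lambdoid_arc_frac,
         suture_modulus_scale = suture_modulus_scale,
         n_layers = n_layers),
    class = "skull_params"
  )
}

#' Osteotomy and spring-site specification
#'
#' Describes the two parasagittal cuts and the two spring sites placed on
#' them.  Distances `a_mm` and `b_mm` are arc lengths measured along the cut
#' line on the outer surface, starting at the coronal-suture centre plane.
#'
#' @param lat_mm Mediolateral distance between the two parasagittal cuts (mm).
#' @param a_mm Arc distance of the anterior spring site from the coronal
#'   suture (mm).
#' @param b_mm Arc distance from the anterior to the posterior spring site
#'   (mm); must be positive (coincident springs are rejected).
#' @param notch_radius_mm Radius of the semicircular notch node set at each
#'   spring foot (mm).
#' @return An object of class `osteotomy_spec`.
#' @export
osteotomy_spec <- function(lat_mm, a_mm, b_mm, notch_radius_mm = 2.5) {
  stopifnot(lat_mm > 0, a_mm >= 0, notch_radius_mm > 0)
  if (!(b_mm > 0)) stop("b_mm must be positive: coincident spring sites")
  structure(list(lat_mm = lat_mm, a_mm = a_mm, b_mm = b_mm,
                 notch_radius_mm = notch_radius_mm),
            class = "osteotomy_spec")
}

# ---- superellipsoid surface helpers -----------------------------------------

# signed power used by the superellipse parameterisation
.spow <- function(u, q) sign(u) * abs(u)^q

# outer-surface point of the vault at parameter (psi, y); psi in [0, pi] runs
# from the anterior base (psi = 0) over the vertex to the posterior base.
.outer_xyz <- function(psi, y, a, b, c, p) {
  m <- pmax(1 - (abs(y) / b)^p, 0)
  r <- m^(1 / p)
  cbind(x = a * r * .spow(cos(psi), 2 / p),
        y = y,
        z = c * r * abs(sin(psi))^(2 / p))
}

# outward unit normal of the superellipsoid F = (|x|/a)^p+(|y|/b)^p+(|z|/c)^p
.outer_normal <- function(xyz, a, b, c, p) {
  g <- cbind(.spow(xyz[, 1] / a, p - 1) / a,
             .spow(xyz[, 2] / b, p - 1) / b,
             .spow(xyz[, 3] / c, p - 1) / c)
  g / sqrt(rowSums(g^2))
}

# arc length of the midsagittal (y = 0) outer curve, finely sampled
.midsagittal_arc <- function(a, c, p, n = 2000) {
  psi <- seq(0, pi, length.out = n + 1)
  pts <- .outer_xyz(psi, 0, a, 1, c, p)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 3])^2)
  list(psi = psi, pts = pts, s = c(0, cumsum(seg)))
}

# signed distances to the suture planes (positive on the anterior side);
# planes contain the mediolateral axis and are inclined to the reference plane
.suture_planes <- function(params) {
  a <- params$ofd_mm / 2
  c <- params$height_mm
  p <- params$superellipse_exponent
  al <- params$alpha_deg * pi / 180
  be <- params$beta_deg * pi / 180
  arc <- .midsagittal_arc(a, c, p)
  total <- arc$s[length(arc$s)]
  anchor <- function(frac, tilt_sign, ang) {
    sp <- arc$s[length(arc$s)] * frac
    i <- which.min(abs(arc$s - sp))
    xf <- arc$pts[i, 1]; zf <- arc$pts[i, 3]
    # plane through (xf, zf): (x - x0) sin(ang) +/- z cos(ang) = 0
    xf + tilt_sign * zf * cos(ang) / sin(ang)
  }
  list(
    coronal = list(x0 = anchor(params$coronal_arc_frac, +1, al), ang = al),
    lambdoid = list(x0 = anchor(params$lambdoid_arc_frac, -1, be), ang = be),
    arc_total = total
  )
}

# coronal: top of the plane leans posteriorly; lambdoid: top leans anteriorly
.dist_coronal <- function(su, x, z)
  (x - su$coronal$x0) * sin(su$coronal$ang) + z * cos(su$coronal$ang)
.dist_lambdoid <- function(su, x, z)
  (x - su$lambdoid$x0) * sin(su$lambdoid$ang) - z * cos(su$lambdoid$ang)

# signed volumes of linear tets, vectorised
.tet_volumes <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  d1 <- nodes[elems[, 2], , drop = FALSE] - p1
  d2 <- nodes[elems[, 3], , drop = FALSE] - p1
  d3 <- nodes[elems[, 4], , drop = FALSE] - p1
  cx <- d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]
  cy <- d2[, 3] * d3[, 1] - d2[, 1] * d3[, 3]
  cz <- d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1]
  (d1[, 1] * cx + d1[, 2] * cy + d1[, 3] * cz) / 6
}

# Kuhn 6-tet decomposition of a hexahedron given its 8 corner ids in
# (000,100,110,010,001,101,111,011) order; translation-consistent so the
# decomposition conforms across neighbouring cells.
.kuhn_tets <- function(v) {
  rbind(c(v[1], v[2], v[3], v[7]),
        c(v[1], v[3], v[4], v[7]),
        c(v[1], v[4], v[8], v[7]),
        c(v[1], v[8], v[5], v[7]),
        c(v[1], v[5], v[6], v[7]),
        c(v[1], v[6], v[2], v[7]))
}

# ---- generator --------------------------------------------------------------

#' Generate the synthetic scaphocephalic calvarium mesh
#'
#' Builds a bilaterally symmetric half-superellipsoid vault shell of the
#' requested outer length/width/height, thickened inward by the shell
#' thickness, meshed with linear tetrahedra (at least two element layers
#' through the thickness).  Elements are partitioned into five regions
#' (frontal, coronal suture, parietal, lambdoid suture, occipital) by two
#' inclined suture planes, and all rim nodes on the reference plane form the
#' fully constrained base set.
#'
#' The mesh is structured: nodes live on a (arc parameter) x (mediolateral
#' station) x (thickness layer) grid.  The left half connectivity is the
#' mirror image of the right half, so the node set, the element set and the
#' region labels are exactly symmetric about the midsagittal plane.
#'
#' @param params A [skull_params()] object.
#' @param y_stations Optional explicit mediolateral station values
#'   (internal use: [apply_osteotomies()] re-generates the mesh with stations
#'   remapped so the cut planes are mesh planes).
#' @return An object of class `skull_mesh` with fields `nodes` (n x 3, mm),
#'   `elems` (m x 4 tetrahedra), `region` (factor per element),
#'   `base_nodes`, `ref_plane`, `outer_nodes`, `inner_nodes`, `notch_pairs`
#'   (empty until osteotomies are applied) and generator bookkeeping.
#' @export
#' @examples
#' sk <- generate_skull(skull_params(mesh_size_mm = 16))
#' table(sk$region)
generate_skull <- function(params, y_stations = NULL) {
  stopifnot(inherits(params, "skull_params"))
  a <- params$ofd_mm / 2
  c <- params$height_mm
  p <- params$superellipse_exponent
  th <- params$thickness_mm
  h <- params$mesh_size_mm
  nw <- params$n_layers

  # parietal-eminence width profile: the wall is widest at the eminence
  # height (free bone), slightly narrower at the constrained base rim
  z_e <- params$eminence_height_frac * c
  w_of_z <- function(z) {
    if (params$eminence_frac == 0) return(rep(1, length(z)))
    1 + params$eminence_frac * (z / z_e) * exp(1 - z / z_e)
  }
  # calibrate the slice half-width so the measured BPD matches bpd_mm
  zz <- seq(0, c, length.out = 400)
  rho0 <- (pmax(1 - (zz / c)^p, 0))^(1 / p)
  b <- (params$bpd_mm / 2) / max(rho0 * w_of_z(zz))

  # keep the most lateral slice large enough that the inward offset cannot
  # invert elements (slice height at least ~5 shell thicknesses)
  m_min <- (5 * th / c)^p
  y_max <- b * (1 - m_min)^(1 / p)

  arc <- .midsagittal_arc(a, c, p)
  sag_len <- arc$s[length(arc$s)]
  crest <- .outer_xyz(pi / 2, seq(-y_max, y_max, length.out = 400), a, b, c, p)
  trans_len <- sum(sqrt(diff(crest[, 2])^2 + diff(crest[, 3])^2))

  npsi <- max(10L, as.integer(ceiling(sag_len / h)))
  ny <- max(10L, as.integer(ceiling(trans_len / h)))
  if (ny %% 2L == 1L) ny <- ny + 1L

  if (is.null(y_stations)) {
    s <- seq(-1, 1, length.out = ny + 1)
    y_stations <- y_max * sin(pi * s / 2)
    y_stations <- (y_stations - rev(y_stations)) / 2  # exact antisymmetry
  } else {
    stopifnot(length(y_stations) == ny + 1)
  }

  psi <- seq(0, pi, length.out = npsi + 1)

  # outer-surface grid (psi x y station), then the eminence morph in y
  gi <- rep(seq_len(npsi + 1), times = ny + 1)
  gk <- rep(seq_len(ny + 1), each = npsi + 1)
  P0 <- .outer_xyz(psi[gi], y_stations[gk], a, b, c, p)
  dim_g <- c(npsi + 1, ny + 1)
  gX <- array(P0[, 1], dim_g)
  gY <- array(P0[, 2] * w_of_z(P0[, 3]), dim_g)
  gZ <- array(P0[, 3], dim_g)

  # outward normals of the morphed surface from grid tangents
  dgrid <- function(M, along) {
    n1 <- dim(M)[1]; n2 <- dim(M)[2]
    D <- array(0, dim(M))
    if (along == 1) {
      D[2:(n1 - 1), ] <- M[3:n1, ] - M[1:(n1 - 2), ]
      D[1, ] <- M[2, ] - M[1, ]
      D[n1, ] <- M[n1, ] - M[n1 - 1, ]
    } else {
      D[, 2:(n2 - 1)] <- M[, 3:n2] - M[, 1:(n2 - 2)]
      D[, 1] <- M[, 2] - M[, 1]
      D[, n2] <- M[, n2] - M[, n2 - 1]
    }
    D
  }
  tx1 <- dgrid(gX, 1); ty1 <- dgrid(gY, 1); tz1 <- dgrid(gZ, 1)
  tx2 <- dgrid(gX, 2); ty2 <- dgrid(gY, 2); tz2 <- dgrid(gZ, 2)
  nx <- ty1 * tz2 - tz1 * ty2
  nyc <- tz1 * tx2 - tx1 * tz2
  nz <- tx1 * ty2 - ty1 * tx2
  nl <- sqrt(nx^2 + nyc^2 + nz^2)
  nx <- nx / nl; nyc <- nyc / nl; nz <- nz / nl
  # orient outward using the analytic pre-morph normal
  g0 <- .outer_normal(P0, a, b, c, p)
  flip <- (nx * array(g0[, 1], dim_g) + nyc * array(g0[, 2], dim_g) +
             nz * array(g0[, 3], dim_g)) < 0
  nx[flip] <- -nx[flip]; nyc[flip] <- -nyc[flip]; nz[flip] <- -nz[flip]

  # nodes: outer surface thickened inward layer by layer
  n_per_layer <- (npsi + 1) * (ny + 1)
  nodes <- matrix(0, n_per_layer * (nw + 1), 3)
  for (w in 0:nw) {
    f <- w / nw * th
    rows <- w * n_per_layer + seq_len(n_per_layer)
    nodes[rows, ] <- cbind(as.vector(gX - f * nx),
                           as.vector(gY - f * nyc),
                           as.vector(gZ - f * nz))
  }
  colnames(nodes) <- c("x", "y", "z")
  idx <- array(seq_len(nrow(nodes)), dim = c(npsi + 1, ny + 1, nw + 1))
  w_top <- w_of_z(max(gZ))

  # hexahedral cells -> tets; right half standard, left half mirrored
  cells <- expand.grid(i = seq_len(npsi), k = seq_len(ny), w = seq_len(nw))
  n_cells <- nrow(cells)
  elems <- matrix(0L, nrow = 6 * n_cells, ncol = 4)
  elem_cell_k <- integer(6 * n_cells)
  corner_order <- cbind(di = c(0, 1, 1, 0, 0, 1, 1, 0),
                        dk = c(0, 0, 1, 1, 0, 0, 1, 1),
                        dw = c(0, 0, 0, 0, 1, 1, 1, 1))
  for (cc in seq_len(n_cells)) {
    i0 <- cells$i[cc]; k0 <- cells$k[cc]; w0 <- cells$w[cc]
    right <- k0 > ny / 2
    dk <- corner_order[, "dk"]
    if (!right) dk <- 1 - dk          # mirror the decomposition on the left
    v <- idx[cbind(i0 + corner_order[, "di"], k0 + dk,
                   w0 + corner_order[, "dw"])]
    tt <- .kuhn_tets(v)
    if (!right) tt <- tt[, c(1, 2, 4, 3)]  # restore orientation after mirror
    rows <- (6 * (cc - 1) + 1):(6 * cc)
    elems[rows, ] <- tt
    elem_cell_k[rows] <- k0
  }

  vols <- .tet_volumes(nodes, elems)
  neg <- vols < 0
  if (any(neg)) {  # orientation fix; geometry unchanged
    elems[neg, 3:4] <- elems[neg, c(4, 3)]
    vols[neg] <- -vols[neg]
  }
  if (any(vols < 1e-9)) {
    bad <- which.min(vols)
    stop(sprintf(paste0("degenerate element %d (volume %.3g mm^3); ",
                        "reduce mesh_size_mm or check thickness_mm"),
                 bad, vols[bad]))
  }

  # region labels from element centroids against the suture planes; elements
  # crossing a plane are labelled as suture so the bands are never empty even
  # when the mesh is coarser than the anatomical suture width
  su <- .suture_planes(params)
  half_w <- params$suture_width_mm / 2
  cent <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
             nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
  dc_n <- matrix(.dist_coronal(su, nodes[t(elems), 1], nodes[t(elems), 3]),
                 ncol = 4, byrow = TRUE)
  dl_n <- matrix(.dist_lambdoid(su, nodes[t(elems), 1], nodes[t(elems), 3]),
                 ncol = 4, byrow = TRUE)
  dc <- .dist_coronal(su, cent[, 1], cent[, 3])
  dl <- .dist_lambdoid(su, cent[, 1], cent[, 3])
  on_cor <- (abs(dc) <= half_w) |
    (apply(dc_n, 1, min) < 0 & apply(dc_n, 1, max) > 0)
  on_lam <- (abs(dl) <= half_w) |
    (apply(dl_n, 1, min) < 0 & apply(dl_n, 1, max) > 0)
  region <- rep("parietal", nrow(elems))
  region[dc > 0] <- "frontal"
  region[dl < 0] <- "occipital"
  region[on_cor] <- "coronal_suture"
  region[on_lam] <- "lambdoid_suture"
  region <- factor(region, levels = c("frontal", "coronal_suture", "parietal",
                                      "lambdoid_suture", "occipital"))

  # rim nodes on (or, for inner layers, within a small offset of) the
  # reference plane
  base_nodes <- which(nodes[, 3] <= 0.15 * th)

  elem_scale <- rep(1, nrow(elems))
  elem_scale[region %in% c("coronal_suture", "lambdoid_suture")] <-
    params$suture_modulus_scale

  structure(
    list(nodes = nodes,
         elems = elems,
         region = region,
         elem_scale = elem_scale,
         base_nodes = base_nodes,
         ref_plane = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
         outer_nodes = as.vector(idx[, , 1]),
         inner_nodes = as.vector(idx[, , nw + 1]),
         outer_all = as.vector(idx[, , 1]),
         node_grid = idx,
         psi = psi, y_stations = y_stations, y_max = y_max,
         elem_cell_k = elem_cell_k,
         morph = list(w_top = w_top, b_slice = b),
         sutures = su,
         params = params,
         notch_pairs = list(),
         cut_faces = list(),
         osteotomy = NULL),
    class = "skull_mesh"
  )
}

#' @export
print.skull_mesh <- function(x, ...) {
  cat("<skull_mesh>", nrow(x$nodes), "nodes,", nrow(x$elems), "tets\n")
  cat("  regions:", paste(sprintf("%s=%d", levels(x$region),
                                  tabulate(x$region)), collapse = ", "), "\n")
  if (!is.null(x$osteotomy))
    cat(sprintf("  osteotomies: LAT %.1f mm, sites at %.1f / %.1f mm arc\n",
                x$osteotomy$lat_mm, x$osteotomy$a_mm,
                x$osteotomy$a_mm + x$osteotomy$b_mm))
  invisible(x)
}

# outer-surface polyline along a cut station and its arc coordinate, with the
# coronal / lambdoid crossings (arc measured from the anterior base)
.cut_line_arcs <- function(mesh, k_station) {
  out <- mesh$node_grid[, k_station, 1]
  pts <- mesh$nodes[out, , drop = FALSE]
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  dc <- .dist_coronal(mesh$sutures, pts[, 1], pts[, 3])
  dl <- .dist_lambdoid(mesh$sutures, pts[, 1], pts[, 3])
  cross0 <- function(d) {
    i <- which(d[-length(d)] > 0 & d[-1] <= 0)[1]
    if (is.na(i)) return(NA_real_)
    f <- d[i] / (d[i] - d[i + 1])
    s[i] + f * (s[i + 1] - s[i])
  }
  list(s = s, d_cor = dc, d_lam = dl,
       s_coronal = cross0(dc), s_lambdoid = cross0(dl))
}

#' Apply parasagittal osteotomies and spring notches
#'
#' Introduces two parasagittal cuts, separated by `lat_mm`, as zero-width
#' duplicated-node cracks spanning the parietal region between the suture
#' bands, and places two notch node-set pairs at arc distances `a_mm` and
#' `a_mm + b_mm` from the coronal suture along the cuts.  Each notch pair
#' holds the lateral (wall-side) faces of the left and right cuts at the same
#' arc station; a spring condition attached to the pair pushes the two
#' parietal walls apart across the freed central strip, so its initial
#' opening equals `lat_mm`.
#'
#' The mesh is re-generated with the mediolateral stations smoothly remapped
#' so that the cut planes are exact mesh planes; region labels, symmetry and
#' shell thickness are preserved.
#'
#' @param mesh A `skull_mesh` from [generate_skull()] (uncut).
#' @param spec An [osteotomy_spec()].
#' @return The cut `skull_mesh`, with `notch_pairs` (named `anterior`,
#'   `posterior`), `cut_faces` bookkeeping and the spec stored.
#' @export
apply_osteotomies <- function(mesh, spec) {
  stopifnot(inherits(mesh, "skull_mesh"), inherits(spec, "osteotomy_spec"))
  if (!is.null(mesh$osteotomy)) stop("mesh already carries osteotomies")
  out <- .build_cut(mesh, spec, spec$lat_mm / 2 / mesh$morph$w_top)
  # one corrective pass: retarget the station so the measured notch-centroid
  # separation equals lat_mm (the eminence morph and the inward thickness
  # offset make the raw station value a close but inexact proxy)
  sep <- mean(vapply(out$notch_pairs, function(np)
    sqrt(sum((colMeans(out$nodes[np$right, , drop = FALSE]) -
                colMeans(out$nodes[np$left, , drop = FALSE]))^2)),
    numeric(1)))
  target <- attr(out, "y_target") * spec$lat_mm / sep
  out <- .build_cut(mesh, spec, target)
  attr(out, "y_target") <- NULL
  out
}

# generate-and-cut at a given (pre-morph) station target for lat/2
.build_cut <- function(mesh, spec, y_target) {
  ny <- length(mesh$y_stations) - 1
  ys <- mesh$y_stations
  if (y_target >= ys[ny]) stop("lat_mm too large for this vault width")

  # choose the station closest to the target (strictly inside the right half)
  cand <- (ny / 2 + 2):(ny - 1)  # 1-based station indices with y > 0, not rim
  k_r <- cand[which.min(abs(ys[cand] - y_target))]

  # piecewise-linear remap of |y| sending that station exactly to the target
  knots_old <- c(0, ys[k_r], mesh$y_max)
  knots_new <- c(0, y_target, mesh$y_max)
  if (any(diff(knots_new) <= 0))
    stop("lat_mm incompatible with mesh resolution; refine the mesh")
  new_ys <- stats::approx(knots_old, knots_new, abs(ys))$y * sign(ys)
  new_ys <- (new_ys - rev(new_ys)) / 2
  mesh2 <- generate_skull(mesh$params, y_stations = new_ys)

  k_l <- ny + 2 - k_r            # mirror station (1-based)

  half_w <- mesh2$params$suture_width_mm / 2

  cut_one <- function(mesh2, k_station, wall_is_positive) {
    cl <- .cut_line_arcs(mesh2, k_station)
    if (is.na(cl$s_coronal) || is.na(cl$s_lambdoid))
      stop("suture planes do not intersect the cut line; check arc fractions")
    # stations strictly between the suture bands
    inside <- which(cl$d_cor < -half_w & cl$d_lam > half_w)
    if (length(inside) < 3)
      stop("mesh too coarse: fewer than 3 stations on the parietal cut")
    dup_ids <- as.vector(mesh2$node_grid[inside, k_station, ])
    n0 <- nrow(mesh2$nodes)
    mesh2$nodes <- rbind(mesh2$nodes, mesh2$nodes[dup_ids, , drop = FALSE])
    new_ids <- n0 + seq_along(dup_ids)
    map <- integer(n0); map[dup_ids] <- new_ids
    # wall-side elements reference the duplicates
    wall <- if (wall_is_positive) mesh2$elem_cell_k >= k_station
            else mesh2$elem_cell_k <= k_station - 1
    ee <- mesh2$elems[wall, , drop = FALSE]
    hit <- ee %in% dup_ids
    ee[hit] <- map[ee[hit]]
    mesh2$elems[wall, ] <- ee
    # wall-side duplicates of outer-surface nodes also carry the deformed
    # outer surface (used for BPD/OFD measurement)
    out_dup <- dup_ids %in% mesh2$outer_nodes
    mesh2$outer_all <- c(mesh2$outer_all, new_ids[out_dup])
    list(mesh = mesh2, stations = inside, dup_ids = dup_ids,
         new_ids = new_ids, arcs = cl)
  }

  cut_r <- cut_one(mesh2, k_r, wall_is_positive = TRUE)
  mesh2 <- cut_r$mesh
  cut_l <- cut_one(mesh2, k_l, wall_is_positive = FALSE)
  mesh2 <- cut_l$mesh

  # spring sites along the cut, arc measured from the coronal suture centre
  site_nodes <- function(cut, k_station, site_arc) {
    cl <- cut$arcs
    s_site <- cl$s_coronal + site_arc
    s_max <- cl$s_lambdoid - half_w
    if (site_arc < half_w || s_site + spec$notch_radius_mm > s_max)
      stop("spring site outside parietal segment")
    s_st <- cl$s[cut$stations]
    h_loc <- stats::median(diff(s_st))
    pick <- which(abs(s_st - s_site) <= max(spec$notch_radius_mm,
                                            0.51 * h_loc))
    if (length(pick) == 0) pick <- which.min(abs(s_st - s_site))
    st <- cut$stations[pick]
    # wall-side duplicated copies at the chosen stations, all layers
    sel <- as.vector(mesh2$node_grid[st, k_station, ]) # original ids
    pos <- match(sel, cut$dup_ids)
    cut$new_ids[pos]
  }

  notch <- function(site_arc, name) {
    list(name = name, arc_mm = site_arc,
         left = site_nodes(cut_l, k_l, site_arc),
         right = site_nodes(cut_r, k_r, site_arc))
  }

  mesh2$notch_pairs <- list(
    anterior = notch(spec$a_mm, "anterior"),
    posterior = notch(spec$a_mm + spec$b_mm, "posterior")
  )
  mesh2$cut_faces <- list(
    right = list(station = k_r, original = cut_r$dup_ids,
                 duplicate = cut_r$new_ids),
    left = list(station = k_l, original = cut_l$dup_ids,
                duplicate = cut_l$new_ids)
  )
  mesh2$osteotomy <- spec
  attr(mesh2, "y_target") <- y_target
  mesh2
}

#' Measure shell thickness over the top of the vault
#'
#' Per-vertex inner-to-outer surface distance, restricted to outer-surface
#' points in the top 25% of the model height above the reference plane (the
#' restriction excludes the orbit/base analogue, mirroring how calvarial
#' thickness is measured on imaging).
#'
#' @param mesh A `skull_mesh`.
#' @param top_fraction Fraction of the height band measured from the vertex
#'   (default 0.25).
#' @return A list with `mean_mm`, `sd_mm` and `map`, a tibble with one row
#'   per measured outer vertex (coordinates and thickness).
#' @export
measure_thickness <- function(mesh, top_fraction = 0.25) {
  stopifnot(inherits(mesh, "skull_mesh"))
  if (is.null(mesh$outer_nodes) || is.null(mesh$inner_nodes))
    stop("inner and outer surfaces are not separable on this mesh")
  zo <- mesh$nodes[mesh$outer_nodes, 3]
  zmax <- max(zo)
  keep <- zo >= (1 - top_fraction) * zmax
  po <- mesh$nodes[mesh$outer_nodes[keep], , drop = FALSE]
  pi_ <- mesh$nodes[mesh$inner_nodes[keep], , drop = FALSE]
  d <- sqrt(rowSums((po - pi_)^2))
  list(mean_mm = mean(d), sd_mm = stats::sd(d),
       map = tibble::tibble(x = po[, 1], y = po[, 2], z = po[, 3],
                            thickness_mm = d))
}

#' Refine a skull mesh
#'
#' Re-generates the mesh from its stored parameters at a target edge length
#' divided by `factor`, and re-applies the stored osteotomy specification if
#' present.  Region labelling, suture planes, base set and notch sites are
#' rebuilt consistently at the finer resolution.
#'
#' @param mesh A `skull_mesh`.
#' @param factor Refinement factor (> 1).
#' @return A finer `skull_mesh`.
#' @export
refine_skull <- function(mesh, factor) {
  stopifnot(inherits(mesh, "skull_mesh"), factor > 1)
  p <- mesh$params
  p$mesh_size_mm <- p$mesh_size_mm / factor
  fine <- generate_skull(p)
  if (!is.null(mesh$osteotomy)) fine <- apply_osteotomies(fine, mesh$osteotomy)
  fine
}

# simple structured box of Kuhn tets; used for patch and oracle tests
.box_mesh <- function(nx, ny, nz, lx, ly, lz) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  g <- expand.grid(i = seq_len(nx + 1), k = seq_len(ny + 1),
                   w = seq_len(nz + 1))
  nodes <- cbind(x = xs[g$i], y = ys[g$k], z = zs[g$w])
  idx <- array(seq_len(nrow(nodes)), dim = c(nx + 1, ny + 1, nz + 1))
  cells <- expand.grid(i = seq_len(nx), k = seq_len(ny), w = seq_len(nz))
  corner <- cbind(di = c(0, 1, 1, 0, 0, 1, 1, 0),
                  dk = c(0, 0, 1, 1, 0, 0, 1, 1),
                  dw = c(0, 0, 0, 0, 1, 1, 1, 1))
  elems <- do.call(rbind, lapply(seq_len(nrow(cells)), function(cc) {
    v <- idx[cbind(cells$i[cc] + corner[, 1], cells$k[cc] + corner[, 2],
                   cells$w[cc] + corner[, 3])]
    .kuhn_tets(v)
  }))
  vols <- .tet_volumes(nodes, elems)
  neg <- vols < 0
  elems[neg, 3:4] <- elems[neg, c(4, 3)]
  structure(list(nodes = nodes, elems = elems,
                 region = factor(rep("parietal", nrow(elems)),
                                 levels = c("frontal", "coronal_suture",
                                            "parietal", "lambdoid_suture",
                                            "occipital")),
                 elem_scale = rep(1, nrow(elems)),
                 base_nodes = which(nodes[, 3] <= 1e-12),
                 ref_plane = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                 outer_nodes = as.vector(idx[, , nz + 1]),
                 inner_nodes = as.vector(idx[, , 1]),
                 outer_all = as.vector(idx[, , nz + 1]),
                 node_grid = idx,
                 notch_pairs = list(), cut_faces = list(), osteotomy = NULL),
            class = "skull_mesh")
}
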