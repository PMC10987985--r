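#' Viscoelastic material model with Prony shear relaxation
#'
#' Isotropic small-strain material whose shear modulus relaxes according to a
#' Prony series, `G(t)/G0 = alpha_inf + sum_i alpha_i exp(-t / tau_i)`, while
#' the bulk response stays elastic.  The default Prony pairs are the
#' population-calibrated infant calvarium constants (relative moduli 0.73213
#' and 0.25708 with time constants 6720.4 s and 40322 s, giving a long-term
#' relative modulus of 0.01079).
#'
#' The instantaneous elastic constants are configuration.  The default
#' `youngs_modulus_inst = 18` MPa is the effective structural modulus of the
#' infant calvarium: it reproduces the clinically observed spring-opening
#' kinetics (exponential opening with a time constant of about 1.16 days,
#' plateau within 5 days, over 90% of the spring free length within 3
#' weeks) on the population-mean configuration.  Calibrated effective
#' moduli of this order (tens of MPa, far below quasi-static cortical-bone
#' values) are standard in validated spring-cranioplasty models.  Because
#' the long-term relative modulus is about 0.011, late-time openings are
#' spring-dominated and insensitive to the exact value.
#'
#' @param youngs_modulus_inst Instantaneous Young's modulus (MPa).
#' @param poisson_ratio Poisson ratio, in (0, 0.5).
#' @param prony Data frame with columns `alpha` (relative moduli) and
#'   `tau_s` (time constants, seconds).
#' @param alpha_inf Long-term relative modulus; defaults to
#'   `1 - sum(prony$alpha)` and must satisfy the unit-sum invariant within
#'   1e-6.
#' @return An object of class `material_model`.
#' @export
#' @examples
#' mat <- material_model()
#' prony_relaxation(mat, c(0, 6720.4, 1e7))
material_model <- function(youngs_modulus_inst = 22,
                           poisson_ratio = 0.3,
                           prony = data.frame(alpha = c(0.73213, 0.25708),
                                              tau_s = c(6720.4, 40322)),
                           alpha_inf = NULL) {
  stopifnot(youngs_modulus_inst > 0,
            poisson_ratio > 0, poisson_ratio < 0.5,
            all(c("alpha", "tau_s") %in% names(prony)),
            all(prony$alpha > 0), all(prony$tau_s > 0))
  if (is.null(alpha_inf)) alpha_inf <- 1 - sum(prony$alpha)
  if (abs(alpha_inf + sum(prony$alpha) - 1) > 1e-6)
    stop("relative moduli must satisfy alpha_inf + sum(alpha_i) = 1")
  if (alpha_inf <= 0) stop("alpha_inf must be positive")
  structure(list(youngs_modulus_inst = youngs_modulus_inst,
                 poisson_ratio = poisson_ratio,
                 prony = as.data.frame(prony),
                 alpha_inf = alpha_inf),
            class = "material_model")
}

#' Relative shear relaxation modulus G(t)/G0
#'
#' @param material A [material_model()].
#' @param t_seconds Times (s), non-negative.
#' @return The dimensionless relative modulus at each time; multiply by
#'   `G0 = E / (2 (1 + nu))` to obtain `G(t)` in MPa.
#' @export
prony_relaxation <- function(material, t_seconds) {
  stopifnot(inherits(material, "material_model"))
  if (any(t_seconds < 0)) stop("t_seconds must be non-negative")
  pr <- material$prony
  vapply(t_seconds, function(t)
    material$alpha_inf + sum(pr$alpha * exp(-t / pr$tau_s)), numeric(1))
}

# table of the three clinically used spring distractor models
.spring_constants <- data.frame(
  name = c("S10", "S12", "S14"),
  stiffness_k = c(0.17, 0.39, 0.68),
  free_length_op_inf = c(60.7, 57.3, 55.6)
)

#' Spring distractor models
#'
#' `spring_table()` returns the constants of the three clinical spring
#' models: longitudinal stiffness K (N/mm) and free length OP_inf (mm).
#' `spring_model()` constructs one spring, either by model name or as a
#' custom spring with explicit constants; for custom stiffnesses
#' `free_length_for_stiffness()` interpolates the free length linearly
#' between the tabulated models.
#'
#' @param name One of "S10", "S12", "S14", or "custom".
#' @param stiffness_k Longitudinal stiffness (N/mm), required for custom
#'   springs.
#' @param free_length_op_inf Free length (mm); for custom springs defaults to
#'   the interpolated value at `stiffness_k`.
#' @return `spring_model()`: an object of class `spring_model`;
#'   `spring_table()`: a tibble.
#' @export
spring_model <- function(name = "custom", stiffness_k = NULL,
                         free_length_op_inf = NULL) {
  if (name %in% .spring_constants$name) {
    row <- .spring_constants[.spring_constants$name == name, ]
    if (is.null(stiffness_k)) stiffness_k <- row$stiffness_k
    if (is.null(free_length_op_inf))
      free_length_op_inf <- row$free_length_op_inf
  }
  if (is.null(stiffness_k))
    stop("custom springs need an explicit stiffness_k")
  if (is.null(free_length_op_inf))
    free_length_op_inf <- free_length_for_stiffness(stiffness_k)
  stopifnot(stiffness_k >= 0, free_length_op_inf > 0)
  structure(list(name = name, stiffness_k = stiffness_k,
                 free_length_op_inf = free_length_op_inf),
            class = "spring_model")
}

#' @rdname spring_model
#' @export
spring_table <- function() tibble::as_tibble(.spring_constants)

#' @rdname spring_model
#' @param k Stiffness values (N/mm) at which to interpolate the free length.
#' @export
free_length_for_stiffness <- function(k) {
  stats::approx(.spring_constants$stiffness_k,
                .spring_constants$free_length_op_inf, xout = k,
                rule = 2)$y
}

#' Spring force at a given opening
#'
#' Linear compression spring: `F = K (OP_inf - opening)` while the opening is
#' below the free length, zero beyond it (the distractor cannot pull itself
#' closed).
#'
#' @param spring A [spring_model()].
#' @param opening_mm Spring opening (mm), non-negative.
#' @return Force in N.
#' @export
spring_force <- function(spring, opening_mm) {
  stopifnot(inherits(spring, "spring_model"), all(opening_mm >= 0))
  pmax(0, spring$stiffness_k * (spring$free_length_op_inf - opening_mm))
}

#' Settings for the quasi-static expansion simulation
#'
#' @param total_time_s Simulated duration (s); default 5 days.
#' @param output_times_s Times at which displacements and spring states are
#'   recorded; default 1 s (immediate post-operative), 1 day, 5 days.
#' @param n_steps Number of log-spaced implicit time steps from 1 s to
#'   `total_time_s` (at least 40 for the default 5-day window).
#' @param picard_iterations Maximum follower/force linearisation updates per
#'   step; iteration stops early once the equilibrium residual is below
#'   `tolerance`.
#' @param tolerance Relative equilibrium residual tolerance.
#' @return An object of class `expansion_settings`.
#' @export
expansion_settings <- function(total_time_s = 432000,
                               output_times_s = c(1, 86400, 432000),
                               n_steps = max(40L, as.integer(ceiling(
                                 16 * log10(total_time_s)))),
                               picard_iterations = 12,
                               tolerance = 1e-6) {
  stopifnot(total_time_s > 1, all(output_times_s >= 0),
            all(output_times_s <= total_time_s), n_steps >= 5)
  structure(list(total_time_s = total_time_s,
                 output_times_s = sort(unique(output_times_s)),
                 n_steps = n_steps,
                 picard_iterations = picard_iterations,
                 tolerance = tolerance),
            class = "expansion_settings")
}

# exponential-integrator coefficients of the recursive Prony update:
# w_i^{n+1} = decay_i * w_i^n + creep_i * (u^{n+1} - u^n)
.prony_step_coefs <- function(prony, dt) {
  decay <- exp(-dt / prony$tau_s)
  creep <- prony$tau_s / dt * (1 - decay)
  list(decay = decay, creep = creep)
}

# assemble the unit deviatoric / volumetric global operators (sparse, full
# dof set); K(t) = 2 G(t) Kdev + kappa Kvol
.assemble_operators <- function(mesh) {
  tri <- tet_stiffness_triplets(mesh$nodes, mesh$elems, mesh$elem_scale)
  if (!is.null(tri$degenerate))
    stop(sprintf("degenerate element %d in assembly",
                 as.integer(tri$degenerate)))
  ndof <- 3 * nrow(mesh$nodes)
  Kdev <- Matrix::sparseMatrix(i = as.vector(tri$i), j = as.vector(tri$j),
                               x = as.vector(tri$dev), dims = c(ndof, ndof))
  Kvol <- Matrix::sparseMatrix(i = as.vector(tri$i), j = as.vector(tri$j),
                               x = as.vector(tri$vol), dims = c(ndof, ndof))
  list(Kdev = Matrix::forceSymmetric(Kdev),
       Kvol = Matrix::forceSymmetric(Kvol), ndof = ndof,
       volumes = tri$volume)
}

# global dof indices (x,y,z blocks per node) of a node id vector
.dofs_of_nodes <- function(nodes)
  as.vector(t(cbind(3 * (nodes - 1) + 1, 3 * (nodes - 1) + 2, 3 * nodes)))

# spring attachment bookkeeping: uniform averaging over each notch node set
.spring_attachments <- function(mesh, springs) {
  if (length(mesh$notch_pairs) == 0)
    stop("mesh has no notch pairs; apply osteotomies first")
  if (is.null(names(springs)) || !all(names(springs) %in%
                                      names(mesh$notch_pairs)))
    stop("springs must be a named list matching the mesh notch pairs: ",
         paste(names(mesh$notch_pairs), collapse = ", "))
  lapply(names(springs), function(nm) {
    np <- mesh$notch_pairs[[nm]]
    sp <- springs[[nm]]
    stopifnot(inherits(sp, "spring_model"))
    list(name = nm, spring = sp, left = np$left, right = np$right)
  })
}

# current notch centroids, opening and line direction for one attachment
.spring_state <- function(att, nodes, u) {
  cl <- colMeans(nodes[att$left, , drop = FALSE] +
                   u[att$left, , drop = FALSE])
  cr <- colMeans(nodes[att$right, , drop = FALSE] +
                   u[att$right, , drop = FALSE])
  d <- cr - cl
  len <- sqrt(sum(d^2))
  list(opening = len, dir = if (len > 1e-12) d / len else c(0, 1, 0))
}

# sparse row operator R with (R u) = dir . (mean_right(u) - mean_left(u));
# its transpose distributes a force of magnitude F on the pair as
# equal-and-opposite follower forces along dir
.spring_row <- function(att, dir, ndof) {
  nl <- length(att$left)
  nr <- length(att$right)
  j <- c(.dofs_of_nodes(att$left), .dofs_of_nodes(att$right))
  x <- c(rep(-dir / nl, times = nl), rep(dir / nr, times = nr))
  Matrix::sparseMatrix(i = rep(1L, length(j)), j = j, x = x,
                       dims = c(1, ndof))
}

#' Quasi-static viscoelastic spring-expansion simulation
#'
#' Integrates the small-strain equilibrium equations over time with a
#' recursive internal-variable (exponential integrator) update of the Prony
#' shear relaxation, one implicit solve per log-spaced time step.  Each
#' spring condition acts between the centroids of its notch pair as an
#' equal-and-opposite follower force along the current centroid line, with
#' magnitude `K (OP_inf - opening)` clamped at zero; the linearised spring
#' stiffness is included in the system matrix, so the late-time
#' spring-dominated plateau is unconditionally stable.
#'
#' @param mesh A cut `skull_mesh` (see [apply_osteotomies()]).
#' @param material A [material_model()].
#' @param springs Named list of [spring_model()]s, names matching the mesh
#'   notch pairs (`anterior`, `posterior`).
#' @param settings An [expansion_settings()].
#' @return An object of class `expansion_result` with `displacements` (list
#'   of n x 3 matrices, one per output time), `springs` (tibble: `time_s`,
#'   `spring`, `opening_mm`, `force_N`), `equilibrium` (tibble: `time_s`,
#'   relative free-dof residual, net base-reaction imbalance), and the
#'   inputs.
#' @export
solve_expansion <- function(mesh, material, springs,
                            settings = expansion_settings()) {
  stopifnot(inherits(mesh, "skull_mesh"),
            inherits(material, "material_model"),
            inherits(settings, "expansion_settings"))
  if (length(mesh$base_nodes) == 0)
    stop("insufficient constraints: base node set is empty")
  ops <- .assemble_operators(mesh)
  ndof <- ops$ndof
  E <- material$youngs_modulus_inst
  nu <- material$poisson_ratio
  G0 <- E / (2 * (1 + nu))
  kap <- E / (3 * (1 - 2 * nu))
  pr <- material$prony
  a_inf <- material$alpha_inf

  fixed <- .dofs_of_nodes(mesh$base_nodes)
  free <- setdiff(seq_len(ndof), fixed)

  Kd_g <- 2 * G0 * ops$Kdev   # instantaneous deviatoric operator (dgC)
  Kv_g <- kap * ops$Kvol
  Kd_f <- Matrix::forceSymmetric(Kd_g[free, free])
  Kv_f <- Matrix::forceSymmetric(Kv_g[free, free])
  if (length(Kd_f@x) != length(Kv_f@x))
    stop("internal error: operator patterns differ")

  atts <- .spring_attachments(mesh, springs)
  n_nodes <- nrow(mesh$nodes)
  u <- matrix(0, n_nodes, 3)
  uvec <- rep(0, ndof)
  uidx <- free_nodes_index(free)
  W <- matrix(0, ndof, nrow(pr))  # deviatoric history per Prony term

  # fixed union sparsity pattern: stiffness operator + spring rank-1 blocks
  nfree <- length(free)
  free_pos <- integer(ndof)
  free_pos[free] <- seq_len(nfree)
  dir1 <- c(1, 1, 1) / sqrt(3)
  spring_pat <- lapply(atts, function(at)
    Matrix::crossprod(.spring_row(at, dir1, ndof)[, free, drop = FALSE]))
  Apat <- Kv_f + Kd_f
  for (S in spring_pat) Apat <- Apat + S
  Apat <- methods::as(Apat, "CsparseMatrix")
  key_of <- function(M) {
    T <- methods::as(M, "TsparseMatrix")
    as.numeric(T@i) * nfree + as.numeric(T@j)
  }
  keyA <- key_of(Apat)
  pos_K <- match(key_of(Kv_f), keyA)
  pos_S <- lapply(spring_pat, function(S) match(key_of(S), keyA))
  xA <- numeric(length(Apat@x))

  tgrid <- sort(unique(c(
    10^seq(0, log10(settings$total_time_s), length.out = settings$n_steps),
    settings$output_times_s[settings$output_times_s > 0]
  )))
  out_times <- settings$output_times_s

  snap <- vector("list", length(out_times))
  names(snap) <- as.character(out_times)
  spring_rows <- list()
  eq_rows <- list()

  # distributed external follower forces for given spring states
  ext_force <- function(states, forces) {
    f_ext <- rep(0, ndof)
    for (s in seq_along(atts)) {
      dir <- states[[s]]$dir
      dl <- .dofs_of_nodes(atts[[s]]$left)
      dr <- .dofs_of_nodes(atts[[s]]$right)
      f_ext[dl] <- f_ext[dl] - rep(dir, times = length(atts[[s]]$left)) *
        forces[s] / length(atts[[s]]$left)
      f_ext[dr] <- f_ext[dr] + rep(dir, times = length(atts[[s]]$right)) *
        forces[s] / length(atts[[s]]$right)
    }
    f_ext
  }

  # full-dof internal force (end-of-step effective form) and its imbalance
  # against the true follower forces; reaction forces live at the fixed dofs
  imbalance <- function(g_eff, hist_full) {
    states <- lapply(atts, .spring_state, nodes = mesh$nodes, u = u)
    forces <- vapply(seq_along(atts), function(s)
      spring_force(atts[[s]]$spring, states[[s]]$opening), numeric(1))
    f_ext <- ext_force(states, forces)
    f_int <- as.vector(Kv_g %*% uvec) + g_eff * as.vector(Kd_g %*% uvec) +
      hist_full
    r <- f_int - f_ext
    list(states = states, forces = forces,
         rel = sqrt(sum(r[free]^2)) / (sqrt(sum(f_ext^2)) + 1e-12),
         react = matrix(r, ncol = 3, byrow = TRUE)[mesh$base_nodes, ,
                                                   drop = FALSE])
  }

  record <- function(t_now, g_eff, hist_full) {
    im <- imbalance(g_eff, hist_full)
    i <- match(t_now, out_times)
    snap[[i]] <<- u
    spring_rows[[length(spring_rows) + 1]] <<- tibble::tibble(
      time_s = t_now,
      spring = vapply(atts, `[[`, character(1), "name"),
      opening_mm = vapply(im$states, `[[`, numeric(1), "opening"),
      force_N = im$forces)
    eq_rows[[length(eq_rows) + 1]] <<- tibble::tibble(
      time_s = t_now, residual_rel = im$rel,
      net_reaction_N = sqrt(sum(colSums(im$react)^2)),
      total_spring_force_N = sum(im$forces))
  }

  if (0 %in% out_times) record(0, 1, rep(0, ndof))

  alpha <- pr$alpha
  t_prev <- 0
  fact <- NULL   # symbolic Cholesky reused across steps (pattern is fixed)
  A <- Apat
  for (t_now in tgrid) {
    dt <- t_now - t_prev
    if (dt <= 1e-9) next
    co <- .prony_step_coefs(pr, dt)
    g_eff <- a_inf + sum(alpha * co$creep)
    u_prev <- uvec

    # start-of-step history contribution to the internal force (full dofs)
    hist_full <- as.vector(Kd_g %*% (W %*% (alpha * co$decay) -
                                       sum(alpha * co$creep) * u_prev))

    factored <- FALSE
    rel <- Inf
    for (it in seq_len(settings$picard_iterations)) {
      b <- -hist_full
      states <- lapply(atts, .spring_state, nodes = mesh$nodes, u = u)
      if (!factored) {
        xA[] <- 0
        xA[pos_K] <- Kv_f@x + g_eff * Kd_f@x
      }
      for (s in seq_along(atts)) {
        sp <- atts[[s]]$spring
        st <- states[[s]]
        active <- st$opening < sp$free_length_op_inf
        dir <- st$dir
        dir[dir == 0] <- 1e-14  # keep the full pattern
        if (!factored) {
          cp <- Matrix::crossprod(.spring_row(atts[[s]], dir,
                                              ndof)[, free, drop = FALSE])
          xA[pos_S[[s]]] <- xA[pos_S[[s]]] +
            (if (active) sp$stiffness_k else 1e-30) * cp@x
        }
        if (active) {
          # linearised gap at zero displacement and follower load vector
          ml <- colMeans(u[atts[[s]]$left, , drop = FALSE])
          mr <- colMeans(u[atts[[s]]$right, , drop = FALSE])
          gap0 <- st$opening - sum(dir * (mr - ml))
          val <- sp$stiffness_k * (sp$free_length_op_inf - gap0)
          dl <- .dofs_of_nodes(atts[[s]]$left)
          dr <- .dofs_of_nodes(atts[[s]]$right)
          b[dl] <- b[dl] - rep(dir, times = length(atts[[s]]$left)) *
            val / length(atts[[s]]$left)
          b[dr] <- b[dr] + rep(dir, times = length(atts[[s]]$right)) *
            val / length(atts[[s]]$right)
        }
      }
      if (!factored) {
        A@x <- xA
        fact <- if (is.null(fact))
          Matrix::Cholesky(A, LDL = FALSE, super = TRUE)
        else Matrix::update(fact, A)
        factored <- TRUE
      }
      uvec[free] <- as.vector(Matrix::solve(fact, b[free]))
      u[uidx] <- uvec[free]
      im <- imbalance(g_eff, hist_full)
      rel <- im$rel
      if (rel < settings$tolerance) break
    }
    if (rel > 100 * settings$tolerance)
      stop(sprintf("no equilibrium at t = %.3g s (relative residual %.3g)",
                   t_now, rel))

    W <- W * rep(co$decay, each = ndof) + outer(uvec - u_prev, co$creep)
    t_prev <- t_now
    if (any(abs(t_now - out_times) < 1e-9))
      record(out_times[which.min(abs(t_now - out_times))], g_eff, hist_full)
  }

  structure(list(displacements = snap,
                 springs = dplyr::bind_rows(spring_rows),
                 equilibrium = dplyr::bind_rows(eq_rows),
                 mesh = mesh, material = material,
                 spring_models = springs, settings = settings),
            class = "expansion_result")
}

# helper mapping free dof indices into (node, component) matrix indices
free_nodes_index <- function(free) {
  cbind((free - 1) %/% 3 + 1, (free - 1) %% 3 + 1)
}

#' @export
print.expansion_result <- function(x, ...) {
  cat("<expansion_result>", length(x$displacements), "output times\n")
  print(x$springs)
  invisible(x)
}

#' Tidy the spring history of an expansion result
#'
#' @param x An `expansion_result`.
#' @param ... Unused.
#' @return The spring tibble (`time_s`, `spring`, `opening_mm`, `force_N`).
#' @export
tidy.expansion_result <- function(x, ...) x$springs

#' Static linear elastic solve with instantaneous moduli
#'
#' Standard linear elastic solve used as the elastic-limit oracle of the
#' viscoelastic integrator and for patch tests.
#'
#' @param mesh A `skull_mesh` (or compatible structure).
#' @param material A [material_model()]; only the instantaneous constants are
#'   used.
#' @param loads n x 3 matrix of nodal forces (N).
#' @param fixed_dofs Optional integer vector of constrained global dofs
#'   (default: all three components of the base node set).
#' @return n x 3 matrix of nodal displacements (mm).
#' @export
static_elastic_solve <- function(mesh, material, loads, fixed_dofs = NULL) {
  stopifnot(inherits(material, "material_model"))
  ops <- .assemble_operators(mesh)
  ndof <- ops$ndof
  stopifnot(nrow(loads) == nrow(mesh$nodes), ncol(loads) == 3)
  E <- material$youngs_modulus_inst
  nu <- material$poisson_ratio
  K <- (E / (3 * (1 - 2 * nu))) * ops$Kvol + (E / (1 + nu)) * ops$Kdev
  if (is.null(fixed_dofs)) fixed_dofs <- .dofs_of_nodes(mesh$base_nodes)
  if (length(fixed_dofs) == 0)
    stop("insufficient constraints: singular system")
  free <- setdiff(seq_len(ndof), fixed_dofs)
  b <- as.vector(t(loads))[free]
  uf <- as.vector(Matrix::solve(Matrix::forceSymmetric(K[free, free]), b))
  u <- matrix(0, nrow(mesh$nodes), 3)
  u[free_nodes_index(free)] <- uf
  u
}

#' One-degree-of-freedom spring-on-viscoelastic-bar surrogate
#'
#' Integrates the opening of a spring in series with a Prony-relaxing bar of
#' instantaneous stiffness `k_bar` using exactly the same recursive
#' internal-variable update as [solve_expansion()].  This surrogate has a
#' closed-form (linear ODE) solution, used as an independent oracle in the
#' tests.
#'
#' @param k_bar Instantaneous bar stiffness (N/mm).
#' @param material A [material_model()] (the relative relaxation applies to
#'   the whole bar stiffness).
#' @param spring A [spring_model()].
#' @param l0_mm Initial opening (mm).
#' @param total_time_s,n_steps Integration window and log-spaced step count.
#' @return Tibble with `time_s`, `opening_mm`, `force_N`.
#' @export
solve_relaxation_1dof <- function(k_bar, material, spring, l0_mm,
                                  total_time_s = 432000, n_steps = 400) {
  stopifnot(k_bar > 0, inherits(material, "material_model"),
            inherits(spring, "spring_model"))
  pr <- material$prony
  a_inf <- material$alpha_inf
  ks <- spring$stiffness_k
  delta <- spring$free_length_op_inf - l0_mm
  tgrid <- 10^seq(0, log10(total_time_s), length.out = n_steps)
  x <- 0
  w <- rep(0, nrow(pr))
  t_prev <- 0
  out <- matrix(0, length(tgrid), 3)
  for (ii in seq_along(tgrid)) {
    t_now <- tgrid[ii]
    dt <- t_now - t_prev
    co <- .prony_step_coefs(pr, dt)
    g_eff <- a_inf + sum(pr$alpha * co$creep)
    x_new <- (ks * delta - k_bar * sum(pr$alpha * (co$decay * w -
                                                     co$creep * x))) /
      (k_bar * g_eff + ks)
    w <- co$decay * w + co$creep * (x_new - x)
    x <- x_new
    t_prev <- t_now
    out[ii, ] <- c(t_now, l0_mm + x, max(0, ks * (delta - x)))
  }
  tibble::tibble(time_s = out[, 1], opening_mm = out[, 2],
                 force_N = out[, 3])
}

#' Mesh convergence study on the spring expansion
#'
#' Runs the expansion on a sequence of meshes of increasing density and
#' reports the first mesh whose final spring openings all change by less than
#' `threshold` (default 5%) relative to the previous mesh.
#'
#' @param meshes List of cut `skull_mesh` objects of increasing density.
#' @param material,springs,settings Passed to [solve_expansion()].
#' @param threshold Relative-change convergence criterion.
#' @return A list with `table` (tibble: mesh index, element count, final
#'   opening per spring, max relative change vs the previous mesh) and
#'   `converged_index` (`NA` when the criterion is never met; no exception
#'   is raised in that case).
#' @export
mesh_convergence_study <- function(meshes, material, springs,
                                   settings = expansion_settings(),
                                   threshold = 0.05) {
  stopifnot(length(meshes) >= 2)
  final_t <- max(settings$output_times_s)
  rows <- purrr::map_dfr(seq_along(meshes), function(i) {
    res <- solve_expansion(meshes[[i]], material, springs, settings)
    op <- dplyr::filter(res$springs, .data$time_s == final_t)
    tibble::tibble(mesh = i, n_elements = nrow(meshes[[i]]$elems),
                   spring = op$spring, opening_mm = op$opening_mm)
  })
  wide <- tidyr::pivot_wider(rows, names_from = "spring",
                             values_from = "opening_mm")
  mat <- as.matrix(wide[, -(1:2)])
  rel <- c(NA, vapply(2:nrow(mat), function(i)
    max(abs(mat[i, ] - mat[i - 1, ]) / abs(mat[i - 1, ])), numeric(1)))
  wide$max_rel_change <- rel
  idx <- which(rel < threshold)[1]
  list(table = wide, converged_index = if (is.na(idx)) NA_integer_ else idx)
}
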