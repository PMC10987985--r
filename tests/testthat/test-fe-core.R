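test_that("Prony relaxation reproduces hand-evaluated values and limits", {
  mat <- material_model()
  expect_equal(prony_relaxation(mat, 0), 1.0, tolerance = 1e-12)
  # hand evaluation of the series at t = tau_1
  a_inf <- 1 - 0.73213 - 0.25708
  expected <- a_inf + 0.73213 * exp(-1) + 0.25708 * exp(-6720.4 / 40322)
  expect_equal(prony_relaxation(mat, 6720.4), expected, tolerance = 1e-12)
  expect_equal(expected, 0.4978, tolerance = 5e-4)
  # long-time limit is the long-term relative modulus
  expect_equal(prony_relaxation(mat, 1e7), a_inf, tolerance = 1e-4)
  expect_error(prony_relaxation(mat, -1), "non-negative")
})

test_that("G(t)/G0 is strictly decreasing and bounded on [alpha_inf, 1]", {
  mat <- material_model()
  g <- prony_relaxation(mat, 10^seq(0, 6, length.out = 60))
  expect_true(all(diff(g) < 0))
  expect_true(all(g <= 1 + 1e-12))
  expect_true(all(g >= mat$alpha_inf - 1e-12))
  # the unit-sum invariant is enforced
  expect_error(material_model(prony = data.frame(alpha = c(0.7, 0.2),
                                                 tau_s = c(10, 100)),
                              alpha_inf = 0.2), "alpha_inf")
})

test_that("spring force follows the clinical linear law", {
  expect_equal(spring_force(spring_model("S12"), 57.3), 0)
  expect_equal(spring_force(spring_model("S12"), 30), 0.39 * 27.3,
               tolerance = 1e-12)
  expect_equal(spring_force(spring_model("S14"), 0), 0.68 * 55.6,
               tolerance = 1e-12)
  # beyond free length the spring cannot pull closed
  expect_equal(spring_force(spring_model("S10"), 80), 0)
  # free-length interpolation passes through the tabulated models
  expect_equal(free_length_for_stiffness(c(0.17, 0.39, 0.68)),
               c(60.7, 57.3, 55.6))
})

test_that("static solve passes the uniform-strain patch test", {
  # unit cube block under uniform top traction with roller sides:
  # uniaxial stress, u_z(top) = sigma * Lz / E
  box <- craniospring:::.box_mesh(2, 2, 2, 10, 10, 10)
  mat <- material_model(youngs_modulus_inst = 100, poisson_ratio = 0.3)
  sigma <- 2  # MPa
  top <- which(abs(box$nodes[, 3] - 10) < 1e-9)
  # consistent nodal loads: area/3 of every element face lying on the top
  loads <- matrix(0, nrow(box$nodes), 3)
  on_top <- matrix(box$elems %in% top, nrow(box$elems), 4)
  faces <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (e in which(rowSums(on_top) >= 3)) {
    for (f in faces) {
      if (all(on_top[e, f])) {
        tri <- box$elems[e, f]
        p1 <- box$nodes[tri[1], ]; p2 <- box$nodes[tri[2], ]
        p3 <- box$nodes[tri[3], ]
        cr <- c((p2 - p1)[2] * (p3 - p1)[3] - (p2 - p1)[3] * (p3 - p1)[2],
                (p2 - p1)[3] * (p3 - p1)[1] - (p2 - p1)[1] * (p3 - p1)[3],
                (p2 - p1)[1] * (p3 - p1)[2] - (p2 - p1)[2] * (p3 - p1)[1])
        area <- sqrt(sum(cr^2)) / 2
        loads[tri, 3] <- loads[tri, 3] + sigma * area / 3
      }
    }
  }
  fix_z <- 3 * (which(abs(box$nodes[, 3]) < 1e-9) - 1) + 3
  fix_x <- 3 * (which(abs(box$nodes[, 1]) < 1e-9) - 1) + 1
  fix_y <- 3 * (which(abs(box$nodes[, 2]) < 1e-9) - 1) + 2
  u <- static_elastic_solve(box, mat, loads, fixed_dofs = c(fix_x, fix_y,
                                                            fix_z))
  expect_equal(max(abs(u[top, 3] - sigma * 10 / 100)), 0, tolerance = 1e-9)
  # lateral contraction: u_x on the far face = -nu * eps_z * Lx
  farx <- which(abs(box$nodes[, 1] - 10) < 1e-9)
  expect_lt(max(abs(u[farx, 1] - (-0.3 * (sigma / 100) * 10))), 1e-8)
})

test_that("static solve is linear and zero loads give zero displacement", {
  box <- craniospring:::.box_mesh(2, 2, 2, 5, 5, 5)
  mat <- material_model(youngs_modulus_inst = 50)
  z0 <- matrix(0, nrow(box$nodes), 3)
  expect_equal(max(abs(static_elastic_solve(box, mat, z0))), 0)
  loads <- z0
  loads[which.max(box$nodes[, 3]), 1] <- 1
  u1 <- static_elastic_solve(box, mat, loads)
  u2 <- static_elastic_solve(box, mat, 2 * loads)
  expect_equal(u2, 2 * u1, tolerance = 1e-9)
})

test_that("1-DOF recursive update matches an independent ODE oracle", {
  skip_if_not_installed("deSolve")
  mat <- material_model()
  spr <- spring_model("S12")
  k_bar <- 5
  l0 <- 18.3
  # independent oracle: with hereditary variables w_i = int e^{-(t-s)/tau_i}
  # xdot ds, substitute v_i = x - w_i (continuous through the t = 0 jump):
  #   vdot_i = (x - v_i) / tau_i
  # and the quasi-static balance k_bar (x - sum a_i v_i) = ks (delta - x)
  # gives x algebraically.  Integrated with deSolve at tight tolerance.
  pr <- mat$prony
  ks <- spr$stiffness_k
  delta <- spr$free_length_op_inf - l0
  x_of <- function(v) (ks * delta + k_bar * sum(pr$alpha * v)) /
    (k_bar + ks)
  rhs <- function(t, v, p) {
    x <- x_of(v)
    list((x - v) / pr$tau_s)
  }
  times <- c(0, 10^seq(0, log10(432000), length.out = 40))
  sol <- deSolve::ode(y = rep(0, 2), times = times, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  x_oracle <- apply(sol[-1, -1, drop = FALSE], 1, x_of) + l0
  ours <- solve_relaxation_1dof(k_bar, mat, spr, l0,
                                total_time_s = 432000, n_steps = 400)
  ours_at <- stats::approx(ours$time_s, ours$opening_mm, xout = times[-1])$y
  expect_lt(max(abs(ours_at - x_oracle) / x_oracle), 0.005)
})

test_that("expansion is monotone, bounded and force-decaying", {
  res <- fix_expansion()
  for (sp in unique(res$springs$spring)) {
    h <- dplyr::filter(res$springs, spring == sp)
    h <- h[order(h$time_s), ]
    expect_true(all(diff(h$opening_mm) > -1e-9))
    expect_true(all(diff(h$force_N) < 1e-9))
    expect_true(all(h$force_N >= 0))
    fl <- res$spring_models[[sp]]$free_length_op_inf
    expect_true(all(h$opening_mm <= fl + 1e-6))
  }
})

test_that("equilibrium holds at every recorded time", {
  res <- fix_expansion()
  expect_true(all(res$equilibrium$residual_rel <
                    res$settings$tolerance))
  # springs are equal-and-opposite, so base reactions must cancel
  expect_true(all(res$equilibrium$net_reaction_N <
                    1e-6 * res$equilibrium$total_spring_force_N))
})

test_that("symmetric springs on a symmetric mesh give a mirror-symmetric field", {
  res <- fix_expansion()
  u <- res$displacements[[length(res$displacements)]]
  cut <- res$mesh
  p_def <- cut$nodes + u
  scale <- max(abs(u))
  expect_setequal_points(p_def, mirror_y(p_def), tol = 1e-6 * max(1, scale))
})

test_that("an effectively elastic material gives a time-constant solution equal to the static solve", {
  mat_el <- material_model(youngs_modulus_inst = 22,
                           prony = data.frame(alpha = 1e-9, tau_s = 1))
  cut <- fix_cut()
  res <- solve_expansion(cut, mat_el, s12_pair(),
                         expansion_settings(n_steps = 12))
  u1 <- res$displacements[[1]]
  for (u in res$displacements)
    expect_lt(max(abs(u - u1)), 1e-6 * max(abs(u1)))
  # the same state solved statically under the equilibrium spring forces
  final <- dplyr::filter(res$springs, time_s == max(time_s))
  loads <- matrix(0, nrow(cut$nodes), 3)
  for (i in seq_len(nrow(final))) {
    np <- cut$notch_pairs[[final$spring[i]]]
    cl <- colMeans(cut$nodes[np$left, ] + u1[np$left, ])
    cr <- colMeans(cut$nodes[np$right, ] + u1[np$right, ])
    dir <- (cr - cl) / sqrt(sum((cr - cl)^2))
    loads[np$left, ] <- loads[np$left, ] -
      matrix(dir * final$force_N[i] / length(np$left), length(np$left), 3,
             byrow = TRUE)
    loads[np$right, ] <- loads[np$right, ] +
      matrix(dir * final$force_N[i] / length(np$right), length(np$right), 3,
             byrow = TRUE)
  }
  u_static <- static_elastic_solve(cut, mat_el, loads)
  expect_lt(max(abs(u_static - u1)), 5e-4 * max(abs(u1)))
})

test_that("convergence study arithmetic and reporting", {
  # direct percentage arithmetic on a synthetic opening sequence
  rel <- function(v) c(NA, abs(diff(v)) / head(v, -1))
  expect_identical(which(rel(c(40, 42, 42.5)) < 0.05)[1], 3L)
  # identical meshes converge immediately (0% change at the second entry)
  m <- generate_skull(skull_params(mesh_size_mm = 18))
  cuts <- lapply(1:2, function(i) apply_osteotomies(m, mean_osteotomy()))
  st <- expansion_settings(total_time_s = 86400, output_times_s = 86400,
                           n_steps = 10)
  cs <- mesh_convergence_study(cuts, material_model(), s12_pair(), st)
  expect_identical(cs$converged_index, 2L)
  expect_equal(cs$table$max_rel_change[2], 0, tolerance = 1e-12)
})

test_that("refining meshes drive the spring expansion towards convergence", {
  st <- expansion_settings(total_time_s = 86400, output_times_s = 86400,
                           n_steps = 10)
  meshes <- lapply(c(20, 15, 11), function(h)
    apply_osteotomies(generate_skull(skull_params(mesh_size_mm = h)),
                      mean_osteotomy()))
  cs <- mesh_convergence_study(meshes, material_model(), s12_pair(), st)
  expect_s3_class(cs$table, "tbl_df")
  rel <- cs$table$max_rel_change[-1]
  # openings settle: the finest change satisfies the 5% criterion and the
  # study reports a converged mesh
  expect_lt(rel[2], 0.05)
  expect_false(is.na(cs$converged_index))
})
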