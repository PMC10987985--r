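test_that("default parameter ranges carry the population statistics", {
  rg <- parameter_ranges()
  expect_equal(unname(rg$lower[rg$name == "lat_pct"]), 14.8)
  expect_equal(unname(rg$upper[rg$name == "lat_pct"]), 19.0)
  expect_equal(rg$midpoint, (rg$lower + rg$upper) / 2)
  expect_error(parameter_ranges(a_pct = c(30, 20)), "lower")
})

test_that("maximin design fills the box, stratifies margins and is seeded", {
  d <- build_design(parameter_ranges(), n_points = 79, seed = 7)
  expect_identical(dim(d), c(79L, 5L))
  rg <- attr(d, "ranges")
  for (i in seq_len(nrow(rg))) {
    v <- d[[rg$name[i]]]
    expect_true(all(v >= rg$lower[i] & v <= rg$upper[i]))
    # latin-hypercube stratification: every one of the 79 bins is occupied
    bins <- floor(79 * (v - rg$lower[i]) / (rg$upper[i] - rg$lower[i]))
    bins <- pmin(bins, 78)
    expect_equal(sort(unique(bins)), as.numeric(0:78))
  }
  expect_identical(build_design(parameter_ranges(), 79, seed = 7), d)
  expect_false(isTRUE(all.equal(
    build_design(parameter_ranges(), 79, seed = 8), d)))
})

test_that("maximin spreads two points further apart than random sampling", {
  rg <- parameter_ranges()
  unit <- function(d) {
    m <- as.matrix(d[, rg$name])
    sweep(sweep(m, 2, rg$lower, `-`), 2, rg$upper - rg$lower, `/`)
  }
  d2 <- unit(build_design(rg, n_points = 10, seed = 3))
  min_dist <- function(m) min(stats::dist(m))
  set.seed(99)
  random_md <- replicate(100, min_dist(matrix(stats::runif(50), ncol = 5)))
  expect_gt(min_dist(d2), stats::median(random_md))
})

test_that("infeasible design points are rejected and resampled", {
  rg <- parameter_ranges()
  d <- build_design(rg, n_points = 12, seed = 5,
                    feasible = function(row) row$a_pct < 30)
  expect_true(all(d$a_pct < 30))
})

test_that("quadratic response surface recovers an exact quadratic", {
  d <- build_design(parameter_ranges(), n_points = 30, seed = 2)
  rg <- attr(d, "ranges")
  code <- craniospring:::.code_vars(tibble::as_tibble(d), rg)
  d$dci_test <- code$lat_pct^2 + 2 * code$a_pct - 0.5 * code$k_ant *
    code$k_post + 0.3
  rs <- fit_response_surface(d, outputs = "dci_test")
  expect_lt(glance(rs)$max_abs_residual, 1e-8)
  co <- tidy(rs)
  expect_equal(co$estimate[co$term == "a_pct"], 2, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "I(lat_pct^2)"], 1, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "k_ant:k_post"], -0.5,
               tolerance = 1e-8)
  # pure-noise output has no explanatory power
  set.seed(1)
  d$dci_noise <- stats::rnorm(nrow(d))
  rsn <- fit_response_surface(d, outputs = "dci_noise")
  expect_lt(glance(rsn)$r_squared, 0.999)  # not an exact fit
  pred <- predict(rsn, d[1:5, ], output = "dci_noise")
  expect_length(pred, 5)
  # too few points for the 21-term basis
  expect_error(fit_response_surface(d[1:15, ], outputs = "dci_test"),
               "at least 21")
})

test_that("local sensitivity has closed-form behaviour on known surfaces", {
  d <- build_design(parameter_ranges(), n_points = 30, seed = 2)
  rg <- attr(d, "ranges")
  code <- craniospring:::.code_vars(tibble::as_tibble(d), rg)
  # linear in one coded variable: S = 100 * c * (upper-lower in coded = 2)
  # divided by the mid-range value
  d$dci_lin <- 5 + 1.5 * code$b_pct
  rs <- fit_response_surface(d, outputs = "dci_lin")
  sens <- local_sensitivity(rs)
  s_b <- sens$sensitivity_pct[sens$parameter == "b_pct"]
  expect_equal(s_b, 100 * 1.5 * 2 / 5, tolerance = 1e-6)
  # independent parameters have zero sensitivity
  expect_lt(max(abs(sens$sensitivity_pct[sens$parameter != "b_pct"])), 1e-6)
  expect_true(all(sens$monotone))
})

test_that("optimum map finds the vertex of a known bowl", {
  d <- build_design(parameter_ranges(), n_points = 40, seed = 4)
  rg <- attr(d, "ranges")
  code <- craniospring:::.code_vars(tibble::as_tibble(d), rg)
  # concave bowl with maximum at coded (a, b) = (0.3, -0.2)
  d$dci_bowl <- 4 - (code$a_pct - 0.3)^2 - (code$b_pct + 0.2)^2
  rs <- fit_response_surface(d, outputs = "dci_bowl")
  m <- optimum_map(rs, output = "dci_bowl", n_grid = 81)
  opt <- attr(m, "optimum")
  mid <- rg$midpoint
  half <- (rg$upper - rg$lower) / 2
  expect_equal(opt$a_pct, unname(mid[rg$name == "a_pct"] +
                 0.3 * half[rg$name == "a_pct"]), tolerance = 0.05)
  expect_equal(opt$b_pct, unname(mid[rg$name == "b_pct"] -
                 0.2 * half[rg$name == "b_pct"]), tolerance = 0.05)
  # map values at design points match the fit prediction
  expect_equal(predict(rs, d[3, ], output = "dci_bowl"),
               d$dci_bowl[3], tolerance = 1e-6)
})

test_that("single-configuration runs show monotone relaxation and null controls", {
  mid <- tibble::tibble(lat_pct = 16.9, a_pct = 31.4, b_pct = 17.2,
                        k_ant = 0.425, k_post = 0.425)
  one <- run_design(mid, params = test_params())
  expect_lt(one$dci_postop, one$dci_day1)
  expect_lt(one$dci_day1, one$dci_followup)
  # zero-stiffness springs leave the skull untouched
  zero <- run_design(dplyr::mutate(mid, k_ant = 0, k_post = 0),
                     params = test_params())
  expect_lt(abs(zero$dci_followup), 1e-8)
  expect_lt(abs(zero$dci_postop), 1e-8)
})

test_that("stiffness matters most immediately and least at follow-up", {
  two <- tibble::tibble(lat_pct = 16.9, a_pct = 31.4, b_pct = 17.2,
                        k_ant = c(0.17, 0.68), k_post = 0.425)
  res <- run_design(two, params = test_params())
  d_post <- abs(diff(res$dci_postop))
  d_fu <- abs(diff(res$dci_followup))
  expect_gt(d_post, 0)
  # relative effect of the stiffness contrast shrinks over time
  expect_lt(d_fu / mean(res$dci_followup), d_post / mean(res$dci_postop))
})

test_that("the full study fits a smooth response surface", {
  rs <- fix_surface()
  g <- glance(rs)
  expect_true(all(g$r_squared > 0.8))
  expect_identical(unique(g$n), 79L)
})
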