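# Fixtures shared across test files, built once per test run and cached.
# All geometry is generated in code at a coarse test resolution (13 mm
# target edge length) to keep the suite fast; the package defaults are finer.

.fix <- new.env(parent = emptyenv())

test_params <- function(...) skull_params(mesh_size_mm = 13, ...)

mean_osteotomy <- function() osteotomy_spec(lat_mm = 18.30, a_mm = 47.92,
                                            b_mm = 26.25)

fix_skull <- function() {
  if (is.null(.fix$skull)) .fix$skull <- generate_skull(test_params())
  .fix$skull
}

fix_cut <- function() {
  if (is.null(.fix$cut))
    .fix$cut <- apply_osteotomies(fix_skull(), mean_osteotomy())
  .fix$cut
}

s12_pair <- function() list(anterior = spring_model("S12"),
                            posterior = spring_model("S12"))

fix_expansion <- function() {
  if (is.null(.fix$expansion))
    .fix$expansion <- solve_expansion(fix_cut(), material_model(),
                                      s12_pair())
  .fix$expansion
}

# the full surgical-parameter study at test resolution (79 design points);
# built once and reused by the design, sensitivity and acceptance tests
fix_study <- function() {
  if (is.null(.fix$study)) {
    d <- build_design(parameter_ranges(), n_points = 79, seed = 42)
    .fix$study <- suppressWarnings(
      run_design(d, params = test_params()))
  }
  .fix$study
}

fix_surface <- function() {
  if (is.null(.fix$surface)) .fix$surface <- fit_response_surface(fix_study())
  .fix$surface
}

# mirror a displacement field / node table about the midsagittal plane
mirror_y <- function(m) {
  m[, 2] <- -m[, 2]
  m
}

expect_setequal_points <- function(a, b, tol = 1e-6) {
  stopifnot(nrow(a) == nrow(b))
  ka <- a[order(round(a[, 1] / tol), round(a[, 2] / tol),
               round(a[, 3] / tol)), ]
  kb <- b[order(round(b[, 1] / tol), round(b[, 2] / tol),
               round(b[, 3] / tol)), ]
  expect_lt(max(abs(ka - kb)), tol)
}
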