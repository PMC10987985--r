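#' Surgical parameter ranges for the design of experiments
#'
#' Default ranges of the five surgical inputs: the osteotomy distance and the
#' two spring positions vary over the population mean plus/minus one standard
#' deviation (LAT% 16.9 +/- 2.1, A% 31.4 +/- 6.5, B% 17.2 +/- 6.9), and both
#' spring stiffnesses vary over the full clinical spring range
#' (0.17 to 0.68 N/mm).
#'
#' @param lat_pct,a_pct,b_pct,k_ant,k_post Length-2 numeric vectors
#'   `c(lower, upper)`.
#' @return Tibble with columns `name`, `lower`, `upper`, `midpoint`, class
#'   `parameter_ranges`.
#' @export
#' @examples
#' parameter_ranges()
parameter_ranges <- function(lat_pct = c(14.8, 19.0),
                             a_pct = c(24.9, 37.9),
                             b_pct = c(10.3, 24.1),
                             k_ant = c(0.17, 0.68),
                             k_post = c(0.17, 0.68)) {
  vals <- list(lat_pct = lat_pct, a_pct = a_pct, b_pct = b_pct,
               k_ant = k_ant, k_post = k_post)
  for (nm in names(vals))
    if (length(vals[[nm]]) != 2 || vals[[nm]][1] >= vals[[nm]][2])
      stop("invalid range for ", nm, ": lower must be below upper")
  out <- tibble::tibble(
    name = names(vals),
    lower = vapply(vals, `[`, numeric(1), 1),
    upper = vapply(vals, `[`, numeric(1), 2)
  )
  out$midpoint <- (out$lower + out$upper) / 2
  class(out) <- c("parameter_ranges", class(out))
  out
}

#' Build an optimal space-filling design
#'
#' Maximin-optimized Latin hypercube over the five surgical parameters,
#' mapped to physical units.  The maximin criterion maximizes the minimum
#' pairwise distance between design points, spreading them uniformly over
#' the design box; the sample is reproducible for a given seed.
#'
#' @param ranges A [parameter_ranges()] tibble.
#' @param n_points Number of design points (default 79).
#' @param seed Integer seed.
#' @param feasible Optional predicate taking a one-row tibble of physical
#'   parameters and returning `TRUE`/`FALSE`; infeasible rows (e.g. spring
#'   sites beyond the parietal segment) are rejected and resampled.
#' @return Tibble of `n_points` rows (class `doe_design`), one column per
#'   parameter, with the ranges, seed and method recorded as attributes.
#' @export
#' @examples
#' d <- build_design(parameter_ranges(), n_points = 10, seed = 1)
#' summary(d$lat_pct)
build_design <- function(ranges, n_points = 79, seed = 1, feasible = NULL) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  k <- nrow(ranges)
  if (n_points < 2 * k)
    stop("n_points must be at least twice the number of parameters")
  set.seed(seed)
  unit <- lhs::maximinLHS(n_points, k)
  to_phys <- function(unit) {
    phys <- sweep(sweep(unit, 2, ranges$upper - ranges$lower, `*`),
                  2, ranges$lower, `+`)
    colnames(phys) <- ranges$name
    tibble::as_tibble(phys)
  }
  design <- to_phys(unit)
  if (!is.null(feasible)) {
    for (tries in 1:100) {
      ok <- vapply(seq_len(nrow(design)), function(i)
        isTRUE(feasible(design[i, ])), logical(1))
      if (all(ok)) break
      n_bad <- sum(!ok)
      design[!ok, ] <- to_phys(matrix(stats::runif(n_bad * k), ncol = k))
    }
    if (!all(ok)) stop("could not find feasible replacements for ",
                       sum(!ok), " design points")
  }
  if (anyDuplicated(design)) stop("design contains duplicated rows")
  attr(design, "ranges") <- ranges
  attr(design, "seed") <- seed
  attr(design, "method_tag") <- "maximin latin hypercube"
  class(design) <- c("doe_design", class(design))
  design
}

#' Run the finite-element pipeline over a design
#'
#' For each design point, converts the normalized parameters back to
#' millimetres on the baseline skull, applies the osteotomies, attaches the
#' two springs (free length interpolated from the clinical spring table at
#' the sampled stiffness, or snapped to the nearest clinical model in
#' `discrete` mode), runs the viscoelastic expansion, and records the CI
#' change at the requested output times.
#'
#' @param design A [build_design()] tibble.
#' @param params [skull_params()] of the baseline skull.
#' @param material A [material_model()].
#' @param times Named vector of output times in seconds; the names become
#'   column suffixes (`dci_<name>`).  Default post-operative (1 s), day 1 and
#'   follow-up (5 days).
#' @param spring_mode How sampled stiffnesses map to springs.
#'   `"continuous"` (default): continuous stiffness with the free length
#'   held at the clinical mid-range value, isolating the stiffness effect
#'   (the clinical spring table couples stiffer wires to slightly shorter
#'   free lengths; imposing that inverse coupling would confound the
#'   stiffness sensitivity with a free-length effect).  `"interpolated"`:
#'   free length interpolated from the clinical table at the sampled
#'   stiffness.  `"discrete"`: snap to the nearest clinical spring model.
#' @param notch_radius_mm Notch radius for the osteotomy spec.
#' @param settings Optional [expansion_settings()]; by default built from
#'   `times`.
#' @param verbose Print progress.
#' @return Tibble: the design columns plus `ci0_pct` and one `dci_<name>`
#'   column per output time (CI change in percentage points).  Failed design
#'   points are kept as `NA` rows with a warning, not errors.
#' @export
run_design <- function(design, params = skull_params(),
                       material = material_model(),
                       times = c(postop = 1, day1 = 86400, followup = 432000),
                       spring_mode = c("continuous", "interpolated",
                                       "discrete"),
                       notch_radius_mm = 2.5,
                       settings = NULL, verbose = FALSE) {
  spring_mode <- match.arg(spring_mode)
  stopifnot(is.data.frame(design),
            all(c("lat_pct", "a_pct", "b_pct", "k_ant", "k_post") %in%
                  names(design)))
  if (is.null(settings))
    settings <- expansion_settings(total_time_s = max(times),
                                   output_times_s = unname(times))
  base <- generate_skull(params)
  bd <- measure_bpd_ofd(base)

  k_mid <- mean(range(.spring_constants$stiffness_k))
  make_spring <- function(k) {
    switch(spring_mode,
      discrete = spring_model(
        .spring_constants$name[which.min(abs(.spring_constants$stiffness_k -
                                               k))]),
      interpolated = spring_model(stiffness_k = k,
                                  free_length_op_inf =
                                    free_length_for_stiffness(k)),
      continuous = spring_model(stiffness_k = k,
                                free_length_op_inf =
                                  free_length_for_stiffness(k_mid))
    )
  }

  one <- function(row) {
    mm <- denormalize_surgical(row$lat_pct, row$a_pct, row$b_pct,
                               params$bpd_mm, params$ofd_mm)
    cut <- apply_osteotomies(base, osteotomy_spec(mm$lat_mm, mm$a_mm,
                                                  mm$b_mm, notch_radius_mm))
    springs <- list(anterior = make_spring(row$k_ant),
                    posterior = make_spring(row$k_post))
    res <- solve_expansion(cut, material, springs, settings)
    cm <- cranial_measurements(res)
    dci <- cm$delta_ci_points[match(unname(times), cm$time_s)]
    ci0 <- 100 * measure_bpd_ofd(cut)[["bpd_mm"]] /
      measure_bpd_ofd(cut)[["ofd_mm"]]
    c(ci0_pct = ci0, stats::setNames(dci, paste0("dci_", names(times))))
  }

  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    if (verbose) message(sprintf("design point %d / %d", i, nrow(design)))
    out[[i]] <- tryCatch(one(design[i, ]), error = function(e) {
      warning(sprintf("design point %d failed: %s", i, conditionMessage(e)),
              call. = FALSE)
      stats::setNames(rep(NA_real_, 1 + length(times)),
                      c("ci0_pct", paste0("dci_", names(times))))
    })
  }
  res <- dplyr::bind_cols(tibble::as_tibble(design),
                          tibble::as_tibble(do.call(rbind, out)))
  attr(res, "ranges") <- attr(design, "ranges")
  attr(res, "times") <- times
  class(res) <- c("doe_results", class(res))
  res
}

# full quadratic basis in coded [-1, 1] variables
.quad_formula <- function(vars) {
  main <- paste(vars, collapse = " + ")
  sq <- paste(sprintf("I(%s^2)", vars), collapse = " + ")
  inter <- paste(utils::combn(vars, 2, FUN = function(p)
    paste(p, collapse = ":")), collapse = " + ")
  stats::as.formula(paste(".y ~", main, "+", sq, "+", inter))
}

.code_vars <- function(df, ranges) {
  for (i in seq_len(nrow(ranges))) {
    nm <- ranges$name[i]
    df[[nm]] <- 2 * (df[[nm]] - ranges$lower[i]) /
      (ranges$upper[i] - ranges$lower[i]) - 1
  }
  df
}

#' Fit a quadratic response surface to design results
#'
#' Ordinary least-squares fit of a full quadratic polynomial (21 terms in
#' five coded variables) to each CI-change output of [run_design()].
#'
#' @param results A `doe_results` tibble (or any data frame containing the
#'   five parameter columns and `dci_*` outputs).
#' @param ranges Parameter ranges used for coding; defaults to the ranges
#'   recorded on `results`.
#' @param outputs Output columns to fit; default all `dci_*` columns.
#' @return An object of class `response_surface` with one `lm` fit per
#'   output; supports [predict()], [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_response_surface <- function(results, ranges = attr(results, "ranges"),
                                 outputs = grep("^dci_", names(results),
                                                value = TRUE)) {
  if (is.null(ranges)) stop("parameter ranges are required for coding")
  stopifnot(length(outputs) >= 1)
  vars <- ranges$name
  keep <- stats::complete.cases(results[, c(vars, outputs)])
  df <- .code_vars(results[keep, , drop = FALSE], ranges)
  n_terms <- 1 + 2 * length(vars) + choose(length(vars), 2)
  if (sum(keep) < n_terms)
    stop(sprintf("need at least %d design points for the quadratic fit, got %d",
                 n_terms, sum(keep)))
  fo <- .quad_formula(vars)
  models <- lapply(outputs, function(out) {
    df$.y <- df[[out]]
    fit <- stats::lm(fo, data = df)
    if (fit$rank < n_terms) {
      bad <- names(which(is.na(stats::coef(fit))))
      stop("rank-deficient response surface; collinear terms: ",
           paste(bad, collapse = ", "))
    }
    fit
  })
  names(models) <- outputs
  structure(list(models = models, ranges = ranges, outputs = outputs),
            class = "response_surface")
}

#' Predict from a response surface
#'
#' @param object A `response_surface`.
#' @param newdata Data frame with the five parameter columns in physical
#'   units.
#' @param output Which output to predict (default the first).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.response_surface <- function(object, newdata,
                                     output = object$outputs[1], ...) {
  df <- .code_vars(tibble::as_tibble(newdata), object$ranges)
  as.vector(stats::predict(object$models[[output]], newdata = df))
}

#' @export
print.response_surface <- function(x, ...) {
  cat("<response_surface> quadratic in",
      paste(x$ranges$name, collapse = ", "), "\n")
  for (out in x$outputs)
    cat(sprintf("  %s: R^2 = %.3f\n", out,
                summary(x$models[[out]])$r.squared))
  invisible(x)
}

#' Tidy method for response surfaces
#'
#' @param x A `response_surface`.
#' @param ... Unused.
#' @return Tibble of coefficients (coded units) per output.
#' @export
tidy.response_surface <- function(x, ...) {
  purrr::map_dfr(x$outputs, function(out) {
    co <- stats::coef(x$models[[out]])
    tibble::tibble(output = out, term = names(co), estimate = unname(co))
  })
}

#' Glance method for response surfaces
#'
#' @param x A `response_surface`.
#' @param ... Unused.
#' @return One row per output with fit diagnostics (R squared, max absolute
#'   residual, number of points).
#' @export
glance.response_surface <- function(x, ...) {
  purrr::map_dfr(x$outputs, function(out) {
    m <- x$models[[out]]
    tibble::tibble(output = out,
                   r_squared = summary(m)$r.squared,
                   max_abs_residual = max(abs(stats::residuals(m))),
                   n = stats::nobs(m))
  })
}

#' Local signed sensitivity of the CI change to each surgical parameter
#'
#' Sensitivity is the rate of output change as one parameter sweeps its
#' range while all others are held at mid-range, normalized by the mid-range
#' output: `S_i = 100 * (f(upper_i) - f(lower_i)) / f(mid)`.  A positive
#' value means the CI change grows with the parameter.  The one-at-a-time
#' sweep is also checked for monotonicity; non-monotone sweeps are flagged
#' (the sign is then that of the end-to-end difference).
#'
#' @param rs A [fit_response_surface()] object.
#' @param ranges Parameter ranges (default those of the surface).
#' @param n_sweep Points per one-at-a-time monotonicity sweep.
#' @return Tibble of class `sensitivity_report`: `output`, `parameter`,
#'   `sensitivity_pct`, `monotone`.
#' @export
local_sensitivity <- function(rs, ranges = rs$ranges, n_sweep = 21) {
  stopifnot(inherits(rs, "response_surface"))
  mid <- stats::setNames(as.list(ranges$midpoint), ranges$name)
  out <- purrr::map_dfr(rs$outputs, function(op) {
    f_mid <- predict(rs, tibble::as_tibble(mid), output = op)
    if (abs(f_mid) < 1e-9)
      stop("mid-range output is ~0; sensitivity normalization undefined")
    purrr::map_dfr(seq_len(nrow(ranges)), function(i) {
      nm <- ranges$name[i]
      sweep_df <- tibble::as_tibble(mid)[rep(1, n_sweep), ]
      sweep_df[[nm]] <- seq(ranges$lower[i], ranges$upper[i],
                            length.out = n_sweep)
      fv <- predict(rs, sweep_df, output = op)
      d <- diff(fv)
      mono <- all(d >= -1e-9 * max(abs(fv))) || all(d <= 1e-9 * max(abs(fv)))
      tibble::tibble(output = op, parameter = nm,
                     sensitivity_pct = 100 * (fv[n_sweep] - fv[1]) / f_mid,
                     monotone = mono)
    })
  })
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' Response map over the spring-position plane and its optimum
#'
#' Evaluates the fitted CI-change surface on a dense (A%, B%) grid with the
#' osteotomy distance and both stiffnesses held at mid-range, and locates
#' the position combination yielding the maximum CI increase.
#'
#' @param rs A [fit_response_surface()] object.
#' @param output Which output (time point) to map.
#' @param n_grid Grid resolution per axis.
#' @return Tibble of class `optimum_map` (`a_pct`, `b_pct`, `dci`) with the
#'   argmax row stored in `attr(, "optimum")`.
#' @export
optimum_map <- function(rs, output = rs$outputs[length(rs$outputs)],
                        n_grid = 61) {
  stopifnot(inherits(rs, "response_surface"))
  rg <- rs$ranges
  ga <- seq(rg$lower[rg$name == "a_pct"], rg$upper[rg$name == "a_pct"],
            length.out = n_grid)
  gb <- seq(rg$lower[rg$name == "b_pct"], rg$upper[rg$name == "b_pct"],
            length.out = n_grid)
  grid <- tidyr::expand_grid(a_pct = ga, b_pct = gb)
  grid$lat_pct <- rg$midpoint[rg$name == "lat_pct"]
  grid$k_ant <- rg$midpoint[rg$name == "k_ant"]
  grid$k_post <- rg$midpoint[rg$name == "k_post"]
  grid$dci <- predict(rs, grid, output = output)
  res <- grid[, c("a_pct", "b_pct", "dci")]
  attr(res, "optimum") <- res[which.max(res$dci), ]
  attr(res, "output") <- output
  class(res) <- c("optimum_map", class(res))
  res
}
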