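# truncated-normal draws via inverse-CDF; bounds default to mean +/- 3 sd
.rtnorm <- function(n, mean, sd, lower = mean - 3 * sd,
                    upper = mean + 3 * sd) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# variance of K_TOT when both springs are drawn uniformly from the three
# clinical models (exact discrete-uniform arithmetic)
.var_k_tot <- function() {
  ks <- .spring_constants$stiffness_k
  2 * (mean(ks^2) - mean(ks)^2)
}

#' Specification of a synthetic clinical cohort
#'
#' Describes a pseudo-clinical cohort emulating one of the two retrospective
#' imaging groups: the X-ray group (n = 42; spring models recorded but not
#' spring positions; CI change at day 1 and follow-up) or the 3D-scan group
#' (n = 20; osteotomy and spring positions recorded but no spring models;
#' CI change at follow-up/removal only).
#'
#' Per patient, surgical parameters are drawn from truncated normals at the
#' population means and standard deviations (bounds at +/- 3 sd), spring
#' models uniformly from the clinical table, and the CI change is generated
#' as a linear effect of the available predictors plus Gaussian noise.  The
#' residual noise standard deviation is chosen so the marginal standard
#' deviation of the CI change matches `delta_ci_sd`; the effect slopes are
#' therefore bounded by the requirement that they cannot explain more
#' variance than the target marginal.
#'
#' Default CI-change moments are the clinical values (X-ray: day 1
#' 3.4 +/- 2.5, follow-up 4.4 +/- 2.5; 3D scan: follow-up 3.7 +/- 1.7
#' percentage points).  Default slopes carry the clinically observed signs
#' (positive combined stiffness, negative LAT%, positive (A+B)%); their
#' magnitudes are free generator parameters, as no slope values are
#' reported clinically.
#'
#' @param modality `"xray"` or `"scan3d"`.
#' @param n_patients Cohort size; defaults to 42 (X-ray) or 20 (3D scan).
#' @param delta_ci_mean,delta_ci_sd Named vectors over time points
#'   (`day1`, `followup`) of the CI-change marginal moments (percentage
#'   points).
#' @param slope_k_tot CI-change slope vs combined stiffness
#'   (points per N/mm; X-ray modality).
#' @param slope_lat,slope_a_plus_b CI-change slopes vs LAT% and (A+B)%
#'   (points per percent; 3D-scan modality).
#' @param age_mean,age_sd Age at imaging (months).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec("xray")
#' cohort_spec("scan3d", n_patients = 50)
cohort_spec <- function(modality = c("xray", "scan3d"),
                        n_patients = NULL,
                        delta_ci_mean = NULL, delta_ci_sd = NULL,
                        slope_k_tot = 3.0,
                        slope_lat = -0.3, slope_a_plus_b = 0.1,
                        age_mean = NULL, age_sd = NULL,
                        seed = 1) {
  modality <- match.arg(modality)
  if (is.null(n_patients)) n_patients <- if (modality == "xray") 42L else 20L
  if (is.null(delta_ci_mean))
    delta_ci_mean <- if (modality == "xray") c(day1 = 3.4, followup = 4.4)
                     else c(followup = 3.7)
  if (is.null(delta_ci_sd))
    delta_ci_sd <- if (modality == "xray") c(day1 = 2.5, followup = 2.5)
                   else c(followup = 1.7)
  if (is.null(age_mean)) age_mean <- if (modality == "xray") 5.3 else 5.1
  if (is.null(age_sd)) age_sd <- if (modality == "xray") 0.9 else 1.0
  stopifnot(n_patients > 1, all(delta_ci_sd > 0),
            identical(names(delta_ci_mean), names(delta_ci_sd)))
  structure(list(modality = modality, n_patients = as.integer(n_patients),
                 delta_ci_mean = delta_ci_mean, delta_ci_sd = delta_ci_sd,
                 slope_k_tot = slope_k_tot, slope_lat = slope_lat,
                 slope_a_plus_b = slope_a_plus_b,
                 age_mean = age_mean, age_sd = age_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic clinical cohort
#'
#' Draws one patient record per row according to the [cohort_spec()]:
#' surgical parameters from truncated normals at the population moments,
#' spring models uniformly from the clinical table (X-ray modality only),
#' CI change as slope times centred predictor plus residual noise, and
#' BPD/OFD pairs back-solved to be exactly consistent with each patient's
#' pre-operative CI and CI change (width change at fixed length).  Records
#' honour the modality availability rules: X-ray records carry spring
#' models but no positions; 3D-scan records carry positions but no spring
#' models.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble of class `patient_cohort`, one row per patient:
#'   `patient_id`, `modality`, `age_months`, spring stiffnesses (`k_ant`,
#'   `k_post`, `k_tot`), positions (`lat_pct`, `a_pct`, `b_pct`,
#'   `a_plus_b_pct`), `bpd_preop_mm`, `ofd_mm`, per-time-point BPD and
#'   `dci_*` columns (percentage points); fields unavailable for the
#'   modality are `NA`.
#' @export
#' @examples
#' coh <- synthesize_cohort(cohort_spec("xray", seed = 7))
#' mean(coh$dci_day1)
synthesize_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  xray <- spec$modality == "xray"

  age <- .rtnorm(n, spec$age_mean, spec$age_sd)

  if (xray) {
    k_ant <- sample(.spring_constants$stiffness_k, n, replace = TRUE)
    k_post <- sample(.spring_constants$stiffness_k, n, replace = TRUE)
    k_tot <- k_ant + k_post
    lat <- a <- b <- rep(NA_real_, n)
    effect <- spec$slope_k_tot * (k_tot - 2 * mean(.spring_constants$stiffness_k))
    explained <- spec$slope_k_tot^2 * .var_k_tot()
  } else {
    k_ant <- k_post <- k_tot <- rep(NA_real_, n)
    lat <- .rtnorm(n, 16.9, 2.1)
    a <- .rtnorm(n, 31.4, 6.5)
    b <- .rtnorm(n, 17.2, 6.9)
    effect <- spec$slope_lat * (lat - 16.9) +
      spec$slope_a_plus_b * (a + b - (31.4 + 17.2))
    # nominal (untruncated) variances; truncation at 3 sd shrinks them by
    # < 3%, well below the cohort sampling error
    explained <- spec$slope_lat^2 * 2.1^2 +
      spec$slope_a_plus_b^2 * (6.5^2 + 6.9^2)
  }

  dci <- list()
  for (tp in names(spec$delta_ci_mean)) {
    resid_var <- spec$delta_ci_sd[[tp]]^2 - explained
    if (resid_var <= 0)
      stop("effect slopes explain more variance than delta_ci_sd allows for ",
           tp)
    dci[[tp]] <- spec$delta_ci_mean[[tp]] + effect +
      stats::rnorm(n, 0, sqrt(resid_var))
  }

  # pre-operative geometry; scaphocephaly requires CI < 1
  ofd <- bpd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      o <- .rtnorm(1, 152.6, 4.3)
      w <- .rtnorm(1, 108.3, 4.2)
      ci_last <- (w / o + max(vapply(dci, `[`, numeric(1), i)) / 100)
      if (w < o && ci_last < 1) break
      if (try == 100) stop("could not back-solve a feasible BPD/OFD pair")
    }
    ofd[i] <- o; bpd[i] <- w
  }
  ci0 <- bpd / ofd

  out <- tibble::tibble(
    patient_id = sprintf("%s_%03d", spec$modality, seq_len(n)),
    modality = spec$modality,
    age_months = age,
    k_ant = k_ant, k_post = k_post, k_tot = k_tot,
    lat_pct = lat, a_pct = a, b_pct = b,
    a_plus_b_pct = a + b,
    ofd_mm = ofd, bpd_preop_mm = bpd, ci_preop_pct = 100 * ci0
  )
  for (tp in names(dci)) {
    out[[paste0("dci_", tp)]] <- dci[[tp]]
    # back-solved width at this time point (length held fixed)
    out[[paste0("bpd_", tp, "_mm")]] <- (ci0 + dci[[tp]] / 100) * ofd
  }
  attr(out, "spec") <- spec
  class(out) <- c("patient_cohort", class(out))
  out
}

#' Fit a linear CI-change trend against one surgical predictor
#'
#' Ordinary least-squares line of a CI-change column against one predictor,
#' as used to compare the simulated design space with clinical measurements.
#'
#' @param records A data frame (cohort records or simulated design results).
#' @param predictor One of `"k_tot"`, `"lat_pct"`, `"a_pct"`,
#'   `"a_plus_b_pct"` (any numeric column is accepted).
#' @param response Name of the CI-change column (default `"dci_followup"`).
#' @return An object of class `trend_result` with `predictor`, `response`,
#'   `slope`, `intercept`, `r_squared`, `n` and the underlying `lm` fit;
#'   supports [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' coh <- synthesize_cohort(cohort_spec("xray", seed = 7))
#' fit_trend(coh, "k_tot", "dci_day1")
fit_trend <- function(records, predictor, response = "dci_followup") {
  stopifnot(is.data.frame(records))
  if (!predictor %in% names(records))
    stop("predictor column not found: ", predictor)
  if (!response %in% names(records))
    stop("response column not found: ", response)
  df <- records[stats::complete.cases(records[, c(predictor, response)]),
                c(predictor, response)]
  if (nrow(df) < 3) stop("need at least 3 records with the predictor present")
  if (stats::sd(df[[predictor]]) < 1e-12)
    stop("constant predictor: trend undefined")
  fit <- stats::lm(stats::reformulate(predictor, response), data = df)
  structure(list(predictor = predictor, response = response,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(df), fit = fit),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %s ~ %s: slope %.4g, R^2 %.3f (n = %d)\n",
              x$response, x$predictor, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Tidy a fitted trend
#'
#' @param x A `trend_result`.
#' @param ... Unused.
#' @return One-row tibble: predictor, response, slope, intercept,
#'   r_squared, n.
#' @export
tidy.trend_result <- function(x, ...) {
  tibble::tibble(predictor = x$predictor, response = x$response,
                 slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}

#' Glance at a fitted trend
#'
#' @param x A `trend_result`.
#' @param ... Unused.
#' @return One-row tibble of fit summaries.
#' @export
glance.trend_result <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = x$r_squared,
                 sigma = s$sigma,
                 p_value = stats::coef(s)[2, 4],
                 n = x$n)
}

#' Compare simulated and clinical CI-change trends
#'
#' Fits the CI-change trend against each shared predictor in the simulated
#' design-point table and in a cohort, and reports whether the slope signs
#' agree.  A simulated slope is flagged as negligible when it explains less
#' than a tenth of a response standard deviation over the predictor range
#' (the anterior-spring position shows this pattern: negligible in the
#' model, positive in the clinical measurements).
#'
#' @param sim_table A `doe_results` tibble from [run_design()] (the
#'   `k_tot` and `a_plus_b_pct` columns are derived on the fly if absent).
#' @param cohort_records A `patient_cohort` tibble.
#' @param predictors Predictors to compare; defaults to every one of
#'   `k_tot`, `lat_pct`, `a_pct`, `a_plus_b_pct` available (non-`NA`) in the
#'   cohort.
#' @param response CI-change column present in both tables.
#' @return Tibble of class `trend_comparison`: per predictor, the simulated
#'   and cohort slopes and R^2, their signs, `agreement`, and a `note`
#'   column flagging negligible simulated slopes.
#' @export
compare_trends <- function(sim_table, cohort_records,
                           predictors = NULL, response = "dci_followup") {
  sim <- tibble::as_tibble(sim_table)
  if (!"k_tot" %in% names(sim) && all(c("k_ant", "k_post") %in% names(sim)))
    sim$k_tot <- sim$k_ant + sim$k_post
  if (!"a_plus_b_pct" %in% names(sim) &&
      all(c("a_pct", "b_pct") %in% names(sim)))
    sim$a_plus_b_pct <- sim$a_pct + sim$b_pct
  if (is.null(predictors)) {
    cand <- c("k_tot", "lat_pct", "a_pct", "a_plus_b_pct")
    predictors <- cand[vapply(cand, function(p)
      p %in% names(cohort_records) && any(!is.na(cohort_records[[p]])),
      logical(1))]
  }
  if (nrow(sim) == 0 || nrow(cohort_records) == 0)
    stop("both tables must be non-empty")
  out <- purrr::map_dfr(predictors, function(p) {
    ts <- fit_trend(sim, p, response)
    tc <- fit_trend(cohort_records, p, response)
    sd_resp <- stats::sd(sim[[response]], na.rm = TRUE)
    span <- diff(range(sim[[p]], na.rm = TRUE))
    negligible <- abs(ts$slope) * span < 0.1 * sd_resp
    tibble::tibble(
      predictor = p, response = response,
      sim_slope = ts$slope, sim_r_squared = ts$r_squared,
      cohort_slope = tc$slope, cohort_r_squared = tc$r_squared,
      sim_sign = sign(ts$slope), cohort_sign = sign(tc$slope),
      agreement = sign(ts$slope) == sign(tc$slope),
      note = dplyr::case_when(
        negligible & tc$slope > 0 ~ "model negligible / cohort positive",
        negligible ~ "model negligible",
        TRUE ~ ""
      )
    )
  })
  class(out) <- c("trend_comparison", class(out))
  out
}
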