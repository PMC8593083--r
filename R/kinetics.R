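#' Fit an SAH standard curve
#'
#' Ordinary least-squares line `signal = slope * amount + intercept` relating
#' luminescence to the amount of product (SAH, equivalently SAM consumed).
#' The inverse conversion `amount(signal) = (signal - intercept) / slope` is
#' applied by [convert_signal()].
#'
#' @param calibration A data frame with columns `amount` (product, in the
#'   concentration unit the assay is calibrated in, e.g. nM equivalent) and
#'   `signal` (luminescence units).
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared` and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(calibration) {
  if (!all(c("amount", "signal") %in% names(calibration))) {
    abort("calibration needs columns `amount` and `signal`")
  }
  if (nrow(calibration) < 3) {
    abort("calibration error: need at least 3 standard-curve points")
  }
  fit <- lm(signal ~ amount, data = calibration)
  slope <- unname(coef(fit)["amount"])
  if (!is.finite(slope) || slope <= 0) {
    abort(sprintf("calibration error: non-positive slope (%.3g)", slope))
  }
  structure(
    list(slope = slope, intercept = unname(coef(fit)["(Intercept)"]),
         r_squared = summary(fit)$r.squared, fit = fit,
         data = as_tibble(calibration)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> signal = %.4g * amount + %.4g (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' Convert assay signal to product amount via a standard curve
#'
#' @param curve A `standard_curve`.
#' @param signal Numeric vector of signals.
#' @return Product amounts, `(signal - intercept) / slope`.
#' @export
convert_signal <- function(curve, signal) {
  stopifnot(inherits(curve, "standard_curve"))
  (signal - curve$intercept) / curve$slope
}

#' Initial rate of a single progress curve
#'
#' Slope of the OLS fit of product versus time. The intercept is free by
#' default (the assay may carry a constant background); `zero_intercept`
#' forces the line through the origin.
#'
#' @param curve A data frame with columns `time_min` and `product`.
#' @param zero_intercept Force the regression through the origin.
#' @return A one-row tibble: `rate` (product units per min), `rate_se`,
#'   `n_points`.
#' @export
initial_rate <- function(curve, zero_intercept = FALSE) {
  if (length(unique(curve$time_min)) < 2) {
    abort("need at least 2 distinct timepoints for an initial rate")
  }
  fit <- if (zero_intercept) lm(product ~ time_min + 0, data = curve)
         else lm(product ~ time_min, data = curve)
  # suppress the spurious "essentially perfect fit" note on exact toy data
  est <- suppressWarnings(summary(fit))$coefficients["time_min", ]
  tibble(rate = unname(est["Estimate"]),
         rate_se = unname(est["Std. Error"]),
         n_points = nrow(curve))
}

#' Initial rates for a full kinetic dataset
#'
#' Converts signals to product amounts (when a standard curve is given),
#' fits each replicate progress curve by OLS, and averages replicate slopes
#' per (condition, substrate) with their standard deviation. With
#' `per_replicate = FALSE` the replicates are pooled into a single
#' regression instead.
#'
#' @param data Tidy kinetic data: columns `condition`, `substrate_nM`,
#'   `time_min`, `replicate`, and either `product` or `signal`.
#' @param standard_curve Optional `standard_curve` used to convert `signal`
#'   to `product`.
#' @param per_replicate Fit replicates independently then average (default),
#'   or pool all replicate points into one fit.
#' @param zero_intercept Force regressions through the origin.
#' @return A tibble: `condition`, `substrate_nM`, `n_replicates`, `rate`
#'   (nM/min), `rate_sd`, `rate_se`.
#' @export
initial_rates <- function(data, standard_curve = NULL, per_replicate = TRUE,
                          zero_intercept = FALSE) {
  needed <- c("condition", "substrate_nM", "time_min", "replicate")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("kinetic data is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"product" %in% names(data)) {
    if (is.null(standard_curve) || !"signal" %in% names(data)) {
      abort("provide a `product` column, or `signal` plus a standard curve")
    }
    data$product <- convert_signal(standard_curve, data$signal)
  }
  if (any(data$substrate_nM <= 0)) abort("substrate concentrations must be > 0")
  if (per_replicate) {
    data |>
      group_by(.data$condition, .data$substrate_nM, .data$replicate) |>
      summarise(initial_rate(dplyr::pick(dplyr::everything()),
                             zero_intercept), .groups = "drop") |>
      group_by(.data$condition, .data$substrate_nM) |>
      summarise(n_replicates = n(),
                rate_sd = sd(.data$rate),
                rate = mean(.data$rate),
                .groups = "drop") |>
      mutate(rate_se = .data$rate_sd / sqrt(.data$n_replicates)) |>
      select("condition", "substrate_nM", "n_replicates", "rate",
             "rate_sd", "rate_se")
  } else {
    data |>
      group_by(.data$condition, .data$substrate_nM) |>
      summarise(n_replicates = dplyr::n_distinct(.data$replicate),
                {
                  ir <- initial_rate(dplyr::pick(dplyr::everything()),
                                     zero_intercept)
                  tibble(rate = ir$rate, rate_sd = NA_real_,
                         rate_se = ir$rate_se)
                },
                .groups = "drop")
  }
}

#' Fit the Michaelis-Menten model to initial rates
#'
#' Nonlinear least squares of \eqn{v = V_{max} S / (K_M + S)} over a
#' substrate series, initialised at `Vmax0 = max(rate)` and `KM0 =` the
#' substrate grid point whose rate is nearest half-maximal. The apparent
#' turnover is `kcat = Vmax / [E]`. Standard errors come from the fit
#' covariance. A fitted `KM` outside the sampled substrate range by more
#' than a factor of 10 raises an extrapolation warning and sets the
#' `extrapolated` flag.
#'
#' @param rates A data frame with columns `substrate_nM` and `rate`
#'   (nM/min), e.g. from [initial_rates()] (optionally filtered to one
#'   condition).
#' @param enzyme_nM Enzyme concentration in nM.
#' @param condition Condition label (taken from the data when unique).
#' @return An object of class `mm_fit` with `vmax`, `km`, `kcat` (min^-1)
#'   and their standard errors.
#' @export
fit_michaelis_menten <- function(rates, enzyme_nM, condition = NULL) {
  if (!all(c("substrate_nM", "rate") %in% names(rates))) {
    abort("rates needs columns `substrate_nM` and `rate`")
  }
  if (is.null(condition)) {
    condition <- if ("condition" %in% names(rates) &&
                     dplyr::n_distinct(rates$condition) == 1)
      rates$condition[1] else NA_character_
  }
  if (enzyme_nM <= 0) abort("enzyme_nM must be > 0")
  s <- rates$substrate_nM
  v <- rates$rate
  if (dplyr::n_distinct(s) < 4) {
    abort("need at least 4 substrate concentrations for a Michaelis-Menten fit")
  }
  vmax0 <- max(v)
  km0 <- s[which.min(abs(v - vmax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s),
                      start = list(vmax = vmax0, km = km0),
                      lower = c(vmax = 0, km = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0("Michaelis-Menten fit failed to converge: ",
                   conditionMessage(e)))
    })
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))),
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  extrapolated <- est["km"] > 10 * max(s) || est["km"] < min(s) / 10
  if (isTRUE(extrapolated)) {
    warn(sprintf(
      "fitted KM (%.3g nM) lies outside the sampled substrate range (%.3g-%.3g nM); parameters are extrapolated",
      est["km"], min(s), max(s)))
  }
  structure(
    list(condition = condition, enzyme_nM = enzyme_nM,
         vmax = unname(est["vmax"]), vmax_se = unname(se["vmax"]),
         km = unname(est["km"]), km_se = unname(se["km"]),
         kcat = unname(est["vmax"]) / enzyme_nM,
         kcat_se = unname(se["vmax"]) / enzyme_nM,
         extrapolated = isTRUE(extrapolated),
         fit = fit, data = as_tibble(rates)),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit>%s kcat = %.4g min^-1 (SE %.2g), KM = %.4g nM (SE %.2g), [E] = %g nM%s\n",
    if (!is.na(x$condition)) paste0(" ", x$condition, ":") else "",
    x$kcat, x$kcat_se, x$km, x$km_se, x$enzyme_nM,
    if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("vmax", "km", "kcat"),
    estimate = c(x$vmax, x$km, x$kcat),
    std.error = c(x$vmax_se, x$km_se, x$kcat_se)
  )
}

#' @exportS3Method generics::glance
glance.mm_fit <- function(x, ...) {
  res <- stats::resid(x$fit)
  tibble(
    condition = x$condition, enzyme_nM = x$enzyme_nM,
    vmax = x$vmax, km = x$km, kcat = x$kcat,
    sigma = sqrt(sum(res^2) / stats::df.residual(x$fit)),
    extrapolated = x$extrapolated,
    n = nrow(x$data)
  )
}

#' Fit Michaelis-Menten parameters for every condition in a rate table
#'
#' @param rates Output of [initial_rates()] covering several conditions.
#' @param enzyme_nM Named numeric vector of enzyme concentrations (nM) per
#'   condition.
#' @return A named list of `mm_fit` objects.
#' @export
fit_mm_panel <- function(rates, enzyme_nM) {
  conds <- unique(rates$condition)
  missing <- setdiff(conds, names(enzyme_nM))
  if (length(missing) > 0) {
    abort(paste0("no enzyme concentration given for: ",
                 paste(missing, collapse = ", ")))
  }
  setNames(purrr::map(conds, function(cc) {
    fit_michaelis_menten(filter(rates, .data$condition == cc),
                         enzyme_nM = enzyme_nM[[cc]], condition = cc)
  }), conds)
}

#' Fold changes of kinetic parameters against a reference condition
#'
#' Ratios mutant/reference for kcat, KM and the catalytic efficiency
#' kcat/KM, with standard errors propagated by the delta method (relative
#' variances add in quadrature). The efficiency fold equals the kcat fold
#' divided by the KM fold exactly on point estimates.
#'
#' @param fits A named list of `mm_fit` objects (e.g. from
#'   [fit_mm_panel()]).
#' @param reference Name of the reference condition (e.g. `"WT"`).
#' @return A tibble with one row per condition.
#' @export
compare_conditions <- function(fits, reference) {
  conds <- names(fits) %||% purrr::map_chr(fits, "condition")
  names(fits) <- conds
  if (!reference %in% conds) {
    abort(sprintf("reference condition '%s' not among fits (%s)",
                  reference, paste(conds, collapse = ", ")))
  }
  ref <- fits[[reference]]
  ratio_se <- function(num, num_se, den, den_se) {
    r <- num / den
    rel <- sqrt((num_se / num)^2 + (den_se / den)^2)
    abs(r) * rel
  }
  purrr::imap_dfr(fits, function(f, cond) {
    kcat_fold <- f$kcat / ref$kcat
    km_fold <- f$km / ref$km
    tibble(
      condition = cond,
      reference = reference,
      kcat = f$kcat, km = f$km,
      kcat_fold = kcat_fold,
      kcat_fold_se = ratio_se(f$kcat, f$kcat_se, ref$kcat, ref$kcat_se),
      km_fold = km_fold,
      km_fold_se = ratio_se(f$km, f$km_se, ref$km, ref$km_se),
      efficiency_fold = kcat_fold / km_fold,
      efficiency_fold_se = abs(kcat_fold / km_fold) * sqrt(
        (f$kcat_se / f$kcat)^2 + (ref$kcat_se / ref$kcat)^2 +
          (f$km_se / f$km)^2 + (ref$km_se / ref$km)^2)
    )
  })
}
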