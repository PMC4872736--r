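# Viability normalization, median-effect (Chou-Talalay) curve fitting and
# Combination Index computation over non-constant-ratio dose grids.

#' Normalize raw viability to vehicle control
#'
#' Averages replicate raw luminescence per condition and expresses it as a
#' percentage of the mean vehicle (all-doses-zero) luminescence; the
#' fraction affected is `fa = 1 - viability/100`. Conditions with
#' `fa <= 0` or `fa >= 1` carry no information for the linearized
#' median-effect fit and are flagged `informative = FALSE` (they stay in
#' the report but are excluded from fits).
#'
#' @param table Viability data.frame: either single-agent (`drug`, `dose`,
#'   `replicate`, `rlu`) or combination (`drug1`, `dose1`, `drug2`,
#'   `dose2`, `replicate`, `rlu`). Vehicle rows have all doses 0.
#' @return data.frame per condition with the dose columns plus
#'   `viability_pct`, `fa` and `informative`.
#' @export
normalize_viability <- function(table) {
  combo <- all(c("dose1", "dose2") %in% names(table))
  if (combo) {
    vehicle <- table$dose1 == 0 & table$dose2 == 0
    key_cols <- c("drug1", "dose1", "drug2", "dose2")
  } else {
    if (!all(c("drug", "dose", "rlu") %in% names(table))) {
      stop("viability table needs columns drug, dose, rlu (or the drug1/drug2 combination layout)",
           call. = FALSE)
    }
    vehicle <- table$dose == 0
    key_cols <- c("drug", "dose")
  }
  if (!any(vehicle)) stop("no vehicle (dose 0) rows found", call. = FALSE)
  if (any(table$rlu < 0)) stop("rlu must be non-negative", call. = FALSE)
  v0 <- mean(table$rlu[vehicle])
  treated <- table[!vehicle, , drop = FALSE]
  key <- interaction(treated[key_cols], drop = TRUE, lex.order = TRUE)
  agg <- treated[!duplicated(key), key_cols, drop = FALSE]
  agg$viability_pct <- 100 * tapply(treated$rlu, key, mean)[
    as.character(key[!duplicated(key)])] / v0
  agg$fa <- 1 - agg$viability_pct / 100
  agg$informative <- agg$fa > 0 & agg$fa < 1
  rownames(agg) <- NULL
  agg
}

#' Fit the median-effect model to dose-response data
#'
#' Ordinary least squares on the linearized median-effect equation
#' `log10(fa / (1 - fa)) = m * log10(D) - m * log10(Dm)`, using only
#' informative points (`D > 0`, `0 < fa < 1`). `Dm` (the IC50) is
#' recovered as `10^(-intercept / m)`. A non-positive fitted slope is
#' reported with `flagged = TRUE` rather than hidden.
#'
#' @param dose Positive dose vector (micromolar).
#' @param fa Fraction affected at each dose.
#' @return A `median_effect_fit` with fields `Dm`, `m`, `r_squared`,
#'   `n_points`, `flagged` and the informative `data` used.
#' @examples
#' tab <- simulate_dose_response(dose_response_spec(cv_noise = 0))
#' nv <- normalize_viability(tab)
#' fit <- fit_median_effect(nv$dose, nv$fa)
#' coef(fit)
#' @export
fit_median_effect <- function(dose, fa) {
  if (length(dose) != length(fa)) {
    stop("dose and fa must have equal length", call. = FALSE)
  }
  ok <- is.finite(dose) & is.finite(fa) & dose > 0 & fa > 0 & fa < 1
  if (sum(ok) < 2L) {
    stop("median-effect fit needs at least 2 informative points (dose > 0, 0 < fa < 1)",
         call. = FALSE)
  }
  x <- log10(dose[ok])
  y <- log10(fa[ok] / (1 - fa[ok]))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(Dm = 10^(-b / m), m = m, r_squared = r2,
                 n_points = sum(ok), flagged = !is.finite(m) || m <= 0,
                 data = data.frame(dose = dose[ok], fa = fa[ok])),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median-effect fit: Dm (IC50) = %.4g uM, m = %.4g, r^2 = %.4f (%d points)%s\n",
              x$Dm, x$m, x$r_squared, x$n_points,
              if (x$flagged) " [flagged: non-positive slope]" else ""))
  invisible(x)
}

#' @export
coef.median_effect_fit <- function(object, ...) {
  c(Dm = object$Dm, m = object$m)
}

#' Predicted fraction affected from a median-effect fit
#'
#' @param object A [fit_median_effect()] result.
#' @param dose Doses at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Vector of predicted fractions affected.
#' @export
predict.median_effect_fit <- function(object, dose, ...) {
  median_effect_fa(dose, object$Dm, object$m)
}

#' @export
plot.median_effect_fit <- function(x, ...) {
  d <- x$data
  grid <- exp(seq(log(min(d$dose)) - 0.7, log(max(d$dose)) + 0.7,
                  length.out = 100))
  graphics::plot(d$dose, 100 * (1 - d$fa), log = "x",
                 xlab = "dose (uM)", ylab = "viability (%)",
                 ylim = c(0, max(105, 100 * (1 - min(d$fa)))), pch = 19, ...)
  graphics::lines(grid, 100 * (1 - predict(x, grid)))
  graphics::abline(v = x$Dm, h = 50, lty = 3, col = "grey50")
  invisible(x)
}

#' Dose producing a given effect under a median-effect fit
#'
#' Inverts the median-effect equation:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`, so `Dx(0.5) = Dm`.
#'
#' @param fit A [fit_median_effect()] result.
#' @param fa Target fraction affected, strictly inside (0, 1).
#' @return Dose(s) `Dx`.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(!is.finite(fa)) || any(fa <= 0) || any(fa >= 1)) {
    stop("fa must lie strictly inside (0, 1)", call. = FALSE)
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination Index over a drug-pair dose grid
#'
#' For every interior grid point (both doses positive), the observed
#' (replicate-mean) fraction affected `fa` is referred to the two
#' single-agent median-effect fits and the Chou-Talalay Combination Index
#' computed as `CI = d1/Dx1(fa) + d2/Dx2(fa)` (mutually exclusive model;
#' the mutually nonexclusive variant adds the product term
#' `(d1 d2)/(Dx1 Dx2)`). This is the non-constant-ratio procedure: each
#' point is assessed at its own observed effect level. `CI < 1` indicates
#' synergy, `CI = 1` additivity (Loewe), `CI > 1` antagonism; the
#' classification applies a configurable `band` around 1. Points with
#' non-informative `fa` get `CI = NA` and classification `"undefined"`.
#'
#' @param grid Combination viability table (`drug1`, `dose1`, `drug2`,
#'   `dose2`, `replicate`, `rlu`) including vehicle rows.
#' @param fitA,fitB Single-agent [fit_median_effect()]s for drug 1 and
#'   drug 2.
#' @param model `"exclusive"` (default) or `"nonexclusive"`.
#' @param band Half-width of the additive band around CI = 1 used only for
#'   the textual classification (default 0.1).
#' @return data.frame with one row per interior grid point: `d1`, `d2`,
#'   `fa`, `Dx1`, `Dx2`, `CI`, `classification`.
#' @export
combination_index <- function(grid, fitA, fitB,
                              model = c("exclusive", "nonexclusive"),
                              band = 0.1) {
  model <- match.arg(model)
  stopifnot(inherits(fitA, "median_effect_fit"),
            inherits(fitB, "median_effect_fit"))
  check_scalar_num(band, "band", lower = 0)
  nv <- normalize_viability(grid)
  interior <- nv[nv$dose1 > 0 & nv$dose2 > 0, , drop = FALSE]
  if (nrow(interior) == 0L) {
    stop("grid has no interior points (both doses > 0)", call. = FALSE)
  }
  out <- data.frame(d1 = interior$dose1, d2 = interior$dose2,
                    fa = interior$fa, Dx1 = NA_real_, Dx2 = NA_real_,
                    CI = NA_real_, classification = "undefined",
                    stringsAsFactors = FALSE)
  ok <- interior$informative
  if (any(ok)) {
    out$Dx1[ok] <- dose_for_effect(fitA, interior$fa[ok])
    out$Dx2[ok] <- dose_for_effect(fitB, interior$fa[ok])
    ci <- out$d1[ok] / out$Dx1[ok] + out$d2[ok] / out$Dx2[ok]
    if (model == "nonexclusive") {
      ci <- ci + (out$d1[ok] * out$d2[ok]) / (out$Dx1[ok] * out$Dx2[ok])
    }
    out$CI[ok] <- ci
    out$classification[ok] <- ifelse(ci < 1 - band, "synergy",
                                     ifelse(ci > 1 + band, "antagonism",
                                            "additive"))
  }
  out
}
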