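#' Fit the exponential decline rate of one trajectory
#'
#' Per-subject model ADAS_T = ADAS_0 * exp(alpha * T) fitted through the
#' fixed baseline in log space: with the offset delta handling zero scores,
#' alpha = sum_T T * (log(y_T + delta) - log(y_0 + delta)) / sum_T T^2 over
#' the follow-up visits, the least-squares solution with the intercept
#' pinned at the observed baseline. With delta = 0 and a single follow-up
#' this reduces to the closed form log(y_T / y_0) / T.
#'
#' @param months visit months (month 0 must be present, strictly increasing).
#' @param adas nonnegative scores, aligned with `months`.
#' @param offset log-offset delta (default 1; use 0 for the raw-scale
#'   variant when all scores are positive).
#' @return an `alpha_fit` list: `alpha` (per month), `baseline_used`,
#'   `n_points`, `residual` (RMS log-scale residual).
#' @export
fit_alpha <- function(months, adas, offset = 1) {
  if (length(months) != length(adas)) stop("length mismatch")
  ok <- is.finite(months) & is.finite(adas)
  months <- months[ok]
  adas <- adas[ok]
  if (length(months) < 2) stop("need at least 2 observations")
  if (anyDuplicated(months)) stop("months must be unique")
  o <- order(months)
  months <- months[o]
  adas <- adas[o]
  if (months[1] != 0) stop("baseline (month 0) observation required")
  if (any(adas < 0)) stop("scores must be nonnegative")
  base <- adas[1]
  if (base + offset <= 0) stop("baseline + offset must be positive")
  t_f <- months[-1]
  if (all(t_f == 0)) stop("all follow-ups at month 0")
  dlog <- log(adas[-1] + offset) - log(base + offset)
  alpha <- sum(t_f * dlog) / sum(t_f^2)
  structure(list(alpha = alpha, baseline_used = base, offset = offset,
                 n_points = length(months),
                 residual = sqrt(mean((dlog - alpha * t_f)^2))),
            class = "alpha_fit")
}

#' Fit decline rates for a whole cohort
#'
#' @param series long data.frame with subject_id, month, adas.
#' @param offset log-offset passed to [fit_alpha].
#' @return data.frame subject_id, alpha, baseline, n_points (subjects whose
#'   series cannot be fitted are dropped).
#' @export
fit_alpha_series <- function(series, offset = 1) {
  out <- lapply(split(series, series$subject_id), function(df) {
    f <- tryCatch(fit_alpha(df$month, df$adas, offset = offset),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(subject_id = df$subject_id[1], alpha = f$alpha,
               baseline = f$baseline_used, n_points = f$n_points,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Filter out improving decliners
#'
#' Removes MCI or AD subjects whose fitted longitudinal trajectory improves
#' (alpha < 0), ascribed to operator noise in the cognitive testing;
#' cognitively normal subjects are retained regardless, and the inequality
#' is strict (alpha = 0 is kept).
#'
#' @param fits data.frame with at least `alpha` and `diagnosis` columns.
#' @return the retained rows.
#' @export
filter_improving_decliners <- function(fits) {
  stopifnot(all(c("alpha", "diagnosis") %in% names(fits)))
  drop <- fits$diagnosis %in% c("MCI", "AD") & fits$alpha < 0
  fits[!drop, , drop = FALSE]
}

#' Forecast future cognition
#'
#' ADAS at month T from a baseline score and decline rate:
#' (baseline + delta) * exp(alpha * T) - delta, clipped at 0. The baseline
#' may be the empirical measurement (known-baseline mode) or the model's
#' predicted baseline cognition (unknown-baseline mode).
#'
#' @param baseline baseline score(s).
#' @param alpha decline rate(s), per month.
#' @param months forecast horizon(s), months (>= 0).
#' @param offset the same delta used in fitting.
#' @return predicted score(s), vectorised over any argument.
#' @export
forecast_adas <- function(baseline, alpha, months, offset = 1) {
  if (any(months < 0)) stop("months must be >= 0")
  pmax((baseline + offset) * exp(alpha * months) - offset, 0)
}

#' Per-visit forecast evaluation
#'
#' R-squared, Pearson r and sample size of the forecasts separately at each
#' visit month; months with fewer than `min_n` evaluable subjects are
#' reported as absent (NA metrics).
#'
#' @param forecasts data.frame subject_id, month, pred.
#' @param truth data.frame subject_id, month, adas.
#' @param min_n minimum subjects per month (default 3).
#' @return data.frame month, n, r2, pearson.
#' @export
per_visit_evaluation <- function(forecasts, truth, min_n = 3) {
  m <- merge(forecasts, truth, by = c("subject_id", "month"))
  months <- sort(unique(m$month))
  rows <- lapply(months, function(mo) {
    d <- m[m$month == mo & is.finite(m$pred) & is.finite(m$adas), ]
    if (nrow(d) < min_n)
      return(data.frame(month = mo, n = nrow(d), r2 = NA_real_,
                        pearson = NA_real_))
    data.frame(month = mo, n = nrow(d), r2 = r_squared(d$pred, d$adas),
               pearson = suppressWarnings(cor(d$pred, d$adas)))
  })
  do.call(rbind, rows)
}
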