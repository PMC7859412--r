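# Log-scale OLS with explicit R^2 bookkeeping. A flat response has zero
# total sum of squares; R^2 is defined as 0 there (the model explains no
# variation because there is none).
log_ols <- function(x, y, degree) {
  X <- stats::poly(x, degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), y)
  if (fit$rank < degree + 1)
    stop(errorCondition("rank-deficient design: too few distinct ages",
                        class = c("ardkit_fit_error", "error")))
  n <- length(y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  flat <- tss <= .Machine$double.eps * n
  if (flat) fit$coefficients[-1] <- 0  # constant response: slope exactly 0
  r2 <- if (flat) 0 else 1 - rss / tss
  r2 <- min(max(r2, 0), 1)
  adj <- 1 - (1 - r2) * (n - 1) / (n - degree - 1)
  list(coef = fit$coefficients, r_squared = r2, adj_r_squared = adj, n = n)
}

positive_ages <- function(q, ages, min_positive_ages, label = "curve") {
  stopifnot(length(q) == length(ages))
  pos <- which(is.finite(q) & q > 0)
  if (length(pos) < min_positive_ages)
    stop(errorCondition(
      sprintf("%s: only %d ages with positive onset rate (need >= %d)",
              label, length(pos), min_positive_ages),
      class = c("ardkit_insufficient_data", "error")))
  pos
}

#' Fit the Gompertz model to an onset curve
#'
#' Ordinary least squares of \eqn{\log q_x} on age \eqn{x} over the ages
#' with a positive rate (the Gompertz law \eqn{q_x = \alpha e^{\beta x}} is
#' linear on the log scale). Zero-rate ages are excluded because their log
#' is undefined; a disease needs at least `min_positive_ages` positive ages
#' to be fit at all.
#'
#' @param q Numeric vector of onset rates over `ages`.
#' @param ages Matching integer ages (default the full 21-84 grid).
#' @param min_positive_ages Minimum number of positive-rate ages (default
#'   10).
#' @return Object of class `gompertz_fit`: `alpha` (`exp` of the fitted
#'   intercept, i.e. the curve extrapolated to age 0 as the log-linear
#'   parameterisation defines it), `beta` (senescent slope per year of
#'   age), `r_squared`, `adj_r_squared` (penalised with p = 1 predictor),
#'   `n_fit`.
#' @export
#' @examples
#' x <- 21:84
#' fit_gompertz(1e-5 * exp(0.08 * x))$beta  # 0.08
fit_gompertz <- function(q, ages = age_grid(), min_positive_ages = 10L) {
  pos <- positive_ages(q, ages, min_positive_ages, "Gompertz fit")
  f <- log_ols(as.numeric(ages[pos]), log(q[pos]), degree = 1L)
  structure(list(alpha = unname(exp(f$coef[1])), beta = unname(f$coef[2]),
                 r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
                 n_fit = f$n),
            class = "gompertz_fit")
}

#' Fit the exponential-quadratic Gompertz-Makeham model
#'
#' Ordinary least squares of \eqn{\log q_x} on \eqn{(x, x^2)} over the
#' positive-rate ages: \eqn{\log q_x = \log a + b x + c x^2}. The quadratic
#' term lets the model track onset curves that rise and then level off or
#' dip, which the monotone Gompertz law cannot. With \eqn{c = 0} the model
#' reduces exactly to the Gompertz fit. Goodness of fit is summarised by
#' the adjusted R-squared with p = 2 predictors, which (unlike the raw
#' R-squared, which can only grow when a regressor is added) increases only
#' if the quadratic term earns its keep.
#'
#' @inheritParams fit_gompertz
#' @return Object of class `gm_fit`: `a`, `b`, `c`, `r_squared`,
#'   `adj_r_squared`, `n_fit`.
#' @export
fit_gompertz_makeham <- function(q, ages = age_grid(),
                                 min_positive_ages = 10L) {
  pos <- positive_ages(q, ages, max(min_positive_ages, 4L),
                       "Gompertz-Makeham fit")
  f <- log_ols(as.numeric(ages[pos]), log(q[pos]), degree = 2L)
  structure(list(a = unname(exp(f$coef[1])), b = unname(f$coef[2]),
                 c = unname(f$coef[3]),
                 r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
                 n_fit = f$n),
            class = "gm_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("<gompertz_fit> alpha = %.4g, beta = %.4g, adj R^2 = %.4f (n = %d)\n",
              x$alpha, x$beta, x$adj_r_squared, x$n_fit))
  invisible(x)
}

#' @export
print.gm_fit <- function(x, ...) {
  cat(sprintf("<gm_fit> a = %.4g, b = %.4g, c = %.4g, adj R^2 = %.4f (n = %d)\n",
              x$a, x$b, x$c, x$adj_r_squared, x$n_fit))
  invisible(x)
}

#' Likelihood bands for ageing-relatedness
#'
#' @return Character vector of the six bands, ordered from highest to
#'   lowest likelihood of being ageing-related, ending with the
#'   negative-slope band.
#' @export
ard_bands <- function() c("very_high", "band_090_095", "band_085_090",
                          "band_080_085", "low", "very_low_beta_negative")

#' Classify a disease's likelihood of being ageing-related
#'
#' Step-wise rule: if the Gompertz slope \eqn{\beta} is negative, onset
#' falls with age and the disease has a very low likelihood of being
#' ageing-related, whatever the Gompertz-Makeham fit. Otherwise
#' (\eqn{\beta = 0} counts as non-negative) the band is read off the
#' adjusted R-squared of the Gompertz-Makeham model using half-open
#' intervals closed at the lower threshold: \[0.95, Inf) very high,
#' \[0.90, 0.95), \[0.85, 0.90), \[0.80, 0.85), and below 0.80 low.
#'
#' @param gomp A `gompertz_fit`.
#' @param gm A `gm_fit` for the same curve.
#' @return Object of class `ard_verdict`: `band` (see [ard_bands()]),
#'   `beta`, `adj_r_squared`.
#' @export
classify_ard <- function(gomp, gm) {
  stopifnot(inherits(gomp, "gompertz_fit"), inherits(gm, "gm_fit"))
  band <- if (gomp$beta < 0) "very_low_beta_negative"
          else if (gm$adj_r_squared >= 0.95) "very_high"
          else if (gm$adj_r_squared >= 0.90) "band_090_095"
          else if (gm$adj_r_squared >= 0.85) "band_085_090"
          else if (gm$adj_r_squared >= 0.80) "band_080_085"
          else "low"
  structure(list(band = band, beta = gomp$beta,
                 adj_r_squared = gm$adj_r_squared),
            class = "ard_verdict")
}

#' @export
print.ard_verdict <- function(x, ...) {
  cat(sprintf("<ard_verdict> band = %s (beta = %.4g, GM adj R^2 = %.4f)\n",
              x$band, x$beta, x$adj_r_squared))
  invisible(x)
}

#' Fit and classify every disease in a rates table
#'
#' Applies [fit_gompertz()], [fit_gompertz_makeham()] and [classify_ard()]
#' per disease. Per-disease failures (too few positive ages, degenerate
#' designs) are collected in the `note` column and never abort the batch.
#'
#' @param rates Long data frame `disease_id`, `age`, `q` from
#'   [compute_onset_rates()], or a diseases-by-ages matrix.
#' @param min_positive_ages Passed to the fitting functions.
#' @return Data frame with one row per disease: `disease_id`, `alpha`,
#'   `beta`, `gomp_r2`, `gomp_adj_r2`, `gm_a`, `gm_b`, `gm_c`,
#'   `gm_adj_r2`, `n_fit`, `band` (`NA` for flagged diseases), `note`.
#'   Attribute `"band_counts"` tabulates bands over classified diseases.
#' @export
classify_all <- function(rates, min_positive_ages = 10L) {
  if (is.matrix(rates)) {
    ids <- rownames(rates)
    get_q <- function(id) rates[id, ]
  } else {
    ord <- rates[order(rates$disease_id, rates$age), ]
    parts <- split(ord, ord$disease_id)
    ids <- names(parts)
    get_q <- function(id) parts[[id]]$q
  }
  if (!length(ids)) {
    res <- data.frame(disease_id = character(0), alpha = numeric(0),
                      beta = numeric(0), gomp_r2 = numeric(0),
                      gomp_adj_r2 = numeric(0), gm_a = numeric(0),
                      gm_b = numeric(0), gm_c = numeric(0),
                      gm_adj_r2 = numeric(0), n_fit = integer(0),
                      band = character(0), note = character(0))
    attr(res, "band_counts") <- table(factor(character(0),
                                             levels = ard_bands()))
    return(res)
  }
  rows <- lapply(ids, function(id) {
    out <- data.frame(disease_id = id, alpha = NA_real_, beta = NA_real_,
                      gomp_r2 = NA_real_, gomp_adj_r2 = NA_real_,
                      gm_a = NA_real_, gm_b = NA_real_, gm_c = NA_real_,
                      gm_adj_r2 = NA_real_, n_fit = NA_integer_,
                      band = NA_character_, note = NA_character_)
    tryCatch({
      q <- get_q(id)
      g <- fit_gompertz(q, min_positive_ages = min_positive_ages)
      gm <- fit_gompertz_makeham(q, min_positive_ages = min_positive_ages)
      v <- classify_ard(g, gm)
      out$alpha <- g$alpha; out$beta <- g$beta
      out$gomp_r2 <- g$r_squared; out$gomp_adj_r2 <- g$adj_r_squared
      out$gm_a <- gm$a; out$gm_b <- gm$b; out$gm_c <- gm$c
      out$gm_adj_r2 <- gm$adj_r_squared
      out$n_fit <- g$n_fit
      out$band <- v$band
      out
    }, error = function(e) {
      out$note <- conditionMessage(e)
      out
    })
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "band_counts") <-
    table(factor(res$band, levels = ard_bands()))
  res
}
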