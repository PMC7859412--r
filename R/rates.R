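#' Compute age-specific rates of disease onset
#'
#' For each disease and integer age \eqn{x} in 21-84, the rate of disease
#' onset is \eqn{q_x = d_x / l_x}, where \eqn{d_x} is the number of patients
#' first recorded with the disease at age \eqn{x} and \eqn{l_x} the number
#' of patients with no record for the disease at that age. Ages with
#' \eqn{l_x = 0} (an exhausted at-risk pool, essentially impossible at EHR
#' scale but reachable in simulation) get \eqn{q_x = 0} and are flagged, so
#' every curve keeps the full 64-point grid required downstream.
#'
#' @param counts Long data frame with columns `disease_id`, `age`, `d`, `l`.
#'   Each disease must cover exactly the ages 21-84 once each, with
#'   `0 <= d <= l`.
#' @param trim If `TRUE`, rows with ages outside 21-84 are dropped before
#'   validation; if `FALSE` (default) such rows are an error, making the
#'   age window an explicit contract of the input.
#' @return Long data frame `disease_id`, `age`, `q`, `at_risk_zero`.
#' @export
#' @examples
#' counts <- data.frame(disease_id = "d1", age = 21:84,
#'                      d = rep(1L, 64), l = rep(100L, 64))
#' head(compute_onset_rates(counts))
compute_onset_rates <- function(counts, trim = FALSE) {
  counts <- check_counts(counts, trim = trim)
  q <- ifelse(counts$l > 0, counts$d / counts$l, 0)
  data.frame(disease_id = counts$disease_id, age = counts$age, q = q,
             at_risk_zero = counts$l == 0)
}

# Validate the long counts table; returns it sorted by (disease_id, age).
check_counts <- function(counts, trim = FALSE) {
  need <- c("disease_id", "age", "d", "l")
  if (!all(need %in% names(counts)))
    stop("counts must have columns disease_id, age, d, l")
  if (trim) counts <- counts[counts$age >= AGE_MIN & counts$age <= AGE_MAX, ]
  counts <- counts[order(counts$disease_id, counts$age), , drop = FALSE]
  ages <- age_grid()
  bad_grid <- vapply(split(counts$age, counts$disease_id),
                     function(a) !identical(as.integer(a), ages),
                     logical(1))
  if (any(bad_grid))
    stop(errorCondition(
      sprintf("disease(s) %s: ages must be exactly 21..84, each once",
              paste(names(bad_grid)[bad_grid], collapse = ", ")),
      class = c("ardkit_grid_error", "error")))
  if (any(counts$d < 0) || any(counts$d > counts$l))
    stop("counts must satisfy 0 <= d <= l at every age")
  counts
}

#' Standardise one onset curve to unit mass
#'
#' Divides each age-specific rate by the sum of the rates over ages 21-84,
#' so the curve integrates to one and shapes are comparable across diseases
#' of very different prevalence.
#'
#' @param q Numeric vector of onset rates (any length >= 1).
#' @return Numeric vector of the same length summing to 1.
#' @export
#' @examples
#' standardise_curve(c(0.01, 0.03))  # 0.25 0.75
standardise_curve <- function(q) {
  stopifnot(is.numeric(q), all(is.finite(q)), all(q >= 0))
  s <- sum(q)
  if (s <= 0)
    stop(errorCondition("cannot standardise an all-zero onset curve",
                        class = c("ardkit_zero_curve", "error")))
  q / s
}

#' Standardise all onset curves in a rates table
#'
#' @param rates Long data frame from [compute_onset_rates()] (columns
#'   `disease_id`, `age`, `q`).
#' @param drop_zero If `TRUE`, diseases whose curve is all zero are dropped
#'   with a warning (they cannot be clustered); if `FALSE` (default) they
#'   are an error naming the disease.
#' @return Long data frame `disease_id`, `age`, `q_hat`; each disease's
#'   `q_hat` sums to 1.
#' @export
standardise_curves <- function(rates, drop_zero = FALSE) {
  parts <- split(rates, rates$disease_id)
  zero <- names(parts)[vapply(parts, function(p) sum(p$q) <= 0, logical(1))]
  if (length(zero)) {
    if (!drop_zero)
      stop(errorCondition(
        sprintf("all-zero onset curve(s), cannot standardise: %s",
                paste(zero, collapse = ", ")),
        class = c("ardkit_zero_curve", "error")))
    warning("dropping all-zero curve(s): ", paste(zero, collapse = ", "))
    parts <- parts[setdiff(names(parts), zero)]
  }
  out <- do.call(rbind, lapply(parts, function(p) {
    p <- p[order(p$age), ]
    data.frame(disease_id = p$disease_id, age = p$age,
               q_hat = standardise_curve(p$q))
  }))
  rownames(out) <- NULL
  out
}

#' Convert a long curve table to a diseases-by-ages matrix
#'
#' @param curves Long data frame with `disease_id`, `age` and one value
#'   column (`q_hat` or `q`).
#' @param value Name of the value column; defaults to `q_hat` if present.
#' @return Numeric matrix with one row per disease (rownames are disease
#'   ids) and one column per age of the 21-84 grid.
#' @export
curve_matrix <- function(curves, value = if ("q_hat" %in% names(curves))
                                           "q_hat" else "q") {
  ids <- unique(curves$disease_id)
  ages <- age_grid()
  m <- matrix(NA_real_, length(ids), length(ages),
              dimnames = list(ids, paste0("age_", ages)))
  for (p in split(curves, curves$disease_id)) {
    p <- p[order(p$age), ]
    stopifnot(identical(as.integer(p$age), ages))
    m[p$disease_id[1], ] <- p[[value]]
  }
  m
}

#' Weighted quantiles of integer ages
#'
#' Quantiles of the age distribution implied by nonnegative integer weights
#' (diagnosis counts) per age, using the inverse-CDF convention with
#' midpoint interpolation at exact mass boundaries. This matches
#' `quantile(rep(ages, w), p, type = 2)` without materialising the expanded
#' vector.
#'
#' @param ages Numeric vector of support points (sorted).
#' @param w Nonnegative weights (counts), same length, positive total.
#' @param probs Probabilities in (0, 1).
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_age_quantile <- function(ages, w, probs) {
  stopifnot(length(ages) == length(w), all(w >= 0), sum(w) > 0,
            all(probs > 0 & probs < 1), !is.unsorted(ages))
  n <- sum(w)
  cum <- cumsum(w)
  value_at <- function(k) ages[which(cum >= k)[1]]  # k-th order statistic
  vapply(probs, function(p) {
    np <- n * p
    j <- floor(np + 1e-9)
    if (abs(np - j) <= 1e-9 && j >= 1) {
      (value_at(j) + value_at(min(j + 1, n))) / 2
    } else {
      value_at(floor(np) + 1)
    }
  }, numeric(1))
}

#' Median and interquartile ages of first recorded diagnosis
#'
#' The age distribution of onset for each disease is the ages 21-84 weighted
#' by diagnosis counts \eqn{d_x}; this returns its weighted median and
#' 25th/75th percentiles (see [weighted_age_quantile()] for the convention).
#'
#' @param counts Long counts table as for [compute_onset_rates()].
#' @return Data frame `disease_id`, `median_age`, `q25`, `q75`.
#' @export
median_age_of_onset <- function(counts) {
  counts <- check_counts(counts)
  out <- do.call(rbind, lapply(split(counts, counts$disease_id), function(p) {
    if (sum(p$d) <= 0)
      stop(errorCondition(
        sprintf("disease '%s': no diagnoses, median onset age undefined",
                p$disease_id[1]),
        class = c("ardkit_zero_curve", "error")))
    qs <- weighted_age_quantile(p$age, p$d, c(0.25, 0.5, 0.75))
    data.frame(disease_id = p$disease_id[1],
               median_age = qs[2], q25 = qs[1], q75 = qs[3])
  }))
  rownames(out) <- NULL
  out
}
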