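#' Configuration for a synthetic onset cohort
#'
#' @param n_diseases_per_family Number of diseases simulated per family.
#' @param cohort_size_at_21 Number of at-risk individuals entering the age
#'   window at age 21 (the study this emulates pooled roughly three million
#'   individuals; the default of one million keeps per-age counts at a
#'   comparable order of magnitude per disease).
#' @param noise_scale Multiplier on the per-disease parameter jitter.
#'   Jitter is multiplicative log-normal (sdlog `0.10 * noise_scale`) on the
#'   level parameter of each family (`alpha`, `a`, `baseline`, `level`) and
#'   additive Gaussian (sd `0.02 * |value| * noise_scale`) on the remaining
#'   shape parameters. The default shape scale is calibrated to stay below
#'   the binomial sampling-noise floor of standardised curves at the
#'   default cohort size, so within-family parameter diversity does not
#'   itself constitute recoverable cluster structure (level jitter does not
#'   affect standardised curves at all). `noise_scale = 0` disables jitter.
#' @param seed Integer master seed; together with the family panel it fully
#'   determines the output.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_diseases_per_family = 20L,
                          cohort_size_at_21 = 1e6,
                          noise_scale = 1,
                          seed = 1L) {
  stopifnot(n_diseases_per_family >= 1L, cohort_size_at_21 >= 1,
            noise_scale >= 0, is.finite(seed))
  structure(list(n_diseases_per_family = as.integer(n_diseases_per_family),
                 cohort_size_at_21 = as.double(cohort_size_at_21),
                 noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Per-disease seed split from the master seed by disease identity (not by
# position), so adding or removing other families/diseases never perturbs a
# disease's draws. Polynomial rolling hash; all intermediates stay well
# below 2^53 so double arithmetic is exact.
disease_seed <- function(master, disease_id) {
  h <- 0
  for (code in utf8ToInt(disease_id)) h <- (h * 31 + code) %% 2147483629
  as.integer((h + as.double(master) * 7919) %% 2147483629)
}

# Which parameter of each hazard form is the multiplicative "level".
level_param <- c(gompertz = "alpha", gompertz_makeham = "a",
                 linear_rise = "baseline", early_peak_decline = "level",
                 declining_exponential = "level", constant = "level")

jitter_family <- function(family, noise_scale) {
  if (noise_scale == 0) return(family)
  p <- family$parameters
  lev <- level_param[[family$hazard_form]]
  for (nm in names(p)) {
    if (nm == lev) {
      p[[nm]] <- p[[nm]] * exp(stats::rnorm(1L, 0, 0.10 * noise_scale))
    } else {
      p[[nm]] <- p[[nm]] + stats::rnorm(1L, 0, 0.02 * abs(p[[nm]]) * noise_scale)
    }
  }
  family$parameters <- p
  family
}

#' Simulate a synthetic cohort of disease onset counts
#'
#' For every disease, individuals enter the age window at 21 as one at-risk
#' pool of size `cohort_size_at_21`. At each integer age \eqn{x} the number
#' of first diagnoses \eqn{d_x} is drawn binomially from the pool with the
#' family's (jittered) hazard, and the pool depletes:
#' \eqn{l_{x+1} = l_x - d_x}. Death and censoring are deliberately not
#' modelled: the at-risk count plays the role of "patients with no record
#' for the disease at age x", which is the denominator the onset-rate
#' definition actually uses.
#'
#' Each disease uses a private random stream split from the master seed by
#' its global index, so the output is bit-reproducible and unaffected by
#' adding or removing other diseases.
#'
#' @param config A [cohort_config()].
#' @param families List of [curve_family()] objects; defaults to
#'   [default_family_panel()].
#' @return A list of class `ard_cohort` with elements
#' \describe{
#'   \item{`counts`}{long data frame `disease_id`, `age`, `d`, `l`.}
#'   \item{`truth`}{data frame `disease_id`, `family_id`,
#'     `is_ageing_related`, `parameters` (generative, post-jitter, as a
#'     `key=value;...` string).}
#'   \item{`depleted`}{character vector of diseases whose at-risk pool hit
#'     zero before age 84 (their remaining `d` are 0).}
#' }
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_diseases_per_family = 2,
#'                                         cohort_size_at_21 = 1e4))
#' head(cohort$counts)
generate_cohort <- function(config, families = default_family_panel()) {
  stopifnot(inherits(config, "cohort_config"))
  lapply(families, validate_family)
  ages <- age_grid()
  n_age <- length(ages)
  rows <- vector("list", length(families) * config$n_diseases_per_family)
  truth <- vector("list", length(rows))
  depleted <- character(0)
  idx <- 0L
  for (fam in families) {
    for (j in seq_len(config$n_diseases_per_family)) {
      idx <- idx + 1L
      id <- sprintf("%s_%03d", fam$family_id, j)
      set.seed(disease_seed(config$seed, id))
      dfam <- jitter_family(fam, config$noise_scale)
      validate_family(dfam)
      h <- family_hazard(dfam, ages)
      d <- integer(n_age)
      l <- numeric(n_age)
      at_risk <- config$cohort_size_at_21
      for (t in seq_len(n_age)) {
        l[t] <- at_risk
        d[t] <- if (at_risk > 0) stats::rbinom(1L, at_risk, h[t]) else 0L
        at_risk <- at_risk - d[t]
      }
      if (at_risk == 0 && any(l == 0)) depleted <- c(depleted, id)
      rows[[idx]] <- data.frame(disease_id = id, age = ages, d = d, l = l)
      truth[[idx]] <- data.frame(
        disease_id = id, family_id = fam$family_id,
        is_ageing_related = fam$is_ageing_related,
        parameters = paste(names(dfam$parameters),
                           vapply(dfam$parameters, format, ""),
                           sep = "=", collapse = ";"))
    }
  }
  structure(list(counts = do.call(rbind, rows),
                 truth = do.call(rbind, truth),
                 depleted = depleted),
            class = "ard_cohort")
}

#' @export
print.ard_cohort <- function(x, ...) {
  cat(sprintf("<ard_cohort> %d diseases x %d ages; %d depleted pool(s)\n",
              nrow(x$truth), length(age_grid()), length(x$depleted)))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort An `ard_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`counts.csv`, `truth.csv`).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.csv", "truth.csv"))
  utils::write.csv(cohort$counts, paths[1], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[2], row.names = FALSE)
  invisible(paths)
}
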