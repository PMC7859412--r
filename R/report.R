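#' Default disease-category vocabulary
#'
#' Fifteen categories corresponding closely to ICD-10 chapters, the
#' grouping conventionally used to summarise EHR disease panels.
#'
#' @return Character vector of 15 category names.
#' @export
ard_categories <- function() c(
  "cardiovascular", "cancers", "respiratory", "eye", "musculoskeletal",
  "endocrine", "haematological/immunological", "infections", "ear",
  "neurological", "genitourinary", "digestive", "benign neoplasms",
  "skin", "psychiatric")

cluster_row_label <- function(partition) {
  ifelse(partition$type == "main",
         paste0("Cluster ", partition$main_label),
         paste0("Outlier ", partition$outlier_label))
}

cluster_row_levels <- function(partition) {
  s <- attr(partition, "summary")
  lab <- function(prefix, x) {
    if (length(x)) paste0(prefix, sort(x)) else character(0)
  }
  c(lab("Cluster ", s$main_label[s$type == "main"]),
    lab("Outlier ", s$outlier_label[s$type == "outlier"]))
}

#' Cross-tabulate clusters against disease categories
#'
#' Counts of diseases per (cluster, category) cell, main clusters first in
#' their median-onset ordering, with row/column totals. The grand total
#' equals the number of clustered diseases.
#'
#' @param partition An `ard_partition` from [split_main_outlier()].
#' @param meta Data frame `disease_id`, `category` (and optionally `name`)
#'   covering every clustered disease.
#' @param categories Category vocabulary used to order the columns;
#'   categories found in `meta` but not in the vocabulary are kept, with a
#'   warning.
#' @return A `table` with `Total` margins.
#' @export
crosstab_cluster_category <- function(partition, meta,
                                      categories = ard_categories()) {
  missing <- setdiff(partition$disease_id, meta$disease_id)
  if (length(missing))
    stop("no metadata for disease(s): ", paste(missing, collapse = ", "))
  cat_of <- stats::setNames(as.character(meta$category), meta$disease_id)
  cats <- cat_of[partition$disease_id]
  unknown <- setdiff(unique(cats), categories)
  if (length(unknown)) {
    warning("categories outside the configured vocabulary: ",
            paste(unknown, collapse = ", "))
    categories <- c(categories, unknown)
  }
  tab <- table(cluster = factor(cluster_row_label(partition),
                                levels = cluster_row_levels(partition)),
               category = factor(cats, levels = categories))
  stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
}

#' Cross-tabulate clusters against ageing-likelihood bands
#'
#' Counts of diseases per (cluster, band) cell. Band columns run from the
#' very-high adjusted R-squared band down to the low band, with the
#' negative-slope (beta < 0) column kept separate as the final column;
#' unclassifiable (flagged) diseases, if any, get their own column.
#'
#' @param partition An `ard_partition`.
#' @param verdicts Data frame from [classify_all()] (needs `disease_id`,
#'   `band`).
#' @return A `table` with `Total` margins; row sums equal cluster sizes.
#' @export
crosstab_cluster_band <- function(partition, verdicts) {
  missing <- setdiff(partition$disease_id, verdicts$disease_id)
  if (length(missing))
    stop("no verdict for disease(s): ", paste(missing, collapse = ", "))
  band_of <- stats::setNames(verdicts$band, verdicts$disease_id)
  bands <- band_of[partition$disease_id]
  lev <- ard_bands()
  if (anyNA(bands)) {
    bands[is.na(bands)] <- "unclassified"
    lev <- c(lev, "unclassified")
  }
  tab <- table(cluster = factor(cluster_row_label(partition),
                                levels = cluster_row_levels(partition)),
               band = factor(bands, levels = lev))
  stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
}

#' Per-main-cluster summary of median onset ages
#'
#' For each main cluster, the median and interquartile range of the member
#' diseases' median ages of first recorded diagnosis, reported in the
#' cluster ordering (descending median, so cluster 1 is the oldest-onset
#' cluster).
#'
#' @param partition An `ard_partition`.
#' @param onset_medians Data frame from [median_age_of_onset()].
#' @return Data frame `main_label`, `n`, `median`, `q25`, `q75`.
#' @export
cluster_median_summary <- function(partition, onset_medians) {
  med <- stats::setNames(onset_medians$median_age, onset_medians$disease_id)
  main <- partition[partition$type == "main", ]
  out <- do.call(rbind, lapply(split(main, main$main_label), function(p) {
    v <- med[p$disease_id]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 2)
    data.frame(main_label = p$main_label[1], n = nrow(p),
               median = qs[2], q25 = qs[1], q75 = qs[3])
  }))
  out <- out[order(out$main_label), ]
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' @param seed Integer seed governing every stochastic step (gap-statistic
#'   reference draws, k-means/spectral restarts).
#' @param algorithms Clustering algorithms to compare; each is evaluated at
#'   its own gap-chosen k and the Dunn index picks the winner.
#' @param linkages Candidate linkages for the cophenetic selection step.
#' @param k_max Upper end of the gap-statistic k search (capped at n - 1).
#' @param gap_B Number of gap-statistic reference datasets.
#' @param min_positive_ages Minimum positive-rate ages for the actuarial
#'   fits.
#' @param trim Whether to trim (rather than reject) input ages outside
#'   21-84.
#' @return List of class `ard_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            algorithms = c("hierarchical_average", "kmeans",
                                           "pam", "spectral"),
                            linkages = c("average", "single", "complete",
                                         "mcquitty"),
                            k_max = 30L, gap_B = 50L,
                            min_positive_ages = 10L, trim = FALSE) {
  structure(list(seed = as.integer(seed), algorithms = algorithms,
                 linkages = linkages, k_max = as.integer(k_max),
                 gap_B = as.integer(gap_B),
                 min_positive_ages = as.integer(min_positive_ages),
                 trim = isTRUE(trim)),
            class = "ard_config")
}

write_csv0 <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' Run the full ARD identification pipeline
#'
#' Orchestrates rates, standardisation, clustering with full model
#' selection (linkage by cophenetic correlation, k by gap statistic,
#' algorithm by Dunn index), main/outlier separation, actuarial
#' classification, and the summary cross-tabulations. All intermediate
#' artefacts are written to `out_dir` as CSV/JSON; the run is a pure
#' function of `(counts, meta, config)`.
#'
#' @param counts Long counts table (`disease_id`, `age`, `d`, `l`).
#' @param meta Optional metadata (`disease_id`, `category`) enabling the
#'   cluster-by-category cross-tab.
#' @param config An [pipeline_config()].
#' @param out_dir Output directory, created if missing. Writes
#'   `rates.csv`, `std.csv` (wide), `assignments.csv`, `fits.csv`,
#'   `verdicts.csv`, `crosstab_band.csv`, `cluster_medians.csv`,
#'   `diagnostics.json`, `manifest.json`, `summary.txt`, and
#'   `crosstab_category.csv` when `meta` is given.
#' @return Invisibly, a list with every intermediate object (`rates`,
#'   `std`, `selection`, `clustering`, `partition`, `fits`, `crosstabs`,
#'   `cluster_medians`, `onset_medians`).
#' @export
run_pipeline <- function(counts, meta = NULL, config = pipeline_config(),
                         out_dir) {
  stopifnot(inherits(config, "ard_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  rates <- stage("rates", compute_onset_rates(counts, trim = config$trim))
  onset_medians <- stage("rates", median_age_of_onset(counts))
  std <- stage("standardise", standardise_curves(rates, drop_zero = TRUE))
  x <- curve_matrix(std)
  write_csv0(rates, file.path(out_dir, "rates.csv"))
  write_csv0(data.frame(disease_id = rownames(x), x,
                        check.names = FALSE),
             file.path(out_dir, "std.csv"))

  dm <- stage("clustering", distance_matrix(x))
  linkage <- stage("clustering", select_linkage(dm, config$linkages))
  k_max <- min(config$k_max, nrow(x) - 1L)
  candidates <- list()
  gap_tables <- list()
  for (alg in config$algorithms) {
    gap <- stage("clustering",
                 gap_statistic(x, algorithm = sub("_average$", "", alg),
                               k_max = k_max, B = config$gap_B,
                               seed = config$seed,
                               linkage = as.character(linkage)))
    res <- stage("clustering", {
      set.seed(config$seed)
      k <- max(gap$k, 2L)  # a single cluster cannot be Dunn-scored
      switch(sub("_average$", "", alg),
             hierarchical = hierarchical_cluster(dm, as.character(linkage),
                                                 k),
             kmeans = kmeans_cluster(x, k),
             pam = pam_cluster(dm, k),
             spectral = spectral_cluster(x, k))
    })
    res$diagnostics$gap_k <- gap$k
    res$diagnostics$dunn <- dunn_index(dm, res$labels)
    candidates[[alg]] <- res
    gap_tables[[alg]] <- gap$table
  }
  best <- stage("clustering", select_algorithm(candidates, dm))
  partition <- stage("clustering", split_main_outlier(best, onset_medians))
  write_csv0(data.frame(partition, algorithm = best$algorithm, k = best$k),
             file.path(out_dir, "assignments.csv"))

  fits <- stage("actuarial",
                classify_all(rates,
                             min_positive_ages = config$min_positive_ages))
  write_csv0(fits, file.path(out_dir, "fits.csv"))
  write_csv0(fits[, c("disease_id", "band")],
             file.path(out_dir, "verdicts.csv"))

  xt_band <- stage("report", crosstab_cluster_band(partition, fits))
  utils::write.csv(as.data.frame.matrix(xt_band),
                   file.path(out_dir, "crosstab_band.csv"))
  xt_cat <- NULL
  if (!is.null(meta)) {
    xt_cat <- stage("report", crosstab_cluster_category(partition, meta))
    utils::write.csv(as.data.frame.matrix(xt_cat),
                     file.path(out_dir, "crosstab_category.csv"))
  }
  med_summary <- stage("report",
                       cluster_median_summary(partition, onset_medians))
  write_csv0(med_summary, file.path(out_dir, "cluster_medians.csv"))

  diagnostics <- list(
    linkage_scores = attr(linkage, "scores"),
    selected_linkage = as.character(linkage),
    gap = gap_tables,
    dunn = attr(best, "comparison"),
    selected_algorithm = best$algorithm,
    selected_k = best$k)
  jsonlite::write_json(diagnostics, file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(seed = config$seed, config = unclass(config),
                   n_diseases = nrow(x),
                   package_version =
                     as.character(utils::packageVersion("ardkit")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  bands <- attr(fits, "band_counts")
  summary_lines <- c(
    sprintf("diseases analysed: %d (clustered: %d)",
            length(unique(counts$disease_id)), nrow(x)),
    sprintf("selected linkage: %s", as.character(linkage)),
    sprintf("selected algorithm: %s with k = %d (Dunn = %.3f)",
            best$algorithm, best$k, best$diagnostics$dunn),
    sprintf("main clusters: %d, outlier clusters: %d",
            sum(attr(partition, "summary")$type == "main"),
            sum(attr(partition, "summary")$type == "outlier")),
    sprintf("bands: %s",
            paste(names(bands), as.integer(bands), sep = "=",
                  collapse = ", ")))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(rates = rates, std = std, onset_medians = onset_medians,
                 selection = diagnostics, clustering = best,
                 partition = partition, fits = fits,
                 crosstabs = list(band = xt_band, category = xt_cat),
                 cluster_medians = med_summary))
}
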