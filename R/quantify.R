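#' Genome proportion of a cluster
#'
#' Percent of one species' analyzed reads that fall in the cluster.
#' @param cluster_reads Reads of that species in the cluster.
#' @param analyzed_reads Total analyzed reads of that species.
#' @return Percent (0-100).
#' @examples
#' genome_proportion(100, 1e6)  # 0.01
#' @export
genome_proportion <- function(cluster_reads, analyzed_reads) {
  stopifnot(analyzed_reads > 0)
  if (any(cluster_reads > analyzed_reads)) {
    stop("cluster_reads cannot exceed analyzed_reads")
  }
  100 * cluster_reads / analyzed_reads
}

#' Convert a genome proportion to megabases per 1C
#'
#' @param gp Genome proportion in percent (0-100).
#' @param c_value_mb 1C-value in Mb.
#' @return Abundance in Mb (full precision; round for display).
#' @examples
#' gp_to_mb(10.20, 4680)  # ~477 Mb
#' @export
gp_to_mb <- function(gp, c_value_mb) {
  stopifnot(all(gp >= 0), all(gp <= 100))
  gp / 100 * c_value_mb
}

#' Genome size ratio between two species
#' @param c_large,c_small 1C-values in Mb (both > 0).
#' @return The ratio `c_large / c_small` (dimensionless).
#' @examples
#' genome_size_ratio(4680, 2480)  # ~1.89
#' @export
genome_size_ratio <- function(c_large, c_small) {
  stopifnot(c_large > 0, c_small > 0)
  c_large / c_small
}

#' Per-lineage read share of a clustering run
#'
#' Aggregates cluster read counts by annotation label, per species, and adds
#' the low/single-copy remainder. The GP columns are percent of each
#' species' analyzed reads and sum to 100 exactly.
#'
#' @param cs A `cluster_set`.
#' @param annotation An [annotate_clusters()] result.
#' @return Data frame: `label`, then one `gp_<code>` column per species.
#' @export
lineage_abundance <- function(cs, annotation) {
  labels <- sort_c(unique(annotation$label))
  out <- data.frame(label = c(labels, "low/single copy"),
                    stringsAsFactors = FALSE)
  for (sp in cs$species) {
    reads <- cs$clusters[[paste0("reads_", sp)]]
    by_label <- vapply(labels, function(lb) {
      sum(reads[annotation$label[match(cs$clusters$id, annotation$id)] == lb])
    }, numeric(1))
    low <- cs$analyzed[[sp]] - sum(by_label)
    out[[paste0("gp_", sp)]] <-
      100 * c(by_label, low) / cs$analyzed[[sp]]
  }
  out
}

#' Abundance table (GP% and Mb/1C per lineage and species)
#'
#' The species summary table of a repeat profiling run: per annotation label
#' the genome proportion (percent of analyzed reads) and the corresponding
#' abundance in Mb/1C (`gp/100 * 1C`). Unrounded values are reported; the
#' per-species Mb columns sum to the species' 1C-value exactly.
#'
#' @param cs A `cluster_set`.
#' @param annotation An [annotate_clusters()] result.
#' @param profiles List of [species_profile()] objects keyed by code.
#' @return Data frame: `label`, `gp_<code>` and `mb_<code>` columns.
#' @export
abundance_table <- function(cs, annotation, profiles) {
  tab <- lineage_abundance(cs, annotation)
  for (p in profiles) {
    gp_col <- paste0("gp_", p$code)
    if (!gp_col %in% names(tab)) next
    tab[[paste0("mb_", p$code)]] <- gp_to_mb(tab[[gp_col]], p$c_value_mb)
  }
  tab
}

#' Comparative cluster table for two species
#'
#' One row per cluster of a comparative run: per-species read counts, genome
#' proportions, the log2 GP ratio (species B over species A; zero means the
#' cluster occupies the same genome proportion in both), and the shared
#' flag. When both species were sampled at the same genome proportion, the
#' expected slope of the reads_B-vs-reads_A scatter equals the genome-size
#' ratio 1C_B / 1C_A; with unequal sampled proportions the expectation is
#' adjusted by the sampling ratio and a warning is raised.
#'
#' @param cs A comparative `cluster_set` (two species).
#' @param annotation An [annotate_clusters()] result.
#' @param profile_a,profile_b [species_profile()]s; A is the reference
#'   (denominator) species.
#' @param sampled_gp_a,sampled_gp_b Genome proportions the two read sets
#'   were down-sampled to (default equal).
#' @return List with `records` (data frame) and `expected_slope`.
#' @export
comparative_table <- function(cs, annotation, profile_a, profile_b,
                              sampled_gp_a = 0.013, sampled_gp_b = 0.013) {
  stopifnot(all(c(profile_a$code, profile_b$code) %in% cs$species))
  ra <- cs$clusters[[paste0("reads_", profile_a$code)]]
  rb <- cs$clusters[[paste0("reads_", profile_b$code)]]
  gp_a <- 100 * ra / cs$analyzed[[profile_a$code]]
  gp_b <- 100 * rb / cs$analyzed[[profile_b$code]]
  expected <- profile_b$c_value_mb / profile_a$c_value_mb
  if (!isTRUE(all.equal(sampled_gp_a, sampled_gp_b))) {
    warning("unequal sampled genome proportions; slope expectation adjusted")
    expected <- expected * (sampled_gp_b / sampled_gp_a)
  }
  lab <- annotation$label[match(cs$clusters$id, annotation$id)]
  records <- data.frame(
    id = cs$clusters$id, lineage = lab,
    reads_a = ra, reads_b = rb, gp_a = gp_a, gp_b = gp_b,
    log2_gp_ratio = ifelse(gp_a > 0 & gp_b > 0, log2(gp_b / gp_a), NA_real_),
    shared = ra > 0 & rb > 0, stringsAsFactors = FALSE)
  list(records = records, expected_slope = expected)
}

#' Slope of the shared-cluster read scatter
#'
#' Estimates the slope of the reads_B-versus-reads_A scatter across shared
#' clusters; when both species were sampled at the same genome proportion
#' this slope estimates the genome-size ratio. Satellite clusters are
#' excluded by default (their abundance difference dominates the scatter
#' and they are analyzed separately).
#'
#' The default `"pooled"` method is the count-weighted through-origin fit
#' `sum(reads_B) / sum(reads_A)` — the weighted least-squares solution with
#' Poisson-appropriate (1/x) weights. It is preferred at desk scale because
#' ordinary least squares on small counts is attenuated toward zero by the
#' sampling noise in the x coordinate; with the large clusters of a
#' full-size run the two estimators agree.
#'
#' @param comp A [comparative_table()] result (or its `records`).
#' @param exclude_satellites Drop clusters labelled `"satellite"` (default
#'   `TRUE`).
#' @param method `"pooled"` (default), `"ols_origin"` (least squares
#'   through the origin) or `"ols"` (with intercept).
#' @return The slope estimate.
#' @export
scatter_slope <- function(comp, exclude_satellites = TRUE,
                          method = c("pooled", "ols_origin", "ols")) {
  method <- match.arg(method)
  rec <- if (is.data.frame(comp)) comp else comp$records
  rec <- rec[rec$shared, , drop = FALSE]
  if (exclude_satellites) {
    rec <- rec[rec$lineage != "satellite", , drop = FALSE]
  }
  if (nrow(rec) < 2L) stop("need at least two shared clusters")
  switch(method,
         pooled = sum(rec$reads_b) / sum(rec$reads_a),
         ols_origin = sum(rec$reads_a * rec$reads_b) / sum(rec$reads_a^2),
         ols = ols_regression(rec$reads_a, rec$reads_b)$slope)
}

#' Ordinary least squares with slope test
#'
#' Closed-form simple linear regression: slope and intercept from the normal
#' equations, coefficient of determination, and the two-sided p-value of the
#' slope from the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3, finite; `x` must vary).
#' @return List with class `ols_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `se_slope`, `n`.
#' @export
ols_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate input: x has zero variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  se <- sqrt(ss_res / (n - 2L) / sxx)
  tval <- if (se == 0) Inf else slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2L)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_value = p, se_slope = se, n = n), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> y = %.4g + %.4g x; R^2 = %.3f, p = %.3g, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Per-lineage regressions across shared clusters
#'
#' For each lineage with at least `min_n` shared clusters, and for the
#' composite groups "All LTR-retrotransposons", "All repeats (including
#' satellites)" and "All repeats (excluding satellites)", regresses the
#' species-B genome proportion of each shared cluster on its species-A
#' genome proportion.
#'
#' @param comp A [comparative_table()] result (or its `records`).
#' @param min_n Minimum shared clusters per group (default 3).
#' @return Data frame: `group`, `n`, `slope`, `intercept`, `r_squared`,
#'   `p_value`.
#' @export
lineage_regressions <- function(comp, min_n = 3L) {
  rec <- if (is.data.frame(comp)) comp else comp$records
  rec <- rec[rec$shared, , drop = FALSE]
  groups <- list()
  for (lg in sort_c(unique(rec$lineage))) {
    groups[[lg]] <- rec$lineage == lg
  }
  groups[["All LTR-retrotransposons"]] <- grepl("^Ty[13]/", rec$lineage)
  groups[["All repeats (including satellites)"]] <- rep(TRUE, nrow(rec))
  groups[["All repeats (excluding satellites)"]] <- rec$lineage != "satellite"
  rows <- lapply(names(groups), function(gname) {
    sub <- rec[groups[[gname]], , drop = FALSE]
    if (nrow(sub) < min_n || length(unique(sub$gp_a)) < 2L) return(NULL)
    fit <- ols_regression(sub$gp_a, sub$gp_b)
    data.frame(group = gname, n = fit$n, slope = fit$slope,
               intercept = fit$intercept, r_squared = fit$r_squared,
               p_value = fit$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
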