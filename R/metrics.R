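#' Aggregate volume fraction
#'
#' The summed volume of all identified aggregates divided by the total
#' imaged volume: the fraction of the imaged region occupied by
#' aggregates. A sample with no aggregates has volume fraction 0.
#'
#' @param x an `aggregate_set`, or a numeric vector of aggregate volumes
#'   (then `imaged_volume` is required).
#' @param imaged_volume total imaged volume in the same cubed unit.
#' @return a number in `[0, 1]`.
#' @export
volume_fraction <- function(x, imaged_volume = NULL) {
  if (inherits(x, "aggregate_set")) {
    v <- x$records$volume_um3
    imaged_volume <- x$imaged_volume_um3
  } else v <- as.numeric(x)
  if (is.null(imaged_volume) || imaged_volume <= 0)
    stop("imaged_volume must be positive", call. = FALSE)
  sum(v) / imaged_volume
}

#' Volume-weighted mean aggregate volume
#'
#' `sum(v_i^2) / sum(v_i)`: the effective average aggregate volume in
#' which a randomly chosen bacterium finds itself. Weighting each
#' aggregate by its own volume makes the statistic reflect the experience
#' of cells rather than of aggregates, so a few large aggregates dominate
#' it, as they dominate the population. Always at least the arithmetic
#' mean, with equality only when all aggregates are the same size.
#'
#' @param volumes positive aggregate volumes (um^3).
#' @return weighted mean volume, or `NULL` for an empty list (an
#'   aggregate-free sample has no defined mean size — it is not 0).
#' @examples
#' weighted_mean_volume(c(1, 3)) # 2.5
#' @export
weighted_mean_volume <- function(volumes) {
  volumes <- as.numeric(volumes)
  if (!length(volumes)) return(NULL)
  if (any(volumes <= 0)) stop("volumes must be positive", call. = FALSE)
  sum(volumes^2) / sum(volumes)
}

#' Area-weighted mean cross-sectional area
#'
#' The 2D analogue of [weighted_mean_volume()], used for whole-well
#' tile-scan data: `sum(a_i^2) / sum(a_i)`.
#'
#' @param areas positive cross-sectional areas (um^2).
#' @return weighted mean area, or `NULL` for an empty list.
#' @export
weighted_mean_area <- function(areas) {
  weighted_mean_volume(areas)
}

#' Two-sample Kolmogorov-Smirnov comparison of pooled size distributions
#'
#' Compares the size distributions of two conditions after pooling the
#' per-aggregate values from all biological replicates of each condition
#' (replicate means are never tested; the distributions are). `D` is the
#' supremum of the absolute difference between the two empirical CDFs; the
#' p-value uses the asymptotic two-sample KS distribution.
#'
#' @param pooled_a,pooled_b numeric vectors of volumes (um^3) or areas
#'   (um^2), already pooled across replicates; both non-empty.
#' @return list of class `ks_comparison`: `statistic` (D), `p_value`,
#'   `n_a`, `n_b`.
#' @export
ks_two_sample <- function(pooled_a, pooled_b) {
  pooled_a <- as.numeric(pooled_a)
  pooled_b <- as.numeric(pooled_b)
  if (!length(pooled_a) || !length(pooled_b))
    stop("both samples must be non-empty", call. = FALSE)
  ht <- suppressWarnings(ks.test(pooled_a, pooled_b, exact = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 n_a = length(pooled_a), n_b = length(pooled_b)),
            class = "ks_comparison")
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.6g, p = %.4g (n = %d vs %d, pooled)\n",
              x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Replicate mean and standard deviation on untransformed data
#'
#' One value per biological replicate (e.g. a volume fraction) in, mean
#' and sample SD (n - 1 denominator) out. Mean and SD are computed on the
#' raw, untransformed values; `bar_lower`/`bar_upper` are `mean -/+ sd` on
#' the raw scale, so on a log axis the error bars are asymmetric — that is
#' expected, not a bug. A single replicate yields SD 0 with a warning.
#'
#' @param values numeric, one entry per replicate.
#' @return list: `mean`, `sd`, `n`, `bar_lower`, `bar_upper`.
#' @export
replicate_summary <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("at least one replicate required", call. = FALSE)
  m <- mean(values)
  s <- if (length(values) == 1L) {
    warning("single replicate: SD reported as 0")
    0
  } else sd(values)
  list(mean = m, sd = s, n = length(values),
       bar_lower = m - s, bar_upper = m + s)
}

#' Relative light units
#'
#' Bioluminescence normalization: counts/min per mL divided by the
#' culture's optical density, `RLU = (counts/min/mL) / OD600`.
#'
#' @param counts_per_min_per_ml bioluminescence rate.
#' @param od600 optical density at 600 nm; must be positive.
#' @return RLU.
#' @export
rlu <- function(counts_per_min_per_ml, od600) {
  if (any(od600 <= 0)) stop("od600 must be positive", call. = FALSE)
  counts_per_min_per_ml / od600
}

#' Summary metrics of a segmented sample
#'
#' @param set an `aggregate_set`.
#' @return list of class `metrics_report`: `volume_fraction`,
#'   `weighted_mean_volume_um3` (`NULL` when the sample has no
#'   aggregates), `n_aggregates`, `volumes` (um^3),
#'   `imaged_volume_um3`.
#' @export
aggregate_metrics <- function(set) {
  stopifnot(inherits(set, "aggregate_set"))
  v <- set$records$volume_um3
  structure(list(volume_fraction = volume_fraction(set),
                 weighted_mean_volume_um3 = weighted_mean_volume(v),
                 n_aggregates = length(v),
                 volumes = v,
                 imaged_volume_um3 = set$imaged_volume_um3),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("volume fraction: %.6g\n", x$volume_fraction))
  cat(sprintf("aggregates: %d; weighted mean volume: %s um^3\n",
              x$n_aggregates,
              if (is.null(x$weighted_mean_volume_um3)) "undefined"
              else sprintf("%.6g", x$weighted_mean_volume_um3)))
  invisible(x)
}

#' Compare two conditions by pooling replicates
#'
#' Pools the per-aggregate sizes from all replicates of each condition and
#' runs [ks_two_sample()] on the pooled distributions.
#'
#' @param reps_a,reps_b lists of `metrics_report` objects (or numeric
#'   vectors of sizes), one entry per biological replicate.
#' @return a `ks_comparison`.
#' @export
compare_conditions <- function(reps_a, reps_b) {
  pool <- function(reps) {
    if (is.numeric(reps)) return(reps)
    unlist(lapply(reps, function(r)
      if (inherits(r, "metrics_report")) r$volumes else as.numeric(r)))
  }
  ks_two_sample(pool(reps_a), pool(reps_b))
}
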