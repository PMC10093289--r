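# Segmentation evaluation metrics: Dice similarity coefficient (DSC),
# volumetric overlap error (VOE), average surface distance (ASD), accuracy,
# sensitivity and specificity, per-slice and aggregated, plus a paired
# Wilcoxon signed-rank comparison between models.
#
# Conventions where the definitions degenerate (declared, and flagged in the
# report rather than silently imputed):
#   * both masks empty: DSC = 1, VOE = 0 (perfect agreement on "nothing").
#   * ASD with an empty surface on either side: NA, excluded from aggregation
#     with a warning.
#   * zero-denominator ACC/SEN/SPE: NA for that metric.

check_binary <- function(m, what) {
  if (!all(m %in% c(0, 1))) {
    abort(sprintf("%s must be binary (0/1); threshold predictions first", what))
  }
}

#' Pixel-wise confusion counts for a prediction/truth pair
#'
#' @param pred,truth binary matrices of identical dimensions.
#' @return a `confusion_counts` list with `tp`, `fp`, `fn`, `tn` summing to
#'   the pixel count.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    abort("pred and truth must have identical dimensions")
  }
  check_binary(pred, "pred"); check_binary(truth, "truth")
  p <- pred == 1; t <- truth == 1
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' Dice similarity coefficient from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`; when both masks are empty the value is defined
#' as 1 (and flagged by [evaluate()] reports via the `both_empty` column).
#'
#' @param c a [confusion()] result.
#' @return fraction in \[0, 1\].
#' @export
dsc <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Volumetric overlap error (percent)
#'
#' `(1 - |A intersect B| / |A union B|) * 100`; 0 when both masks are empty.
#'
#' @param pred,truth binary matrices.
#' @return percentage in \[0, 100\].
#' @export
voe <- function(pred, truth) {
  cc <- confusion(pred, truth)
  un <- cc$tp + cc$fp + cc$fn
  if (un == 0) return(0)
  (1 - cc$tp / un) * 100
}

#' Extract the surface (boundary) pixels of a binary mask
#'
#' A surface pixel is a foreground pixel with at least one background
#' neighbour under the chosen connectivity; the image border counts as
#' background.
#'
#' @param mask binary matrix.
#' @param spacing physical pixel spacing `c(row_mm, col_mm)`.
#' @param connectivity 4 (default) or 8.
#' @return a `surface_set`: list with `coords` (n x 2 matrix of row/col
#'   indices), `indicator` (logical matrix), and `spacing`.
#' @export
surface <- function(mask, spacing = c(1, 1), connectivity = 4L) {
  check_binary(mask, "mask")
  stopifnot(connectivity %in% c(4L, 8L), length(spacing) == 2, all(spacing > 0))
  m <- mask == 1
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  up    <- pad[1:h, 2:(w + 1)]
  down  <- pad[3:(h + 2), 2:(w + 1)]
  left  <- pad[2:(h + 1), 1:w]
  right <- pad[2:(h + 1), 3:(w + 2)]
  bg_neighbor <- !up | !down | !left | !right
  if (connectivity == 8L) {
    ul <- pad[1:h, 1:w]; ur <- pad[1:h, 3:(w + 2)]
    dl <- pad[3:(h + 2), 1:w]; dr <- pad[3:(h + 2), 3:(w + 2)]
    bg_neighbor <- bg_neighbor | !ul | !ur | !dl | !dr
  }
  ind <- m & bg_neighbor
  structure(list(coords = which(ind, arr.ind = TRUE),
                 indicator = ind, spacing = as.numeric(spacing)),
            class = "surface_set")
}

#' Average surface distance between two binary masks (mm)
#'
#' The symmetric mean of nearest-surface Euclidean distances:
#' `(sum_{a in S(A)} d(a, S(B)) + sum_{b in S(B)} d(b, S(A))) / (|S(A)| + |S(B)|)`
#' with distances measured between pixel centres in physical spacing units.
#' Computed with an exact Euclidean distance transform of each surface.
#'
#' @param pred,truth binary matrices.
#' @param spacing physical pixel spacing `c(row_mm, col_mm)`.
#' @param connectivity surface connectivity, 4 or 8.
#' @return distance in mm, or `NA` (with a warning) if either mask is empty.
#' @export
asd <- function(pred, truth, spacing = c(1, 1), connectivity = 4L) {
  sa <- surface(pred, spacing, connectivity)
  sb <- surface(truth, spacing, connectivity)
  na_ <- nrow(sa$coords); nb_ <- nrow(sb$coords)
  if (na_ == 0 || nb_ == 0) {
    warn("average surface distance undefined for an empty mask; returning NA")
    return(NA_real_)
  }
  dist_to_b <- .edt(sb$indicator, spacing)
  dist_to_a <- .edt(sa$indicator, spacing)
  (sum(dist_to_b[sa$indicator]) + sum(dist_to_a[sb$indicator])) / (na_ + nb_)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `ACC = (TP+TN)/total`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`; a metric
#' with a zero denominator is `NA`.
#'
#' @param c a [confusion()] result.
#' @return named numeric vector `c(acc, sen, spe)`.
#' @export
acc_sen_spe <- function(c) {
  total <- c$tp + c$fp + c$fn + c$tn
  acc <- if (total > 0) (c$tp + c$tn) / total else NA_real_
  sen <- if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else NA_real_
  spe <- if (c$tn + c$fp > 0) c$tn / (c$tn + c$fp) else NA_real_
  c(acc = acc, sen = sen, spe = spe)
}

#' All six metrics for one prediction/truth pair
#'
#' @param pred,truth binary matrices.
#' @param spacing physical pixel spacing `c(row_mm, col_mm)`.
#' @return one-row tibble with `dsc`, `voe`, `asd`, `acc`, `sen`, `spe`, and
#'   a `both_empty` flag marking the degenerate convention.
#' @export
slice_metrics <- function(pred, truth, spacing = c(1, 1)) {
  cc <- confusion(pred, truth)
  ass <- acc_sen_spe(cc)
  asd_v <- if (sum(pred) == 0 || sum(truth) == 0) {
    if (sum(pred) == 0 && sum(truth) == 0) NA_real_ else {
      suppressWarnings(asd(pred, truth, spacing))
    }
  } else asd(pred, truth, spacing)
  tibble(dsc = dsc(cc), voe = voe(pred, truth), asd = asd_v,
         acc = ass[["acc"]], sen = ass[["sen"]], spe = ass[["spe"]],
         both_empty = sum(pred) == 0 && sum(truth) == 0)
}

#' Aggregate per-slice metric rows into a report
#'
#' @param per_slice tibble with columns `dsc`, `voe`, `asd`, `acc`, `sen`,
#'   `spe` (one row per slice; `NA` allowed).
#' @return a `metric_report`: list with `per_slice` and `summary` (mean,
#'   sample sd, max, min, n, n_missing per metric). All-missing metrics are
#'   flagged with a warning and `NaN` mean.
#' @export
aggregate_metrics <- function(per_slice) {
  stopifnot(nrow(per_slice) >= 1)
  metrics <- c("dsc", "voe", "asd", "acc", "sen", "spe")
  summary <- purrr::list_rbind(purrr::map(metrics, function(m) {
    v <- per_slice[[m]]
    ok <- !is.na(v)
    if (!any(ok)) {
      warn(sprintf("metric '%s' is missing for every slice", m))
      return(tibble(metric = m, mean = NaN, sd = NA_real_, max = NA_real_,
                    min = NA_real_, n = 0L, n_missing = sum(!ok)))
    }
    tibble(metric = m, mean = mean(v[ok]),
           sd = if (sum(ok) > 1) sd(v[ok]) else 0,
           max = max(v[ok]), min = min(v[ok]),
           n = sum(ok), n_missing = sum(!ok))
  }))
  structure(list(per_slice = as_tibble(per_slice), summary = summary),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d slices\n", nrow(x$per_slice)))
  print(x$summary)
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison of per-slice metric values
#'
#' Two-sided signed-rank test on paired per-slice values from two models.
#' Zero differences are dropped (the standard signed-rank convention); if all
#' differences are zero the test is degenerate and `p = 1` is returned with a
#' warning.
#'
#' @param values_a,values_b equal-length (>= 5) paired numeric vectors.
#' @return one-row tibble: `statistic`, `p_value`, `n_used`, `method`.
#' @export
wilcoxon_paired <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 5)
  d <- values_a - values_b
  if (all(d == 0)) {
    warn("all paired differences are zero; Wilcoxon test degenerate, p = 1")
    return(tibble(statistic = 0, p_value = 1, n_used = 0L,
                  method = "Wilcoxon signed rank (degenerate)"))
  }
  ht <- suppressWarnings(wilcox.test(values_a, values_b, paired = TRUE,
                                     alternative = "two.sided"))
  nu <- sum(d != 0)
  # signed statistic: positive minus negative rank sum (antisymmetric under
  # swapping the two models); wilcox.test reports the positive rank sum V
  signed <- 2 * unname(ht$statistic) - nu * (nu + 1) / 2
  tibble(statistic = signed, p_value = ht$p.value,
         n_used = nu, method = ht$method)
}

#' Write a metric report as CSV + JSON summary
#'
#' CSV holds one row per slice; the JSON summary mirrors a results-table
#' layout (VOE, ASD mm, DSC max/min/mean, ACC, SEN, SPE).
#'
#' @param report a `metric_report`.
#' @param csv_path,json_path output file paths (either may be `NULL`).
#' @return the report, invisibly.
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  if (!is.null(csv_path)) {
    write.csv(report$per_slice, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    s <- report$summary
    g <- function(m, f) s[[f]][s$metric == m]
    out <- list(
      VOE = g("voe", "mean"), VOE_sd = g("voe", "sd"),
      ASD_mm = g("asd", "mean"), ASD_sd = g("asd", "sd"),
      DSC_max = g("dsc", "max"), DSC_min = g("dsc", "min"),
      DSC_mean = g("dsc", "mean"), DSC_sd = g("dsc", "sd"),
      ACC = g("acc", "mean"), SEN = g("sen", "mean"), SPE = g("spe", "mean"),
      n_slices = nrow(report$per_slice))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
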