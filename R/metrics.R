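# Validation metrics: Dice overlap, predictive values, necrosis
# fraction, correlation and group comparison, and the TUNEL histology
# threshold reference.

#' Per-label confusion counts between two label maps
#'
#' @param pred,ref integer label maps of the same shape (0 = background).
#' @param label the tissue label to score.
#' @param mask voxels to score over; defaults to the union of the two
#'   foregrounds.
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, ref, label,
                             mask = pred > 0 | ref > 0) {
  stopifnot(identical(dim(pred), dim(ref)))
  p <- pred[mask] == label
  r <- ref[mask] == label
  list(tp = sum(p & r), fp = sum(p & !r), tn = sum(!p & !r),
       fn = sum(!p & r))
}

#' Dice similarity between two label maps
#'
#' Per label L present in either map, `2|A_L intersect B_L| /
#' (|A_L| + |B_L|)`; the multi-class coefficient is the mean over those
#' labels. Labels empty in both maps are skipped.
#'
#' @param a,b integer label maps of the same shape.
#' @return list with `per_label` (named vector) and `mean`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  labs <- sort(setdiff(union(unique(as.vector(a)), unique(as.vector(b))), 0))
  per <- vapply(labs, function(L) {
    na <- sum(a == L); nb <- sum(b == L)
    if (na + nb == 0) return(NA_real_)
    2 * sum(a == L & b == L) / (na + nb)
  }, numeric(1))
  names(per) <- labs
  list(per_label = per, mean = mean(per, na.rm = TRUE))
}

#' Positive and negative predictive value of a label
#'
#' `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`; `NA` when a denominator is
#' zero.
#'
#' @inheritParams confusion_counts
#' @return list with `ppv` and `npv`.
#' @export
predictive_values <- function(pred, ref, label) {
  cc <- confusion_counts(pred, ref, label)
  list(ppv = if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_,
       npv = if (cc$tn + cc$fn > 0) cc$tn / (cc$tn + cc$fn) else NA_real_)
}

#' Voxelwise accuracy of a label map against ground truth
#'
#' Fraction of voxels carrying the correct tissue label, over voxels
#' labelled in both maps. With `match = "best"` the predicted labels are
#' first re-mapped by the label bijection maximizing agreement (all 5!
#' permutations of the five tissue labels), which scores the clustering
#' independently of the cluster-to-label assignment.
#'
#' @param pred,truth integer label maps.
#' @param match `"labels"` (as given) or `"best"` (optimal bijection).
#' @return accuracy in [0, 1].
#' @export
segmentation_accuracy <- function(pred, truth,
                                  match = c("labels", "best")) {
  match <- match.arg(match)
  stopifnot(identical(dim(pred), dim(truth)))
  sel <- pred > 0 & truth > 0
  if (!any(sel)) return(NA_real_)
  p <- pred[sel]; tr <- truth[sel]
  if (match == "labels") return(mean(p == tr))
  perms <- .permutations5()
  max(vapply(seq_len(nrow(perms)), function(i) {
    mean(perms[i, ][p] == tr)
  }, numeric(1)))
}

.permutations5 <- function() {
  p <- expand.grid(a = 1:5, b = 1:5, c = 1:5, d = 1:5, e = 1:5)
  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 5), ])
  dimnames(p) <- NULL
  p
}

#' Intratumoural necrosis fraction of a label map
#'
#' Necrosis/apoptosis voxels over tumour + necrosis/apoptosis voxels;
#' other labels are ignored. `NA` if no tumour or necrosis voxels exist.
#'
#' @param labels integer label map (or vector).
#' @return fraction in [0, 1], or `NA`.
#' @export
necrosis_fraction <- function(labels) {
  n_nec <- sum(labels == .tissue_labels[["necrosis_apoptosis"]])
  n_tum <- sum(labels == .tissue_labels[["active_tumour"]])
  if (n_nec + n_tum == 0) return(NA_real_)
  n_nec / (n_nec + n_tum)
}

#' Pearson correlation with two-sided test
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @return list with `r` and `p`; both `NA` if either input has zero
#'   variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Unpaired two-sample t-test
#'
#' Student's t-test (equal variances) by default, with a Welch option.
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @param var_equal assume equal variances.
#' @return list with `t` and `p`.
#' @export
unpaired_ttest <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Threshold a TUNEL histology image into tumour and necrosis
#'
#' Inside the crop mask, pixels with blue-channel value strictly below
#' the threshold are classified active tumour and pixels at or above it
#' necrosis/apoptosis. Channels must be on the unit scale.
#'
#' @param rgb h x w x 3 array with values in [0, 1].
#' @param crop_mask logical/integer matrix excluding non-tumour tissue.
#' @param threshold blue-channel threshold (default 0.78).
#' @return integer label map (1 tumour, 2 necrosis/apoptosis, 0 outside
#'   the crop).
#' @export
segment_tunel <- function(rgb, crop_mask, threshold = 0.78) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  if (min(rgb) < 0 || max(rgb) > 1) {
    stop("image values outside [0, 1]; rescale (e.g. divide 8-bit data by 255)")
  }
  stopifnot(identical(dim(rgb)[1:2], dim(crop_mask)))
  blue <- rgb[, , 3]
  out <- matrix(0L, nrow(blue), ncol(blue))
  inmask <- crop_mask > 0
  out[inmask & blue < threshold] <- .tissue_labels[["active_tumour"]]
  out[inmask & blue >= threshold] <- .tissue_labels[["necrosis_apoptosis"]]
  out
}
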