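# End-to-end unsupervised segmentation: observation matrix -> ICA ->
# NMI ordering -> GMM -> rule-based tissue label assignment, plus the
# named acquisition protocols, leave-one-out robustness, protocol
# optimization against reference necrosis fractions, and feature-subset
# selection.

#' Tissue label codes
#'
#' Integer labels of the five tissue classes used throughout:
#' 1 active tumour, 2 necrosis/apoptosis, 3 blood/edema,
#' 4 muscle/connective, 5 muscle (0 is background).
#' @return named integer vector.
#' @export
tissue_labels <- function() .tissue_labels

#' Image-type names of a named acquisition protocol
#'
#' The seven candidate protocols: T1/T2 maps only; all Z-spectrum images;
#' low-B1 (0.5, 2 uT) Z images; high-B1 (3, 6 uT) Z images; and each map
#' set combined with them. `"optimized"` is an alias for T1/T2 plus the
#' high-B1 images — 24 image types under the default schedule.
#'
#' @param preproc an `stx_preproc` (supplies the available image types).
#' @param protocol one of `"t1t2"`, `"all_z"`, `"low_b1"`, `"high_b1"`,
#'   `"t1t2_high_b1"` (= `"optimized"`), `"t1t2_low_b1"`, `"t1t2_all"`,
#'   or a character vector of explicit image-type names.
#' @return character vector of image-type names.
#' @export
protocol_features <- function(preproc, protocol = "optimized") {
  stopifnot(inherits(preproc, "stx_preproc"))
  info <- preproc$feature_info
  maps <- info$name[info$type == "map"]
  lo <- info$name[info$role == "low_b1"]
  hi <- info$name[info$role == "high_b1"]
  if (length(protocol) > 1 || !protocol %in%
      c("t1t2", "all_z", "low_b1", "high_b1", "t1t2_high_b1",
        "optimized", "t1t2_low_b1", "t1t2_all")) {
    missing <- setdiff(protocol, info$name)
    if (length(missing)) stop("unknown image type(s): ",
                              paste(missing, collapse = ", "))
    return(protocol)
  }
  switch(protocol,
         t1t2 = maps,
         all_z = c(lo, hi),
         low_b1 = lo,
         high_b1 = hi,
         t1t2_high_b1 = c(maps, hi),
         optimized = c(maps, hi),
         t1t2_low_b1 = c(maps, lo),
         t1t2_all = c(maps, lo, hi))
}

#' Assign tissue labels to GMM clusters
#'
#' Implements the rule-based assignment: (1) the cluster with the largest
#' absolute GMM mean on IC1 is blood/edema; (2) each IC axis is reflected
#' (sign-flipped) as required so the blood/edema mean lies in the
#' all-positive orthant — ICA does not identify source signs; (3) the
#' remaining four clusters are ranked by their (reflected) IC2 means:
#' smallest muscle, then muscle/connective, then necrosis/apoptosis,
#' largest active tumour. Exact ties are broken by cluster index with a
#' warning.
#'
#' @param gmm a fitted `stx_gmm` with 5 clusters over >= 2 ICs.
#' @return list with `assignment` (integer vector: cluster -> tissue
#'   label), `signs` (per-IC reflection), and the reflected means.
#' @export
assign_cluster_labels <- function(gmm) {
  stopifnot(inherits(gmm, "stx_gmm"))
  if (gmm$k != 5) {
    stop("label assignment ruleset is defined for 5 clusters, got ", gmm$k)
  }
  if (gmm$d < 2) stop("label assignment requires at least 2 ICs")
  means <- gmm$means
  a1 <- abs(means[, 1])
  if (anyDuplicated(a1[a1 == max(a1)]) || sum(a1 == max(a1)) > 1) {
    warning("tie in |mean IC1|; broken by cluster index")
  }
  blood <- which.max(a1)
  signs <- ifelse(means[blood, ] < 0, -1, 1)
  refl <- sweep(means, 2, signs, `*`)
  rest <- setdiff(seq_len(5), blood)
  m2 <- refl[rest, 2]
  if (anyDuplicated(m2)) warning("tie in mean IC2; broken by cluster index")
  ranked <- rest[order(m2)]    # ascending IC2
  assignment <- integer(5)
  assignment[blood] <- .tissue_labels[["blood_edema"]]
  assignment[ranked[1]] <- .tissue_labels[["muscle"]]
  assignment[ranked[2]] <- .tissue_labels[["muscle_connective"]]
  assignment[ranked[3]] <- .tissue_labels[["necrosis_apoptosis"]]
  assignment[ranked[4]] <- .tissue_labels[["active_tumour"]]
  list(assignment = assignment, signs = signs, means_reflected = refl)
}

#' Segment a cohort of preprocessed studies
#'
#' The full unsupervised pipeline: pool the eroded-mask voxels of all
#' subjects into an observation matrix over the protocol image types, fit
#' and NMI-order an ICA, cluster the IC scores with a 5-component
#' full-covariance GMM, assign tissue labels by the rule set, and write a
#' per-subject label map. Deterministic given `seed`.
#'
#' @param preprocs list of [preprocess_study()] results.
#' @param protocol protocol name or image-type vector
#'   (see [protocol_features()]).
#' @param n_ics number of independent components.
#' @param n_clusters number of GMM clusters (the label rule set requires
#'   5).
#' @param seed RNG seed.
#' @param n_init GMM restarts.
#' @param subsample optionally fit ICA/GMM on at most this many pooled
#'   voxels (labels are still assigned to every voxel).
#' @return object of class `stx_segmentation`: the fitted transform,
#'   mixture, assignment and per-subject label maps.
#' @export
stx_segment <- function(preprocs, protocol = "optimized", n_ics = 3,
                        n_clusters = 5, seed = 1, n_init = 10,
                        subsample = NULL) {
  stopifnot(length(preprocs) >= 1)
  feats <- protocol_features(preprocs[[1]], protocol)
  if (length(feats) < n_ics) {
    stop("protocol has ", length(feats), " image types but ", n_ics,
         " ICs requested; the number of unique image types must be equal ",
         "to or greater than the number of ICs")
  }
  x <- build_observation_matrix(preprocs, feats)
  # fit on canonically sorted rows so results do not depend on subject
  # order (floating-point summation order would otherwise leak through)
  xfit <- x[do.call(order, as.data.frame(x)), , drop = FALSE]
  if (!is.null(subsample) && nrow(xfit) > subsample) {
    set.seed(seed)
    xfit <- xfit[sort(sample.int(nrow(xfit), subsample)), , drop = FALSE]
  }
  ica <- fit_ica(xfit, n_ics, seed = seed)
  ica <- order_components(ica, xfit)
  scores_fit <- project_ica(ica, xfit)
  gmm <- fit_gmm(scores_fit, k = n_clusters, seed = seed, n_init = n_init)
  asg <- assign_cluster_labels(gmm)
  scores <- project_ica(ica, x)
  cl <- predict_gmm(gmm, scores)$cluster
  labels_row <- asg$assignment[cl]
  ri <- attr(x, "row_index")
  label_maps <- lapply(preprocs, function(p) {
    lm <- matrix(0L, p$shape[1], p$shape[2])
    sel <- ri$subject_id == p$subject_id
    lm[ri$voxel[sel]] <- labels_row[sel]
    lm
  })
  names(label_maps) <- vapply(preprocs, `[[`, "", "subject_id")
  structure(list(
    protocol = protocol, features = feats,
    n_ics = n_ics, n_clusters = n_clusters,
    ica = ica, gmm = gmm,
    assignment = asg$assignment, signs = asg$signs,
    means_reflected = asg$means_reflected,
    label_maps = label_maps,
    seed = seed
  ), class = "stx_segmentation")
}

#' @export
print.stx_segmentation <- function(x, ...) {
  cat(sprintf("stx_segmentation: %d subjects, protocol '%s' (%d images), %d ICs, %d clusters\n",
              length(x$label_maps), paste(x$protocol, collapse = "+"),
              length(x$features), x$n_ics, x$n_clusters))
  invisible(x)
}

#' @export
summary.stx_segmentation <- function(object, ...) {
  counts <- t(vapply(object$label_maps, function(lm) {
    tabulate(lm[lm > 0], nbins = 5)
  }, numeric(5)))
  colnames(counts) <- names(.tissue_labels)
  nf <- apply(counts, 1, function(r) {
    if (r[1] + r[2] > 0) r[2] / (r[1] + r[2]) else NA_real_
  })
  out <- list(counts = counts, necrosis_fraction = nf)
  class(out) <- "summary.stx_segmentation"
  out
}

#' @export
print.summary.stx_segmentation <- function(x, ...) {
  print(cbind(as.data.frame(x$counts),
              necrosis_fraction = round(x$necrosis_fraction, 3)))
  invisible(x)
}

#' Apply a fitted segmentation model to a new subject
#'
#' Projects the subject's feature images through the stored ICA transform,
#' computes GMM posteriors, and maps clusters to tissue labels with the
#' stored assignment.
#'
#' @param object an `stx_segmentation`.
#' @param preproc an `stx_preproc` for the new subject.
#' @param ... unused.
#' @return integer label map matrix.
#' @export
predict.stx_segmentation <- function(object, preproc, ...) {
  stopifnot(inherits(preproc, "stx_preproc"))
  x <- build_observation_matrix(list(preproc), object$features)
  scores <- project_ica(object$ica, x)
  cl <- predict_gmm(object$gmm, scores)$cluster
  lm <- matrix(0L, preproc$shape[1], preproc$shape[2])
  lm[preproc$mask_idx] <- object$assignment[cl]
  lm
}

#' @export
plot.stx_segmentation <- function(x, subject = 1, ...) {
  lm <- x$label_maps[[subject]]
  cols <- c("black", "firebrick", "goldenrod", "royalblue", "grey70",
            "grey40")
  graphics::image(seq_len(nrow(lm)), seq_len(ncol(lm)), lm,
                  col = cols, zlim = c(0, 5), asp = 1,
                  xlab = "", ylab = "",
                  main = names(x$label_maps)[subject], ...)
  invisible(x)
}

#' Leave-one-out robustness of the segmentation
#'
#' For each subject, retrains the full pipeline (ICA basis, IC order, GMM,
#' label assignment) on the remaining subjects, applies the trained model
#' to the held-out subject, and scores the agreement with the
#' whole-cohort segmentation of that subject by the multi-class Dice
#' coefficient.
#'
#' @param preprocs list of preprocessed subjects (>= 3).
#' @param protocol,n_ics,seed,n_init as in [stx_segment()].
#' @param reference optional precomputed whole-cohort `stx_segmentation`.
#' @return data.frame of per-subject Dice with mean and SD in
#'   `attr(, "summary")`.
#' @export
leave_one_out <- function(preprocs, protocol = "optimized", n_ics = 3,
                          seed = 1, n_init = 10, reference = NULL) {
  stopifnot(length(preprocs) >= 3)
  if (is.null(reference)) {
    reference <- stx_segment(preprocs, protocol, n_ics = n_ics, seed = seed,
                             n_init = n_init)
  }
  res <- vapply(seq_along(preprocs), function(i) {
    fit <- stx_segment(preprocs[-i], protocol, n_ics = n_ics, seed = seed,
                       n_init = n_init)
    pred <- predict(fit, preprocs[[i]])
    dice(pred, reference$label_maps[[i]])$mean
  }, numeric(1))
  out <- data.frame(subject_id = vapply(preprocs, `[[`, "", "subject_id"),
                    dice = res, stringsAsFactors = FALSE)
  attr(out, "summary") <- c(mean = mean(res), sd = stats::sd(res))
  out
}

#' Select the acquisition protocol by necrosis-fraction agreement
#'
#' Segments the cohort under every feasible (protocol, number of ICs)
#' combination, computes the per-subject machine-learning necrosis
#' fraction, and correlates it (Pearson) with reference fractions (from
#' histology or phantom truth). Combinations with fewer image types than
#' ICs are infeasible and reported as NA.
#'
#' @param preprocs list of preprocessed subjects.
#' @param reference_fractions numeric vector of per-subject reference
#'   necrosis fractions.
#' @param protocols character vector of protocol names.
#' @param ics_range candidate IC counts.
#' @param seed,n_init,subsample as in [stx_segment()].
#' @return list with `best_protocol`, `best_n_ics` and the full `table`.
#' @export
optimize_protocol <- function(preprocs, reference_fractions,
                              protocols = c("t1t2", "all_z", "low_b1",
                                            "high_b1", "t1t2_high_b1",
                                            "t1t2_low_b1", "t1t2_all"),
                              ics_range = 2:4, seed = 1, n_init = 10,
                              subsample = NULL) {
  stopifnot(length(reference_fractions) == length(preprocs))
  grid <- expand.grid(protocol = protocols, n_ics = ics_range,
                      stringsAsFactors = FALSE)
  grid$rho <- NA_real_
  grid$p_value <- NA_real_
  for (i in seq_len(nrow(grid))) {
    feats <- protocol_features(preprocs[[1]], grid$protocol[i])
    if (length(feats) < grid$n_ics[i]) next
    seg <- stx_segment(preprocs, grid$protocol[i], n_ics = grid$n_ics[i],
                       seed = seed, n_init = n_init, subsample = subsample)
    nf <- summary(seg)$necrosis_fraction
    ok <- is.finite(nf) & is.finite(reference_fractions)
    if (sum(ok) >= 3) {
      ct <- pearson_r(nf[ok], reference_fractions[ok])
      grid$rho[i] <- ct$r
      grid$p_value[i] <- ct$p
    }
  }
  best <- which.max(grid$rho)
  list(best_protocol = grid$protocol[best], best_n_ics = grid$n_ics[best],
       table = grid)
}

# mean multi-class Dice of a candidate segmentation against reference
# label maps, averaged over subjects
.subset_score <- function(preprocs, feats, reference_maps, n_ics, seed,
                          n_init, subsample) {
  seg <- stx_segment(preprocs, feats, n_ics = n_ics, seed = seed,
                     n_init = n_init, subsample = subsample)
  mean(vapply(seq_along(preprocs), function(i) {
    dice(seg$label_maps[[i]], reference_maps[[i]])$mean
  }, numeric(1)))
}

#' Feature-subset selection against the full-protocol segmentation
#'
#' Searches image subsets of each requested size that best reproduce the
#' reference (full optimized protocol) segmentation, scoring candidates
#' by the subject-mean multi-class Dice coefficient. The search is
#' exhaustive while the number of candidate subsets stays within
#' `budget`; beyond that it degrades to a greedy forward search growing
#' the best smaller subset by one image (and, for the smallest size,
#' where no smaller subset exists, a seeded random search over `budget`
#' candidates). For the best subset of each size, PPV and NPV of the
#' active-tumour and necrosis/apoptosis labels against the reference are
#' reported.
#'
#' @param preprocs list of preprocessed subjects.
#' @param reference an `stx_segmentation` from the full protocol (its
#'   label maps are the reference), or a list of label maps.
#' @param subset_sizes vector of subset sizes to search.
#' @param pool candidate image-type names (default: the reference
#'   protocol's features).
#' @param n_ics,seed,n_init,subsample as in [stx_segment()].
#' @param budget maximum number of candidate subsets per size for
#'   exhaustive search.
#' @return list with `best` (data.frame per size: subset, Dice, PPV/NPV)
#'   and `evaluated` (all scored subsets per size).
#' @export
feature_select <- function(preprocs, reference, subset_sizes = 3:9,
                           pool = NULL, n_ics = 3, seed = 1, n_init = 5,
                           subsample = NULL, budget = 1e5) {
  if (inherits(reference, "stx_segmentation")) {
    if (is.null(pool)) pool <- reference$features
    reference_maps <- reference$label_maps
  } else {
    reference_maps <- reference
    if (is.null(pool)) stop("pool must be given when reference is a list")
  }
  stopifnot(all(subset_sizes >= n_ics))
  score <- function(feats) .subset_score(preprocs, feats, reference_maps,
                                         n_ics, seed, n_init, subsample)
  best_rows <- list()
  evaluated <- list()
  prev_best <- NULL
  for (s in sort(subset_sizes)) {
    n_cand <- choose(length(pool), s)
    if (n_cand <= budget) {
      cand <- utils::combn(pool, s, simplify = FALSE)
    } else if (!is.null(prev_best) && length(prev_best) == s - 1) {
      # greedy forward: grow the previous best subset by one image
      cand <- lapply(setdiff(pool, prev_best), function(f) c(prev_best, f))
    } else {
      # no smaller subset to grow: seeded random search
      set.seed(seed + s)
      cand <- unique(lapply(seq_len(budget), function(i) {
        sort(sample(pool, s))
      }))
    }
    sc <- vapply(cand, score, numeric(1))
    i <- which.max(sc)
    feats <- cand[[i]]
    seg <- stx_segment(preprocs, feats, n_ics = n_ics, seed = seed,
                       n_init = n_init, subsample = subsample)
    pv <- lapply(c(tumour = 1L, necrosis = 2L), function(lbl) {
      vals <- vapply(seq_along(preprocs), function(j) {
        unlist(predictive_values(seg$label_maps[[j]], reference_maps[[j]],
                                 lbl))
      }, numeric(2))
      rowMeans(vals, na.rm = TRUE)
    })
    best_rows[[as.character(s)]] <- data.frame(
      size = s, subset = paste(feats, collapse = "+"), dice = sc[i],
      ppv_tumour = pv$tumour[1], npv_tumour = pv$tumour[2],
      ppv_necrosis = pv$necrosis[1], npv_necrosis = pv$necrosis[2],
      stringsAsFactors = FALSE)
    evaluated[[as.character(s)]] <- data.frame(
      subset = vapply(cand, paste, "", collapse = "+"), dice = sc,
      stringsAsFactors = FALSE)
    prev_best <- feats
  }
  list(best = do.call(rbind, best_rows), evaluated = evaluated)
}
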