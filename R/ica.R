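# Independent component analysis of the voxel-by-image observation
# matrix: fixed-point negentropy maximization (log-cosh contrast) with
# symmetric decorrelation after PCA whitening. The stored transform
# (centre, whitening matrix, rotation) projects held-out subjects
# identically to the training data.

#' Build the voxel-by-image observation matrix
#'
#' Concatenates the eroded-mask voxels of all subjects (rows) over the
#' requested image types (columns). Row count is the summed per-subject
#' voxel count.
#'
#' @param preprocs list of [preprocess_study()] results.
#' @param feature_names character vector of image-type names (columns of
#'   each subject's feature matrix).
#' @return matrix with attributes `row_index` (data.frame of subject id
#'   and voxel index) and `column_names`.
#' @export
build_observation_matrix <- function(preprocs, feature_names) {
  stopifnot(length(preprocs) >= 1)
  rows <- lapply(preprocs, function(p) {
    stopifnot(inherits(p, "stx_preproc"))
    missing <- setdiff(feature_names, colnames(p$features))
    if (length(missing)) {
      stop("subject '", p$subject_id, "' is missing image type(s): ",
           paste(missing, collapse = ", "))
    }
    if (length(p$mask_idx) == 0) stop("empty eroded mask for subject '",
                                      p$subject_id, "'")
    p$features[, feature_names, drop = FALSE]
  })
  m <- do.call(rbind, rows)
  ri <- do.call(rbind, lapply(preprocs, function(p) {
    data.frame(subject_id = p$subject_id, voxel = p$mask_idx,
               stringsAsFactors = FALSE)
  }))
  rownames(m) <- NULL
  attr(m, "row_index") <- ri
  attr(m, "column_names") <- feature_names
  m
}

#' Fit an ICA transform to an observation matrix
#'
#' FastICA with symmetric (parallel) decorrelation and the log-cosh
#' contrast after PCA whitening to `k` components. Deterministic given
#' `seed`. The number of components may not exceed the number of image
#' types.
#'
#' @param x observation matrix (voxels x image types).
#' @param k number of independent components.
#' @param seed RNG seed for the initial rotation.
#' @param max_iter,tol fixed-point iteration controls.
#' @return object of class `stx_ica` holding the centring vector,
#'   whitening matrix `K`, rotation `W`, the combined `unmixing` matrix
#'   (scores = centred data %*% unmixing) and its pseudo-inverse `mixing`.
#' @export
fit_ica <- function(x, k, seed = 1, max_iter = 500, tol = 1e-6) {
  x <- as.matrix(x)
  n <- ncol(x); m <- nrow(x)
  if (k > n) {
    stop("number of ICs (", k, ") exceeds the number of unique image ",
         "types (", n, "); the image count must be equal to or greater ",
         "than the number of ICs")
  }
  if (m < 10 * k) stop("too few voxels (", m, ") for ", k, " components")
  centre <- colMeans(x)
  xc <- sweep(x, 2, centre)
  cv <- crossprod(xc) / (m - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[k] < 1e-12 * eg$values[1]) {
    stop("observation matrix is rank-deficient for k = ", k)
  }
  K <- eg$vectors[, 1:k, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[1:k]), k)        # whitening: z = xc %*% K
  z <- xc %*% K
  set.seed(seed)
  W <- matrix(stats::rnorm(k * k), k, k)
  sym_decorrelate <- function(W) {
    s <- W %*% t(W)
    e <- eigen(s, symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(e$values), k) %*% t(e$vectors)
    solve_sqrt %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- z %*% t(W)              # m x k
    gs <- tanh(s)
    gps <- colMeans(1 - gs^2)
    W1 <- crossprod(gs, z) / m - diag(gps, k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("ICA did not converge in ", max_iter, " iterations")
  unmixing <- K %*% t(W)                     # n x k
  mixing <- .pinv(unmixing)                  # k x n: xc ~ scores %*% mixing
  structure(list(
    k = k, centre = centre, K = K, W = W,
    unmixing = unmixing, mixing = mixing,
    column_names = colnames(x),
    mi_scores = NULL, component_order = seq_len(k),
    seed = seed, converged = converged, n_iter = it
  ), class = "stx_ica")
}

# Moore-Penrose pseudo-inverse (small matrices only)
.pinv <- function(a, tol = 1e-10) {
  sv <- svd(a)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
    t(sv$u[, pos, drop = FALSE])
}

#' Project data through a fitted ICA transform
#'
#' @param transform an `stx_ica`.
#' @param x matrix with the same image-type columns used in fitting.
#' @return matrix of IC scores (voxels x k), columns in component order.
#' @export
project_ica <- function(transform, x) {
  stopifnot(inherits(transform, "stx_ica"))
  sweep(as.matrix(x), 2, transform$centre) %*% transform$unmixing
}

# normalized mutual information between two signals after equal-width
# binning; normalization is the arithmetic mean of the two entropies
.nmi <- function(a, b, bins = 32) {
  cut_bins <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(rep(1L, length(v)))
    findInterval(v, seq(r[1], r[2], length.out = bins + 1),
                 rightmost.closed = TRUE, all.inside = TRUE)
  }
  ia <- cut_bins(a); ib <- cut_bins(b)
  joint <- table(ia, ib) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0) return(0)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  mi / ((ha + hb) / 2)
}

#' Order independent components by mutual information
#'
#' Computes the normalized mutual information (32 equal-width bins,
#' normalized to the arithmetic mean of the entropies) between each IC
#' and the voxelwise mean over all protocol images, and relabels the
#' components IC1, IC2, ... in increasing NMI — so IC1 is the component
#' least related to overall image intensity.
#'
#' @param transform an `stx_ica`.
#' @param x the observation matrix the transform was fitted to.
#' @param bins number of histogram bins.
#' @return the transform with permuted components and `mi_scores`
#'   (ascending) filled in.
#' @export
order_components <- function(transform, x, bins = 32) {
  stopifnot(inherits(transform, "stx_ica"))
  scores <- project_ica(transform, x)
  mean_img <- rowMeans(as.matrix(x))
  nmi <- apply(scores, 2, .nmi, b = mean_img, bins = bins)
  ord <- order(nmi)
  transform$unmixing <- transform$unmixing[, ord, drop = FALSE]
  transform$W <- transform$W[ord, , drop = FALSE]
  transform$mixing <- transform$mixing[ord, , drop = FALSE]
  transform$mi_scores <- nmi[ord]
  transform$component_order <- ord
  transform
}

#' @export
print.stx_ica <- function(x, ...) {
  cat(sprintf("stx_ica: %d components over %d image types (%s)\n",
              x$k, nrow(x$unmixing),
              if (x$converged) "converged" else "not converged"))
  if (!is.null(x$mi_scores)) {
    cat("  NMI vs mean image:",
        paste(sprintf("%.3f", x$mi_scores), collapse = ", "), "\n")
  }
  invisible(x)
}
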