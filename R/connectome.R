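# Per-subject weighted network construction.

new_connectivity_matrix <- function(W, modality) {
  stopifnot(is_symmetric_matrix(W, 1e-9))
  diag(W) <- 0
  structure(W, modality = modality, class = c("connectivity_matrix", "matrix"))
}

#' Build a functional connectivity matrix
#'
#' Pairwise Pearson correlations of the region-level signals are Fisher
#' z-transformed (`atanh`); connections are retained where `z > z_threshold`
#' (strictly) and set to 0 otherwise, so the weight of a surviving edge is
#' the magnitude of its z-score and negative correlations never survive a
#' positive threshold. Correlations are clipped to +/-(1 - 1e-12) before
#' `atanh` so duplicated signals keep finite weights.
#'
#' @param series Numeric matrix, time points x regions, with region labels
#'   as column names.
#' @param z_threshold Retention threshold on the z-scale (default 0.3,
#'   equivalent to `r > tanh(0.3)` ~= 0.2913).
#' @return A symmetric, zero-diagonal `connectivity_matrix` with modality
#'   `"functional"`.
#' @examples
#' ts <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("A", "B")))
#' functional_network(ts)
#' @export
functional_network <- function(series, z_threshold = 0.3) {
  if (!is.matrix(series) || ncol(series) < 2) {
    stop("series must be a matrix with at least 2 regions")
  }
  if (nrow(series) < 8) stop("at least 8 time points are required")
  if (!all(is.finite(series))) stop("series contains non-finite values")
  sds <- apply(series, 2, sd)
  flat <- sds == 0
  if (any(flat)) {
    warning("constant signal in region(s) ",
            paste(colnames(series)[flat], collapse = ", "),
            "; their edges are set to 0")
  }
  r <- suppressWarnings(cor(series))
  r[is.na(r)] <- 0
  z <- atanh(clip(r, -1 + 1e-12, 1 - 1e-12))
  W <- ifelse(z > z_threshold, z, 0)
  W[flat, ] <- 0
  W[, flat] <- 0
  diag(W) <- 0
  dimnames(W) <- list(colnames(series), colnames(series))
  new_connectivity_matrix(W, "functional")
}

#' Build an anatomical connectivity matrix
#'
#' Edge weights are the absolute fiber count normalized by the volumes of
#' the two interconnected regions. The default convention divides by the sum
#' of the two volumes (the common streamline-density choice); `"product"`
#' and `"mean"` are selectable alternatives.
#'
#' @param counts Symmetric nonnegative fiber-count matrix.
#' @param volumes Positive per-region volumes, aligned with `counts`.
#' @param anat_norm Volume-normalization convention.
#' @return A symmetric, zero-diagonal `connectivity_matrix` with modality
#'   `"anatomical"`.
#' @examples
#' cnt <- matrix(c(0, 10, 10, 0), 2, 2)
#' anatomical_network(cnt, c(2, 3))  # weight 10 / (2 + 3) = 2
#' @export
anatomical_network <- function(counts, volumes,
                               anat_norm = c("sum", "product", "mean")) {
  anat_norm <- match.arg(anat_norm)
  if (!is_symmetric_matrix(counts, 1e-9)) stop("counts must be a symmetric matrix")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (length(volumes) != nrow(counts)) stop("volumes must match matrix dimension")
  if (any(volumes <= 0)) stop("volumes must be strictly positive")
  denom <- switch(anat_norm,
                  sum = outer(volumes, volumes, "+"),
                  product = outer(volumes, volumes, "*"),
                  mean = outer(volumes, volumes, "+") / 2)
  W <- counts / denom
  diag(W) <- 0
  dimnames(W) <- dimnames(counts)
  new_connectivity_matrix(W, "anatomical")
}

#' Build all per-subject connectomes of a cohort
#'
#' @param cohort A `bgm_cohort` from [simulate_cohort()].
#' @param z_threshold Functional retention threshold on the Fisher z scale.
#' @param anat_norm Anatomical volume-normalization convention; see
#'   [anatomical_network()].
#' @return An object of class `bgm_connectomes`: lists `functional` and
#'   `anatomical` of `connectivity_matrix` objects keyed by subject id
#'   (subjects with an excluded anatomical scan are absent from
#'   `anatomical`), plus the region table.
#' @export
build_connectomes <- function(cohort, z_threshold = 0.3, anat_norm = "sum") {
  stopifnot(inherits(cohort, "bgm_cohort"))
  func <- lapply(cohort$timeseries, functional_network, z_threshold = z_threshold)
  anat <- lapply(cohort$fibers$counts, anatomical_network,
                 volumes = cohort$fibers$volumes, anat_norm = anat_norm)
  structure(list(functional = func, anatomical = anat,
                 regions = cohort$regions,
                 z_threshold = z_threshold, anat_norm = anat_norm),
            class = "bgm_connectomes")
}

#' @export
print.bgm_connectomes <- function(x, ...) {
  cat(sprintf("Connectomes: %d functional, %d anatomical (%d regions)\n",
              length(x$functional), length(x$anatomical), nrow(x$regions)))
  cat(sprintf("  z threshold %.3g (r > %.4f); anatomical norm: %s\n",
              x$z_threshold, tanh(x$z_threshold), x$anat_norm))
  invisible(x)
}
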