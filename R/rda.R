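#' Redundancy analysis (RDA) of dosages on environmental predictors
#'
#' Constrained ordination: the centered response matrix is projected onto the
#' column space of the predictors by least squares, and a PCA of the fitted
#' values yields the constrained axes. Each constrained axis's variance
#' fraction is its variance divided by the total variance of the (centered)
#' response, so the fractions measure how much genotypic variation geography
#' explains.
#'
#' Predictors whose pairwise absolute correlation exceeds 0.7 trigger a
#' collinearity warning (advisory, not an error).
#'
#' @param dosage a `dosage_matrix` or individuals x loci matrix (response).
#' @param predictors individuals x p numeric matrix (e.g. latitude and
#'   longitude).
#' @param n_axes constrained axes to return (<= p).
#' @return An `ordination_result` with `method = "RDA"`; also carries the
#'   total constrained variance fraction as attribute `"constrained_fraction"`.
#' @export
rda_fit <- function(dosage, predictors, n_axes = 2) {
  y <- if (inherits(dosage, "dosage_matrix")) dosage$dosage else as.matrix(dosage)
  x <- as.matrix(predictors)
  if (nrow(x) != nrow(y)) stop("predictors must match response rows")
  if (any(apply(x, 2, sd) == 0)) stop("constant predictor")
  if (ncol(x) >= 2) {
    cc <- cor(x)
    if (max(abs(cc[upper.tri(cc)])) > 0.7) {
      warning("predictor pairwise |correlation| exceeds 0.7; interpret with care")
    }
  }
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) stop("predictors are rank deficient")
  yc <- scale(y, center = TRUE, scale = FALSE)
  fitted <- qr.fitted(qrx, yc)
  total_var <- sum(yc^2)
  n_axes <- min(n_axes, ncol(x), nrow(y) - 1)
  sv <- svd(fitted, nu = n_axes, nv = 0)
  scores <- sv$u * rep(sv$d[seq_len(n_axes)], each = nrow(y))
  rownames(scores) <- rownames(y)
  colnames(scores) <- paste0("RDA", seq_len(n_axes))
  out <- structure(
    list(
      scores = scores,
      axis_variance_fraction = if (total_var > 0) {
        sv$d[seq_len(n_axes)]^2 / total_var
      } else {
        rep(0, n_axes)
      },
      loadings = NULL,
      method = "RDA"
    ),
    class = "ordination_result"
  )
  attr(out, "constrained_fraction") <-
    if (total_var > 0) sum(fitted^2) / total_var else 0
  out
}
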