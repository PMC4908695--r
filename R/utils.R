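#' @useDynLib lekscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dist kmeans lm.fit prcomp quantile rbeta rbinom rnorm
#'   rpois runif sd setNames var
#' @importFrom utils read.csv read.table write.csv write.table
NULL

# Evaluate `expr` under a locally-set RNG seed, restoring the caller's
# RNG state afterwards so library functions never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic 31-bit sub-seed from a master seed and a stage label
#' (a small polynomial hash), so that adding or reordering pipeline stages
#' never perturbs the seeds of other stages.
#'
#' @param master_seed integer master seed.
#' @param label character stage label.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, label) {
  h <- as.double(master_seed) %% 2147483647
  for (k in utf8ToInt(label)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Permutation test result
#'
#' Container for a permutation test: the observed statistic, the null sample,
#' and the add-one p-value \eqn{p = (\#\{null \ge observed\} + 1)/(B + 1)}
#' (or the lower-tail / two-sided analogue), which is never exactly zero.
#'
#' @param observed observed value of the statistic.
#' @param null_sample numeric vector of statistics under the permutation null.
#' @param tail one of `"upper"`, `"lower"`, `"two-sided"`.
#' @return An object of class `perm_test` with fields `observed`,
#'   `null_sample`, `p_value`, `n_permutations`, `tail`.
#' @export
perm_test_result <- function(observed, null_sample, tail = c("upper", "lower", "two-sided")) {
  tail <- match.arg(tail)
  b <- length(null_sample)
  n_extreme <- switch(tail,
    upper = sum(null_sample >= observed),
    lower = sum(null_sample <= observed),
    `two-sided` = sum(abs(null_sample) >= abs(observed))
  )
  structure(
    list(
      observed = observed,
      null_sample = null_sample,
      p_value = (n_extreme + 1) / (b + 1),
      n_permutations = b,
      tail = tail
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s tail): observed = %.6g, p = %.4g (%d permutations)\n",
    x$tail, x$observed, x$p_value, x$n_permutations
  ))
  invisible(x)
}

#' Labeled symmetric pairwise matrix
#'
#' Symmetric lek-by-lek (or complex-by-complex) matrix tagged with the kind of
#' quantity it holds: `"fst"`, `"nei_d"`, `"geographic"`, or `"least_cost"`.
#' The diagonal is zero by construction.
#'
#' @param values square numeric matrix (symmetrized by averaging with its
#'   transpose; diagonal forced to zero).
#' @param labels character vector of population labels.
#' @param kind matrix kind tag.
#' @return A `pairwise_matrix` object.
#' @export
pairwise_matrix <- function(values, labels, kind = c("fst", "nei_d", "geographic", "least_cost")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("pairwise matrix must be square")
  if (length(labels) != nrow(values)) stop("labels must match matrix dimension")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(labels = as.character(labels), values = values, kind = kind),
    class = "pairwise_matrix"
  )
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix [%s], %d labels\n", x$kind, length(x$labels)))
  print(round(x$values, 5))
  invisible(x)
}

#' Lower-triangle unfold of a pairwise matrix
#'
#' Off-diagonal lower-triangle entries (column-major order), the vector form
#' used by every distance-matrix statistic in the package.
#'
#' @param m a [pairwise_matrix()] or plain symmetric matrix.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
lower_triangle <- function(m) {
  v <- if (inherits(m, "pairwise_matrix")) m$values else as.matrix(m)
  v[lower.tri(v)]
}

#' Write a pairwise matrix as labeled CSV
#' @param x a `pairwise_matrix`.
#' @param path output file path.
#' @export
write_pairwise_csv <- function(x, path) {
  stopifnot(inherits(x, "pairwise_matrix"))
  df <- as.data.frame(x$values)
  df <- cbind(label = x$labels, df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pairwise matrix from labeled CSV
#' @param path file written by [write_pairwise_csv()].
#' @param kind matrix kind tag.
#' @export
read_pairwise_csv <- function(path, kind = "geographic") {
  df <- read.csv(path, check.names = FALSE)
  labels <- as.character(df[[1]])
  pairwise_matrix(as.matrix(df[, -1, drop = FALSE]), labels, kind)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be in [%g, %g]", name, lo, hi))
  }
  as.numeric(x)
}
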