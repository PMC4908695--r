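# Snap a point to its containing cell id (column-major, row + (col-1)*nrows);
# errors if the point falls outside the raster or on a nodata cell.
snap_to_cell <- function(r, x, y, label) {
  nr <- nrow(r$values)
  nc <- ncol(r$values)
  col <- floor((x - r$origin[1]) / r$cell_size) + 1
  row <- nr - floor((y - r$origin[2]) / r$cell_size)
  if (col < 1 || col > nc || row < 1 || row > nr) {
    stop(sprintf("point `%s` lies outside the raster extent", label))
  }
  if (r$values[row, col] == r$nodata || is.na(r$values[row, col])) {
    stop(sprintf("point `%s` falls on a nodata cell", label))
  }
  row + (col - 1) * nr
}

# 8-neighbor grid graph edge list; edge cost = mean of the two cell
# resistances * cell_size (* sqrt(2) for diagonal moves)
grid_edges <- function(r) {
  v <- r$values
  nr <- nrow(v)
  nc <- ncol(v)
  live <- v != r$nodata & !is.na(v)
  id <- matrix(seq_len(nr * nc), nr, nc)
  res <- v
  edges <- list()
  wts <- list()
  push <- function(from, to, diag) {
    ok <- live[from] & live[to]
    f <- from[ok]
    t <- to[ok]
    w <- (res[f] + res[t]) / 2 * r$cell_size * if (diag) sqrt(2) else 1
    edges[[length(edges) + 1]] <<- rbind(f, t)
    wts[[length(wts) + 1]] <<- w
  }
  if (nc > 1) push(id[, -nc], id[, -1], FALSE) # east
  if (nr > 1) push(id[-nr, ], id[-1, ], FALSE) # south
  if (nr > 1 && nc > 1) {
    push(id[-nr, -nc], id[-1, -1], TRUE) # southeast
    push(id[-1, -nc], id[-nr, -1], TRUE) # northeast
  }
  list(edges = as.integer(unlist(edges)), weights = unlist(wts), n = nr * nc)
}

#' Least-cost distances among lek locations over a resistance surface
#'
#' Builds an 8-neighbor grid graph over the raster (edge cost = mean of the
#' two cell resistances x cell size, diagonal moves scaled by sqrt(2)), snaps
#' each lek to its containing cell center, and measures pairwise shortest
#' path costs by Dijkstra search.
#'
#' @param resistance a [resistance_raster()].
#' @param points data.frame or matrix with columns x, y (map units), one row
#'   per lek.
#' @param labels lek labels (default: rownames or lek_01, ...).
#' @return A [pairwise_matrix()] of kind `"least_cost"`.
#' @export
least_cost_distances <- function(resistance, points, labels = NULL) {
  stopifnot(inherits(resistance, "resistance_raster"))
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (is.null(labels)) {
    labels <- rownames(points) %||% sprintf("lek_%02d", seq_len(nrow(pts)))
  }
  cells <- vapply(
    seq_len(nrow(pts)),
    function(i) snap_to_cell(resistance, pts[i, 1], pts[i, 2], labels[i]),
    numeric(1)
  )
  ge <- grid_edges(resistance)
  g <- igraph::make_graph(ge$edges, n = ge$n, directed = FALSE)
  d <- igraph::distances(g, v = cells, to = cells, weights = ge$weights,
                         algorithm = "dijkstra")
  pairwise_matrix(d, labels, "least_cost")
}

#' Pairwise geographic distances among leks
#'
#' Planar Euclidean distances for projected coordinates, or great-circle
#' (haversine, mean Earth radius 6371 km) distances in km for
#' longitude/latitude input.
#'
#' @param points matrix or data.frame: columns x, y (projected mode) or
#'   lon, lat in degrees (lonlat mode).
#' @param mode `"projected"` or `"lonlat"`.
#' @param labels lek labels.
#' @return A [pairwise_matrix()] of kind `"geographic"` (km in lonlat mode,
#'   map units otherwise).
#' @export
geographic_distances <- function(points, mode = c("projected", "lonlat"),
                                 labels = NULL) {
  mode <- match.arg(mode)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (any(!is.finite(pts))) stop("missing or non-finite coordinates")
  if (is.null(labels)) {
    labels <- rownames(points) %||% sprintf("lek_%02d", seq_len(nrow(pts)))
  }
  n <- nrow(pts)
  if (mode == "projected") {
    m <- as.matrix(dist(pts))
  } else {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      m[i, (i + 1):n] <- geosphere::distHaversine(
        pts[i, , drop = FALSE], pts[(i + 1):n, , drop = FALSE],
        r = 6371000
      ) / 1000
      m[(i + 1):n, i] <- m[i, (i + 1):n]
    }
  }
  pairwise_matrix(m, labels, "geographic")
}

check_matching_labels <- function(a, b) {
  if (inherits(a, "pairwise_matrix") && inherits(b, "pairwise_matrix") &&
    !identical(a$labels, b$labels)) {
    stop("pairwise matrices have different labels")
  }
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the lower-triangle entries; the null permutes the
#' rows and columns of one matrix simultaneously (preserving its internal
#' dependence structure); upper-tail add-one p-value.
#'
#' @param d1,d2 [pairwise_matrix()] objects (or plain symmetric matrices)
#'   over the same labels.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return List: `r`, `R2`, `test` (a [perm_test_result()]).
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L) {
  check_matching_labels(d1, d2)
  m1 <- if (inherits(d1, "pairwise_matrix")) d1$values else as.matrix(d1)
  m2 <- if (inherits(d2, "pairwise_matrix")) d2$values else as.matrix(d2)
  v1 <- m1[lower.tri(m1)]
  if (sd(v1) == 0 || sd(m2[lower.tri(m2)]) == 0) {
    stop("zero variance among distances; correlation undefined")
  }
  observed <- cor(v1, m2[lower.tri(m2)])
  n <- nrow(m1)
  null_r <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    mp <- m2[p, p]
    cor(v1, mp[lower.tri(mp)])
  }, numeric(1)))
  list(r = observed, R2 = observed^2,
       test = perm_test_result(observed, null_r, tail = "upper"))
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the unfolded response lower triangle on the
#' unfolded predictor triangles (with intercept). Significance of the model
#' R^2 comes from simultaneous row/column permutations of the response
#' matrix, refitting each replicate. With a single predictor the R^2 equals
#' the squared Mantel correlation exactly.
#'
#' @param response a [pairwise_matrix()] (e.g. Nei's D among leks).
#' @param predictors named list of [pairwise_matrix()] objects.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return List: `R2`, `coefficients`, `coefficient_signs`, `test`
#'   (a [perm_test_result()] on R^2, upper tail).
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = 1L) {
  if (!is.list(predictors)) predictors <- list(predictors)
  for (p in predictors) check_matching_labels(response, p)
  ym <- if (inherits(response, "pairwise_matrix")) response$values else as.matrix(response)
  xs <- vapply(predictors, function(p) {
    m <- if (inherits(p, "pairwise_matrix")) p$values else as.matrix(p)
    m[lower.tri(m)]
  }, numeric(sum(lower.tri(ym))))
  xs <- cbind(1, xs)
  pnames <- names(predictors) %||% paste0("predictor", seq_along(predictors))
  if (any(pnames == "")) pnames <- paste0("predictor", seq_along(predictors))
  colnames(xs) <- c("intercept", pnames)
  xtx <- crossprod(xs)
  kappa_x <- kappa(xtx, exact = TRUE)
  if (kappa_x > 1e10) warning("predictor matrices are nearly collinear")
  r2_of <- function(yv) {
    fit <- lm.fit(xs, yv)
    1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
  }
  yv <- ym[lower.tri(ym)]
  fit <- lm.fit(xs, yv)
  observed_r2 <- 1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
  n <- nrow(ym)
  null_r2 <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    yp <- ym[p, p]
    r2_of(yp[lower.tri(yp)])
  }, numeric(1)))
  coefs <- fit$coefficients
  list(
    R2 = observed_r2,
    coefficients = coefs,
    coefficient_signs = sign(coefs[-1]),
    test = perm_test_result(observed_r2, null_r2, tail = "upper")
  )
}
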