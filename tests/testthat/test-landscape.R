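test_that("ESRI ASCII grids round-trip through write and read", {
  r <- simulate_resistance_raster(6, 8, cell_size = 2.5, roughness = 1,
    r_max = 30, origin = c(100, 200), seed = 31
  )
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(r, path)
  r2 <- read_esri_ascii(path)
  expect_equal(r2$values, r$values, tolerance = 1e-6)
  expect_equal(r2$origin, r$origin)
  expect_equal(r2$cell_size, r$cell_size)
})

test_that("suitability inversion is monotone and hits the documented endpoints", {
  s <- matrix(c(0.5, 1, 0.5, 1), 2, 2)
  res <- invert_suitability(s, r_max = 100)
  expect_equal(sort(unique(as.numeric(res$values))), c(1, 100))
  expect_equal(res$values[s == 0.5][1], 100)
  # constant suitability -> constant resistance 1
  flat <- invert_suitability(matrix(0.7, 3, 3), r_max = 100)
  expect_true(all(flat$values == 1))
  # monotone: higher suitability, lower resistance
  s2 <- matrix(seq(0.1, 1, length.out = 9), 3, 3)
  res2 <- invert_suitability(s2, r_max = 50)
  expect_true(all(diff(res2$values[order(s2)]) <= 0))
  expect_error(invert_suitability(matrix(c(0, 0.5), 1, 2)), "positive")
  # complement reading is also monotone decreasing
  res3 <- invert_suitability(s2, r_max = 50, method = "complement")
  expect_true(all(diff(res3$values[order(s2)]) <= 0))
})

test_that("barrier buffering hits cells within radius at the right tier", {
  vals <- matrix(runif(20 * 20, 1, 10), 20, 20)
  r <- resistance_raster(vals, origin = c(0, 0), cell_size = 10)
  lines <- data.frame(x1 = 100, y1 = 0, x2 = 100, y2 = 200) # vertical barrier
  perm <- apply_barriers(r, barrier_set(lines, buffer_radius = 15, "permeable"))
  lowp <- apply_barriers(r, barrier_set(lines, buffer_radius = 15, "low_permeable"))
  rmax <- max(vals)
  hit <- perm$values != r$values | perm$values == rmax
  # permeable never lowers any cell
  expect_true(all(perm$values >= r$values))
  # buffered cells: exactly the 10^4 ratio between tiers
  buffered <- lowp$values != r$values
  expect_true(any(buffered))
  expect_equal(unique(lowp$values[buffered] / perm$values[buffered]), 1e4)
  # empty barrier set is identity
  expect_equal(apply_barriers(r, barrier_set())$values, r$values)
  # unbuffered cells untouched
  expect_equal(perm$values[!buffered], r$values[!buffered])
})

test_that("least-cost distances are exact on uniform rasters and bounded below", {
  r <- resistance_raster(matrix(1, 10, 10), cell_size = 2)
  pts <- rbind(c(1, 1), c(13, 1)) # same row, 6 cells apart
  d <- least_cost_distances(r, pts, c("a", "b"))
  expect_equal(d$values["a", "b"], 6 * 2, tolerance = 1e-12)
  expect_equal(d$kind, "least_cost")
  # lower bound: Euclidean distance times minimum resistance
  for (s in 1:5) {
    rr <- simulate_resistance_raster(12, 12, cell_size = 1, roughness = 1,
      r_max = 20, seed = 40 + s
    )
    p <- rbind(c(0.5, 0.5), c(11.5, 11.5))
    dd <- least_cost_distances(rr, p)$values[1, 2]
    eps <- sqrt(sum((p[2, ] - p[1, ])^2)) * min(rr$values)
    expect_gte(dd, eps - 1e-9)
  }
  expect_error(least_cost_distances(r, rbind(c(-5, 1)), "far"), "outside")
})

test_that("least-cost distances equal the brute-force shortest-path oracle", {
  for (s in 1:6) {
    rr <- simulate_resistance_raster(20, 20, cell_size = 1, roughness = 1,
      r_max = 50, seed = 70 + s
    )
    pts <- rbind(c(2.5, 3.5), c(17.5, 16.5), c(5.5, 15.5))
    d <- least_cost_distances(rr, pts, c("p1", "p2", "p3"))
    src <- 17 + (3 - 1) * 20 # cell containing p1: row 20 - 3 = 17, col 3
    oracle <- bf_least_cost(rr, src)
    cell2 <- 4 + (18 - 1) * 20 # p2: row 20 - 16 = 4, col 18
    cell3 <- 5 + (6 - 1) * 20 # p3: row 20 - 15 = 5, col 6
    expect_equal(d$values["p1", "p2"], oracle[cell2], tolerance = 1e-9)
    expect_equal(d$values["p1", "p3"], oracle[cell3], tolerance = 1e-9)
  }
})

test_that("raising resistance anywhere never shortens a least-cost path", {
  rr <- simulate_resistance_raster(15, 15, cell_size = 1, roughness = 1,
    r_max = 10, seed = 77
  )
  pts <- rbind(c(1.5, 1.5), c(13.5, 13.5))
  d0 <- least_cost_distances(rr, pts)$values[1, 2]
  bumped <- rr
  bumped$values[5:8, 5:8] <- bumped$values[5:8, 5:8] * 3
  d1 <- least_cost_distances(bumped, pts)$values[1, 2]
  expect_gte(d1, d0 - 1e-12)
})

test_that("geographic distances cover both coordinate modes", {
  # 3-4-5 triangle in projected units
  pts <- rbind(c(0, 0), c(3, 0), c(3, 4))
  d <- geographic_distances(pts, mode = "projected", labels = c("o", "a", "b"))
  expect_equal(d$values["o", "b"], 5)
  # one degree of latitude is ~111.2 km
  ll <- rbind(c(-116, 39), c(-116, 40))
  dll <- geographic_distances(ll, mode = "lonlat")
  expect_equal(dll$values[1, 2], 111.2, tolerance = 0.01)
  expect_error(geographic_distances(rbind(c(NA, 1), c(0, 0))), "coordinates")
})

test_that("Mantel test recovers affine dependence and respects relabeling", {
  set.seed(50)
  pts <- matrix(rnorm(20), 10, 2)
  d1 <- pairwise_matrix(as.matrix(dist(pts)), letters[1:10], "geographic")
  d2 <- pairwise_matrix(2 + 3 * d1$values, letters[1:10], "nei_d")
  res <- mantel_test(d1, d2, n_perm = 999, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$test$p_value, 1 / 1000)
  # common relabeling leaves r unchanged
  perm <- sample(10)
  d1p <- pairwise_matrix(d1$values[perm, perm], d1$labels[perm], "geographic")
  d2p <- pairwise_matrix(d2$values[perm, perm], d2$labels[perm], "nei_d")
  expect_equal(mantel_test(d1p, d2p, n_perm = 9, seed = 2)$r, 1, tolerance = 1e-12)
  expect_error(
    mantel_test(d1, pairwise_matrix(d2$values, LETTERS[1:10], "nei_d"), 9),
    "labels"
  )
  expect_error(
    mantel_test(d1, pairwise_matrix(matrix(0, 10, 10), letters[1:10], "nei_d"), 9),
    "zero variance"
  )
})

test_that("single-predictor MRM equals the squared Mantel correlation", {
  set.seed(51)
  pts <- matrix(rnorm(24), 12, 2)
  d1 <- pairwise_matrix(as.matrix(dist(pts)), letters[1:12], "geographic")
  noise <- matrix(rnorm(144, sd = 0.3), 12, 12)
  d2 <- pairwise_matrix(0.5 * d1$values + noise + t(noise), letters[1:12], "nei_d")
  m <- mantel_test(d1, d2, n_perm = 99, seed = 3)
  fit <- mrm(d2, list(distance = d1), n_perm = 99, seed = 3)
  expect_equal(fit$R2, m$R2, tolerance = 1e-12)
  # adding a predictor never decreases in-sample R2
  set.seed(52)
  extra <- pairwise_matrix(as.matrix(dist(matrix(rnorm(24), 12, 2))),
    letters[1:12], "least_cost"
  )
  fit2 <- mrm(d2, list(distance = d1, habitat = extra), n_perm = 99, seed = 4)
  expect_gte(fit2$R2, fit$R2 - 1e-12)
  expect_named(fit2$coefficient_signs, c("distance", "habitat"))
})

test_that("MRM recovers a known isolation-by-distance slope", {
  set.seed(53)
  pts <- matrix(runif(20, 0, 60), 10, 2)
  geo <- pairwise_matrix(as.matrix(dist(pts)), letters[1:10], "geographic")
  eps <- matrix(rnorm(100, sd = 0.15), 10, 10)
  resp <- pairwise_matrix(0.179 + 0.142 * geo$values + eps + t(eps),
    letters[1:10], "nei_d"
  )
  fit <- mrm(resp, list(distance = geo), n_perm = 199, seed = 5)
  slope <- unname(fit$coefficients["distance"])
  # recovered within a loose 2-SE band of the generating slope 0.142
  se <- 0.142 / sqrt(45) * 3
  expect_lt(abs(slope - 0.142), max(2 * se, 0.05))
  expect_lt(fit$test$p_value, 0.05)
})
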