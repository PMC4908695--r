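#' Discriminant analysis of principal components (DAPC)
#'
#' Reduces the dosage matrix to `n_pcs` principal components and fits a
#' linear discriminant analysis on the retained scores, maximizing
#' between-group relative to total variance. Group assignment probabilities
#' come from classification in the discriminant space with equal group
#' priors.
#'
#' @param dosage a `dosage_matrix` or individuals x loci matrix.
#' @param groups group label per individual; every group needs >= 2 members.
#' @param n_pcs number of PCs to retain (<= min(individuals - 1, loci)).
#' @return A `dapc_model` with the retained PC scores, discriminant
#'   functions, individual DF scores, per-individual assignment
#'   probabilities, per-DF eigenvalues, predicted groups, and the observed
#'   reassignment proportions (overall and per group).
#' @export
dapc_fit <- function(dosage, groups, n_pcs) {
  x <- if (inherits(dosage, "dosage_matrix")) dosage$dosage else as.matrix(dosage)
  groups <- factor(groups)
  if (nrow(x) != length(groups)) stop("one group label per individual required")
  if (any(table(groups) < 2)) {
    stop("every group needs at least two members (within-group scatter undefined)")
  }
  n_pcs <- check_count(n_pcs, "n_pcs")
  if (n_pcs > min(nrow(x) - 1, ncol(x))) {
    stop("n_pcs exceeds min(individuals - 1, loci)")
  }
  pca <- run_pca(x, n_axes = n_pcs)
  k <- nlevels(groups)
  fit <- MASS::lda(pca$scores, grouping = groups, prior = rep(1 / k, k))
  pred <- stats::predict(fit, pca$scores)
  structure(
    list(
      n_pcs_retained = n_pcs,
      pc_scores = pca$scores,
      discriminant_functions = fit$scaling,
      df_scores = pred$x,
      assignment_probs = pred$posterior,
      eigenvalues = fit$svd^2,
      group_labels = groups,
      predicted = pred$class,
      reassignment_overall = mean(pred$class == groups),
      reassignment_by_group = vapply(
        levels(groups),
        function(g) mean(pred$class[groups == g] == g),
        numeric(1)
      )
    ),
    class = "dapc_model"
  )
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf(
    "DAPC: %d PCs retained, %d groups, %d DFs; correct reassignment %.1f%%\n",
    x$n_pcs_retained, nlevels(x$group_labels),
    ncol(x$discriminant_functions), 100 * x$reassignment_overall
  ))
  invisible(x)
}

# mean per-group reassignment proportion for a DAPC fit with npc PCs;
# scores are precomputed once, LDA refit per call
dapc_reassignment <- function(scores, groups, npc) {
  k <- nlevels(groups)
  fit <- MASS::lda(scores[, seq_len(npc), drop = FALSE],
    grouping = groups, prior = rep(1 / k, k)
  )
  pred <- stats::predict(fit, scores[, seq_len(npc), drop = FALSE])$class
  mean(vapply(levels(groups), function(g) mean(pred[groups == g] == g), numeric(1)))
}

#' Choose the number of retained PCs by the alpha-score
#'
#' For each candidate PC count, the alpha-score is the observed group-wise
#' mean reassignment proportion minus the reassignment proportion obtained
#' with randomized group labels; randomization is replicated `n_replicates`
#' times with fresh label permutations, penalizing the overfitting that
#' inflates reassignment as more PCs are retained. Returns the candidate
#' maximizing the mean alpha-score, plus the replicate mean and sd at that
#' optimum.
#'
#' @inheritParams dapc_fit
#' @param candidates integer vector of PC counts to evaluate.
#' @param n_replicates randomized replicates per candidate (default 20).
#' @param seed integer seed.
#' @return List: `optimal_n_pcs`, `mean`, `sd` (at the optimum),
#'   `alpha_scores` (candidates x replicates matrix), `candidates`.
#' @export
optimize_a_score <- function(dosage, groups, candidates, n_replicates = 20, seed = 1L) {
  x <- if (inherits(dosage, "dosage_matrix")) dosage$dosage else as.matrix(dosage)
  groups <- factor(groups)
  max_pc <- min(nrow(x) - 1, ncol(x))
  if (any(candidates < 1) || any(candidates > max_pc)) {
    stop("candidate PC counts outside the valid range")
  }
  scores <- run_pca(x, n_axes = max(candidates))$scores
  n <- nrow(x)
  alpha <- with_seed(seed, {
    vapply(candidates, function(npc) {
      obs <- dapc_reassignment(scores, groups, npc)
      vapply(seq_len(n_replicates), function(r) {
        obs - dapc_reassignment(scores, groups[sample.int(n)], npc)
      }, numeric(1))
    }, numeric(n_replicates))
  })
  alpha <- matrix(alpha, nrow = n_replicates) # replicates x candidates
  means <- colMeans(alpha)
  best <- which.max(means)
  list(
    optimal_n_pcs = candidates[best],
    mean = means[best],
    sd = sd(alpha[, best]),
    alpha_scores = t(alpha),
    candidates = candidates
  )
}

#' Infer the number of genetic clusters by K-means and BIC
#'
#' Runs K-means (multiple seeded restarts) on retained PC scores for
#' K = 1..k_max and scores each solution with
#' BIC(K) = n log(WSS_K / n) + K log(n); the most likely K minimizes BIC.
#'
#' @inheritParams dapc_fit
#' @param k_max largest K to consider (>= 2).
#' @param n_pcs_for_kmeans PCs retained before clustering.
#' @param n_start K-means restarts per K.
#' @param seed integer seed.
#' @return List: `bic` (per K), `best_k`, `assignment` (for the best K),
#'   `k` (the K values).
#' @export
find_clusters <- function(dosage, k_max, n_pcs_for_kmeans = 10, n_start = 10, seed = 1L) {
  x <- if (inherits(dosage, "dosage_matrix")) dosage$dosage else as.matrix(dosage)
  k_max <- check_count(k_max, "k_max", 2)
  n_pcs_for_kmeans <- min(n_pcs_for_kmeans, nrow(x) - 1, ncol(x))
  scores <- run_pca(x, n_axes = n_pcs_for_kmeans)$scores
  n <- nrow(scores)
  with_seed(seed, {
    fits <- lapply(seq_len(k_max), function(k) {
      if (k == 1) {
        list(tot.withinss = sum(scale(scores, scale = FALSE)^2),
             cluster = rep(1L, n))
      } else {
        kmeans(scores, centers = k, nstart = n_start, iter.max = 50)
      }
    })
    bic <- vapply(seq_len(k_max), function(k) {
      n * log(fits[[k]]$tot.withinss / n) + k * log(n)
    }, numeric(1))
    best <- which.min(bic)
    list(bic = bic, best_k = best, assignment = fits[[best]]$cluster,
         k = seq_len(k_max))
  })
}
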