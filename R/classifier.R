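# Affinity-blind classification core: within-subject rank vectors ->
# pairwise Spearman dissimilarity -> metric MDS under the squared-stress
# criterion -> stratified 10-fold cross-validated linear SVM ->
# permutation-null significance; multimodal 4-D fusion of two ligands.
#
# The defining property is affinity-blindness: any strictly increasing
# transform of one subject's region vector leaves that subject's ranks, and
# hence every downstream result, exactly unchanged.  This controls for
# between-subject differences in ligand affinity.

#' Between-subject rank dissimilarity
#'
#' Converts each subject's region vector to ranks and computes, for every
#' pair of subjects, `d = 1 - rho` where `rho` is the Spearman rank
#' correlation (average-rank ties).  Values lie in `[0, 2]` with a zero
#' diagonal.
#'
#' @param values a [binding_matrix()] or numeric subjects x regions matrix
#'   (>= 3 subjects, >= 3 regions).
#' @param subset optional subject ids (or row indices) to restrict to.
#' @return object of class `dissimilarity_matrix`: `d` (n x n symmetric),
#'   `subjects` (ids), `groups` (labels if available).
#' @export
rank_dissimilarity <- function(values, subset = NULL) {
  grp <- NULL
  if (inherits(values, "binding_matrix")) {
    if (!is.null(subset)) values <- subset_subjects(values, subset)
    grp <- values$subjects$group
    Y <- values$values
  } else {
    Y <- as.matrix(values)
    if (!is.null(subset)) {
      Y <- Y[subset, , drop = FALSE]
    }
  }
  n <- nrow(Y)
  if (n < 3 || ncol(Y) < 3) stop("need >= 3 subjects and >= 3 regions")
  const <- which(apply(Y, 1, function(r) max(r) == min(r)))
  if (length(const))
    stop("constant region vector (Spearman undefined) for subject(s): ",
         paste(if (is.null(rownames(Y))) const else rownames(Y)[const],
               collapse = ", "))
  rho <- cor(t(Y), method = "spearman")
  d <- 1 - rho
  diag(d) <- 0
  d <- (d + t(d)) / 2
  ids <- rownames(Y)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dimnames(d) <- list(ids, ids)
  structure(list(d = d, subjects = ids, groups = grp),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat("<dissimilarity_matrix>", nrow(x$d), "subjects; d = 1 - Spearman rho",
      sprintf("(range %.3f..%.3f off-diagonal)\n",
              min(x$d[upper.tri(x$d)]), max(x$d[upper.tri(x$d)])))
  invisible(x)
}

sstress_value <- function(X, D2, denom) {
  E <- as.matrix(dist(X))^2 - D2
  sqrt(sum(E[upper.tri(E)]^2) / denom)
}

#' Metric MDS under the squared-stress criterion
#'
#' Finds `k`-dimensional coordinates minimizing the squared metric stress
#' `S = sqrt( sum_(i<j) (delta_ij^2 - d_ij^2)^2 / sum_(i<j) d_ij^4 )`,
#' where `delta` are the embedded Euclidean distances.  Optimization is
#' quasi-Newton (BFGS with analytic gradient) from a classical-scaling
#' start plus seeded random restarts; the best configuration is returned,
#' centred at the origin.
#'
#' @param d a `dissimilarity_matrix` (see [rank_dissimilarity()]) or a
#'   symmetric matrix.
#' @param k embedding dimension (default 2, must be < n).
#' @param n_restarts number of starts (1 classical + the rest random).
#' @param seed RNG seed for the random restarts.
#' @return object of class `mds_embedding`: `coords` (n x k), `stress`
#'   (achieved S, equal to the value recomputed from `coords`),
#'   `n_restarts_used`, `seed`.
#' @export
mds_sstress <- function(d, k = 2, n_restarts = 8, seed = 1L) {
  D <- if (inherits(d, "dissimilarity_matrix")) d$d else as.matrix(d)
  n <- nrow(D)
  if (k >= n) stop("k must be < number of points")
  if (max(abs(D - t(D))) > 1e-8) stop("dissimilarity matrix not symmetric")
  ids <- rownames(D)
  if (all(D[upper.tri(D)] == 0)) {
    warning("all dissimilarities are zero; returning degenerate embedding")
    X <- matrix(0, n, k, dimnames = list(ids, NULL))
    return(structure(list(coords = X, stress = 0, n_restarts_used = 0L,
                          seed = seed), class = "mds_embedding"))
  }
  D2 <- D^2
  denom <- sum(D2[upper.tri(D2)]^2)
  fobj <- function(x) {
    X <- matrix(x, n, k)
    E <- as.matrix(dist(X))^2 - D2
    sum(E[upper.tri(E)]^2)
  }
  gobj <- function(x) {
    X <- matrix(x, n, k)
    E <- as.matrix(dist(X))^2 - D2   # symmetric, zero diagonal
    G <- matrix(0, n, k)
    for (j in seq_len(k)) {
      dx <- outer(X[, j], X[, j], "-")
      G[, j] <- 4 * rowSums(E * dx)
    }
    as.vector(G)
  }
  starts <- list()
  cs <- suppressWarnings(cmdscale(D, k = k))
  if (ncol(cs) < k)
    cs <- cbind(cs, matrix(0, n, k - ncol(cs)))
  starts[[1]] <- as.vector(cs)
  if (n_restarts > 1) {
    set.seed(seed)
    scl <- max(D) / 2
    for (s in seq_len(n_restarts - 1))
      starts[[s + 1]] <- rnorm(n * k, 0, scl)
  }
  best <- NULL
  for (st in starts) {
    op <- optim(st, fobj, gobj, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || op$value < best$value) best <- op
  }
  X <- matrix(best$par, n, k)
  X <- sweep(X, 2, colMeans(X))
  dimnames(X) <- list(ids, NULL)
  structure(list(coords = X, stress = sqrt(best$value / denom),
                 n_restarts_used = length(starts), seed = seed),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d points in %dD, s-stress = %.4g\n",
              nrow(x$coords), ncol(x$coords), x$stress))
  invisible(x)
}

#' Recompute the squared stress of an embedding
#'
#' @param embedding an `mds_embedding`.
#' @param d the dissimilarities it was fitted to.
#' @return the squared metric stress of `embedding$coords` against `d`.
#' @export
sstress_of <- function(embedding, d) {
  D <- if (inherits(d, "dissimilarity_matrix")) d$d else as.matrix(d)
  D2 <- D^2
  denom <- sum(D2[upper.tri(D2)]^2)
  if (denom == 0) return(0)
  sstress_value(embedding$coords, D2, denom)
}

# Stratified fold assignment; guarantees every training set contains both
# classes (refolds with a perturbed seed up to 10 times otherwise).
make_folds <- function(labels, n_folds, seed) {
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    folds <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(labels[folds != f])) == 2, logical(1)))
    if (ok) return(folds)
  }
  stop("could not build folds whose training sets contain both classes")
}

#' Cross-validated linear SVM classification
#'
#' Stratified `n_folds`-fold cross-validation of a linear support vector
#' machine (fixed cost C = 1, no feature scaling) on embedded coordinates;
#' the loss is the pooled misclassification fraction.  Deterministic given
#' the seed.
#'
#' @param coords an `mds_embedding` or numeric n x k coordinate matrix.
#' @param labels two-level factor (or coercible) of group labels.
#' @param n_folds number of folds (default 10; requires `n >= n_folds`).
#' @param seed RNG seed controlling fold assignment.
#' @return object of class `classification_result`: `accuracy`, `loss`,
#'   `fold_assignments`, `n`, `seed` (`null_losses` and `p` are `NA` until
#'   [permutation_test()] fills them).
#' @export
cv_svm_classify <- function(coords, labels, n_folds = 10, seed = 1L) {
  X <- if (inherits(coords, "mds_embedding")) coords$coords
       else as.matrix(coords)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two label values")
  n <- nrow(X)
  if (n < n_folds) stop("need n >= n_folds")
  folds <- make_folds(labels, n_folds, seed)
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (f in seq_len(n_folds)) {
    te <- which(folds == f)
    if (!length(te)) next
    tr <- which(folds != f)
    fit <- e1071::svm(x = X[tr, , drop = FALSE], y = labels[tr],
                      kernel = "linear", cost = 1, scale = FALSE,
                      type = "C-classification")
    pred[te] <- predict(fit, X[te, , drop = FALSE])
  }
  acc <- mean(pred == labels)
  structure(list(accuracy = acc, loss = 1 - acc, null_losses = NULL,
                 p = NA_real_, fold_assignments = folds, n = n,
                 seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> accuracy %.1f%% (n = %d)",
              100 * x$accuracy, x$n))
  if (!is.na(x$p))
    cat(sprintf(", permutation p = %.4g (%d shuffles)", x$p,
                length(x$null_losses)))
  cat("\n")
  invisible(x)
}

#' Permutation-null significance of the classification
#'
#' Repeats the cross-validated SVM on the identical coordinates with
#' shuffled group labels, building a null distribution of losses.  The
#' p-value uses the add-one rule
#' `p = (1 + #\{null loss <= observed loss\}) / (1 + n_perm)`, so it is
#' never exactly zero (best attainable: `1/(n_perm + 1)`).
#'
#' @param coords embedding coordinates (the scaling does not depend on
#'   labels, so it is computed once and reused across shuffles).
#' @param labels two-level labels.
#' @param n_perm number of label shuffles (default 1000; < 100 draws a
#'   warning about coarse p resolution).
#' @param n_folds folds for each CV run.
#' @param seed master seed; per-permutation fold seeds are derived from it.
#' @return `classification_result` with `null_losses` and `p` filled in.
#' @export
permutation_test <- function(coords, labels, n_perm = 1000, n_folds = 10,
                             seed = 1L) {
  if (n_perm < 100)
    warning("n_perm < 100 gives a coarse permutation p-value")
  labels <- factor(labels)
  obs <- cv_svm_classify(coords, labels, n_folds = n_folds, seed = seed)
  null_losses <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + 7919L * b)
    lab_b <- sample(labels)
    null_losses[b] <- cv_svm_classify(coords, lab_b, n_folds = n_folds,
                                      seed = seed + b)$loss
  }
  obs$null_losses <- null_losses
  obs$p <- (1 + sum(null_losses <= obs$loss)) / (1 + n_perm)
  obs
}

rms_standardize <- function(X) {
  r <- sqrt(mean(X^2))
  if (r == 0) X else X / r
}

#' Pairwise affinity-blind classification for a group pair
#'
#' Full pipeline for one pair of diagnostic groups: restrict each ligand's
#' binding matrix to the two groups, compute the Spearman rank
#' dissimilarities, embed in 2-D by squared-stress MDS, classify with the
#' stratified 10-fold CV linear SVM and assess significance by permutation.
#' With `multimodal = TRUE`, subjects scanned with both ligands are
#' additionally classified on the concatenation of the two embeddings
#' (each standardized to unit RMS coordinate scale), i.e. in 4-D.
#'
#' @param values_by_ligand named list of [binding_matrix()] objects, one
#'   per ligand.
#' @param group_a,group_b the two diagnostic groups.
#' @param multimodal also run the combined 4-D classification.
#' @param n_perm permutations for the null distribution.
#' @param n_folds CV folds.
#' @param n_restarts MDS restarts.
#' @param seed master seed for MDS restarts, folds and permutations.
#' @return named list with one `classification_result` per ligand (each
#'   carrying its `embedding` and `dissimilarity`) and, when requested,
#'   `multimodal`.
#' @export
classify_pair <- function(values_by_ligand, group_a, group_b,
                          multimodal = FALSE, n_perm = 1000, n_folds = 10,
                          n_restarts = 8, seed = 1L) {
  if (inherits(values_by_ligand, "binding_matrix"))
    values_by_ligand <- setNames(list(values_by_ligand),
                                 values_by_ligand$ligand)
  out <- list()
  embeddings <- list()
  subj_sets <- list()
  for (lig in names(values_by_ligand)) {
    m <- values_by_ligand[[lig]]
    ids <- m$subjects$subject_id[m$subjects$group %in% c(group_a, group_b)]
    sub <- subset_subjects(m, ids)
    dm <- rank_dissimilarity(sub)
    emb <- mds_sstress(dm, k = 2, n_restarts = n_restarts, seed = seed)
    res <- permutation_test(emb, factor(sub$subjects$group),
                            n_perm = n_perm, n_folds = n_folds,
                            seed = seed)
    res$embedding <- emb
    res$dissimilarity <- dm
    out[[lig]] <- res
    embeddings[[lig]] <- emb
    subj_sets[[lig]] <- ids
  }
  if (multimodal) {
    if (length(values_by_ligand) < 2)
      stop("multimodal classification needs two ligands")
    common <- Reduce(intersect, subj_sets)
    dropped <- length(unique(unlist(subj_sets))) - length(common)
    if (dropped > 0)
      message(dropped, " subject(s) without both ligands dropped from ",
              "multimodal classification")
    if (length(common) < n_folds)
      stop("too few subjects with both ligands for ", n_folds, " folds")
    coords <- do.call(cbind, lapply(names(values_by_ligand), function(lig) {
      m <- subset_subjects(values_by_ligand[[lig]], common)
      emb <- mds_sstress(rank_dissimilarity(m), k = 2,
                         n_restarts = n_restarts, seed = seed)
      rms_standardize(emb$coords)
    }))
    labs <- factor(values_by_ligand[[1]]$subjects$group[
      match(common, values_by_ligand[[1]]$subjects$subject_id)])
    res <- permutation_test(coords, labs, n_perm = n_perm,
                            n_folds = n_folds, seed = seed)
    res$coords <- coords
    out$multimodal <- res
  }
  out
}
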