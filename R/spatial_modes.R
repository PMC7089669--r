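# Principal spatial-mode analysis: covariance PCA of subjects x regions
# binding, scree-elbow (Cattell) component retention, and group tests on
# component expressions.

#' Principal component analysis of regional binding
#'
#' Eigendecomposition of the pooled region covariance after column
#' mean-centring (no scaling; BP_ND shares units across regions).  Loading
#' signs follow the convention that each column's largest-magnitude element
#' is positive.
#'
#' @param values a [binding_matrix()] or numeric subjects x regions matrix
#'   (>= 3 subjects).
#' @return object of class `pca_result`: `loadings` (regions x m,
#'   orthonormal columns), `scores` (subjects x m, centred data times
#'   loadings), `explained_variance_ratio`, `sdev`, `center`, `retained`
#'   (filled by [cattell_retain()], initially `NA`).
#' @export
pca_modes <- function(values) {
  Y <- values_of(values)
  if (nrow(Y) < 3) stop("need at least 3 subjects")
  if (all(apply(Y, 2, var) == 0)) stop("all columns are constant")
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(nrow(Y) - 1, ncol(Y), ncol(pc$rotation)))
  L <- pc$rotation[, keep, drop = FALSE]
  S <- pc$x[, keep, drop = FALSE]
  pc$sdev <- pc$sdev[keep]
  for (j in seq_len(ncol(L))) {       # sign convention
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) {
      L[, j] <- -L[, j]
      S[, j] <- -S[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = L, scores = S,
                 explained_variance_ratio = evr, sdev = pc$sdev,
                 center = pc$center, retained = NA_integer_),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", nrow(x$loadings), "regions,", ncol(x$loadings),
      "components\n  explained variance ratio:",
      paste(sprintf("%.3f", utils::head(x$explained_variance_ratio, 6)),
            collapse = " "),
      if (ncol(x$loadings) > 6) "..." else "", "\n")
  if (!is.na(x$retained)) cat("  retained:", x$retained, "\n")
  invisible(x)
}

#' Scree-elbow (Cattell) component retention
#'
#' Locates the elbow of the scree curve as the maximizer of the second
#' forward difference of the explained-variance ratios; components strictly
#' before the elbow are retained.  Ties are broken toward the smallest
#' retained count, with a warning.  A manual override is honoured
#' unconditionally, since elbow placement is ultimately a judgement call.
#'
#' @param explained_variance_ratio non-increasing numeric vector,
#'   length >= 3.
#' @param override optional integer: retain exactly this many components.
#' @return integer number of retained components (>= 1).
#' @export
cattell_retain <- function(explained_variance_ratio, override = NULL) {
  evr <- as.numeric(explained_variance_ratio)
  if (!is.null(override)) {
    override <- as.integer(override)
    if (override < 1 || override > length(evr))
      stop("override outside 1..", length(evr))
    return(override)
  }
  if (length(evr) < 3) stop("need at least 3 ratios")
  if (any(diff(evr) > 1e-12)) stop("ratios must be non-increasing")
  d2 <- evr[-(1:2)] - 2 * evr[-c(1, length(evr))] +
    evr[-((length(evr) - 1):length(evr))]
  elbow <- which(d2 >= max(d2) - 1e-12)
  if (length(elbow) > 1)
    warning("no unique scree elbow (tied second differences); ",
            "retaining the smallest count")
  max(1L, elbow[1])          # elbow position is elbow[1] + 1; retain m - 1
}

#' Group tests on component expressions
#'
#' Repeated-measures ANOVA with component as the within-subject factor and
#' diagnosis between subjects (reusing [rm_anova()]), plus Welch post hoc
#' t-tests per retained component for each patient group against controls,
#' FDR-corrected over components within each contrast.  With a single
#' retained component the within factor is degenerate and the function
#' falls back to a one-way ANCOVA on that component, with a warning.
#'
#' @param pca a `pca_result` (see [pca_modes()]).
#' @param groups group label per subject.
#' @param m number of retained components; defaults to
#'   `cattell_retain(pca$explained_variance_ratio)`.
#' @param covariates optional per-subject covariate data frame.
#' @param control_group reference group for post hocs.
#' @param alpha flag level for post hoc significance.
#' @return list `anova` (class `rm_anova`), `posthoc` (data frame:
#'   `component`, `group`, `t`, `df`, `p_raw`, `p_fdr`, `sig_fdr`),
#'   `retained`.
#' @export
component_group_tests <- function(pca, groups, m = NULL, covariates = NULL,
                                  control_group = "control",
                                  alpha = 0.05) {
  stopifnot(inherits(pca, "pca_result"))
  groups <- factor(groups)
  if (is.null(m)) m <- cattell_retain(pca$explained_variance_ratio)
  m <- min(m, ncol(pca$scores))
  S <- pca$scores[, seq_len(m), drop = FALSE]
  if (m >= 2) {
    an <- rm_anova(S, groups, covariates)
    an$effect <- sub("^region", "component", an$effect)
  } else {
    warning("single retained component: falling back to one-way ANCOVA")
    dat <- data.frame(score = S[, 1], .group = groups)
    if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
    fit <- lm(score ~ ., data = dat)
    a <- anova(fit)
    an <- data.frame(effect = "diagnosis", F = a[".group", "F value"],
                     df1 = a[".group", "Df"], df2 = a["Residuals", "Df"],
                     epsilon = NA_real_, df1_gg = NA_real_,
                     df2_gg = NA_real_, p = a[".group", "Pr(>F)"])
    class(an) <- c("rm_anova", "data.frame")
  }
  pat_groups <- setdiff(levels(groups), control_group)
  ph <- do.call(rbind, lapply(pat_groups, function(g) {
    rows <- lapply(seq_len(m), function(j) {
      tt <- t.test(S[groups == g, j], S[groups == control_group, j])
      data.frame(component = j, group = g, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_raw = tt$p.value,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    rows$p_fdr <- p.adjust(rows$p_raw, method = "BH")
    rows
  }))
  ph$sig_fdr <- ph$p_fdr < alpha
  list(anova = an, posthoc = ph, retained = m)
}
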