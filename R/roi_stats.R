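# Univariate regional statistics: partial-volume correction, mixed
# region x diagnosis repeated-measures ANOVA with Greenhouse-Geisser
# correction, and per-region Welch post hoc tests with FDR / Bonferroni
# adjustment over regions.

#' Partial-volume correct regional values
#'
#' Divides each regional value by that cell's combined grey + white tissue
#' fraction, compensating for CSF contamination of the regional signal.
#'
#' @param values a [binding_matrix()].
#' @param gm,wm [covariate_matrix()] objects of kinds `gm_fraction` /
#'   `wm_fraction` on the same axes.
#' @return corrected [binding_matrix()].
#' @export
partial_volume_correct <- function(values, gm, wm) {
  v <- values_of(values)
  g <- values_of(gm)
  w <- values_of(wm)
  if (!all(dim(v) == dim(g)) || !all(dim(v) == dim(w)))
    stop("axes of values and tissue fractions do not match")
  tf <- g + w
  bad <- which(tf <= 0 | tf > 1 + 1e-6)
  if (length(bad))
    stop("grey+white fraction outside (0, 1] in cell(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  out <- values
  out$values <- v / tf
  out
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor for a k-level within-subject factor,
#' computed from the double-centred covariance matrix:
#' `eps = tr(Cc)^2 / ((k-1) * tr(Cc %*% Cc))`, equivalently
#' `(sum lambda)^2 / ((k-1) * sum lambda^2)` over its eigenvalues; clipped
#' to `[1/(k-1), 1]`.  Equals 1 under compound symmetry and attains the
#' lower bound for a rank-1 centred covariance.
#'
#' @param cov symmetric positive-semidefinite k x k covariance matrix of
#'   the within-subject measures.
#' @return epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(cov) {
  cov <- as.matrix(cov)
  k <- nrow(cov)
  if (k < 2 || ncol(cov) != k) stop("need a square matrix, k >= 2")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance matrix is not symmetric")
  J <- diag(k) - 1 / k
  cc <- J %*% cov %*% J
  num <- sum(diag(cc))^2
  den <- (k - 1) * sum(cc * cc)   # tr(cc %*% cc) for symmetric cc
  eps <- if (den <= 0) 1 else num / den
  min(1, max(1 / (k - 1), eps))
}

# Orthonormal within-subject contrast matrix (k x k-1), columns spanning
# the space orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1, drop = FALSE]
}

# Type-III hypothesis SSCP for the coefficient rows `idx` of a multivariate
# linear model with design X (sum-to-zero contrasts assumed upstream).
hyp_sscp <- function(B, XtXi, idx) {
  L <- diag(nrow(B))[idx, , drop = FALSE]
  LB <- L %*% B
  t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB
}

#' Mixed region x diagnosis repeated-measures ANOVA
#'
#' Split-plot ANCOVA with region as the k-level within-subject factor,
#' diagnostic group between subjects, and optional numeric/categorical
#' covariates (e.g. age, sex) entered as between-subject regressors on both
#' the subject means and the within-subject contrasts.  All effects that
#' involve the within-subject factor carry Greenhouse-Geisser-corrected
#' degrees of freedom and p-values; covariates are mean-centred so the
#' region main effect is evaluated at the covariate mean.
#'
#' @param values a [binding_matrix()] or numeric subjects x regions matrix.
#' @param groups group label per subject; defaults to the binding matrix's
#'   subject metadata.
#' @param covariates optional data frame of per-subject covariates.
#' @return data frame of class `rm_anova` with one row per effect:
#'   `effect`, `F`, `df1`, `df2`, `epsilon`, `df1_gg`, `df2_gg`, `p`
#'   (epsilon and GG columns are `NA` for purely between-subject effects,
#'   whose `p` is the ordinary F probability).
#' @export
rm_anova <- function(values, groups = NULL, covariates = NULL) {
  Y <- values_of(values)
  if (is.null(groups) && inherits(values, "binding_matrix"))
    groups <- values$subjects$group
  groups <- factor(groups)
  N <- nrow(Y); k <- ncol(Y)
  if (k < 2) stop("need at least 2 within-subject levels")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2))
    stop("every group needs at least 2 subjects (no within-group variance ",
         "otherwise): ", paste(names(which(table(groups) < 2)),
                               collapse = ", "))

  dat <- data.frame(.group = groups)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      if (is.numeric(covariates[[nm]]))
        dat[[nm]] <- covariates[[nm]] - mean(covariates[[nm]])
      else dat[[nm]] <- factor(covariates[[nm]])
    }
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  rhs <- paste(c(".group", setdiff(names(dat), ".group")), collapse = " + ")
  X <- model.matrix(as.formula(paste("~", rhs)), dat)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient between-subject design")
  XtXi <- solve(crossprod(X))
  asgn <- attr(X, "assign")
  term_labels <- attr(terms(as.formula(paste("~", rhs))), "term.labels")
  df_e <- N - p
  if (df_e < 1) stop("no residual degrees of freedom")

  res <- list()
  add_row <- function(effect, F, df1, df2, epsilon = NA_real_) {
    if (is.na(epsilon)) {
      res[[length(res) + 1]] <<- data.frame(
        effect = effect, F = F, df1 = df1, df2 = df2,
        epsilon = NA_real_, df1_gg = NA_real_, df2_gg = NA_real_,
        p = pf(F, df1, df2, lower.tail = FALSE))
    } else {
      res[[length(res) + 1]] <<- data.frame(
        effect = effect, F = F, df1 = df1, df2 = df2, epsilon = epsilon,
        df1_gg = epsilon * df1, df2_gg = epsilon * df2,
        p = pf(F, epsilon * df1, epsilon * df2, lower.tail = FALSE))
    }
  }

  # Between-subject part: subject means.
  m <- rowMeans(Y)
  Bm <- XtXi %*% crossprod(X, m)
  rm <- m - X %*% Bm
  sse_m <- sum(rm^2)
  for (ti in seq_along(term_labels)) {
    idx <- which(asgn == ti)
    H <- hyp_sscp(matrix(Bm, ncol = 1), XtXi, idx)
    eff <- if (term_labels[ti] == ".group") "diagnosis" else term_labels[ti]
    add_row(eff, (H[1, 1] / length(idx)) / (sse_m / df_e),
            length(idx), df_e)
  }

  # Within-subject part: orthonormal region contrasts.
  C <- orthonormal_contrasts(k)
  Z <- Y %*% C
  B <- XtXi %*% crossprod(X, Z)
  E <- crossprod(Z - X %*% B)
  Sigma_e <- E / df_e
  eps <- {  # epsilon in contrast space == double-centred original-space form
    num <- sum(diag(Sigma_e))^2
    den <- (k - 1) * sum(Sigma_e * Sigma_e)
    min(1, max(1 / (k - 1), if (den <= 0) 1 else num / den))
  }
  within_terms <- c(list(region = which(asgn == 0)),
                    setNames(lapply(seq_along(term_labels),
                                    function(ti) which(asgn == ti)),
                             paste0("region:", ifelse(
                               term_labels == ".group", "diagnosis",
                               term_labels))))
  tre <- sum(diag(E))
  for (nm in names(within_terms)) {
    idx <- within_terms[[nm]]
    H <- hyp_sscp(B, XtXi, idx)
    dfh <- length(idx)
    F <- (sum(diag(H)) / (dfh * (k - 1))) / (tre / (df_e * (k - 1)))
    add_row(nm, F, dfh * (k - 1), df_e * (k - 1), epsilon = eps)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (Greenhouse-Geisser corrected where",
      "applicable)\n")
  y <- as.data.frame(x)
  y$F <- signif(y$F, 4); y$p <- signif(y$p, 4)
  for (nm in c("epsilon", "df1_gg", "df2_gg"))
    y[[nm]] <- round(y[[nm]], 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Per-region post hoc group comparison
#'
#' Welch (unequal-variance) two-sample t-test per region for
#' `group_a - group_b`, with Benjamini-Hochberg FDR and Bonferroni
#' adjustment across the regions.  A pooled-variance Student test is
#' available via `var_equal = TRUE`.  Regions with zero variance in both
#' groups are flagged untested (`tested = FALSE`, `NA` statistics).
#'
#' @param values a [binding_matrix()].
#' @param group_a,group_b group labels to compare.
#' @param alpha significance level for the flag columns.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return data frame of class `region_tests`: `region`, `t`, `df`
#'   (fractional for Welch), `p_raw`, `p_fdr`, `p_bonf`, `sig_fdr`,
#'   `sig_bonf`, `tested`.
#' @export
posthoc_region_tests <- function(values, group_a, group_b, alpha = 0.05,
                                 var_equal = FALSE) {
  stopifnot(inherits(values, "binding_matrix"))
  va <- values$values[values$subjects$group == group_a, , drop = FALSE]
  vb <- values$values[values$subjects$group == group_b, , drop = FALSE]
  if (nrow(va) == 0 || nrow(vb) == 0)
    stop("empty group: ", if (nrow(va) == 0) group_a else group_b)
  R <- ncol(values$values)
  t_ <- df_ <- p_ <- rep(NA_real_, R)
  tested <- rep(TRUE, R)
  for (r in seq_len(R)) {
    if (var(va[, r]) == 0 && var(vb[, r]) == 0) {
      tested[r] <- FALSE
      next
    }
    tt <- t.test(va[, r], vb[, r], var.equal = var_equal)
    t_[r] <- unname(tt$statistic)
    df_[r] <- unname(tt$parameter)
    p_[r] <- tt$p.value
  }
  p_fdr <- p_bonf <- rep(NA_real_, R)
  p_fdr[tested] <- p.adjust(p_[tested], method = "BH")
  p_bonf[tested] <- p.adjust(p_[tested], method = "bonferroni")
  out <- data.frame(region = values$regions$name, t = t_, df = df_,
                    p_raw = p_, p_fdr = p_fdr, p_bonf = p_bonf,
                    sig_fdr = !is.na(p_fdr) & p_fdr < alpha,
                    sig_bonf = !is.na(p_bonf) & p_bonf < alpha,
                    tested = tested, stringsAsFactors = FALSE)
  class(out) <- c("region_tests", "data.frame")
  out
}
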