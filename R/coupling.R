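# Between-ligand regional coupling: control-mean adjustment, regional
# atrophy t-scores, Pearson and first-order partial correlations over
# regions, and the lobe-wise ANCOVA robustness check.

#' Subtract the control-mean regional profile
#'
#' Removes the shared non-specific regional baseline (e.g. low temporal /
#' high deep-nuclei signal common to all scans) by subtracting, per region,
#' the mean value over control subjects.
#'
#' @param values a [binding_matrix()] to adjust.
#' @param controls a [binding_matrix()] of control subjects on the same
#'   region axis (may be the same object, to centre controls on
#'   themselves).
#' @return adjusted [binding_matrix()].
#' @export
control_adjust <- function(values, controls) {
  v <- values_of(values)
  cv <- values_of(controls)
  if (ncol(v) != ncol(cv)) stop("region axes do not match")
  if (nrow(cv) == 0) stop("empty control set")
  out <- values
  out$values <- sweep(v, 2, colMeans(cv))
  out
}

#' Regional atrophy t-scores
#'
#' Per-region Welch t statistic comparing a patient group's combined
#' grey+white volumes to controls (patients minus controls); negative
#' values indicate atrophy.
#'
#' @param volumes a [covariate_matrix()] of kind `gmwm_volume`.
#' @param group patient group label.
#' @param control_group control group label (default `"control"`).
#' @return data frame `region`, `t`, `df` of class `atrophy_scores`.
#' @export
atrophy_tscores <- function(volumes, group, control_group = "control") {
  stopifnot(inherits(volumes, "covariate_matrix"))
  if (volumes$kind != "gmwm_volume")
    stop("volumes must be of kind gmwm_volume")
  vp <- volumes$values[volumes$subjects$group == group, , drop = FALSE]
  vc <- volumes$values[volumes$subjects$group == control_group, ,
                       drop = FALSE]
  if (nrow(vp) == 0 || nrow(vc) == 0) stop("empty group")
  R <- ncol(volumes$values)
  t_ <- df_ <- rep(NA_real_, R)
  for (r in seq_len(R)) {
    if (var(vp[, r]) == 0 && var(vc[, r]) == 0) {
      if (mean(vp[, r]) == mean(vc[, r])) { t_[r] <- 0; df_[r] <- NA }
      next
    }
    tt <- t.test(vp[, r], vc[, r])
    t_[r] <- unname(tt$statistic)
    df_[r] <- unname(tt$parameter)
  }
  out <- data.frame(region = volumes$regions$name, t = t_, df = df_,
                    stringsAsFactors = FALSE)
  class(out) <- c("atrophy_scores", "data.frame")
  out
}

#' First-order partial correlation
#'
#' `r(x, y | z)` via the standard recursion
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`; identical (to
#' numerical precision) to correlating the residuals of `x ~ z` and
#' `y ~ z`.
#'
#' @param x,y,z numeric vectors of equal length.
#' @return list `r`, `df` (= n - 3), `p` (two-sided t).
#' @export
partial_cor <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, n >= 4)
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0)
    stop("zero-variance input to partial correlation")
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(-1, min(1, r))
  df <- n - 3
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df,
       p = if (abs(r) >= 1) 0 else 2 * pt(-abs(t), df))
}

#' Between-ligand regional coupling
#'
#' Pearson correlation across regions between the per-region group means of
#' the two ligands (df = R - 2).  When regional atrophy t-scores are
#' supplied, additionally returns the three first-order partial
#' correlations (df = R - 3): ligand-ligand given atrophy, and each
#' ligand-atrophy correlation given the other ligand.
#'
#' @param pk_means,av_means per-region group-mean vectors (equal length,
#'   R >= 4).
#' @param atrophy optional `atrophy_scores` table or numeric t vector.
#' @return data frame of class `coupling_result` with columns `pair`,
#'   `partialled_out`, `r`, `df`, `p`.
#' @export
regional_coupling <- function(pk_means, av_means, atrophy = NULL) {
  x <- as.numeric(pk_means); y <- as.numeric(av_means)
  R <- length(x)
  if (length(y) != R || R < 4) stop("need equal-length vectors, R >= 4")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance regional mean vector")
  ct <- cor.test(x, y)
  rows <- data.frame(pair = "PK~AV", partialled_out = "none",
                     r = unname(ct$estimate), df = R - 2, p = ct$p.value,
                     stringsAsFactors = FALSE)
  if (!is.null(atrophy)) {
    z <- if (is.data.frame(atrophy)) atrophy$t else as.numeric(atrophy)
    if (length(z) != R) stop("atrophy vector length does not match regions")
    pc1 <- partial_cor(x, y, z)
    pc2 <- partial_cor(y, z, x)
    pc3 <- partial_cor(x, z, y)
    rows <- rbind(rows, data.frame(
      pair = c("PK~AV", "AV~atrophy", "PK~atrophy"),
      partialled_out = c("atrophy", "PK", "AV"),
      r = c(pc1$r, pc2$r, pc3$r),
      df = R - 3,
      p = c(pc1$p, pc2$p, pc3$p), stringsAsFactors = FALSE))
  }
  class(rows) <- c("coupling_result", "data.frame")
  rows
}

#' Group-mean regional profile
#'
#' @param values a [binding_matrix()].
#' @param group group label.
#' @return named numeric vector of per-region unweighted means over the
#'   group's subjects.
#' @export
group_region_means <- function(values, group) {
  stopifnot(inherits(values, "binding_matrix"))
  v <- values$values[values$subjects$group == group, , drop = FALSE]
  if (nrow(v) == 0) stop("empty group: ", group)
  colMeans(v)
}

#' Lobe-wise coupling ANCOVA
#'
#' Robustness check that between-ligand coupling is not driven by the
#' shared non-specific regional profile: within one lobe, regress the AV
#' regional group means on the PK regional group means, diagnosis, and
#' their interaction.  The observational unit is the region (within the
#' lobe) per diagnostic group, and effects are Type-III F tests.
#'
#' @param pk,av control-adjusted [binding_matrix()] objects (both ligands,
#'   same region axis).
#' @param lobe lobe label to analyse.
#' @param groups diagnostic groups to stack (default: all non-control
#'   groups present in `pk`).
#' @return data frame `term`, `F`, `df1`, `df2`, `p` of class
#'   `lobe_ancova`.
#' @export
lobe_ancova <- function(pk, av, lobe, groups = NULL) {
  stopifnot(inherits(pk, "binding_matrix"), inherits(av, "binding_matrix"))
  ridx <- which(pk$regions$lobe == lobe)
  if (length(ridx) < 2) stop("lobe '", lobe, "' has fewer than 2 regions")
  if (is.null(groups))
    groups <- setdiff(unique(pk$subjects$group), "control")
  dat <- do.call(rbind, lapply(groups, function(g) {
    data.frame(pk = group_region_means(pk, g)[ridx],
               av = group_region_means(av, g)[ridx],
               group = g, stringsAsFactors = FALSE)
  }))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  if (length(groups) >= 2) {
    dat$group <- factor(dat$group)
    fit <- lm(av ~ pk * group, data = dat)
    a <- car::Anova(fit, type = 3)
    keep <- c("pk", "group", "pk:group")
    out <- data.frame(term = c("PK", "diagnosis", "PK:diagnosis"),
                      F = a[keep, "F value"],
                      df1 = a[keep, "Df"],
                      df2 = a["Residuals", "Df"],
                      p = a[keep, "Pr(>F)"], stringsAsFactors = FALSE)
  } else {
    fit <- lm(av ~ pk, data = dat)
    a <- anova(fit)
    out <- data.frame(term = "PK", F = a["pk", "F value"],
                      df1 = a["pk", "Df"], df2 = a["Residuals", "Df"],
                      p = a["pk", "Pr(>F)"], stringsAsFactors = FALSE)
  }
  class(out) <- c("lobe_ancova", "data.frame")
  out
}
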