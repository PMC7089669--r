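# Seeded synthetic-cohort generator.
#
# Emulates the statistical structure the analyses assume: a shared
# non-specific regional baseline per ligand, group-specific spatial
# pathology modes expressed through a per-subject severity draw, a
# per-subject multiplicative affinity gain, two ligands coupled through one
# shared latent pathology field, atrophy negatively coupled to pathology,
# and CSF contamination rising with pathology.

#' Construct a spatial mode
#'
#' A spatial mode is a unit-norm per-region loading vector; disease groups
#' express weighted combinations of modes (e.g. a temporal-pole mode for
#' semantic-variant-like groups, a frontal mode for behavioural-variant-like
#' groups).
#'
#' @param loading numeric per-region weights; normalised to unit Euclidean
#'   norm.
#' @param name mode label.
#' @return object of class `spatial_mode`.
#' @export
spatial_mode <- function(loading, name = "mode") {
  loading <- as.numeric(loading)
  if (any(!is.finite(loading))) stop("mode loadings must be finite")
  nrm <- sqrt(sum(loading^2))
  if (nrm == 0) stop("mode loading is all-zero")
  structure(list(loading = loading / nrm, name = name),
            class = "spatial_mode")
}

#' Default spatial modes for a parcellation
#'
#' Builds three unit-norm modes from region metadata: a global cortical
#' mode, a temporal-pole-weighted mode and a frontal mode.  A deterministic
#' within-lobe ripple makes the loadings non-constant over the involved
#' regions so that rank-based analyses see genuine spatial structure.
#'
#' @param regions region metadata table.
#' @return named list of [spatial_mode()] objects
#'   (`global`, `temporal`, `frontal`).
#' @export
default_modes <- function(regions) {
  R <- nrow(regions)
  ripple <- function(idx) 1 + 0.3 * sin(seq_along(idx))
  gl <- rep(1, R)
  gl[regions$lobe %in% c("cerebellum", "brainstem")] <- 0.2
  tm <- numeric(R)
  tidx <- which(regions$lobe == "temporal")
  if (length(tidx)) tm[tidx] <- ripple(tidx)
  iidx <- which(regions$lobe == "insula_cingulate")
  if (length(iidx)) tm[iidx] <- 0.3
  fr <- numeric(R)
  fidx <- which(regions$lobe == "frontal")
  if (length(fidx)) fr[fidx] <- ripple(fidx)
  if (length(iidx)) fr[iidx] <- 0.3
  if (!length(tidx)) tm[seq_len(max(1, R %/% 3))] <- 1
  if (!length(fidx)) fr[R - seq_len(max(1, R %/% 3)) + 1] <- 1
  list(global = spatial_mode(gl, "global"),
       temporal = spatial_mode(tm, "temporal"),
       frontal = spatial_mode(fr, "frontal"))
}

# Deterministic non-specific baseline: low in temporal cortex, high in deep
# nuclei, with a fixed per-region ripple so no two regions tie exactly.
default_baseline <- function(regions, scale = 1) {
  base <- c(frontal = 0.20, temporal = 0.06, parietal = 0.18,
            occipital = 0.16, insula_cingulate = 0.22,
            deep_nuclei = 0.35, cerebellum = 0.12, brainstem = 0.25)
  b <- base[regions$lobe] + 0.02 * sin(7 * seq_len(nrow(regions)))
  unname(b * scale)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions of a two-ligand FTD PET cohort:
#' 15 controls, 10 bvFTD, 11 svPPA, 10 nfvPPA; 83 regions; group-specific
#' weights over a global, a temporal-pole and a frontal spatial mode;
#' log-normal per-subject affinity gains; additive Gaussian regional noise;
#' atrophy and CSF fraction coupled to the latent pathology field.
#'
#' @param n_per_group named integer vector of subjects per group; names are
#'   the group labels, `"control"` carries zero mode weights.
#' @param R region count (default 83).
#' @param regions region metadata; defaults to [default_region_table()].
#' @param modes list of [spatial_mode()]; defaults to
#'   [default_modes()].
#' @param group_mode_weights named list: group -> numeric vector of mode
#'   amplitudes (BP_ND units per unit severity), one per mode.
#' @param baseline_profile named list of per-region baseline vectors, one
#'   per ligand.
#' @param ligand_coupling named numeric: slope from the latent pathology
#'   field to each ligand's signal.
#' @param affinity_gain_sd log-scale SD of the per-subject multiplicative
#'   gain.
#' @param noise_sd residual additive SD (BP_ND units).
#' @param gamma_sd SD of the per-subject severity draw (truncated normal,
#'   mean 1, floor 0).
#' @param mode_expression_sd relative SD of per-subject, per-mode
#'   independent expression variability: each subject's amplitude on mode
#'   m is `w[g, m] * gamma_i + N(0, mode_expression_sd * w[g, m])`, so
#'   individuals within a group vary independently in how strongly each
#'   spatial mode is expressed (controls, with zero weights, stay clean).
#' @param atrophy_slope fractional volume loss per unit pathology.
#' @param csf_slope rise in regional CSF fraction per unit pathology.
#' @param spatial_noise_corr optional AR(1)-style correlation of the
#'   regional noise along the region ordering (0 = i.i.d., default).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = c(control = 15, bvFTD = 10,
                                             svPPA = 11, nfvPPA = 10),
                             R = 83,
                             regions = default_region_table(R),
                             modes = default_modes(regions),
                             group_mode_weights = NULL,
                             baseline_profile = NULL,
                             ligand_coupling = c(PK = 1, AV = 1),
                             affinity_gain_sd = 0.2,
                             noise_sd = 0.05,
                             gamma_sd = 0.3,
                             mode_expression_sd = 0.3,
                             atrophy_slope = 0.15,
                             csf_slope = 0.1,
                             spatial_noise_corr = 0,
                             seed = 1L) {
  if (nrow(regions) != R) stop("regions table does not have R rows")
  if (is.null(group_mode_weights)) {
    z <- setNames(numeric(length(modes)), names(modes))
    w <- function(...) {
      v <- z; a <- c(...); v[names(a)] <- a; v
    }
    group_mode_weights <- list(
      control = z,
      bvFTD = w(global = 0.10, temporal = 0.15, frontal = 0.90),
      svPPA = w(global = 0.08, temporal = 1.10, frontal = 0.06),
      nfvPPA = w(global = 0.08, temporal = 0.05, frontal = 0.85))
    group_mode_weights <-
      group_mode_weights[intersect(names(group_mode_weights),
                                   names(n_per_group))]
  }
  miss <- setdiff(names(n_per_group), names(group_mode_weights))
  if (length(miss))
    stop("group(s) absent from group_mode_weights: ",
         paste(miss, collapse = ", "))
  group_mode_weights <- lapply(group_mode_weights, function(w) {
    if (length(w) != length(modes))
      stop("each group's mode weights must have one entry per mode")
    if (!is.null(names(w)) && !is.null(names(modes))) {
      if (!setequal(names(w), names(modes)))
        stop("mode-weight names do not match mode names")
      w <- w[names(modes)]
    }
    as.numeric(w)
  })
  if (is.null(baseline_profile))
    baseline_profile <- list(PK = default_baseline(regions, 1),
                             AV = default_baseline(regions, 1.3))
  stopifnot(affinity_gain_sd >= 0, noise_sd >= 0, gamma_sd >= 0,
            mode_expression_sd >= 0)
  structure(list(n_per_group = n_per_group, R = R, regions = regions,
                 modes = modes, group_mode_weights = group_mode_weights,
                 baseline_profile = baseline_profile,
                 ligand_coupling = ligand_coupling,
                 affinity_gain_sd = affinity_gain_sd, noise_sd = noise_sd,
                 gamma_sd = gamma_sd,
                 mode_expression_sd = mode_expression_sd,
                 atrophy_slope = atrophy_slope,
                 csf_slope = csf_slope,
                 spatial_noise_corr = spatial_noise_corr, seed = seed),
            class = "synthetic_config")
}

#' Load a synthetic-cohort configuration from YAML
#'
#' Scalar fields map directly onto [synthetic_config()] arguments;
#' `group_mode_weights` is a mapping group -> list of mode amplitudes.
#'
#' @param path YAML file.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$n_per_group)) args$n_per_group <- unlist(y$n_per_group)
  for (f in c("R", "affinity_gain_sd", "noise_sd", "gamma_sd",
              "mode_expression_sd", "atrophy_slope", "csf_slope",
              "spatial_noise_corr", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$ligand_coupling)) args$ligand_coupling <-
      unlist(y$ligand_coupling)
  if (!is.null(y$group_mode_weights))
    args$group_mode_weights <- lapply(y$group_mode_weights, unlist)
  do.call(synthetic_config, args)
}

# Demographic emulation: group-specific mean ages and sex ratios similar to
# published FTD PET cohorts.
group_age_mean <- c(control = 68, bvFTD = 60, svPPA = 68, nfvPPA = 71)
group_male_frac <- c(control = 0.5, bvFTD = 0.5, svPPA = 0.8, nfvPPA = 0.3)

#' Generate a synthetic two-ligand cohort
#'
#' The latent pathology field for subject i is
#' `s[i, ] = gamma_i * sum_m w[g(i), m] * mode_m`, with `gamma_i` a
#' nonnegative severity draw; both ligands share this field (their coupling
#' is the planted truth).  The observed ligand value is
#' `a_i * (baseline_r + beta_L * s[i, r]) + eps`, with
#' `a_i = exp(N(0, affinity_gain_sd))` a per-subject affinity gain.
#' Regional volume falls and CSF fraction rises with pathology.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `binding` (list of [binding_matrix()] per
#'   ligand), `covariates` (list of [covariate_matrix()]: gm, wm, csf,
#'   volume), `subjects`, `truth` (latent field `s`, severities, affinity
#'   gains, modes, weights).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  N <- length(groups)
  R <- cfg$R
  age_mu <- ifelse(groups %in% names(group_age_mean),
                   group_age_mean[groups], 67)
  male_p <- ifelse(groups %in% names(group_male_frac),
                   group_male_frac[groups], 0.5)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(N)),
    group = groups,
    age = round(pmax(40, rnorm(N, age_mu, 7)), 1),
    sex = ifelse(runif(N) < male_p, "M", "F"),
    stringsAsFactors = FALSE)
  subjects$scans_available <- paste(names(cfg$ligand_coupling),
                                    collapse = "+")

  gamma <- pmax(0, rnorm(N, 1, cfg$gamma_sd))
  M <- vapply(cfg$modes, function(m) m$loading, numeric(R))  # R x n_modes
  W <- do.call(rbind, cfg$group_mode_weights[groups])        # N x n_modes
  expr <- W * gamma                                          # amplitudes
  if (cfg$mode_expression_sd > 0)
    expr <- expr + matrix(
      rnorm(length(W), 0, as.vector(cfg$mode_expression_sd * W)),
      nrow(W), ncol(W))
  s <- expr %*% t(M)                                         # N x R

  a <- exp(rnorm(N, 0, cfg$affinity_gain_sd))
  noise_draw <- function() {
    e <- matrix(rnorm(N * R, 0, cfg$noise_sd), N, R)
    rho <- cfg$spatial_noise_corr
    if (rho > 0 && R > 1) {       # AR(1) smoothing along the region order
      for (r in 2:R) e[, r] <- rho * e[, r - 1] +
          sqrt(1 - rho^2) * e[, r]
    }
    e
  }
  binding <- list()
  for (lig in names(cfg$ligand_coupling)) {
    base <- cfg$baseline_profile[[lig]]
    v <- a * (matrix(base, N, R, byrow = TRUE) +
                cfg$ligand_coupling[[lig]] * s) + noise_draw()
    binding[[lig]] <- binding_matrix(v, cfg$regions, subjects, ligand = lig)
  }

  v0 <- 6 + 4 * sin(3 * seq_len(R))^2          # region base volumes, cm^3
  vol_noise <- matrix(rnorm(N * R, 0, 0.02), N, R)
  vol <- matrix(v0, N, R, byrow = TRUE) *
    pmax(0.1, 1 - cfg$atrophy_slope * s) * (1 + vol_noise)
  csf0 <- 0.12
  csf <- csf0 + cfg$csf_slope * s + matrix(rnorm(N * R, 0, 0.01), N, R)
  csf <- pmin(pmax(csf, 0), 0.9)
  gm <- (1 - csf) * 0.55
  wm <- (1 - csf) * 0.45
  covs <- list(
    gm = covariate_matrix(gm, cfg$regions, subjects, "gm_fraction"),
    wm = covariate_matrix(wm, cfg$regions, subjects, "wm_fraction"),
    csf = covariate_matrix(csf, cfg$regions, subjects, "csf_fraction"),
    volume = covariate_matrix(vol, cfg$regions, subjects, "gmwm_volume"))

  list(binding = binding, covariates = covs, subjects = subjects,
       truth = list(s = s, gamma = gamma, affinity = a, modes = cfg$modes,
                    weights = W, expression = expr))
}

#' Apply per-subject monotone transforms to a binding matrix
#'
#' Transform hook used by the affinity-blindness invariance tests: a
#' strictly increasing map applied to one subject's region vector changes
#' its values but not its within-subject ranks, so every rank-based
#' downstream result must be unchanged.
#'
#' @param m a [binding_matrix()].
#' @param fns a single function or a list of one function per subject.
#' @return transformed `binding_matrix`.
#' @export
transform_subject_rows <- function(m, fns) {
  v <- values_of(m)
  if (is.function(fns)) fns <- rep(list(fns), nrow(v))
  if (length(fns) != nrow(v))
    stop("need one transform per subject (or a single function)")
  for (i in seq_len(nrow(v))) v[i, ] <- fns[[i]](v[i, ])
  m$values <- v
  m
}
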