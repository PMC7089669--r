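# End-to-end orchestration: run every analysis stage on a generated (or
# loaded) cohort, writing per-stage CSV/JSON outputs plus a run manifest.
# Outputs are deterministic given the master seed: the manifest carries the
# seed and a config hash but no timestamps, so identical runs are
# byte-identical.

# Small stable FNV-1a hash of a canonical JSON serialization; good enough
# for manifest provenance, not cryptographic.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

stage_log <- function(verbose, ...) if (verbose) message("[copath] ", ...)

#' Run the full analysis pipeline
#'
#' Generates a synthetic cohort (or accepts one already built), then runs
#' the selected stages in dependency order: per-ligand regional
#' repeated-measures ANOVA and post hoc maps (`roi`), between-ligand
#' coupling with atrophy partialling and lobe-wise ANCOVA (`coupling`),
#' principal spatial modes with scree retention and group tests (`modes`),
#' pairwise affinity-blind classification (`classify`), and stereological
#' histology quantification (`histo`).  Per-stage tables are written under
#' `out_dir` along with `manifest.json` recording the seed, package
#' version and a config hash.
#'
#' @param config a [synthetic_config()], a path to its YAML form, or a
#'   pre-generated cohort list from [generate_cohort()].
#' @param out_dir output directory (`NULL` to skip writing files).
#' @param stages character subset of
#'   `c("roi", "coupling", "modes", "classify", "histo")`.
#' @param n_perm permutations for each classification.
#' @param classify_pairs list of 2-vectors of group labels to classify;
#'   defaults to all patient-group pairs.
#' @param seed master seed; overrides the config's seed if given.
#' @param verbose emit per-stage progress messages.
#' @return list with the cohort and one element per executed stage.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = NULL,
                         stages = c("roi", "coupling", "modes",
                                    "classify", "histo"),
                         n_perm = 200, classify_pairs = NULL, seed = NULL,
                         verbose = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(config)) config <- read_synthetic_config(config)
  if (inherits(config, "synthetic_config")) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    stage_log(verbose, "generating cohort (seed ", config$seed, ")")
    cohort <- generate_cohort(config)
    cfg_echo <- config[setdiff(names(config), c("regions", "modes"))]
    master_seed <- config$seed
  } else {
    cohort <- config
    cfg_echo <- list(note = "pre-generated cohort")
    master_seed <- if (is.null(seed)) 1L else as.integer(seed)
  }
  ligands <- names(cohort$binding)
  groups <- cohort$subjects$group
  pat <- setdiff(unique(groups), "control")
  out <- list(cohort = cohort, seed = master_seed)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) if (!is.null(out_dir))
    write.csv(x, file.path(out_dir, name), row.names = FALSE)

  covs <- data.frame(age = cohort$subjects$age,
                     sex = cohort$subjects$sex)

  if ("roi" %in% stages) {
    stage_log(verbose, "stage roi: repeated-measures ANOVA + post hocs")
    roi <- list()
    for (lig in ligands) {
      an <- rm_anova(cohort$binding[[lig]], covariates = covs)
      ph <- do.call(rbind, lapply(pat, function(g) {
        cbind(group = g,
              posthoc_region_tests(cohort$binding[[lig]], g, "control"))
      }))
      roi[[lig]] <- list(anova = an, posthoc = ph)
      wcsv(an, paste0("roi_anova_", lig, ".csv"))
      wcsv(ph, paste0("roi_posthoc_", lig, ".csv"))
    }
    out$roi <- roi
  }

  if ("coupling" %in% stages && length(ligands) >= 2) {
    stage_log(verbose, "stage coupling: between-ligand correlations")
    l1 <- ligands[1]; l2 <- ligands[2]
    ctrl1 <- subset_subjects(cohort$binding[[l1]],
                             group_subjects(cohort$binding[[l1]],
                                            "control"))
    ctrl2 <- subset_subjects(cohort$binding[[l2]],
                             group_subjects(cohort$binding[[l2]],
                                            "control"))
    adj1 <- control_adjust(cohort$binding[[l1]], ctrl1)
    adj2 <- control_adjust(cohort$binding[[l2]], ctrl2)
    rows <- do.call(rbind, lapply(pat, function(g) {
      atr <- atrophy_tscores(cohort$covariates$volume, g)
      raw <- regional_coupling(group_region_means(cohort$binding[[l1]], g),
                               group_region_means(cohort$binding[[l2]], g))
      adj <- regional_coupling(group_region_means(adj1, g),
                               group_region_means(adj2, g),
                               atrophy = atr)
      rbind(cbind(group = g, adjusted = FALSE, raw),
            cbind(group = g, adjusted = TRUE, adj))
    }))
    lobes <- intersect(VALID_LOBES, unique(cohort$binding[[l1]]$regions$lobe))
    lobe_tab <- do.call(rbind, lapply(lobes, function(lb) {
      tb <- try(lobe_ancova(adj1, adj2, lb, groups = pat), silent = TRUE)
      if (inherits(tb, "try-error")) NULL else cbind(lobe = lb, tb)
    }))
    out$coupling <- list(correlations = rows, lobes = lobe_tab,
                         adjusted = list(adj1, adj2))
    wcsv(rows, "coupling_correlations.csv")
    wcsv(lobe_tab, "coupling_lobe_ancova.csv")
  }

  if ("modes" %in% stages) {
    stage_log(verbose, "stage modes: principal spatial modes")
    modes <- list()
    for (lig in ligands) {
      pc <- pca_modes(cohort$binding[[lig]])
      m <- cattell_retain(pc$explained_variance_ratio)
      pc$retained <- m
      tests <- component_group_tests(pc, groups, m = m, covariates = covs)
      modes[[lig]] <- list(pca = pc, retained = m, tests = tests)
      wcsv(data.frame(region = cohort$binding[[lig]]$regions$name,
                      pc$loadings[, seq_len(m), drop = FALSE]),
           paste0("modes_loadings_", lig, ".csv"))
      wcsv(tests$posthoc, paste0("modes_posthoc_", lig, ".csv"))
    }
    out$modes <- modes
  }

  if ("classify" %in% stages) {
    stage_log(verbose, "stage classify: affinity-blind CV-SVM")
    if (is.null(classify_pairs))
      classify_pairs <- utils::combn(pat, 2, simplify = FALSE)
    cls <- list()
    for (pr in classify_pairs) {
      key <- paste(pr, collapse = "_vs_")
      stage_log(verbose, "  ", key)
      cls[[key]] <- classify_pair(cohort$binding, pr[1], pr[2],
                                  multimodal = length(ligands) >= 2,
                                  n_perm = n_perm, seed = master_seed)
    }
    summ <- do.call(rbind, lapply(names(cls), function(key) {
      do.call(rbind, lapply(names(cls[[key]]), function(lig) {
        r <- cls[[key]][[lig]]
        data.frame(pair = key, input = lig, accuracy = r$accuracy,
                   p = r$p, stringsAsFactors = FALSE)
      }))
    }))
    out$classify <- cls
    out$classify_summary <- summ
    wcsv(summ, "classification_summary.csv")
  }

  if ("histo" %in% stages) {
    stage_log(verbose, "stage histo: stereological quantification")
    histo <- histology_study(seed = master_seed)
    out$histo <- histo
    wcsv(histo$samples, "histo_densities.csv")
    wcsv(as.data.frame(histo$glm_total), "histo_glm_total.csv")
  }

  if (!is.null(out_dir)) {
    manifest <- list(package = "copath",
                     version = as.character(utils::packageVersion("copath")),
                     seed = master_seed,
                     stages = stages,
                     n_perm = n_perm,
                     config = cfg_echo,
                     config_hash = config_hash(cfg_echo))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Simulated post-mortem density study
#'
#' Generates a multi-subject, multi-region histology study with a planted
#' pathology -> amoeboid-microglia coupling, counts densities
#' stereologically, and fits the three companion generalized linear models
#' (total, amoeboid-only, ramified-only microglial density).
#'
#' @param n_per_diagnosis subjects per diagnostic group.
#' @param diagnoses diagnostic group labels.
#' @param region_base named base pathology intensities per region
#'   (per mm^2).
#' @param beta planted amoeboid-microglia slope on pathology intensity.
#' @param alpha amoeboid intercept (per mm^2).
#' @param gamma_sd log-scale SD of the per-subject severity multiplier.
#' @param pitch_um,fov_um stereological grid parameters.
#' @param section_mm section dimensions.
#' @param amoeboid_noise_sd between-sample biological variability of
#'   amoeboid intensity.
#' @param seed RNG seed.
#' @return list: `samples` (per-sample density table), `glm_total`,
#'   `glm_amoeboid`, `glm_ramified`, `correlation` (nuclei-partialled),
#'   `beta`.
#' @export
histology_study <- function(n_per_diagnosis = 3,
                            diagnoses = c("FTLD_TDP_A", "FTLD_TDP_C",
                                          "FTLD_Picks", "AD"),
                            region_base = c(prefrontal = 120,
                                            temporal = 240,
                                            parietal = 80,
                                            occipital = 40),
                            beta = 0.5, alpha = 20, gamma_sd = 0.3,
                            pitch_um = 250, fov_um = 125,
                            section_mm = c(10, 10),
                            amoeboid_noise_sd = 8, seed = 1L) {
  set.seed(seed)
  rows <- list()
  sid <- 0
  for (dg in diagnoses) {
    for (s in seq_len(n_per_diagnosis)) {
      sid <- sid + 1
      gam <- exp(rnorm(1, 0, gamma_sd))
      for (rg in names(region_base)) {
        lam <- region_base[[rg]] * gam
        sec_seed <- seed + 1000L * sid +
          match(rg, names(region_base))
        sec <- generate_section(lam, alpha = alpha, beta = beta,
                                ramified_intensity = 30,
                                nuclei_intensity = 300,
                                amoeboid_noise_sd = amoeboid_noise_sd,
                                section_mm = section_mm, seed = sec_seed)
        fovs <- place_fields(sec, pitch_um = pitch_um, fov_um = fov_um,
                             seed = sec_seed + 1L)
        dt <- count_fields(sec, fovs)
        dens <- setNames(dt$density_per_mm2, dt$class)
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("case%02d", sid), region = rg,
          diagnosis = dg,
          pathology_density = dens[["inclusion"]],
          amoeboid_density = dens[["amoeboid_microglia"]],
          ramified_density = dens[["ramified_microglia"]],
          microglia_density = dens[["amoeboid_microglia"]] +
            dens[["ramified_microglia"]],
          nuclei_density = dens[["nucleus"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, rows)
  list(samples = samples,
       glm_total = pathology_microglia_glm(samples, "microglia_density"),
       glm_amoeboid = pathology_microglia_glm(samples,
                                              "amoeboid_density"),
       glm_ramified = pathology_microglia_glm(samples,
                                              "ramified_density"),
       correlation = partial_density_correlation(
         samples$pathology_density, samples$microglia_density,
         samples$nuclei_density),
       beta = beta)
}
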