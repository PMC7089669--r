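# Stereological quantification of section point patterns: systematic
# uniform random field placement on a virtual grid, classed counting,
# density estimation per mm^2, nuclei-partialled correlations, and the
# pathology -> microglia generalized linear model with subjects nested
# within diagnostic group.

HISTO_CLASSES <- c("inclusion", "amoeboid_microglia", "ramified_microglia",
                   "macrophage", "nucleus")

#' Construct a section point pattern
#'
#' A planar point pattern of classed objects (protein-aggregate inclusions,
#' amoeboid/ramified microglia, macrophages, cell nuclei) within a
#' rectangular section outline, with an optional rectangular grey-matter
#' mask restricting where counting fields may be placed.
#'
#' @param points data frame with columns `x_um`, `y_um`, `class` (class
#'   drawn from the fixed vocabulary).
#' @param width_um,height_um section outline dimensions in micrometres.
#' @param grey_mask `NULL` (whole outline is grey matter) or
#'   `c(x0, y0, x1, y1)` in micrometres.
#' @return object of class `section_pattern`.
#' @export
section_pattern <- function(points, width_um, height_um,
                            grey_mask = NULL) {
  if (width_um <= 0 || height_um <= 0)
    stop("section dimensions must be positive")
  points <- as.data.frame(points)
  if (nrow(points)) {
    stopifnot(all(c("x_um", "y_um", "class") %in% names(points)))
    bad <- setdiff(unique(points$class), HISTO_CLASSES)
    if (length(bad)) stop("unknown point class(es): ",
                          paste(bad, collapse = ", "))
    inside <- points$x_um >= 0 & points$x_um <= width_um &
      points$y_um >= 0 & points$y_um <= height_um
    if (!all(inside)) stop("point(s) outside the section outline")
  } else {
    points <- data.frame(x_um = numeric(), y_um = numeric(),
                         class = character())
  }
  if (!is.null(grey_mask)) stopifnot(length(grey_mask) == 4)
  structure(list(points = points, width_um = width_um,
                 height_um = height_um, grey_mask = grey_mask),
            class = "section_pattern")
}

#' @export
print.section_pattern <- function(x, ...) {
  cat(sprintf("<section_pattern> %.1f x %.1f mm, %d points\n",
              x$width_um / 1000, x$height_um / 1000, nrow(x$points)))
  if (nrow(x$points)) print(table(x$points$class))
  invisible(x)
}

#' Generate a synthetic immunostained section
#'
#' Homogeneous Poisson point processes over the section: pathology
#' inclusions at `pathology_intensity`; amoeboid microglia at
#' `alpha + beta * pathology_intensity` (plus optional Gaussian
#' between-sample variability, truncated at zero) so that only the
#' amoeboid compartment tracks pathology; ramified microglia, macrophages
#' and cell nuclei at constant intensities.
#'
#' @param pathology_intensity inclusions per mm^2 (>= 0).
#' @param alpha,beta intercept and slope (per mm^2) coupling amoeboid
#'   microglial intensity to pathology intensity; `beta = 0` decouples
#'   them.
#' @param ramified_intensity,nuclei_intensity,macrophage_intensity
#'   constant intensities per mm^2.
#' @param amoeboid_noise_sd SD of between-sample biological variability
#'   added to the amoeboid intensity (per mm^2).
#' @param section_mm `c(width, height)` of the section in millimetres.
#' @param grey_mask optional mask rectangle in micrometres.
#' @param seed RNG seed.
#' @return a [section_pattern()].
#' @export
generate_section <- function(pathology_intensity, alpha = 20, beta = 0.5,
                             ramified_intensity = 30,
                             nuclei_intensity = 300,
                             macrophage_intensity = 2,
                             amoeboid_noise_sd = 0,
                             section_mm = c(10, 10), grey_mask = NULL,
                             seed = 1L) {
  stopifnot(pathology_intensity >= 0, ramified_intensity >= 0,
            nuclei_intensity >= 0, macrophage_intensity >= 0)
  if (any(section_mm <= 0)) stop("section dimensions must be positive")
  set.seed(seed)
  w <- section_mm[1] * 1000
  h <- section_mm[2] * 1000
  area <- prod(section_mm)
  am_int <- max(0, alpha + beta * pathology_intensity +
                  if (amoeboid_noise_sd > 0)
                    rnorm(1, 0, amoeboid_noise_sd) else 0)
  scatter <- function(intensity, cls) {
    n <- rpois(1, intensity * area)
    if (n == 0) return(NULL)
    data.frame(x_um = runif(n, 0, w), y_um = runif(n, 0, h), class = cls,
               stringsAsFactors = FALSE)
  }
  pts <- do.call(rbind, Filter(Negate(is.null), list(
    scatter(pathology_intensity, "inclusion"),
    scatter(am_int, "amoeboid_microglia"),
    scatter(ramified_intensity, "ramified_microglia"),
    scatter(macrophage_intensity, "macrophage"),
    scatter(nuclei_intensity, "nucleus"))))
  if (is.null(pts)) pts <- data.frame(x_um = numeric(), y_um = numeric(),
                                      class = character())
  section_pattern(pts, w, h, grey_mask = grey_mask)
}

#' Place counting fields on a systematic uniform random grid
#'
#' Superimposes a virtual grid of pitch `pitch_um` with a uniformly random
#' origin in `[0, pitch)^2`; square fields of view of side `fov_um` are
#' centred at the grid intersections, retained only where the intersection
#' falls within the grey-matter mask.  Fields straddling the section
#' outline are discarded (a frame partly outside the tissue would sample
#' empty space and bias the density estimate downward).
#'
#' @param section a [section_pattern()].
#' @param pitch_um grid line spacing (default 1875 um).
#' @param fov_um field-of-view side (default 125 um); must be < pitch.
#' @param seed RNG seed for the grid origin.
#' @return data frame of FOVs: `x0_um`, `y0_um` (lower-left corner),
#'   `cx_um`, `cy_um` (the grid intersection), `fov_um`.  Zero rows (with
#'   a warning) if the section admits no intersection.
#' @export
place_fields <- function(section, pitch_um = 1875, fov_um = 125,
                         seed = 1L) {
  stopifnot(inherits(section, "section_pattern"))
  if (!(pitch_um > fov_um && fov_um > 0))
    stop("need pitch > fov > 0")
  set.seed(seed)
  ox <- runif(1, 0, pitch_um)
  oy <- runif(1, 0, pitch_um)
  cx <- if (ox <= section$width_um)
    seq(ox, section$width_um, by = pitch_um) else numeric(0)
  cy <- if (oy <= section$height_um)
    seq(oy, section$height_um, by = pitch_um) else numeric(0)
  if (!length(cx) || !length(cy)) {
    warning("section smaller than one grid pitch; no fields placed")
    return(data.frame(x0_um = numeric(), y0_um = numeric(),
                      cx_um = numeric(), cy_um = numeric(),
                      fov_um = numeric()))
  }
  half <- fov_um / 2
  cx <- cx[cx >= half & cx <= section$width_um - half]
  cy <- cy[cy >= half & cy <= section$height_um - half]
  if (!length(cx) || !length(cy)) {
    warning("no field of view fits fully inside the section")
    return(data.frame(x0_um = numeric(), y0_um = numeric(),
                      cx_um = numeric(), cy_um = numeric(),
                      fov_um = numeric()))
  }
  g <- expand.grid(cx_um = cx, cy_um = cy)
  if (!is.null(section$grey_mask)) {
    m <- section$grey_mask
    keep <- g$cx_um >= m[1] & g$cx_um <= m[3] &
      g$cy_um >= m[2] & g$cy_um <= m[4]
    g <- g[keep, , drop = FALSE]
  }
  if (!nrow(g)) {
    warning("grey-matter mask excludes every grid intersection")
    return(data.frame(x0_um = numeric(), y0_um = numeric(),
                      cx_um = numeric(), cy_um = numeric(),
                      fov_um = numeric()))
  }
  data.frame(x0_um = g$cx_um - fov_um / 2, y0_um = g$cy_um - fov_um / 2,
             cx_um = g$cx_um, cy_um = g$cy_um, fov_um = fov_um,
             row.names = NULL)
}

#' Count classed objects within the placed fields
#'
#' Tallies each object class over the union of fields of view.  Field
#' membership is half-open (`[x0, x0 + fov)` in each axis) so a point on a
#' shared boundary is counted exactly once.  Density is count divided by
#' the total sampled area, expressed per square millimetre; the sampled
#' area is the number of fields times `fov^2`.
#'
#' @param section a [section_pattern()].
#' @param fovs field table from [place_fields()].
#' @return data frame of class `density_table`: `class`, `count`,
#'   `area_mm2`, `density_per_mm2`, one row per vocabulary class.
#' @export
count_fields <- function(section, fovs) {
  stopifnot(inherits(section, "section_pattern"))
  fov <- if (nrow(fovs)) fovs$fov_um[1] else 0
  area_mm2 <- nrow(fovs) * (fov / 1000)^2
  counts <- setNames(integer(length(HISTO_CLASSES)), HISTO_CLASSES)
  pts <- section$points
  if (nrow(pts) && nrow(fovs)) {
    # Fields never overlap (pitch > fov), so each point lies in at most
    # one: locate the candidate field per axis by interval search, then
    # require the (x, y) candidate pair to be a placed field.
    xs <- sort(unique(fovs$x0_um))
    ys <- sort(unique(fovs$y0_um))
    xi <- findInterval(pts$x_um, xs)
    yi <- findInterval(pts$y_um, ys)
    ok <- xi >= 1 & yi >= 1
    ok[ok] <- pts$x_um[ok] < xs[xi[ok]] + fov &
      pts$y_um[ok] < ys[yi[ok]] + fov
    placed <- matrix(FALSE, length(xs), length(ys))
    placed[cbind(match(fovs$x0_um, xs), match(fovs$y0_um, ys))] <- TRUE
    ok[ok] <- placed[cbind(xi[ok], yi[ok])]
    if (any(ok)) {
      tb <- table(pts$class[ok])
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    }
  }
  out <- data.frame(class = HISTO_CLASSES, count = as.integer(counts),
                    area_mm2 = area_mm2,
                    density_per_mm2 = if (area_mm2 > 0)
                      counts / area_mm2 else NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("density_table", "data.frame")
  out
}

#' Nuclei-partialled pathology-microglia correlation
#'
#' Pearson correlation between pathology and microglial densities across
#' samples, and the first-order partial correlation after factoring out
#' the density of cell nuclei (an atrophy surrogate: fewer neurons per
#' area concentrates all densities alike).
#'
#' @param pathology,microglia,nuclei per-sample densities (>= 4 samples).
#' @return data frame: `measure` (`"r"`, `"partial_rho"`), `value`, `df`,
#'   `p`.
#' @export
partial_density_correlation <- function(pathology, microglia, nuclei) {
  n <- length(pathology)
  stopifnot(length(microglia) == n, length(nuclei) == n, n >= 4)
  if (sd(pathology) == 0 || sd(microglia) == 0 || sd(nuclei) == 0)
    stop("zero-variance density vector")
  ct <- cor.test(pathology, microglia)
  pc <- partial_cor(pathology, microglia, nuclei)
  data.frame(measure = c("r", "partial_rho"),
             value = c(unname(ct$estimate), pc$r),
             df = c(n - 2, pc$df),
             p = c(ct$p.value, pc$p), stringsAsFactors = FALSE)
}

# Design columns for subjects nested within diagnostic group: per group
# with s subjects, s-1 sum-to-zero deviation columns scoped to that group.
nested_subject_columns <- function(subject, diagnosis) {
  subject <- as.character(subject)
  diagnosis <- as.character(diagnosis)
  cols <- NULL
  nms <- character()
  for (g in unique(diagnosis)) {
    subs <- unique(subject[diagnosis == g])
    if (length(subs) < 2) next
    ct <- stats::contr.sum(length(subs))
    for (j in seq_len(ncol(ct))) {
      v <- numeric(length(subject))
      for (si in seq_along(subs))
        v[subject == subs[si] & diagnosis == g] <- ct[si, j]
      cols <- cbind(cols, v)
      nms <- c(nms, paste0("subj_", g, "_", j))
    }
  }
  colnames(cols) <- nms
  cols
}

#' Pathology-to-microglia generalized linear model
#'
#' Gaussian identity-link model of microglial density on pathology
#' density, with brain region, diagnosis, their interaction, subject
#' factors nested within diagnostic group, and the density of cell nuclei
#' as a covariate of no interest.  Each term is assessed by a Wald
#' chi-square test on its coefficient block.  Companion fits swap the
#' response between total, amoeboid-only and ramified-only microglial
#' density to test whether the association is amoeboid-specific.
#'
#' @param table data frame with one row per sample and columns `subject`,
#'   `region`, `diagnosis`, `pathology_density`, `nuclei_density` and the
#'   response named by `response` (e.g. `microglia_density`,
#'   `amoeboid_density`, `ramified_density`).
#' @param response name of the response column.
#' @return data frame of class `histo_glm`: `term`, `wald_chisq`, `df`,
#'   `p`, plus attributes `fit` (the underlying `lm`) and
#'   `pathology_ci` (95% Wald CI for the pathology slope).
#' @export
pathology_microglia_glm <- function(table,
                                    response = "microglia_density") {
  table <- as.data.frame(table)
  need <- c("subject", "region", "diagnosis", "pathology_density",
            "nuclei_density", response)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ",
                         paste(miss, collapse = ", "))
  if (length(unique(table$region)) < 2 ||
      length(unique(table$diagnosis)) < 2)
    stop("need >= 2 regions and >= 2 diagnoses")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  reg <- factor(table$region)
  dia <- factor(table$diagnosis)
  mmf <- model.matrix(~ reg * dia)
  asgn <- attr(mmf, "assign")
  Xr <- mmf[, asgn == 1, drop = FALSE]
  Xd <- mmf[, asgn == 2, drop = FALSE]
  Xi <- mmf[, asgn == 3, drop = FALSE]
  Xs <- nested_subject_columns(table$subject, table$diagnosis)
  blocks <- list(pathology = cbind(pathology = table$pathology_density),
                 nuclei = cbind(nuclei = table$nuclei_density),
                 region = Xr, diagnosis = Xd,
                 `region:diagnosis` = Xi,
                 `subject(diagnosis)` = Xs)
  blocks <- Filter(function(b) !is.null(b) && ncol(b) > 0, blocks)
  X <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  y <- table[[response]]
  fit <- lm(y ~ X - 1)
  V <- vcov(fit)
  b <- coef(fit)
  names(b) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  rows <- lapply(names(blocks), function(nm) {
    idx <- colnames(blocks[[nm]])
    if (is.null(idx)) idx <- nm
    W <- as.numeric(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*%
                      b[idx])
    data.frame(term = nm, wald_chisq = W, df = length(idx),
               p = pchisq(W, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  se_path <- sqrt(V["pathology", "pathology"])
  tq <- stats::qt(0.975, fit$df.residual)
  attr(out, "fit") <- fit
  attr(out, "pathology_ci") <- c(b[["pathology"]] - tq * se_path,
                                 b[["pathology"]] + tq * se_path)
  class(out) <- c("histo_glm", "data.frame")
  out
}

#' @export
print.histo_glm <- function(x, ...) {
  cat("Generalized linear model Wald tests\n")
  y <- as.data.frame(x)
  y$wald_chisq <- round(y$wald_chisq, 2)
  y$p <- signif(y$p, 3)
  print(y, row.names = FALSE)
  invisible(x)
}
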