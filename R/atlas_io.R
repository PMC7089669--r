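# Data model and delimited-text I/O for regional binding-potential tables.
#
# A `binding_matrix` couples a subjects x regions value matrix with the
# region metadata (name, lobe, hemisphere) and subject metadata (group, age,
# sex) that the downstream analyses need.  All tables are plain CSV, UTF-8,
# "." decimal, one table per ligand.

VALID_LOBES <- c("frontal", "temporal", "parietal", "occipital",
                 "insula_cingulate", "deep_nuclei", "cerebellum", "brainstem")
VALID_HEMIS <- c("left", "right", "midline")

#' Construct a regional binding matrix
#'
#' Bundles a subjects x regions matrix of non-displaceable binding potential
#' (BP_ND) with its subject and region metadata.  BP_ND is dimensionless and
#' may legitimately be negative; values are only required to be finite.
#'
#' @param values numeric matrix, subjects in rows, regions in columns.
#' @param regions data frame with columns `region_id` (0-based contiguous
#'   integers), `name`, `lobe`, `hemisphere`.
#' @param subjects data frame with columns `subject_id`, `group`, `age`,
#'   `sex`.
#' @param ligand ligand tag, e.g. `"PK"` (TSPO / activated microglia) or
#'   `"AV"` (non-amyloid protein aggregation).
#' @return an object of class `binding_matrix`.
#' @export
binding_matrix <- function(values, regions, subjects, ligand = "PK") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  regions <- validate_region_table(regions)
  subjects <- validate_subject_table(subjects)
  if (nrow(values) != nrow(subjects))
    stop("values has ", nrow(values), " rows but there are ",
         nrow(subjects), " subjects")
  if (ncol(values) != nrow(regions))
    stop("values has ", ncol(values), " columns but there are ",
         nrow(regions), " regions")
  if (any(!is.finite(values)))
    stop("non-finite cells in binding matrix: ",
         paste(utils::head(which(!is.finite(values)), 5), collapse = ", "))
  dimnames(values) <- list(subjects$subject_id, regions$name)
  structure(list(ligand = ligand, values = values,
                 regions = regions, subjects = subjects),
            class = "binding_matrix")
}

#' Construct a regional covariate matrix
#'
#' Same axes as [binding_matrix()] but holding a per-region covariate:
#' tissue fractions (grey, white, CSF, each in \[0, 1\]) or combined
#' grey+white volumes (strictly positive).
#'
#' @param values numeric subjects x regions matrix.
#' @param regions,subjects metadata tables as in [binding_matrix()].
#' @param kind one of `"gm_fraction"`, `"wm_fraction"`, `"csf_fraction"`,
#'   `"gmwm_volume"`.
#' @return an object of class `covariate_matrix`.
#' @export
covariate_matrix <- function(values, regions, subjects,
                             kind = c("gm_fraction", "wm_fraction",
                                      "csf_fraction", "gmwm_volume")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  regions <- validate_region_table(regions)
  subjects <- validate_subject_table(subjects)
  if (nrow(values) != nrow(subjects) || ncol(values) != nrow(regions))
    stop("covariate matrix axes do not match metadata")
  if (kind == "gmwm_volume") {
    if (any(values <= 0)) stop("volumes must be > 0")
  } else {
    if (any(values < -1e-9 | values > 1 + 1e-9))
      stop("tissue fractions must lie in [0, 1]")
  }
  dimnames(values) <- list(subjects$subject_id, regions$name)
  structure(list(kind = kind, values = values,
                 regions = regions, subjects = subjects),
            class = "covariate_matrix")
}

validate_region_table <- function(regions) {
  regions <- as.data.frame(regions)
  need <- c("region_id", "name", "lobe", "hemisphere")
  miss <- setdiff(need, names(regions))
  if (length(miss)) stop("region table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(regions$region_id) || anyDuplicated(regions$name))
    stop("region ids and names must be unique")
  if (!identical(sort(as.integer(regions$region_id)),
                 seq_len(nrow(regions)) - 1L))
    stop("region_id must be contiguous 0..R-1")
  if (!all(regions$lobe %in% VALID_LOBES))
    stop("unknown lobe label(s): ",
         paste(unique(setdiff(regions$lobe, VALID_LOBES)), collapse = ", "))
  if (!all(regions$hemisphere %in% VALID_HEMIS))
    stop("unknown hemisphere label(s): ",
         paste(unique(setdiff(regions$hemisphere, VALID_HEMIS)),
               collapse = ", "))
  regions[order(regions$region_id), need, drop = FALSE]
}

validate_subject_table <- function(subjects) {
  subjects <- as.data.frame(subjects)
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("subject table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  if (any(!is.finite(subjects$age) | subjects$age <= 0))
    stop("ages must be positive")
  rownames(subjects) <- NULL
  subjects
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat("<binding_matrix> ligand:", x$ligand, "-",
      nrow(x$values), "subjects x", ncol(x$values), "regions\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$subjects$group)),
                                 table(x$subjects$group)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat("<covariate_matrix> kind:", x$kind, "-",
      nrow(x$values), "subjects x", ncol(x$values), "regions\n")
  invisible(x)
}

#' @export
as.matrix.binding_matrix <- function(x, ...) x$values

#' @export
as.matrix.covariate_matrix <- function(x, ...) x$values

# Accept either a binding_matrix/covariate_matrix or a bare numeric matrix.
values_of <- function(x) {
  if (inherits(x, c("binding_matrix", "covariate_matrix"))) x$values
  else as.matrix(x)
}

#' Load region metadata
#'
#' @param path CSV with columns region_id,name,lobe,hemisphere.
#' @return validated region table ordered by `region_id`.
#' @export
load_region_table <- function(path) {
  validate_region_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Load subject metadata
#'
#' @param path CSV with columns subject_id,group,age,sex.
#' @return validated subject table.
#' @export
load_subject_table <- function(path) {
  validate_subject_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Default 83-region parcellation metadata
#'
#' Returns the region metadata shipped with the package: a synthetic
#' stand-in for a modified Hammers-style 83-region parcellation (the exact
#' region list of such atlases varies between studies), with left/right
#' pairs grouped into the eight lobes used by the lobe-wise analyses.  For
#' `R != 83` a generic parcellation is synthesised by cycling lobes, which
#' keeps small fast test fixtures possible.
#'
#' @param R number of regions (default 83).
#' @return region metadata data frame.
#' @export
default_region_table <- function(R = 83) {
  if (R == 83) {
    path <- system.file("extdata", "regions_synthetic_83.csv",
                        package = "copath")
    if (nzchar(path)) return(load_region_table(path))
  }
  lobes <- rep(VALID_LOBES, length.out = R)
  hemi <- rep(c("left", "right"), length.out = R)
  validate_region_table(data.frame(
    region_id = seq_len(R) - 1L,
    name = sprintf("region_%02d_%s", seq_len(R) - 1L, lobes),
    lobe = lobes, hemisphere = hemi, stringsAsFactors = FALSE))
}

#' Read a subjects x regions value table
#'
#' Expects one header row, subject ids in the first column, and one column
#' per region named exactly as in the region metadata.  Rows and columns are
#' canonicalized to the metadata order, so files whose rows/columns are
#' shuffled load to identical objects.
#'
#' @param path CSV file of values.
#' @param region_meta region metadata file or data frame.
#' @param subject_meta subject metadata file or data frame.
#' @param ligand ligand tag for the result.
#' @return a [binding_matrix()].
#' @export
load_binding_table <- function(path, region_meta, subject_meta,
                               ligand = "PK") {
  regions <- if (is.character(region_meta)) load_region_table(region_meta)
             else validate_region_table(region_meta)
  subjects <- if (is.character(subject_meta)) load_subject_table(subject_meta)
              else validate_subject_table(subject_meta)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("value table needs an id column plus regions")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate subject row(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  miss_col <- setdiff(regions$name, names(raw)[-1])
  if (length(miss_col))
    stop("missing region column(s) in ", path, ": ",
         paste(miss_col, collapse = ", "))
  extra <- setdiff(names(raw)[-1], regions$name)
  if (length(extra))
    stop("region column(s) absent from metadata: ",
         paste(extra, collapse = ", "))
  miss_row <- setdiff(subjects$subject_id, ids)
  if (length(miss_row))
    stop("missing subject row(s) in ", path, ": ",
         paste(miss_row, collapse = ", "))
  m <- raw[match(subjects$subject_id, ids), regions$name, drop = FALSE]
  bad <- which(vapply(m, function(col) any(is.na(suppressWarnings(
    as.numeric(col)))), logical(1)))
  if (length(bad)) {
    col1 <- names(m)[bad[1]]
    row1 <- which(is.na(suppressWarnings(as.numeric(m[[col1]]))))[1]
    stop("non-numeric cell in ", path, " at subject '",
         subjects$subject_id[row1], "', region '", col1, "'")
  }
  binding_matrix(vapply(m, as.numeric, numeric(nrow(m))),
                 regions, subjects, ligand = ligand)
}

#' Write a subjects x regions value table
#'
#' Full double precision is preserved (17 significant digits) so that
#' `load_binding_table(write_binding_table(m))` round-trips bit-for-bit.
#'
#' @param m a [binding_matrix()] or [covariate_matrix()].
#' @param path output CSV path.
#' @export
write_binding_table <- function(m, path) {
  v <- values_of(m)
  if (nrow(v) == 0) stop("refusing to write a table with no subjects")
  df <- data.frame(subject_id = rownames(v), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v)))
    df[[colnames(v)[j]]] <- sprintf("%.17g", v[, j])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write region / subject metadata tables
#'
#' @param x metadata data frame (region or subject table).
#' @param path output CSV path.
#' @export
write_meta_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a binding or covariate matrix by subjects
#'
#' @param m a [binding_matrix()] or [covariate_matrix()].
#' @param subject_ids character ids, or a logical/integer row index.
#' @return object of the same class restricted to those subjects.
#' @export
subset_subjects <- function(m, subject_ids) {
  idx <- if (is.character(subject_ids))
    match(subject_ids, m$subjects$subject_id) else subject_ids
  if (is.character(subject_ids) && anyNA(idx))
    stop("unknown subject id(s): ",
         paste(subject_ids[is.na(idx)], collapse = ", "))
  m$values <- m$values[idx, , drop = FALSE]
  m$subjects <- m$subjects[idx, , drop = FALSE]
  rownames(m$subjects) <- NULL
  m
}

#' Subjects belonging to given diagnostic groups
#'
#' @param m a [binding_matrix()] or [covariate_matrix()].
#' @param groups character vector of group labels.
#' @return subject ids in metadata order.
#' @export
group_subjects <- function(m, groups) {
  m$subjects$subject_id[m$subjects$group %in% groups]
}
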