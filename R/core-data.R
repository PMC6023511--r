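#' @keywords internal
"_PACKAGE"

#' Disease stage labels
#'
#' The three stages of the Alzheimer's disease cohort design: `CON` (aged
#' controls), `MCI` (mild cognitive impairment) and `TAD` (total/acute
#' Alzheimer's disease), in increasing order of severity. All stage arguments
#' throughout the package are validated against this vector, and all
#' severity-ordered tie-breaks use its ordering.
#'
#' @return Character vector `c("CON", "MCI", "TAD")`.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() c("CON", "MCI", "TAD")

#' @rdname stage_levels
#' @param stage character scalar to validate.
#' @return `as_stage()` returns the validated stage label.
#' @export
as_stage <- function(stage) {
  if (!is.character(stage) || length(stage) != 1L || !stage %in% stage_levels())
    stop("stage must be one of ", paste(stage_levels(), collapse = ", "),
         call. = FALSE)
  stage
}

chip_levels <- c("CM10", "IMAC30", "Q10")
energy_levels <- c("low", "high")

#' Leaf metadata for a cohort
#'
#' A leaf of the study design tree: one proteinChip surface chemistry
#' (`CM10`, `IMAC30` or `Q10`), one laser bombardment energy level
#' (`low` = 1800 nJ, `high` = 4000 nJ) and the protein source sample
#' (saliva by default).
#'
#' @param chip proteinChip, one of `"CM10"`, `"IMAC30"`, `"Q10"`.
#' @param energy laser energy level, `"low"` or `"high"`.
#' @param pss protein source sample tag.
#' @return An object of class `leaf_meta`.
#' @export
#' @examples
#' leaf_meta("CM10", "low")
leaf_meta <- function(chip = "CM10", energy = "low", pss = "saliva") {
  chip <- match.arg(chip, chip_levels)
  energy <- match.arg(energy, energy_levels)
  stopifnot(is.character(pss), length(pss) == 1L)
  structure(list(chip = chip, energy = energy, pss = pss),
            class = "leaf_meta")
}

#' @export
format.leaf_meta <- function(x, ...) {
  sprintf("%s-%s (%s)", x$chip, x$energy, x$pss)
}

#' @export
print.leaf_meta <- function(x, ...) {
  cat("<leaf>", format(x), "\n")
  invisible(x)
}

#' Construct a spectrum matrix data point
#'
#' One SELDI-TOF assay result: an n-by-2 matrix whose rows are differentially
#' expressed peaks, each a (m/z, intensity) vector. The matrix -- not any
#' single peak -- is the unit of classification. Peaks are stored sorted
#' strictly ascending by mass; duplicate masses within one data point are
#' rejected.
#'
#' @param mass numeric vector of m/z values in Daltons (positive).
#' @param intensity numeric vector of TOF intensities (finite), same length.
#' @param stage stage label, see [stage_levels()].
#' @param sample_index integer identifier of the data point within its stage.
#' @param leaf a [leaf_meta()] object.
#' @return An object of class `spectrum_matrix` with elements `peaks`
#'   (n-by-2 numeric matrix, columns `mass` and `intensity`), `stage`,
#'   `sample_index` and `leaf`.
#' @export
#' @examples
#' spectrum_matrix(c(1000, 2000), c(5.2, 1.1), "CON", 1, leaf_meta())
spectrum_matrix <- function(mass, intensity, stage, sample_index = 1L,
                            leaf = leaf_meta()) {
  if (!is.numeric(mass) || !is.numeric(intensity))
    stop("mass and intensity must be numeric", call. = FALSE)
  if (length(mass) != length(intensity))
    stop("mass and intensity lengths differ", call. = FALSE)
  if (length(mass) < 1L)
    stop("a spectrum matrix needs at least one peak", call. = FALSE)
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("all masses must be positive and finite", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("all intensities must be finite", call. = FALSE)
  if (anyDuplicated(mass))
    stop("duplicate masses within one spectrum matrix", call. = FALSE)
  ord <- order(mass)
  peaks <- cbind(mass = as.numeric(mass[ord]),
                 intensity = as.numeric(intensity[ord]))
  stopifnot(inherits(leaf, "leaf_meta"))
  structure(list(peaks = peaks,
                 stage = as_stage(stage),
                 sample_index = as.integer(sample_index),
                 leaf = leaf),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> stage=%s sample=%d n=%d peaks, %s\n",
              x$stage, x$sample_index, n_peaks(x), format(x$leaf)))
  invisible(x)
}

#' Number of peaks of a spectrum matrix
#' @param x a `spectrum_matrix`.
#' @return integer peak count n.
#' @export
n_peaks <- function(x) {
  stopifnot(inherits(x, "spectrum_matrix"))
  nrow(x$peaks)
}

#' Construct a cohort of spectrum matrices
#'
#' A cohort is one leaf of the design tree populated with data points for each
#' disease stage (the study design uses 20 per stage). All members must carry
#' the cohort's leaf metadata.
#'
#' @param members named list mapping each stage label to a list of
#'   [spectrum_matrix()] objects. Stages may be empty but the names must be a
#'   subset of [stage_levels()].
#' @param leaf a [leaf_meta()] object shared by all members.
#' @return An object of class `seldi_cohort` with elements `leaf` and
#'   `members` (always carrying all three stage names).
#' @export
cohort <- function(members, leaf = leaf_meta()) {
  stopifnot(inherits(leaf, "leaf_meta"), is.list(members))
  if (is.null(names(members)) || !all(names(members) %in% stage_levels()))
    stop("members must be a named list keyed by stage labels", call. = FALSE)
  full <- stats::setNames(vector("list", 3L), stage_levels())
  for (s in stage_levels()) full[[s]] <- members[[s]] %||% list()
  for (s in stage_levels()) {
    for (m in full[[s]]) {
      stopifnot(inherits(m, "spectrum_matrix"))
      if (m$stage != s)
        stop("member under ", s, " carries stage ", m$stage, call. = FALSE)
      if (!identical(unclass(m$leaf), unclass(leaf)))
        stop("member leaf metadata differs from cohort leaf", call. = FALSE)
    }
  }
  structure(list(leaf = leaf, members = full), class = "seldi_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.seldi_cohort <- function(x, ...) {
  sizes <- vapply(x$members, length, integer(1))
  cat(sprintf("<seldi_cohort> %s: %s\n", format(x$leaf),
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = " ")))
  invisible(x)
}

#' Flatten a cohort to a list of spectrum matrices
#'
#' @param x a `seldi_cohort`.
#' @param stages stages to include, default all three.
#' @return list of `spectrum_matrix` objects, CON first, then MCI, then TAD.
#' @export
cohort_matrices <- function(x, stages = stage_levels()) {
  stopifnot(inherits(x, "seldi_cohort"))
  unlist(x$members[stages], recursive = FALSE, use.names = FALSE)
}

#' Per-stage membership counts
#' @param x a `seldi_cohort`.
#' @return named integer vector of stage sizes.
#' @export
cohort_sizes <- function(x) {
  stopifnot(inherits(x, "seldi_cohort"))
  vapply(x$members, length, integer(1))
}

# ---- file I/O --------------------------------------------------------------

#' Read a peak-list spectrum file
#'
#' Reads a two-column delimited text file (comma or tab, auto-detected) of
#' m/z and intensity values into a [spectrum_matrix()]. A header line naming
#' the columns (`mz,intensity`) is optional and detected by its non-numeric
#' first field. Rows are re-sorted ascending by mass; malformed rows raise an
#' error naming the offending line.
#'
#' @param path path to the spectrum file.
#' @param stage stage label of the sample.
#' @param leaf a [leaf_meta()] object.
#' @param sample_index integer identifier.
#' @return A `spectrum_matrix`.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, stage, leaf = leaf_meta(), sample_index = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0L)
    stop("empty spectrum file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[lines_keep[1]], fixed = TRUE)) "\t" else ","
  first <- strsplit(lines[lines_keep[1]], sep, fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(trimws(first[1]))))
  data_lines <- if (has_header) lines_keep[-1] else lines_keep
  if (length(data_lines) == 0L)
    stop("no data rows in spectrum file: ", path, call. = FALSE)
  mass <- numeric(length(data_lines))
  intensity <- numeric(length(data_lines))
  for (i in seq_along(data_lines)) {
    ln <- data_lines[i]
    fields <- trimws(strsplit(lines[ln], sep, fixed = TRUE)[[1]])
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) < 2L || anyNA(vals[1:2]))
      stop(sprintf("malformed row at line %d of %s: '%s'", ln, path,
                   lines[ln]), call. = FALSE)
    mass[i] <- vals[1]
    intensity[i] <- vals[2]
  }
  if (anyDuplicated(mass))
    stop("duplicate mass values in ", path, call. = FALSE)
  spectrum_matrix(mass, intensity, stage, sample_index, leaf)
}

#' Write a spectrum matrix to a peak-list file
#'
#' Writes a `mz,intensity` CSV with 17 significant digits so that
#' [read_spectrum()] round-trips masses and intensities exactly.
#'
#' @param x a `spectrum_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum_matrix"))
  body <- sprintf("%.17g,%.17g", x$peaks[, "mass"], x$peaks[, "intensity"])
  writeLines(c("mz,intensity", body), path)
  invisible(path)
}

#' Write / read a cohort as a manifest plus spectrum files
#'
#' The on-disk layout is a JSON manifest recording the leaf metadata and, per
#' stage, the member spectrum file paths (relative to the manifest), with one
#' CSV per data point.
#'
#' @param x a `seldi_cohort`.
#' @param dir directory to create the manifest (`manifest.json`) and spectrum
#'   files in.
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns a `seldi_cohort`.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "seldi_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (s in stage_levels()) {
    fs <- character(0)
    for (m in x$members[[s]]) {
      f <- sprintf("%s_%03d.csv", s, m$sample_index)
      write_spectrum(m, file.path(dir, f))
      fs <- c(fs, f)
    }
    files[[s]] <- fs
  }
  manifest <- list(leaf = unclass(x$leaf), files = files)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @param manifest path to a cohort manifest JSON file.
#' @export
read_cohort <- function(manifest) {
  info <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  leaf <- leaf_meta(info$leaf$chip, info$leaf$energy, info$leaf$pss)
  base <- dirname(manifest)
  members <- list()
  for (s in stage_levels()) {
    fs <- info$files[[s]]
    members[[s]] <- lapply(seq_along(fs), function(i)
      read_spectrum(file.path(base, fs[i]), s, leaf, sample_index = i))
  }
  cohort(members, leaf)
}

# ---- grid alignment --------------------------------------------------------

#' Align a cohort onto a common mass grid
#'
#' Inter-sample peak correspondence ("equal mass values" across data points)
#' requires a shared m/z grid. Masses from all members are pooled, sorted and
#' greedily merged: a mass joins the current grid bin when it lies within
#' `tolerance` (relative) of the bin's running mean, and each bin's grid mass
#' is the mean of its contributors. Every member is then re-expressed on the
#' grid; grid masses absent from a sample get intensity 0, and multiple peaks
#' of one sample falling into one bin are averaged.
#'
#' The operation is idempotent: aligned cohorts pass through unchanged.
#'
#' @param x a `seldi_cohort`.
#' @param tolerance non-negative relative mass tolerance (default `1e-4`).
#' @return A `seldi_cohort` whose members all share one mass vector.
#' @export
align_to_common_grid <- function(x, tolerance = 1e-4) {
  stopifnot(inherits(x, "seldi_cohort"))
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop("tolerance must be a non-negative number", call. = FALSE)
  mats <- cohort_matrices(x)
  if (length(mats) == 0L) stop("cohort is empty", call. = FALSE)
  all_masses <- sort(unique(unlist(lapply(mats, function(m) m$peaks[, "mass"]))))
  # greedy single-pass binning on the sorted pooled masses
  grid <- numeric(0)
  bin_sum <- all_masses[1]
  bin_n <- 1L
  for (m in all_masses[-1]) {
    mu <- bin_sum / bin_n
    if (m - mu <= tolerance * mu) {
      bin_sum <- bin_sum + m
      bin_n <- bin_n + 1L
    } else {
      grid <- c(grid, mu)
      bin_sum <- m
      bin_n <- 1L
    }
  }
  grid <- c(grid, bin_sum / bin_n)

  remap <- function(m) {
    idx <- findInterval(m$peaks[, "mass"], grid)
    # nearest grid mass (findInterval gives the bin at or below)
    idx[idx == 0L] <- 1L
    up <- idx < length(grid) &
      (grid[pmin(idx + 1L, length(grid))] - m$peaks[, "mass"]) <
        (m$peaks[, "mass"] - grid[idx])
    idx[up] <- idx[up] + 1L
    intensity <- numeric(length(grid))
    counts <- integer(length(grid))
    for (j in seq_along(idx)) {
      i <- idx[j]
      intensity[i] <- intensity[i] + m$peaks[j, "intensity"]
      counts[i] <- counts[i] + 1L
    }
    intensity[counts > 1L] <- intensity[counts > 1L] / counts[counts > 1L]
    out <- m
    out$peaks <- cbind(mass = grid, intensity = intensity)
    out
  }
  members <- lapply(x$members, function(ms) lapply(ms, remap))
  structure(list(leaf = x$leaf, members = members), class = "seldi_cohort")
}

#' Test whether all members of a cohort share one mass grid
#' @param x a `seldi_cohort`.
#' @return logical.
#' @export
is_aligned <- function(x) {
  mats <- cohort_matrices(x)
  if (length(mats) <= 1L) return(TRUE)
  g <- mats[[1]]$peaks[, "mass"]
  all(vapply(mats[-1], function(m)
    nrow(m$peaks) == length(g) && all(m$peaks[, "mass"] == g), logical(1)))
}

# ---- pooling ---------------------------------------------------------------

#' Pool unique peaks of one disease stage
#'
#' Collapses a set of same-stage data points to one representative peak list:
#' the union of their masses, each carrying the mean intensity across the
#' samples that contain it, after an optional per-sample normalization
#' (`tic` divides each sample by its total intensity, `max` by its maximum).
#' This is the per-stage "unique peak" spectrum used for pooled overviews.
#'
#' @param matrices list of `spectrum_matrix` objects sharing one stage.
#' @param normalization `"tic"`, `"none"` or `"max"`.
#' @return A two-column matrix (`mass`, `intensity`) sorted by mass.
#' @export
pool_unique_peaks <- function(matrices, normalization = c("tic", "none", "max")) {
  normalization <- match.arg(normalization)
  if (length(matrices) == 0L) stop("no matrices to pool", call. = FALSE)
  stages <- vapply(matrices, function(m) m$stage, character(1))
  if (length(unique(stages)) != 1L)
    stop("pool_unique_peaks requires a single stage, got: ",
         paste(unique(stages), collapse = ", "), call. = FALSE)
  norm_one <- function(m) {
    i <- m$peaks[, "intensity"]
    switch(normalization,
           none = i,
           tic = i / sum(i),
           max = i / max(i))
  }
  mass <- unlist(lapply(matrices, function(m) m$peaks[, "mass"]))
  intensity <- unlist(lapply(matrices, norm_one))
  agg <- tapply(intensity, mass, mean)
  out_mass <- as.numeric(names(agg))
  ord <- order(out_mass)
  cbind(mass = out_mass[ord], intensity = as.numeric(agg)[ord])
}

# ---- train/test split ------------------------------------------------------

#' Stratified train/test split of a cohort
#'
#' Splits each stage independently: the test set receives
#' `round(stage size * (1 - train_fraction))` members sampled without
#' replacement, the remainder train. Deterministic given `seed`; the caller's
#' RNG state is left untouched.
#'
#' @param x a `seldi_cohort`.
#' @param train_fraction proportion in (0, 1), default 0.7 (the 70-30 design).
#' @param seed integer seed.
#' @return A list with `seldi_cohort` elements `train` and `test`.
#' @export
split_cohort <- function(x, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(x, "seldi_cohort"))
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  sizes <- cohort_sizes(x)
  if (any(sizes < 2L))
    stop("every stage needs at least 2 members to split", call. = FALSE)
  tr <- list(); te <- list()
  with_local_seed(seed, {
    for (s in stage_levels()) {
      n <- length(x$members[[s]])
      n_test <- round(n * (1 - train_fraction))
      n_test <- max(0L, min(n - 1L, n_test))
      test_idx <- sort(sample.int(n, n_test))
      te[[s]] <- x$members[[s]][test_idx]
      tr[[s]] <- x$members[[s]][setdiff(seq_len(n), test_idx)]
    }
  })
  list(train = cohort(tr, x$leaf), test = cohort(te, x$leaf))
}

# run expr under a temporary RNG seed, restoring the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
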