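# Classification by transformation: stage eigenmatrices, 2x2 projections,
# the 3x3 projection grid, cluster-spread (shrinkage) quantification, and a
# nearest-signature-centroid classifier.

#' Compute the eigenmatrix of a stage pool
#'
#' Stacks the pool's intensity vectors into a samples-by-n matrix, takes the
#' eigen decomposition of its n-by-n covariance (mean-centered over samples),
#' ranks eigenvectors by absolute eigenvalue and concatenates the top two
#' into an n-by-2 eigenmatrix -- the projection operator of the stage. Each
#' eigenvector is sign-fixed so that its largest-magnitude entry is positive,
#' making projections reproducible across linear-algebra backends.
#'
#' Mass values play no role in eigenmatrix estimation; they enter only the
#' projection product itself.
#'
#' @param matrices list of at least 2 aligned `spectrum_matrix` objects
#'   sharing one stage, with at least 2 peaks.
#' @return An object of class `eigen_matrix`: list with `stage`, `vectors`
#'   (n-by-2 orthonormal columns), `values` (the 2 eigenvalues, by descending
#'   magnitude) and `masses` (the grid).
#' @export
compute_stage_eigenmatrix <- function(matrices) {
  if (length(matrices) < 2L)
    stop("need at least 2 matrices for an eigenmatrix", call. = FALSE)
  stages <- unique(vapply(matrices, function(m) m$stage, character(1)))
  if (length(stages) != 1L)
    stop("eigenmatrix pool mixes stages: ",
         paste(stages, collapse = ", "), call. = FALSE)
  n <- n_peaks(matrices[[1]])
  if (n < 2L) stop("need at least 2 peaks", call. = FALSE)
  grid <- matrices[[1]]$peaks[, "mass"]
  ints <- t(vapply(matrices, function(m) {
    if (n_peaks(m) != n || any(m$peaks[, "mass"] != grid))
      stop("matrices are not aligned to one grid", call. = FALSE)
    m$peaks[, "intensity"]
  }, numeric(n)))
  ev <- eigen(stats::cov(ints), symmetric = TRUE)
  ord <- order(abs(ev$values), decreasing = TRUE)[1:2]
  vectors <- ev$vectors[, ord, drop = FALSE]
  for (j in 1:2) {
    i_max <- which.max(abs(vectors[, j]))
    if (vectors[i_max, j] < 0) vectors[, j] <- -vectors[, j]
  }
  colnames(vectors) <- c("ev1", "ev2")
  structure(list(stage = stages, vectors = vectors,
                 values = ev$values[ord], masses = grid),
            class = "eigen_matrix")
}

#' @export
print.eigen_matrix <- function(x, ...) {
  cat(sprintf("<eigen_matrix> stage=%s n=%d eigenvalues=(%.4g, %.4g)\n",
              x$stage, nrow(x$vectors), x$values[1], x$values[2]))
  invisible(x)
}

#' Project a data point through an eigenmatrix
#'
#' The projection is the 2-by-2 matrix product `t(P) %*% M` of the data
#' point's n-by-2 (mass, intensity) matrix P with the n-by-2 eigenmatrix M.
#' Row 1 of the result carries the mass column's coordinates along the two
#' eigenvectors, row 2 the intensity column's; the intensity row is the 2D
#' point used for cluster plots and spread.
#'
#' @param p a `spectrum_matrix` aligned to the grid `m` was built on.
#' @param m an `eigen_matrix`.
#' @return An object of class `projection_result`: list with `eigen_stage`,
#'   `data_stage`, `sample_index` and `matrix2x2`.
#' @export
project <- function(p, m) {
  stopifnot(inherits(p, "spectrum_matrix"), inherits(m, "eigen_matrix"))
  if (n_peaks(p) != nrow(m$vectors))
    stop("shape mismatch: data point and eigenmatrix disagree on n",
         call. = FALSE)
  res <- t(p$peaks) %*% m$vectors
  if (any(!is.finite(res)))
    stop("projection produced non-finite entries", call. = FALSE)
  dimnames(res) <- list(c("mass", "intensity"), c("ev1", "ev2"))
  structure(list(eigen_stage = m$stage, data_stage = p$stage,
                 sample_index = p$sample_index, matrix2x2 = res),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection> eigen=%s data=%s sample=%d point=(%.4g, %.4g)\n",
              x$eigen_stage, x$data_stage, x$sample_index,
              x$matrix2x2["intensity", 1], x$matrix2x2["intensity", 2]))
  invisible(x)
}

#' Full projection grid of a cohort
#'
#' Builds one eigenmatrix per stage from the cohort and projects every data
#' point through every eigenmatrix, yielding the 9 grid cells (eigen stage x
#' data stage): CC, CM, CT, MC, MM, MT, TC, TM, TT.
#'
#' @param x an aligned `seldi_cohort` with all three stages present.
#' @return An object of class `projection_grid`: list with `eigenmatrices`
#'   (named by stage) and `results` (list of `projection_result`).
#' @seealso [projection_points()], [cluster_spread()]
#' @export
projection_grid <- function(x) {
  stopifnot(inherits(x, "seldi_cohort"))
  if (any(cohort_sizes(x) < 2L))
    stop("projection grid needs every stage populated (>= 2 members)",
         call. = FALSE)
  if (!is_aligned(x))
    stop("cohort must be aligned to a common grid first", call. = FALSE)
  eigenmatrices <- lapply(stats::setNames(stage_levels(), stage_levels()),
                          function(s) compute_stage_eigenmatrix(x$members[[s]]))
  results <- list()
  for (es in stage_levels())
    for (ds in stage_levels())
      for (p in x$members[[ds]])
        results[[length(results) + 1L]] <- project(p, eigenmatrices[[es]])
  structure(list(eigenmatrices = eigenmatrices, results = results),
            class = "projection_grid")
}

#' @export
print.projection_grid <- function(x, ...) {
  cat(sprintf("<projection_grid> %d projections in 9 cells\n",
              length(x$results)))
  invisible(x)
}

#' Tabulate projection grid points
#'
#' @param grid a `projection_grid` (or plain list of `projection_result`).
#' @return data.frame with columns `eigen_stage`, `data_stage`, `sample`,
#'   `x`, `y` -- the intensity-row coordinates of each projection.
#' @export
projection_points <- function(grid) {
  results <- if (inherits(grid, "projection_grid")) grid$results else grid
  data.frame(
    eigen_stage = vapply(results, function(r) r$eigen_stage, character(1)),
    data_stage = vapply(results, function(r) r$data_stage, character(1)),
    sample = vapply(results, function(r) r$sample_index, integer(1)),
    x = vapply(results, function(r) r$matrix2x2["intensity", 1], numeric(1)),
    y = vapply(results, function(r) r$matrix2x2["intensity", 2], numeric(1)))
}

#' Cluster spread of one projection-grid cell
#'
#' Root-mean-square distance of a cell's 2D intensity-row points from their
#' centroid. Comparing spreads across the data stages of one eigenmatrix
#' quantifies cluster shrinkage: with severity-monotone down-regulation,
#' spreads under the CON eigenmatrix shrink with the projected stage's
#' severity.
#'
#' @param results list of at least 2 `projection_result` objects from one
#'   grid cell.
#' @return Non-negative scalar.
#' @export
cluster_spread <- function(results) {
  if (length(results) < 2L)
    stop("cluster_spread needs at least 2 projections", call. = FALSE)
  es <- unique(vapply(results, function(r) r$eigen_stage, character(1)))
  ds <- unique(vapply(results, function(r) r$data_stage, character(1)))
  if (length(es) != 1L || length(ds) != 1L)
    stop("projections mix grid cells (eigen ", paste(es, collapse = "/"),
         ", data ", paste(ds, collapse = "/"), ")", call. = FALSE)
  pts <- t(vapply(results, function(r) r$matrix2x2["intensity", ],
                  numeric(2)))
  centroid <- colMeans(pts)
  sqrt(mean(rowSums(sweep(pts, 2, centroid)^2)))
}

#' Per-eigenmatrix spread summary of a projection grid
#'
#' @param grid a `projection_grid`.
#' @return data.frame with columns `eigen_stage`, `data_stage`, `spread`.
#' @export
spread_summary <- function(grid) {
  stopifnot(inherits(grid, "projection_grid"))
  pts <- projection_points(grid)
  out <- expand.grid(eigen_stage = stage_levels(),
                     data_stage = stage_levels(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$spread <- mapply(function(es, ds) {
    sel <- pts$eigen_stage == es & pts$data_stage == ds
    cluster_spread(grid$results[sel])
  }, out$eigen_stage, out$data_stage)
  out
}

#' Fit the projection classifier
#'
#' Training stores the three stage eigenmatrices and, per training stage, the
#' centroid of the members' projection signatures. A signature is the
#' concatenation of a data point's three 2-by-2 projections (one per stage
#' eigenmatrix) into a vector of length 12.
#'
#' @param train an aligned `seldi_cohort` with all stages present.
#' @return An object of class `projection_model`.
#' @seealso [classify_by_projection()]
#' @export
fit_projection_model <- function(train) {
  grid <- projection_grid(train)
  centroids <- lapply(stats::setNames(stage_levels(), stage_levels()),
                      function(s) {
    sigs <- vapply(train$members[[s]],
                   function(p) projection_signature(p, grid$eigenmatrices),
                   numeric(12))
    rowMeans(sigs)
  })
  structure(list(eigenmatrices = grid$eigenmatrices, centroids = centroids),
            class = "projection_model")
}

projection_signature <- function(p, eigenmatrices) {
  unlist(lapply(stage_levels(),
                function(s) as.numeric(project(p, eigenmatrices[[s]])$matrix2x2)),
         use.names = FALSE)
}

#' Classify a data point by its projection signature
#'
#' Computes the test data point's signature (its 2-by-2 projection under each
#' of the three stage eigenmatrices, concatenated) and assigns the stage
#' whose training-signature centroid is nearest in Euclidean distance; exact
#' ties resolve to the least severe stage (CON before MCI before TAD).
#'
#' @param test a `spectrum_matrix` aligned to the training grid.
#' @param model a `projection_model` from [fit_projection_model()].
#' @return A stage label.
#' @export
classify_by_projection <- function(test, model) {
  stopifnot(inherits(model, "projection_model"))
  sig <- projection_signature(test, model$eigenmatrices)
  d <- vapply(stage_levels(),
              function(s) sqrt(sum((sig - model$centroids[[s]])^2)),
              numeric(1))
  stage_levels()[which.min(d)]   # which.min keeps the first (least severe) tie
}
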