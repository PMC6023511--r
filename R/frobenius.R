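# Whole-matrix Frobenius baseline: the negative control showing that global
# matrix distances do not separate disease stages.

#' Frobenius distance between two spectrum matrices
#'
#' Square root of the sum of squared entry-wise differences over both the
#' mass and intensity columns. On grid-aligned data points the mass columns
#' cancel, so the value reduces to the Euclidean distance between intensity
#' vectors.
#'
#' @param a,b `spectrum_matrix` objects with equal peak counts.
#' @return Non-negative scalar; 0 iff all entries coincide.
#' @export
#' @examples
#' m1 <- spectrum_matrix(c(1000, 2000), c(1, 2), "CON")
#' m2 <- spectrum_matrix(c(1000, 2000), c(2, 1), "MCI")
#' frobenius_distance(m1, m2)
frobenius_distance <- function(a, b) {
  stopifnot(inherits(a, "spectrum_matrix"), inherits(b, "spectrum_matrix"))
  if (!identical(dim(a$peaks), dim(b$peaks)))
    stop("shape mismatch: matrices have different peak counts", call. = FALSE)
  sqrt(sum((a$peaks - b$peaks)^2))
}

#' Pairwise Frobenius distance matrix
#'
#' @param matrices list of aligned `spectrum_matrix` objects.
#' @return Symmetric matrix with zero diagonal; entry (i, j) is
#'   [frobenius_distance()] between matrices i and j.
#' @export
pairwise_distance_matrix <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  n <- vapply(matrices, n_peaks, integer(1))
  if (length(unique(n)) != 1L)
    stop("shape mismatch: matrices must share one grid", call. = FALSE)
  flat <- t(vapply(matrices, function(m) as.numeric(m$peaks),
                   numeric(2L * n[1])))
  d <- as.matrix(stats::dist(flat, method = "euclidean"))
  dimnames(d) <- NULL
  d
}

#' Dendrogram node sequence of one stage pool
#'
#' Agglomerative clustering of data points reduced to their intensity vectors
#' (masses serve only to fix the peak order), recording the sequence in which
#' members become conjoined. Merging picks, at each step, the globally
#' closest pair of clusters under the chosen linkage, with ties broken by the
#' lowest-index pair; the node sequence lists the original members in the
#' order they are first absorbed into any cluster.
#'
#' @param matrices list of at least 2 aligned `spectrum_matrix` objects.
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return An object of class `dendrogram_sequence`: list with `stage` (label
#'   of the first member, `NA` if mixed), `nodes` (integer member positions
#'   in absorption order), `merges` (list of per-step merged member sets) and
#'   `heights` (merge distances).
#' @export
build_dendrogram_sequence <- function(matrices,
                                      linkage = c("average", "single",
                                                  "complete")) {
  linkage <- match.arg(linkage)
  if (length(matrices) < 2L)
    stop("need at least 2 matrices to build a dendrogram", call. = FALSE)
  ints <- do.call(rbind, lapply(matrices, function(m) m$peaks[, "intensity"]))
  d <- as.matrix(stats::dist(ints))
  n <- nrow(d)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1L, n)
  nodes <- integer(0)
  merges <- list()
  heights <- numeric(0)
  for (step in seq_len(n - 1L)) {
    best <- NULL; best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in seq(ii + 1L, length(active))) {
        i <- active[ii]; j <- active[jj]
        if (d[i, j] < best_d) {      # strict: first (lowest-index) pair wins ties
          best_d <- d[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    for (m in c(members[[i]], members[[j]]))
      if (!m %in% nodes) nodes <- c(nodes, m)
    merges[[step]] <- sort(c(members[[i]], members[[j]]))
    heights[step] <- best_d
    # Lance-Williams update of distances to the merged cluster, stored at i
    for (k in setdiff(active, c(i, j))) {
      dk <- switch(linkage,
                   single = min(d[k, i], d[k, j]),
                   complete = max(d[k, i], d[k, j]),
                   average = (sizes[i] * d[k, i] + sizes[j] * d[k, j]) /
                     (sizes[i] + sizes[j]))
      d[k, i] <- dk; d[i, k] <- dk
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  stages <- unique(vapply(matrices, function(m) m$stage, character(1)))
  structure(list(stage = if (length(stages) == 1L) stages else NA_character_,
                 nodes = nodes, merges = merges, heights = heights),
            class = "dendrogram_sequence")
}

#' @export
print.dendrogram_sequence <- function(x, ...) {
  cat(sprintf("<dendrogram_sequence> stage=%s: %s\n", x$stage,
              paste(x$nodes, collapse = " - ")))
  invisible(x)
}

#' Silhouette-style stage-separation score
#'
#' Quantifies whether a pairwise distance matrix separates the stages: for
#' each sample, `a` is its mean within-stage distance and `b` the smallest
#' mean distance to any other stage; the sample score is `(b - a) / max(a,
#' b)` and the overall score their mean. Values near 1 indicate tight,
#' well-separated stages; values near 0 or below indicate no separation
#' (the Frobenius baseline's failure mode). Samples whose stage has a single
#' member are skipped with a warning; if all pairwise distances are equal the
#' score is 0.
#'
#' @param dist square symmetric distance matrix.
#' @param labels character vector of stage labels, one per row of `dist`.
#' @return Scalar in \[-1, 1\].
#' @export
stage_separation_score <- function(dist, labels) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (ncol(dist) != n || length(labels) != n)
    stop("dist must be square with one label per row", call. = FALSE)
  labels <- vapply(labels, as_stage, character(1))
  counts <- table(labels)
  scores <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n)) {
    if (counts[[labels[i]]] < 2L) { skipped <- skipped + 1L; next }
    own <- setdiff(which(labels == labels[i]), i)
    a <- mean(dist[i, own])
    others <- setdiff(unique(labels), labels[i])
    b <- min(vapply(others, function(s) mean(dist[i, labels == s]),
                    numeric(1)))
    m <- max(a, b)
    scores <- c(scores, if (m == 0) 0 else (b - a) / m)
  }
  if (skipped > 0L)
    warning(skipped, " sample(s) in singleton stages skipped", call. = FALSE)
  if (length(scores) == 0L)
    stop("no sample has a stage with >= 2 members", call. = FALSE)
  mean(scores)
}
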