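# Lightweight S3 containers shared across the pipeline.

#' ROI time series for a single run
#'
#' One run's T x N matrix of BOLD samples, with region labels, the repetition
#' time, and a censor mask (TRUE = frame retained for correlation).
#'
#' @param samples numeric T x N matrix (rows = volumes, columns = regions).
#' @param region_labels character vector of N unique region labels.
#' @param tr_seconds repetition time in seconds.
#' @param censor_mask logical vector of length T; defaults to all retained.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(samples, region_labels = colnames(samples),
                           tr_seconds = 1, censor_mask = rep(TRUE, nrow(samples))) {
  samples <- as.matrix(samples)
  if (is.null(region_labels)) {
    region_labels <- sprintf("R%02d", seq_len(ncol(samples)))
  }
  stopifnot(
    ncol(samples) >= 2, nrow(samples) >= 10,
    length(region_labels) == ncol(samples),
    !anyDuplicated(region_labels),
    length(censor_mask) == nrow(samples),
    is.logical(censor_mask),
    is.numeric(tr_seconds), tr_seconds > 0
  )
  if (!all(is.finite(samples))) stop("roi_timeseries: non-finite samples")
  colnames(samples) <- region_labels
  structure(
    list(samples = samples, region_labels = region_labels,
         tr_seconds = tr_seconds, censor_mask = censor_mask),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d volumes x %d regions, TR %.3g s, %d censored\n",
              nrow(x$samples), ncol(x$samples), x$tr_seconds, sum(!x$censor_mask)))
  invisible(x)
}

#' Six-parameter rigid-body motion trace for one run
#'
#' @param translations numeric T x 3 matrix of translations in mm.
#' @param rotations numeric T x 3 matrix of rotations in radians.
#' @param tr_seconds repetition time in seconds.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations, tr_seconds = 1) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  stopifnot(ncol(translations) == 3, ncol(rotations) == 3,
            nrow(translations) == nrow(rotations))
  if (!all(is.finite(translations)) || !all(is.finite(rotations))) {
    stop("motion_trace: non-finite motion parameters")
  }
  structure(list(translations = translations, rotations = rotations,
                 tr_seconds = tr_seconds),
            class = "motion_trace")
}

#' Framewise-displacement series
#'
#' @param fd numeric vector of non-negative framewise displacements (mm);
#'   the first entry is 0 by convention.
#' @param threshold_mm censoring threshold in mm (default 0.2).
#' @return An object of class `fd_series`.
#' @export
fd_series <- function(fd, threshold_mm = 0.2) {
  stopifnot(is.numeric(fd), all(is.finite(fd)), all(fd >= 0), fd[1] == 0,
            threshold_mm > 0)
  structure(list(fd = fd, threshold_mm = threshold_mm), class = "fd_series")
}

#' Functional-connectivity matrix for one dog at one timepoint
#'
#' Symmetric N x N matrix of edge strengths, either Pearson r (unit diagonal)
#' or Fisher z (zero diagonal by convention). Undefined edges (zero-variance
#' regions) are stored as NA.
#'
#' @param values symmetric numeric N x N matrix.
#' @param scale `"pearson_r"` or `"fisher_z"`.
#' @param dog_id,timepoint identifiers carried through the pipeline.
#' @param region_labels character vector of N region labels.
#' @return An object of class `fc_matrix`.
#' @export
fc_matrix <- function(values, scale = c("pearson_r", "fisher_z"),
                      dog_id = NA_character_, timepoint = NA_character_,
                      region_labels = colnames(values)) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(region_labels)) {
    region_labels <- sprintf("R%02d", seq_len(ncol(values)))
  }
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8) {
    stop("fc_matrix: values must be symmetric")
  }
  if (scale == "pearson_r") {
    offd <- values[upper.tri(values)]
    if (any(abs(offd) > 1 + 1e-12, na.rm = TRUE)) {
      stop("fc_matrix: pearson_r entries must lie in [-1, 1]")
    }
    diag(values) <- 1
  } else {
    diag(values) <- 0
  }
  dimnames(values) <- list(region_labels, region_labels)
  structure(list(values = values, scale = scale, dog_id = dog_id,
                 timepoint = timepoint, region_labels = region_labels),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %s %s: %d regions, scale %s, %d missing edges\n",
              x$dog_id, x$timepoint, length(x$region_labels), x$scale,
              sum(is.na(x$values[upper.tri(x$values)]))))
  invisible(x)
}

#' Lexicographic edge index for an N-region connectome
#'
#' Edges are ordered (1,2), (1,3), ..., (1,N), (2,3), ...; this ordering is
#' stable across the whole pipeline.
#'
#' @param n_regions number of regions N.
#' @return Integer matrix with E = N(N-1)/2 rows and columns `i`, `j` (i < j).
#' @export
edge_pairs <- function(n_regions) {
  stopifnot(n_regions >= 2)
  ep <- t(combn(n_regions, 2L))
  colnames(ep) <- c("i", "j")
  ep
}

# Map (i, j) pairs to positions in the lexicographic edge order.
edge_ids <- function(edges, n_regions) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  i <- pmin(edges[, 1], edges[, 2]); j <- pmax(edges[, 1], edges[, 2])
  stopifnot(all(i >= 1), all(j <= n_regions), all(i < j))
  # edges before row block i: sum_{k<i} (N-k); offset within block: j - i
  as.integer((i - 1) * n_regions - i * (i - 1) / 2 + (j - i))
}
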