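# Edge-wise FC: Pearson matrices, Fisher-z handling, run averaging, and the
# cohort edge table used by all downstream statistics.

#' Pearson functional-connectivity matrix for one run
#'
#' Pairwise Pearson correlation between regions over the retained frames
#' (the censor mask is honoured, so interpolated frames never enter the
#' correlation). Zero-variance regions yield undefined edges, recorded as NA
#' and excluded downstream.
#'
#' @param ts a [roi_timeseries()].
#' @param dog_id,timepoint identifiers stamped on the result.
#' @return An [fc_matrix()] on the `pearson_r` scale.
#' @export
fc_pearson <- function(ts, dog_id = NA_character_, timepoint = NA_character_) {
  stopifnot(inherits(ts, "roi_timeseries"))
  keep <- ts$censor_mask
  if (sum(keep) < 3) stop("fc_pearson: fewer than 3 retained frames")
  x <- ts$samples[keep, , drop = FALSE]
  sds <- apply(x, 2, sd)
  degenerate <- sds == 0 | !is.finite(sds)
  vals <- suppressWarnings(cor(x))
  if (any(degenerate)) {
    warning("fc_pearson: zero-variance region(s) ",
            paste(ts$region_labels[degenerate], collapse = ", "),
            "; edges recorded as missing")
    vals[degenerate, ] <- NA_real_
    vals[, degenerate] <- NA_real_
  }
  diag(vals) <- 1
  vals[] <- pmin(1, pmax(-1, vals))
  fc_matrix(vals, "pearson_r", dog_id, timepoint, ts$region_labels)
}

#' Fisher-z transform an FC matrix
#'
#' Applies atanh elementwise off-diagonal (variance stabilization before run
#' averaging and cohort statistics). Edges at exactly |r| = 1 are mapped to
#' atanh(1 - 1e-7) with a warning.
#'
#' @param fc an [fc_matrix()] on the `pearson_r` scale.
#' @return The [fc_matrix()] on the `fisher_z` scale (zero diagonal).
#' @export
to_fisher_z <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  if (fc$scale != "pearson_r") stop("to_fisher_z: input must be pearson_r scale")
  vals <- fc$values
  saturated <- abs(vals) >= 1 & row(vals) != col(vals)
  if (any(saturated, na.rm = TRUE)) {
    warning("to_fisher_z: |r| = 1 clipped to 1 - 1e-7")
    vals[which(saturated)] <- sign(vals[which(saturated)]) * (1 - 1e-7)
  }
  z <- atanh(vals)
  diag(z) <- 0
  fc_matrix(z, "fisher_z", fc$dog_id, fc$timepoint, fc$region_labels)
}

#' Inverse of [to_fisher_z()]
#' @param fc an [fc_matrix()] on the `fisher_z` scale.
#' @return The [fc_matrix()] on the `pearson_r` scale.
#' @export
from_fisher_z <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"), fc$scale == "fisher_z")
  vals <- tanh(fc$values)
  diag(vals) <- 1
  fc_matrix(vals, "pearson_r", fc$dog_id, fc$timepoint, fc$region_labels)
}

#' Average FC matrices across runs
#'
#' Elementwise mean on the Fisher-z scale, ignoring edges missing in a run;
#' an edge is missing in the result only if it is missing in every run.
#'
#' @param fcs list of [fc_matrix()] objects for the same dog and timepoint,
#'   all on the `fisher_z` scale.
#' @return The averaged [fc_matrix()].
#' @export
average_runs <- function(fcs) {
  if (!length(fcs)) stop("average_runs: empty run list")
  stopifnot(all(vapply(fcs, function(f) inherits(f, "fc_matrix"), logical(1))))
  scales <- vapply(fcs, `[[`, character(1), "scale")
  if (!all(scales == "fisher_z")) stop("average_runs: runs must be fisher_z scale")
  ids <- unique(vapply(fcs, `[[`, character(1), "dog_id"))
  tps <- unique(vapply(fcs, `[[`, character(1), "timepoint"))
  if (length(ids) > 1 || length(tps) > 1) {
    stop("average_runs: runs must share dog_id and timepoint")
  }
  arr <- simplify2array(lapply(fcs, `[[`, "values"))
  m <- apply(arr, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  fc_matrix(m, "fisher_z", ids, tps, fcs[[1]]$region_labels)
}

#' Build the cohort edge table
#'
#' Vectorizes per-dog per-timepoint FC matrices into a dogs x timepoints x
#' edges array with the stable lexicographic (i < j) edge ordering. Dogs
#' missing any of the required timepoints are dropped (complete-case) with a
#' message.
#'
#' @param fc_list nested list `[[dog_id]][[timepoint]]` of [fc_matrix()]
#'   objects, all on the same scale with identical region labels.
#' @param timepoints required timepoints (default: all seen).
#' @return An object of class `edge_table` with elements `edges` (E x 2
#'   index matrix), `values` (dogs x timepoints x E array), `dogs`,
#'   `timepoints`, `region_labels`, `scale`.
#' @export
build_edge_table <- function(fc_list, timepoints = NULL) {
  stopifnot(length(fc_list) >= 1)
  all_tps <- unique(unlist(lapply(fc_list, names)))
  if (is.null(timepoints)) timepoints <- all_tps
  have_all <- vapply(fc_list, function(dl) all(timepoints %in% names(dl)) &&
                       !any(vapply(dl[timepoints], is.null, logical(1))),
                     logical(1))
  if (any(!have_all)) {
    message("build_edge_table: dropping ", sum(!have_all),
            " dog(s) without all required timepoints: ",
            paste(names(fc_list)[!have_all], collapse = ", "))
  }
  fc_list <- fc_list[have_all]
  if (!length(fc_list)) stop("build_edge_table: no dog has all required timepoints")
  ref <- fc_list[[1]][[timepoints[1]]]
  labels <- ref$region_labels
  scale <- ref$scale
  N <- length(labels)
  ep <- edge_pairs(N)
  ut <- upper.tri(matrix(0, N, N))
  dogs <- names(fc_list)
  values <- array(NA_real_, dim = c(length(dogs), length(timepoints), nrow(ep)),
                  dimnames = list(dogs, timepoints, NULL))
  for (d in seq_along(dogs)) {
    for (t in seq_along(timepoints)) {
      fc <- fc_list[[d]][[timepoints[t]]]
      if (!identical(fc$region_labels, labels)) {
        stop("build_edge_table: inconsistent region labels across dogs")
      }
      if (fc$scale != scale) stop("build_edge_table: mixed FC scales")
      values[d, t, ] <- t(fc$values)[t(ut)]  # row-major upper triangle = lexicographic
    }
  }
  structure(list(edges = ep, values = values, dogs = dogs,
                 timepoints = timepoints, region_labels = labels,
                 scale = scale),
            class = "edge_table")
}

#' @export
print.edge_table <- function(x, ...) {
  cat(sprintf("<edge_table> %d dogs x %d timepoints x %d edges (%s)\n",
              length(x$dogs), length(x$timepoints), nrow(x$edges), x$scale))
  invisible(x)
}

#' Reassemble an FC matrix from one edge-table slice
#'
#' Exact inverse of the vectorization in [build_edge_table()].
#'
#' @param edge_table an `edge_table`.
#' @param dog,timepoint which slice to reassemble.
#' @return An [fc_matrix()].
#' @export
edge_table_to_matrix <- function(edge_table, dog, timepoint) {
  v <- edge_table$values[dog, timepoint, ]
  N <- length(edge_table$region_labels)
  m <- matrix(if (edge_table$scale == "fisher_z") 0 else 1, N, N)
  m[cbind(edge_table$edges[, 1], edge_table$edges[, 2])] <- v
  m[cbind(edge_table$edges[, 2], edge_table$edges[, 1])] <- v
  if (edge_table$scale == "pearson_r") diag(m) <- 1 else diag(m) <- 0
  fc_matrix(m, edge_table$scale, dog, timepoint, edge_table$region_labels)
}

#' Compute per-dog per-timepoint FC matrices for a whole cohort
#'
#' Runs preprocessing and Pearson FC for every run, Fisher-z transforms, and
#' averages runs within dog x timepoint.
#'
#' @param cohort a `synthetic_cohort` (or any object with the same `runs` /
#'   `motion` layout).
#' @param fd_threshold_mm,head_radius_mm,band,filter see [preprocess_run()].
#' @param preprocess set FALSE to correlate the raw series (used by tests).
#' @return Nested list `[[dog_id]][[timepoint]]` of fisher-z [fc_matrix()]
#'   objects.
#' @export
cohort_fc <- function(cohort, fd_threshold_mm = 0.2, head_radius_mm = 50,
                      band = c(0.01, 0.1), filter = "ideal",
                      preprocess = TRUE) {
  out <- list()
  for (d in names(cohort$runs)) {
    out[[d]] <- list()
    for (tp in names(cohort$runs[[d]])) {
      rl <- cohort$runs[[d]][[tp]]
      if (is.null(rl)) next
      zs <- vector("list", length(rl))
      for (r in seq_along(rl)) {
        ts <- rl[[r]]
        if (preprocess) {
          ts <- preprocess_run(ts, cohort$motion[[d]][[tp]][[r]],
                               fd_threshold_mm, head_radius_mm, band, filter)
        }
        zs[[r]] <- to_fisher_z(fc_pearson(ts, d, tp))
      }
      out[[d]][[tp]] <- average_runs(zs)
    }
  }
  out
}
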