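# Flexible-periphery selection: edges whose FC change tracks behavior change
# and whose FC strengthens with training then maintains.

ibs_by_dog <- function(behavior, dogs, timepoint) {
  sub <- behavior[behavior$timepoint == timepoint, ]
  out <- sub$ibs[match(dogs, sub$dog_id)]
  if (anyNA(out)) stop("missing IBS for some dogs at ", timepoint)
  out
}

#' Per-dog FC and IBS changes between two timepoints
#'
#' @param edge_table an `edge_table` containing both timepoints.
#' @param behavior behavior data.frame (as from [generate_behavior()]).
#' @param tp_a,tp_b timepoint labels; changes are `tp_b - tp_a`.
#' @return List with `delta_fc` (dogs x edges matrix), `delta_ibs` (vector),
#'   `dogs`, and the edge index.
#' @export
delta_across_timepoints <- function(edge_table, behavior, tp_a = "TP1",
                                    tp_b = "TP2") {
  stopifnot(inherits(edge_table, "edge_table"),
            all(c(tp_a, tp_b) %in% edge_table$timepoints))
  have_beh <- vapply(edge_table$dogs, function(d) {
    all(c(tp_a, tp_b) %in% behavior$timepoint[behavior$dog_id == d])
  }, logical(1))
  if (any(!have_beh)) {
    message("delta_across_timepoints: excluding ", sum(!have_beh),
            " dog(s) missing behavior at ", tp_a, " or ", tp_b, ": ",
            paste(edge_table$dogs[!have_beh], collapse = ", "))
  }
  dogs <- edge_table$dogs[have_beh]
  delta_fc <- edge_table$values[dogs, tp_b, , drop = FALSE][, 1, ] -
    edge_table$values[dogs, tp_a, , drop = FALSE][, 1, ]
  delta_fc <- matrix(delta_fc, nrow = length(dogs),
                     dimnames = list(dogs, NULL))
  delta_ibs <- ibs_by_dog(behavior, dogs, tp_b) -
    ibs_by_dog(behavior, dogs, tp_a)
  list(delta_fc = delta_fc, delta_ibs = delta_ibs, dogs = dogs,
       edges = edge_table$edges)
}

#' Correlate per-edge FC changes with IBS changes across dogs
#'
#' Pearson correlation (two-sided t-based p) of each edge's deltaFC against
#' deltaIBS across dogs; Spearman available as an option. With no behavioral
#' spread all p-values are 1, with a warning.
#'
#' @param delta output of [delta_across_timepoints()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with columns `i`, `j`, `r_delta`, `p_delta`.
#' @export
correlate_delta <- function(delta, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(delta$delta_ibs)
  if (n < 4) stop("correlate_delta: need at least 4 dogs")
  y <- delta$delta_ibs
  out <- data.frame(i = delta$edges[, 1], j = delta$edges[, 2])
  if (sd(y) == 0) {
    warning("correlate_delta: zero-variance deltaIBS; all p set to 1")
    out$r_delta <- NA_real_
    out$p_delta <- 1
    return(out)
  }
  X <- delta$delta_fc
  if (method == "spearman") {
    X <- apply(X, 2, rank)
    y <- rank(y)
  }
  r <- suppressWarnings(as.vector(cor(y, X)))
  tval <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[abs(r) >= 1] <- 0
  p[is.na(r)] <- NA_real_
  out$r_delta <- r
  out$p_delta <- p
  out
}

#' Paired change test per edge between two timepoints
#'
#' Paired t-test on per-dog edge values, returning the two-sided p and the
#' signed mean change (tp_b minus tp_a). Edges with zero within-pair
#' variance get p = 1 when the mean change is zero and p = 0 otherwise,
#' with a degenerate-input warning.
#'
#' @param edge_table an `edge_table`.
#' @param tp_a,tp_b timepoint labels.
#' @return data.frame with columns `i`, `j`, `mean_change`, `p`.
#' @export
paired_change_test <- function(edge_table, tp_a, tp_b) {
  stopifnot(all(c(tp_a, tp_b) %in% edge_table$timepoints))
  d <- edge_table$values[, tp_b, ] - edge_table$values[, tp_a, ]
  d <- matrix(d, nrow = length(edge_table$dogs))
  n <- colSums(!is.na(d))
  if (any(n < 3)) stop("paired_change_test: fewer than 3 dogs with both timepoints")
  m <- colMeans(d, na.rm = TRUE)
  s <- apply(d, 2, sd, na.rm = TRUE)
  p <- rep(NA_real_, length(m))
  degen <- s == 0
  if (any(degen)) {
    warning("paired_change_test: zero within-pair variance on ",
            sum(degen), " edge(s)")
    p[degen] <- ifelse(m[degen] == 0, 1, 0)
  }
  ok <- !degen
  tval <- m[ok] / (s[ok] / sqrt(n[ok]))
  p[ok] <- 2 * pt(-abs(tval), df = n[ok] - 1)
  data.frame(i = edge_table$edges[, 1], j = edge_table$edges[, 2],
             mean_change = m, p = p)
}

#' Per-edge periphery statistics
#'
#' Assembles, for every edge, the deltaFC-deltaIBS correlation (TP1 to TP2),
#' the paired TP1-to-TP2 and TP2-to-TP3 change tests, and the confirmatory
#' TP3-minus-TP1 delta-delta correlation and (TP2-TP1) vs (TP2-TP3)
#' difference-of-differences test.
#'
#' @param edge_table an `edge_table` with TP1, TP2, TP3.
#' @param behavior behavior data.frame.
#' @param method correlation method for the delta-delta step.
#' @return A `path_stats` data.frame, one row per edge.
#' @export
periphery_stats <- function(edge_table, behavior, method = "pearson") {
  stopifnot(all(c("TP1", "TP2", "TP3") %in% edge_table$timepoints))
  d12 <- delta_across_timepoints(edge_table, behavior, "TP1", "TP2")
  cd12 <- correlate_delta(d12, method)
  inc <- paired_change_test(edge_table, "TP1", "TP2")
  mnt <- paired_change_test(edge_table, "TP2", "TP3")
  d13 <- delta_across_timepoints(edge_table, behavior, "TP1", "TP3")
  cd13 <- correlate_delta(d13, method)
  # (TP2-TP1) vs (TP2-TP3): paired test on the per-dog difference of changes.
  v <- edge_table$values
  dd <- (v[, "TP2", ] - v[, "TP1", ]) - (v[, "TP2", ] - v[, "TP3", ])
  dd <- matrix(dd, nrow = length(edge_table$dogs))
  ddm <- colMeans(dd, na.rm = TRUE)
  dds <- apply(dd, 2, sd, na.rm = TRUE)
  ddn <- colSums(!is.na(dd))
  ddt <- ddm / (dds / sqrt(ddn))
  p_dd <- ifelse(dds == 0, ifelse(ddm == 0, 1, 0),
                 2 * pt(-abs(ddt), df = ddn - 1))
  out <- data.frame(
    i = edge_table$edges[, 1], j = edge_table$edges[, 2],
    region_i = edge_table$region_labels[edge_table$edges[, 1]],
    region_j = edge_table$region_labels[edge_table$edges[, 2]],
    r_delta = cd12$r_delta, p_delta = cd12$p_delta,
    mean_increase_tp1_tp2 = inc$mean_change, p_increase_tp1_tp2 = inc$p,
    mean_change_tp2_tp3 = mnt$mean_change, p_change_tp2_tp3 = mnt$p,
    r_delta_tp3_tp1 = cd13$r_delta, p_tp3_tp1_delta = cd13$p_delta,
    p_diff_of_diffs = p_dd
  )
  class(out) <- c("path_stats", class(out))
  out
}

#' Select the flexible periphery network
#'
#' An edge is selected iff (a) its TP1-to-TP2 FC change correlates with the
#' IBS change at `alpha` (uncorrected); (b) its FC significantly increased
#' from TP1 to TP2 (two-sided paired test at `alpha` plus a positive mean
#' change by default; `one_sided = TRUE` reproduces the laxer one-sided
#' reading); and (c) it did not change significantly from TP2 to TP3
#' (p > `alpha` — an absence-of-evidence rule whose meaning depends on the
#' sample size; see the vignette). `strict = TRUE` adds the confirmatory
#' criteria: the (TP2-TP1) change exceeds the (TP2-TP3) change at `alpha`
#' and the TP3-minus-TP1 delta-delta correlation holds at `alpha`. An FDR
#' column (Benjamini-Hochberg on the delta-delta p-values) is reported for
#' transparency but never gates selection.
#'
#' @param stats a `path_stats` table from [periphery_stats()].
#' @param alpha significance level (default 0.05, uncorrected).
#' @param one_sided use a one-sided increase test at `alpha`.
#' @param strict add the confirmatory criteria (d) and (e).
#' @return The `path_stats` table with logical column `selected` and
#'   `q_delta_fdr` appended.
#' @export
select_periphery <- function(stats, alpha = 0.05, one_sided = FALSE,
                             strict = FALSE) {
  p_inc <- if (one_sided) {
    ifelse(stats$mean_increase_tp1_tp2 > 0, stats$p_increase_tp1_tp2 / 2,
           1 - stats$p_increase_tp1_tp2 / 2)
  } else {
    stats$p_increase_tp1_tp2
  }
  sel <- !is.na(stats$p_delta) & stats$p_delta < alpha &
    !is.na(p_inc) & p_inc < alpha & stats$mean_increase_tp1_tp2 > 0 &
    !is.na(stats$p_change_tp2_tp3) & stats$p_change_tp2_tp3 > alpha
  if (strict) {
    sel <- sel & !is.na(stats$p_diff_of_diffs) & stats$p_diff_of_diffs < alpha &
      !is.na(stats$p_tp3_tp1_delta) & stats$p_tp3_tp1_delta < alpha
  }
  stats$selected <- sel
  stats$q_delta_fdr <- stats::p.adjust(stats$p_delta, method = "BH")
  stats
}
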