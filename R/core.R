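# Stable-core selection: group-difference edges at TP1 and their stability
# across timepoints.

check_labels <- function(labels, dogs) {
  if (is.data.frame(labels)) {
    lv <- labels$label[match(dogs, labels$dog_id)]
  } else if (!is.null(names(labels))) {
    lv <- labels[dogs]
  } else {
    stopifnot(length(labels) == length(dogs))
    lv <- labels
  }
  if (anyNA(lv)) stop("every dog must be labeled exactly once")
  succ <- lv == "successful" | lv == TRUE
  if (!any(succ) || all(succ)) stop("both outcome classes must be non-empty")
  succ
}

#' Group-difference test per edge (successful vs non-successful)
#'
#' Welch two-sample t-test per edge at one timepoint, two-sided p, with the
#' direction flag requiring the successful-group mean to exceed the
#' non-successful mean ("significantly stronger"). Degenerate zero-variance
#' edges are excluded with a warning.
#'
#' @param edge_table an `edge_table`.
#' @param labels outcome labels: a manifest data.frame (`dog_id`, `label`),
#'   a named vector, or a logical vector aligned with `edge_table$dogs`
#'   (TRUE = successful).
#' @param timepoint which timepoint to test (default `"TP1"`).
#' @return data.frame with columns `i`, `j`, `mean_successful`,
#'   `mean_non_successful`, `t`, `p`, `stronger_in_successful`.
#' @export
group_difference_test <- function(edge_table, labels, timepoint = "TP1") {
  stopifnot(timepoint %in% edge_table$timepoints)
  succ <- check_labels(labels, edge_table$dogs)
  if (sum(succ) < 2 || sum(!succ) < 2) stop("need at least 2 dogs per group")
  x <- matrix(edge_table$values[, timepoint, ], nrow = length(edge_table$dogs))
  xs <- x[succ, , drop = FALSE]
  xf <- x[!succ, , drop = FALSE]
  n1 <- colSums(!is.na(xs)); n2 <- colSums(!is.na(xf))
  m1 <- colMeans(xs, na.rm = TRUE); m2 <- colMeans(xf, na.rm = TRUE)
  v1 <- apply(xs, 2, var, na.rm = TRUE); v2 <- apply(xf, 2, var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  tval <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tval), df)
  degen <- !is.na(se2) & se2 == 0
  if (any(degen)) {
    warning("group_difference_test: zero-variance edge(s) excluded: ",
            sum(degen))
    p[degen] <- NA_real_
    tval[degen] <- NA_real_
  }
  data.frame(i = edge_table$edges[, 1], j = edge_table$edges[, 2],
             mean_successful = m1, mean_non_successful = m2,
             t = tval, p = p, stronger_in_successful = m1 > m2)
}

#' Select the stable-core candidate edges at one timepoint
#'
#' Edges significantly stronger in the successful group (two-sided Welch p
#' below `alpha` with the successful mean larger).
#'
#' @param diff_stats output of [group_difference_test()].
#' @param alpha selection threshold (default 0.01, uncorrected).
#' @return The rows of `diff_stats` that pass, i.e. the core candidate set.
#' @export
select_core <- function(diff_stats, alpha = 0.01) {
  sel <- !is.na(diff_stats$p) & diff_stats$p < alpha &
    diff_stats$stronger_in_successful
  diff_stats[sel, , drop = FALSE]
}

#' Verify stability of core edges across timepoints
#'
#' For every core edge and each outcome group, paired tests between every
#' pair of timepoints; an edge is flagged stable iff none of the six tests
#' rejects at `alpha` (identical values at all timepoints count as stable:
#' the degenerate zero-variance, zero-change case yields p = 1).
#'
#' @param edge_table an `edge_table` with at least two timepoints.
#' @param labels outcome labels (see [group_difference_test()]).
#' @param core_edges data.frame with columns `i`, `j` (the TP1 selection).
#' @param alpha per-test level (default 0.05).
#' @return data.frame with one row per core edge: the six p-values and a
#'   logical `stable` flag.
#' @export
verify_core_stability <- function(edge_table, labels, core_edges,
                                  alpha = 0.05) {
  succ <- check_labels(labels, edge_table$dogs)
  tps <- edge_table$timepoints
  prs <- t(combn(length(tps), 2))
  N <- length(edge_table$region_labels)
  ids <- edge_ids(core_edges[, c("i", "j"), drop = FALSE], N)
  out <- data.frame(i = core_edges$i, j = core_edges$j)
  pair_p <- function(rows, id, a, b) {
    d <- edge_table$values[rows, b, id] - edge_table$values[rows, a, id]
    d <- d[!is.na(d)]
    if (length(d) < 2) return(NA_real_)
    if (sd(d) == 0) return(ifelse(mean(d) == 0, 1, 0))
    2 * pt(-abs(mean(d) / (sd(d) / sqrt(length(d)))), df = length(d) - 1)
  }
  for (g in c("successful", "non_successful")) {
    rows <- if (g == "successful") which(succ) else which(!succ)
    for (k in seq_len(nrow(prs))) {
      a <- tps[prs[k, 1]]; b <- tps[prs[k, 2]]
      col <- sprintf("p_%s_%s_%s", g, a, b)
      out[[col]] <- vapply(ids, function(id) pair_p(rows, id, a, b), numeric(1))
    }
  }
  pcols <- grep("^p_", names(out))
  out$stable <- apply(out[pcols], 1, function(p) all(!is.na(p) & p > alpha))
  out
}
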