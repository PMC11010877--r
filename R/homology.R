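# Connectivity fingerprints and cross-cohort region matching.

#' Build a connectivity fingerprint for one source region
#'
#' The fingerprint is the vector of FC values from the source region to a
#' fixed, ordered list of target regions (19 targets by convention, covering
#' cortical and subcortical regions known to guide canine behavior).
#'
#' @param fc an [fc_matrix()].
#' @param source source region label.
#' @param targets character vector of target labels (source must not be a
#'   target).
#' @return An object of class `fingerprint`: list with `source_region`,
#'   `target_labels`, `profile`, `subject_id`, `species`.
#' @param species optional species/cohort tag.
#' @export
build_fingerprint <- function(fc, source, targets, species = NA_character_) {
  stopifnot(inherits(fc, "fc_matrix"))
  missing_lab <- setdiff(c(source, targets), fc$region_labels)
  if (length(missing_lab)) {
    stop("build_fingerprint: unknown region label(s): ",
         paste(missing_lab, collapse = ", "))
  }
  if (source %in% targets) stop("build_fingerprint: source must not be a target")
  profile <- fc$values[source, targets]
  structure(list(source_region = source, target_labels = targets,
                 profile = unname(profile), subject_id = fc$dog_id,
                 species = species),
            class = "fingerprint")
}

#' Cohort-mean fingerprints for a set of source regions
#'
#' Builds per-subject fingerprints and averages them within the cohort
#' (average-then-match; per-subject matching is available by passing single
#' subjects).
#'
#' @param fc_list list of [fc_matrix()] objects (one per subject).
#' @param sources character vector of source region labels.
#' @param targets shared ordered target labels.
#' @param species cohort tag.
#' @return Matrix of mean profiles (rows = sources, columns = targets) with
#'   attribute `species`.
#' @export
cohort_fingerprints <- function(fc_list, sources, targets,
                                species = NA_character_) {
  profs <- vapply(sources, function(src) {
    rowMeans(vapply(fc_list, function(fc) {
      build_fingerprint(fc, src, targets, species)$profile
    }, numeric(length(targets))), na.rm = TRUE)
  }, numeric(length(targets)))
  out <- t(profs)
  dimnames(out) <- list(sources, targets)
  attr(out, "species") <- species
  out
}

similarity_fun <- function(metric) {
  switch(metric,
    cosine = function(a, b) {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) return(0)
      sum(a * b) / (na * nb)
    },
    pearson = function(a, b) suppressWarnings(cor(a, b)),
    manhattan = function(a, b) -sum(abs(a - b)),
    stop("unknown similarity metric: ", metric)
  )
}

#' Match regions across two cohorts by fingerprint similarity
#'
#' Ranks every cohort-B candidate region against each cohort-A source region
#' by the similarity of their mean connectivity fingerprints (cosine by
#' default; Pearson-across-targets and negative Manhattan distance as
#' options). A permutation p-value for the top match is obtained by
#' shuffling the target entries of the source profile.
#'
#' @param fingerprints_a,fingerprints_b matrices from
#'   [cohort_fingerprints()] with identical target columns in the same
#'   order.
#' @param metric similarity metric.
#' @param n_perm permutations for the top-match p-value (default 1000).
#' @return data.frame with one row per (source, candidate) pair: `source`,
#'   `rank`, `candidate`, `similarity`, and `p_perm` on each source's
#'   top-ranked row (NA elsewhere).
#' @export
match_regions <- function(fingerprints_a, fingerprints_b,
                          metric = c("cosine", "pearson", "manhattan"),
                          n_perm = 1000) {
  metric <- match.arg(metric)
  if (!identical(colnames(fingerprints_a), colnames(fingerprints_b))) {
    stop("match_regions: cohorts must share the same target list in the same order")
  }
  simf <- similarity_fun(metric)
  res <- list()
  for (src in rownames(fingerprints_a)) {
    a <- fingerprints_a[src, ]
    sims <- vapply(rownames(fingerprints_b),
                   function(cand) simf(a, fingerprints_b[cand, ]), numeric(1))
    ord <- order(sims, decreasing = TRUE)
    p_perm <- NA_real_
    if (n_perm > 0) {
      top <- fingerprints_b[rownames(fingerprints_b)[ord[1]], ]
      obs <- sims[ord[1]]
      exceed <- sum(vapply(seq_len(n_perm), function(k) {
        simf(a[sample.int(length(a))], top) >= obs
      }, numeric(1)))
      p_perm <- (1 + exceed) / (n_perm + 1)
    }
    res[[src]] <- data.frame(
      source = src, rank = seq_along(ord),
      candidate = rownames(fingerprints_b)[ord],
      similarity = unname(sims[ord]),
      p_perm = c(p_perm, rep(NA_real_, length(ord) - 1))
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
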