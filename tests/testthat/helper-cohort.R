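# Shared fixtures: small configurations and a cached planted cohort so the
# expensive generation/preprocessing happens once per test run.

planted_edges_default <- function() {
  list(
    periphery = data.frame(i = c(1, 3, 5, 7, 9), j = c(2, 4, 6, 8, 10),
                           coupling_rho = 0.8, fc_gain = 0.36),
    core = data.frame(i = c(11, 13, 15, 17, 19, 21, 23),
                      j = c(12, 14, 16, 18, 20, 22, 24),
                      group_effect_d = 1.5)
  )
}

# A small, fast cohort for structural tests (few regions, short runs).
tiny_config <- function(seed = 1, ...) {
  cohort_config(n_success = 3, n_fail = 4, n_regions = 6,
                volumes_per_run = 40, runs_per_tp = 2, spike_prob = 0,
                seed = seed, ...)
}

cohort_cache <- new.env(parent = emptyenv())

# One full-size planted cohort plus its FC/edge tables, cached.
planted_fixture <- function() {
  if (is.null(cohort_cache$planted)) {
    co <- generate_cohort(planted_cohort_config(seed = 42))
    fcs <- cohort_fc(co)
    complete <- co$manifest$dog_id[co$manifest$complete]
    et_long <- suppressMessages(
      build_edge_table(fcs[complete], c("TP1", "TP2", "TP3")))
    et_tp1 <- suppressMessages(build_edge_table(fcs, "TP1"))
    cohort_cache$planted <- list(cohort = co, fcs = fcs,
                                 et_long = et_long, et_tp1 = et_tp1)
  }
  cohort_cache$planted
}

# Direct construction of an edge_table from a dogs x timepoints x edges
# array, bypassing the FC stage (for statistical unit tests).
make_edge_table <- function(values, n_regions,
                            timepoints = c("TP1", "TP2", "TP3")) {
  dogs <- sprintf("dog%02d", seq_len(dim(values)[1]))
  dimnames(values) <- list(dogs, timepoints, NULL)
  structure(list(edges = edge_pairs(n_regions), values = values, dogs = dogs,
                 timepoints = timepoints,
                 region_labels = sprintf("R%02d", seq_len(n_regions)),
                 scale = "fisher_z"),
            class = "edge_table")
}

make_behavior <- function(ibs_by_tp) {
  # ibs_by_tp: dogs x timepoints matrix of IBS values
  dogs <- sprintf("dog%02d", seq_len(nrow(ibs_by_tp)))
  do.call(rbind, lapply(seq_len(ncol(ibs_by_tp)), function(t) {
    data.frame(dog_id = dogs, timepoint = sprintf("TP%d", t),
               retrieve = 3, hunt = 3, environment = 3,
               ibs = ibs_by_tp[, t])
  }))
}

# Brute-force AUC oracle: all-pairs concordance with half credit for ties.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
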