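# End-to-end orchestration: synth -> prep -> FC -> periphery + core ->
# classification -> fingerprint matching -> report bundle.

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. Thresholds follow the
#' study design: periphery selection at 0.05 uncorrected, core selection at
#' 0.01 with the successful group stronger, 1000 stratified 75/25 shuffles.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed controlling cohort generation and every
#'   stochastic stage.
#' @param cohort a [cohort_config()]; default [planted_cohort_config()]
#'   with this seed.
#' @param fd_threshold_mm,head_radius_mm,band,filter preprocessing settings
#'   (see [preprocess_run()]).
#' @param alpha_periphery,alpha_core selection thresholds.
#' @param one_sided_increase,strict_periphery see [select_periphery()].
#' @param n_iterations,test_fraction,lambda classifier settings.
#' @param mode `"full_sample"` (feature selection on the full TP1 data
#'   before cross-validation) or `"nested"` (selection repeated inside every
#'   training fold; recommended, see vignette).
#' @param homology_sources,homology_n_targets fingerprint demo settings: the
#'   source regions matched against a label-permuted copy of the cohort
#'   connectome, and the number of target regions (19 by convention).
#' @param homology_metric,homology_noise_sd,n_perm fingerprint similarity
#'   metric, profile noise added to the comparison cohort, and permutations.
#' @param write_matrices write per-dog FC matrices as CSV (default TRUE).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("caninefc_run_"), seed = 1L,
                       cohort = NULL,
                       fd_threshold_mm = 0.2, head_radius_mm = 50,
                       band = c(0.01, 0.1), filter = "ideal",
                       alpha_periphery = 0.05, alpha_core = 0.01,
                       one_sided_increase = FALSE, strict_periphery = FALSE,
                       n_iterations = 1000, test_fraction = 0.25, lambda = 1,
                       mode = c("full_sample", "nested"),
                       homology_sources = 10, homology_n_targets = 19,
                       homology_metric = "cosine", homology_noise_sd = 0,
                       n_perm = 1000, write_matrices = TRUE) {
  mode <- match.arg(mode)
  if (is.null(cohort)) cohort <- planted_cohort_config(seed = seed)
  stopifnot(alpha_periphery > 0, alpha_periphery < 1,
            alpha_core > 0, alpha_core < 1,
            test_fraction > 0, test_fraction < 1, n_iterations >= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 fd_threshold_mm = fd_threshold_mm,
                 head_radius_mm = head_radius_mm, band = band, filter = filter,
                 alpha_periphery = alpha_periphery, alpha_core = alpha_core,
                 one_sided_increase = one_sided_increase,
                 strict_periphery = strict_periphery,
                 n_iterations = as.integer(n_iterations),
                 test_fraction = test_fraction, lambda = lambda, mode = mode,
                 homology_sources = homology_sources,
                 homology_n_targets = homology_n_targets,
                 homology_metric = homology_metric,
                 homology_noise_sd = homology_noise_sd,
                 n_perm = as.integer(n_perm),
                 write_matrices = write_matrices),
            class = "run_config")
}

config_hash <- function(config) {
  x <- unclass_rec(config)
  x$out_dir <- NULL  # the hash identifies the analysis, not its destination
  x$write_matrices <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(f))
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}

subset_edge_table <- function(edge_table, dogs) {
  keep <- edge_table$dogs %in% dogs
  structure(list(edges = edge_table$edges,
                 values = edge_table$values[keep, , , drop = FALSE],
                 dogs = edge_table$dogs[keep],
                 timepoints = edge_table$timepoints,
                 region_labels = edge_table$region_labels,
                 scale = edge_table$scale),
            class = "edge_table")
}

#' Classify training success from the three feature sets
#'
#' In `"full_sample"` mode the periphery and core edge sets supplied (the
#' full-sample selections) are used as fixed features; in `"nested"` mode
#' the core and periphery selections are recomputed inside every training
#' fold, so held-out dogs never influence feature selection.
#'
#' @param edge_table_tp1 `edge_table` over all dogs at TP1.
#' @param edge_table_long `edge_table` over complete dogs at all timepoints
#'   (needed for nested periphery selection; may be NULL in full-sample
#'   mode).
#' @param behavior,labels cohort behavior table and outcome labels.
#' @param periphery_edges,core_edges full-sample selections (data.frames
#'   with `i`, `j`).
#' @param mode,alpha_periphery,alpha_core,one_sided_increase,n_iterations,test_fraction,lambda
#'   see [run_config()].
#' @return Named list of `classifier_result`s (`behavior`, `periphery`,
#'   `core`).
#' @export
classify_cohort <- function(edge_table_tp1, edge_table_long, behavior, labels,
                            periphery_edges, core_edges,
                            mode = "full_sample",
                            alpha_periphery = 0.05, alpha_core = 0.01,
                            one_sided_increase = FALSE,
                            n_iterations = 1000, test_fraction = 0.25,
                            lambda = 1) {
  if (mode == "full_sample") {
    return(compare_feature_sets(edge_table_tp1, behavior, labels,
                                periphery_edges, core_edges,
                                n_iterations, test_fraction, lambda))
  }
  dogs <- edge_table_tp1$dogs
  y <- check_labels(labels, dogs)
  N <- length(edge_table_tp1$region_labels)
  tp1 <- matrix(edge_table_tp1$values[, "TP1", ], nrow = length(dogs))
  core_selector <- function(train) {
    sub <- subset_edge_table(edge_table_tp1, dogs[train])
    sel <- select_core(group_difference_test(sub, y[train], "TP1"), alpha_core)
    if (!nrow(sel)) integer(0) else edge_ids(sel[, c("i", "j")], N)
  }
  periphery_selector <- function(train) {
    if (is.null(edge_table_long)) return(integer(0))
    tr_dogs <- intersect(dogs[train], edge_table_long$dogs)
    if (length(tr_dogs) < 4) return(integer(0))
    sub <- subset_edge_table(edge_table_long, tr_dogs)
    st <- select_periphery(periphery_stats(sub, behavior),
                           alpha_periphery, one_sided_increase)
    sel <- st[st$selected, , drop = FALSE]
    if (!nrow(sel)) integer(0) else edge_ids(sel[, c("i", "j")], N)
  }
  list(
    behavior = stratified_shuffle_eval(
      matrix(ibs_by_dog(behavior, dogs, "TP1"), ncol = 1), y,
      n_iterations, test_fraction, lambda),
    periphery = stratified_shuffle_eval(tp1, y, n_iterations, test_fraction,
                                        lambda, selector = periphery_selector),
    core = stratified_shuffle_eval(tp1, y, n_iterations, test_fraction,
                                   lambda, selector = core_selector)
  )
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Export a subnetwork in BrainNet Viewer .node/.edge text format
#'
#' Without an anatomical atlas the node coordinates are a circular layout
#' (display convenience only); node size encodes degree within the
#' subnetwork and color encodes membership.
#'
#' @param region_labels all region labels.
#' @param edges data.frame with `i`, `j` (and optionally `weight`).
#' @param prefix output path prefix (writes `<prefix>.node`,
#'   `<prefix>.edge`).
#' @return Invisibly, the two file paths.
#' @export
export_brainnet <- function(region_labels, edges, prefix) {
  N <- length(region_labels)
  ang <- 2 * pi * (seq_len(N) - 1) / N
  deg <- tabulate(c(edges$i, edges$j), nbins = N)
  nodes <- data.frame(x = round(50 * cos(ang), 3), y = round(50 * sin(ang), 3),
                      z = 0, color = as.integer(deg > 0), size = pmax(1, deg),
                      label = region_labels)
  w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
  m <- matrix(0, N, N)
  if (nrow(edges)) {
    m[cbind(edges$i, edges$j)] <- w
    m[cbind(edges$j, edges$i)] <- w
  }
  node_f <- paste0(prefix, ".node"); edge_f <- paste0(prefix, ".edge")
  utils::write.table(nodes, node_f, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(m, edge_f, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(c(node_f, edge_f))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: cohort generation, temporal preprocessing + FC, periphery
#' selection, core selection + stability, three-way classification,
#' fingerprint matching against a label-permuted copy of the cohort
#' connectome (a self-match validation in place of a second species), and a
#' report bundle under `config$out_dir`. Identical config + seed reproduce
#' every output byte for byte; a failing stage aborts with a stage-named
#' error, preserving completed outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  cohort <- stage("synth", generate_cohort(config$cohort))
  set.seed(seed + 1L)  # downstream stochastic stages, decoupled from synth
  write_stamped_csv(cohort$manifest, file.path(config$out_dir, "manifest.csv"),
                    hash, seed)
  write_stamped_csv(cohort$behavior, file.path(config$out_dir, "behavior.csv"),
                    hash, seed)
  tick("synth")

  fcs <- stage("prep_fc", cohort_fc(cohort, config$fd_threshold_mm,
                                    config$head_radius_mm, config$band,
                                    config$filter))
  complete_dogs <- cohort$manifest$dog_id[cohort$manifest$complete]
  et_long <- stage("prep_fc", suppressMessages(
    build_edge_table(fcs[complete_dogs], tp_labels(config$cohort$n_timepoints))))
  et_tp1 <- stage("prep_fc", suppressMessages(build_edge_table(fcs, "TP1")))
  if (config$write_matrices) {
    edge_long <- do.call(rbind, lapply(et_tp1$dogs, function(d) {
      do.call(rbind, lapply(names(fcs[[d]]), function(tp) {
        fc <- fcs[[d]][[tp]]
        data.frame(dog_id = d, timepoint = tp,
                   i = et_tp1$edges[, 1], j = et_tp1$edges[, 2],
                   value = t(fc$values)[t(upper.tri(fc$values))])
      }))
    }))
    write_stamped_csv(edge_long, file.path(config$out_dir, "edge_table.csv"),
                      hash, seed)
  }
  tick("prep_fc")

  peri <- stage("periphery", select_periphery(
    periphery_stats(et_long, cohort$behavior),
    config$alpha_periphery, config$one_sided_increase,
    config$strict_periphery))
  peri_sel <- peri[peri$selected, , drop = FALSE]
  write_stamped_csv(peri, file.path(config$out_dir, "periphery.csv"),
                    hash, seed)
  export_brainnet(et_long$region_labels, peri_sel,
                  file.path(config$out_dir, "periphery"))
  tick("periphery")

  gdt <- stage("core", group_difference_test(et_tp1, cohort$manifest, "TP1"))
  core_sel <- select_core(gdt, config$alpha_core)
  stability <- if (nrow(core_sel)) {
    stage("core", verify_core_stability(et_long, cohort$manifest, core_sel))
  } else NULL
  core_out <- if (nrow(core_sel)) {
    cbind(core_sel, stable = stability$stable)
  } else cbind(core_sel, stable = logical(0))
  write_stamped_csv(core_out, file.path(config$out_dir, "core.csv"),
                    hash, seed)
  export_brainnet(et_tp1$region_labels, core_sel,
                  file.path(config$out_dir, "core"))
  tick("core")

  cls <- stage("classify", classify_cohort(
    et_tp1, et_long, cohort$behavior, cohort$manifest,
    peri_sel, core_sel, config$mode,
    config$alpha_periphery, config$alpha_core, config$one_sided_increase,
    config$n_iterations, config$test_fraction, config$lambda))
  cls_json <- list(
    config_hash = hash, seed = seed, mode = config$mode,
    n_iterations = config$n_iterations, test_fraction = config$test_fraction,
    results = lapply(cls, function(r) {
      if (isTRUE(r$not_applicable)) list(not_applicable = TRUE)
      else list(auc = r$auc, mean_iteration_auc = r$mean_iteration_auc,
                roc = r$roc)
    }))
  jsonlite::write_json(cls_json, file.path(config$out_dir, "classifier.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  tick("classify")

  hom <- stage("homology", {
    n_src <- config$homology_sources
    labels_all <- et_tp1$region_labels
    n_tgt <- min(config$homology_n_targets, length(labels_all) - n_src)
    sources <- labels_all[seq_len(n_src)]
    targets <- utils::tail(labels_all, n_tgt)
    mean_fc <- lapply(complete_dogs, function(d) fcs[[d]][["TP1"]])
    fpA <- cohort_fingerprints(mean_fc, sources, targets, species = "cohort_a")
    # Comparison cohort: same connectome, source labels permuted (+ noise).
    perm <- sample(n_src)
    fpB <- fpA[perm, , drop = FALSE]
    rownames(fpB) <- paste0("b_", rownames(fpA))
    if (config$homology_noise_sd > 0) {
      fpB <- fpB + rnorm(length(fpB), 0, config$homology_noise_sd)
    }
    attr(fpB, "species") <- "cohort_b"
    mr <- match_regions(fpA, fpB, config$homology_metric, config$n_perm)
    truth <- setNames(paste0("b_", sources), sources[perm])
    top <- mr[mr$rank == 1, ]
    recovered <- mean(truth[top$source] == top$candidate)
    list(matches = mr, recovered_fraction = recovered)
  })
  write_stamped_csv(hom$matches, file.path(config$out_dir, "homology.csv"),
                    hash, seed)
  tick("homology")

  summary <- list(
    config_hash = hash, seed = seed,
    n_dogs = nrow(cohort$manifest), n_complete = length(complete_dogs),
    n_regions = config$cohort$n_regions,
    periphery_selected = nrow(peri_sel),
    periphery_edges = peri_sel[, c("i", "j")],
    core_selected = nrow(core_sel),
    core_edges = core_sel[, c("i", "j")],
    core_stable = if (is.null(stability)) 0L else sum(stability$stable),
    auc = lapply(cls, function(r) if (isTRUE(r$not_applicable)) NA else r$auc),
    mean_iteration_auc = lapply(cls, function(r) {
      if (isTRUE(r$not_applicable)) NA else r$mean_iteration_auc
    }),
    homology_recovered_fraction = hom$recovered_fraction
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE)
  # Timings are logged separately: they vary run to run, the summary must not.
  writeLines(c(sprintf("config_hash=%s seed=%d", hash, seed),
               sprintf("%s: %.3f s", names(timings), unlist(timings))),
             file.path(config$out_dir, "pipeline.log"))
  summary$stage_seconds <- as.list(timings)
  invisible(summary)
}
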