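# Synthetic cohort generator: behavior, target connectomes, time series,
# motion traces, and cohort orchestration with recorded ground truth.

tp_labels <- function(n) sprintf("TP%d", seq_len(n))

#' Generate integrated behavioral scores for a cohort
#'
#' Each dog receives latent retrieve / hunt / environmental-soundness
#' subscores at TP1 (successful dogs drawn with a higher latent mean), gains
#' `behavior_gain_mean` IBS points on average from TP1 to TP2 (across-dog SD
#' `behavior_gain_sd`, split evenly over the three subscores), and drifts
#' only by noise from TP2 on. Observed subscores are the latent values
#' rounded and clipped to the ordinal 1-5 rubric; IBS is their sum.
#'
#' @param config a [cohort_config()].
#' @param labels optional logical vector (TRUE = successful) per dog;
#'   defaults to `n_success` successes followed by `n_fail` failures.
#' @param dog_ids optional character ids.
#' @return data.frame with columns `dog_id`, `timepoint`, `retrieve`,
#'   `hunt`, `environment`, `ibs`.
#' @export
generate_behavior <- function(config, labels = NULL, dog_ids = NULL) {
  n_dogs <- config$n_success + config$n_fail
  if (is.null(labels)) {
    labels <- rep(c(TRUE, FALSE), c(config$n_success, config$n_fail))
  }
  if (is.null(dog_ids)) dog_ids <- sprintf("dog%02d", seq_len(n_dogs))
  stopifnot(length(labels) == n_dogs, length(dog_ids) == n_dogs)
  n_tp <- config$n_timepoints

  # Misconfiguration guard: a gain that pushes most latent subscores outside
  # the rubric signals a broken configuration rather than a usable cohort.
  mu2 <- config$subscore_base_mean + max(0, config$subscore_success_shift) +
    config$behavior_gain_mean / 3
  sd2 <- sqrt(config$subscore_sd^2 + (config$behavior_gain_sd / 3)^2)
  p_out <- if (sd2 > 0) {
    pnorm(0.5, mu2, sd2) + pnorm(5.5, mu2, sd2, lower.tail = FALSE)
  } else {
    as.numeric(mu2 < 0.5 || mu2 > 5.5)
  }
  if (p_out > 0.5) {
    stop("behavior_gain_mean forces subscores outside [1,5] more than 50% ",
         "of the time; check the configuration")
  }

  obs <- function(latent) {
    latent[] <- pmin(5, pmax(1, round(latent)))
    latent
  }
  rows <- vector("list", n_dogs)
  for (d in seq_len(n_dogs)) {
    base <- config$subscore_base_mean +
      config$subscore_success_shift * labels[d] +
      rnorm(3, 0, config$subscore_sd)
    gain <- config$behavior_gain_mean + config$behavior_gain_sd * rnorm(1)
    latent <- matrix(NA_real_, n_tp, 3)
    latent[1, ] <- base
    if (n_tp >= 2) latent[2, ] <- base + gain / 3
    if (n_tp >= 3) {
      for (t in 3:n_tp) {
        latent[t, ] <- latent[t - 1, ] + rnorm(3, 0, config$behavior_tp3_sd)
      }
    }
    sc <- obs(latent)
    rows[[d]] <- data.frame(
      dog_id = dog_ids[d], timepoint = tp_labels(n_tp),
      retrieve = sc[, 1], hunt = sc[, 2], environment = sc[, 3],
      ibs = rowSums(sc)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nearest correlation matrix by alternating projections
#'
#' Projects a symmetric matrix onto the set of unit-diagonal positive
#' semi-definite matrices (Higham's alternating-projection algorithm, via
#' [Matrix::nearPD]). An input that is already a valid correlation matrix is
#' returned unchanged.
#'
#' @param x symmetric numeric matrix with unit diagonal.
#' @param tol convergence / PSD tolerance (default 1e-8).
#' @return The repaired correlation matrix.
#' @export
nearest_correlation <- function(x, tol = 1e-8) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == ncol(x), max(abs(x - t(x))) < 1e-10)
  ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol) return(x)  # fixed point: valid input passes through
  res <- Matrix::nearPD(x, corr = TRUE, conv.tol = tol, eig.tol = tol,
                        maxit = 500, do2eigen = TRUE)
  if (!res$converged) stop("nearest_correlation: repair did not converge")
  out <- as.matrix(res$mat)
  dimnames(out) <- dimnames(x)
  out
}

# Per-dog latent state: baseline connectome + planted Fisher-z offsets.
#
# Baseline model: r_ij = c * <u_i, u_j> with unit random directions u_i in
# R^k and c = noise_sd * sqrt(k), i.e. B = c U U' + (1 - c) I. This has unit
# diagonal, off-diagonal SD exactly noise_sd, and smallest eigenvalue >=
# 1 - c, so planted offsets rarely break positive definiteness.
make_dog_state <- function(config, success, ibs_delta_std) {
  k <- config$n_latent_factors
  N <- config$n_regions
  c_mix <- config$noise_sd * sqrt(k)
  U <- matrix(rnorm(N * k), N, k)
  U <- U / sqrt(rowSums(U^2))
  pe <- config$periphery_edges
  ce <- config$core_edges
  periph_gain <- numeric(0)
  periph_tp1 <- numeric(0)
  if (!is.null(pe) && nrow(pe)) {
    noise <- rnorm(nrow(pe))
    periph_gain <- pe$fc_gain + config$periphery_spread_sd *
      (pe$coupling_rho * ibs_delta_std +
         sqrt(1 - pe$coupling_rho^2) * noise)
    periph_tp1 <- rep(config$periphery_group_d * config$noise_sd * success,
                      nrow(pe))
  }
  core_off <- numeric(0)
  if (!is.null(ce) && nrow(ce)) {
    core_off <- ce$group_effect_d * config$noise_sd * success
  }
  list(U = U, c_mix = c_mix, success = success,
       periph_gain = periph_gain, periph_tp1 = periph_tp1,
       core_off = core_off)
}

# Fisher-z offsets relative to the dog's baseline at one timepoint.
planted_offsets <- function(config, state, tp_index) {
  off <- list()
  pe <- config$periphery_edges
  ce <- config$core_edges
  if (!is.null(pe) && nrow(pe)) {
    z <- state$periph_tp1
    if (tp_index >= 2) z <- z + state$periph_gain
    off$periphery <- z
  }
  if (!is.null(ce) && nrow(ce)) off$core <- state$core_off
  off
}

assemble_target <- function(config, state, tp_index, gamma) {
  B <- (gamma * state$c_mix) * tcrossprod(state$U)
  diag(B) <- 1
  off <- planted_offsets(config, state, tp_index)
  apply_off <- function(B, edges, z) {
    for (e in seq_len(nrow(edges))) {
      i <- edges$i[e]; j <- edges$j[e]
      r <- tanh(atanh(B[i, j]) + z[e])
      r <- max(-0.98, min(0.98, r))
      B[i, j] <- B[j, i] <- r
    }
    B
  }
  if (!is.null(off$periphery)) B <- apply_off(B, config$periphery_edges, off$periphery)
  if (!is.null(off$core)) B <- apply_off(B, config$core_edges, off$core)
  B
}

# Build the target correlation matrices for one dog at every timepoint,
# shrinking the baseline toward the identity (same factor at all timepoints,
# so within-dog timepoint differences equal the planted offsets exactly) if
# the planted offsets would otherwise break positive definiteness.
build_dog_targets <- function(config, state, psd_tol = 0.02) {
  n_tp <- config$n_timepoints
  eigmin_all <- function(gamma) {
    min(vapply(seq_len(n_tp), function(tp) {
      min(eigen(assemble_target(config, state, tp, gamma),
                symmetric = TRUE, only.values = TRUE)$values)
    }, numeric(1)))
  }
  gamma <- 1
  if (eigmin_all(1) < psd_tol) {
    lo <- 0; hi <- 1
    for (it in 1:12) {
      mid <- (lo + hi) / 2
      if (eigmin_all(mid) >= psd_tol) lo <- mid else hi <- mid
    }
    gamma <- lo
  }
  targets <- lapply(seq_len(n_tp), function(tp) {
    tgt <- assemble_target(config, state, tp, gamma)
    if (min(eigen(tgt, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
      tgt <- nearest_correlation(tgt)  # safety net, rarely reached
    }
    tgt
  })
  names(targets) <- tp_labels(n_tp)
  list(targets = targets, gamma = gamma)
}

#' Build the target correlation matrix for one dog at one timepoint
#'
#' Combines the dog's latent baseline connectome with the planted periphery
#' and core Fisher-z offsets for the requested timepoint, guaranteeing a
#' unit-diagonal positive semi-definite result (baseline shrinkage shared
#' across timepoints; alternating-projection repair as a final safety net).
#'
#' @param config a [cohort_config()].
#' @param dog_state per-dog latent state as stored in a cohort's
#'   `truth$states` (baseline factor loadings and planted offsets).
#' @param timepoint timepoint label, e.g. `"TP2"`, or index.
#' @param psd_tol smallest admissible eigenvalue before shrinkage engages.
#' @return N x N target correlation matrix.
#' @export
build_target_fc <- function(config, dog_state, timepoint, psd_tol = 0.02) {
  tp <- if (is.character(timepoint)) match(timepoint, tp_labels(config$n_timepoints)) else as.integer(timepoint)
  stopifnot(!is.na(tp), tp >= 1, tp <= config$n_timepoints)
  build_dog_targets(config, dog_state, psd_tol)$targets[[tp]]
}

#' Sample a stationary ROI time series with a given correlation target
#'
#' Draws T rows from a zero-mean Gaussian process whose stationary
#' cross-correlation equals `target_fc` (independent volumes by default; an
#' AR(1) temporal kernel, identical across regions, leaves the spatial
#' correlation unchanged and is available via `ar1`).
#'
#' @param target_fc positive semi-definite correlation matrix.
#' @param volumes number of volumes T.
#' @param tr_seconds repetition time.
#' @param ar1 lag-one autocorrelation in (0, 1); 0 disables.
#' @return A [roi_timeseries()].
#' @export
generate_timeseries <- function(target_fc, volumes, tr_seconds = 1, ar1 = 0) {
  target_fc <- as.matrix(target_fc)
  N <- ncol(target_fc)
  stopifnot(nrow(target_fc) == N, max(abs(target_fc - t(target_fc))) < 1e-8,
            max(abs(diag(target_fc) - 1)) < 1e-8, volumes >= 10,
            ar1 >= 0, ar1 < 1)
  R <- tryCatch(chol(target_fc + diag(1e-10, N)),
                error = function(e) stop("generate_timeseries: target is not positive semi-definite"))
  Z <- matrix(rnorm(volumes * N), volumes, N)
  if (ar1 > 0) {
    for (t in 2:volumes) Z[t, ] <- ar1 * Z[t - 1, ] + sqrt(1 - ar1^2) * Z[t, ]
  }
  samples <- Z %*% R
  labels <- colnames(target_fc)
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(N))
  roi_timeseries(samples, labels, tr_seconds)
}

#' Generate a six-parameter motion trace
#'
#' Baseline drift is a bounded random walk (framewise displacement below
#' 0.01 mm); with probability `spike_prob` a frame receives an additional
#' translation jump of `spike_mm`, so the expected fraction of frames whose
#' FD exceeds 0.2 mm is `spike_prob` whenever `spike_mm` clears the
#' threshold.
#'
#' @param volumes number of frames.
#' @param spike_prob per-frame spike probability in `[0, 1]`.
#' @param spike_mm spike translation magnitude (mm).
#' @param tr_seconds repetition time.
#' @return A [motion_trace()].
#' @export
generate_motion <- function(volumes, spike_prob = 0.02, spike_mm = 0.5,
                            tr_seconds = 1) {
  stopifnot(volumes >= 2, spike_prob >= 0, spike_prob <= 1, spike_mm >= 0)
  dtrans <- matrix(runif(3 * (volumes - 1), -1e-3, 1e-3), volumes - 1, 3)
  drot <- matrix(runif(3 * (volumes - 1), -1e-5, 1e-5), volumes - 1, 3)
  spikes <- runif(volumes - 1) < spike_prob
  if (any(spikes)) {
    axis <- sample.int(3, sum(spikes), replace = TRUE)
    sgn <- sample(c(-1, 1), sum(spikes), replace = TRUE)
    idx <- which(spikes)
    for (s in seq_along(idx)) {
      dtrans[idx[s], axis[s]] <- dtrans[idx[s], axis[s]] + sgn[s] * spike_mm
    }
  }
  translations <- rbind(0, apply(dtrans, 2, cumsum))
  rotations <- rbind(0, apply(drot, 2, cumsum))
  motion_trace(translations, rotations, tr_seconds)
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates behavior, per-dog target connectomes, motion traces and runs
#' for every dog x timepoint, and records the planted ground truth. The
#' per-dog periphery increment is coupled to the dog's realized
#' (rounded-and-summed) IBS change from TP1 to TP2, standardized across the
#' cohort, so the configured `coupling_rho` is the population correlation
#' between the planted Fisher-z FC change and the observed IBS change.
#' Identical config and seed reproduce the cohort bit for bit.
#'
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_cohort` with elements `config`,
#'   `manifest`, `behavior`, `truth` (planted edges, per-dog offsets, target
#'   matrices, shrinkage factors) and `runs` / `motion` (nested
#'   `[[dog_id]][[timepoint]][[run]]`).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n_dogs <- config$n_success + config$n_fail
  n_tp <- config$n_timepoints
  dog_ids <- sprintf("dog%02d", seq_len(n_dogs))
  labels <- rep(c(TRUE, FALSE), c(config$n_success, config$n_fail))

  # Sex ratio follows the 17M/13F make-up of the usable TP1 sample.
  n_male <- round(n_dogs * 17 / 30)
  sex <- rep("F", n_dogs)
  sex[sample.int(n_dogs, n_male)] <- "M"

  # Incomplete dogs (scans at TP1 only), drawn from both outcome groups in
  # proportion; behavior assessments are retained at every timepoint.
  complete <- rep(TRUE, n_dogs)
  n_complete <- if (is.null(config$n_complete)) n_dogs else config$n_complete
  n_drop <- n_dogs - n_complete
  if (n_drop > 0) {
    drop_s <- min(config$n_success, round(n_drop * config$n_success / n_dogs))
    drop_f <- n_drop - drop_s
    idx_s <- sample(which(labels), drop_s)
    idx_f <- sample(which(!labels), drop_f)
    complete[c(idx_s, idx_f)] <- FALSE
  }
  manifest <- data.frame(dog_id = dog_ids, sex = sex,
                         label = ifelse(labels, "successful", "non_successful"),
                         complete = complete)

  behavior <- generate_behavior(config, labels, dog_ids)

  # Standardized realized IBS change TP1 -> TP2 drives the coupling.
  ibs_delta_std <- rep(0, n_dogs)
  if (n_tp >= 2) {
    ibs <- matrix(behavior$ibs, nrow = n_tp)  # timepoints x dogs
    d_ibs <- ibs[2, ] - ibs[1, ]
    s <- sd(d_ibs)
    if (is.finite(s) && s > 0) ibs_delta_std <- (d_ibs - mean(d_ibs)) / s
  }

  states <- vector("list", n_dogs)
  targets <- vector("list", n_dogs)
  gammas <- numeric(n_dogs)
  runs <- vector("list", n_dogs)
  motion <- vector("list", n_dogs)
  names(states) <- names(targets) <- names(runs) <- names(motion) <- dog_ids
  region_labels <- sprintf("R%02d", seq_len(config$n_regions))

  for (d in seq_len(n_dogs)) {
    states[[d]] <- make_dog_state(config, labels[d], ibs_delta_std[d])
    built <- build_dog_targets(config, states[[d]])
    gammas[d] <- built$gamma
    tps <- if (complete[d]) seq_len(n_tp) else 1L
    targets[[d]] <- built$targets
    runs[[d]] <- motion[[d]] <- setNames(vector("list", n_tp), tp_labels(n_tp))
    for (tp in tps) {
      tgt <- built$targets[[tp]]
      dimnames(tgt) <- list(region_labels, region_labels)
      rlist <- mlist <- vector("list", config$runs_per_tp)
      for (r in seq_len(config$runs_per_tp)) {
        mlist[[r]] <- generate_motion(config$volumes_per_run,
                                      config$spike_prob, config$spike_mm,
                                      config$tr_seconds)
        rlist[[r]] <- generate_timeseries(tgt, config$volumes_per_run,
                                          config$tr_seconds)
      }
      runs[[d]][[tp]] <- rlist
      motion[[d]][[tp]] <- mlist
    }
  }

  structure(
    list(config = config, manifest = manifest, behavior = behavior,
         truth = list(periphery_edges = config$periphery_edges,
                      core_edges = config$core_edges,
                      states = states, targets = targets, gammas = gammas,
                      ibs_delta_std = ibs_delta_std),
         runs = runs, motion = motion),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d dogs (%d successful), %d regions, %d timepoints, %d complete\n",
    nrow(x$manifest), sum(x$manifest$label == "successful"),
    x$config$n_regions, x$config$n_timepoints, sum(x$manifest$complete)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the package's plain-text layout
#'
#' Per-run time-series TSVs (header = region labels), per-run motion TSVs
#' (tx, ty, tz in mm; rx, ry, rz in radians), a cohort manifest CSV, a
#' behavior CSV and a planted-truth JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest of written run files.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (d in cohort$manifest$dog_id) {
    for (tp in names(cohort$runs[[d]])) {
      rl <- cohort$runs[[d]][[tp]]
      if (is.null(rl)) next
      for (r in seq_along(rl)) {
        ts_file <- file.path(dir, sprintf("%s_%s_run%d_bold.tsv", d, tp, r))
        mo_file <- file.path(dir, sprintf("%s_%s_run%d_motion.tsv", d, tp, r))
        utils::write.table(rl[[r]]$samples, ts_file, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        mo <- cohort$motion[[d]][[tp]][[r]]
        mp <- cbind(mo$translations, mo$rotations)
        colnames(mp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
        utils::write.table(mp, mo_file, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        files[[length(files) + 1L]] <- data.frame(
          dog_id = d,
          sex = cohort$manifest$sex[cohort$manifest$dog_id == d],
          label = cohort$manifest$label[cohort$manifest$dog_id == d],
          timepoint = tp, run = r, file = basename(ts_file),
          motion_file = basename(mo_file))
      }
    }
  }
  run_manifest <- do.call(rbind, files)
  write.csv(run_manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$behavior, file.path(dir, "behavior.csv"), row.names = FALSE)
  truth <- list(
    seed = cohort$config$seed,
    periphery_edges = cohort$truth$periphery_edges,
    core_edges = cohort$truth$core_edges,
    gammas = cohort$truth$gammas
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(run_manifest)
}

#' Read one run's time series and motion trace from the on-disk layout
#'
#' @param ts_file path to a `*_bold.tsv` written by [write_cohort()].
#' @param motion_file path to the matching `*_motion.tsv`.
#' @param tr_seconds repetition time.
#' @return List with elements `ts` ([roi_timeseries()]) and `motion`
#'   ([motion_trace()]).
#' @export
read_run <- function(ts_file, motion_file, tr_seconds = 1) {
  samples <- as.matrix(utils::read.delim(ts_file, check.names = FALSE))
  mp <- as.matrix(utils::read.delim(motion_file))
  list(ts = roi_timeseries(samples, colnames(samples), tr_seconds),
       motion = motion_trace(mp[, 1:3], mp[, 4:6], tr_seconds))
}
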