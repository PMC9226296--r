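# Synthetic-cohort generators. Two tiers:
#   tier A - ROI time series with state-switching covariance, exercising the
#            full pipeline end-to-end (no exact metric targets: engineering
#            BOLD signals to hit exact graph-metric values is ill-posed);
#   tier B - property matrices with an injected per-region linear gradient,
#            giving exact ground truth for the TGI estimator.
# Every generator is deterministic given its seed.

#' Build a contiguous block partition
#'
#' @param n_regions total region count.
#' @param module_sizes integer vector summing to \code{n_regions}.
#' @param module_names optional names, defaults to \code{M1..Mk}.
#' @param region_labels optional region labels, defaults to \code{R1..Rn}.
#' @return a \code{\link{module_partition}} assigning contiguous blocks of
#'   regions to modules in order.
#' @export
make_partition <- function(n_regions, module_sizes, module_names = NULL,
                           region_labels = NULL) {
  module_sizes <- as.integer(module_sizes)
  if (sum(module_sizes) != n_regions)
    stop_dim("module sizes sum to %d but n_regions = %d",
             sum(module_sizes), n_regions)
  if (any(module_sizes <= 0L)) stop("module sizes must be positive", call. = FALSE)
  if (is.null(module_names)) module_names <- paste0("M", seq_along(module_sizes))
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n_regions))
  module_partition(region_labels, rep(module_names, times = module_sizes))
}

#' Default 274-region, 9-module partition
#'
#' The modular structure used for the participation coefficient: seven
#' cortical functional systems (visual, somatomotor, dorsal attention,
#' ventral attention, limbic, frontoparietal, default), one subcortical
#' module, and one cerebellar module. The subcortical module collects the
#' atlas's amygdala (labels 211-214), caudate (219-220, 227-228), putamen
#' (225-226, 229-230), globus pallidus (221-222), nucleus accumbens
#' (223-224) and thalamus (231-246) regions -- 32 in all; the cerebellar
#' module is labels 247-274 (28 regions). The cortex-to-system assignment is
#' a synthetic default (contiguous blocks over the remaining 214 cortical
#' labels); analyses of real data should supply the atlas's own lookup table
#' via \code{\link{read_partition_table}}.
#'
#' @return a \code{\link{module_partition}} over regions \code{R1..R274}.
#' @export
default_partition <- function() {
  subcortical <- c(211:214, 219:230, 231:246)
  cerebellar <- 247:274
  cortical <- setdiff(1:274, c(subcortical, cerebellar))  # 214 regions
  yeo <- c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
           "limbic", "frontoparietal", "default")
  sizes <- c(31L, 31L, 31L, 31L, 30L, 30L, 30L)
  module <- character(274L)
  module[cortical] <- rep(yeo, times = sizes)
  module[subcortical] <- "subcortical"
  module[cerebellar] <- "cerebellar"
  module_partition(paste0("R", 1:274), module)
}

# Module-structured random correlation matrix: within-module baseline
# correlation rho_in, between-module rho_out, plus a random low-rank
# perturbation, projected to the nearest positive-definite correlation
# matrix by eigenvalue clamping.
random_state_cov <- function(partition, rho_in = 0.35, rho_out = 0.05,
                             jitter = 0.15, max_tries = 5L) {
  n <- length(partition)
  same <- outer(partition$module, partition$module, "==")
  base <- ifelse(same, rho_in, rho_out)
  diag(base) <- 1
  for (k in seq_len(max_tries)) {
    q <- matrix(stats::rnorm(n * 3L), n, 3L)
    pert <- tcrossprod(q) / 3
    pert <- jitter * (pert - diag(diag(pert)))
    s <- base + pert
    e <- eigen(s, symmetric = TRUE)
    vals <- pmax(e$values, 1e-6)
    s <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(s))
    s <- s / tcrossprod(d)
    if (all(eigen(s, symmetric = TRUE, only.values = TRUE)$values > 0))
      return(s)
  }
  stop("failed to construct a positive-definite state covariance", call. = FALSE)
}

# Boost within-module and damp between-module correlation, then re-project.
shift_state_cov <- function(s, partition, shift) {
  if (shift == 0) return(s)
  same <- outer(partition$module, partition$module, "==")
  out <- s
  out[same] <- pmin(out[same] * (1 + shift), 0.99)
  out[!same] <- out[!same] * (1 - shift)
  diag(out) <- 1
  e <- eigen(out, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out / tcrossprod(d)
}

# Geometric dwell-time state sequence over T samples.
state_sequence <- function(T, n_states, dwell_mean) {
  if (n_states == 1L) return(rep(1L, T))
  p_switch <- 1 / dwell_mean
  s <- integer(T)
  cur <- sample.int(n_states, 1L)
  for (t in seq_len(T)) {
    if (t > 1L && stats::runif(1L) < p_switch) {
      cur <- sample(setdiff(seq_len(n_states), cur), 1L)
    }
    s[t] <- cur
  }
  s
}

#' Simulate a two-group cohort of ROI time series (tier A)
#'
#' Each subject is zero-mean multivariate Gaussian noise whose covariance
#' switches among \code{n_states} module-structured positive-definite states
#' with geometric dwell times, so windowed correlation networks fluctuate.
#' Patients (CBP group) draw from state covariances with within-module
#' correlations boosted and between-module correlations damped by
#' \code{cbp_shift}; at \code{cbp_shift = 0} the two groups are exchangeable
#' draws from the same process. Subject metadata (VAS, BDI, age, gender)
#' follow the emulated cohort profile: VAS 6.8 +/- 1.7 for patients
#' (clipped to [0,10]), BDI 6.3 +/- 5.6 vs 1.3 +/- 2.2, age ~ 50 +/- 9.
#'
#' @param n_hc,n_cbp group sizes (defaults 29 and 30, the emulated
#'   post-QC cohort).
#' @param n_regions region count (atlas default 274).
#' @param T time points per subject before truncation (default 245).
#' @param tr repetition time, seconds.
#' @param n_states number of covariance states; use >= 2 so windowed
#'   networks fluctuate beyond sampling noise (1 gives a stationary
#'   process, useful as a control condition).
#' @param dwell_mean mean state dwell time in TRs.
#' @param cbp_shift patient covariance perturbation strength (0 = null).
#' @param seed master seed; identical seeds give identical cohorts.
#' @param partition optional \code{module_partition} (defaults to contiguous
#'   equal-size modules; for \code{n_regions = 274} the
#'   \code{\link{default_partition}}).
#' @return a list with \code{subjects} (list of \code{\link{roi_ts}}),
#'   \code{meta} (data.frame of subject records), \code{partition}, and the
#'   per-group state covariance lists.
#' @export
simulate_cohort_timeseries <- function(n_hc = 29L, n_cbp = 30L,
                                       n_regions = 274L, T = 245L, tr = 2.5,
                                       n_states = 4L, dwell_mean = 30,
                                       cbp_shift = 0, seed = 1L,
                                       partition = NULL) {
  stopifnot(n_states >= 1L, T >= 2L, n_regions >= 2L)
  if (is.null(partition)) {
    partition <- if (n_regions == 274L) default_partition() else {
      k <- max(2L, min(6L, n_regions %/% 3L))
      sizes <- rep(n_regions %/% k, k)
      sizes[seq_len(n_regions - sum(sizes))] <- sizes[seq_len(n_regions - sum(sizes))] + 1L
      make_partition(n_regions, sizes)
    }
  }
  if (length(partition) != n_regions)
    stop_dim("partition covers %d regions, expected %d", length(partition), n_regions)

  states_hc <- with_local_seed(derive_seed(seed, "states"), {
    lapply(seq_len(n_states), function(i) random_state_cov(partition))
  })
  states_cbp <- lapply(states_hc, shift_state_cov, partition = partition,
                       shift = cbp_shift)
  chol_hc <- lapply(states_hc, chol)
  chol_cbp <- lapply(states_cbp, chol)

  ids <- c(sprintf("HC%03d", seq_len(n_hc)), sprintf("CBP%03d", seq_len(n_cbp)))
  grp <- c(rep("HC", n_hc), rep("CBP", n_cbp))

  subjects <- vector("list", n_hc + n_cbp)
  for (i in seq_along(ids)) {
    subjects[[i]] <- with_local_seed(derive_seed(seed, "subject", i), {
      ch <- if (grp[i] == "HC") chol_hc else chol_cbp
      st <- state_sequence(T, n_states, dwell_mean)
      z <- matrix(stats::rnorm(T * n_regions), T, n_regions)
      x <- matrix(0, T, n_regions)
      for (s in seq_len(n_states)) {
        rows <- which(st == s)
        if (length(rows)) x[rows, ] <- z[rows, , drop = FALSE] %*% ch[[s]]
      }
      roi_ts(x, tr = tr, labels = partition$region, subject_id = ids[i])
    })
  }

  meta <- with_local_seed(derive_seed(seed, "meta"), {
    is_cbp <- grp == "CBP"
    vas <- ifelse(is_cbp, pmin(pmax(stats::rnorm(length(ids), 6.8, 1.7), 0), 10), NA_real_)
    bdi <- pmax(ifelse(is_cbp, stats::rnorm(length(ids), 6.3, 5.6),
                       stats::rnorm(length(ids), 1.3, 2.2)), 0)
    age <- pmax(stats::rnorm(length(ids), 50, 8.7), 18)
    gender <- ifelse(stats::runif(length(ids)) < 17 / 29.5, "M", "F")
    data.frame(subject_id = ids, group = grp, vas = vas, bdi = bdi,
               age = age, gender = gender, stringsAsFactors = FALSE)
  })

  list(subjects = subjects, meta = meta, partition = partition,
       states_hc = states_hc, states_cbp = states_cbp)
}

#' Simulate patient property matrices with known gradients (tier B)
#'
#' Inverts the deviation-slope model: given the norm property time course
#' \code{x} per region, a patient's course is
#' \code{y = (1 + k) * x + b + noise}, so the deviation \code{y - x}
#' regressed on \code{x} has true slope \code{k} and intercept \code{b}.
#'
#' @param x_hc_mean a \code{\link{property_matrix}} (t x n) holding the
#'   healthy-control norm property over windows.
#' @param k_true,b_true per-region true slopes and intercepts (length n).
#' @param noise_sd i.i.d. Gaussian noise standard deviation added per window.
#' @param n_patients number of patients to generate.
#' @param seed master seed.
#' @return a list of \code{property_matrix} objects with attributes
#'   \code{k_true}, \code{b_true}, \code{noise_sd}.
#' @export
simulate_property_matrices <- function(x_hc_mean, k_true, b_true,
                                       noise_sd = 0.1, n_patients = 30L,
                                       seed = 1L) {
  stopifnot(inherits(x_hc_mean, "property_matrix"))
  x <- x_hc_mean$data
  n <- ncol(x)
  if (length(k_true) != n || length(b_true) != n)
    stop_dim("k_true/b_true must have length %d", n)
  stopifnot(noise_sd >= 0)
  lapply(seq_len(n_patients), function(i) {
    y <- with_local_seed(derive_seed(seed, "tierB", i), {
      sweep(x, 2L, 1 + k_true, "*") +
        matrix(b_true, nrow(x), n, byrow = TRUE) +
        matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), n)
    })
    out <- property_matrix(y, property = x_hc_mean$property,
                           subject_id = sprintf("CBP%03d", i),
                           labels = x_hc_mean$labels)
    attr(out, "k_true") <- k_true
    attr(out, "b_true") <- b_true
    attr(out, "noise_sd") <- noise_sd
    out
  })
}

#' Simulate VAS pain scores from a feature matrix
#'
#' \code{vas_i = clip(intercept + features_i . weights + noise, 0, 10)}.
#' Warns when more than 5 percent of draws hit the scale bounds, since heavy
#' clipping breaks the linear coupling the generator is meant to provide.
#'
#' @param features numeric subjects x features matrix.
#' @param weights coefficient vector (length = feature count).
#' @param intercept scalar intercept.
#' @param noise_sd Gaussian noise sd.
#' @param seed seed.
#' @return numeric vector of VAS scores in [0, 10].
#' @export
simulate_vas <- function(features, weights, intercept = 5, noise_sd = 0.5,
                         seed = 1L) {
  features <- as.matrix(features)
  if (length(weights) != ncol(features))
    stop_dim("weights length %d != feature count %d",
             length(weights), ncol(features))
  raw <- with_local_seed(derive_seed(seed, "vas"), {
    drop(features %*% weights) + intercept +
      stats::rnorm(nrow(features), 0, noise_sd)
  })
  clipped <- pmin(pmax(raw, 0), 10)
  frac <- mean(clipped != raw)
  if (frac > 0.05)
    warning(sprintf("%.0f%% of simulated VAS values clipped to [0,10]",
                    100 * frac), call. = FALSE)
  clipped
}

#' Simulate a six-parameter rigid-body motion trace
#'
#' A smooth random walk (independent Gaussian increments per axis) plus
#' isolated spikes, for exercising the motion-exclusion rule. Rotation
#' increments are scaled so that, through the head-radius conversion, each
#' rotation axis contributes to framewise displacement on the same mm scale
#' as a translation axis with sd \code{base_sd}.
#'
#' @param T number of time points.
#' @param base_sd per-step increment sd for translations, mm.
#' @param n_spikes number of single-volume impulses.
#' @param spike_amp impulse magnitude, mm (applied to one translation axis).
#' @param seed seed.
#' @param head_radius radius (mm) used for the rotation scale matching.
#' @return a T x 6 matrix, columns \code{trans_x,trans_y,trans_z} (mm) and
#'   \code{rot_x,rot_y,rot_z} (degrees).
#' @export
simulate_motion_trace <- function(T, base_sd = 0.02, n_spikes = 0L,
                                  spike_amp = 3, seed = 1L, head_radius = 50) {
  stopifnot(T >= 1L)
  rot_sd <- base_sd * 180 / (pi * head_radius)  # degrees matching base_sd mm
  with_local_seed(derive_seed(seed, "motion"), {
    tr_inc <- matrix(stats::rnorm(T * 3L, 0, base_sd), T, 3L)
    ro_inc <- matrix(stats::rnorm(T * 3L, 0, rot_sd), T, 3L)
    tr_inc[1L, ] <- 0; ro_inc[1L, ] <- 0
    m <- cbind(apply(tr_inc, 2L, cumsum), apply(ro_inc, 2L, cumsum))
    if (n_spikes > 0L) {
      at <- sample(seq(2L, max(2L, T)), min(n_spikes, T - 1L))
      ax <- sample(1:3, length(at), replace = TRUE)
      for (j in seq_along(at)) m[at[j], ax[j]] <- m[at[j], ax[j]] + spike_amp
    }
    colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    m
  })
}
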