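# Synthetic longitudinal stroke-like cohort: band-limited community BOLD
# time series on a 3-D grid, lesion signal dropout, motion traces, and
# clinical-score trajectories coupled to the injected connectivity change.

#' Community specification for the synthetic cohort
#'
#' A community is a set of voxels sharing one band-limited latent signal.
#' The voxel loading on the latent controls within-community correlation:
#' after band-pass filtering (which keeps the full latent but only the
#' in-band fraction of the white noise) the expected pairwise correlation
#' is `l^2 / (l^2 + f * noise_sd^2)` where `f` is the in-band fraction.
#' Patient loadings evolve linearly in days post-onset from
#' `loading_baseline` with slope `loading_slope_per_day` (clipped at 0);
#' controls sit at the static `control_loading`.
#'
#' @param name community label.
#' @param voxels integer vector of linear voxel indices.
#' @param role `"sensorimotor"`, `"cognitive"` or `"background"`.
#' @param loading_baseline patient loading at day 0.
#' @param loading_slope_per_day patient loading change per day.
#' @param control_loading static control loading.
#' @param latent name of the shared latent signal (communities listing the
#'   same latent are long-range coupled, e.g. bilateral homologues).
#' @return a `community_spec` list.
#' @export
community_spec <- function(name, voxels, role = c("sensorimotor", "cognitive", "background"),
                           loading_baseline, loading_slope_per_day,
                           control_loading, latent = name) {
  role <- match.arg(role)
  structure(list(name = name, voxels = as.integer(voxels), role = role,
                 loading_baseline = loading_baseline,
                 loading_slope_per_day = loading_slope_per_day,
                 control_loading = control_loading, latent = latent),
            class = "community_spec")
}

default_communities <- function(dims) {
  smc_l <- box_indices(list(x = c(4, 7), y = c(4, 7), z = c(14, 17)), dims)
  smc_r <- box_indices(list(x = c(14, 17), y = c(4, 7), z = c(14, 17)), dims)
  dlpfc_l <- box_indices(list(x = c(4, 7), y = c(14, 17), z = c(14, 17)), dims)
  dlpfc_r <- box_indices(list(x = c(14, 17), y = c(14, 17), z = c(14, 17)), dims)
  # Sensorimotor hubs: depressed at onset, recovering to the control level
  # by one year. Cognitive hubs: elevated at onset, normalising by one year.
  list(
    community_spec("smc_ipsi", smc_l, "sensorimotor",
                   loading_baseline = 0.20,
                   loading_slope_per_day = (0.60 - 0.20) / 370,
                   control_loading = 0.60, latent = "smc"),
    community_spec("smc_contra", smc_r, "sensorimotor",
                   loading_baseline = 0.20,
                   loading_slope_per_day = (0.60 - 0.20) / 370,
                   control_loading = 0.60, latent = "smc"),
    community_spec("dlpfc_ipsi", dlpfc_l, "cognitive",
                   loading_baseline = 0.55,
                   loading_slope_per_day = (0.30 - 0.55) / 370,
                   control_loading = 0.30, latent = "dlpfc"),
    community_spec("dlpfc_contra", dlpfc_r, "cognitive",
                   loading_baseline = 0.55,
                   loading_slope_per_day = (0.30 - 0.55) / 370,
                   control_loading = 0.30, latent = "dlpfc")
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 3 mm isotropic voxels, TR 2 s,
#' 170 retained volumes, eight patients scanned at five time points (3, 13,
#' 31, 98, 370 days post-onset — the printed interval means), ten controls
#' scanned once, a 0.01-0.08 Hz latent passband, and a central lesion box
#' whose mean intensity falls below the grey-matter criterion.
#'
#' @param grid_shape voxels per axis.
#' @param voxel_size voxel edge, mm.
#' @param tr repetition time, seconds.
#' @param n_volumes retained time points per scan.
#' @param n_patients,n_controls group sizes.
#' @param session_days patient scan days post-onset.
#' @param communities list of [community_spec()]s; default two bilateral
#'   sensorimotor and two bilateral cognitive hubs of 64 voxels each.
#' @param lesion_box lesion as list(x =, y =, z =) index ranges.
#' @param noise_sd white measurement-noise SD (latent signals have SD 1).
#' @param passband latent passband, Hz.
#' @param mean_intensity baseline voxel intensity; lesion voxels get
#'   `lesion_attenuation` times this.
#' @param lesion_attenuation intensity factor for lesion voxels.
#' @param signal_amplitude intensity units per unit of latent + noise.
#' @param nuisance_weight loading of every brain voxel on the white-matter
#'   and ventricle nuisance signals.
#' @param motion_sd per-frame random-walk innovation SD (mm / radians).
#' @param clinical_noise_sd SD of noise on MI scores.
#' @param seed base RNG seed; every per-scan seed derives from it.
#' @return a `sim_config` list (validated).
#' @export
sim_config <- function(grid_shape = c(20L, 20L, 20L), voxel_size = 3,
                       tr = 2, n_volumes = 170L,
                       n_patients = 8L, n_controls = 10L,
                       session_days = c(3, 13, 31, 98, 370),
                       communities = NULL,
                       lesion_box = list(x = c(8, 10), y = c(9, 11), z = c(8, 10)),
                       noise_sd = 0.5, passband = c(0.01, 0.08),
                       mean_intensity = 100, lesion_attenuation = 0.1,
                       signal_amplitude = 2, nuisance_weight = 0.3,
                       motion_sd = 0.02, clinical_noise_sd = 8,
                       seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  cfg <- structure(list(
    grid_shape = grid_shape, voxel_size = voxel_size, tr = tr,
    n_volumes = as.integer(n_volumes), n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls), session_days = session_days,
    communities = communities %||% default_communities(grid_shape),
    lesion_box = lesion_box, noise_sd = noise_sd, passband = passband,
    mean_intensity = mean_intensity, lesion_attenuation = lesion_attenuation,
    signal_amplitude = signal_amplitude, nuisance_weight = nuisance_weight,
    motion_sd = motion_sd, clinical_noise_sd = clinical_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  nyq <- 1 / (2 * cfg$tr)
  if (!(cfg$passband[1] > 0 && cfg$passband[1] < cfg$passband[2] &&
          cfg$passband[2] < nyq)) {
    abort("passband must satisfy 0 < low < high < Nyquist")
  }
  if (any(diff(cfg$session_days) <= 0)) abort("session_days must increase")
  n_vox <- prod(cfg$grid_shape)
  lesion <- box_indices(cfg$lesion_box, cfg$grid_shape)
  for (cm in cfg$communities) {
    if (any(cm$voxels < 1 | cm$voxels > n_vox)) {
      abort(paste0("community ", cm$name, " outside the grid"))
    }
    if (length(intersect(cm$voxels, lesion)) > 0) {
      abort(paste0("community ", cm$name, " overlaps the lesion"))
    }
  }
  invisible(cfg)
}

# Band-limited unit-variance latent signal: FFT-filtered white noise.
band_limited_noise <- function(n, tr, low, high) {
  x <- rnorm(n)
  f <- fft(x)
  freq <- (seq_len(n) - 1) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq)  # two-sided
  keep <- freq >= low & freq <= high
  f[!keep] <- 0
  y <- Re(fft(f, inverse = TRUE)) / n
  as.numeric(scale(y))
}

#' One subject-session 4-D BOLD scan
#'
#' Holds the time series array (x, y, z, t), grid geometry, TR, the rigid
#' motion trace, and generator-supplied white-matter / ventricle mean
#' signals used as nuisance regressors.
#'
#' @param data 4-D numeric array.
#' @param voxel_size voxel edge, mm.
#' @param tr repetition time, s.
#' @param subject_id,session_index,days_post_onset identity fields.
#' @param motion t x 6 matrix (3 translations mm, 3 rotations rad).
#' @param wm_signal,vent_signal length-t nuisance signals.
#' @param is_patient logical flag.
#' @return a `bold_session`.
#' @export
bold_session <- function(data, voxel_size, tr, subject_id, session_index,
                         days_post_onset, motion, wm_signal = NULL,
                         vent_signal = NULL, is_patient = NA) {
  stopifnot(length(dim(data)) == 4, all(is.finite(data)))
  nt <- dim(data)[4]
  stopifnot(nrow(motion) == nt, ncol(motion) == 6)
  structure(list(data = data, voxel_size = voxel_size, tr = tr,
                 subject_id = subject_id, session_index = session_index,
                 days_post_onset = days_post_onset, motion = motion,
                 wm_signal = wm_signal, vent_signal = vent_signal,
                 is_patient = is_patient),
            class = "bold_session")
}

#' @export
print.bold_session <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_session> %s session %s (day %s): %dx%dx%d grid, %d vols, TR %gs\n",
              x$subject_id, x$session_index, x$days_post_onset,
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

patient_loading <- function(cm, day) {
  max(0, cm$loading_baseline + cm$loading_slope_per_day * day)
}

#' Simulate one BOLD session
#'
#' Each voxel's series is `amplitude * (loading * latent + nuisance + noise)`
#' added to a positive mean intensity; lesion voxels get an attenuated mean
#' so the default grey-matter criterion excludes them. Deterministic given
#' `(config$seed, subject_id, session_index)`.
#'
#' @param config a [sim_config()].
#' @param subject_id subject label (used in the derived seed via its index).
#' @param session_index session number (patients), or 1 for controls.
#' @param is_patient if `TRUE`, community loadings are evaluated at the
#'   session's days post-onset; controls use static control loadings.
#' @param subject_index integer used for seed derivation; defaults to a
#'   parse of the trailing digits of `subject_id`.
#' @return a [bold_session()].
#' @export
simulate_session <- function(config, subject_id, session_index,
                             is_patient = TRUE, subject_index = NULL) {
  validate_sim_config(config)
  if (is.null(subject_index)) {
    subject_index <- suppressWarnings(as.integer(gsub("\\D", "", subject_id)))
    if (is.na(subject_index)) subject_index <- 0L
  }
  if (!is_patient) subject_index <- subject_index + 1000L
  set.seed(derive_seed(config$seed, subject_index, session_index))
  dims <- config$grid_shape
  n_vox <- prod(dims)
  nt <- config$n_volumes
  day <- if (is_patient) config$session_days[session_index] else 0

  latents <- list()
  for (cm in config$communities) {
    if (is.null(latents[[cm$latent]])) {
      latents[[cm$latent]] <- band_limited_noise(nt, config$tr,
                                                 config$passband[1],
                                                 config$passband[2])
    }
  }
  wm <- as.numeric(scale(rnorm(nt)))
  vent <- as.numeric(scale(rnorm(nt)))

  loading <- numeric(n_vox)
  latent_of <- rep(NA_integer_, n_vox)
  latent_names <- names(latents)
  for (cm in config$communities) {
    l <- if (is_patient) patient_loading(cm, day) else cm$control_loading
    loading[cm$voxels] <- l
    latent_of[cm$voxels] <- match(cm$latent, latent_names)
  }
  L <- do.call(cbind, latents)              # nt x n_latents
  sig <- matrix(0, nt, n_vox)
  has <- !is.na(latent_of)
  if (any(has)) sig[, has] <- L[, latent_of[has], drop = FALSE] *
      rep(loading[has], each = nt)
  noise <- matrix(rnorm(nt * n_vox, sd = config$noise_sd), nt, n_vox)
  series <- sig + config$nuisance_weight * (wm + vent) + noise

  base <- rep(config$mean_intensity, n_vox)
  lesion <- box_indices(config$lesion_box, dims)
  base[lesion] <- config$mean_intensity * config$lesion_attenuation
  series <- config$signal_amplitude * series +
    rep(base, each = nt)

  data <- aperm(array(series, dim = c(nt, dims)), c(2, 3, 4, 1))
  motion <- apply(matrix(rnorm(nt * 6, sd = config$motion_sd), nt, 6), 2, cumsum)
  bold_session(data, config$voxel_size, config$tr, subject_id, session_index,
               day, motion, wm_signal = wm, vent_signal = vent,
               is_patient = is_patient)
}

#' Simulate the full longitudinal cohort
#'
#' Patients get one session per entry of `session_days`; controls one
#' static session each. Also returns the true (non-lesion) analysis mask,
#' a clinical table whose MI rises and NIHSS falls with each patient's
#' sensorimotor recovery fraction (plus noise), a regional grey-matter
#' volume table whose sensorimotor entries fall as connectivity recovers
#' (an anticorrelated structural component), and the community voxel sets
#' as seed ROIs.
#'
#' @param config a [sim_config()].
#' @return list with elements `patients` (list of lists of sessions),
#'   `controls`, `gm_mask`, `clinical` (a `stroke_cohort`), `gmv` (tibble:
#'   region, patient_id, session, gmv), `rois` (named list of voxel-index
#'   vectors), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  if (config$n_patients < 2) abort("need at least 2 patients")
  dims <- config$grid_shape
  n_sess <- length(config$session_days)

  patients <- lapply(seq_len(config$n_patients), function(i) {
    lapply(seq_len(n_sess), function(j) {
      simulate_session(config, sprintf("patient%02d", i), j,
                       is_patient = TRUE, subject_index = i)
    })
  })
  names(patients) <- sprintf("patient%02d", seq_len(config$n_patients))
  controls <- lapply(seq_len(config$n_controls), function(i) {
    simulate_session(config, sprintf("control%02d", i), 1L,
                     is_patient = FALSE, subject_index = i)
  })
  names(controls) <- sprintf("control%02d", seq_len(config$n_controls))

  lesion <- box_indices(config$lesion_box, dims)
  gm_mask <- array(TRUE, dim = dims)
  gm_mask[lesion] <- FALSE

  # Recovery fraction shared by the clinical and structural couplings.
  sm <- Filter(function(cm) cm$role == "sensorimotor", config$communities)[[1]]
  frac <- function(day) {
    l <- patient_loading(sm, day)
    (l - sm$loading_baseline) / (sm$control_loading - sm$loading_baseline)
  }

  set.seed(derive_seed(config$seed, 999999L, 1L))
  clin <- purrr::map_dfr(seq_len(config$n_patients), function(i) {
    days <- config$session_days +
      round(rnorm(n_sess, sd = pmax(1, config$session_days * 0.05)))
    days <- pmax(0, days)
    days <- cummax(days + seq_len(n_sess) * 1e-9)  # keep strictly increasing
    days <- round(days)
    while (any(diff(days) <= 0)) days[which(diff(days) <= 0) + 1] <-
        days[which(diff(days) <= 0)] + 1
    fr <- vapply(days, frac, numeric(1))
    mi <- pmin(200, pmax(0, 20 + 10 * (i %% 4) + 150 * fr +
                           rnorm(n_sess, sd = config$clinical_noise_sd)))
    nihss <- pmax(0, round(12 - 10 * fr + rnorm(n_sess, sd = 1)))
    tibble::tibble(
      patient_id = sprintf("patient%02d", i),
      age = round(49 + rnorm(1, sd = 4)),
      session = seq_len(n_sess), day = as.numeric(days),
      mi = round(mi), nihss = nihss
    )
  })
  clinical <- new_stroke_cohort(clin, n_sess)

  rois <- setNames(lapply(config$communities, `[[`, "voxels"),
                   vapply(config$communities, `[[`, "", "name"))
  gmv <- purrr::map_dfr(seq_along(rois), function(r) {
    cm <- config$communities[[r]]
    purrr::map_dfr(seq_len(config$n_patients), function(i) {
      g0 <- 100 + rnorm(1, sd = 3)
      fr <- vapply(config$session_days, frac, numeric(1))
      coupling <- if (cm$role == "sensorimotor") -8 * fr else 0 * fr
      tibble::tibble(region = cm$name,
                     patient_id = sprintf("patient%02d", i),
                     session = seq_len(n_sess),
                     gmv = g0 + coupling + rnorm(n_sess, sd = 1))
    })
  })

  list(patients = patients, controls = controls, gm_mask = gm_mask,
       clinical = clinical, gmv = gmv, rois = rois, config = config)
}
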