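# End-to-end orchestration: simulate -> preprocess -> FCD -> voxel-wise
# longitudinal model -> cluster correction -> seed FCS -> clinical / GMV
# associations -> trajectory report.

#' Run configuration for the full analysis
#'
#' @param sim a [sim_config()].
#' @param fcd an [fcd_config()].
#' @param voxel_p per-voxel p for cluster-forming. Default 0.01.
#' @param n_sims Monte-Carlo iterations for the cluster-extent null.
#' @param connection_radius_mm cluster connection radius, mm.
#' @param corrected_alpha familywise level for cluster correction.
#' @param fcs_alpha familywise level of the control seed-connectivity mask.
#' @param include_quadratic quadratic term in the voxel-wise time model.
#' @param use_fd_covariate include mean framewise displacement as a fixed
#'   effect in voxel-wise fits. Default `TRUE`.
#' @param out_dir optional directory: numeric tables are written as TSV
#'   with a JSON provenance sidecar.
#' @param seed global seed; all stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(), fcd = fcd_config(),
                       voxel_p = 0.01, n_sims = 1000L,
                       connection_radius_mm = 5, corrected_alpha = 0.05,
                       fcs_alpha = 0.05, include_quadratic = TRUE,
                       use_fd_covariate = TRUE, out_dir = NULL,
                       seed = 42L) {
  structure(list(sim = sim, fcd = fcd, voxel_p = voxel_p,
                 n_sims = as.integer(n_sims),
                 connection_radius_mm = connection_radius_mm,
                 corrected_alpha = corrected_alpha, fcs_alpha = fcs_alpha,
                 include_quadratic = include_quadratic,
                 use_fd_covariate = use_fd_covariate, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full longitudinal FCD/FCS analysis on a synthetic cohort
#'
#' Stages, mirroring the analysis order: (1) simulate the cohort;
#' (2) preprocess every session (nuisance regression, 0.01-0.08 Hz
#' band-pass) and compute mean FD; (3) FCD maps per session; (4)
#' voxel-wise random-intercept time model on the scaled smoothed short-
#' and long-range FCD; (5) Monte-Carlo cluster-extent correction, with
#' positive- and negative-slope clusters becoming seed ROIs; (6) control
#' seed-connectivity masks and per-session ROI FCS; (7) patient-vs-control
#' comparisons per time point; (8) clinical (centred MI / NIHSS) and GMV
#' association models per detected region; (9) trajectory tables.
#'
#' @param config a [run_config()].
#' @return an `fcd_report` list; see the returned element names.
#' @export
run_full_analysis <- function(config = run_config()) {
  cfg <- config
  sim <- cfg$sim
  sim$seed <- derive_seed(cfg$seed, 1L, 0L)
  cohort <- simulate_cohort(sim)
  dims <- sim$grid_shape
  n_sess <- length(sim$session_days)
  n_pat <- sim$n_patients

  # ---- preprocessing + masks -------------------------------------------
  gm_masks <- list()
  prep <- function(sess) {
    m <- make_gm_mask(sess, cfg$fcd$gm_fraction)
    gm_masks[[length(gm_masks) + 1]] <<- m
    list(session = preprocess_session(sess), mask = m,
         mean_fd = compute_fd(sess$motion)$mean_fd)
  }
  pat <- lapply(cohort$patients, function(ss) lapply(ss, prep))
  ctl <- lapply(cohort$controls, prep)
  # common analysis mask: voxels in-mask in every session
  mask <- Reduce(`&`, gm_masks)

  # ---- FCD maps --------------------------------------------------------
  fcd_of <- function(p) compute_fcd_maps(p$session, mask, cfg$fcd)
  pat_fcd <- lapply(pat, function(ss) lapply(ss, fcd_of))
  ctl_fcd <- lapply(ctl, fcd_of)

  # ---- voxel-wise time model on patients -------------------------------
  obs <- tidyr::expand_grid(i = seq_len(n_pat), j = seq_len(n_sess))
  obs <- dplyr::mutate(obs,
                       subject = sprintf("patient%02d", .data$i),
                       x = sim$session_days[.data$j],
                       mean_fd = purrr::map2_dbl(.data$i, .data$j,
                                                 ~ pat[[.x]][[.y]]$mean_fd))
  covars <- if (cfg$use_fd_covariate) "mean_fd" else NULL
  fits <- list()
  for (kind in c("short", "long")) {
    maps <- purrr::map2(obs$i, obs$j, function(i, j) {
      pat_fcd[[i]][[j]][[paste0(kind, "_scaled_smooth")]]
    })
    fits[[kind]] <- voxelwise_fit(maps, obs, mask,
                                  include_quadratic = cfg$include_quadratic,
                                  covariates = covars)
  }

  # ---- cluster correction ----------------------------------------------
  null_cfg <- cluster_sim_config(mask, voxel_mm = sim$voxel_size,
                                 voxel_p = cfg$voxel_p, n_sims = cfg$n_sims,
                                 fwhm_mm = cfg$fcd$smoothing_fwhm,
                                 connection_radius_mm = cfg$connection_radius_mm,
                                 corrected_alpha = cfg$corrected_alpha,
                                 seed = derive_seed(cfg$seed, 2L, 0L))
  cluster_null <- simulate_cluster_null(null_cfg)
  offsets <- neighbor_offsets(cfg$connection_radius_mm, sim$voxel_size)
  clusters <- list()
  for (kind in c("short", "long")) {
    for (sgn in c(1, -1)) {
      cl <- apply_cluster_threshold(fits[[kind]]$p_beta1, cfg$voxel_p,
                                    cluster_null$size_threshold, offsets,
                                    stat_map = fits[[kind]]$t_beta1,
                                    sign = sgn)
      if (nrow(cl$table) > 0) {
        nm <- sprintf("%s_%s", kind, if (sgn > 0) "pos" else "neg")
        for (r in seq_len(nrow(cl$table))) {
          clusters[[sprintf("%s_%d", nm, r)]] <- list(
            kind = kind, sign = sgn, voxels = cl$voxels[[r]],
            table = cl$table[r, ])
        }
      }
    }
  }
  rois <- purrr::map(clusters, "voxels")

  # ---- per-region FCD trajectories + group comparisons -----------------
  region_value <- function(fcdmaps, voxels, kind) {
    mean(fcdmaps[[paste0(kind, "_scaled_smooth")]][voxels])
  }
  traj <- purrr::imap_dfr(clusters, function(cl, nm) {
    pat_tbl <- tidyr::expand_grid(i = seq_len(n_pat), j = seq_len(n_sess))
    pat_tbl <- dplyr::mutate(pat_tbl,
      region = nm, group = "patient",
      subject = sprintf("patient%02d", .data$i), session = .data$j,
      value = purrr::map2_dbl(.data$i, .data$j,
                              ~ region_value(pat_fcd[[.x]][[.y]], cl$voxels, cl$kind)))
    ctl_tbl <- tibble::tibble(
      region = nm, group = "control",
      subject = names(ctl_fcd), session = NA_integer_,
      value = vapply(ctl_fcd, region_value, numeric(1),
                     voxels = cl$voxels, kind = cl$kind))
    dplyr::bind_rows(dplyr::select(pat_tbl, -"i", -"j"), ctl_tbl)
  })

  group_tests <- purrr::imap_dfr(clusters, function(cl, nm) {
    ctl_vals <- traj$value[traj$region == nm & traj$group == "control"]
    purrr::map_dfr(seq_len(n_sess), function(j) {
      pv <- traj$value[traj$region == nm & traj$group == "patient" &
                         traj$session == j]
      dplyr::mutate(group_difference_at_timepoint(pv, ctl_vals),
                    region = nm, session = j, .before = 1)
    })
  })

  # ---- seed FCS: control-derived masks + ROI-pair trajectories ---------
  fcs <- NULL
  if (length(rois) > 0) {
    ctl_smooth <- lapply(ctl, function(p) smooth_session(p$session,
                                                         cfg$fcd$smoothing_fwhm,
                                                         mask))
    pat_smooth <- lapply(pat, function(ss) lapply(ss, function(p)
      smooth_session(p$session, cfg$fcd$smoothing_fwhm, mask)))
    fcs <- purrr::imap(rois, function(voxels, nm) {
      zmaps <- lapply(ctl_smooth, seed_z_map, seed = voxels, mask = mask)
      gmask <- group_connectivity_mask(zmaps, mask, alpha = cfg$fcs_alpha)
      target <- which(gmask$mask & !indices_to_mask(voxels, dims))
      if (length(target) == 0) return(NULL)
      vals <- tidyr::expand_grid(i = seq_len(n_pat), j = seq_len(n_sess))
      vals <- dplyr::mutate(vals,
        subject = sprintf("patient%02d", .data$i), session = .data$j,
        z = purrr::map2_dbl(.data$i, .data$j, function(i, j)
          roi_pair_fcs(pat_smooth[[i]][[j]], voxels, target)))
      ctl_z <- vapply(ctl_smooth, roi_pair_fcs, numeric(1),
                      roi_a = voxels, roi_b = target)
      list(region = nm, group_mask = gmask, patient_fcs = vals,
           control_fcs = ctl_z)
    })
    fcs <- purrr::compact(fcs)
  }

  # ---- association models (clinical scores, GMV) -----------------------
  clin_mi <- normalize_scores(cohort$clinical, "mi")
  clin_ni <- normalize_scores(cohort$clinical, "nihss")
  assoc <- purrr::imap_dfr(clusters, function(cl, nm) {
    resp <- tidyr::expand_grid(i = seq_len(n_pat), j = seq_len(n_sess))
    resp <- dplyr::mutate(resp,
      subject = sprintf("patient%02d", .data$i), session = .data$j,
      y = purrr::map2_dbl(.data$i, .data$j,
                          ~ region_value(pat_fcd[[.x]][[.y]], cl$voxels, cl$kind)))
    one <- function(scores, label) {
      d <- dplyr::left_join(resp, scores[, c("patient_id", "session", "score_centered")],
                            by = c(subject = "patient_id", session = "session"))
      d$x <- d$score_centered
      fit <- fit_eq1(d[!is.na(d$x), ], include_quadratic = FALSE,
                     center_predictor = FALSE)
      tibble::tibble(region = nm, predictor = label,
                     beta1 = unname(fit$coefficients["x"]),
                     t = unname(fit$t["x"]), p_value = unname(fit$p["x"]))
    }
    out <- dplyr::bind_rows(one(clin_mi, "mi"), one(clin_ni, "nihss"))
    gmv_region <- best_matching_region(cl$voxels, cohort$rois)
    gmv_r <- if (is.na(gmv_region)) cohort$gmv[0, ] else
      cohort$gmv[cohort$gmv$region == gmv_region, ]
    if (nrow(gmv_r) > 0) {
      d <- dplyr::left_join(resp, gmv_r[, c("patient_id", "session", "gmv")],
                            by = c(subject = "patient_id", session = "session"))
      d$x <- d$gmv
      fit <- fit_eq1(d[!is.na(d$x), ], include_quadratic = FALSE)
      out <- dplyr::bind_rows(out, tibble::tibble(
        region = nm, predictor = "gmv",
        beta1 = unname(fit$coefficients["x"]),
        t = unname(fit$t["x"]), p_value = unname(fit$p["x"])))
    }
    out
  })

  report <- structure(list(
    cohort = cohort, mask = mask, fits = fits,
    cluster_null = cluster_null, clusters = clusters, rois = rois,
    trajectories = traj, group_tests = group_tests, fcs = fcs,
    associations = assoc, config = cfg
  ), class = "fcd_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# Which generator ROI a detected cluster overlaps most.
best_matching_region <- function(voxels, rois) {
  ov <- vapply(rois, function(r) length(intersect(voxels, r)), integer(1))
  if (max(ov) == 0) return(NA_character_)
  names(rois)[which.max(ov)]
}

#' @export
print.fcd_report <- function(x, ...) {
  cat(sprintf("<fcd_report> %d patients x %d sessions + %d controls; %d significant cluster(s)\n",
              x$config$sim$n_patients, length(x$config$sim$session_days),
              x$config$sim$n_controls, length(x$clusters)))
  if (length(x$clusters) > 0) {
    cat("  clusters:", paste(names(x$clusters), collapse = ", "), "\n")
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tbl, name) {
    utils::write.table(tbl, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wr(report$trajectories, "trajectories")
  wr(report$group_tests, "group_tests")
  wr(report$associations, "associations")
  cfg <- report$config
  jsonlite::write_json(list(
    seed = cfg$seed, voxel_p = cfg$voxel_p, n_sims = cfg$n_sims,
    corrected_alpha = cfg$corrected_alpha,
    size_threshold = report$cluster_null$size_threshold,
    grid = cfg$sim$grid_shape, n_patients = cfg$sim$n_patients,
    n_controls = cfg$sim$n_controls,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("fcdlong"))
  ), file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Trajectory table and figure for a region
#'
#' Per time point: patient mean with standard-error bars, against a
#' horizontal control mean line with a standard-error band.
#'
#' @param values tibble with columns `subject`, `session`, `value`
#'   (patients; one row per attended session).
#' @param control_values numeric vector of control values.
#' @param region label used in the figure title.
#' @return list with `table` (tibble: `session`, `mean`, `se`, `n`,
#'   `control_mean`, `control_se`) and `plot` (a ggplot).
#' @export
make_trajectory_report <- function(values, control_values, region = "region") {
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(values), session = .data$session),
    mean = mean(.data$value, na.rm = TRUE),
    se = if (sum(!is.na(.data$value)) > 1)
      sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value)))
    else NA_real_,
    n = sum(!is.na(.data$value)), .groups = "drop")
  if (any(is.na(tab$se))) {
    warn("single observation at some time point; error bars omitted there")
  }
  cm <- mean(control_values)
  cse <- if (length(control_values) > 1)
    sd(control_values) / sqrt(length(control_values)) else 0
  tab$control_mean <- cm
  tab$control_se <- cse
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$session, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = cm, linetype = "solid", colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(cm - cse, cm + cse),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1, na.rm = TRUE) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Time point", y = "Value", title = region) +
    ggplot2::theme_minimal()
  list(table = tab, plot = p)
}

#' Plot per-region trajectories of an `fcd_report`
#'
#' @param object an `fcd_report`.
#' @param ... unused.
#' @return a ggplot (faceted by region).
#' @export
autoplot.fcd_report <- function(object, ...) {
  traj <- object$trajectories
  pats <- traj[traj$group == "patient", ]
  sum_tbl <- dplyr::summarise(
    dplyr::group_by(pats, .data$region, .data$session),
    mean = mean(.data$value), se = sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop")
  ctls <- dplyr::summarise(
    dplyr::group_by(traj[traj$group == "control", ], .data$region),
    cm = mean(.data$value), cse = sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop")
  ggplot2::ggplot(sum_tbl, ggplot2::aes(x = .data$session, y = .data$mean)) +
    ggplot2::geom_hline(data = ctls, ggplot2::aes(yintercept = .data$cm),
                        colour = "grey40") +
    ggplot2::geom_hline(data = ctls, ggplot2::aes(yintercept = .data$cm + .data$cse),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_hline(data = ctls, ggplot2::aes(yintercept = .data$cm - .data$cse),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se), width = 0.1) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "Time point", y = "Grand-mean scaled FCD") +
    ggplot2::theme_minimal()
}
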