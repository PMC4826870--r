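# Random-intercept mixed-effects model for longitudinal voxel/ROI data:
#   Y_ij = u + b_i + X_ij b1 + X_ij^2 b2 (+ covariates) + e_ij,
#   b_i ~ N(0, sigma_b^2), e_ij ~ N(0, sigma_e^2),
# fitted by REML through 1-D profiling of lambda = sigma_b^2 / sigma_e^2.
# Given lambda the GLS solution is closed-form via per-subject Woodbury
# identities, so each criterion evaluation costs O(rows x p^2).

# Sufficient statistics of the REML criterion at a given lambda.
reml_pieces <- function(X, y, subj_idx, lambda) {
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y * y)
  logdetV <- 0
  for (rows in subj_idx) {
    ni <- length(rows)
    w <- lambda / (1 + lambda * ni)
    sx <- colSums(X[rows, , drop = FALSE]); sy <- sum(y[rows])
    XtX <- XtX - w * tcrossprod(sx)
    Xty <- Xty - w * sx * sy
    yty <- yty - w * sy * sy
    logdetV <- logdetV + log1p(lambda * ni)
  }
  A <- XtX
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, backsolve(ch, Xty, transpose = TRUE))
  rss <- yty - sum(Xty * beta)            # y'V^-1 y - y'V^-1 X beta
  rss <- max(rss, .Machine$double.eps)
  sigma_e2 <- rss / (n - p)
  logdetA <- 2 * sum(log(diag(ch)))
  crit <- (n - p) * (1 + log(2 * pi * sigma_e2)) + logdetV + logdetA
  list(beta = beta, sigma_e2 = sigma_e2, crit = crit, chol = ch,
       logdetV = logdetV)
}

#' Fit the random-intercept longitudinal model by REML
#'
#' Fits `y ~ intercept + x (+ x^2) (+ covariates)` with a per-subject
#' random intercept. The ratio `lambda = sigma_b^2 / sigma_e^2` is profiled
#' by bounded 1-D optimisation of the REML criterion over `log(lambda)` in
#' `[-12, 12]`; the boundary `sigma_b^2 = 0` is evaluated exactly and wins
#' ties, so a boundary fit reproduces OLS exactly. Wald t-tests use
#' `df = n_obs - rank(design)`.
#'
#' @param data data frame with columns `subject`, `x` (predictor), `y`
#'   (response), plus any covariate columns.
#' @param include_quadratic add an `x^2` fixed effect. Default `TRUE`.
#' @param covariates character vector of covariate column names (e.g.
#'   mean framewise displacement). Default none.
#' @param center_predictor centre `x` before squaring (better conditioning;
#'   with a quadratic term this re-parameterises the intercept and linear
#'   coefficient but not the model fit). Default `TRUE`.
#' @return an `eq1_fit` object; see [tidy.eq1_fit()] / [glance.eq1_fit()].
#' @export
fit_eq1 <- function(data, include_quadratic = TRUE, covariates = NULL,
                    center_predictor = TRUE) {
  data <- as.data.frame(data)
  need <- c("subject", "x", "y", covariates)
  if (!all(need %in% names(data))) {
    abort(paste0("data must have columns: ", paste(need, collapse = ", ")))
  }
  data <- data[!is.na(data$y) & !is.na(data$x), , drop = FALSE]
  if (any(!is.finite(data$y))) abort("non-finite response values")
  subjects <- unique(data$subject)
  if (length(subjects) < 2) abort("need at least 2 subjects")
  x <- data$x
  x_center <- if (center_predictor) mean(x) else 0
  xc <- x - x_center
  X <- cbind(`(Intercept)` = 1, x = xc)
  if (include_quadratic) X <- cbind(X, x2 = xc^2)
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(data[, covariates, drop = FALSE]))
  }
  n <- nrow(X); p <- qr(X)$rank
  if (n <= ncol(X) + 1) abort("fewer observations than model parameters")
  if (p < ncol(X)) abort("rank-deficient fixed-effect design")
  y <- data$y
  subj_idx <- split(seq_len(n), match(data$subject, subjects))

  crit_fn <- function(loglam) {
    pc <- reml_pieces(X, y, subj_idx, exp(loglam))
    if (is.null(pc)) return(Inf)
    pc$crit
  }
  opt <- optimize(crit_fn, interval = c(-12, 12), tol = 1e-9)
  at0 <- reml_pieces(X, y, subj_idx, 0)
  boundary <- FALSE
  if (at0$crit <= opt$objective + 1e-8) {
    lambda <- 0; fit <- at0; boundary <- TRUE
  } else {
    lambda <- exp(opt$minimum)
    fit <- reml_pieces(X, y, subj_idx, lambda)
    if (abs(opt$minimum) > 12 - 1e-3) boundary <- TRUE
  }
  sigma_e2 <- fit$sigma_e2
  sigma_b2 <- lambda * sigma_e2
  Ainv <- chol2inv(fit$chol)
  se <- sqrt(diag(Ainv) * sigma_e2)
  beta <- as.numeric(fit$beta)
  df <- n - ncol(X)
  t_stat <- beta / se
  p_val <- 2 * pt(-abs(t_stat), df = df)
  terms <- colnames(X)
  structure(list(
    coefficients = setNames(beta, terms), se = setNames(se, terms),
    t = setNames(t_stat, terms), p = setNames(p_val, terms), df = df,
    sigma_b2 = sigma_b2, sigma_e2 = sigma_e2, lambda = lambda,
    reml_loglik = -fit$crit / 2, boundary = boundary,
    n_obs = n, n_subjects = length(subjects),
    include_quadratic = include_quadratic, covariates = covariates,
    x_center = x_center
  ), class = "eq1_fit")
}

#' @export
print.eq1_fit <- function(x, ...) {
  cat(sprintf("<eq1_fit> random-intercept REML: %d obs, %d subjects%s\n",
              x$n_obs, x$n_subjects, if (x$boundary) " (boundary)" else ""))
  cat(sprintf("  sigma_b^2 = %.4g, sigma_e^2 = %.4g\n", x$sigma_b2, x$sigma_e2))
  print(tidy(x))
  invisible(x)
}

#' Tidy the fixed effects of an `eq1_fit`
#'
#' @param x an `eq1_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `df`, `p.value`.
#' @export
tidy.eq1_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(x$t),
                 df = x$df,
                 p.value = unname(x$p))
}

#' One-row model summary of an `eq1_fit`
#'
#' @param x an `eq1_fit`.
#' @param ... unused.
#' @return tibble with variance components, REML log-likelihood and sizes.
#' @export
glance.eq1_fit <- function(x, ...) {
  tibble::tibble(sigma_b2 = x$sigma_b2, sigma_e2 = x$sigma_e2,
                 lambda = x$lambda, reml_loglik = x$reml_loglik,
                 boundary = x$boundary, n_obs = x$n_obs,
                 n_subjects = x$n_subjects)
}

#' Voxel-wise random-intercept fits over a map stack
#'
#' Applies [fit_eq1()] independently at every in-mask voxel. The response
#' at observation (subject, session) is that observation's map value; the
#' predictor is the `x` column of `obs` (days post-onset for the time
#' model, a subject-centred clinical score for association models, or a
#' regional grey-matter volume for structure-function models).
#' Observations with a missing map are dropped with a message.
#'
#' @param maps list of 3-D arrays, one per row of `obs` (`NULL` allowed =
#'   missing scan).
#' @param obs data frame with columns `subject`, `x`, plus any covariate
#'   columns, one row per map.
#' @param mask logical 3-D array.
#' @param include_quadratic,covariates,center_predictor passed to
#'   [fit_eq1()].
#' @return a `voxelwise_fit`: list with 3-D arrays `beta1`, `t_beta1`,
#'   `p_beta1`, `beta2`, `t_beta2`, `p_beta2` (quadratic arrays `NULL`
#'   when not fitted), the `mask`, and `n_obs`.
#' @export
voxelwise_fit <- function(maps, obs, mask, include_quadratic = TRUE,
                          covariates = NULL, center_predictor = TRUE) {
  obs <- as.data.frame(obs)
  if (nrow(obs) != length(maps)) abort("one map per observation row required")
  present <- !vapply(maps, is.null, TRUE) & !is.na(obs$x)
  if (any(!present)) {
    inform(sprintf("dropping %d observations with missing maps or predictor",
                   sum(!present)))
  }
  maps <- maps[present]; obs <- obs[present, , drop = FALSE]
  dims <- dim(mask)
  if (!all(vapply(maps, function(m) identical(dim(m), dims), TRUE))) {
    abort("map grids do not match the mask")
  }
  vox <- which(mask)
  Y <- vapply(maps, function(m) m[vox], numeric(length(vox)))  # vox x obs
  empty <- array(NA_real_, dim = dims)
  b1 <- empty; t1 <- empty; p1 <- empty
  b2 <- empty; t2 <- empty; p2 <- empty
  for (k in seq_along(vox)) {
    yk <- Y[k, ]
    if (var(yk) == 0) {
      b1[vox[k]] <- 0; t1[vox[k]] <- 0; p1[vox[k]] <- 1
      if (include_quadratic) { b2[vox[k]] <- 0; t2[vox[k]] <- 0; p2[vox[k]] <- 1 }
      next
    }
    d <- obs; d$y <- yk
    fit <- fit_eq1(d, include_quadratic = include_quadratic,
                   covariates = covariates,
                   center_predictor = center_predictor)
    b1[vox[k]] <- fit$coefficients["x"]
    t1[vox[k]] <- fit$t["x"]
    p1[vox[k]] <- fit$p["x"]
    if (include_quadratic) {
      b2[vox[k]] <- fit$coefficients["x2"]
      t2[vox[k]] <- fit$t["x2"]
      p2[vox[k]] <- fit$p["x2"]
    }
  }
  structure(list(beta1 = b1, t_beta1 = t1, p_beta1 = p1,
                 beta2 = if (include_quadratic) b2 else NULL,
                 t_beta2 = if (include_quadratic) t2 else NULL,
                 p_beta2 = if (include_quadratic) p2 else NULL,
                 mask = mask, n_obs = nrow(obs)),
            class = "voxelwise_fit")
}

#' Welch two-sample comparison of patients versus controls
#'
#' Used per region and time point to classify trajectories (initial
#' deficit/excess relative to controls, later normalisation).
#'
#' @param patient_values,control_values numeric vectors (>= 2 each).
#' @return tibble with `t`, `p_value`, `mean_patient`, `mean_control`.
#' @export
group_difference_at_timepoint <- function(patient_values, control_values) {
  patient_values <- patient_values[!is.na(patient_values)]
  control_values <- control_values[!is.na(control_values)]
  if (length(patient_values) < 2 || length(control_values) < 2) {
    abort("need at least 2 values per group")
  }
  if (var(patient_values) == 0 && var(control_values) == 0) {
    if (mean(patient_values) == mean(control_values)) {
      return(tibble::tibble(t = 0, p_value = 1,
                            mean_patient = mean(patient_values),
                            mean_control = mean(control_values)))
    }
    abort("both groups degenerate with different means; t undefined")
  }
  tt <- t.test(patient_values, control_values)
  tibble::tibble(t = unname(tt$statistic), p_value = tt$p.value,
                 mean_patient = mean(patient_values),
                 mean_control = mean(control_values))
}
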