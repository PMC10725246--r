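#' BOLD run container
#'
#' @param data Numeric matrix, voxels x volumes.
#' @param tr Repetition time in seconds.
#' @param subject_id,run_id Optional identifiers.
#' @param geometry Optional list with `dim` (3D grid) and `affine` when the
#'   data came from an image; voxel order is the column-major flattening of
#'   the grid.
#' @return An object of class `sniff_bold`.
#' @export
bold_run <- function(data, tr = 2, subject_id = NA_character_,
                     run_id = NA_character_, geometry = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  stopifnot(tr > 0)
  structure(list(data = data, tr = tr, subject_id = subject_id,
                 run_id = run_id, geometry = geometry),
            class = "sniff_bold")
}

#' @export
print.sniff_bold <- function(x, ...) {
  cat(sprintf("<sniff_bold> %d voxels x %d volumes, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Voxel-wise statistic map
#'
#' @param values Per-voxel statistic (NA marks masked voxels).
#' @param kind One of `"beta"`, `"t"`, `"z"`, `"g"`, `"p"`.
#' @param level One of `"run"`, `"subject"`, `"group"`.
#' @param label Analysis strategy label.
#' @param dof Degrees of freedom, when meaningful.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, kind = c("beta", "t", "z", "g", "p"),
                     level = c("run", "subject", "group"),
                     label = NA_character_, dof = NA_real_) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  structure(list(values = as.numeric(values), kind = kind, level = level,
                 label = label, dof = dof),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s/%s (%s): %d voxels, %d masked\n",
              x$kind, x$level, ifelse(is.na(x$label), "-", x$label),
              length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Fit a voxel-wise general linear model
#'
#' Ordinary least squares per voxel via the QR decomposition of the design.
#'
#' @param run A [bold_run()] or a plain voxels x volumes matrix.
#' @param X A [design_matrix()] with as many rows as the run has volumes.
#' @return An object of class `sniff_glm` with per-voxel coefficients,
#'   residual variances (`RSS / dof`) and the residual degrees of freedom.
#' @export
fit_glm <- function(run, X) {
  stopifnot(inherits(X, "sniff_design"))
  Y <- if (inherits(run, "sniff_bold")) run$data else as.matrix(run)
  Xm <- X$values
  if (ncol(Y) != nrow(Xm)) stop("run volumes do not match design rows")
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) stop("rank-deficient design matrix")
  dof <- nrow(Xm) - ncol(Xm)
  if (dof <= 0) stop("no residual degrees of freedom")
  betas <- t(qr.coef(qrX, t(Y)))
  res <- Y - betas %*% t(Xm)
  structure(
    list(betas = betas, residual_variance = rowSums(res^2) / dof, dof = dof,
         design = X, residuals_matrix = res,
         subject_id = if (inherits(run, "sniff_bold")) run$subject_id else NA_character_,
         run_id = if (inherits(run, "sniff_bold")) run$run_id else NA_character_),
    class = "sniff_glm"
  )
}

#' @export
coef.sniff_glm <- function(object, ...) object$betas

#' @export
residuals.sniff_glm <- function(object, ...) object$residuals_matrix

#' @export
fitted.sniff_glm <- function(object, ...) {
  object$betas %*% t(object$design$values)
}

#' @export
print.sniff_glm <- function(x, ...) {
  cat(sprintf("<sniff_glm> %s: %d voxels, %d predictors, dof = %d\n",
              ifelse(is.na(x$design$label), "design", x$design$label),
              nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}

#' @export
summary.sniff_glm <- function(object, ...) {
  out <- data.frame(
    predictor = colnames(object$betas),
    mean_beta = colMeans(object$betas),
    sd_beta = apply(object$betas, 2, sd))
  rownames(out) <- NULL
  cat(sprintf("GLM over %d voxels (dof = %d), design %s\n",
              nrow(object$betas), object$dof, object$design$label))
  print(out, row.names = FALSE)
  invisible(out)
}

# Sign-preserving z from t: two-sided p at the fit's dof mapped back through
# the standard-normal quantile. Works in log space for numerical range.
.t_to_z <- function(t, dof) {
  z <- sign(t) * qnorm(pt(abs(t), dof, lower.tail = FALSE, log.p = TRUE),
                       lower.tail = FALSE, log.p = TRUE)
  z[t == 0] <- 0
  z
}

#' Contrast estimate, t map and z map from a fitted GLM
#'
#' The contrast is keyed by predictor name (the constant gets implicit weight
#' zero), so results are invariant to design column order. Voxels with zero
#' residual variance are masked.
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Named contrast vector or preset label.
#' @return List of [stat_map()]s: `estimate` (beta contrast), `t`, `z`.
#' @export
contrast_stats <- function(fit, contrast) {
  stopifnot(inherits(fit, "sniff_glm"))
  Xm <- fit$design$values
  cvec <- .resolve_contrast(contrast, colnames(Xm))
  est <- drop(fit$betas %*% cvec)
  cvc <- drop(cvec %*% solve(crossprod(Xm), cvec))
  se <- sqrt(fit$residual_variance * cvc)
  mask <- !is.finite(se) | se <= 0
  tval <- est / se
  tval[mask & est == 0] <- 0        # exact fit with zero contrast
  tval[mask & est != 0] <- NA_real_ # masked: no error variance
  zval <- .t_to_z(tval, fit$dof)
  lab <- fit$design$label
  list(estimate = stat_map(est, "beta", "run", lab),
       t = stat_map(tval, "t", "run", lab, dof = fit$dof),
       z = stat_map(zval, "z", "run", lab))
}

# Stack a list of stat_map values into a voxels x maps matrix.
.map_matrix <- function(maps) {
  n <- unique(vapply(maps, function(m) length(m$values), integer(1)))
  if (length(n) != 1L) stop("maps are not on a common voxel grid")
  matrix(vapply(maps, `[[`, numeric(n[1]), "values"), nrow = n[1])
}

#' Subject-level map across runs
#'
#' Fixed-effects aggregation: the per-voxel mean of the run-level contrast
#' estimates. Masked voxels (NA) propagate.
#'
#' @param run_maps List of run-level `beta` [stat_map()]s on a common grid.
#' @return A subject-level `beta` [stat_map()].
#' @export
second_level_subject <- function(run_maps) {
  stopifnot(length(run_maps) >= 1L)
  V <- .map_matrix(run_maps)
  stat_map(rowMeans(V), "beta", "subject", run_maps[[1]]$label)
}

#' Group-level one-sample t and z maps
#'
#' Random-effects one-sample t test of the subject-level values against zero,
#' per voxel, with `n - 1` degrees of freedom. Voxels with zero
#' between-subject variance are masked unless all values are exactly zero
#' (then t = 0 by convention).
#'
#' @param subject_maps List of subject-level [stat_map()]s (n >= 2).
#' @return List of [stat_map()]s `t` and `z` at group level.
#' @export
group_level <- function(subject_maps) {
  n <- length(subject_maps)
  if (n < 2L) stop("group level needs at least 2 subjects")
  V <- .map_matrix(subject_maps)
  m <- rowMeans(V)
  s <- apply(V, 1, sd)
  tval <- m / (s / sqrt(n))
  tval[s == 0 & m == 0] <- 0
  tval[s == 0 & m != 0] <- NA_real_
  dof <- n - 1
  lab <- subject_maps[[1]]$label
  list(t = stat_map(tval, "t", "group", lab, dof = dof),
       z = stat_map(.t_to_z(tval, dof), "z", "group", lab))
}

#' Benjamini-Hochberg FDR thresholding of a map
#'
#' Two-sided p-values are derived from a z map (or taken directly from a
#' `p`-kind map) and submitted to the Benjamini-Hochberg step-up rule. Masked
#' voxels are excluded from the procedure and never rejected.
#'
#' @param map A `z` or `p` [stat_map()].
#' @param q Acceptable false discovery rate (0 < q < 1).
#' @return List with `mask` (logical rejections), `n_rejected`, and
#'   `z_threshold` (smallest rejected |z|; `Inf` when nothing is rejected, and
#'   `NA` for p-kind input).
#' @export
fdr_threshold <- function(map, q = 0.05) {
  stopifnot(inherits(map, "stat_map"), q > 0, q < 1)
  if (length(map$values) == 0L) stop("empty map")
  if (map$kind == "p") {
    p <- map$values
  } else if (map$kind == "z") {
    p <- 2 * pnorm(-abs(map$values))
  } else {
    stop("fdr_threshold expects a z or p map")
  }
  ok <- !is.na(p)
  padj <- rep(NA_real_, length(p))
  padj[ok] <- p.adjust(p[ok], method = "BH")
  mask <- !is.na(padj) & padj <= q
  zthr <- if (map$kind == "z") {
    if (any(mask)) min(abs(map$values[mask])) else Inf
  } else NA_real_
  list(mask = mask, n_rejected = sum(mask), z_threshold = zthr)
}

#' Hedge's g effect-size map
#'
#' One-sample standardized mean difference against zero across subjects with
#' the small-sample correction `J = 1 - 3 / (4 (n - 1) - 1)`. Voxels with
#' zero between-subject variance are masked unless all values are exactly
#' zero (g = 0 by convention).
#'
#' @param subject_maps List of subject-level [stat_map()]s (n >= 2).
#' @return A group-level `g` [stat_map()].
#' @export
hedges_g_map <- function(subject_maps) {
  n <- length(subject_maps)
  if (n < 2L) stop("Hedge's g needs at least 2 subjects")
  V <- .map_matrix(subject_maps)
  m <- rowMeans(V)
  s <- apply(V, 1, sd)
  J <- 1 - 3 / (4 * (n - 1) - 1)
  g <- m / s * J
  g[s == 0 & m == 0] <- 0
  g[s == 0 & m != 0] <- NA_real_
  stat_map(g, "g", "group", subject_maps[[1]]$label)
}

#' Winner map across effect-size maps
#'
#' For each voxel, the analysis strategy with the largest Hedge's g, provided
#' that maximum exceeds the threshold; otherwise `"none"`. Ties are broken by
#' the fixed label order SBD1 < SBD2 < MBD1 < MBD2. Masked g values never
#' win.
#'
#' @param g_maps Named list of exactly the four `g` maps `SBD1`, `SBD2`,
#'   `MBD1`, `MBD2` on a common grid.
#' @param threshold Minimum winning g (default 0.4).
#' @return An object of class `winner_map`: a factor with levels `SBD1`,
#'   `SBD2`, `MBD1`, `MBD2`, `none`, with the threshold as attribute.
#' @export
winner_map <- function(g_maps, threshold = 0.4) {
  labels <- c("SBD1", "SBD2", "MBD1", "MBD2")
  if (!setequal(names(g_maps), labels)) {
    stop("g_maps must be named exactly SBD1, SBD2, MBD1, MBD2")
  }
  G <- .map_matrix(g_maps[labels])
  G[is.na(G)] <- -Inf
  best <- max.col(G, ties.method = "first")
  mx <- G[cbind(seq_len(nrow(G)), best)]
  lab <- ifelse(mx > threshold, labels[best], "none")
  structure(factor(lab, levels = c(labels, "none")),
            threshold = threshold, class = c("winner_map", "factor"))
}

#' @export
print.winner_map <- function(x, ...) {
  cat(sprintf("<winner_map> threshold g > %g\n", attr(x, "threshold")))
  print(table(factor(as.character(x), levels = levels(x))))
  invisible(x)
}

#' Block-wise amplitude estimates (habituation profile)
#'
#' Refits the run with one predictor per odorant block: for the SBD
#' strategies the block's boxcar, for the MBD strategies that block's
#' i_odorant inhalation events. The `*2` variants add the odorless-air
#' predictor of the corresponding strategy (air boxcar, or all i_air events).
#' Odorant blocks without any inhalation event under an MBD strategy are
#' masked (NA) rather than estimated.
#'
#' @param run A [bold_run()] or voxels x volumes matrix.
#' @param schedule A [block_schedule()].
#' @param events Labelled events (required for MBD strategies).
#' @param strategy One of `"SBD1"`, `"SBD2"`, `"MBD1"`, `"MBD2"`.
#' @param model An [hrf_model()].
#' @param tr Repetition time (s).
#' @return Matrix voxels x odorant blocks of amplitude estimates.
#' @export
blockwise_amplitudes <- function(run, schedule, events = NULL,
                                 strategy = c("SBD1", "SBD2", "MBD1", "MBD2"),
                                 model = hrf_model(), tr = 2) {
  strategy <- match.arg(strategy)
  Y <- if (inherits(run, "sniff_bold")) run$data else as.matrix(run)
  n_volumes <- ncol(Y)
  dur <- ceiling(schedule$run_duration)
  ph <- schedule_phases(schedule)
  odor_ph <- ph[ph$phase == "odorant", , drop = FALSE]
  K <- nrow(odor_ph)
  modulated <- strategy %in% c("MBD1", "MBD2")
  if (modulated && is.null(events)) stop("MBD strategies need labelled events")
  cols <- list()
  for (k in seq_len(K)) {
    neural <- if (modulated) {
      sel <- events$condition == "i_odorant" &
        events$onset >= odor_ph$start[k] &
        events$onset + events$duration <= odor_ph$end[k]
      sel <- events[sel, , drop = FALSE]
      if (nrow(sel) == 0L) NULL else
        .boxcar_1hz(data.frame(start = sel$onset, end = sel$onset + sel$duration), dur)
    } else {
      .boxcar_1hz(odor_ph[k, , drop = FALSE], dur)
    }
    cols[[paste0("block_", k)]] <- neural
  }
  present <- !vapply(cols, is.null, logical(1))
  mat <- vapply(cols[present], .predictor_at_volumes, numeric(n_volumes),
                model = model, tr = tr, n_volumes = n_volumes)
  if (strategy == "SBD2") {
    mat <- cbind(mat, air = .predictor_at_volumes(
      .boxcar_1hz(ph[ph$phase == "air", ], dur), model, tr, n_volumes))
  } else if (strategy == "MBD2") {
    sel <- events[events$condition == "i_air", , drop = FALSE]
    if (nrow(sel) > 0L) {
      mat <- cbind(mat, i_air = .predictor_at_volumes(
        .boxcar_1hz(data.frame(start = sel$onset, end = sel$onset + sel$duration),
                    dur), model, tr, n_volumes))
    }
  }
  X <- design_matrix((seq_len(n_volumes) - 1) * tr,
                     cbind(mat, constant = 1), strategy)
  fit <- fit_glm(Y, X)
  out <- matrix(NA_real_, nrow(Y), K,
                dimnames = list(NULL, paste0("block_", seq_len(K))))
  out[, present] <- fit$betas[, paste0("block_", which(present)), drop = FALSE]
  out
}

#' Gaussian spatial smoothing of a 3D map (optional utility)
#'
#' Separable Gaussian smoothing with the kernel width given as full width at
#' half maximum in millimetres. Intended for maps carrying 3D geometry; it is
#' never applied implicitly.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm Full width at half maximum, millimetres.
#' @param voxel_size_mm Voxel edge lengths (length 1 or 3), millimetres.
#' @return The smoothed array.
#' @export
smooth_gaussian <- function(volume, fwhm_mm = 8, voxel_size_mm = 2) {
  stopifnot(length(dim(volume)) == 3L)
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  out <- volume
  for (axis in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm[axis]
    half <- max(1L, ceiling(3 * sigma))
    k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    k <- k / sum(k)
    out <- apply(out, setdiff(1:3, axis), function(v) {
      n <- length(v)
      padded <- c(rep(v[1], half), v, rep(v[n], half))
      as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + n)]
    })
    out <- aperm(out, order(c(axis, setdiff(1:3, axis))))
  }
  out
}
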