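# Deformation-based morphometry statistics.
#
# The Jacobian determinant of the deformation taking an individual brain to
# atlas space gives the local volume-change factor at each voxel; summing it
# over an atlas structure (times the voxel volume) yields that structure's
# volume in the individual. Group analysis fits, separately within each sex,
# a linear model with a genotype contrast at every brain voxel, with
# Benjamini-Hochberg FDR control across voxels.

#' Integrate structure volumes from a Jacobian map
#'
#' Absolute volume of structure S for a subject is
#' `sum over voxels v in S of jac(v) * voxel_size^3`; the whole-brain volume
#' is the same sum over all labels > 0. With an identity Jacobian this is
#' simply voxel count times voxel volume.
#'
#' @param atlas A [label_atlas()].
#' @param jac A [jacobian_map()] on the same grid.
#' @return A data.frame with columns `subject_id`, `structure`,
#'   `absolute_volume` (mm^3), plus attribute `whole_brain` (mm^3).
#' @export
integrate_structure_volumes <- function(atlas, jac) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(jac, "jacobian_map"))
  if (!identical(dim(atlas$labels), dim(jac$values))) {
    stop(sprintf("grid mismatch: atlas %s vs map %s",
                 paste(dim(atlas$labels), collapse = "x"),
                 paste(dim(jac$values), collapse = "x")), call. = FALSE)
  }
  if (any(jac$values <= 0)) {
    stop("Jacobian determinants must be strictly positive", call. = FALSE)
  }
  lab <- as.vector(atlas$labels)
  val <- as.vector(jac$values)
  in_brain <- lab > 0
  sums <- rowsum(val[in_brain], lab[in_brain]) * atlas$voxel_size^3
  lab_order <- as.integer(rownames(sums))
  out <- data.frame(
    subject_id = jac$subject_id,
    structure = names(atlas$name_map)[match(lab_order, atlas$name_map)],
    absolute_volume = as.vector(sums),
    stringsAsFactors = FALSE
  )
  attr(out, "whole_brain") <- sum(sums)
  out
}

#' Add whole-brain-relative volumes to a volume table
#'
#' Because whole-brain size itself differs between groups (growth
#' retardation), structure volumes are also expressed relative to each
#' subject's whole-brain volume: `relative = absolute / whole_brain`.
#'
#' @param volumes Data.frame with columns `subject_id`, `structure`,
#'   `absolute_volume` covering, per subject, a full partition of the brain.
#' @return The table with a `relative_volume` column added.
#' @export
relative_volumes <- function(volumes) {
  wb <- tapply(volumes$absolute_volume, volumes$subject_id, sum)
  if (any(wb <= 0)) stop("whole-brain volume must be > 0", call. = FALSE)
  volumes$relative_volume <-
    volumes$absolute_volume / as.vector(wb[volumes$subject_id])
  volumes
}

# Vectorized one-covariate least squares across many responses.
# y: n x V matrix, g: 0/1 genotype indicator. Returns per-column t (on the
# genotype coefficient), two-sided p on n-2 df, and the coefficient itself.
# Columns with (numerically) zero residual variance get NA t and p.
lm_contrast_cols <- function(y, g) {
  n <- length(g)
  if (n != nrow(y)) stop("design/response size mismatch", call. = FALSE)
  x <- cbind(1, g)
  xtx_inv <- solve(crossprod(x))
  beta <- xtx_inv %*% crossprod(x, y)          # 2 x V
  fitted <- x %*% beta
  rss <- colSums((y - fitted)^2)
  df <- n - 2L
  sigma2 <- rss / df
  # flag voxels where the residual SS is zero to numerical precision
  scale_ref <- colSums(y^2) + 1
  undefined <- rss <= scale_ref * 1e-24
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  t_stat <- beta[2, ] / se
  t_stat[undefined] <- NA_real_
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(estimate = beta[2, ], t = t_stat, p = p, df = df,
       n_undefined = sum(undefined))
}

#' Voxel-wise linear model with genotype contrast, within one sex
#'
#' At every brain voxel fits `response = intercept + genotype` on the
#' (by default log-transformed) Jacobian values of the stratum's subjects and
#' reports the genotype-contrast t statistic and two-sided p value on n - 2
#' degrees of freedom. With a single binary covariate this is algebraically
#' the pooled-variance two-sample t test. Voxels with zero residual variance
#' are reported as NA and excluded from any subsequent FDR step.
#'
#' @param jacs Named list of [jacobian_map()]s (names = subject ids).
#' @param design Cohort design data.frame (`subject_id`, `sex`, `genotype`).
#' @param sex Stratum to analyze, `"M"` or `"F"`.
#' @param atlas Optional [label_atlas()]; if given, statistics are computed
#'   for brain voxels (label > 0) only and returned as maps with NA outside.
#' @param scale `"log"` (default) to model log-Jacobians, `"raw"` for the
#'   untransformed values.
#' @return A list of class `voxel_stats` with 3D arrays `t` and `p`, plus
#'   `df`, `sex`, `n_subjects`, `n_undefined`.
#' @export
voxelwise_lm <- function(jacs, design, sex, atlas = NULL,
                         scale = c("log", "raw")) {
  scale <- match.arg(scale)
  stratum <- design[design$sex == sex, ]
  counts <- table(factor(stratum$genotype, levels = c("WT", "KO")))
  if (any(counts == 0)) {
    stop(sprintf("genotype level(s) absent in sex stratum %s: %s", sex,
                 paste(names(counts)[counts == 0], collapse = ", ")),
         call. = FALSE)
  }
  if (any(counts < 2)) {
    stop(sprintf("need >= 2 subjects per genotype in stratum %s", sex),
         call. = FALSE)
  }
  missing_maps <- setdiff(stratum$subject_id, names(jacs))
  if (length(missing_maps)) {
    stop(sprintf("no Jacobian map for subject(s): %s",
                 paste(missing_maps, collapse = ", ")), call. = FALSE)
  }
  shp <- dim(jacs[[stratum$subject_id[1]]]$values)
  keep <- if (is.null(atlas)) rep(TRUE, prod(shp)) else as.vector(atlas$labels) > 0
  y <- vapply(stratum$subject_id, function(s) {
    v <- as.vector(jacs[[s]]$values)[keep]
    if (scale == "log") log(v) else v
  }, numeric(sum(keep)))
  y <- t(y)                       # subjects x voxels
  g <- as.integer(stratum$genotype == "KO")
  fit <- lm_contrast_cols(y, g)
  t_map <- array(NA_real_, shp); t_map[keep] <- fit$t
  p_map <- array(NA_real_, shp); p_map[keep] <- fit$p
  structure(
    list(t = t_map, p = p_map, df = fit$df, sex = sex,
         n_subjects = nrow(stratum), n_undefined = fit$n_undefined,
         scale = scale),
    class = "voxel_stats"
  )
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: with ordered p values p_(1) <= ... <= p_(m), reject all
#' hypotheses up to the largest i with p_(i) <= (i/m) q. Adjusted q values
#' are the monotone-corrected p * m / i. NA p values (e.g. zero-variance
#' voxels) are excluded from m and never significant.
#'
#' @param p Numeric vector (or array) of p values in \[0, 1\]; NAs allowed.
#' @param level FDR level q (default 0.01, the stringent 1% setting used for
#'   the voxel maps).
#' @return A list with `q` (adjusted values, same shape as `p`) and
#'   `significant` (logical, `q <= level`, FALSE for NA).
#' @export
fdr_bh <- function(p, level = 0.01) {
  dims <- dim(p)
  pv <- as.vector(p)
  if (!length(pv)) {
    return(list(q = p, significant = logical(0), level = level))
  }
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) {
    stop("p values must be in [0, 1]", call. = FALSE)
  }
  ok <- !is.na(pv)
  q <- rep(NA_real_, length(pv))
  q[ok] <- stats::p.adjust(pv[ok], method = "BH")
  sig <- !is.na(q) & q <= level
  if (!is.null(dims)) { dim(q) <- dims; dim(sig) <- dims }
  list(q = q, significant = sig, level = level)
}

#' Per-sex genotype tests on structure-level relative volumes
#'
#' Applies the same genotype-contrast linear model to each structure's
#' per-subject relative volumes, within each sex stratum, and adds
#' BH-adjusted q values across structures within the stratum.
#'
#' @param volumes Volume table with `relative_volume` (see
#'   [relative_volumes()]).
#' @param design Cohort design data.frame.
#' @return Data.frame with one row per sex x structure: `estimate` (KO - WT
#'   mean difference), `t`, `p`, `q`.
#' @export
structure_level_tests <- function(volumes, design) {
  out <- list()
  for (sx in unique(design$sex)) {
    stratum <- design[design$sex == sx, ]
    sub <- volumes[volumes$subject_id %in% stratum$subject_id, ]
    wide <- stats::reshape(
      sub[, c("subject_id", "structure", "relative_volume")],
      direction = "wide", idvar = "subject_id", timevar = "structure"
    )
    structures <- sub("^relative_volume\\.", "", names(wide)[-1])
    y <- as.matrix(wide[, -1, drop = FALSE])
    g <- as.integer(stratum$genotype[match(wide$subject_id,
                                           stratum$subject_id)] == "KO")
    fit <- lm_contrast_cols(y, g)
    adj <- fdr_bh(fit$p, level = 1)  # q values; significance judged by caller
    out[[sx]] <- data.frame(
      sex = sx, structure = structures, estimate = fit$estimate,
      t = fit$t, p = fit$p, q = adj$q, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full morphometry analysis of a cohort
#'
#' Integrates absolute and whole-brain-relative structure volumes for every
#' subject, runs the per-sex voxel-wise genotype linear model with BH FDR at
#' `level` across brain voxels, and runs per-sex structure-level genotype
#' tests on relative volumes (reported with uncorrected p and BH q).
#'
#' @param atlas A [label_atlas()].
#' @param jacs Named list of [jacobian_map()]s.
#' @param design Cohort design data.frame.
#' @param level Voxel-wise FDR level (default 0.01).
#' @param scale Modeling scale for the voxel-wise analysis, `"log"` or
#'   `"raw"`.
#' @return A list with `volumes` (per-subject absolute + relative volumes),
#'   `voxel_stats` (per-sex list; each with `t`, `p`, `q`, `significant`
#'   maps) and `structure_tests`.
#' @export
run_morphometry <- function(atlas, jacs, design, level = 0.01,
                            scale = c("log", "raw")) {
  scale <- match.arg(scale)
  vols <- do.call(rbind, lapply(design$subject_id, function(s) {
    if (!s %in% names(jacs)) {
      stop(sprintf("no Jacobian map for subject %s", s), call. = FALSE)
    }
    integrate_structure_volumes(atlas, jacs[[s]])
  }))
  rownames(vols) <- NULL
  vols <- relative_volumes(vols)
  meta_idx <- match(vols$subject_id, design$subject_id)
  vols$sex <- design$sex[meta_idx]
  vols$genotype <- design$genotype[meta_idx]
  voxel <- list()
  for (sx in unique(design$sex)) {
    vs <- voxelwise_lm(jacs, design, sx, atlas = atlas, scale = scale)
    adj <- fdr_bh(vs$p, level = level)
    vs$q <- adj$q
    vs$significant <- adj$significant
    voxel[[sx]] <- vs
  }
  list(volumes = vols, voxel_stats = voxel,
       structure_tests = structure_level_tests(vols, design),
       fdr_level = level)
}
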