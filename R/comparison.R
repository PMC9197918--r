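#' Normalize a velocity field by a reference speed
#'
#' Dividing by the inlet peak speed V_ref removes the modality-dependent
#' absolute velocity scale before fields from differently scaled systems
#' are compared.
#'
#' @param field a [velocity_field].
#' @param v_ref reference speed, m/s, > 0.
#' @return the [velocity_field] with all components divided by `v_ref`
#'   (now dimensionless).
#' @export
normalize_velocity <- function(field, v_ref) {
  if (!is.finite(v_ref) || v_ref <= 0) stop("v_ref must be > 0")
  field$u <- field$u / v_ref
  field
}

#' Down-sample a velocity field by trilinear interpolation
#'
#' Resamples the source at the voxel centres of a coarser grid ("bilinear"
#' matching in 3D, hence trilinear — exact on affine fields).  A target
#' voxel is lumen only when all 8 enclosing source corners are lumen;
#' everything else is masked out.
#'
#' @param field a [velocity_field].
#' @param target_spacing scalar or length-3, m; must be >= the source
#'   spacing componentwise.
#' @return a [velocity_field] at the target spacing.
#' @export
downsample <- function(field, target_spacing) {
  sp_t <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(sp_t < field$spacing - 1e-15))
    stop("target_spacing must be >= source spacing componentwise")
  d <- field$dims
  extent_hi <- field$origin + (d - 1) * field$spacing
  nt <- pmax(1, floor((extent_hi - field$origin) / sp_t + 1e-9) + 1)
  if (any(nt < 1)) stop("target grid is empty")
  idx <- arrayInd(seq_len(prod(nt)), nt)
  pts <- sweep(sweep(idx - 1, 2, sp_t, "*"), 2, field$origin, "+")
  comps <- lapply(1:3, function(c3) array(field$u[, , , c3], d))
  smp <- trilinear_sample(field, comps, pts)
  mask_t <- array(!is.na(smp[, 1]) & !is.na(smp[, 2]) & !is.na(smp[, 3]), nt)
  smp[is.na(smp)] <- 0
  u_t <- array(0, c(nt, 3))
  for (c3 in 1:3) u_t[, , , c3] <- array(smp[, c3], nt)
  velocity_field(u_t, sp_t, field$origin, mask_t)
}

#' Sample a velocity-magnitude profile along a line
#'
#' Equally spaced trilinear samples of the speed from `start` to `end`
#' inclusive; samples falling outside the lumen are `NA`.
#'
#' @param field a [velocity_field].
#' @param start,end length-3 numeric endpoints, m.
#' @param n_samples number of samples, >= 2.
#' @return object of class `"profile_line"`: list with `start`, `end`,
#'   `n_samples`, `positions` (arc length from `start`, m), `values`.
#' @export
extract_profile <- function(field, start, end, n_samples = 50) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  start <- as.numeric(start); end <- as.numeric(end)
  t <- seq(0, 1, length.out = n_samples)
  pts <- cbind(start[1] + t * (end[1] - start[1]),
               start[2] + t * (end[2] - start[2]),
               start[3] + t * (end[3] - start[3]))
  vals <- trilinear_sample(field, field_speed(field), pts)
  if (all(is.na(vals)))
    stop("profile lies entirely outside the lumen")
  structure(list(start = start, end = end, n_samples = as.integer(n_samples),
                 positions = t * sqrt(sum((end - start)^2)), values = vals),
            class = "profile_line")
}

#' Pearson correlation of two profiles
#'
#' Computed over the samples that are non-missing in both profiles.
#'
#' @param a,b `profile_line` objects (or plain numeric vectors) of equal
#'   length.
#' @return the sample Pearson correlation coefficient, in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  va <- if (inherits(a, "profile_line")) a$values else as.numeric(a)
  vb <- if (inherits(b, "profile_line")) b$values else as.numeric(b)
  if (length(va) != length(vb))
    stop("profiles must have the same number of samples")
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 2) stop("need at least 2 shared non-missing samples")
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(va[ok], vb[ok])
}

#' Bland-Altman agreement analysis
#'
#' Pairwise differences `a - b` summarised by their mean, sample standard
#' deviation (n - 1 denominator) and the 95% limits of agreement
#' `mean +/- 1.96 * SD`.  Non-finite pairs are dropped pairwise.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return object of class `"bland_altman"`: list with `mean_diff`, `sd`,
#'   `loa_low`, `loa_high`, `pairs`, and the per-pair `means` and `diffs`
#'   for plotting and proportional-bias inspection.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("need at least 2 finite pairs")
  diffs <- a - b
  means <- (a + b) / 2
  md <- mean(diffs)
  s <- stats::sd(diffs)
  structure(list(mean_diff = md, sd = s,
                 loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
                 pairs = length(a), means = means, diffs = diffs),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman over %d pairs: mean diff %.4g, SD %.4g, LoA [%.4g, %.4g]\n",
              x$pairs, x$mean_diff, x$sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' Proportional-bias slope of a Bland-Altman result
#'
#' Least-squares slope of difference versus mean — a descriptive trend
#' statistic: a positive slope says the disagreement grows with the
#' magnitude of the measured quantity.
#'
#' @param result a `bland_altman` object with >= 3 pairs.
#' @return the slope (dimensionless).
#' @export
proportional_bias <- function(result) {
  stopifnot(inherits(result, "bland_altman"))
  if (result$pairs < 3) stop("need at least 3 pairs for a trend estimate")
  if (stats::sd(result$means) == 0)
    stop("slope undefined: zero variance of the pair means")
  unname(stats::coef(stats::lm(result$diffs ~ result$means))[2])
}
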