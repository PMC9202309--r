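#' Pulling work and rupture force from a force profile
#'
#' `W_pull = sum_i F_i (x_i - x_{i-1})` over the recorded samples (a
#' left-Riemann discretization of the force-displacement integral, with the
#' first sample as the integration origin); `F_max` is the largest recorded
#' spring force. Displacement is the cumulative projected pulled-atom
#' displacement along the instantaneous direction, accumulated across
#' intervals, so the sum integrates across direction changes.
#'
#' @param profile a `force_profile`.
#' @param units `"kJ/mol"` (default) or `"kcal/mol"` for the work.
#' @param method `"riemann"` (the printed per-step sum) or `"trapezoid"`.
#' @param trajectory_id optional label.
#' @return list of class `work_result` with `w_pull`, `f_max`, `units`,
#'   `trajectory_id`.
#' @export
compute_work <- function(profile, units = c("kJ/mol", "kcal/mol"),
                         method = c("riemann", "trapezoid"),
                         trajectory_id = NA) {
  units <- match.arg(units)
  method <- match.arg(method)
  f <- profile$forces
  x <- profile$displacements
  n <- length(f)
  stopifnot(n >= 1, length(x) == n)
  dx <- diff(x)
  w <- if (n == 1) 0
  else if (method == "riemann") sum(f[-1] * dx)
  else sum((f[-1] + f[-n]) / 2 * dx)
  if (units == "kcal/mol") w <- w / .KJ_PER_KCAL
  structure(list(w_pull = w, f_max = max(f), units = units,
                 trajectory_id = trajectory_id),
            class = "work_result")
}

#' Pearson correlation between pulling work and an affinity proxy
#'
#' Standard product-moment correlation; `r_squared = r^2` (the square of
#' the correlation coefficient of a simple linear fit, not a multi-model
#' coefficient of determination).
#'
#' @param work,ln_ic50 equal-length numeric vectors (n >= 3), both with
#'   nonzero variance.
#' @return list of class `correlation_result`: `r`, `r_squared`, `n`.
#' @export
pearson <- function(work, ln_ic50) {
  stopifnot(length(work) == length(ln_ic50), length(work) >= 3)
  if (stats::sd(work) == 0 || stats::sd(ln_ic50) == 0)
    stop("undefined correlation: zero variance in an input")
  r <- stats::cor(work, ln_ic50)
  structure(list(r = r, r_squared = r^2, n = length(work)),
            class = "correlation_result")
}

#' Affinity records from IC50 values
#'
#' @param ligand_id identifiers.
#' @param ic50 IC50 in mol/L (> 0).
#' @return data frame with `ligand_id`, `ic50`, `ln_ic50 = log(ic50)`.
#' @export
affinity_table <- function(ligand_id, ic50) {
  stopifnot(all(ic50 > 0))
  data.frame(ligand_id = ligand_id, ic50 = ic50, ln_ic50 = log(ic50))
}

#' Success rate of an ensemble
#'
#' Percentage of trajectories whose status is `exited` (trajectories that
#' ended with the ligand fully outside the receptor).
#'
#' @param results list of `path_result`s (error entries count as failures).
#' @return percent.
#' @export
success_rate <- function(results) {
  stopifnot(length(results) >= 1)
  ok <- vapply(results, function(p)
    inherits(p, "path_result") && p$status == "exited", logical(1))
  100 * mean(ok)
}

#' Per-pathway percentages from counts
#'
#' @param counts named integer vector (or data frame with `label`,
#'   `count`) of trajectories per pathway; total must be positive.
#' @return data frame with `label`, `count`, `percent` (exact) and
#'   `percent_rounded` (nearest integer).
#' @export
pathway_percentage <- function(counts) {
  if (is.data.frame(counts)) counts <- setNames(counts$count, counts$label)
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  data.frame(label = names(counts), count = as.integer(counts),
             percent = 100 * counts / total,
             percent_rounded = round(100 * counts / total),
             row.names = NULL)
}

#' Classify egress paths by ground-truth gates
#'
#' A path is labeled with the first gate sphere its ligand-CoM track enters
#' after first leaving the binding-site sphere; paths entering no gate are
#' `"unassigned"`. With `gates = NULL` a heuristic fallback clusters exit
#' directions (complete linkage on angular distance, threshold
#' `angle_threshold`) and labels clusters `C1, C2, ...`.
#'
#' @param paths list of `path_result`s.
#' @param gates data frame with `label`, `x`, `y`, `z`, `radius` (pairwise
#'   disjoint spheres), or NULL for the clustering fallback.
#' @param site_center,site_radius binding-site sphere (nm).
#' @param angle_threshold degrees, for the gate-free fallback.
#' @return character vector of labels, one per path.
#' @export
classify_pathways <- function(paths, gates = NULL,
                              site_center = c(0, 0, 0), site_radius = 0.5,
                              angle_threshold = 45) {
  com_track <- function(p)
    as.matrix(p$waypoints[, c("com_x", "com_y", "com_z")])
  if (is.null(gates)) {
    exits <- t(vapply(paths, function(p) {
      tr <- com_track(p)
      unit_vec(tr[nrow(tr), ] - site_center)
    }, numeric(3)))
    if (nrow(exits) == 1) return("C1")
    ang <- acos(pmin(pmax(tcrossprod(exits), -1), 1)) * 180 / pi
    cl <- stats::cutree(stats::hclust(stats::as.dist(ang), "complete"),
                        h = angle_threshold)
    return(paste0("C", cl))
  }
  gc <- as.matrix(gates[, c("x", "y", "z")])
  # disjointness
  if (nrow(gates) > 1) {
    dd <- as.matrix(stats::dist(gc))
    rr <- outer(gates$radius, gates$radius, `+`)
    diag(dd) <- Inf
    if (any(dd < rr)) stop("gate spheres must be pairwise disjoint")
  }
  vapply(paths, function(p) {
    tr <- com_track(p)
    outside <- sqrt(colSums((t(tr) - site_center)^2)) > site_radius
    first_out <- match(TRUE, outside)
    if (is.na(first_out)) return("unassigned")
    for (i in first_out:nrow(tr)) {
      d <- sqrt(colSums((t(gc) - tr[i, ])^2))
      hit <- which(d <= gates$radius)
      if (length(hit)) return(as.character(gates$label[hit[1]]))
    }
    "unassigned"
  }, character(1))
}

#' Bootstrap pathway populations
#'
#' Resamples the label list with replacement `n_resamples` times and
#' reports, per label, the mean and standard deviation of its percentage
#' across resamples.
#'
#' @param labels character vector of pathway labels.
#' @param n_resamples bootstrap resample count (default 20000).
#' @param seed optional RNG seed.
#' @return data frame of class `pathway_population`: `label`, `count`,
#'   `mean_percent`, `sd_percent`.
#' @export
bootstrap_populations <- function(labels, n_resamples = 20000,
                                  seed = NULL) {
  stopifnot(length(labels) >= 1)
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  n <- length(labels)
  codes <- match(labels, lev)
  draws <- matrix(codes[sample.int(n, n * n_resamples, replace = TRUE)],
                  n_resamples, n)
  means <- numeric(length(lev))
  sds <- numeric(length(lev))
  for (k in seq_along(lev)) {
    pct <- 100 * rowMeans(draws == k)
    means[k] <- mean(pct)
    sds[k] <- stats::sd(pct)
  }
  structure(data.frame(label = lev, count = as.integer(table(codes)),
                       mean_percent = means, sd_percent = sds),
            class = c("pathway_population", "data.frame"))
}

#' Detect force peaks in a pulling profile
#'
#' Smooths the force trace with a running mean and reports local maxima
#' that stand above `min_height_frac` of the global maximum and are
#' separated from a previously accepted peak by a valley dropping below
#' `valley_frac` of the smaller of the two peaks. Two or more peaks signal
#' the collision artifact of unidirectional pulling (a secondary rupture
#' event after the main one).
#'
#' @param profile a `force_profile`.
#' @param smooth_ps running-mean window, ps.
#' @param min_height_frac minimum peak height as a fraction of the global
#'   smoothed maximum.
#' @param valley_frac required relative drop between consecutive peaks.
#' @return data frame with `time_ps`, `force` per detected peak.
#' @export
detect_force_peaks <- function(profile, smooth_ps = 4,
                               min_height_frac = 0.35, valley_frac = 0.6) {
  f <- profile$forces
  t <- profile$times
  if (length(f) < 3) return(data.frame(time_ps = numeric(0),
                                       force = numeric(0)))
  dt <- stats::median(diff(t))
  w <- max(3L, as.integer(round(smooth_ps / dt)))
  if (w %% 2 == 0) w <- w + 1L
  fs <- as.numeric(stats::filter(f, rep(1 / w, w), sides = 2))
  fs[is.na(fs)] <- f[is.na(fs)]
  gmax <- max(fs)
  if (gmax <= 0) return(data.frame(time_ps = numeric(0),
                                   force = numeric(0)))
  # local maxima on the smoothed trace
  core <- seq(2, length(fs) - 1)
  is_max <- c(FALSE, fs[core] >= fs[core - 1] & fs[core] > fs[core + 1],
              FALSE) & fs >= min_height_frac * gmax
  idx <- which(is_max)
  kept <- integer(0)
  for (i in idx) {
    if (!length(kept)) { kept <- i; next }
    last <- kept[length(kept)]
    valley <- min(fs[last:i])
    if (valley < valley_frac * min(fs[last], fs[i])) kept <- c(kept, i)
    else if (fs[i] > fs[last]) kept[length(kept)] <- i
  }
  data.frame(time_ps = t[kept], force = fs[kept])
}

#' Has a pulling profile a secondary force peak?
#'
#' @inheritParams detect_force_peaks
#' @return TRUE when [detect_force_peaks()] finds two or more peaks.
#' @export
has_secondary_peak <- function(profile, smooth_ps = 4,
                               min_height_frac = 0.35, valley_frac = 0.6) {
  nrow(detect_force_peaks(profile, smooth_ps, min_height_frac,
                          valley_frac)) >= 2
}

#' Summarize pulling work over an ensemble
#'
#' Means and standard deviations of `W_pull` and `F_max` over the exited
#' trajectories; warns when the work SD exceeds 10% of the mean (the
#' trajectory-count adequacy rule).
#'
#' @param results list of `path_result`s.
#' @param units passed to [compute_work()].
#' @param exited_only restrict to exited trajectories (default TRUE).
#' @return data frame with one row: `n`, `mean_work`, `sd_work`,
#'   `mean_fmax`, `sd_fmax`.
#' @export
summarize_work <- function(results, units = "kJ/mol", exited_only = TRUE) {
  keep <- vapply(results, function(p)
    inherits(p, "path_result") &&
      (!exited_only || p$status == "exited"), logical(1))
  ws <- vapply(results[keep], function(p)
    compute_work(p$profile, units)$w_pull, numeric(1))
  fm <- vapply(results[keep], function(p)
    compute_work(p$profile, units)$f_max, numeric(1))
  if (length(ws) >= 2 && stats::sd(ws) > 0.1 * abs(mean(ws)))
    warning("work SD exceeds 10% of the mean; consider more trajectories")
  data.frame(n = length(ws), mean_work = mean(ws),
             sd_work = if (length(ws) > 1) stats::sd(ws) else NA_real_,
             mean_fmax = mean(fm),
             sd_fmax = if (length(fm) > 1) stats::sd(fm) else NA_real_)
}
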