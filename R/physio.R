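#' Step-locked physiological epochs
#'
#' Container for channels x time epochs locked to message steps, one
#' surprise value per epoch.
#'
#' @param data Numeric 4-d array: subjects x epochs x channels x
#'   timepoints.
#' @param step_surprise Numeric matrix, subjects x epochs.
#' @param neighbors Symmetric logical/0-1 channel adjacency matrix.
#' @param times Time axis in ms (one value per timepoint).
#' @return An object of class `tcg_epochs`.
#' @export
tcg_epochs <- function(data, step_surprise, neighbors, times) {
  stopifnot(length(dim(data)) == 4L)
  step_surprise <- as.matrix(step_surprise)
  if (!all(dim(step_surprise) == dim(data)[1:2]))
    stop("step_surprise must be subjects x epochs")
  neighbors <- neighbors | t(neighbors)  # enforce symmetry
  if (nrow(neighbors) != dim(data)[3L])
    stop("neighbor graph size does not match the channel count")
  if (length(times) != dim(data)[4L])
    stop("times must have one value per timepoint")
  structure(list(data = data, step_surprise = step_surprise,
                 neighbors = neighbors, times = times,
                 baseline_window = NULL),
            class = "tcg_epochs")
}

#' @export
print.tcg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Step-locked epochs: %d subjects x %d epochs x %d channels x %d timepoints (%g-%g ms)\n",
              d[1L], d[2L], d[3L], d[4L], min(x$times), max(x$times)))
  if (!is.null(x$baseline_window))
    cat(sprintf(" baseline-corrected over [%g, %g] ms\n",
                x$baseline_window[1L], x$baseline_window[2L]))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean activity inside the baseline
#' window from the whole epoch.  The correction is idempotent and records
#' the window in the object's metadata.
#'
#' @param epochs A [tcg_epochs()].
#' @param window `c(lo, hi)` ms; must contain at least one sample.
#' @param mode Only `"subtract_mean"` is defined.
#' @return The corrected `tcg_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(0, 100),
                             mode = "subtract_mean") {
  stopifnot(inherits(epochs, "tcg_epochs"))
  mode <- match.arg(mode)
  idx <- which(epochs$times >= window[1L] & epochs$times <= window[2L])
  if (!length(idx)) stop("empty baseline window")
  base <- apply(epochs$data[, , , idx, drop = FALSE], 1:3, mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over time, dim 4
  epochs$baseline_window <- window
  epochs
}

#' Mass-univariate regression of epochs on step surprise
#'
#' Per subject, channel and timepoint, the least-squares slope (with
#' intercept) of the epoch signal on the epoch's surprise value.
#'
#' @param epochs A [tcg_epochs()].
#' @param epoch_mask Optional logical matrix (subjects x epochs) selecting
#'   epochs to include.
#' @return Numeric array subjects x channels x timepoints of regression
#'   slopes, with attribute `excluded` listing subjects dropped for zero
#'   surprise variance (or fewer than 3 epochs).
#' @export
epoch_regression <- function(epochs, epoch_mask = NULL) {
  stopifnot(inherits(epochs, "tcg_epochs"))
  d <- dim(epochs$data)
  betas <- array(NA_real_, d[c(1L, 3L, 4L)])
  excluded <- integer(0)
  for (s in seq_len(d[1L])) {
    keep <- if (is.null(epoch_mask)) rep(TRUE, d[2L]) else epoch_mask[s, ]
    x <- epochs$step_surprise[s, keep]
    if (length(x) < 3L || stats::var(x) == 0) {
      excluded <- c(excluded, s)
      next
    }
    y <- matrix(epochs$data[s, keep, , ], nrow = length(x))
    xc <- x - mean(x)
    b <- crossprod(xc, sweep(y, 2L, colMeans(y))) / sum(xc^2)
    betas[s, , ] <- matrix(b, d[3L], d[4L])
  }
  structure(betas, excluded = excluded)
}

# connected components of supra-threshold (channel, time) points under
# spatial (neighbor graph) x temporal (consecutive samples) adjacency
.find_clusters <- function(mask, neighbors) {
  nc <- nrow(mask); nt <- ncol(mask)
  lab <- matrix(0L, nc, nt)
  clusters <- list()
  pts <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(pts))) {
    if (lab[pts[k, 1L], pts[k, 2L]] != 0L) next
    id <- length(clusters) + 1L
    queue <- list(pts[k, ])
    members <- matrix(integer(0), 0L, 2L)
    lab[pts[k, 1L], pts[k, 2L]] <- id
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      members <- rbind(members, p)
      ch <- p[1L]; tp <- p[2L]
      cand <- rbind(
        if (tp > 1L) c(ch, tp - 1L),
        if (tp < nt) c(ch, tp + 1L),
        cbind(which(neighbors[ch, ]), tp))
      for (j in seq_len(nrow(cand))) {
        q <- cand[j, ]
        if (mask[q[1L], q[2L]] && lab[q[1L], q[2L]] == 0L) {
          lab[q[1L], q[2L]] <- id
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    clusters[[id]] <- unname(members)
  }
  clusters
}

# max cluster mass of a t-map at threshold, over both signs
.max_cluster_mass <- function(tmap, thresh, neighbors) {
  m <- 0
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) > thresh
    if (!any(mask)) next
    for (cl in .find_clusters(mask, neighbors))
      m <- max(m, abs(sum(tmap[cl])))
  }
  m
}

#' Cluster-based permutation test of regression weights
#'
#' One-sample t statistics of the per-subject regression slopes against
#' zero are thresholded at the cluster-forming level (two-sided,
#' `cluster_alpha = 0.005`); supra-threshold points of equal sign are
#' clustered under spatial x temporal adjacency and summarized by their
#' mass (summed t).  The null distribution of the maximal cluster mass is
#' built by randomly sign-flipping whole subjects; the corrected p of each
#' observed cluster is its rank in that distribution.  Family-wise error
#' over the full channels x time map is thereby controlled at the chosen
#' level.
#'
#' @param betas Subjects x channels x timepoints array (from
#'   [epoch_regression()]); subjects with any `NA` are dropped.
#' @param neighbors Channel adjacency matrix.
#' @param cluster_alpha Cluster-forming significance level of the t test.
#' @param n_perm Number of sign-flip permutations.
#' @return An object of class `tcg_clusters`: a data frame of clusters
#'   (sign, size, mass, corrected p), the cluster index sets, the observed
#'   t map, and the permutation null.
#' @export
cluster_permutation_test <- function(betas, neighbors,
                                     cluster_alpha = 0.005,
                                     n_perm = 1000L) {
  b <- betas
  keep <- apply(b, 1L, function(x) !anyNA(x))
  b <- b[keep, , , drop = FALSE]
  n <- dim(b)[1L]
  if (n < 5L) stop("need at least 5 subjects with valid betas")
  nc <- dim(b)[2L]; nt <- dim(b)[3L]
  bm <- matrix(b, n)  # subjects x (channels*timepoints), column-major
  s1 <- colSums(bm); s2 <- colSums(bm^2)
  tfrom <- function(s1) {
    mean_ <- s1 / n
    var_ <- (s2 - n * mean_^2) / (n - 1)
    mean_ / sqrt(var_ / n)
  }
  thresh <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  tmap <- matrix(tfrom(s1), nc, nt)
  # observed clusters, per sign
  cl_list <- list(); sign_v <- numeric(0)
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) > thresh
    if (!any(mask)) next
    found <- .find_clusters(mask, neighbors)
    cl_list <- c(cl_list, found)
    sign_v <- c(sign_v, rep(sgn, length(found)))
  }
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    tm <- matrix(tfrom(colSums(bm * flips)), nc, nt)
    null_max[p] <- .max_cluster_mass(tm, thresh, neighbors)
  }
  mass <- vapply(cl_list, function(cl) sum(tmap[cl]), numeric(1))
  pcorr <- vapply(mass, function(m)
    (1 + sum(null_max >= abs(m))) / (n_perm + 1), numeric(1))
  tab <- data.frame(cluster = seq_along(cl_list), sign = sign_v,
                    size = vapply(cl_list, nrow, integer(1)),
                    mass = mass, p = pcorr)
  structure(list(clusters = tab, members = cl_list, tmap = tmap,
                 threshold = thresh, null_max = null_max,
                 n_subjects = n, n_perm = n_perm),
            class = "tcg_clusters")
}

#' @export
print.tcg_clusters <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d subjects, %d permutations, |t| threshold %.2f\n",
              x$n_subjects, x$n_perm, x$threshold))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  else cat("no supra-threshold clusters\n")
  invisible(x)
}

#' Mask of significant cluster points
#'
#' @param clusters A `tcg_clusters` result.
#' @param alpha Corrected significance level.
#' @return Logical channels x timepoints matrix.
#' @export
cluster_mask <- function(clusters, alpha = 0.05) {
  stopifnot(inherits(clusters, "tcg_clusters"))
  mask <- matrix(FALSE, nrow(clusters$tmap), ncol(clusters$tmap))
  sig <- which(clusters$clusters$p < alpha)
  for (i in sig) mask[clusters$members[[i]]] <- TRUE
  mask
}

#' Two-stage test of the pupil-surprise slope
#'
#' Summary-statistics analogue of a mixed model with random intercepts and
#' slopes: an ordinary least-squares slope of PDR on surprise per subject,
#' then a one-sample t test of the slopes across subjects.  For balanced
#' data the group estimate coincides asymptotically with the mixed-model
#' fixed effect.
#'
#' @param pdr Per-step PDR values.
#' @param step_surprise Matching surprise values (bits).
#' @param subject Subject labels, one per step.
#' @param conf_level Confidence level of the slope CI.
#' @return List of class `tcg_pdr_test`: slope estimate, CI, t statistic,
#'   df, p value, per-subject slopes, dropped subjects.
#' @export
pdr_slope_test <- function(pdr, step_surprise, subject,
                           conf_level = 0.95) {
  stopifnot(length(pdr) == length(step_surprise),
            length(pdr) == length(subject))
  subs <- split(seq_along(pdr), subject)
  if (length(subs) < 3L) stop("need at least 3 subjects")
  slopes <- c(); dropped <- character(0)
  for (nm in names(subs)) {
    i <- subs[[nm]]
    if (length(i) < 10L || stats::var(step_surprise[i]) == 0) {
      dropped <- c(dropped, nm)
      warning("subject ", nm, " dropped (too few steps or no surprise variance)")
      next
    }
    slopes[nm] <- stats::coef(stats::lm(pdr[i] ~ step_surprise[i]))[2L]
  }
  if (stats::sd(slopes) < 1e-12) {
    # degenerate noiseless case: all subjects share the slope exactly
    return(structure(list(slope = mean(slopes),
                          ci = rep(mean(slopes), 2), statistic = Inf,
                          df = length(slopes) - 1L,
                          p_value = if (mean(slopes) == 0) 1 else 0,
                          subject_slopes = slopes, dropped = dropped),
                     class = "tcg_pdr_test"))
  }
  tt <- stats::t.test(slopes, conf.level = conf_level)
  structure(list(slope = unname(tt$estimate), ci = unname(tt$conf.int),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 subject_slopes = slopes, dropped = dropped),
            class = "tcg_pdr_test")
}

#' @export
print.tcg_pdr_test <- function(x, ...) {
  cat(sprintf("Pupil-surprise slope (two-stage): %.4f units/bit, %d%% CI [%.4f, %.4f]\n",
              x$slope, 95, x$ci[1L], x$ci[2L]))
  cat(sprintf(" t(%d) = %.2f, p = %.3g (%d subjects, %d dropped)\n",
              x$df, x$statistic, x$p_value, length(x$subject_slopes),
              length(x$dropped)))
  invisible(x)
}

#' Regression weights and surprise by message type
#'
#' Repeats the mass-univariate regression separately for the epochs of
#' each message type, averages the resulting slopes over the channels of a
#' significant-cluster mask (yielding one time course per type), and pairs
#' each with the type's mean model surprise.  Subjects contributing fewer
#' than 3 epochs of a type are excluded for that type.
#'
#' @param epochs A [tcg_epochs()].
#' @param message_types Character matrix (subjects x epochs) of type
#'   labels.
#' @param mask Logical channels x timepoints mask from [cluster_mask()].
#' @return List with `time_course` (types x timepoints matrix of mean
#'   masked betas), `mean_surprise` (per type) and `n_subjects` per type.
#' @export
regression_by_message_type <- function(epochs, message_types, mask) {
  stopifnot(inherits(epochs, "tcg_epochs"))
  types <- sort(unique(as.vector(message_types)))
  chans <- which(rowSums(mask) > 0)
  if (!length(chans)) stop("empty cluster mask")
  nt <- dim(epochs$data)[4L]
  tc <- matrix(NA_real_, length(types), nt,
               dimnames = list(types, NULL))
  ms <- stats::setNames(numeric(length(types)), types)
  nsub <- stats::setNames(integer(length(types)), types)
  for (ty in types) {
    emask <- message_types == ty
    enough <- rowSums(emask) >= 3L
    emask[!enough, ] <- FALSE
    betas <- epoch_regression(epochs, epoch_mask = emask)
    ok <- setdiff(which(enough), attr(betas, "excluded"))
    nsub[ty] <- length(ok)
    if (!length(ok)) next
    # mean over subjects and masked channels -> time course
    tc[ty, ] <- apply(betas[ok, chans, , drop = FALSE], 3L, mean)
    ms[ty] <- mean(epochs$step_surprise[emask])
  }
  list(time_course = tc, mean_surprise = ms, n_subjects = nsub,
       channels = chans)
}
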