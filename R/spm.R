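# One-dimensional statistical parametric mapping over the gait cycle:
# node-wise t continua, random-field-theory (RFT) thresholds from the
# expected Euler characteristic of a smooth t field, cluster inference, and
# a permutation-based nonparametric twin.

# central-difference gradient along the node axis (one-sided at the ends),
# unit node spacing; X is an n_curves x n_nodes matrix
row_gradient <- function(X) {
  Q <- ncol(X)
  G <- matrix(0, nrow(X), Q)
  G[, 2:(Q - 1)] <- (X[, 3:Q] - X[, 1:(Q - 2)]) / 2
  G[, 1] <- X[, 2] - X[, 1]
  G[, Q] <- X[, Q] - X[, Q - 1]
  G
}

#' Estimate the smoothness (FWHM) of residual fields
#'
#' Global scalar FWHM (in grid units) of a set of residual curves, from the
#' gradients of the normalized residuals: per node, the squared-gradient to
#' sum-of-squares ratio gives a local reciprocal FWHM; the global estimate
#' is the reciprocal of the mean reciprocal (the standard 1D estimator used
#' with random-field thresholds).
#'
#' @param R n_curves x n_nodes matrix of residuals (curves minus their
#'   group mean).
#' @return FWHM in grid units (nodes).
#' @export
estimate_fwhm <- function(R) {
  stopifnot(is.matrix(R), nrow(R) >= 2, ncol(R) >= 3)
  ssq <- colSums(R^2)
  G <- row_gradient(R)
  v <- colSums(G^2) / (ssq + .Machine$double.eps)
  v <- v[is.finite(v) & v > 0]
  if (!length(v)) return(Inf)
  rpn <- sqrt(v / (4 * log(2)))  # reciprocal FWHM per node
  1 / mean(rpn)
}

# 1D Euler-characteristic density of a t field at height u
ec1_t <- function(u, df) {
  sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

# expected Euler characteristic (expected number of suprathreshold
# upcrossings) of a smooth t field with `resels` 1D resolution elements
expected_ec <- function(u, df, resels) {
  (1 - pt(u, df)) + resels * ec1_t(u, df)
}

#' Random-field-theory critical threshold for a 1D t field
#'
#' Smallest t* whose expected Euler characteristic (expected number of
#' suprathreshold clusters) over the search continuum equals the per-tail
#' significance level.  The resel count is `(n_nodes - 1) / fwhm`.  As
#' `fwhm` grows without bound the threshold approaches the univariate
#' critical t value.
#'
#' @param df degrees of freedom (>= 1).
#' @param n_nodes number of continuum nodes.
#' @param fwhm field smoothness in node units (> 0; may be `Inf`).
#' @param alpha significance level in (0, 1).
#' @param tails 2 (default) for two-tailed inference on |t|, or 1.
#' @return Critical t value.
#' @export
rft_threshold <- function(df, n_nodes, fwhm, alpha = 0.05, tails = 2) {
  stopifnot(is.finite(df), df >= 1, n_nodes >= 2, fwhm > 0,
            alpha > 0, alpha < 1, tails %in% c(1, 2))
  a <- alpha / tails
  resels <- if (is.infinite(fwhm)) 0 else (n_nodes - 1) / fwhm
  lo <- qt(1 - a, df)          # univariate bound; EC(lo) >= a
  if (resels == 0) return(lo)
  f <- function(u) expected_ec(u, df, resels) - a
  hi <- lo + 1
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) > 0)
    stop("RFT threshold undefined: too few degrees of freedom for the ",
         "requested alpha at this smoothness")
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# supra-threshold clusters of |t| (or t if tails == 1) with endpoints
# linearly interpolated between nodes; returns data.frame(start, end,
# extent_nodes, peak)
find_clusters <- function(t_cont, grid, u, tails = 2) {
  z <- if (tails == 2) abs(t_cont) else t_cont
  above <- z >= u
  above[is.na(above)] <- FALSE  # undefined t (zero-variance nodes) never crosses
  if (!any(above)) {
    return(data.frame(start_pct = numeric(0), end_pct = numeric(0),
                      extent_nodes = numeric(0), peak = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  out <- lapply(idx, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    # interpolate the threshold crossings just outside the run
    s <- if (i0 > 1) {
      grid[i0 - 1] + (u - z[i0 - 1]) / (z[i0] - z[i0 - 1]) * (grid[i0] - grid[i0 - 1])
    } else grid[1]
    e <- if (i1 < length(z)) {
      grid[i1] + (z[i1] - u) / (z[i1] - z[i1 + 1]) * (grid[i1 + 1] - grid[i1])
    } else grid[length(z)]
    data.frame(start_pct = s, end_pct = e,
               extent_nodes = (e - s) / (grid[2] - grid[1]),
               peak = max(abs(t_cont[i0:i1])))
  })
  do.call(rbind, out)
}

# RFT cluster p-value: the smaller of the cluster-extent approximation
# (Poisson clumping with the 1D extent distribution) and the height-based
# set-level probability of the cluster peak; both folded for two tails.
rft_cluster_p <- function(extent_nodes, peak, u, df, n_nodes, fwhm, tails = 2) {
  resels <- (n_nodes - 1) / fwhm
  m <- expected_ec(u, df, resels)             # expected cluster count
  ev <- n_nodes * (1 - pt(u, df))             # expected suprathreshold nodes
  p_ext <- if (ev <= 0 || m <= 0) 1 else {
    beta <- (gamma(1.5) * m / ev)^2
    1 - exp(-m * exp(-beta * extent_nodes^2))
  }
  p_height <- expected_ec(peak, df, resels)
  min(1, tails * p_ext, tails * p_height)
}

spm_from_t <- function(t_cont, df, R, grid, alpha, tails, test, nA, nB) {
  fwhm <- estimate_fwhm(R)
  Q <- length(t_cont)
  u <- rft_threshold(df, Q, fwhm, alpha, tails)
  cl <- find_clusters(t_cont, grid, u, tails)
  cl$p <- if (nrow(cl)) {
    vapply(seq_len(nrow(cl)), function(i)
      rft_cluster_p(cl$extent_nodes[i], cl$peak[i], u, df, Q, fwhm, tails),
      numeric(1))
  } else numeric(0)
  structure(list(test = test, method = "rft", t = t_cont, grid = grid,
                 df = df, fwhm = fwhm, resels = (Q - 1) / fwhm,
                 t_critical = u, alpha = alpha, tails = tails,
                 clusters = cl, n = c(nA = nA, nB = nB)),
            class = "spm_t")
}

as_curve_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && all(vapply(x, is.numeric, logical(1))))
    return(do.call(rbind, x))
  stop("curves must be a matrix (rows = curves) or a list of numeric vectors")
}

#' Two-sample SPM t-test over a continuum
#'
#' Node-wise two-sample t statistic (pooled variance) between two groups of
#' curves, thresholded with the 1D random-field-theory critical value at the
#' smoothness estimated from the pooled residuals.  Supra-threshold clusters
#' are reported with interpolated percent-gait-cycle extents and RFT cluster
#' p-values.
#'
#' @param YA,YB matrices of curves (rows = subjects, columns = nodes), or
#'   lists of numeric vectors.  At least 2 curves per group.
#' @param alpha significance level (default 0.05).
#' @param tails 2 (default) or 1.
#' @param grid node positions (percent gait cycle); default `0..100`.
#' @return Object of class `spm_t` with elements `t`, `df`, `fwhm`,
#'   `t_critical`, `clusters` (`start_pct`, `end_pct`, `p`), etc.
#' @export
spm_ttest2 <- function(YA, YB, alpha = 0.05, tails = 2, grid = NULL) {
  YA <- as_curve_matrix(YA); YB <- as_curve_matrix(YB)
  if (ncol(YA) != ncol(YB)) stop("grid mismatch between groups")
  nA <- nrow(YA); nB <- nrow(YB)
  if (nA < 2 || nB < 2) stop("need at least 2 curves per group")
  grid <- grid %||% seq(0, 100, length.out = ncol(YA))
  mA <- colMeans(YA); mB <- colMeans(YB)
  sA <- colSums(sweep(YA, 2, mA)^2)
  sB <- colSums(sweep(YB, 2, mB)^2)
  df <- nA + nB - 2
  sp2 <- (sA + sB) / df
  t_cont <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
  R <- rbind(sweep(YA, 2, mA), sweep(YB, 2, mB))
  spm_from_t(t_cont, df, R, grid, alpha, tails, "ttest2", nA, nB)
}

#' Paired SPM t-test over a continuum
#'
#' Node-wise paired t statistic on the within-pair differences
#' `YA - YB`, thresholded as in [spm_ttest2()].
#'
#' @param YA,YB matched curve matrices (same dimensions, rows paired).
#' @inheritParams spm_ttest2
#' @return Object of class `spm_t`.
#' @export
spm_ttest_paired <- function(YA, YB, alpha = 0.05, tails = 2, grid = NULL) {
  YA <- as_curve_matrix(YA); YB <- as_curve_matrix(YB)
  if (!all(dim(YA) == dim(YB))) stop("paired inputs must have equal dimensions")
  n <- nrow(YA)
  if (n < 2) stop("need at least 2 pairs")
  D <- YA - YB
  grid <- grid %||% seq(0, 100, length.out = ncol(D))
  mD <- colMeans(D)
  s2 <- colSums(sweep(D, 2, mD)^2) / (n - 1)
  t_cont <- mD / sqrt(s2 / n)
  R <- sweep(D, 2, mD)
  spm_from_t(t_cont, n - 1, R, grid, alpha, tails, "ttest_paired", n, n)
}

#' Permutation (nonparametric) SPM
#'
#' Nonparametric twin of [spm_ttest2()] / [spm_ttest_paired()]: the critical
#' threshold is the `1 - alpha` quantile of the permutation distribution of
#' the continuum maximum of |t| (group-label permutations for two samples,
#' sign flips of the paired differences for paired data), and cluster
#' p-values come from the permutation null of the maximum cluster extent.
#' The observed labelling is always included in the null.  Deterministic
#' given `seed`.
#'
#' @inheritParams spm_ttest2
#' @param paired treat `YA`/`YB` as matched pairs.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return Object of class `spm_t` with `method = "permutation"`.
#' @export
spm_permutation <- function(YA, YB, alpha = 0.05, paired = FALSE,
                            n_perm = 1000L, seed = 1L, grid = NULL) {
  YA <- as_curve_matrix(YA); YB <- as_curve_matrix(YB)
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (n_perm * alpha < 1)
    stop("too few permutations for the requested alpha")
  grid <- grid %||% seq(0, 100, length.out = ncol(YA))
  Q <- ncol(YA)

  if (paired) {
    if (!all(dim(YA) == dim(YB))) stop("paired inputs must have equal dimensions")
    D <- YA - YB
    n <- nrow(D)
    ssq <- colSums(D^2)
    t_of_signs <- function(S) {  # S: n_perm x n matrix of +-1
      mD <- (S %*% D) / n
      s2 <- sweep(-(n * mD^2), 2, ssq, `+`) / (n - 1)
      mD / sqrt(pmax(s2, .Machine$double.eps) / n)
    }
    T_obs <- t_of_signs(matrix(1, 1, n))[1, ]
    Tperm <- with_seed(seed, {
      S <- matrix(sample(c(-1, 1), (n_perm - 1) * n, replace = TRUE),
                  n_perm - 1, n)
      t_of_signs(S)
    })
    df <- n - 1
  } else {
    X <- rbind(YA, YB)
    nA <- nrow(YA); nB <- nrow(YB); n <- nA + nB
    if (nA < 2 || nB < 2) stop("need at least 2 curves per group")
    X2 <- X^2
    t_of_labels <- function(L) {  # L: n_perm x n, 1 for group A
      SA <- L %*% X;  SB <- sweep(-SA, 2, colSums(X), `+`)
      QA <- L %*% X2; QB <- sweep(-QA, 2, colSums(X2), `+`)
      mA <- SA / nA; mB <- SB / nB
      sp2 <- (QA - nA * mA^2 + QB - nB * mB^2) / (n - 2)
      (mA - mB) / sqrt(pmax(sp2, .Machine$double.eps) * (1 / nA + 1 / nB))
    }
    L_obs <- matrix(c(rep(1, nA), rep(0, nB)), 1, n)
    T_obs <- t_of_labels(L_obs)[1, ]
    Tperm <- with_seed(seed, {
      L <- t(vapply(seq_len(n_perm - 1L), function(i) {
        z <- numeric(n); z[sample.int(n, nA)] <- 1; z
      }, numeric(n)))
      t_of_labels(L)
    })
    df <- n - 2
  }

  maxT <- c(max(abs(T_obs)), apply(abs(Tperm), 1, max))
  u <- as.numeric(quantile(maxT, 1 - alpha, type = 1))
  cl <- find_clusters(T_obs, grid, u, tails = 2)
  if (nrow(cl)) {
    # permutation null of the maximum cluster extent at threshold u
    max_ext <- function(tv) {
      cc <- find_clusters(tv, grid, u, tails = 2)
      if (nrow(cc)) max(cc$extent_nodes) else 0
    }
    null_ext <- c(max_ext(T_obs), apply(Tperm, 1, max_ext))
    cl$p <- vapply(cl$extent_nodes, function(k) mean(null_ext >= k), numeric(1))
  } else cl$p <- numeric(0)

  structure(list(test = if (paired) "ttest_paired" else "ttest2",
                 method = "permutation", t = T_obs, grid = grid, df = df,
                 fwhm = NA_real_, resels = NA_real_, t_critical = u,
                 alpha = alpha, tails = 2, clusters = cl,
                 n = if (paired) c(nA = n, nB = n) else c(nA = nA, nB = nB),
                 n_perm = n_perm, seed = seed),
            class = "spm_t")
}

#' Node-wise normality check of a set of continua
#'
#' Shapiro-Wilk test applied at every node across curves, with a summary
#' flag raised when more than 5% of nodes reject at the 0.05 level.
#'
#' @param Y matrix of curves (rows = subjects) or list of numeric vectors;
#'   at least 3 curves.
#' @return List with `p` (per-node p-values) and `non_normal` (logical flag).
#' @export
normality_continuum <- function(Y) {
  Y <- as_curve_matrix(Y)
  if (nrow(Y) < 3) stop("normality check needs at least 3 curves")
  p <- apply(Y, 2, function(v) {
    if (diff(range(v)) == 0) return(0)  # degenerate: treat as non-normal
    shapiro.test(v)$p.value
  })
  list(p = p, non_normal = mean(p < 0.05) > 0.05)
}

#' Amplitude ("spatial") normalization of a cycle
#'
#' Rescales each joint's curve to a dimensionless amplitude so that SPM on
#' the result compares timing rather than amplitude (isolating temporal
#' shifts such as a delayed flexion peak).  `"minmax"` (default) maps each
#' joint's cycle min/max to 0/1; `"zscore"` standardizes each joint's curve
#' to zero mean and unit SD.
#'
#' @param cycle a `normalized_cycle`, or a numeric vector (one curve).
#' @param method `"minmax"` or `"zscore"`.
#' @return Same shape as the input, amplitude-normalized.
#' @export
spatial_normalize <- function(cycle, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  f <- function(v) {
    r <- diff(range(v))
    if (r == 0) stop("zero-ROM joint cannot be amplitude-normalized")
    if (method == "minmax") (v - min(v)) / r else (v - mean(v)) / sd(v)
  }
  if (is.numeric(cycle)) return(f(cycle))
  stopifnot(inherits(cycle, "normalized_cycle"))
  cycle$hip <- f(cycle$hip)
  cycle$knee <- f(cycle$knee)
  cycle$centered <- FALSE
  cycle
}

#' Simulate smooth unit-variance Gaussian fields
#'
#' White Gaussian noise convolved with a Gaussian kernel of the requested
#' FWHM (node units) and rescaled to unit pointwise variance — the standard
#' null model for validating continuum-level inference.
#'
#' @param n_curves number of fields.
#' @param n_nodes nodes per field (default 101).
#' @param fwhm smoothness in node units (default 15).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return `n_curves x n_nodes` matrix.
#' @export
sim_smooth_field <- function(n_curves, n_nodes = 101L, fwhm = 15, seed = NULL) {
  stopifnot(n_curves >= 1, n_nodes >= 3, fwhm > 0)
  sdk <- fwhm / (2 * sqrt(2 * log(2)))
  pad <- ceiling(3 * sdk)
  W <- outer(seq_len(n_nodes + 2 * pad), seq_len(n_nodes) + pad,
             function(i, j) exp(-(i - j)^2 / (2 * sdk^2)))
  W <- sweep(W, 2, sqrt(colSums(W^2)), `/`)  # unit variance after smoothing
  gen <- function() matrix(rnorm(n_curves * (n_nodes + 2 * pad)),
                           n_curves) %*% W
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @export
print.spm_t <- function(x, ...) {
  cat(sprintf("SPM{t} %s (%s)\n", x$test, x$method))
  cat(sprintf("  n = %d vs %d, df = %g", x$n["nA"], x$n["nB"], x$df))
  if (is.finite(x$fwhm)) cat(sprintf(", FWHM = %.2f, resels = %.2f", x$fwhm, x$resels))
  cat("\n")
  cat(sprintf("  alpha = %g (%d-tailed), t* = %.3f\n", x$alpha, x$tails,
              x$t_critical))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %.1f%% - %.1f%% of gait cycle, p = %.4f\n",
                  i, x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$p[i]))
  } else cat("  no supra-threshold clusters\n")
  invisible(x)
}

#' @export
summary.spm_t <- function(object, ...) {
  out <- list(test = object$test, method = object$method, df = object$df,
              fwhm = object$fwhm, t_critical = object$t_critical,
              alpha = object$alpha, max_abs_t = max(abs(object$t)),
              clusters = object$clusters)
  class(out) <- "summary.spm_t"
  out
}

#' @export
print.summary.spm_t <- function(x, ...) {
  cat(sprintf("SPM{t} %s (%s): max |t| = %.3f, t* = %.3f, %d cluster(s)\n",
              x$test, x$method, x$max_abs_t, x$t_critical, nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Plot an SPM t continuum
#'
#' Statistic continuum over the gait cycle with the critical threshold and
#' shaded supra-threshold clusters.
#'
#' @param x an `spm_t` object.
#' @param ... passed to [plot()].
#' @export
plot.spm_t <- function(x, ...) {
  ylim <- range(c(x$t, x$t_critical, -x$t_critical)) * 1.1
  plot(x$grid, x$t, type = "l", lwd = 2, xlab = "% gait cycle",
       ylab = "SPM{t}", ylim = ylim, ...)
  abline(h = c(-1, 1) * x$t_critical, lty = 2, col = "red")
  abline(h = 0, col = "grey")
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      polygon(c(x$clusters$start_pct[i], x$clusters$end_pct[i],
                x$clusters$end_pct[i], x$clusters$start_pct[i]),
              c(ylim[1], ylim[1], ylim[2], ylim[2]),
              col = adjustcolor("lightblue", 0.4), border = NA)
    }
    lines(x$grid, x$t, lwd = 2)
  }
  invisible(x)
}

#' Serialize an SPM result to JSON
#'
#' @param x an `spm_t` object.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
spm_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "spm_t"))
  obj <- list(test = x$test, method = x$method, df = x$df, fwhm = x$fwhm,
              t_critical = x$t_critical, alpha = x$alpha,
              clusters = if (nrow(x$clusters)) {
                lapply(seq_len(nrow(x$clusters)), function(i)
                  list(start_pct = x$clusters$start_pct[i],
                       end_pct = x$clusters$end_pct[i],
                       p = x$clusters$p[i]))
              } else list())
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
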