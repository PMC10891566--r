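#' Fit a PCA model on z-scored data
#'
#' SVD-based principal component analysis of an already centered and
#' scaled matrix (the z-scored urban block; no internal re-centering is
#' applied).  The number of retained components is either given
#' explicitly or chosen by Kaiser's rule: keep components whose
#' eigenvalue exceeds the mean of the positive eigenvalues.
#'
#' @param x numeric matrix of z-scores (samples x variables), or a
#'   z-scored `feature_table`.
#' @param n_components integer, or `"auto"` for Kaiser's rule.
#' @param scaling optional `scaling_model` carried along for projection.
#' @return object of class `pca_model`: `loadings` (variables x A,
#'   orthonormal), `eigenvalues` (all positive eigenvalues),
#'   `n_components`, `explained_variance` (fraction per retained
#'   component), `scaling`, `n_train`.
#' @export
pca_fit <- function(x, n_components = "auto", scaling = NULL) {
  if (inherits(x, "feature_table")) x <- x$areas
  if (nrow(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  sv <- svd(x)
  lambda <- sv$d^2 / (nrow(x) - 1)
  pos <- lambda > max(lambda) * 1e-12
  lambda <- lambda[pos]
  rank <- length(lambda)
  if (identical(n_components, "auto")) {
    A <- sum(lambda > mean(lambda))
    if (A < 1L) A <- 1L
  } else {
    A <- as.integer(n_components)
    if (A < 1L) stop("n_components must be >= 1", call. = FALSE)
    if (A > rank) {
      stop(sprintf("n_components (%d) exceeds the data rank (%d)", A, rank),
           call. = FALSE)
    }
  }
  structure(list(loadings = sv$v[, seq_len(A), drop = FALSE],
                 eigenvalues = lambda,
                 n_components = A,
                 explained_variance = lambda[seq_len(A)] / sum(lambda),
                 scaling = scaling,
                 n_train = nrow(x),
                 variable_ids = colnames(x)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components (of rank %d), %.0f%% variance explained\n",
              x$n_components, length(x$eigenvalues),
              100 * sum(x$explained_variance)))
  invisible(x)
}

#' Score and orthogonal distances of samples from a PCA model
#'
#' For each (z-scored) sample `x`: scores `t = x V`; score distance
#' `SD = sum_k t_k^2 / lambda_k` (Mahalanobis distance in the retained
#' score space); orthogonal distance `OD = ||x - t V'||^2` (squared
#' residual off the component subspace).  The two components satisfy the
#' Pythagorean decomposition `OD + ||t V'||^2 = ||x||^2`.
#'
#' @param model a [pca_fit()] model.
#' @param x matrix of z-scored samples, or a `feature_table` (scaled
#'   through `model$scaling` if raw).
#' @return data.frame (`pca_distances`) with `sample_id`, `sd`, `od`.
#' @export
pca_distances <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  sample_ids <- NULL
  if (inherits(x, "feature_table")) {
    if (!inherits(x, "scaled_feature_table")) {
      if (is.null(model$scaling)) {
        stop("raw feature table given but the model carries no scaling model",
             call. = FALSE)
      }
      x <- zscore_apply(x, model$scaling)
    }
    sample_ids <- x$samples$sample_id
    x <- x$areas
  }
  if (ncol(x) != nrow(model$loadings)) {
    stop(sprintf("data has %d variables; model expects %d",
                 ncol(x), nrow(model$loadings)), call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(x)
    if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(x)))
  }
  A <- model$n_components
  scores <- x %*% model$loadings
  sd_vals <- colSums(t(scores^2) / model$eigenvalues[seq_len(A)])
  resid <- x - scores %*% t(model$loadings)
  od_vals <- rowSums(resid^2)
  out <- data.frame(sample_id = sample_ids, sd = sd_vals, od = od_vals,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("pca_distances", "data.frame")
  out
}

#' Chi-square critical limits for score and orthogonal distances
#'
#' Moment-matched scaled chi-square limits per distance axis: with the
#' training distances' mean `u0` and variance `v`, the degrees of
#' freedom are `N = max(1, round(2 u0^2 / v))` and the distance is
#' modelled as `u0 * chisq(N) / N`.  The extreme limit is the upper
#' `alpha` quantile; the outlier limit applies a per-object correction
#' `(1 - gamma)^(1/n)` so that a clean training set of size `n` exceeds
#' it with probability about `gamma` overall.
#'
#' @param train_distances [pca_distances()] of the training samples.
#' @param alpha significance level for extreme objects (default 0.05).
#' @param gamma significance level for outliers (default 0.05).
#' @return object of class `pca_limits`: per axis (`sd`, `od`) a list
#'   with `u0`, `dof`, `extreme`, `outlier`; plus `alpha`, `gamma`,
#'   `n_train`.
#' @export
pca_critical_limits <- function(train_distances, alpha = 0.05,
                                gamma = 0.05) {
  stopifnot(is.data.frame(train_distances))
  n <- nrow(train_distances)
  one_axis <- function(u) {
    m <- mean(u)
    v <- stats::var(u)
    if (v == 0) stop("zero-variance training distances", call. = FALSE)
    dof <- max(1, round_half_up(2 * m^2 / v))
    list(u0 = m, dof = dof,
         extreme = m * stats::qchisq(1 - alpha, dof) / dof,
         outlier = m * stats::qchisq((1 - gamma)^(1 / n), dof) / dof)
  }
  structure(list(sd = one_axis(train_distances$sd),
                 od = one_axis(train_distances$od),
                 alpha = alpha, gamma = gamma, n_train = n),
            class = "pca_limits")
}

#' Classify samples as regular, extreme or outlier
#'
#' A sample is an `outlier` if its score distance or its orthogonal
#' distance exceeds the corresponding outlier limit; otherwise `extreme`
#' if either exceeds the extreme limit; otherwise `regular`.
#'
#' @param records a [pca_distances()] data.frame.
#' @param limits a [pca_critical_limits()] object.
#' @return `records` with an added `category` factor.
#' @export
pca_classify <- function(records, limits) {
  stopifnot(inherits(limits, "pca_limits"))
  out_flag <- records$sd > limits$sd$outlier | records$od > limits$od$outlier
  ext_flag <- records$sd > limits$sd$extreme | records$od > limits$od$extreme
  records$category <- factor(
    ifelse(out_flag, "outlier", ifelse(ext_flag, "extreme", "regular")),
    levels = c("regular", "extreme", "outlier"))
  records
}

#' Distance-distance plot coordinates
#'
#' Normalizes each distance by its extreme critical limit (so the limit
#' sits at 1.0) and adds base-10 log coordinates for plotting, together
#' with a group label (urban concentrated / urban diluted / industrial)
#' when sample metadata is supplied.
#'
#' @param records classified records from [pca_classify()].
#' @param limits a [pca_critical_limits()] object.
#' @param samples optional sample metadata data.frame (`sample_id`,
#'   `site_type`, `dilution`) used for the group label.
#' @return data.frame with `sample_id`, `sd_norm`, `od_norm`,
#'   `log_sd`, `log_od`, `category`, `group`.
#' @export
dd_plot_data <- function(records, limits, samples = NULL) {
  stopifnot(inherits(limits, "pca_limits"))
  if (nrow(records) == 0L) stop("no distance records", call. = FALSE)
  sd_norm <- records$sd / limits$sd$extreme
  od_norm <- records$od / limits$od$extreme
  group <- rep(NA_character_, nrow(records))
  if (!is.null(samples)) {
    idx <- match(records$sample_id, samples$sample_id)
    group <- ifelse(samples$site_type[idx] == "industrial", "industrial",
                    paste("urban", samples$dilution[idx]))
  }
  data.frame(sample_id = records$sample_id,
             sd_norm = sd_norm, od_norm = od_norm,
             log_sd = log10(sd_norm), log_od = log10(od_norm),
             category = records$category,
             group = group,
             stringsAsFactors = FALSE)
}
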