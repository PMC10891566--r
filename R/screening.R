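#' @name screening
#' @title Compound screening filters
#' @description
#' Three filters remove undesired features from a peak-area table before
#' modelling:
#' * [blank_filter()] — compounds whose area is less than `factor` (default
#'   five) times the mean area of the same compound in the site's sequence
#'   blanks, in any sample, are background and discarded.
#' * [dilution_ttest_filter()] — compounds whose areas do not differ
#'   between the concentrated and the 1:10-diluted replicates (Welch
#'   t-test, p > alpha) show no area-concentration relationship and are
#'   discarded.
#' * [correctness_filter()] — a per-site dummy codes whether the diluted
#'   site mean is lower than the concentrated one; compounds whose median
#'   dummy over sites is below 1 are dilution-ignoring artifacts and are
#'   discarded.
#'
#' Each filter returns the reduced table together with a `filter_report`
#' bookkeeping object; [filter_report_merge()] chains reports across a
#' pipeline.
NULL

new_filter_report <- function(n_input, flags) {
  counts <- c(blank = 0L, ttest = 0L, correctness = 0L)
  if (length(flags)) {
    tab <- table(unlist(flags))
    counts[names(tab)] <- as.integer(tab)
  }
  structure(list(n_input = as.integer(n_input),
                 n_discarded_blank = counts[["blank"]],
                 n_discarded_ttest = counts[["ttest"]],
                 n_discarded_correctness = counts[["correctness"]],
                 n_retained = as.integer(n_input - length(flags)),
                 per_compound_flags = flags),
            class = "filter_report")
}

#' Merge filter reports from successive pipeline stages
#'
#' @param ... `filter_report` objects in pipeline order; each compound is
#'   counted once, at the stage that discarded it.
#' @return a combined `filter_report` whose `n_input` is the first
#'   stage's input count.
#' @export
filter_report_merge <- function(...) {
  reports <- list(...)
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, TRUE, "filter_report")))
  flags <- do.call(c, lapply(reports, `[[`, "per_compound_flags"))
  new_filter_report(reports[[1L]]$n_input, flags)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("filter_report: %d compounds in, %d retained\n",
                     "  discarded: blank=%d, t-test=%d, correctness=%d\n"),
              x$n_input, x$n_retained, x$n_discarded_blank,
              x$n_discarded_ttest, x$n_discarded_correctness))
  invisible(x)
}

#' Five-fold blank filter
#'
#' Discards a compound when, in any sample, its peak area is strictly less
#' than `factor` times the mean area of the same compound in the blanks of
#' that sample's site sequence (falling back to the mean over all blanks
#' for sites without their own).  A compound with zero blank area
#' everywhere is always retained.
#'
#' @param table a [feature_table()] of study samples.
#' @param blanks a `feature_table` of blank injections sharing the
#'   compound set of `table` (site column links blanks to sample sites).
#' @param factor blank multiplication factor (default 5).
#' @return list with `table` (retained compounds) and `report`
#'   (`filter_report`).
#' @export
blank_filter <- function(table, blanks, factor = 5) {
  stopifnot(inherits(table, "feature_table"),
            inherits(blanks, "feature_table"))
  if (factor <= 0) stop("blank factor must be > 0", call. = FALSE)
  if (!identical(table$compounds$compound_id, blanks$compounds$compound_id)) {
    stop("blank table does not share the compound set", call. = FALSE)
  }
  grand_mean <- colMeans(blanks$areas)
  blank_mean_for_site <- function(site) {
    rows <- blanks$samples$site == site
    if (!any(rows)) grand_mean else
      colMeans(blanks$areas[rows, , drop = FALSE])
  }
  discard <- rep(FALSE, ncol(table$areas))
  for (site in unique(table$samples$site)) {
    bm <- blank_mean_for_site(site)
    rows <- which(table$samples$site == site)
    thr <- factor * bm
    for (r in rows) discard <- discard | (table$areas[r, ] < thr)
  }
  flags <- rep(list("blank"), sum(discard))
  names(flags) <- table$compounds$compound_id[discard]
  list(table = ft_subset(table, compounds = which(!discard)),
       report = new_filter_report(ncol(table$areas), flags))
}

# Welch two-sample t-test p-value, tolerant of zero-variance groups:
# identical degenerate groups count as "no difference" (p = 1).
welch_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each dilution group needs >= 2 samples", call. = FALSE)
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx + vy == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  se2 <- vx / length(x) + vy / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                 vy^2 / (length(y)^2 * (length(y) - 1)))
  2 * stats::pt(-abs(tstat), df)
}

# one-sample t-test p-value for paired differences, tolerant of
# zero-variance: all-equal nonzero differences are maximal evidence of a
# difference (p = 0); all-zero differences mean none (p = 1)
paired_p <- function(d) {
  if (length(d) < 2L) {
    stop("each dilution group needs >= 2 samples", call. = FALSE)
  }
  v <- stats::var(d)
  if (v == 0) return(if (mean(d) == 0) 1 else 0)
  tstat <- mean(d) / sqrt(v / length(d))
  2 * stats::pt(-abs(tstat), length(d) - 1)
}

#' Dilution-response t-test filter
#'
#' Per compound, tests whether the areas of the concentrated samples
#' differ from those of their diluted counterparts; compounds with
#' p > `alpha` show no area-concentration relationship and are discarded.
#' Two test variants are available:
#'
#' * `"paired"` (default) — each concentrated replicate is paired with
#'   the corresponding diluted replicate of the same site, and a
#'   one-sample t-test is run on the paired differences.  Pairing
#'   removes the between-site level variation, which otherwise swamps
#'   the dilution effect for compounds whose level differs strongly
#'   across sites.
#' * `"welch"` — Welch (unequal-variance) two-sample t-test of all
#'   concentrated areas against all diluted areas, pooled over sites.
#'
#' By default the test runs on `log10(area + 1)`: site-to-site and
#' dilution effects on peak areas are multiplicative, so the log scale
#' turns the expected 1:10 dilution into a constant additive shift (set
#' `log10_areas = FALSE` to test raw areas).
#'
#' @param table a [feature_table()] containing both dilution levels.
#' @param alpha significance level (default 0.05); a compound is retained
#'   iff p <= alpha.
#' @param method `"paired"` or `"welch"` (see above).
#' @param log10_areas test `log10(area + 1)` instead of raw areas.
#' @return list with `table`, `report` (as in [blank_filter()]), and
#'   `p_values`.
#' @export
dilution_ttest_filter <- function(table, alpha = 0.05,
                                  method = c("paired", "welch"),
                                  log10_areas = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  conc <- table$samples$dilution == "concentrated"
  dil <- table$samples$dilution == "diluted"
  if (!any(conc) || !any(dil)) {
    stop("both dilution levels must be present", call. = FALSE)
  }
  x <- table$areas
  if (log10_areas) x <- log10(x + 1)
  if (method == "welch") {
    p <- vapply(seq_len(ncol(x)),
                function(j) welch_p(x[conc, j], x[dil, j]), numeric(1))
  } else {
    key <- paste(table$samples$site, table$samples$replicate)
    ci <- which(conc)[order(key[conc])]
    di <- which(dil)[order(key[dil])]
    if (length(ci) != length(di) ||
        !identical(key[ci], key[di])) {
      stop("paired test needs matching site/replicate pairs at both ",
           "dilution levels", call. = FALSE)
    }
    d <- x[ci, , drop = FALSE] - x[di, , drop = FALSE]
    p <- vapply(seq_len(ncol(d)), function(j) paired_p(d[, j]), numeric(1))
  }
  discard <- p > alpha
  flags <- rep(list("ttest"), sum(discard))
  names(flags) <- table$compounds$compound_id[discard]
  list(table = ft_subset(table, compounds = which(!discard)),
       report = new_filter_report(ncol(x), flags),
       p_values = stats::setNames(p, table$compounds$compound_id))
}

#' Dilution "Correctness" filter
#'
#' For each compound and site, the mean of the diluted replicates is
#' compared with the mean of the concentrated ones; a dummy is coded 1
#' when the diluted mean is strictly lower (the expected direction for a
#' real, dilution-responsive feature) and 0 otherwise.  A compound is
#' retained iff the median of its per-site dummies is not below 1.  The
#' rule depends only on within-site mean orderings, so it is invariant to
#' any per-compound strictly increasing affine rescaling of the areas.
#'
#' @param table a [feature_table()]; every site must carry both dilution
#'   levels.
#' @return list with `table`, `report`, and `dummies` (sites x compounds
#'   0/1 matrix).
#' @export
correctness_filter <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  sites <- unique(table$samples$site)
  dummies <- matrix(NA_real_, length(sites), ncol(table$areas),
                    dimnames = list(sites, table$compounds$compound_id))
  for (s in sites) {
    conc <- table$samples$site == s & table$samples$dilution == "concentrated"
    dil <- table$samples$site == s & table$samples$dilution == "diluted"
    if (!any(conc) || !any(dil)) {
      stop("site '", s, "' is missing a dilution level", call. = FALSE)
    }
    cm <- colMeans(table$areas[conc, , drop = FALSE])
    dm <- colMeans(table$areas[dil, , drop = FALSE])
    dummies[s, ] <- as.numeric(dm < cm)
  }
  med <- apply(dummies, 2, stats::median)
  discard <- med < 1
  flags <- rep(list("correctness"), sum(discard))
  names(flags) <- table$compounds$compound_id[discard]
  list(table = ft_subset(table, compounds = which(!discard)),
       report = new_filter_report(ncol(table$areas), flags),
       dummies = dummies)
}

#' Fit a per-compound z-score scaling model
#'
#' Records the mean and sample standard deviation (n - 1 denominator) of
#' every compound over the given samples.  Compounds with zero standard
#' deviation cannot be scaled; their ids are recorded in the model and
#' dropped by [zscore_apply()].
#'
#' @param table a [feature_table()] with at least two samples.
#' @return a `scaling_model` with fields `means`, `sds`, `fitted_on`
#'   (sample ids) and `dropped` (constant-compound ids).
#' @export
zscore_fit <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$areas) < 2L) {
    stop("z-score fit needs >= 2 samples", call. = FALSE)
  }
  means <- colMeans(table$areas)
  sds <- apply(table$areas, 2, stats::sd)
  dropped <- table$compounds$compound_id[sds == 0]
  structure(list(means = means, sds = sds,
                 fitted_on = table$samples$sample_id,
                 dropped = dropped),
            class = "scaling_model")
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf("scaling_model: %d compounds (%d constant, dropped), fitted on %d samples\n",
              length(x$means), length(x$dropped), length(x$fitted_on)))
  invisible(x)
}

#' Apply a z-score scaling model
#'
#' Transforms each compound to `(area - mean) / sd` using the model's
#' training statistics; compounds recorded as constant in the model are
#' dropped.  Every modelled compound must be present in `table`.
#'
#' @param table a [feature_table()].
#' @param model a `scaling_model` from [zscore_fit()].
#' @return a `feature_table` whose `areas` hold z-scores (note: values may
#'   be negative; validation of non-negativity is bypassed for scaled
#'   tables).
#' @export
zscore_apply <- function(table, model) {
  stopifnot(inherits(table, "feature_table"),
            inherits(model, "scaling_model"))
  want <- names(model$means)
  missing_ids <- setdiff(want, table$compounds$compound_id)
  if (length(missing_ids)) {
    stop("table lacks modeled compound(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(want, model$dropped)
  idx <- match(keep, table$compounds$compound_id)
  z <- sweep(table$areas[, idx, drop = FALSE], 2, model$means[keep], "-")
  z <- sweep(z, 2, model$sds[keep], "/")
  out <- list(areas = z,
              samples = table$samples,
              compounds = table$compounds[idx, , drop = FALSE])
  class(out) <- c("scaled_feature_table", "feature_table")
  out
}
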