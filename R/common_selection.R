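#' Hierarchical clustering of samples or compounds
#'
#' Agglomerative clustering with Euclidean distance and Ward's linkage in
#' the Ward.D2 convention (merge cost equals the increase in total
#' within-cluster sum of squares; merge heights are on the distance
#' scale).  Applied to both axes of a z-scored table this yields the
#' two-way clustering underlying the common-compound heatmap.
#'
#' @param x numeric matrix of z-scores (samples x compounds), or a
#'   `feature_table` whose `areas` hold z-scores.
#' @param axis cluster the `"samples"` (rows) or the `"compounds"`
#'   (columns).
#' @return object of class `ntsom_dendrogram`: list with `merge`,
#'   `height`, `order`, `labels` (as in [stats::hclust()]), plus
#'   `linkage = "ward.D2"`, `distance = "euclidean"`, `axis`, and the
#'   underlying `hclust` object.
#' @export
hca <- function(x, axis = c("compounds", "samples")) {
  axis <- match.arg(axis)
  if (inherits(x, "feature_table")) x <- x$areas
  m <- if (axis == "compounds") t(x) else x
  if (any(!is.finite(m))) stop("non-finite values in matrix", call. = FALSE)
  if (nrow(m) < 1L) stop("empty matrix", call. = FALSE)
  labels <- rownames(m)
  if (nrow(m) == 1L) {
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height = numeric(0), order = 1L,
                          labels = labels, linkage = "ward.D2",
                          distance = "euclidean", axis = axis,
                          hclust = NULL),
                     class = "ntsom_dendrogram"))
  }
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = labels, linkage = "ward.D2",
                 distance = "euclidean", axis = axis, hclust = hc),
            class = "ntsom_dendrogram")
}

#' @export
print.ntsom_dendrogram <- function(x, ...) {
  cat(sprintf("ntsom_dendrogram: %d %s, %s linkage, %s distance\n",
              length(x$order), x$axis, x$linkage, x$distance))
  invisible(x)
}

#' Select the "unknown common" compound set
#'
#' Cuts the compound dendrogram into `k` clusters and scores each cluster
#' for industrial peculiarity: a cluster is peculiar iff, for some
#' industrial site, the mean z-score of the cluster's compounds over that
#' site's samples exceeds the mean over all urban samples by more than
#' `delta` z-units.  Compounds in peculiar clusters are candidates for
#' removal as industrial fingerprint features; everything else is
#' "unknown common" — shared by urban and industrial effluents — and
#' becomes the modelling variable set.
#'
#' Elevated intensity alone does not make a feature industrial-exclusive:
#' a compound present in every effluent can still be strongly
#' concentrated at one site, and such compounds carry exactly the
#' intensity fingerprint the downstream models rely on.  When the raw
#' (untransformed) table is supplied, a compound inside a peculiar
#' cluster is therefore only removed if it is also essentially absent
#' from the urban samples: its mean urban area falls below
#' `presence_threshold` times its maximum area over all samples.
#' Without `raw_table` the whole peculiar cluster is removed (z-scores
#' carry no absolute-presence information).
#'
#' An explicit id list (`manual_ids`) overrides the automatic rule,
#' mirroring a visual cluster selection on the heatmap.
#'
#' @param table z-scored `feature_table` containing urban and industrial
#'   samples.
#' @param dend compound-axis [hca()] dendrogram of `table`.
#' @param k number of clusters to cut (default 4: one cluster of shared
#'   compounds plus up to three site-specific fingerprint clusters).
#' @param delta peculiarity threshold in z-units (default 1).
#' @param manual_ids optional explicit character vector of unknown-common
#'   compound ids, bypassing the rule.
#' @param raw_table optional raw-area `feature_table` with the same
#'   compounds, enabling the urban-absence test.
#' @param presence_threshold urban-absence cutoff (default `1e-4`): a
#'   compound counts as absent from urban effluent when its mean urban
#'   area is at least four orders of magnitude below its peak area.
#' @return object of class `common_selection`: list with
#'   `unknown_common_ids`, `discarded` (data.frame compound_id, cluster,
#'   peculiarity), `cluster` (assignment per compound) and
#'   `peculiarity` (per-cluster score).
#' @export
select_unknown_common <- function(table, dend, k = 4L, delta = 1.0,
                                  manual_ids = NULL, raw_table = NULL,
                                  presence_threshold = 1e-4) {
  stopifnot(inherits(table, "feature_table"))
  ids <- table$compounds$compound_id
  if (!is.null(manual_ids)) {
    unknown <- intersect(ids, manual_ids)
    sel <- list(unknown_common_ids = unknown,
                discarded = data.frame(compound_id = setdiff(ids, unknown),
                                       cluster = NA_integer_,
                                       peculiarity = NA_real_),
                cluster = NULL, peculiarity = NULL)
    class(sel) <- "common_selection"
    return(sel)
  }
  stopifnot(inherits(dend, "ntsom_dendrogram"))
  if (dend$axis != "compounds") {
    stop("dendrogram must be built on the compounds axis", call. = FALSE)
  }
  if (!identical(dend$labels, ids)) {
    stop("dendrogram labels do not match the table's compounds",
         call. = FALSE)
  }
  if (k > length(ids)) stop("k exceeds the number of compounds",
                            call. = FALSE)
  urban <- table$samples$site_type == "urban"
  industrial <- table$samples$site_type == "industrial"
  if (!any(industrial)) stop("table has no industrial samples",
                             call. = FALSE)
  cl <- if (k == 1L || is.null(dend$hclust)) {
    stats::setNames(rep(1L, length(ids)), ids)
  } else {
    stats::cutree(dend$hclust, k = k)
  }
  ind_sites <- unique(table$samples$site[industrial])
  pec <- vapply(sort(unique(cl)), function(g) {
    cols <- which(cl == g)
    urban_mean <- mean(table$areas[urban, cols])
    max(vapply(ind_sites, function(s) {
      rows <- table$samples$site == s
      mean(table$areas[rows, cols]) - urban_mean
    }, numeric(1)))
  }, numeric(1))
  names(pec) <- sort(unique(cl))
  peculiar <- names(pec)[pec > delta]
  candidate <- cl %in% as.integer(peculiar)
  if (!is.null(raw_table) && any(candidate)) {
    stopifnot(inherits(raw_table, "feature_table"))
    idx <- match(ids, raw_table$compounds$compound_id)
    if (anyNA(idx)) {
      stop("raw_table does not cover the table's compounds", call. = FALSE)
    }
    raw <- raw_table$areas[, idx, drop = FALSE]
    raw_urban <- raw_table$samples$site_type == "urban"
    urban_presence <- colMeans(raw[raw_urban, , drop = FALSE]) /
      pmax(apply(raw, 2, max), .Machine$double.xmin)
    discard <- candidate & urban_presence < presence_threshold
  } else {
    discard <- candidate
  }
  unknown <- ids[!discard]
  disc <- ids[discard]
  sel <- list(unknown_common_ids = unknown,
              discarded = data.frame(
                compound_id = disc,
                cluster = cl[disc],
                peculiarity = pec[as.character(cl[disc])],
                row.names = NULL),
              cluster = cl, peculiarity = pec)
  class(sel) <- "common_selection"
  sel
}

#' @export
print.common_selection <- function(x, ...) {
  cat(sprintf("common_selection: %d unknown commons, %d discarded\n",
              length(x$unknown_common_ids), nrow(x$discarded)))
  invisible(x)
}

#' Split a feature table into urban and industrial subsets
#'
#' Partitions rows by `site_type`, excluding blanks, with row order
#' preserved within each subset.
#'
#' @param table a [feature_table()].
#' @return list with `urban` and `industrial` feature tables.
#' @export
split_subsets <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  bad <- setdiff(unique(table$samples$site_type),
                 c("urban", "industrial", "blank"))
  if (length(bad)) stop("unknown site_type: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  take <- function(type) {
    rows <- which(table$samples$site_type == type)
    if (length(rows) == 0L) {
      # empty subset: bypass the non-empty validation of feature_table()
      out <- list(areas = table$areas[integer(0), , drop = FALSE],
                  samples = table$samples[integer(0), , drop = FALSE],
                  compounds = table$compounds)
      class(out) <- class(table)
      return(out)
    }
    ft_subset(table, samples = rows)
  }
  list(urban = take("urban"), industrial = take("industrial"))
}

#' Export the two-way clustered heatmap matrix
#'
#' Returns the z-score matrix with rows and columns permuted into the
#' dendrogram leaf orders, i.e. the matrix a clustered heatmap displays.
#'
#' @param table z-scored `feature_table`.
#' @param sample_dend,compound_dend [hca()] dendrograms on the two axes.
#' @return numeric matrix in clustered order.
#' @export
heatmap_matrix <- function(table, sample_dend, compound_dend) {
  stopifnot(inherits(table, "feature_table"))
  table$areas[sample_dend$order, compound_dend$order, drop = FALSE]
}
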