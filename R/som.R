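#' @name som
#' @title Batch Self-Organizing Map on a hexagonal lattice
#' @description
#' A deterministic batch-mode Kohonen Self-Organizing Map in the
#' SOM-Toolbox lineage: hexagonal sheet lattice, map sizing by Vesanto's
#' heuristics ([map_size()], [eigen_ratio()]), linear initialization of
#' the codebook on the plane of the first two principal components,
#' two-phase batch training with a Gaussian neighborhood and linearly
#' decaying radius ([som_train()]), and the standard quality metrics —
#' quantization error (QE), topographic error (TE), distribution matching
#' error (DME) and dead-node count ([som_quality()]).  New samples are
#' projected onto a trained map by best-matching-unit search
#' ([som_project()]); samples whose quantization error exceeds the
#' training maximum are flagged as outliers.  Node vectors can be folded
#' back through the scaling model into pseudo-chromatogram signatures
#' ([node_signature()]).
NULL

# round half away from zero (R's round() is half-to-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Construct a hexagonal SOM grid
#'
#' Nodes are laid out row-major (1-based index) on a hexagonal sheet:
#' node in 0-based row `r`, column `c` sits at planar coordinates
#' `(c + 0.5 * (r %% 2), r * sqrt(3) / 2)`, so every pair of neighboring
#' nodes is at planar distance 1.
#'
#' @param xdim columns (the long side; `xdim >= ydim` is enforced by
#'   [map_size()], not here).
#' @param ydim rows.
#' @return object of class `som_grid` with `xdim`, `ydim`, `n_nodes` and
#'   `coords` (n_nodes x 2 planar coordinates).
#' @export
som_grid <- function(xdim, ydim) {
  xdim <- as.integer(xdim)
  ydim <- as.integer(ydim)
  if (xdim < 1L || ydim < 1L) stop("grid sides must be >= 1", call. = FALSE)
  idx <- seq_len(xdim * ydim) - 1L
  r <- idx %/% xdim
  c <- idx %% xdim
  coords <- cbind(x = c + 0.5 * (r %% 2), y = r * sqrt(3) / 2)
  structure(list(xdim = xdim, ydim = ydim, n_nodes = xdim * ydim,
                 coords = coords),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %d x %d hexagonal (%d nodes)\n",
              x$xdim, x$ydim, x$n_nodes))
  invisible(x)
}

#' Vesanto map-size heuristic
#'
#' The number of map units is `ceiling(5 * sqrt(n))` for a "regular" map
#' or `ceiling(5/4 * sqrt(n))` for a "small" map.  The side lengths are
#' chosen so that the map dimension ratio approximates the square root of
#' the ratio of the first two eigenvalues of the training data:
#' `ydim = round(sqrt(munits / eigen_ratio))`, `xdim = round(munits /
#' ydim)`, rounding half away from zero, then swapping so `xdim >= ydim`.
#'
#' @param n_samples number of training samples (>= 2).
#' @param eigen_ratio target side ratio, `sqrt(lambda1 / lambda2)` from
#'   [eigen_ratio()] (>= 1).
#' @param mode `"regular"`, `"small"`, or `"explicit"` (return `dims`
#'   unchanged).
#' @param dims integer `c(xdim, ydim)`, required for `mode = "explicit"`.
#' @return a [som_grid()].
#' @export
#' @examples
#' map_size(24, 1.4, "regular")  # 6 x 4
#' map_size(24, 1.4, "small")    # 4 x 2
map_size <- function(n_samples, eigen_ratio = 1,
                     mode = c("regular", "small", "explicit"), dims = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit") {
    if (is.null(dims) || length(dims) != 2L) {
      stop("explicit mode requires dims = c(xdim, ydim)", call. = FALSE)
    }
    return(som_grid(dims[[1L]], dims[[2L]]))
  }
  if (n_samples < 2L) stop("need >= 2 samples", call. = FALSE)
  if (eigen_ratio < 1) stop("eigen_ratio must be >= 1", call. = FALSE)
  munits <- ceiling(switch(mode,
                           regular = 5 * sqrt(n_samples),
                           small = 5 / 4 * sqrt(n_samples)))
  ydim <- max(1, round_half_up(sqrt(munits / eigen_ratio)))
  xdim <- max(1, round_half_up(munits / ydim))
  if (xdim < ydim) {
    tmp <- xdim
    xdim <- ydim
    ydim <- tmp
  }
  som_grid(xdim, ydim)
}

#' Ratio of the first two eigenvalues of a data matrix
#'
#' Computes `sqrt(lambda1 / lambda2)` from the covariance eigen-spectrum
#' of an (already z-scored) matrix, rounded to one decimal as used by the
#' map-sizing heuristic.
#'
#' @param x numeric matrix (samples x variables), or a `feature_table`
#'   of z-scores.
#' @return the rounded ratio (>= 1).
#' @export
eigen_ratio <- function(x) {
  if (inherits(x, "feature_table")) x <- x$areas
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need >= 2 samples and >= 2 variables", call. = FALSE)
  }
  d <- svd(scale(x, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  lambda <- d^2 / (nrow(x) - 1)
  if (length(lambda) < 2L || lambda[2L] <= lambda[1L] * 1e-12) {
    stop("second eigenvalue is (numerically) zero", call. = FALSE)
  }
  round(sqrt(lambda[1L] / lambda[2L]), 1)
}

# first and second BMU indices + distances for every row of x
bmu_search <- function(codebook, x) {
  x <- rbind(x)
  # squared distances via the expansion ||x||^2 - 2 x.m + ||m||^2
  cross <- x %*% t(codebook)
  d2 <- outer(rowSums(x^2), rep(1, nrow(codebook))) - 2 * cross +
    outer(rep(1, nrow(x)), rowSums(codebook^2))
  d2[d2 < 0] <- 0
  first <- unname(apply(d2, 1L, which.min))  # lowest index wins ties
  second <- vapply(seq_len(nrow(d2)), function(i) {
    row <- d2[i, ]
    row[first[i]] <- Inf
    unname(which.min(row))
  }, integer(1))
  list(first = first, second = second,
       qe = unname(sqrt(d2[cbind(seq_len(nrow(d2)), first)])))
}

#' Train a batch Self-Organizing Map
#'
#' Deterministic batch training: the codebook is initialized linearly on
#' the plane spanned by the first two principal components of the data
#' (so no random seed enters), then refined in two phases — a rough phase
#' with neighborhood radius decaying linearly from `max(1, xdim/2)` to
#' `max(1, xdim/8)`, and a fine-tuning phase decaying to 1.  Each epoch
#' assigns every sample to its best matching unit and replaces each node
#' vector by the neighborhood-weighted mean of all samples,
#' `m_j = sum_i h(bmu_i, j) x_i / sum_i h(bmu_i, j)` with Gaussian
#' neighborhood `h = exp(-d_grid^2 / (2 sigma^2))`; a node with zero
#' weight keeps its previous vector.  Every updated node vector is a
#' convex combination of training samples.
#'
#' @param x numeric matrix of z-scores (samples x variables), or a
#'   z-scored `feature_table`.
#' @param grid a [som_grid()].
#' @param rough_epochs,finetune_epochs epochs per phase.
#' @param radius_end neighborhood radius at the end of fine-tuning
#'   (default 1; values near 0 drive the map towards hard k-means-like
#'   assignment).
#' @param scaling optional `scaling_model` carried along for projection
#'   and signature reconstruction.
#' @return object of class `som_model`: `grid`, `codebook` (n_nodes x
#'   n_variables), `scaling`, `training_config`, `hit_counts`,
#'   `training_qe` (per training sample), and `quality`
#'   ([som_quality()] on the training data).
#' @export
som_train <- function(x, grid, rough_epochs = 50L, finetune_epochs = 100L,
                      radius_end = 1, scaling = NULL) {
  ft <- if (inherits(x, "feature_table")) x else NULL
  if (!is.null(ft)) x <- ft$areas
  if (!is.matrix(x) || nrow(x) < 1L) stop("empty data", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in data", call. = FALSE)
  stopifnot(inherits(grid, "som_grid"))

  n <- nrow(x)
  p <- ncol(x)
  center <- colMeans(x)
  codebook <- matrix(rep(center, each = grid$n_nodes), grid$n_nodes, p)

  if (grid$n_nodes > 1L) {
    sv <- svd(sweep(x, 2, center), nu = 0, nv = min(2L, p, n))
    lambda <- sv$d^2 / max(1L, n - 1L)
    # canonical eigenvector signs, so initialization (and hence the
    # whole deterministic fit) is invariant to sample order
    for (j in seq_len(ncol(sv$v))) {
      if (sv$v[which.max(abs(sv$v[, j])), j] < 0) sv$v[, j] <- -sv$v[, j]
    }
    span <- function(v) {
      rng <- v - mean(v)
      if (max(abs(rng)) == 0) rep(0, length(v)) else rng / max(abs(rng))
    }
    a1 <- span(grid$coords[, "x"])
    a2 <- span(grid$coords[, "y"])
    if (ncol(sv$v) >= 1L && lambda[1L] > 0) {
      codebook <- codebook + outer(a1, sqrt(lambda[1L]) * sv$v[, 1L])
    }
    if (ncol(sv$v) >= 2L && length(lambda) >= 2L && lambda[2L] > 0) {
      codebook <- codebook + outer(a2, sqrt(lambda[2L]) * sv$v[, 2L])
    }
  }

  grid_d2 <- as.matrix(stats::dist(grid$coords))^2
  r_hi <- max(1, grid$xdim / 2)
  r_mid <- max(1, grid$xdim / 8)
  schedule <- c(phase_radii(r_hi, r_mid, rough_epochs),
                phase_radii(r_mid, radius_end, finetune_epochs))

  qe_history <- numeric(length(schedule))
  for (e in seq_along(schedule)) {
    sigma <- schedule[e]
    bm <- bmu_search(codebook, x)
    h <- exp(-grid_d2[bm$first, , drop = FALSE] / (2 * sigma^2))
    den <- colSums(h)
    num <- t(h) %*% x
    upd <- den > 0
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    qe_history[e] <- mean(bmu_search(codebook, x)$qe)
  }

  bm <- bmu_search(codebook, x)
  hits <- tabulate(bm$first, nbins = grid$n_nodes)
  colnames(codebook) <- colnames(x)
  model <- structure(
    list(grid = grid, codebook = codebook, scaling = scaling,
         training_config = list(rough_epochs = as.integer(rough_epochs),
                                finetune_epochs = as.integer(finetune_epochs),
                                radius_start = r_hi, radius_mid = r_mid,
                                radius_end = radius_end,
                                initialization = "linear-pca",
                                neighborhood = "gaussian"),
         hit_counts = hits,
         qe_history = qe_history,
         training_qe = bm$qe,
         n_variables = p,
         variable_ids = colnames(x),
         sample_ids = rownames(x)),
    class = "som_model")
  model$quality <- som_quality(model, x)
  model
}

phase_radii <- function(from, to, epochs) {
  epochs <- as.integer(epochs)
  if (epochs <= 0L) return(numeric(0))
  if (epochs == 1L) return(to)
  from + (to - from) * (seq_len(epochs) - 1) / (epochs - 1)
}

#' @export
print.som_model <- function(x, ...) {
  q <- x$quality
  cat(sprintf("som_model: %d x %d hexagonal map, %d variables\n",
              x$grid$xdim, x$grid$ydim, x$n_variables))
  if (!is.null(q)) {
    cat(sprintf("  QE %.3f | TE %.3f | DME %.3f | dead nodes %d/%d\n",
                q$qe, q$te, q$dme, q$dead_nodes, x$grid$n_nodes))
  }
  invisible(x)
}

#' Best matching unit of a sample
#'
#' @param model a [som_train()] model.
#' @param x numeric vector (one sample, in the model's variable space)
#'   or matrix of such rows.
#' @return list with `node` (index, lowest index wins ties) and `qe`
#'   (Euclidean distance to the BMU); vectors if `x` has several rows.
#' @export
som_bmu <- function(model, x) {
  stopifnot(inherits(model, "som_model"))
  x <- rbind(x)
  if (ncol(x) != model$n_variables) {
    stop(sprintf("sample has %d variables; model expects %d",
                 ncol(x), model$n_variables), call. = FALSE)
  }
  bm <- bmu_search(model$codebook, x)
  list(node = bm$first, qe = bm$qe)
}

# two-sample Kolmogorov-Smirnov statistic
ks_stat <- function(x, y) {
  pooled <- c(x, y)
  ord <- order(pooled)
  flag <- c(rep(1 / length(x), length(x)),
            rep(-1 / length(y), length(y)))[ord]
  max(abs(cumsum(flag)))
}

#' SOM quality metrics
#'
#' * `qe` — mean Euclidean distance between samples and their BMU.
#' * `te` — fraction of samples whose first and second BMUs are not
#'   adjacent on the grid (planar distance > 1.01).
#' * `dme` — fraction of variables whose two-sample Kolmogorov–Smirnov
#'   statistic, comparing the data column with the hit-weighted codebook
#'   column, exceeds the alpha = 0.05 critical value: a summary of how
#'   well the fitted node values reproduce the per-variable data
#'   distributions.
#' * `dead_nodes` — nodes that are BMU of no sample.
#'
#' @param model a `som_model`.
#' @param x data matrix or z-scored `feature_table` to evaluate against.
#' @return list (`som_quality`) with `qe`, `te`, `dme`, `dead_nodes`,
#'   `dead_node_fraction`.
#' @export
som_quality <- function(model, x) {
  stopifnot(inherits(model, "som_model"))
  if (inherits(x, "feature_table")) x <- x$areas
  if (nrow(x) < 1L) stop("data is empty", call. = FALSE)
  bm <- bmu_search(model$codebook, x)
  coords <- model$grid$coords
  planar <- sqrt(rowSums((coords[bm$first, , drop = FALSE] -
                            coords[bm$second, , drop = FALSE])^2))
  te <- mean(planar > 1.01)
  hits <- tabulate(bm$first, nbins = model$grid$n_nodes)
  weighted_cols <- rep(seq_len(model$grid$n_nodes), hits)
  ks_crit <- 1.3581 * sqrt((nrow(x) + length(weighted_cols)) /
                             (nrow(x) * length(weighted_cols)))
  flagged <- vapply(seq_len(ncol(x)), function(j) {
    ks_stat(x[, j], model$codebook[weighted_cols, j]) > ks_crit
  }, logical(1))
  structure(list(qe = mean(bm$qe),
                 te = te,
                 dme = mean(flagged),
                 dead_nodes = sum(hits == 0L),
                 dead_node_fraction = mean(hits == 0L)),
            class = "som_quality")
}

#' @export
print.som_quality <- function(x, ...) {
  cat(sprintf("som_quality: QE %.4f, TE %.3f, DME %.3f, dead nodes %d (%.0f%%)\n",
              x$qe, x$te, x$dme, x$dead_nodes, 100 * x$dead_node_fraction))
  invisible(x)
}

#' Project samples onto a trained SOM and flag outliers
#'
#' Each sample is assigned to its best matching unit; its quantization
#' error (Euclidean distance to the BMU) is compared against a threshold
#' equal to `multiplier` times the maximum quantization error observed on
#' the training samples.  Samples above the threshold do not resemble any
#' signature the map learned and are flagged as outliers.
#'
#' @param model a [som_train()] model.
#' @param newdata a raw-area `feature_table` (scaled internally through
#'   the model's `scaling`; an error if the model carries none), a
#'   z-scored `feature_table`, or a numeric matrix already in the model's
#'   variable space.
#' @param multiplier threshold multiplier on the maximum training QE
#'   (default 1).
#' @return data.frame (`som_projection`) with `sample_id`, `bmu`, `qe`,
#'   `log10_qe`, `is_outlier` and attribute `threshold`.
#' @export
som_project <- function(model, newdata, multiplier = 1) {
  stopifnot(inherits(model, "som_model"))
  sample_ids <- NULL
  if (inherits(newdata, "feature_table")) {
    if (!inherits(newdata, "scaled_feature_table")) {
      if (is.null(model$scaling)) {
        stop("raw feature table given but the model carries no scaling model",
             call. = FALSE)
      }
      newdata <- zscore_apply(newdata, model$scaling)
    }
    sample_ids <- newdata$samples$sample_id
    newdata <- newdata$areas
  }
  if (ncol(newdata) != model$n_variables) {
    stop(sprintf("data has %d variables; model expects %d",
                 ncol(newdata), model$n_variables), call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(newdata)
    if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(newdata)))
  }
  bm <- bmu_search(model$codebook, newdata)
  threshold <- multiplier * max(model$training_qe)
  out <- data.frame(sample_id = sample_ids,
                    bmu = bm$first,
                    qe = bm$qe,
                    log10_qe = log10(bm$qe),
                    is_outlier = bm$qe > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("som_projection", "data.frame")
  out
}

#' Reconstruct a node signature as a pseudo-chromatogram
#'
#' Folds a codebook vector back through the model's z-score scaling
#' (`area = z * sd + mean`, clipped at zero) and attaches retention time
#' and m/z, giving the stick-chromatogram representation of the recurrent
#' sample signature the node encodes.
#'
#' @param model a `som_model` carrying a `scaling` model.
#' @param node node index (1-based, row-major).
#' @param compounds compound metadata data.frame aligned with the model's
#'   variables (columns `compound_id`, `mz`, `rt`).
#' @return data.frame with `compound_id`, `rt`, `mz`, `area`, sorted by
#'   ascending retention time.
#' @export
node_signature <- function(model, node, compounds) {
  stopifnot(inherits(model, "som_model"))
  if (node < 1L || node > model$grid$n_nodes) {
    stop("node index out of range", call. = FALSE)
  }
  if (is.null(model$scaling)) {
    stop("model carries no scaling model; cannot invert z-scores",
         call. = FALSE)
  }
  ids <- model$variable_ids
  if (is.null(ids)) ids <- setdiff(names(model$scaling$means),
                                   model$scaling$dropped)
  idx <- match(ids, compounds$compound_id)
  if (anyNA(idx)) {
    stop("compound metadata does not cover the model's variables",
         call. = FALSE)
  }
  z <- model$codebook[node, ]
  area <- pmax(0, z * model$scaling$sds[ids] + model$scaling$means[ids])
  out <- data.frame(compound_id = ids,
                    rt = compounds$rt[idx],
                    mz = compounds$mz[idx],
                    area = unname(area),
                    stringsAsFactors = FALSE)
  out[order(out$rt), , drop = FALSE]
}

#' Table-1-style model quality summary for candidate maps
#'
#' Trains the "regular" and "small" Vesanto-sized maps plus any explicit
#' candidate grids on the same data and tabulates their dimensions, side
#' ratio and quality metrics, supporting the human trade-off choice of a
#' final map.
#'
#' @param x z-scored training matrix or `feature_table`.
#' @param extra_dims list of integer `c(xdim, ydim)` candidates to add.
#' @param ... passed to [som_train()].
#' @return data.frame: `map`, `xdim`, `ydim`, `ratio`, `dead_nodes`,
#'   `dead_node_pct`, `dme`, `qe`, `te`.
#' @export
som_candidates <- function(x, extra_dims = list(), ...) {
  m <- if (inherits(x, "feature_table")) x$areas else x
  er <- eigen_ratio(m)
  grids <- list(regular = map_size(nrow(m), er, "regular"),
                small = map_size(nrow(m), er, "small"))
  for (d in extra_dims) {
    grids[[sprintf("%dx%d", d[[1L]], d[[2L]])]] <-
      som_grid(d[[1L]], d[[2L]])
  }
  rows <- lapply(names(grids), function(nm) {
    g <- grids[[nm]]
    model <- som_train(m, g, ...)
    q <- model$quality
    data.frame(map = nm, xdim = g$xdim, ydim = g$ydim,
               ratio = round(g$xdim / g$ydim, 1),
               dead_nodes = q$dead_nodes,
               dead_node_pct = round(100 * q$dead_node_fraction),
               dme = q$dme, qe = q$qe, te = q$te,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
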