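test_that("map sizing reproduces the published heuristic grids", {
  reg <- map_size(24, 1.4, "regular")
  expect_equal(c(reg$xdim, reg$ydim), c(6L, 4L))
  expect_equal(round(reg$xdim / reg$ydim, 1), 1.5)
  sml <- map_size(24, 1.4, "small")
  expect_equal(c(sml$xdim, sml$ydim), c(4L, 2L))
  expect_equal(round(sml$xdim / sml$ydim, 1), 2.0)
  # n = 100, isotropic data: munits = 50, 7 x 7 by hand
  sq <- map_size(100, 1.0, "regular")
  expect_equal(c(sq$xdim, sq$ydim), c(7L, 7L))
  # explicit mode returns the requested grid unchanged
  exp_grid <- map_size(24, 1.4, "explicit", dims = c(4, 3))
  expect_equal(c(exp_grid$xdim, exp_grid$ydim), c(4L, 3L))
  expect_equal(exp_grid$n_nodes, 12L)
  expect_error(map_size(24, 1.4, "explicit"), "dims")
  expect_error(map_size(1, 1.4, "regular"), ">= 2")
  # the long side always comes first
  for (n in c(5, 24, 60, 144)) {
    for (r in c(1, 1.4, 2.5)) {
      g <- map_size(n, r, "regular")
      expect_gte(g$xdim, g$ydim)
    }
  }
})

test_that("hexagonal grid geometry has unit nearest-neighbor spacing", {
  for (dims in list(c(4, 3), c(6, 4), c(2, 1), c(5, 5))) {
    g <- som_grid(dims[1], dims[2])
    expect_equal(g$n_nodes, dims[1] * dims[2])
    if (g$n_nodes > 1) {
      d <- as.matrix(dist(g$coords))
      diag(d) <- Inf
      expect_equal(min(d), 1, tolerance = 1e-12)
      # every node touches at least one neighbor at exactly distance 1
      expect_true(all(rowSums(d < 1.01) >= 1))
    }
  }
})

test_that("eigen ratio matches the eigen-decomposition oracle", {
  # isotropic two-variable cloud: equal eigenvalues, ratio 1.0
  iso <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(eigen_ratio(iso), 1.0)
  # constructed sample covariance with eigenvalues 4 and 1
  x <- cbind(c(-1, -1, 1, 1) * sqrt(3), c(-1, 1, -1, 1) * sqrt(3) / 2)
  ev <- eigen(stats::cov(x))$values
  expect_equal(ev, c(4, 1))
  expect_equal(eigen_ratio(x), round(sqrt(ev[1] / ev[2]), 1))
  expect_equal(eigen_ratio(x), 2.0)
  # rank-1 data has no second eigenvalue
  expect_error(eigen_ratio(cbind(1:5, (1:5) * 2)), "second eigenvalue")
})

test_that("single-node training collapses to the column means", {
  set.seed(7)
  x <- matrix(rnorm(60), 10, 6)
  model <- som_train(x, som_grid(1, 1), rough_epochs = 3,
                     finetune_epochs = 3)
  expect_equal(as.vector(model$codebook), colMeans(x), tolerance = 1e-12)
})

test_that("batch training is deterministic and stays in the data hull", {
  set.seed(8)
  x <- matrix(rnorm(24 * 15), 24, 15)
  m1 <- som_train(x, som_grid(4, 3))
  m2 <- som_train(x, som_grid(4, 3))
  expect_identical(m1$codebook, m2$codebook)
  # every codebook vector is a convex combination of samples, so each
  # coordinate lies within the per-variable data range
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  expect_true(all(sweep(m1$codebook, 2, lo, ">=")))
  expect_true(all(sweep(m1$codebook, 2, hi, "<=")))
  # the batch update is order-free up to floating point
  perm <- sample(nrow(x))
  m3 <- som_train(x[perm, ], som_grid(4, 3))
  expect_equal(m1$codebook, m3$codebook, tolerance = 1e-9)
  expect_error(som_train(matrix(numeric(0), 0, 3), som_grid(2, 1)),
               "empty")
})

test_that("training QE stabilizes over the final fine-tuning epochs", {
  dat <- generate_synthetic(small_synth_config(seed = 2))
  blocks <- split_subsets(dat$table)
  scaling <- zscore_fit(blocks$urban)
  z <- zscore_apply(blocks$urban, scaling)
  model <- som_train(z$areas, som_grid(4, 3), scaling = scaling)
  tail_qe <- utils::tail(model$qe_history, 10)
  expect_true(all(diff(tail_qe) <= 1e-9))
})

test_that("a map with enough nodes memorizes well-separated points", {
  pts <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- pts[rep(1:3, each = 2), ]   # duplicated so n > k
  model <- som_train(x, som_grid(2, 2), rough_epochs = 20,
                     finetune_epochs = 50, radius_end = 0.05)
  proj <- som_project(model, x)
  expect_lte(max(proj$qe), 1e-6)
  expect_equal(model$quality$dead_nodes, 1L)  # 4 nodes, 3 clusters
})

test_that("BMU search minimizes distance with index tie-breaking", {
  set.seed(3)
  x <- matrix(rnorm(40), 10, 4)
  model <- som_train(x, som_grid(4, 2), rough_epochs = 5,
                     finetune_epochs = 5)
  # a query equal to codebook vector 7 maps to node 7 at distance 0
  hit <- som_bmu(model, model$codebook[7, ])
  expect_equal(hit$node, 7L)
  expect_lt(hit$qe, 1e-6)
  # hand-built 3-4-5 geometry
  toy <- structure(list(grid = som_grid(2, 1),
                        codebook = rbind(c(3, 4), c(6, 8)),
                        n_variables = 2L),
                   class = "som_model")
  hit2 <- som_bmu(toy, c(0, 0))
  expect_equal(hit2$node, 1L)
  expect_equal(hit2$qe, 5)
  # equidistant nodes: the lower index wins
  tie <- structure(list(grid = som_grid(2, 1),
                        codebook = rbind(c(1, 0), c(-1, 0)),
                        n_variables = 2L),
                   class = "som_model")
  expect_equal(som_bmu(tie, c(0, 1))$node, 1L)
  expect_error(som_bmu(toy, c(1, 2, 3)), "variables")
})

test_that("quality metrics respect their definitions and ranges", {
  dat <- generate_synthetic(small_synth_config(seed = 5))
  blocks <- split_subsets(dat$table)
  scaling <- zscore_fit(blocks$urban)
  z <- zscore_apply(blocks$urban, scaling)
  for (dims in list(c(4, 3), c(6, 4), c(4, 2))) {
    model <- som_train(z$areas, som_grid(dims[1], dims[2]),
                       scaling = scaling)
    q <- model$quality
    expect_gte(q$te, 0); expect_lte(q$te, 1)
    expect_gte(q$dme, 0); expect_lte(q$dme, 1)
    expect_gte(q$qe, 0)
    expect_gte(q$dead_nodes, 0)
    expect_lte(q$dead_nodes, model$grid$n_nodes)
    expect_equal(q$dead_nodes, sum(model$hit_counts == 0))
  }
  # a model that memorizes its data has QE ~ 0 and counts unused nodes
  pts <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  mem <- som_train(pts, som_grid(3, 2), rough_epochs = 20,
                   finetune_epochs = 50, radius_end = 0.05)
  expect_lt(mem$quality$qe, 1e-6)
  expect_equal(mem$quality$dead_nodes, 6L - 4L)
})

test_that("projection flags samples beyond the training QE envelope", {
  dat <- generate_synthetic(synthetic_config(seed = 6))
  b <- blank_filter(dat$table, dat$blanks)
  t <- dilution_ttest_filter(b$table)
  c <- correctness_filter(t$table)
  scaling_all <- zscore_fit(c$table)
  z_all <- zscore_apply(c$table, scaling_all)
  sel <- select_unknown_common(z_all, hca(z_all, "compounds"),
                               raw_table = c$table)
  blocks <- split_subsets(ft_subset(c$table,
                                    compounds = sel$unknown_common_ids))
  scaling <- zscore_fit(blocks$urban)
  z_urban <- zscore_apply(blocks$urban, scaling)
  model <- som_train(z_urban$areas, som_grid(4, 3), scaling = scaling)

  # training samples never exceed their own maximum QE
  self_proj <- som_project(model, z_urban)
  expect_false(any(self_proj$is_outlier))
  expect_equal(attr(self_proj, "threshold"), max(model$training_qe))

  # a sample equal to a codebook vector has QE zero
  cb_proj <- som_project(model, model$codebook[3, , drop = FALSE])
  expect_lt(cb_proj$qe, 1e-6)

  # the industrial block is entirely outlying, diluted samples included
  ind_proj <- som_project(model, blocks$industrial)  # scaled via the model
  expect_true(all(ind_proj$is_outlier))
  dil_ids <- blocks$industrial$samples$sample_id[
    blocks$industrial$samples$dilution == "diluted"]
  expect_true(all(ind_proj$is_outlier[ind_proj$sample_id %in% dil_ids]))

  # raw tables need the model's scaling
  bare <- som_train(z_urban$areas, som_grid(4, 3))
  expect_error(som_project(bare, blocks$industrial), "scaling")
})

test_that("node signatures invert the z-score transform", {
  dat <- generate_synthetic(small_synth_config(seed = 4))
  blocks <- split_subsets(dat$table)
  scaling <- zscore_fit(blocks$urban)
  z <- zscore_apply(blocks$urban, scaling)
  model <- som_train(z$areas, som_grid(4, 3), scaling = scaling)

  sig <- node_signature(model, 1, dat$table$compounds)
  expect_true(all(diff(sig$rt) >= 0))          # chromatogram order
  expect_true(all(sig$area >= 0))              # clipped at zero
  # a zero z-value reconstructs the training mean
  model2 <- model
  model2$codebook[1, ] <- 0
  sig2 <- node_signature(model2, 1, dat$table$compounds)
  expect_equal(sig2$area[order(sig2$compound_id)],
               unname(model$scaling$means[sort(sig2$compound_id)]))
  # z = -mean/sd lands exactly on the clip boundary
  ids <- model$variable_ids
  model2$codebook[1, ] <- -model$scaling$means[ids] / model$scaling$sds[ids]
  sig3 <- node_signature(model2, 1, dat$table$compounds)
  expect_equal(sig3$area, rep(0, nrow(sig3)))
  expect_error(node_signature(model, 99, dat$table$compounds),
               "out of range")
})

test_that("candidate-map table reports the heuristic grids with quality", {
  dat <- generate_synthetic(small_synth_config(seed = 3))
  blocks <- split_subsets(dat$table)
  z <- zscore_apply(blocks$urban, zscore_fit(blocks$urban))
  tab <- som_candidates(z$areas, extra_dims = list(c(4, 3)),
                        rough_epochs = 10, finetune_epochs = 10)
  expect_equal(tab$map, c("regular", "small", "4x3"))
  expect_equal(tab$xdim[3], 4)
  expect_true(all(tab$qe >= 0))
  expect_true(all(tab$te >= 0 & tab$te <= 1))
})
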