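make_blanks <- function(blank_areas, site = "U1") {
  make_table(blank_areas, sites = rep(site, nrow(blank_areas)),
             dilutions = rep("blank", nrow(blank_areas)),
             replicates = seq_len(nrow(blank_areas)))
}

test_that("blank filter applies a strict five-fold rule per site", {
  # compound A: area 100 vs blank mean 25 -> 100 < 125 -> background
  # compound B: area 125 vs blank mean 25 -> not 'less than' -> retained
  # compound C: blank mean 0 -> retained whatever its area
  areas <- matrix(c(100, 100, 125, 125, 1, 1), 2, 3,
                  dimnames = list(NULL, c("A", "B", "C")))
  tab <- two_level_table(areas[1, , drop = FALSE], areas[2, , drop = FALSE])
  blanks <- make_blanks(matrix(c(25, 25, 25, 25, 0, 0), 2, 3,
                               dimnames = list(NULL, c("A", "B", "C"))))
  res <- blank_filter(tab, blanks, factor = 5)
  expect_equal(res$table$compounds$compound_id, c("B", "C"))
  expect_equal(res$report$n_discarded_blank, 1L)
  expect_equal(names(res$report$per_compound_flags), "A")
  expect_error(blank_filter(tab, blanks, factor = 0), "factor")
})

test_that("Welch dilution filter matches the closed-form oracle", {
  conc <- c(100, 102, 98, 101, 99, 100)
  dil <- c(10.0, 10.2, 9.8, 10.1, 9.9, 10.0)
  tab <- two_level_table(matrix(conc, 6, 1, dimnames = list(NULL, "A")),
                         matrix(dil, 6, 1, dimnames = list(NULL, "A")))
  res <- dilution_ttest_filter(tab, method = "welch", log10_areas = FALSE)
  p_oracle <- welch_oracle_p(conc, dil)
  expect_equal(unname(res$p_values["A"]), p_oracle, tolerance = 1e-12)
  expect_lt(p_oracle, 0.05)
  expect_equal(res$table$compounds$compound_id, "A")  # retained

  # identical groups: t = 0, p = 1 -> discarded
  tab2 <- two_level_table(matrix(conc, 6, 1, dimnames = list(NULL, "A")),
                          matrix(conc, 6, 1, dimnames = list(NULL, "A")))
  res2 <- dilution_ttest_filter(tab2, method = "welch",
                                log10_areas = FALSE)
  expect_equal(unname(res2$p_values["A"]), 1)
  expect_equal(ncol(res2$table$areas), 0L)

  # alpha = 0 discards everything, responsive or not
  res3 <- dilution_ttest_filter(tab, alpha = 0, method = "welch",
                                log10_areas = FALSE)
  expect_equal(ncol(res3$table$areas), 0L)

  # degenerate group sizes are refused
  tab4 <- two_level_table(matrix(1, 1, 1), matrix(1, 1, 1))
  expect_error(dilution_ttest_filter(tab4, method = "welch"), ">= 2")
})

test_that("paired dilution filter keeps responsive compounds and drops flat ones", {
  set.seed(1)
  n_sites <- 5
  sites <- rep(paste0("U", seq_len(n_sites)), each = 4)
  dil <- rep(rep(c("concentrated", "diluted"), each = 2), n_sites)
  reps <- rep(c(1, 2), 2 * n_sites)
  # pair (site, replicate) shares a latent level; levels vary a lot
  # across sites, which is what defeats a pooled two-sample test
  level <- 10^rnorm(2 * n_sites, 6, 1)
  pair_idx <- as.integer(factor(paste(sites, reps)))
  base <- level[pair_idx]
  responsive <- ifelse(dil == "diluted", base * 0.1, base)
  flat <- base * exp(rnorm(length(base), 0, 0.05))
  areas <- cbind(resp = responsive, flat = flat)
  tab <- make_table(areas, sites, dil, reps)
  res <- dilution_ttest_filter(tab, method = "paired")
  expect_true("resp" %in% res$table$compounds$compound_id)
  expect_false("flat" %in% res$table$compounds$compound_id)
})

test_that("Correctness filter implements the per-site median dummy rule", {
  # 10 sites, one compound per dummy scenario; the dummy of a site is 1
  # iff the diluted site mean is below the concentrated one
  build <- function(n_ones) {
    conc <- matrix(100, 20, 1)
    dil <- matrix(rep(ifelse(seq_len(10) <= n_ones, 10, 200), each = 2),
                  20, 1)
    make_table(rbind(conc, dil),
               sites = rep(paste0("U", 1:10), each = 2, times = 2),
               dilutions = rep(c("concentrated", "diluted"), each = 20),
               replicates = rep(c(1, 2), 20))
  }
  # brute-force medians of sorted 0/1 vectors decide the expectation
  for (n_ones in c(10, 6, 5, 0)) {
    med <- median(c(rep(1, n_ones), rep(0, 10 - n_ones)))
    res <- correctness_filter(build(n_ones))
    if (med >= 1) {
      expect_equal(ncol(res$table$areas), 1L)
    } else {
      expect_equal(ncol(res$table$areas), 0L)
      expect_equal(res$report$n_discarded_correctness, 1L)
    }
  }

  # a site missing one dilution level is a design error
  tab <- two_level_table(matrix(1:2, 2, 1), matrix(1:2, 2, 1))
  tab$samples$dilution <- "concentrated"
  expect_error(correctness_filter(tab), "missing a dilution level")
})

test_that("Correctness is invariant to increasing affine rescaling", {
  dat <- generate_synthetic(small_synth_config(seed = 9))
  raw <- dat$table
  a <- runif(ncol(raw$areas), 0.5, 3)
  b <- runif(ncol(raw$areas), 0, 50)
  scaled <- raw
  scaled$areas <- sweep(sweep(raw$areas, 2, a, "*"), 2, b, "+")
  r1 <- correctness_filter(raw)
  r2 <- correctness_filter(scaled)
  expect_identical(r1$table$compounds$compound_id,
                   r2$table$compounds$compound_id)
  expect_identical(r1$dummies, r2$dummies)
})

test_that("screening removes the generator's background and artifact classes", {
  dat <- generate_synthetic(synthetic_config(seed = 4))
  cls <- dat$truth$compound_class
  b <- blank_filter(dat$table, dat$blanks)
  expect_false(any(cls[b$table$compounds$compound_id] == "background"))
  expect_true(all(names(cls)[cls != "background"] %in%
                    b$table$compounds$compound_id))
  t <- dilution_ttest_filter(b$table)
  c <- correctness_filter(t$table)
  surv <- c$table$compounds$compound_id
  expect_false(any(cls[surv] == "artifact"))
  # every artifact fails the Correctness dummy rule by construction
  art_tab <- ft_subset(dat$table,
                       compounds = names(cls)[cls == "artifact"])
  expect_equal(ncol(correctness_filter(art_tab)$table$areas), 0L)
  # commons and exclusives survive screening
  expect_true(all(names(cls)[cls %in% c("common", "industrial_exclusive")]
                  %in% surv))
  # the report chain accounts for every compound exactly once
  rep <- filter_report_merge(b$report, t$report, c$report)
  expect_equal(rep$n_input, ncol(dat$table$areas))
  expect_equal(rep$n_retained, length(surv))
  expect_equal(rep$n_input - rep$n_discarded_blank - rep$n_discarded_ttest -
                 rep$n_discarded_correctness, rep$n_retained)
})

test_that("z-scoring matches its definition and handles constants", {
  tab <- two_level_table(matrix(c(1, 2, 5, 5), 2, 2,
                                dimnames = list(NULL, c("A", "B"))),
                         matrix(c(3, 0, 5, 5), 2, 2,
                                dimnames = list(NULL, c("A", "B"))))
  model <- zscore_fit(tab)
  expect_equal(unname(model$means["A"]), 1.5)
  expect_equal(unname(model$sds["A"]), stats::sd(c(1, 2, 3, 0)))
  expect_equal(model$dropped, "B")          # constant column is dropped
  z <- zscore_apply(tab, model)
  expect_equal(colnames(z$areas), "A")

  col <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "A"))
  tab3 <- make_table(col, rep("U1", 3), rep("concentrated", 3), 1:3)
  z3 <- zscore_apply(tab3, zscore_fit(tab3))
  expect_equal(unname(z3$areas[, 1]), c(-1, 0, 1))

  # applying fit(t) to t standardizes every retained column
  dat <- generate_synthetic(small_synth_config(seed = 6))
  m <- zscore_fit(dat$table)
  z <- zscore_apply(dat$table, m)
  expect_lt(max(abs(colMeans(z$areas))), 1e-12)
  expect_lt(max(abs(apply(z$areas, 2, stats::sd) - 1)), 1e-12)

  # a table lacking a modeled compound is refused
  expect_error(zscore_apply(ft_subset(dat$table, compounds = 1:3), m),
               "lacks modeled compound")
  expect_error(zscore_fit(ft_subset(dat$table, samples = 1L)), ">= 2")
})
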