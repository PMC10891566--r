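# Shared fixture builders and independent oracles.

# minimal valid feature table from an areas matrix; samples follow the
# site/dilution/replicate naming convention
make_table <- function(areas, sites, dilutions, replicates) {
  ids <- sample_name_build(sites, dilutions, replicates)
  rownames(areas) <- ids
  if (is.null(colnames(areas))) {
    colnames(areas) <- sprintf("C%03d", seq_len(ncol(areas)))
  }
  is_blank <- dilutions == "blank"
  feature_table(
    areas,
    data.frame(sample_id = ids, site = sites,
               site_type = ifelse(is_blank, "blank",
                                  ifelse(grepl("^I", sites), "industrial",
                                         "urban")),
               dilution = ifelse(is_blank, "concentrated", dilutions),
               replicate = replicates,
               stringsAsFactors = FALSE),
    data.frame(compound_id = colnames(areas),
               mz = seq(100, 100 + ncol(areas) - 1),
               rt = seq_len(ncol(areas)),
               name = NA_character_,
               confidence_level = 5L,
               stringsAsFactors = FALSE))
}

# one site, two dilution levels, n replicates each: the smallest design
# accepted by the dilution filters
two_level_table <- function(conc_areas, dil_areas, site = "U1") {
  n <- nrow(conc_areas)
  make_table(rbind(conc_areas, dil_areas),
             sites = rep(site, 2 * n),
             dilutions = rep(c("concentrated", "diluted"), each = n),
             replicates = rep(seq_len(n), 2))
}

# a fast-running synthetic design for tests that do not need the full
# default compound counts
small_synth_config <- function(seed = 1L, ...) {
  synthetic_config(n_common_compounds = 60L, n_industrial_exclusive = 15L,
                   n_background = 10L, n_artifact = 8L, seed = seed, ...)
}

# Brute-force agglomerative clustering oracle: Lance-Williams recurrence
# for Ward's method in the distance-scale (Ward.D2) convention.  Returns
# merge heights in merge order.
ward_oracle_heights <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b) {
          i <- active[a]; j <- active[b]
          if (d[i, j] < best_d) {
            best_d <- d[i, j]
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- best_d
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      d_new <- sqrt(((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
                       nk * d[i, j]^2) / (ni + nj + nk))
      d[i, k] <- d[k, i] <- d_new
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Welch two-sample t-test p-value from the closed-form expressions
welch_oracle_p <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  2 * stats::pt(-abs(tstat), df)
}
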