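#' Configuration for the synthetic feature-table generator
#'
#' Encodes the sampling design the generator emulates: a set of urban and
#' industrial wastewater treatment plants, each sampled with replicate
#' injections at two dilution levels (concentrated and 1:10 diluted), with
#' per-site sequence blanks.  Compound classes control the statistical
#' structure that the downstream screening and selection stages are meant
#' to exploit:
#'
#' * `common` — present at every site at a shared log10 baseline level;
#'   industrial sites additionally receive per-site log-scale intensity
#'   offsets on a random half of these compounds (same substance, different
#'   level).
#' * `industrial_exclusive` — at trace level everywhere except the
#'   industrial site(s) each compound is assigned to, where it is high.
#' * `background` — instrument/solvent features that dominate the blanks,
#'   so they violate the five-fold blank rule.
#' * `artifact` — features whose apparent area ignores dilution (the
#'   diluted site mean exceeds the concentrated one by construction), the
#'   signature of integration artifacts.
#'
#' @param n_urban_sites,n_industrial_sites number of urban (`U1`, `U2`,
#'   ...) and industrial (`I1`, ...) sites.
#' @param n_replicates replicate injections per site and dilution level.
#' @param dilution_factor fraction of the concentrated level measured in
#'   the diluted replicates (default 0.1, i.e. a 1:10 dilution).
#' @param n_common_compounds,n_industrial_exclusive,n_background,n_artifact
#'   compound counts per class.
#' @param n_peculiar_sites how many industrial sites (taken from `I1` up)
#'   share the industrial-exclusive compounds.
#' @param baseline_log10_mean,baseline_log10_sd log10 peak-area baseline
#'   distribution across compounds.
#' @param replicate_cv coefficient of variation of the multiplicative
#'   (log-normal) replicate noise.
#' @param industrial_shift_sd standard deviation (log10 units) of the
#'   per-site intensity offsets applied to shifted common compounds at
#'   industrial sites.
#' @param blank_level_fraction blank area of background compounds as a
#'   fraction of their sample-level area.
#' @param trace_log10 log10 area of industrial-exclusive compounds where
#'   they are absent (trace level).
#' @param exclusive_boost_log10 log10 increment above baseline at the
#'   assigned site for industrial-exclusive compounds.
#' @param seed integer seed; the generator is fully reproducible.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_urban_sites = 6L,
                             n_industrial_sites = 4L,
                             n_replicates = 2L,
                             dilution_factor = 0.1,
                             n_common_compounds = 300L,
                             n_industrial_exclusive = 60L,
                             n_background = 40L,
                             n_artifact = 30L,
                             n_peculiar_sites = 3L,
                             baseline_log10_mean = 6.0,
                             baseline_log10_sd = 0.5,
                             replicate_cv = 0.15,
                             industrial_shift_sd = 2.0,
                             blank_level_fraction = 0.5,
                             trace_log10 = 2.0,
                             exclusive_boost_log10 = 1.0,
                             seed = 1L) {
  cfg <- list(n_urban_sites = as.integer(n_urban_sites),
              n_industrial_sites = as.integer(n_industrial_sites),
              n_replicates = as.integer(n_replicates),
              dilution_factor = dilution_factor,
              n_common_compounds = as.integer(n_common_compounds),
              n_industrial_exclusive = as.integer(n_industrial_exclusive),
              n_background = as.integer(n_background),
              n_artifact = as.integer(n_artifact),
              n_peculiar_sites = as.integer(n_peculiar_sites),
              baseline_log10_mean = baseline_log10_mean,
              baseline_log10_sd = baseline_log10_sd,
              replicate_cv = replicate_cv,
              industrial_shift_sd = industrial_shift_sd,
              blank_level_fraction = blank_level_fraction,
              trace_log10 = trace_log10,
              exclusive_boost_log10 = exclusive_boost_log10,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_urban_sites", "n_industrial_sites",
                         "n_replicates", "n_common_compounds",
                         "n_industrial_exclusive", "n_background",
                         "n_artifact")])
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (cfg$dilution_factor <= 0 || cfg$dilution_factor >= 1) {
    stop("dilution_factor must be in (0, 1)", call. = FALSE)
  }
  if (cfg$replicate_cv < 0) stop("replicate_cv must be >= 0", call. = FALSE)
  if (cfg$n_common_compounds < 2L) {
    stop("n_common_compounds must be >= 2 (clustering undefined otherwise)",
         call. = FALSE)
  }
  if (cfg$n_peculiar_sites > cfg$n_industrial_sites) {
    stop("n_peculiar_sites cannot exceed n_industrial_sites", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic feature table with known ground truth
#'
#' Draws a samples-by-compounds peak-area matrix plus a matching per-site
#' blank table under the design described in [synthetic_config()].  Areas
#' are log-normal: each compound has a log10 baseline, each measurement
#' multiplies the expected level by `exp(N(0, sdlog))` noise with the
#' configured coefficient of variation, and diluted replicates of all
#' dilution-responsive compounds scale by `dilution_factor`.
#'
#' @param config a [synthetic_config()].
#' @return list with elements
#'   * `table` — [feature_table()] of the study samples,
#'   * `blanks` — `feature_table` of the sequence blanks (two per site),
#'   * `truth` — ground truth: `compound_class` (named character vector
#'     over compound ids with levels `common`, `industrial_exclusive`,
#'     `background`, `artifact`), `shifted_common_ids`,
#'     `exclusive_site` (assigned site per exclusive compound) and
#'     `site_profiles` (latent expected log10 concentrated areas,
#'     sites x compounds).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)

  sites <- c(if (cfg$n_urban_sites > 0) paste0("U", seq_len(cfg$n_urban_sites)),
             if (cfg$n_industrial_sites > 0)
               paste0("I", seq_len(cfg$n_industrial_sites)))
  site_type <- c(rep("urban", cfg$n_urban_sites),
                 rep("industrial", cfg$n_industrial_sites))
  names(site_type) <- sites

  n_cmp <- cfg$n_common_compounds + cfg$n_industrial_exclusive +
    cfg$n_background + cfg$n_artifact
  compound_class <- rep(c("common", "industrial_exclusive", "background",
                          "artifact"),
                        c(cfg$n_common_compounds, cfg$n_industrial_exclusive,
                          cfg$n_background, cfg$n_artifact))
  prefix <- c(common = "CMN", industrial_exclusive = "IEX",
              background = "BKG", artifact = "ART")
  compound_id <- paste0(prefix[compound_class],
                        unlist(lapply(table(factor(compound_class,
                                                   levels = names(prefix))),
                                      function(n) sprintf("%04d", seq_len(n)))))
  names(compound_class) <- compound_id

  compounds <- data.frame(
    compound_id = compound_id,
    mz = round(stats::runif(n_cmp, 60, 990), 4),
    rt = round(stats::runif(n_cmp, 0.5, 26), 3),
    name = NA_character_,
    confidence_level = sample(1:5, n_cmp, replace = TRUE,
                              prob = c(0.01, 0.03, 0.03, 0.85, 0.08)),
    stringsAsFactors = FALSE)

  # latent expected log10 concentrated area, sites x compounds
  baseline <- stats::rnorm(n_cmp, cfg$baseline_log10_mean,
                           cfg$baseline_log10_sd)
  profile <- matrix(rep(baseline, each = length(sites)),
                    nrow = length(sites),
                    dimnames = list(sites, compound_id))

  is_common <- compound_class == "common"
  shifted <- rep(FALSE, n_cmp)
  shifted[is_common] <- seq_len(sum(is_common)) %in%
    sample(sum(is_common), floor(sum(is_common) / 2))
  ind_sites <- sites[site_type == "industrial"]
  for (s in ind_sites) {
    k <- sum(shifted)
    if (k > 0 && cfg$industrial_shift_sd > 0) {
      profile[s, shifted] <- profile[s, shifted] +
        stats::rnorm(k, 0, cfg$industrial_shift_sd)
    }
  }

  is_excl <- compound_class == "industrial_exclusive"
  peculiar_sites <- ind_sites[seq_len(min(cfg$n_peculiar_sites,
                                          length(ind_sites)))]
  exclusive_site <- character(0)
  if (any(is_excl)) {
    if (length(peculiar_sites) == 0L) {
      stop("industrial-exclusive compounds require >= 1 industrial site",
           call. = FALSE)
    }
    exclusive_site <- peculiar_sites[
      ((seq_len(sum(is_excl)) - 1L) %% length(peculiar_sites)) + 1L]
    names(exclusive_site) <- compound_id[is_excl]
    profile[, is_excl] <- cfg$trace_log10
    for (j in which(is_excl)) {
      profile[exclusive_site[[compound_id[j]]], j] <-
        baseline[j] + cfg$exclusive_boost_log10
    }
  }

  sdlog <- if (cfg$replicate_cv > 0) sqrt(log(1 + cfg$replicate_cv^2)) else 0
  noise <- function(n) if (sdlog > 0) exp(stats::rnorm(n, 0, sdlog)) else rep(1, n)

  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         dilution = c("concentrated", "diluted"),
                         site = sites, stringsAsFactors = FALSE)
  samples <- samples[, c("site", "dilution", "replicate")]
  samples$site_type <- site_type[samples$site]
  samples$sample_id <- sample_name_build(samples$site, samples$dilution,
                                         samples$replicate)
  samples <- samples[, c("sample_id", "site", "site_type", "dilution",
                         "replicate")]

  is_art <- compound_class == "artifact"
  areas <- matrix(0, nrow(samples), n_cmp,
                  dimnames = list(samples$sample_id, compound_id))
  for (s in sites) {
    conc_rows <- which(samples$site == s & samples$dilution == "concentrated")
    dil_rows <- which(samples$site == s & samples$dilution == "diluted")
    level <- 10^profile[s, ]
    for (r in conc_rows) areas[r, ] <- level * noise(n_cmp)
    conc_mean <- colMeans(areas[conc_rows, , drop = FALSE])
    for (r in dil_rows) {
      areas[r, ] <- level * cfg$dilution_factor * noise(n_cmp)
      # artifacts ignore dilution: diluted reps sit just above the
      # concentrated site mean, so the per-site dilution dummy is 0
      if (any(is_art)) {
        areas[r, is_art] <- conc_mean[is_art] *
          (1.005 + 0.1 * abs(stats::rnorm(sum(is_art))))
      }
    }
  }

  is_bkg <- compound_class == "background"
  blanks_meta <- expand.grid(replicate = seq_len(2L), site = sites,
                             stringsAsFactors = FALSE)
  blanks_meta <- data.frame(
    sample_id = sample_name_build(blanks_meta$site, "blank",
                                  blanks_meta$replicate),
    site = blanks_meta$site,
    site_type = "blank",
    dilution = "concentrated",
    replicate = blanks_meta$replicate,
    stringsAsFactors = FALSE)
  blank_areas <- matrix(0, nrow(blanks_meta), n_cmp,
                        dimnames = list(blanks_meta$sample_id, compound_id))
  if (any(is_bkg)) {
    for (i in seq_len(nrow(blanks_meta))) {
      lev <- 10^profile[blanks_meta$site[i], is_bkg] *
        cfg$blank_level_fraction
      blank_areas[i, is_bkg] <- lev * noise(sum(is_bkg))
    }
  }

  truth <- list(compound_class = compound_class,
                shifted_common_ids = compound_id[shifted],
                exclusive_site = exclusive_site,
                site_profiles = profile)
  list(table = feature_table(areas, samples, compounds),
       blanks = feature_table(blank_areas, blanks_meta, compounds),
       truth = truth)
}

#' Expected filter outcome implied by the generator's ground truth
#'
#' Translates a `truth` object from [generate_synthetic()] into the
#' compound sets the screening and common-selection stages are expected to
#' produce under the default effect sizes: background and artifact
#' compounds are removed by screening, industrial-exclusive compounds
#' survive screening but are excluded from the unknown-common set, and
#' common compounds survive everything.
#'
#' @param truth the `truth` element of [generate_synthetic()] output.
#' @return list with `screened` (ids expected to survive the three
#'   screening filters) and `unknown_common` (ids expected in the
#'   unknown-common set).
#' @export
truth_filter_outcome <- function(truth) {
  cls <- truth$compound_class
  list(screened = names(cls)[cls %in% c("common", "industrial_exclusive")],
       unknown_common = names(cls)[cls == "common"])
}
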