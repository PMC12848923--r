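#' Generator settings for the synthetic isotope datasets
#'
#' Bundles every tunable of the synthetic-data module. Defaults reproduce
#' the statistical structure of the study system: 26 precipitation events
#' whose regression of dD on d18O has expected R^2 = 0.963, nine sampled
#' soil depth intervals with three replicates each, and xylem water built
#' as layer mixtures with small residual scatter.
#'
#' The default precipitation noise SD is derived in closed form: with
#' d18O ~ U(-15, 5) (variance 400/12) and slope 7.8, solving
#' R^2 = s^2 var(x) / (s^2 var(x) + sigma^2) for sigma at R^2 = 0.963
#' gives sigma ~= 8.83 permil.
#'
#' @param seed Integer seed; all generators derive their RNG state from it.
#' @param n_precip_events Number of precipitation samples (default 26).
#' @param precip_noise_sd Gaussian dD scatter about the meteoric line,
#'   permil; default derived from the target R^2 (see Details).
#' @param soil_layer_sd_dD,soil_layer_sd_d18O Within-layer replicate SDs, permil.
#' @param xylem_residual_sd_dD,xylem_residual_sd_d18O Xylem residual SDs, permil.
#' @param n_replicates Replicates per soil layer / xylem samples per species.
#' @param evap_line_slope,evap_line_intercept Soil evaporation line
#'   dD = slope * d18O + intercept used to derive soil/xylem d18O from dD.
#' @return List of class `generator_settings`.
#' @export
generator_settings <- function(seed = 1L,
                               n_precip_events = 26L,
                               precip_noise_sd = NULL,
                               soil_layer_sd_dD = 2,
                               soil_layer_sd_d18O = 0.4,
                               xylem_residual_sd_dD = 1.5,
                               xylem_residual_sd_d18O = 0.3,
                               n_replicates = 3L,
                               evap_line_slope = 5.5,
                               evap_line_intercept = -20) {
  if (is.null(precip_noise_sd)) {
    precip_noise_sd <- derive_precip_noise_sd()
  }
  s <- list(seed = as.integer(seed),
            n_precip_events = as.integer(n_precip_events),
            precip_noise_sd = precip_noise_sd,
            soil_layer_sd_dD = soil_layer_sd_dD,
            soil_layer_sd_d18O = soil_layer_sd_d18O,
            xylem_residual_sd_dD = xylem_residual_sd_dD,
            xylem_residual_sd_d18O = xylem_residual_sd_d18O,
            n_replicates = as.integer(n_replicates),
            evap_line_slope = evap_line_slope,
            evap_line_intercept = evap_line_intercept)
  sds <- c(s$precip_noise_sd, s$soil_layer_sd_dD, s$soil_layer_sd_d18O,
           s$xylem_residual_sd_dD, s$xylem_residual_sd_d18O)
  if (any(sds < 0)) stop("invalid settings: SDs must be >= 0")
  if (s$n_precip_events < 3) stop("invalid settings: n_precip_events must be >= 3")
  if (s$n_replicates < 1) stop("invalid settings: n_replicates must be >= 1")
  class(s) <- "generator_settings"
  s
}

#' Closed-form precipitation noise SD for a target regression R^2
#'
#' Inverts R^2 = s^2 var(x) / (s^2 var(x) + sigma^2) for sigma, with
#' d18O uniform on \[-15, 5\] permil (variance 400/12).
#'
#' @param slope Meteoric line slope (default 7.8).
#' @param r_squared Target coefficient of determination (default 0.963).
#' @param x_var Variance of d18O (default 400/12, the U(-15,5) variance).
#' @return Noise SD in permil (~8.83 at the defaults).
#' @export
derive_precip_noise_sd <- function(slope = 7.8, r_squared = 0.963,
                                   x_var = 400 / 12) {
  sqrt(slope^2 * x_var * (1 / r_squared - 1))
}

# Meteoric line of the study region: dD = 7.8 d18O + 12.2
lmwl_slope <- 7.8
lmwl_intercept <- 12.2

#' Default chronosequence site configuration
#'
#' One row per site: the eight dated revegetation stands (planted 1953,
#' 1970, 1995, 2000, 2005, 2009, 2015, 2020; ages relative to the 2022
#' sampling year) plus the natural-vegetation control CK (assigned the
#' maximum age + 1 for ordering only; excluded from age trends).
#'
#' True shrub deep-water (40-100 cm) means are anchored at the reported
#' site values for the two oldest stands (55.6 and 57.6 %) and chosen for
#' the remaining stands so that their Pearson correlation with restoration
#' age over the eight dated sites is 0.862. Herb shallow-water (0-20 cm)
#' means are derived from the per-site herb-to-shrub ratios of the study's
#' stability table (R values 0.81 ... 1.61, CK 1.4), so the generated
#' chronosequence reproduces both the age trend and the ratio series.
#' Semi-shrubs are present only in a subset of sites (1995, 2009, 2015,
#' 2020 and CK), mirroring their successional decline; their mid-layer
#' (20-40 cm) means correlate with age at r ~= 0.89 among those sites.
#'
#' Soil-profile endmembers follow the observed pattern: old stands have
#' smooth, flatter profiles; younger stands a stronger surface-to-depth
#' contrast; CK roughly 30 permil of total contrast.
#'
#' @return Data frame of class `site_config` with columns `site_id`,
#'   `planting_year`, `restoration_age`, `shrub_deep_mean`,
#'   `herb_shallow_mean`, `semi_shrub_present`, `semi_shrub_mid_mean`,
#'   `target_ratio`, `soil_surface_delta`, `soil_deep_delta`,
#'   `profile_scale`.
#' @export
default_chronosequence <- function() {
  site_id <- c("1953a", "1970a", "1995a", "2000a", "2005a",
               "2009a", "2015a", "2020a", "CK")
  year <- c(1953, 1970, 1995, 2000, 2005, 2009, 2015, 2020, NA)
  age <- ifelse(is.na(year), max(2022 - year, na.rm = TRUE) + 1, 2022 - year)
  shrub_deep <- c(55.60, 57.60, 52.23, 45.27, 50.60, 44.13, 39.77, 43.23, 52.30)
  ratio <- c(0.81, 0.86, 1.01, 1.03, 1.05, 1.08, 1.45, 1.61, 1.40)
  herb_shallow <- ratio * shrub_deep
  semi_present <- site_id %in% c("1995a", "2009a", "2015a", "2020a", "CK")
  semi_mid <- ifelse(semi_present,
                     c(NA, NA, 23.00, NA, NA, 18.84, 20.16, 17.50, 19.80),
                     NA_real_)
  surface <- c(-85, -85, -72, -70, -70, -70, -68, -68, -75)
  deep <- c(-105, -105, -110, -110, -110, -110, -110, -110, -110)
  scale <- c(60, 60, 35, 35, 35, 35, 30, 30, 45)
  cfg <- data.frame(site_id = site_id, planting_year = year,
                    restoration_age = age,
                    shrub_deep_mean = shrub_deep,
                    herb_shallow_mean = herb_shallow,
                    semi_shrub_present = semi_present,
                    semi_shrub_mid_mean = semi_mid,
                    target_ratio = ratio,
                    soil_surface_delta = surface,
                    soil_deep_delta = deep,
                    profile_scale = scale,
                    stringsAsFactors = FALSE)
  validate_site_config(cfg)
  class(cfg) <- c("site_config", "data.frame")
  cfg
}

validate_site_config <- function(cfg) {
  stopifnot(all(cfg$shrub_deep_mean > 0 & cfg$shrub_deep_mean < 100),
            all(cfg$herb_shallow_mean > 0 & cfg$herb_shallow_mean < 100),
            all(cfg$soil_surface_delta > cfg$soil_deep_delta),
            all(cfg$profile_scale > 0))
  invisible(cfg)
}

# The nine sampled depth intervals (cm); mixing sources use the 8 shallowest.
sampled_intervals <- function() {
  data.frame(depth_top_cm = c(0, 5, 10, 20, 40, 60, 80, 100, 120),
             depth_bottom_cm = c(5, 10, 20, 40, 60, 80, 100, 120, 150))
}

# Species per functional group
group_species <- function(group) {
  switch(group,
    shrub = c("Caragana korshinskii", "Calligonum mongolicum", "Hedysarum scoparium"),
    `semi-shrub` = "Artemisia ordosica",
    herb = c("Bassia dasyphylla", "Corispermum declinatum"),
    stop(sprintf("unknown group: '%s'", group)))
}

# Seed fan-out: each stage derives its RNG state from the master seed plus
# a fixed offset so stages can be rerun in isolation. Site-specific stages
# add 10 * site index.
stage_seed <- function(seed, stage, site_index = 0L, extra = 0L) {
  base <- c(precipitation = 100L, soil = 2000L, xylem = 30000L)[[stage]]
  as.integer(seed + base + 10L * site_index + extra)
}

#' Generate synthetic precipitation isotope samples
#'
#' Draws d18O uniformly on \[-15, 5\] permil and dD from the local meteoric
#' line dD = 7.8 d18O + 12.2 plus Gaussian noise, reproducing the reported
#' regression (R^2 = 0.963 at n = 26 in expectation).
#'
#' @param settings A [generator_settings()] object.
#' @return Data frame in the standard sample schema.
#' @export
generate_precipitation <- function(settings = generator_settings()) {
  if (settings$n_precip_events <= 0) stop("invalid settings: n_precip_events")
  set.seed(stage_seed(settings$seed, "precipitation"))
  n <- settings$n_precip_events
  d18O <- stats::runif(n, -15, 5)
  d2H <- lmwl_slope * d18O + lmwl_intercept +
    stats::rnorm(n, 0, settings$precip_noise_sd)
  # enforce the documented delta sanity envelope by redrawing outliers
  # (enriched summer events can otherwise stray just past +50 permil dD)
  for (i in 1:100) {
    bad <- d2H > 50 | d2H < -200
    if (!any(bad)) break
    d18O[bad] <- stats::runif(sum(bad), -15, 5)
    d2H[bad] <- lmwl_slope * d18O[bad] + lmwl_intercept +
      stats::rnorm(sum(bad), 0, settings$precip_noise_sd)
  }
  new_samples(site_id = "region", sample_type = "precipitation",
              d2H = d2H, d18O = d18O,
              replicate = seq_along(d18O))
}

#' Generate a synthetic soil isotope profile for one site
#'
#' Layer-mean dD follows an exponential depth profile
#' dD(d) = deep + (surface - deep) * exp(-d / scale) evaluated at the
#' interval midpoint, emulating evaporative enrichment at the surface and
#' depletion at depth. Replicates add Gaussian within-layer noise; d18O is
#' derived from dD through the soil evaporation line plus noise.
#'
#' @param site One row of a site configuration (data frame or list).
#' @param settings A [generator_settings()] object.
#' @return Data frame in the standard sample schema (9 intervals x
#'   `n_replicates` rows).
#' @export
generate_soil_profile <- function(site, settings = generator_settings()) {
  site <- as.list(site)
  iv <- sampled_intervals()
  mid <- (iv$depth_top_cm + iv$depth_bottom_cm) / 2
  mu_dD <- site$soil_deep_delta +
    (site$soil_surface_delta - site$soil_deep_delta) * exp(-mid / site$profile_scale)
  set.seed(stage_seed(settings$seed, "soil", site_index(site)))
  n <- settings$n_replicates
  rows <- lapply(seq_len(nrow(iv)), function(i) {
    d2H <- mu_dD[i] + stats::rnorm(n, 0, settings$soil_layer_sd_dD)
    d18O <- (d2H - settings$evap_line_intercept) / settings$evap_line_slope +
      stats::rnorm(n, 0, settings$soil_layer_sd_d18O)
    new_samples(site_id = site$site_id, sample_type = "soil",
                depth_top_cm = iv$depth_top_cm[i],
                depth_bottom_cm = iv$depth_bottom_cm[i],
                d2H = d2H, d18O = d18O, replicate = seq_len(n))
  })
  do.call(rbind, rows)
}

#' True source-proportion vector for a functional group
#'
#' Builds the proportion vector over the source layers: the group's main
#' depth block (shrub: 40-100 cm; semi-shrub: 20-40 cm; herb: 0-20 cm)
#' receives the target mass, split across its member layers in proportion
#' to layer thickness; the remaining mass decays geometrically (ratio 0.5
#' per layer step) away from the block and is renormalized.
#'
#' @param sources Source summary table ([summarize_sources()]).
#' @param group One of "shrub", "semi-shrub", "herb".
#' @param target Main-block mass as a fraction in (0, 1).
#' @param groups Depth-group mapping ([default_depth_groups()]).
#' @return Named numeric simplex vector over `sources$layer`.
#' @export
true_proportions <- function(sources, group, target,
                             groups = default_depth_groups()) {
  main_group <- switch(group, shrub = "40-100 cm", `semi-shrub` = "20-40 cm",
                       herb = "0-20 cm",
                       stop(sprintf("unknown group: '%s'", group)))
  if (!is.finite(target) || target <= 0 || target >= 1) {
    stop("target must be in (0, 1)")
  }
  lab <- sources$layer
  block <- which(groups[lab] == main_group)
  if (length(block) == 0) stop("no source layers in the group's main block")
  p <- numeric(length(lab))
  thick <- sources$depth_bottom_cm - sources$depth_top_cm
  p[block] <- target * thick[block] / sum(thick[block])
  outside <- setdiff(seq_along(lab), block)
  if (length(outside) > 0) {
    dist <- vapply(outside, function(i) min(abs(i - block)), numeric(1))
    w <- 0.5^dist
    p[outside] <- (1 - target) * w / sum(w)
  }
  stats::setNames(p / sum(p), lab)
}

#' Generate synthetic xylem isotope samples for one group at one site
#'
#' Expected xylem isotope values are the proportion-weighted source means
#' (zero discrimination at root uptake); each sample adds a Gaussian
#' residual. One set of `n_replicates` samples is generated per species of
#' the group. The injected truth vector is returned for recovery tests.
#'
#' @param site One row of a site configuration.
#' @param group Functional group: "shrub", "semi-shrub" or "herb".
#' @param soil_sources Source summary table ([summarize_sources()]).
#' @param settings A [generator_settings()] object.
#' @param target Optional main-block mass fraction override; defaults to
#'   the site's configured mean for the group (percent / 100).
#' @param groups Depth-group mapping used to locate the main block.
#' @return List with `samples` (standard schema data frame) and
#'   `true_proportions` (named simplex vector).
#' @export
generate_xylem <- function(site, group, soil_sources,
                           settings = generator_settings(), target = NULL,
                           groups = default_depth_groups()) {
  site <- as.list(site)
  if (is.null(target)) {
    target <- switch(group,
      shrub = site$shrub_deep_mean,
      `semi-shrub` = site$semi_shrub_mid_mean,
      herb = site$herb_shallow_mean,
      stop(sprintf("unknown group: '%s'", group))) / 100
    if (is.null(target) || !is.finite(target)) {
      stop(sprintf("group '%s' has no configured target at site %s",
                   group, site$site_id))
    }
  }
  p <- true_proportions(soil_sources, group, target, groups)
  mu_H <- sum(p * soil_sources$mean_d2H)
  mu_O <- sum(p * soil_sources$mean_d18O)
  species <- group_species(group)
  gi <- match(group, c("shrub", "semi-shrub", "herb"))
  set.seed(stage_seed(settings$seed, "xylem", site_index(site), gi))
  n <- settings$n_replicates
  rows <- lapply(species, function(sp) {
    new_samples(site_id = site$site_id, sample_type = "xylem",
                group = group, species = sp,
                d2H = mu_H + stats::rnorm(n, 0, settings$xylem_residual_sd_dD),
                d18O = mu_O + stats::rnorm(n, 0, settings$xylem_residual_sd_d18O),
                replicate = seq_len(n))
  })
  list(samples = do.call(rbind, rows), true_proportions = p)
}

#' Generate the full synthetic chronosequence dataset
#'
#' Produces precipitation, soil profiles and xylem samples for all nine
#' sites of the default chronosequence (or a supplied configuration),
#' together with a truth table of every injected proportion. Deterministic
#' given the settings seed.
#'
#' @param settings A [generator_settings()] object.
#' @param sites Site configuration ([default_chronosequence()]).
#' @return List with `sites`, `precipitation`, `soil`, `xylem` (data
#'   frames) and `truth` (per site x group: the injected main-block share
#'   in percent plus the full layer-wise truth vectors as columns `p_<layer>`).
#' @export
generate_chronosequence <- function(settings = generator_settings(),
                                    sites = default_chronosequence()) {
  precip <- generate_precipitation(settings)
  soil_all <- list(); xylem_all <- list(); truth_rows <- list()
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    soil <- generate_soil_profile(site, settings)
    soil_all[[i]] <- soil
    sources <- suppressWarnings(summarize_sources(soil))
    groups <- c("shrub", "herb", if (site$semi_shrub_present) "semi-shrub")
    for (g in groups) {
      xy <- generate_xylem(site, g, sources, settings)
      xylem_all[[length(xylem_all) + 1]] <- xy$samples
      main <- switch(g, shrub = "40-100 cm", `semi-shrub` = "20-40 cm",
                     herb = "0-20 cm")
      grp_map <- default_depth_groups()
      tr <- data.frame(site_id = site$site_id,
                       restoration_age = site$restoration_age,
                       is_control = is.na(site$planting_year),
                       group = g, main_group = main,
                       true_main_pct = 100 * sum(xy$true_proportions[grp_map[names(xy$true_proportions)] == main]),
                       stringsAsFactors = FALSE)
      pr <- as.data.frame(as.list(xy$true_proportions))
      names(pr) <- paste0("p_", names(xy$true_proportions))
      truth_rows[[length(truth_rows) + 1]] <- cbind(tr, pr)
    }
  }
  list(sites = sites,
       precipitation = precip,
       soil = do.call(rbind, soil_all),
       xylem = do.call(rbind, xylem_all),
       truth = do.call(rbind, truth_rows))
}

# --- internal helpers -------------------------------------------------------

site_index <- function(site) {
  ids <- default_chronosequence()$site_id
  i <- match(site$site_id, ids)
  if (is.na(i)) i <- 1L + (sum(utf8ToInt(as.character(site$site_id))) %% 88L)
  i
}

new_samples <- function(site_id, sample_type, d2H, d18O,
                        depth_top_cm = NA_real_, depth_bottom_cm = NA_real_,
                        group = NA_character_, species = NA_character_,
                        replicate = NA_integer_, date = NA_character_) {
  data.frame(site_id = site_id, sample_type = sample_type,
             depth_top_cm = depth_top_cm, depth_bottom_cm = depth_bottom_cm,
             group = group, species = species, replicate = replicate,
             d2H_permil = d2H, d18O_permil = d18O, date = date,
             stringsAsFactors = FALSE)
}

#' Write a generated dataset to CSV files
#'
#' @param data List returned by [generate_chronosequence()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(precipitation = file.path(dir, "precipitation.csv"),
             soil = file.path(dir, "soil.csv"),
             xylem = file.path(dir, "xylem.csv"),
             truth = file.path(dir, "truth.csv"),
             sites = file.path(dir, "sites.csv"))
  utils::write.csv(data$precipitation, paths["precipitation"], row.names = FALSE)
  utils::write.csv(data$soil, paths["soil"], row.names = FALSE)
  utils::write.csv(data$xylem, paths["xylem"], row.names = FALSE)
  utils::write.csv(data$truth, paths["truth"], row.names = FALSE)
  utils::write.csv(data$sites, paths["sites"], row.names = FALSE)
  invisible(paths)
}
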