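#' Pipeline configuration
#'
#' Bundles every stage's settings for an end-to-end run: data source
#' (synthetic generation or CSV paths), layer scheme and depth groups,
#' mixing MCMC settings, stability thresholds and dynamics parameters.
#' A single master seed fans out to the stage seeds through fixed offsets
#' so any stage can be rerun in isolation.
#'
#' @param mode "synthetic" or "csv".
#' @param paths Named list of CSV paths (`soil`, `xylem`, `precipitation`)
#'   required in csv mode.
#' @param generator A [generator_settings()] object (synthetic mode).
#' @param sites Site configuration; `site_ids` optionally restricts the
#'   run to a subset of sites.
#' @param site_ids Optional character vector of sites to process.
#' @param layer_scheme See [default_layer_scheme()].
#' @param depth_groups See [default_depth_groups()].
#' @param mixing A [mixing_config()] object.
#' @param thresholds Stability-class boundaries, see [classify_stability()].
#' @param dynamics A [dyn_params()] object.
#' @param seed Master seed; overrides the generator and mixing seeds.
#' @param outdir Optional output directory for CSV reports.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "csv"), paths = NULL,
                            generator = generator_settings(),
                            sites = default_chronosequence(),
                            site_ids = NULL,
                            layer_scheme = default_layer_scheme(),
                            depth_groups = default_depth_groups(),
                            mixing = mixing_config(),
                            thresholds = c(0.9, 1.4),
                            dynamics = dyn_params(),
                            seed = 1L, outdir = NULL) {
  mode <- match.arg(mode)
  if (mode == "csv") {
    needed <- c("soil", "xylem", "precipitation")
    if (is.null(paths) || !all(needed %in% names(paths))) {
      stop("csv mode requires paths$soil, paths$xylem, paths$precipitation")
    }
    missing <- unlist(paths[needed])[!file.exists(unlist(paths[needed]))]
    if (length(missing) > 0) {
      stop("input file not found: ", paste(missing, collapse = ", "))
    }
  }
  generator$seed <- as.integer(seed)
  mixing$seed <- as.integer(seed + 500000L)
  structure(list(mode = mode, paths = paths, generator = generator,
                 sites = sites, site_ids = site_ids,
                 layer_scheme = layer_scheme, depth_groups = depth_groups,
                 mixing = mixing, thresholds = thresholds,
                 dynamics = dynamics, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Validate an input sample table
#'
#' Schema and plausibility checks on a sample table: required columns,
#' known sample types, soil depth ordering, and the delta sanity envelope
#' \[-200, 50\] permil. Violations of structure are errors; out-of-envelope
#' deltas are warnings.
#'
#' @param samples Data frame in the standard sample schema.
#' @return Data frame with columns `severity` ("error"/"warning"),
#'   `check`, `message`, `n`. Zero rows means a clean table.
#' @export
validate_inputs <- function(samples) {
  issues <- list()
  add <- function(severity, check, message, n) {
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, check = check, message = message, n = n,
      stringsAsFactors = FALSE)
  }
  required <- c("site_id", "sample_type", "d2H_permil", "d18O_permil")
  miss <- setdiff(required, names(samples))
  if (length(miss) > 0) {
    add("error", "columns", paste("missing column(s):",
                                  paste(miss, collapse = ", ")), length(miss))
    return(do.call(rbind, issues))
  }
  bad_type <- !samples$sample_type %in% c("precipitation", "soil", "xylem")
  if (any(bad_type)) {
    add("error", "sample_type", "unknown sample_type value(s)", sum(bad_type))
  }
  soil <- samples[samples$sample_type == "soil", , drop = FALSE]
  if (nrow(soil) > 0) {
    if (!all(c("depth_top_cm", "depth_bottom_cm") %in% names(samples))) {
      add("error", "depth", "soil rows lack depth columns", nrow(soil))
    } else {
      bad_depth <- !is.finite(soil$depth_top_cm) | !is.finite(soil$depth_bottom_cm) |
        soil$depth_top_cm >= soil$depth_bottom_cm
      if (any(bad_depth)) {
        add("error", "depth", "soil rows with depth_top_cm >= depth_bottom_cm",
            sum(bad_depth))
      }
    }
  }
  out_range <- !is.finite(samples$d2H_permil) | !is.finite(samples$d18O_permil) |
    samples$d2H_permil < -200 | samples$d2H_permil > 50 |
    samples$d18O_permil < -200 | samples$d18O_permil > 50
  if (any(out_range)) {
    add("warning", "delta_range",
        "delta value(s) outside the [-200, 50] permil envelope", sum(out_range))
  }
  if (length(issues) == 0) {
    return(data.frame(severity = character(0), check = character(0),
                      message = character(0), n = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Run the full analysis pipeline
#'
#' Orchestrates data generation (or ingestion), meteoric line fitting,
#' per-site per-species mixing, the contribution and stability tables,
#' the age trend, and the dynamics regime report.
#'
#' @param config A [pipeline_config()] object.
#' @return List (report bundle): `lmwl` (meteoric line fit),
#'   `contributions` (per site x group x species depth-group posterior
#'   summaries), `group_table` (per-group main-layer summary in the shape
#'   of the study's contribution table), `site_table` (per-site C_h, C_s,
#'   R_h/s, class), `age_trend`, `dynamics_table`, `bifurcation`,
#'   `manifest`. Tables are also written as CSV when `config$outdir` is
#'   set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  data <- switch(config$mode,
    synthetic = generate_chronosequence(config$generator, config$sites),
    csv = {
      read1 <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
      list(sites = config$sites,
           precipitation = read1(config$paths$precipitation),
           soil = read1(config$paths$soil),
           xylem = read1(config$paths$xylem),
           truth = NULL)
    })
  issues <- validate_inputs(rbind(data$soil, data$xylem, data$precipitation))
  if (any(issues$severity == "error")) {
    stop("input validation failed: ",
         paste(issues$message[issues$severity == "error"], collapse = "; "))
  }

  lmwl <- fit_meteoric_line(data$precipitation)

  sites <- config$sites
  if (!is.null(config$site_ids)) {
    sites <- sites[sites$site_id %in% config$site_ids, , drop = FALSE]
  }
  contrib_rows <- list()
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    soil_i <- data$soil[data$soil$site_id == sid, , drop = FALSE]
    if (nrow(soil_i) == 0) stop(sprintf("stage mixing: no soil samples for site %s", sid))
    sources <- suppressWarnings(summarize_sources(soil_i, config$layer_scheme))
    xy_i <- data$xylem[data$xylem$site_id == sid, , drop = FALSE]
    for (sp in unique(xy_i$species)) {
      mix <- xy_i[xy_i$species == sp, , drop = FALSE]
      cfg <- config$mixing
      cfg$seed <- config$mixing$seed + 97L * i + match(sp, unique(xy_i$species))
      post <- run_mixing(mix, sources, cfg)
      agg <- aggregate_layers(post, config$depth_groups)
      sm <- summarize_posterior(agg)
      sm$site_id <- sid
      sm$restoration_age <- sites$restoration_age[i]
      sm$is_control <- is.na(sites$planting_year[i])
      sm$group <- mix$group[1]
      sm$species <- sp
      sm$max_rhat <- max(agg$rhat)
      contrib_rows[[length(contrib_rows) + 1]] <- sm
    }
  }
  contributions <- do.call(rbind, contrib_rows)

  main_of <- c(shrub = "40-100 cm", `semi-shrub` = "20-40 cm", herb = "0-20 cm")
  group_table <- do.call(rbind, lapply(names(main_of), function(g) {
    rows <- contributions[contributions$group == g &
                          contributions$source == main_of[[g]], , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    data.frame(group = g, main_layers = main_of[[g]],
               mean_pct = mean(rows$mean_pct),
               sd_pct = stats::sd(rows$mean_pct),
               ci_low_pct = mean(rows$ci_low_pct),
               ci_high_pct = mean(rows$ci_high_pct),
               n_estimates = nrow(rows), stringsAsFactors = FALSE)
  }))

  species_table <- do.call(rbind, lapply(
    split(contributions, list(contributions$site_id, contributions$species),
          drop = TRUE),
    function(sc) data.frame(
      site_id = sc$site_id[1], restoration_age = sc$restoration_age[1],
      is_control = sc$is_control[1], group = sc$group[1],
      species = sc$species[1],
      shallow_pct = sc$mean_pct[sc$source == "0-20 cm"],
      deep_pct = sc$mean_pct[sc$source == "40-100 cm"],
      stringsAsFactors = FALSE)))
  site_table <- site_contribution_table(species_table, config$thresholds)

  shrub_deep <- do.call(rbind, lapply(
    split(contributions[contributions$group == "shrub" &
                        contributions$source == "40-100 cm", , drop = FALSE],
          contributions$site_id[contributions$group == "shrub" &
                                contributions$source == "40-100 cm"]),
    function(sc) data.frame(site_id = sc$site_id[1],
                            restoration_age = sc$restoration_age[1],
                            is_control = sc$is_control[1],
                            deep_pct = mean(sc$mean_pct),
                            stringsAsFactors = FALSE)))
  dated <- shrub_deep[!shrub_deep$is_control, , drop = FALSE]
  trend <- if (nrow(dated) >= 3) {
    age_trend(dated$restoration_age, dated$deep_pct)
  } else {
    list(r = NA_real_, p_value = NA_real_, n_sites = nrow(dated))
  }

  dyn_rows <- lapply(seq_len(nrow(site_table)), function(i) {
    st <- site_stability(site_table$R_hs[i], config$dynamics)
    data.frame(site_id = site_table$site_id[i], R_hs = site_table$R_hs[i],
               max_re = st$max_re, regime = st$regime,
               stringsAsFactors = FALSE)
  })
  dynamics_table <- do.call(rbind, dyn_rows)
  bifurcation <- bifurcation_scan(config$dynamics,
                                  R_grid = seq(0.5, 2, by = 0.005))

  manifest <- list(seed = config$seed, mode = config$mode,
                   generator = unclass(config$generator),
                   mixing = unclass(config$mixing),
                   thresholds = config$thresholds,
                   dynamics = unclass(config$dynamics),
                   package_version = as.character(utils::packageVersion("hydroniche")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))

  bundle <- list(lmwl = lmwl, contributions = contributions,
                 group_table = group_table, site_table = site_table,
                 age_trend = trend, dynamics_table = dynamics_table,
                 bifurcation = bifurcation, manifest = manifest,
                 truth = data$truth)
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(data.frame(slope = bundle$lmwl$slope, intercept = bundle$lmwl$intercept,
               r_squared = bundle$lmwl$r_squared, n = bundle$lmwl$n,
               residual_sd = bundle$lmwl$residual_sd), "lmwl.csv")
  w(bundle$contributions, "contributions.csv")
  w(bundle$group_table, "group_table.csv")
  w(bundle$site_table, "site_table.csv")
  w(data.frame(r = bundle$age_trend$r, p_value = bundle$age_trend$p_value,
               n_sites = bundle$age_trend$n_sites), "age_trend.csv")
  w(bundle$dynamics_table, "dynamics_table.csv")
  w(bundle$bifurcation, "bifurcation_scan.csv")
  writeLines(paste(names(unlist(bundle$manifest)), unlist(bundle$manifest),
                   sep = ": "), file.path(dir, "manifest.txt"))
  invisible(dir)
}
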