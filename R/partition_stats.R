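#' Mean functional-group water contribution
#'
#' Plot-scale mean of per-species contributions: C_h is the mean
#' herbaceous shallow-water (0-20 cm) contribution over the n herb species
#' of a plot, C_s the mean shrub deep-water (40-100 cm) contribution over
#' its m shrub species.
#'
#' @param per_species_props Numeric vector of per-species contributions
#'   in percent, each in (0, 100].
#' @param role Label used in error messages ("herb" or "shrub").
#' @return Arithmetic mean, percent.
#' @export
mean_contribution <- function(per_species_props, role = "group") {
  if (length(per_species_props) == 0) {
    stop(sprintf("missing group: no %s species present in this plot", role))
  }
  if (any(!is.finite(per_species_props)) ||
      any(per_species_props <= 0 | per_species_props > 100)) {
    stop("contributions must be in (0, 100]")
  }
  mean(per_species_props)
}

#' Herb-to-shrub water-use ratio
#'
#' R_h/s = C_h / C_s: the plot's mean herbaceous shallow-water
#' contribution divided by its mean shrub deep-water contribution. The
#' study system's stability statistic: high values indicate reliance on
#' shallow, precipitation-driven water and competitive pressure on shrubs.
#'
#' @param C_h Mean herb 0-20 cm contribution, percent.
#' @param C_s Mean shrub 40-100 cm contribution, percent; must be > 0.
#' @return Unitless ratio.
#' @export
herb_shrub_ratio <- function(C_h, C_s) {
  if (any(!is.finite(C_s)) || any(C_s <= 0)) {
    stop("undefined ratio: C_s must be > 0")
  }
  C_h / C_s
}

#' Classify ecosystem stability from the herb-to-shrub ratio
#'
#' Thresholds: stable when R < 0.9; semi-stable when 0.9 <= R <= 1.4;
#' unstable when R > 1.4. The closed interval at both boundaries follows
#' the eigenvalue analysis in which R = 1.4 is the critical (bifurcation)
#' value, not yet unstable.
#'
#' @param R_hs Herb-to-shrub ratio(s), > 0.
#' @param thresholds Length-2 numeric: lower and upper class boundaries.
#' @return Character vector: "stable", "semi-stable" or "unstable".
#' @export
classify_stability <- function(R_hs, thresholds = c(0.9, 1.4)) {
  if (any(!is.finite(R_hs)) || any(R_hs <= 0)) {
    stop("domain error: R_hs must be > 0")
  }
  ifelse(R_hs < thresholds[1], "stable",
         ifelse(R_hs <= thresholds[2], "semi-stable", "unstable"))
}

#' Age trend of a site-level quantity
#'
#' Pearson correlation of a per-site value with restoration age, with the
#' two-sided t-test p-value. The undated control site must be excluded by
#' the caller (it has no restoration age).
#'
#' @param age Restoration ages, years (>= 3 sites).
#' @param value Site-level values (same length).
#' @return List: `r`, `p_value`, `n_sites`.
#' @export
age_trend <- function(age, value) {
  ok <- is.finite(age) & is.finite(value)
  age <- age[ok]; value <- value[ok]
  if (length(age) < 3) stop("insufficient data: need >= 3 dated sites")
  ct <- stats::cor.test(age, value, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_sites = length(age))
}

#' Proportional similarity index (niche overlap)
#'
#' PSI = sum_k min(p_k, q_k) between two source-proportion vectors on the
#' same layers; 100 % iff the vectors are identical, 0 % for disjoint
#' supports.
#'
#' @param p,q Proportion vectors on the simplex (fractions or percent;
#'   both normalized internally). If named, names must match as sets.
#' @return Overlap in percent.
#' @export
niche_overlap <- function(p, q) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q))) {
      stop("mapping error: layer sets differ")
    }
    q <- q[names(p)]
  } else if (length(p) != length(q)) {
    stop("mapping error: vectors have different lengths")
  }
  p <- p / sum(p); q <- q / sum(q)
  100 * sum(pmin(p, q))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Standard single-factor analysis of variance across groups (e.g. sites),
#' followed by Tukey's honestly-significant-difference pairwise test at
#' alpha = 0.05.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (same length), >= 2 groups with >= 2 values each.
#' @return List: `F`, `p_value`, `df` (length 2), `tukey` (data frame of
#'   pairwise comparisons: `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop("insufficient data: need >= 2 groups with >= 2 values each")
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$groups
  list(F = tab[["F value"]][1],
       p_value = tab[["Pr(>F)"]][1],
       df = tab[["Df"]],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Per-site contribution table with stability classification
#'
#' Builds the site-level stability table from per-species posterior
#' contribution summaries: C_h (mean herb 0-20 cm contribution), C_s
#' (mean shrub 40-100 cm contribution), R_h/s and its class.
#'
#' @param species_table Data frame with one row per site x species:
#'   columns `site_id`, `restoration_age`, `is_control`, `group`
#'   ("shrub"/"herb"/...), `shallow_pct` (posterior mean 0-20 cm
#'   contribution) and `deep_pct` (posterior mean 40-100 cm contribution).
#' @param thresholds Passed to [classify_stability()].
#' @return Data frame per site: `site_id`, `restoration_age`,
#'   `is_control`, `C_h`, `C_s`, `n_herb`, `m_shrub`, `R_hs`,
#'   `stability_class`.
#' @export
site_contribution_table <- function(species_table, thresholds = c(0.9, 1.4)) {
  out <- lapply(split(species_table, species_table$site_id), function(st) {
    herbs <- st[st$group == "herb", ]
    shrubs <- st[st$group == "shrub", ]
    C_h <- mean_contribution(herbs$shallow_pct, "herb")
    C_s <- mean_contribution(shrubs$deep_pct, "shrub")
    R <- herb_shrub_ratio(C_h, C_s)
    data.frame(site_id = st$site_id[1],
               restoration_age = st$restoration_age[1],
               is_control = st$is_control[1],
               C_h = C_h, C_s = C_s,
               n_herb = nrow(herbs), m_shrub = nrow(shrubs),
               R_hs = R,
               stability_class = classify_stability(R, thresholds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$is_control, -out$restoration_age), , drop = FALSE]
}
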