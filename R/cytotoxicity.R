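#' Cytotoxicity plates
#'
#' Optical densities (arbitrary absorbance units, measured at 490/492 nm)
#' for the four conditions of an LDH release assay: effector + target
#' wells, effector-only wells, maximal-lysis wells and spontaneous-lysis
#' wells, each with >= 1 replicate.
#'
#' @param od_effector_plus_target,od_effector_only,od_max_lysis,od_spontaneous
#'   Non-empty numeric vectors of non-negative ODs.
#' @return A `cytotox_plate` list.
#' @export
cytotox_plate <- function(od_effector_plus_target, od_effector_only,
                          od_max_lysis, od_spontaneous) {
  p <- list(od_effector_plus_target = as.numeric(od_effector_plus_target),
            od_effector_only = as.numeric(od_effector_only),
            od_max_lysis = as.numeric(od_max_lysis),
            od_spontaneous = as.numeric(od_spontaneous))
  for (nm in names(p)) {
    if (!length(p[[nm]])) stop_invariant("lists non-empty", nm)
    if (any(p[[nm]] < 0)) stop_invariant("all ODs >= 0", nm)
  }
  class(p) <- "cytotox_plate"
  p
}

#' Percent cytotoxicity from an LDH plate
#'
#' Replicate wells are averaged per condition ("calculated in doubles"),
#' then
#' \deqn{\%\,\mathrm{cytotoxicity} = 100 \cdot
#'   \frac{OD_{T+targets} - OD_{T}}{OD_{max\,lysis} - OD_{spont.\,lysis}}}
#' A non-positive denominator (maximal lysis not exceeding spontaneous
#' lysis) is an error. The statistic is invariant to a common offset added
#' to all four condition means and to a common positive rescaling.
#'
#' @param plate A [cytotox_plate()].
#' @return Percent cytotoxicity (a single number; 50 means 50%).
#' @export
percent_cytotoxicity <- function(plate) {
  stopifnot(inherits(plate, "cytotox_plate"))
  den <- mean(plate$od_max_lysis) - mean(plate$od_spontaneous)
  if (den <= 0) {
    stop("non-positive denominator: mean maximal-lysis OD must exceed ",
         "mean spontaneous-lysis OD")
  }
  num <- mean(plate$od_effector_plus_target) - mean(plate$od_effector_only)
  100 * num / den
}

#' Summarize per-donor cytotoxicity by group
#'
#' @param table A data.frame with columns `donor`, `cell_line`,
#'   `condition` (e.g. "LV"/"Veh") and `pct`, one row per
#'   (donor, cell_line, condition).
#' @return A data.table with one row per (cell_line, condition): `n`,
#'   `mean`, `sd` (sample SD, n-1; `NA` and flagged when n < 2), plus
#'   2-decimal `mean_2dp`/`sd_2dp` report columns.
#' @export
summarize_donors <- function(table) {
  dt <- as.data.table(table)
  req <- c("donor", "cell_line", "condition", "pct")
  miss <- setdiff(req, names(dt))
  if (length(miss)) {
    stop("donor table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(dt, by = c("donor", "cell_line", "condition"))) {
    stop_invariant("one row per (donor, cell_line, condition)",
                   "duplicate donor rows")
  }
  out <- dt[, .(n = .N, mean = mean(pct),
                sd = if (.N >= 2L) stats::sd(pct) else NA_real_),
            by = .(cell_line, condition)]
  out[, sd_flag := ifelse(n < 2L, "n < 2: SD unavailable", "")]
  out[, mean_2dp := round(mean, 2)]
  out[, sd_2dp := round(sd, 2)]
  setorder(out, cell_line, condition)
  out[]
}

#' One-way ANOVA with Tukey HSD over donor cytotoxicity groups
#'
#' Fits a one-way ANOVA of percent cytotoxicity across the
#' (cell_line x condition) groups and computes all pairwise comparisons
#' with studentized-range (Tukey HSD / Tukey-Kramer for unbalanced groups)
#' adjusted p-values.
#'
#' @param table As in [summarize_donors()]; needs >= 2 groups with >= 2
#'   observations each.
#' @return A list: `f_statistic`, `df` (c(between, within)), `p_value`
#'   (ANOVA omnibus), and `comparisons` (data.table: group1, group2, diff,
#'   lwr, upr, p_adj).
#' @export
anova_tukey <- function(table) {
  dt <- as.data.table(table)
  dt[, group := paste(cell_line, condition)]
  sizes <- dt[, .N, by = group]
  if (nrow(sizes) < 2L) {
    stop("anova_tukey requires at least 2 groups")
  }
  if (any(sizes$N < 2L)) {
    stop("every group needs at least 2 observations")
  }
  dt[, group := factor(group)]
  fit <- stats::aov(pct ~ group, data = dt)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  # rebuild the pair labels from the level order rather than splitting the
  # rownames, which is ambiguous when group names contain hyphens
  cmb <- utils::combn(levels(dt$group), 2L)
  stopifnot(nrow(tk) == ncol(cmb))
  comparisons <- data.table(group1 = cmb[2L, ], group2 = cmb[1L, ],
                            diff = tk[, "diff"], lwr = tk[, "lwr"],
                            upr = tk[, "upr"], p_adj = tk[, "p adj"])
  list(f_statistic = an[["F value"]][1L],
       df = c(between = an[["Df"]][1L], within = an[["Df"]][2L]),
       p_value = an[["Pr(>F)"]][1L],
       comparisons = comparisons)
}

#' Extract one Tukey-adjusted p-value by group pair
#'
#' @param result The list returned by [anova_tukey()].
#' @param group1,group2 Group labels as `"<cell_line> <condition>"`, in
#'   either order.
#' @return The adjusted p-value.
#' @export
tukey_p <- function(result, group1, group2) {
  cmp <- result$comparisons
  hit <- (cmp$group1 == group1 & cmp$group2 == group2) |
    (cmp$group1 == group2 & cmp$group2 == group1)
  if (!any(hit)) {
    stop("no comparison between \"", group1, "\" and \"", group2, "\"")
  }
  cmp$p_adj[which(hit)[1L]]
}

#' Per-donor enrichment fold change
#'
#' Fold change of antigen-specific T-cell percentages after versus before
#' an expansion protocol, per donor, with mean and sample SD.
#'
#' @param pre_pct,post_pct Equal-length numeric vectors of per-donor
#'   percentages; all `pre_pct` must be positive (a zero baseline leaves
#'   the fold change undefined).
#' @return A list: `fold_change` (per donor), `mean_fc`, `sd_fc`.
#' @export
enrichment_fold_change <- function(pre_pct, post_pct) {
  if (length(pre_pct) != length(post_pct)) {
    stop("pre_pct and post_pct must have equal length")
  }
  if (any(pre_pct <= 0)) {
    stop("fold change undefined: pre_pct must be > 0 elementwise")
  }
  fc <- post_pct / pre_pct
  list(fold_change = fc, mean_fc = mean(fc),
       sd_fc = if (length(fc) >= 2L) stats::sd(fc) else NA_real_)
}

#' Packaged donor cytotoxicity fixture
#'
#' The per-donor percent-cytotoxicity table (n = 7 donors) for three tumor
#' cell lines (SK-MEL-5, HCT-116, MDA-MB-231) under TCR-encoding
#' lentiviral transduction (LV) versus vehicle transduction (Veh), shipped
#' as a plain-text fixture with decimal commas normalized to points.
#'
#' @return A data.table with columns donor, cell_line, condition, pct.
#' @export
table1_cytotoxicity <- function() {
  path <- system.file("extdata", "donor_cytotoxicity.csv",
                      package = "clonoscape", mustWork = TRUE)
  fread(path)
}
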