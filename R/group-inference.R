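# Node-wise covariate-adjusted group screening (MANCOVA/ANCOVA + FDR).

# Build the analysis design: group kept numeric 0/1 (0 = Western-like,
# 1 = Eastern-like), sex/site as factors, remaining covariates standardised
# for design-matrix conditioning.
prepare_design <- function(phenotypes, covariates,
                           factor_covariates = c("sex", "site")) {
  missing_cols <- setdiff(c("group", covariates), names(phenotypes))
  if (length(missing_cols)) {
    stopf("phenotype table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df <- phenotypes[, c("group", covariates), drop = FALSE]
  if (!all(df$group %in% c(0, 1))) stopf("`group` must be coded 0/1")
  for (cv in covariates) {
    if (anyNA(df[[cv]])) stopf("missing values in covariate '%s'", cv)
    if (cv %in% factor_covariates) {
      df[[cv]] <- factor(df[[cv]])
      if (nlevels(df[[cv]]) < 2) df[[cv]] <- NULL  # constant factor: drop
    } else if (stats::sd(df[[cv]]) == 0) {
      df[[cv]] <- NULL  # constant covariate carries no information
    } else {
      df[[cv]] <- as.numeric(scale(df[[cv]]))
    }
  }
  df
}

design_formula <- function(df) {
  covs <- setdiff(names(df), c("group", ".y", ".y1", ".y2"))
  rhs <- paste(c(covs, "group"), collapse = " + ")
  stats::as.formula(paste("~", rhs))
}

check_full_rank <- function(mm) {
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    bad <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
}

#' Covariate-adjusted group test for one nodal metric (ANCOVA)
#'
#' Fits `metric ~ covariates + group` by least squares and tests the group
#' term (sum of squares of group adjusted for the covariates). The
#' direction maps the adjusted group difference to `"W"` (higher in group
#' 0) or `"E"` (higher in group 1).
#'
#' @param metric numeric vector, one value per subject (same order as
#'   `phenotypes`).
#' @param phenotypes phenotype data frame with `group` (0/1) and the
#'   covariate columns.
#' @param covariates covariate column names; `sex` and `site` are entered
#'   as factors, the rest standardised.
#' @return list with `F`, `p`, `eta_p2` (partial eta squared), `direction`
#'   (`"W"`/`"E"`), `df1`, `df2`.
#' @export
ancova_node <- function(metric, phenotypes,
                        covariates = c("age", "sex", "motion", "site")) {
  df <- prepare_design(phenotypes, covariates)
  if (length(metric) != nrow(df)) stopf("metric length != subject count")
  if (!all(is.finite(metric))) stopf("metric contains non-finite values")
  if (nrow(df) < length(covariates) + 3) stopf("too few subjects for the design")
  mm <- stats::model.matrix(design_formula(df), df)
  check_full_rank(mm)
  if (stats::sd(metric) == 0) {
    warnf("metric is constant across subjects; F undefined")
    return(list(F = NA_real_, p = NA_real_, eta_p2 = NA_real_,
                direction = NA_character_, df1 = 1L, df2 = NA_integer_))
  }
  df$.y <- metric
  fit <- stats::lm(stats::update(design_formula(df), .y ~ .), data = df)
  an <- stats::anova(fit)
  ss_group <- an["group", "Sum Sq"]
  ss_res <- an["Residuals", "Sum Sq"]
  list(F = an["group", "F value"], p = an["group", "Pr(>F)"],
       eta_p2 = ss_group / (ss_group + ss_res),
       direction = if (stats::coef(fit)[["group"]] > 0) "E" else "W",
       df1 = an["group", "Df"], df2 = an["Residuals", "Df"])
}

#' Covariate-adjusted multivariate group test for one node (MANCOVA)
#'
#' Tests the 2-vector (degree AUC, efficiency AUC) for a group difference
#' adjusting for covariates, using Pillai's trace with the standard F
#' approximation. With a single-df group term Pillai's trace equals the
#' multivariate partial eta squared.
#'
#' @param degree,efficiency numeric subject-vectors (the two dependent
#'   variables).
#' @inheritParams ancova_node
#' @return list with `F`, `p`, `eta_p2`, `pillai`, `df1`, `df2`.
#' @export
mancova_node <- function(degree, efficiency, phenotypes,
                         covariates = c("age", "sex", "motion", "site")) {
  df <- prepare_design(phenotypes, covariates)
  if (length(degree) != nrow(df) || length(efficiency) != nrow(df)) {
    stopf("metric length != subject count")
  }
  mm <- stats::model.matrix(design_formula(df), df)
  check_full_rank(mm)
  y <- cbind(degree, efficiency)
  if (qr(stats::cov(y))$rank < 2) {
    stopf("dependent variables are collinear; residual covariance singular")
  }
  df$.y1 <- degree
  df$.y2 <- efficiency
  fit <- stats::manova(stats::update(design_formula(df),
                                     cbind(.y1, .y2) ~ .), data = df)
  st <- summary(fit, test = "Pillai")$stats
  list(F = st["group", "approx F"], p = st["group", "Pr(>F)"],
       eta_p2 = st["group", "Pillai"], pillai = st["group", "Pillai"],
       df1 = st["group", "num Df"], df2 = st["group", "den Df"])
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up adjustment across a family of p-values; items with adjusted
#' value at or below `q_level` are rejected.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param q_level FDR level (default 0.05).
#' @return list with `rejected` (logical) and `adjusted` (BH-adjusted
#'   p-values, monotone in p-rank).
#' @export
fdr_bh <- function(p, q_level = 0.05) {
  if (length(p) == 0) {
    return(list(rejected = logical(0), adjusted = numeric(0)))
  }
  if (any(!is.na(p) & (p < 0 | p > 1))) stopf("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p, method = "BH")
  list(rejected = !is.na(adjusted) & adjusted <= q_level, adjusted = adjusted)
}

#' Screen all nodes for covariate-adjusted group differences
#'
#' Runs the MANCOVA plus both single-metric ANCOVAs at every node, controls
#' FDR separately within the three test families (each across all nodes),
#' and flags "consistent" nodes: significant after FDR in the MANCOVA and
#' in both ANCOVAs, with per-metric directions recorded.
#'
#' @param metrics list with subjects x nodes matrices `degree_auc` and
#'   `efficiency_auc` (rownames = subject ids matching `phenotypes$subject_id`).
#' @inheritParams ancova_node
#' @param q_level FDR level applied within each family.
#' @return list with `stats` (one row per node: F/p/q/eta for the three
#'   tests plus directions), `consistent_nodes` (character vector of ROI
#'   labels) and `q_level`.
#' @export
screen_nodes <- function(metrics, phenotypes, q_level = 0.05,
                         covariates = c("age", "sex", "motion", "site")) {
  deg <- metrics$degree_auc
  eff <- metrics$efficiency_auc
  stopifnot(is.matrix(deg), is.matrix(eff),
            identical(dimnames(deg), dimnames(eff)))
  idx <- match(phenotypes$subject_id, rownames(deg))
  if (anyNA(idx)) stopf("metrics missing for subject(s): %s",
                        paste(phenotypes$subject_id[is.na(idx)], collapse = ", "))
  deg <- deg[idx, , drop = FALSE]
  eff <- eff[idx, , drop = FALSE]

  nodes <- colnames(deg)
  rows <- lapply(seq_along(nodes), function(j) {
    man <- mancova_node(deg[, j], eff[, j], phenotypes, covariates)
    a_d <- ancova_node(deg[, j], phenotypes, covariates)
    a_e <- ancova_node(eff[, j], phenotypes, covariates)
    data.frame(node = nodes[j],
               F_mancova = man$F, p_mancova = man$p, eta_p2_mancova = man$eta_p2,
               F_deg = a_d$F, p_deg = a_d$p, eta_p2_deg = a_d$eta_p2,
               direction_deg = a_d$direction,
               F_eff = a_e$F, p_eff = a_e$p, eta_p2_eff = a_e$eta_p2,
               direction_eff = a_e$direction,
               stringsAsFactors = FALSE)
  })
  stats_tab <- do.call(rbind, rows)
  stats_tab$q_mancova <- fdr_bh(stats_tab$p_mancova, q_level)$adjusted
  stats_tab$q_deg <- fdr_bh(stats_tab$p_deg, q_level)$adjusted
  stats_tab$q_eff <- fdr_bh(stats_tab$p_eff, q_level)$adjusted
  ok <- !is.na(stats_tab$q_mancova) & stats_tab$q_mancova <= q_level &
    !is.na(stats_tab$q_deg) & stats_tab$q_deg <= q_level &
    !is.na(stats_tab$q_eff) & stats_tab$q_eff <= q_level
  list(stats = stats_tab, consistent_nodes = stats_tab$node[ok],
       q_level = q_level)
}
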