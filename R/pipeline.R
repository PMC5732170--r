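#' Pipeline configuration
#'
#' Collects the tunable settings of the per-nodule and cohort pipelines in
#' one validated list: segmentation HU bounds, shell thickness, parenchymal
#' thresholds, stepwise alphas and the ROC target sensitivity.
#'
#' @param hu_low,hu_high Region-growing HU bounds (ground-glass through
#'   solid by default).
#' @param connectivity Region-growing connectivity (6, 18, 26).
#' @param shell_mm Peritumoral shell thickness in mm (default 10).
#' @param median_filter Apply in-plane 3x3 median smoothing before
#'   analysis (for edge-enhancing reconstruction kernels).
#' @param thresholds A [parenchyma_thresholds()].
#' @param entry_p,stay_p Stepwise selection alphas.
#' @param target_sensitivity ROC operating-point target (default 0.80).
#' @param candidates Candidate covariates for stepwise EGFR modelling.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(hu_low = -750, hu_high = 200, connectivity = 26,
                            shell_mm = 10, median_filter = FALSE,
                            thresholds = parenchyma_thresholds(),
                            entry_p = 0.05, stay_p = 0.05,
                            target_sensitivity = 0.80,
                            candidates = c("Y_pct", "G_pct", "VIRO_pct",
                                           "fibrosis", "never_smoker")) {
  if (hu_low >= hu_high) stop("hu_low must be below hu_high")
  if (shell_mm <= 0) stop("shell_mm must be positive")
  if (target_sensitivity <= 0 || target_sensitivity > 1)
    stop("target_sensitivity must lie in (0, 1]")
  structure(list(hu_low = hu_low, hu_high = hu_high,
                 connectivity = connectivity, shell_mm = shell_mm,
                 median_filter = median_filter, thresholds = thresholds,
                 entry_p = entry_p, stay_p = stay_p,
                 target_sensitivity = target_sensitivity,
                 candidates = candidates), class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Analyze one nodule end to end
#'
#' Runs the full per-nodule chain: (optional) median smoothing, lung
#' segmentation, seeded region growing from `seed_point`, nearest-exemplar
#' voxel labeling, glyph and composite features with the registered
#' screening cutoffs, peritumoral shell construction and parenchymal
#' scoring. Deterministic given its inputs; errors carry the failing
#' stage's name.
#'
#' @param volume A [ct_volume()].
#' @param seed_point Voxel index triple inside the nodule.
#' @param model A fitted [fit_exemplar_model()].
#' @param config A [pipeline_config()].
#' @return A one-row `data.frame`: nine glyph percentages (`glyph_V`, ...),
#'   composite features, cutoff flags (`flag_VIRO_le_71`,
#'   `flag_YP_ge_23.5`), `nodule_volume_cc`, and the five shell parenchyma
#'   fractions with `fibrosis` and `low_attenuation`.
#' @export
run_nodule <- function(volume, seed_point, model,
                       config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (isTRUE(config$median_filter))
    volume <- with_stage("median_filter", median_filter_inplane(volume))
  lung <- with_stage("segment_lung", segment_lung(volume))
  seed_point <- check_in_bounds(seed_point, dim(volume$data), "seed_point")
  with_stage("segment_lung", {
    if (!lung$data[seed_point[1], seed_point[2], seed_point[3]])
      stop("seed outside lung")
  })
  nodule <- with_stage("grow_nodule",
    grow_nodule(volume, seed_point, config$hu_low, config$hu_high,
                config$connectivity))
  labels <- with_stage("classify_voxels",
                       classify_voxels(volume, nodule, model))
  glyph <- with_stage("glyph", compute_glyph(labels, nodule))
  comp <- composite_features(glyph)
  shell <- with_stage("peritumoral_shell",
                      peritumoral_shell(nodule, lung, config$shell_mm))
  par <- with_stage("parenchyma",
                    summarize_parenchyma(volume, shell, config$thresholds))
  g <- as.list(stats::setNames(unclass(glyph),
                               paste0("glyph_", names(glyph))))
  out <- data.frame(
    g,
    VIRO_pct = unname(comp["VIRO"]), YP_pct = unname(comp["YP"]),
    BCG_pct = unname(comp["BCG"]), Y_pct = unname(comp["Y"]),
    G_pct = unname(comp["G"]), YplusG_pct = unname(comp["YplusG"]),
    flag_VIRO_le_71 = apply_cutoff(comp, "VIRO"),
    flag_YP_ge_23.5 = apply_cutoff(comp, "YP"),
    nodule_volume_cc = mask_volume_cc(nodule),
    frac_N = par$fraction_normal, frac_LA = par$fraction_LA,
    frac_GG = par$fraction_GG, frac_R = par$fraction_reticular,
    frac_HC = par$fraction_HC, fibrosis = par$fibrosis,
    low_attenuation = par$low_attenuation,
    check.names = FALSE)
  attr(out, "masks") <- list(lung = lung, nodule = nodule, shell = shell)
  out
}

#' Cohort-level statistical report
#'
#' Runs the statistics layer over a cohort table (simulated or assembled
#' from per-nodule records plus clinical covariates): contingency tests of
#' smoking and gender against mutation status, stepwise logistic selection
#' of EGFR predictors, ROC cutoffs at the configured target sensitivity
#' for the composite features, the rescaled odds ratio per 10-point VIRO
#' decrease, and Kaplan-Meier / Cox survival by risk group when survival
#' columns are present.
#'
#' @param cohort Data frame; requires columns `egfr`, `smoking`, `Y_pct`,
#'   `G_pct`, `VIRO_pct`, `YplusG_pct`, `fibrosis`; uses `kras`,
#'   `never_smoker`, `gender`, `risk_group`, `dfs_time`, `dfs_event` when
#'   present.
#' @param config A [pipeline_config()].
#' @param report_path Optional path; when given the report is also written
#'   as JSON.
#' @return A list of class `cohort_report`.
#' @export
run_cohort <- function(cohort, config = pipeline_config(),
                       report_path = NULL) {
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0) stop("empty cohort")
  required <- c("egfr", "smoking", "Y_pct", "G_pct", "VIRO_pct",
                "YplusG_pct", "fibrosis")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (length(unique(cohort$egfr)) < 2)
    stop("EGFR outcome has a single class; cohort statistics undefined")
  if (!"never_smoker" %in% names(cohort))
    cohort$never_smoker <- as.integer(cohort$smoking == "never")
  if (all(c("egfr", "kras") %in% names(cohort)) &&
      any(cohort$egfr == 1 & cohort$kras == 1))
    warning("EGFR and KRAS flagged together in ",
            sum(cohort$egfr == 1 & cohort$kras == 1),
            " subjects; the two mutations are expected to be mutually ",
            "exclusive")
  report <- list(n = nrow(cohort))

  smoking_tab <- table(cohort$smoking, cohort$egfr)
  report$smoking_vs_egfr <- fisher_exact(smoking_tab)
  if ("gender" %in% names(cohort) &&
      length(unique(cohort$gender)) > 1)
    report$gender_vs_egfr <- chi_square_test(table(cohort$gender,
                                                   cohort$egfr))
  if ("age" %in% names(cohort))
    report$age_vs_egfr <- wilcoxon_rank_sum(cohort$age[cohort$egfr == 1],
                                            cohort$age[cohort$egfr == 0])

  cand <- intersect(config$candidates, names(cohort))
  sw <- stepwise_select(cohort[, cand, drop = FALSE], cohort$egfr,
                        entry_p = config$entry_p, stay_p = config$stay_p)
  report$stepwise_egfr <- list(selected = attr(sw, "selected"),
                               coefficients = sw$coefficients,
                               p_values = sw$p_value,
                               trace = attr(sw, "trace"))

  # screening cutoffs at the target sensitivity
  roc_viro <- roc_curve(cohort$VIRO_pct, cohort$egfr, direction = "lower")
  roc_yg <- roc_curve(cohort$YplusG_pct, cohort$egfr, direction = "higher")
  report$roc <- list(
    VIRO = c(auc = roc_viro$auc,
             unlist(threshold_at_sensitivity(roc_viro,
                                             config$target_sensitivity))),
    YplusG = c(auc = roc_yg$auc,
               unlist(threshold_at_sensitivity(roc_yg,
                                               config$target_sensitivity))))

  # odds ratio per 10-point VIRO decrease from the univariate model
  viro_fit <- fit_logistic(cohort[, "VIRO_pct", drop = FALSE], cohort$egfr)
  report$or_viro_per_10pt_decrease <-
    rescale_odds_ratio(unname(viro_fit$coefficients["VIRO_pct"]), -10)

  if (all(c("risk_group", "dfs_time", "dfs_event") %in% names(cohort)) &&
      length(unique(cohort$risk_group)) > 1 &&
      sum(cohort$dfs_event) > 0) {
    report$km_by_risk_group <- lapply(
      split(cohort, cohort$risk_group),
      function(g) km_estimator(g$dfs_time, g$dfs_event))
    report$cox_risk_group <- cox_lrt(cohort$dfs_time, cohort$dfs_event,
                                     factor(cohort$risk_group))[
                                       c("hazard_ratio", "lrt_statistic",
                                         "df", "p_value")]
  }
  class(report) <- "cohort_report"
  if (!is.null(report_path)) {
    jsonlite::write_json(
      report[setdiff(names(report), "km_by_risk_group")],
      report_path, auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> n = ", x$n, "\n", sep = "")
  cat("  smoking vs EGFR Fisher p = ",
      format(x$smoking_vs_egfr$p_value, digits = 3), "\n", sep = "")
  cat("  stepwise EGFR predictors: ",
      if (length(x$stepwise_egfr$selected) == 0) "(intercept only)"
      else paste(x$stepwise_egfr$selected, collapse = ", "), "\n", sep = "")
  cat("  VIRO AUC = ", format(x$roc$VIRO["auc"], digits = 3),
      ", Y+G AUC = ", format(x$roc$YplusG["auc"], digits = 3), "\n",
      sep = "")
  cat("  OR per 10-point VIRO decrease = ",
      format(x$or_viro_per_10pt_decrease, digits = 3), "\n", sep = "")
  invisible(x)
}
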