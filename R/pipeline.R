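#' Run the full phosphorylation-rate pipeline
#'
#' Chains the stages — read (or simulate) spot tables, per-gel
#' total-density normalization, profile matching, per-spot rate estimation
#' with bootstrap CIs, dephosphorylation-pattern classification, and the
#' study-level summary — writing every intermediate to \code{out_dir}:
#' \code{matched.csv}, \code{pr_results.csv}, \code{patterns.csv},
#' \code{summary.txt} (flat key = value), and \code{run.log}. Outputs are
#' byte-identical across reruns with the same inputs, configuration and
#' seed. On any stage failure, partially written outputs are removed and
#' the error names the failing stage.
#'
#' @param out_dir output directory (created if needed).
#' @param tables character vector of spot-table paths (all profiles and
#'   replicates; ignored when \code{synthetic} is given).
#' @param design a [study_design()] or path to a design file; defaults to
#'   3 replicates with the 2-of-3 rule when synthetic.
#' @param synthetic \code{NULL}, \code{TRUE} (default generator at
#'   \code{seed}) or a [generator_config()].
#' @param seed root seed for bootstrap streams (and the generator when
#'   \code{synthetic = TRUE}).
#' @param n_boot,conf_level,alpha,bonferroni_m,significance_rule passed to
#'   [phospho_rates()].
#' @param tolerance coordinate-matching tolerance, see [match_profiles()].
#' @param vol_drop_min,pi_shift_min pattern thresholds, see
#'   [classify_patterns()].
#' @param gradient [ph_gradient()] for pI conversion.
#' @param ladder optional [marker_ladder()] for Mr deltas.
#' @return (invisibly) a list with the \code{fit} (\code{pr_analysis}),
#'   \code{patterns}, \code{summary} (study-level list) and \code{truth}
#'   (when synthetic).
#' @export
run_pipeline <- function(out_dir, tables = NULL, design = NULL,
                         synthetic = NULL, seed = 1, n_boot = 2000,
                         conf_level = 0.95, alpha = 0.05,
                         bonferroni_m = NULL,
                         significance_rule = "ci_overlap",
                         tolerance = c(0.01, 0.01),
                         vol_drop_min = 0.10, pi_shift_min = 0.05,
                         gradient = ph_gradient(), ladder = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- file.path(out_dir, c("matched.csv", "pr_results.csv",
                                  "patterns.csv", "summary.txt", "run.log",
                                  "truth.csv"))
  stage <- "setup"
  result <- tryCatch({
    truth <- NULL
    if (!is.null(synthetic)) {
      stage <- "synthetic_gels"
      cfg <- if (isTRUE(synthetic)) generator_config(seed = seed)
             else synthetic
      stopifnot(inherits(cfg, "generator_config"))
      sim <- generate_study(cfg)
      records <- sim$records
      design <- sim$design
      truth <- sim$truth
      utils::write.table(truth, file.path(out_dir, "truth.csv"), sep = ",",
                         row.names = FALSE, qmethod = "double", quote = TRUE,
                         na = "")
    } else {
      stage <- "spot_io"
      if (is.null(tables)) stop("no input tables and no synthetic config")
      records <- do.call(rbind, lapply(tables, read_spot_table))
      if (is.character(design)) design <- read_study_design(design)
      if (is.null(design)) stop("a study design is required")
    }

    stage <- "preprocess"
    records <- normalize_study(records, design$normalization_scale)
    matched <- match_profiles(records, design, tolerance = tolerance)
    write_matched_table(matched, file.path(out_dir, "matched.csv"))

    stage <- "pr_statistics"
    fit <- phospho_rates(matched, n_boot = n_boot, conf_level = conf_level,
                         alpha = alpha, bonferroni_m = bonferroni_m,
                         seed = seed, significance_rule = significance_rule)
    write_pr_table(fit, file.path(out_dir, "pr_results.csv"))

    stage <- "pattern_classify"
    patterns <- classify_patterns(matched, vol_drop_min = vol_drop_min,
                                  pi_shift_min = pi_shift_min,
                                  gradient = gradient, ladder = ladder)
    write_pattern_table(patterns, file.path(out_dir, "patterns.csv"))

    stage <- "report"
    summ <- study_summary(fit, patterns)
    check_summary_consistency(summ, fit, patterns)
    write_summary(summ, file.path(out_dir, "summary.txt"))
    writeLines(c(
      "phosphoRate pipeline run",
      paste0("input = ", if (is.null(synthetic)) paste(tables, collapse = ";")
             else "synthetic"),
      paste0("seed = ", seed),
      paste0("n_boot = ", n_boot),
      paste0("conf_level = ", conf_level),
      paste0("alpha = ", alpha),
      paste0("bonferroni_m = ", fit$settings$bonferroni_m),
      paste0("significance_rule = ", significance_rule),
      paste0("n_spots = ", length(spot_ids(matched))),
      "status = ok"), file.path(out_dir, "run.log"))
    list(fit = fit, patterns = patterns, summary = summ, truth = truth)
  }, error = function(e) {
    unlink(outputs)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Study-level summary
#'
#' Collates the detection counts and percentages, fold ratio, Fisher exact
#' p-value, significance tally and pattern counts into one flat record.
#' Percentages are rounded half-up to 1 decimal.
#'
#' @param fit a \code{pr_analysis}.
#' @param patterns optional data frame from [classify_patterns()].
#' @return list of class \code{study_summary}.
#' @export
study_summary <- function(fit, patterns = NULL) {
  det <- summarize_detection(fit)
  h <- fit$results[fit$results$method == "hfp", ]
  n_sig <- sum(h$significant == "significant")
  pattern_counts <- NULL
  if (!is.null(patterns)) {
    lv <- c("reduced", "shifted_basic", "disappeared", "novel", "unchanged")
    pattern_counts <- as.integer(table(factor(patterns$pattern, levels = lv)))
    names(pattern_counts) <- lv
  }
  structure(list(
    n_spots_total = det$n_total,
    n_hfp_positive = det$n_hfp_positive,
    n_proq_positive = det$n_proq_positive,
    pct_hfp = det$pct_hfp, pct_proq = det$pct_proq,
    fold_ratio = det$fold_ratio, fisher_p = det$fisher_p,
    n_significant = n_sig,
    pct_significant = round_half_up(100 * n_sig / det$n_total, 1),
    pattern_counts = pattern_counts), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Matched spots: %d\n", x$n_spots_total))
  cat(sprintf("Phosphorylated by HF-P: %d (%.1f%%)\n",
              x$n_hfp_positive, x$pct_hfp))
  cat(sprintf("Phosphorylated by phosphostain: %d (%.1f%%)\n",
              x$n_proq_positive, x$pct_proq))
  cat(sprintf("Fold ratio (HF-P / phosphostain): %s\n",
              ifelse(is.na(x$fold_ratio), "NA",
                     sprintf("%.2f", x$fold_ratio))))
  cat(sprintf("Fisher two-tailed p: %.4g\n", x$fisher_p))
  cat(sprintf("Significant method differences: %d (%.1f%%)\n",
              x$n_significant, x$pct_significant))
  if (!is.null(x$pattern_counts)) {
    cat("Dephosphorylation patterns:\n")
    for (nm in names(x$pattern_counts))
      cat(sprintf("  %-14s %d\n", nm, x$pattern_counts[[nm]]))
  }
  invisible(x)
}

# summary counts must equal column-wise tallies of the per-spot tables
#' @keywords internal
check_summary_consistency <- function(summ, fit, patterns) {
  det <- summarize_detection(fit)
  stopifnot(summ$n_hfp_positive == det$n_hfp_positive,
            summ$n_proq_positive == det$n_proq_positive,
            summ$n_significant == sum(
              fit$results$significant[fit$results$method == "hfp"] ==
                "significant"),
            is.null(summ$pattern_counts) ||
              sum(summ$pattern_counts) == nrow(patterns))
  invisible(TRUE)
}

#' @keywords internal
write_summary <- function(summ, path) {
  num <- function(v) formatC(v, format = "g", digits = 15)
  lines <- c(
    paste0("n_spots_total = ", summ$n_spots_total),
    paste0("n_hfp_positive = ", summ$n_hfp_positive),
    paste0("n_proq_positive = ", summ$n_proq_positive),
    paste0("pct_hfp = ", sprintf("%.1f", summ$pct_hfp)),
    paste0("pct_proq = ", sprintf("%.1f", summ$pct_proq)),
    paste0("fold_ratio = ", ifelse(is.na(summ$fold_ratio), "NA",
                                   num(summ$fold_ratio))),
    paste0("fisher_p = ", num(summ$fisher_p)),
    paste0("n_significant = ", summ$n_significant),
    paste0("pct_significant = ", sprintf("%.1f", summ$pct_significant)))
  if (!is.null(summ$pattern_counts))
    lines <- c(lines, paste0("pattern_", names(summ$pattern_counts), " = ",
                             summ$pattern_counts))
  writeLines(lines, path)
  invisible(path)
}
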