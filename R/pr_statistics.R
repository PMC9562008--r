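#' Phosphorylation rate from the phosphostain profile
#'
#' PR = (P / T) x 100, where P is the phosphostain (Pro-Q Diamond type)
#' volume and T the total-protein (reference stain) volume of the same spot.
#' Phosphostain volumes exceeding the reference volume are clamped to 100;
#' a spot with no phosphostain signal (P absent, \code{NA}) has PR 0.
#'
#' @param P phosphostain normalized volume, or \code{NA} if not detected.
#' @param T_ reference normalized volume; must be positive.
#' @return percent in [0, 100].
#' @export
pr_proq <- function(P, T_) {
  if (is.na(T_) || T_ <= 0)
    stop("phosphorylation rate undefined: reference volume T must be > 0")
  if (is.na(P)) return(0)
  if (P < 0) stop("negative phosphostain volume")
  min(100 * P / T_, 100)
}

#' Phosphorylation rate from the chemical-dephosphorylation profile
#'
#' PR = ((T - D) / T) x 100, where T is the untreated reference volume and D
#' the volume of the same spot after dephosphorylation with HF-P. A spot
#' that disappears after treatment (D absent, \code{NA}) has PR 100; a spot
#' with MORE volume after treatment (D > T) has no applicable rate and
#' returns \code{NA}.
#'
#' @param T_ reference normalized volume; must be positive.
#' @param D dephosphorylated normalized volume, or \code{NA} if the spot
#'   disappeared.
#' @return percent in [0, 100], or \code{NA} when D > T.
#' @export
pr_hfp <- function(T_, D) {
  if (is.na(T_) || T_ <= 0)
    stop("phosphorylation rate undefined: reference volume T must be > 0")
  if (is.na(D)) return(100)
  if (D < 0) stop("negative dephosphorylated volume")
  if (D > T_) return(NA_real_)
  100 * (T_ - D) / T_
}

#' Bias-corrected percentile bootstrap confidence interval for a mean
#'
#' Draws \code{n_boot} resamples with replacement of size N from the
#' replicate values, computes resample means, and returns the
#' bias-corrected (BC) percentile interval: the empirical quantiles of the
#' resample means at normal-shifted levels
#' \eqn{\Phi(2 z_0 + z_{\alpha/2})} and \eqn{\Phi(2 z_0 + z_{1-\alpha/2})},
#' where the bias constant \eqn{z_0 = \Phi^{-1}} of the fraction of resample
#' means below the observed mean. No acceleration constant is used (BC, not
#' BCa).
#'
#' With N as small as 3 the resample-mean distribution is discrete (27
#' equiprobable atoms), so ties with the observed mean are common; they are
#' counted half when estimating the bias fraction, and the fraction is
#' clamped to [1/(2B), 1 - 1/(2B)] to keep \eqn{z_0} finite. Quantiles use
#' the inverse-empirical-CDF (type 1) definition for determinism at small B.
#'
#' @param values numeric replicate values (percent); NAs are dropped.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param conf_level confidence level in (0, 1) (default 0.95).
#' @param seed integer seed for the resampling stream; \code{NULL} uses the
#'   current RNG state.
#' @return named numeric \code{c(ci_low, ci_high)} with attribute
#'   \code{"z0"}; \code{c(NA, NA)} if no non-missing values.
#' @export
bootstrap_ci_bc <- function(values, n_boot = 2000, conf_level = 0.95,
                            seed = NULL) {
  v <- values[!is.na(values)]
  if (!length(v)) return(c(ci_low = NA_real_, ci_high = NA_real_))
  if (conf_level <= 0 || conf_level >= 1) stop("conf_level must be in (0, 1)")
  if (n_boot < 100)
    warning("n_boot < 100: interval endpoints will be unstable")
  if (length(v) == 1)
    return(structure(c(ci_low = v, ci_high = v), z0 = 0))
  n <- length(v)
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  thetas <- colMeans(matrix(v[idx], nrow = n))
  ci_from_thetas(thetas, mean(v), conf_level, n_boot)
}

# BC endpoints from a vector of resample means (shared with the paired
# difference rule)
#' @keywords internal
ci_from_thetas <- function(thetas, theta_hat, conf_level, n_boot) {
  tol <- 1e-9 * max(1, abs(theta_hat))
  frac <- (sum(thetas < theta_hat - tol) +
           0.5 * sum(abs(thetas - theta_hat) <= tol)) / n_boot
  frac <- min(max(frac, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- stats::qnorm(frac)
  alpha <- 1 - conf_level
  lev <- stats::pnorm(2 * z0 + stats::qnorm(c(alpha / 2, 1 - alpha / 2)))
  sorted <- sort(thetas)
  q1 <- function(p) sorted[min(n_boot, max(1L, ceiling(p * n_boot)))]
  structure(c(ci_low = q1(lev[1]), ci_high = q1(lev[2])), z0 = z0)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of comparisons (here, the number of spots tested).
#' @return the per-comparison level \code{alpha / m}; per-spot confidence
#'   intervals are then built at confidence \code{1 - alpha / m}.
#' @export
bonferroni_level <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is_count(m) || m < 1) stop("m must be a positive integer")
  alpha / m
}

#' Per-spot between-method significance by CI overlap
#'
#' Two methods differ significantly for a spot when their
#' Bonferroni-adjusted bootstrap confidence intervals are disjoint.
#'
#' @param res_hfp,res_proq lists (or one-row data frames) with fields
#'   \code{spot_id}, \code{mean_pr}, \code{ci_low}, \code{ci_high} for the
#'   same spot.
#' @return one of \code{"significant"}, \code{"ns"},
#'   \code{"not_comparable"} (either mean missing).
#' @export
compare_methods_per_spot <- function(res_hfp, res_proq) {
  if (!identical(as.character(res_hfp$spot_id),
                 as.character(res_proq$spot_id)))
    stop("results are for different spots: ", res_hfp$spot_id, " vs ",
         res_proq$spot_id)
  if (is.na(res_hfp$mean_pr) || is.na(res_proq$mean_pr))
    return("not_comparable")
  disjoint <- res_hfp$ci_low > res_proq$ci_high ||
              res_proq$ci_low > res_hfp$ci_high
  if (disjoint) "significant" else "ns"
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-tailed p-value computed from first principles: with the table
#' margins fixed, every admissible table has a hypergeometric probability
#' (accumulated as log-binomial coefficients); the p-value sums the
#' probabilities of all tables no more probable than the observed one
#' (within a relative tolerance of 1e-7 for the comparison).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1]. A table with a zero margin carries no
#'   information and returns 1 with a warning.
#' @export
fisher_exact_two_tailed <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) {
    warning("zero margin: Fisher's exact test is uninformative, p = 1")
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  lp_obs <- logp[match(tab[1, 1], support)]
  min(sum(exp(logp[logp <= lp_obs + log(1 + 1e-7)])), 1)
}

#' Fit per-spot phosphorylation rates for both detection methods
#'
#' The central estimator: for every matched master spot it computes the
#' replicate phosphorylation rates by both methods
#' (phosphostain: [pr_proq()]; chemical dephosphorylation: [pr_hfp()]),
#' their mean and standard error, a bias-corrected percentile bootstrap
#' confidence interval for the mean at the Bonferroni-adjusted confidence
#' level \code{1 - alpha/m}, and a per-spot between-method significance
#' call.
#'
#' Conventions carried through from the estimator's definitions:
#' \itemize{
#'   \item a replicate with no reference volume T contributes no rate;
#'   \item a phosphostain signal failing the replicate detection rule is
#'     treated as not detected (all replicate PRs 0), and absent P in a
#'     detected spot contributes a replicate PR of 0;
#'   \item a dephospho volume exceeding its reference (D > T) makes that
#'     replicate's HF-P rate not applicable (NA), and the spot's mean rate
#'     is then not applicable as a whole (the spot-level N/A convention of
#'     the results table); such spots are "not comparable";
#'   \item novel spots (no reference presence) have no rate by either
#'     method;
#'   \item the dephosphorylation rate measures volume loss at the spot's
#'     original gel position: if the dephospho consensus position lies
#'     farther than \code{position_tol} from the reference position (a
#'     pre-matched spot recorded as shifted), the original position is
#'     vacated and D is treated as absent (PR 100). Coordinate-mode
#'     matching never pairs spots beyond the tolerance box, so this makes
#'     the two input modes consistent.
#' }
#'
#' @param matched a \code{matched_spots} object (see [match_profiles()]).
#' @param n_boot bootstrap resamples per spot and method (default 2000).
#' @param conf_level nominal confidence level before Bonferroni adjustment
#'   (default 0.95).
#' @param alpha family-wise error rate for the between-method comparisons
#'   (default 0.05).
#' @param bonferroni_m number of comparisons m; default the number of
#'   matched spots.
#' @param seed root seed; each spot/method pair draws from its own derived
#'   stream, so adding a spot never changes another spot's interval.
#' @param significance_rule \code{"ci_overlap"} (disjoint adjusted CIs;
#'   default) or \code{"diff_bootstrap"} (BC bootstrap of the difference in
#'   means excludes 0 at the adjusted level).
#' @param position_tol c(dx, dy): maximum displacement of the dephospho
#'   consensus position from the reference position for the matched D
#'   volume to count as "the same gel position" (default 0.01, 0.01 — the
#'   coordinate-matching tolerance).
#' @return object of class \code{pr_analysis}: list with \code{results}
#'   (long data frame, one row per spot x method), \code{settings}, and the
#'   \code{matched} input.
#' @examples
#' vols <- data.frame(spot_id = rep("s1", 3), replicate_id = c("r1","r2","r3"),
#'                    T = c(100, 110, 90), P = c(55, 60, 40),
#'                    D = c(45, 50, 40))
#' m <- matched_spots(vols, study_design())
#' fit <- phospho_rates(m, seed = 1)
#' coef(fit)
#' @export
phospho_rates <- function(matched, n_boot = 2000, conf_level = 0.95,
                          alpha = 0.05, bonferroni_m = NULL, seed = 1,
                          significance_rule = c("ci_overlap",
                                                "diff_bootstrap"),
                          position_tol = c(0.01, 0.01)) {
  stopifnot(inherits(matched, "matched_spots"))
  significance_rule <- match.arg(significance_rule)
  ids <- spot_ids(matched)
  reps <- matched$design$replicate_ids
  min_n <- matched$design$min_replicates_detected
  m <- bonferroni_m %||% length(ids)
  adj_conf <- 1 - bonferroni_level(alpha, m)

  vol <- matched$volumes
  co <- matched$coords
  rows <- vector("list", 2 * length(ids))
  signif_call <- character(length(ids))
  for (i in seq_along(ids)) {
    v <- vol[vol$spot_id == ids[i], , drop = FALSE]
    v <- v[match(reps, v$replicate_id), , drop = FALSE]
    has_T <- !is.na(v$T) & v$T > 0
    ci_ <- co[co$spot_id == ids[i], , drop = FALSE]
    shifted_away <- !is.na(ci_$x_reference) && !is.na(ci_$x_dephospho) &&
      (abs(ci_$x_dephospho - ci_$x_reference) > position_tol[1] ||
       abs(ci_$y_dephospho - ci_$y_reference) > position_tol[2])
    if (shifted_away) v$D <- NA_real_  # original position vacated
    p_detected <- apply_detection_rule(!is.na(v$P), matched$design)

    pr_h <- pr_q <- rep(NA_real_, length(reps))
    for (r in which(has_T)) {
      pr_h[r] <- pr_hfp(v$T[r], v$D[r])
      pr_q[r] <- if (p_detected) pr_proq(v$P[r], v$T[r]) else 0
    }
    if (!any(has_T)) pr_q[] <- NA_real_  # novel spot: no denominator
    # the mean of the replicate rates is "not applicable" as soon as any
    # usable replicate is (D > T): Table-2-style spot-level N/A
    if (any(has_T) && anyNA(pr_h[has_T])) pr_h[] <- NA_real_

    res_h <- spot_pr_result(ids[i], "hfp", pr_h, n_boot, adj_conf, seed)
    res_q <- spot_pr_result(ids[i], "proq", pr_q, n_boot, adj_conf, seed)
    signif_call[i] <- switch(significance_rule,
      ci_overlap = compare_methods_per_spot(res_h, res_q),
      diff_bootstrap = diff_bootstrap_call(pr_h, pr_q, ids[i], n_boot,
                                           adj_conf, seed))
    res_h$significant <- res_q$significant <- signif_call[i]
    rows[[2 * i - 1]] <- res_h
    rows[[2 * i]] <- res_q
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(
    results = results,
    settings = list(n_boot = n_boot, conf_level = conf_level, alpha = alpha,
                    bonferroni_m = m, adjusted_conf = adj_conf, seed = seed,
                    significance_rule = significance_rule,
                    replicate_ids = reps, min_replicates_detected = min_n),
    matched = matched), class = "pr_analysis")
}

#' @keywords internal
spot_pr_result <- function(spot_id, method, pr, n_boot, conf, root_seed) {
  ok <- !is.na(pr)
  mean_pr <- if (any(ok)) mean(pr[ok]) else NA_real_
  se_pr <- if (sum(ok) > 1) stats::sd(pr[ok]) / sqrt(sum(ok))
           else if (sum(ok) == 1) 0 else NA_real_
  ci <- bootstrap_ci_bc(pr, n_boot = n_boot, conf_level = conf,
                        seed = derive_seed(root_seed,
                                           paste0(spot_id, ":", method)))
  out <- data.frame(spot_id = spot_id, method = method,
                    mean_pr = mean_pr, se_pr = se_pr,
                    ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                    n_replicates = sum(ok), n_boot = n_boot,
                    significant = NA_character_, stringsAsFactors = FALSE)
  for (r in seq_along(pr)) out[[paste0("pr_rep", r)]] <- pr[r]
  out
}

# alternative rule: BC bootstrap CI of the difference of method means
# (methods resampled independently: HF-P gels are physically separate from
# the double-stained reference/phosphostain gels)
#' @keywords internal
diff_bootstrap_call <- function(pr_h, pr_q, spot_id, n_boot, conf,
                                root_seed) {
  h <- pr_h[!is.na(pr_h)]; q <- pr_q[!is.na(pr_q)]
  if (!length(h) || !length(q)) return("not_comparable")
  set.seed(derive_seed(root_seed, paste0(spot_id, ":diff")))
  bh <- colMeans(matrix(h[sample.int(length(h), length(h) * n_boot,
                                     replace = TRUE)], nrow = length(h)))
  bq <- colMeans(matrix(q[sample.int(length(q), length(q) * n_boot,
                                     replace = TRUE)], nrow = length(q)))
  ci <- ci_from_thetas(bh - bq, mean(h) - mean(q), conf, n_boot)
  if (ci[1] > 0 || ci[2] < 0) "significant" else "ns"
}

#' Method-level detection summary
#'
#' Tallies how many matched spots each method calls phosphorylated — by
#' chemical dephosphorylation (HF-P): mean PR > 0 (which includes every
#' disappeared spot, whose PR is 100); by phosphostain: mean PR > 0, i.e.
#' the phosphostain profile passed the detection rule with signal —
#' and reports the 2x2 detection table, percentages (1 decimal, half-up),
#' the HF-P/phosphostain fold ratio, and the two-tailed Fisher exact
#' p-value for the difference in detection counts.
#'
#' Spots with no rate by either method (dephospho-only novel candidates,
#' which lack the reference denominator) are excluded from the total, so
#' the denominator is the count of spots matched across the reference
#' profile, as in the study's "174 matched spots".
#'
#' @param fit a \code{pr_analysis} object.
#' @return list with \code{table} (2x2 matrix, rows hfp/proq, columns
#'   phosphorylated/not), counts, percentages, \code{fold_ratio} (NA when
#'   no phosphostain positives) and \code{fisher_p}.
#' @export
summarize_detection <- function(fit) {
  stopifnot(inherits(fit, "pr_analysis"))
  res <- fit$results
  h <- res[res$method == "hfp", ]
  q <- res[res$method == "proq", ]
  q <- q[match(h$spot_id, q$spot_id), ]
  rated <- !(is.na(h$mean_pr) & is.na(q$mean_pr))
  h <- h[rated, ]; q <- q[rated, ]
  n_total <- nrow(h)
  n_hfp <- sum(!is.na(h$mean_pr) & h$mean_pr > 0)
  n_proq <- sum(!is.na(q$mean_pr) & q$mean_pr > 0)
  tab <- matrix(c(n_hfp, n_total - n_hfp, n_proq, n_total - n_proq),
                nrow = 2, byrow = TRUE,
                dimnames = list(method = c("hfp", "proq"),
                                c("phosphorylated", "not")))
  list(table = tab, n_total = n_total,
       n_hfp_positive = n_hfp, n_proq_positive = n_proq,
       pct_hfp = round_half_up(100 * n_hfp / n_total, 1),
       pct_proq = round_half_up(100 * n_proq / n_total, 1),
       fold_ratio = if (n_proq > 0) n_hfp / n_proq else NA_real_,
       fisher_p = fisher_exact_two_tailed(tab))
}

#' @export
print.pr_analysis <- function(x, ...) {
  n <- length(unique(x$results$spot_id))
  cat("Phosphorylation-rate analysis of", n, "spots x 2 methods\n")
  cat(sprintf(
    "  bootstrap B = %d, conf = %.2f, Bonferroni m = %d (adjusted %.5f), rule = %s\n",
    x$settings$n_boot, x$settings$conf_level, x$settings$bonferroni_m,
    x$settings$adjusted_conf, x$settings$significance_rule))
  ns <- sum(x$results$significant[x$results$method == "hfp"] == "significant")
  cat("  spots with significant between-method difference:", ns, "\n")
  invisible(x)
}

#' @export
summary.pr_analysis <- function(object, ...) {
  det <- summarize_detection(object)
  h <- object$results[object$results$method == "hfp", ]
  n_sig <- sum(h$significant == "significant")
  out <- list(detection = det, n_significant = n_sig,
              pct_significant = round_half_up(100 * n_sig / det$n_total, 1),
              settings = object$settings)
  class(out) <- "summary.pr_analysis"
  out
}

#' @export
print.summary.pr_analysis <- function(x, ...) {
  d <- x$detection
  cat("Detection of phosphorylated spots (n =", d$n_total, "matched):\n")
  cat(sprintf("  HF-P (dephosphorylation): %d (%.1f%%)\n",
              d$n_hfp_positive, d$pct_hfp))
  cat(sprintf("  phosphostain:             %d (%.1f%%)\n",
              d$n_proq_positive, d$pct_proq))
  cat(sprintf("  fold ratio: %s;  Fisher two-tailed p = %.3g\n",
              ifelse(is.na(d$fold_ratio), "NA",
                     sprintf("%.2f", d$fold_ratio)), d$fisher_p))
  cat(sprintf("  spots with significant method difference: %d (%.1f%%)\n",
              x$n_significant, x$pct_significant))
  invisible(x)
}

#' @export
coef.pr_analysis <- function(object, ...) {
  res <- object$results
  ids <- unique(res$spot_id)
  cbind(hfp = res$mean_pr[res$method == "hfp"][match(ids,
          res$spot_id[res$method == "hfp"])],
        proq = res$mean_pr[res$method == "proq"][match(ids,
          res$spot_id[res$method == "proq"])]) |>
    `rownames<-`(ids)
}

#' @export
plot.pr_analysis <- function(x, ...) {
  pr <- coef(x)
  res <- x$results
  sig <- res$significant[res$method == "hfp"][match(rownames(pr),
           res$spot_id[res$method == "hfp"])]
  col <- ifelse(sig == "significant", "firebrick", "grey40")
  graphics::plot(pr[, "hfp"], pr[, "proq"],
                 xlab = "PR by chemical dephosphorylation (%)",
                 ylab = "PR by phosphostain (%)",
                 xlim = c(0, 100), ylim = c(0, 100), pch = 19, col = col, ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  graphics::legend("topleft", pch = 19, col = c("firebrick", "grey40"),
                   legend = c("significant difference", "ns"), bty = "n")
  invisible(x)
}

#' Write the per-spot results table
#'
#' CSV with one row per spot and method: replicate PRs, mean, SE, the
#' Bonferroni-adjusted bootstrap CI, and the significance call.
#'
#' @param fit a \code{pr_analysis}.
#' @param path output path.
#' @export
write_pr_table <- function(fit, path) {
  stopifnot(inherits(fit, "pr_analysis"))
  utils::write.table(fit$results, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = TRUE,
                     na = "")
  invisible(path)
}
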