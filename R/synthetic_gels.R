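#' Configuration for the synthetic 2-DE study generator
#'
#' Defaults mirror the scale of the motivating study: 174 master spots,
#' 3 biological replicates, 450 ug protein load per strip, a pH 4--7 first
#' dimension, a phosphostain detection limit of 4 ng/spot versus 1 ng/spot
#' for the total-protein stain, and roughly 13\% never-phosphorylated
#' spots.
#'
#' @param n_spots number of master protein spots (default 174).
#' @param n_replicates biological replicates (default 3).
#' @param total_load_ug protein load per gel in ug (default 450; recorded
#'   for provenance, volumes are normalized downstream so only ratios
#'   matter).
#' @param noise_sigma sd of the log-normal multiplicative replicate noise
#'   on spot volumes (natural-log scale; default 0.15).
#' @param pi_shift_per_phosphate basic pI shift per removed phosphate group
#'   in pH units (default 0.05).
#' @param saturation_cap optional ceiling on phosphostain volumes
#'   (arbitrary units), emulating ultra-saturated high-abundance spots
#'   whose phosphostain PR reads ~100; default \code{NULL} (no cap).
#' @param seed root seed; every spot derives its own stream from it.
#' @param frac_nonphospho fraction of spots with true phospho-fraction 0
#'   (default 0.13).
#' @param frac_full_phospho fraction with phospho-fraction exactly 1, the
#'   spots that disappear or shift wholesale after dephosphorylation
#'   (default 0.05).
#' @param phospho_frac_min lower bound of the uniform phospho-fraction for
#'   the remaining spots (default 0: uniform on (0, 1]); raising it
#'   separates effect sizes from the classifier thresholds.
#' @param proq_limit_ng,sypro_limit_ng per-spot detection limits of the
#'   phosphostain (4 ng) and total-protein stain (1 ng).
#' @param abundance_median_ng,abundance_log10_sd log-normal spot abundance:
#'   median 50 ng, sd 0.6 in log10, truncated to [1, 5000] ng.
#' @param gradient [ph_gradient()] of the simulated strip.
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_spots = 174, n_replicates = 3,
                             total_load_ug = 450, noise_sigma = 0.15,
                             pi_shift_per_phosphate = 0.05,
                             saturation_cap = NULL, seed = 1,
                             frac_nonphospho = 0.13,
                             frac_full_phospho = 0.05,
                             phospho_frac_min = 0,
                             proq_limit_ng = 4, sypro_limit_ng = 1,
                             abundance_median_ng = 50,
                             abundance_log10_sd = 0.6,
                             gradient = ph_gradient()) {
  stopifnot(is_count(n_spots), n_spots >= 1,
            is_count(n_replicates), n_replicates >= 2,
            total_load_ug > 0, noise_sigma >= 0,
            pi_shift_per_phosphate > 0,
            is.null(saturation_cap) || saturation_cap > 0,
            frac_nonphospho >= 0, frac_full_phospho >= 0,
            frac_nonphospho + frac_full_phospho < 1,
            phospho_frac_min >= 0, phospho_frac_min < 1,
            proq_limit_ng > 0, sypro_limit_ng > 0,
            abundance_median_ng > 0, abundance_log10_sd > 0,
            inherits(gradient, "ph_gradient"))
  structure(as.list(environment()), class = "generator_config")
}

# 1 ng of protein renders 1000 densitometric volume units (arbitrary; the
# pipeline normalizes per gel so only ratios survive)
.ng_to_volume <- 1000

#' Generate a synthetic 2-DE phosphoproteome study with known truth
#'
#' Simulates the spot-volume tables of a three-profile 2-DE study. Each
#' master spot gets a log-normal abundance, a true phospho-fraction f (the
#' estimand of both phosphorylation-rate statistics), a phosphate count,
#' and a gel position. Per replicate and profile, volumes are the
#' underlying protein mass times independent log-normal noise:
#' \itemize{
#'   \item reference: full abundance, emitted when above the total-stain
#'     limit (1 ng);
#'   \item phospho: mass abundance x f, emitted only above the
#'     phosphostain limit (4 ng) — low-abundance phosphoproteins are thus
#'     invisible to the phosphostain — optionally capped (saturation);
#'   \item dephospho: the unphosphorylated residue abundance x (1-f) stays
#'     at the reference position; the phospho-derived mass reappears
#'     shifted toward basic pI by n_phosphates x pi_shift_per_phosphate.
#'     If the residue is detectable the shifted mass forms a separate
#'     dephospho-only master (novel partner, id suffix "N"); if not, a
#'     singly-phosphorylated spot keeps its id at the shifted position
#'     (truth shifted_basic) while a multiply-phosphorylated one vanishes
#'     from its position (truth disappeared) and its mass appears as the
#'     novel partner.
#' }
#'
#' @param config a [generator_config()].
#' @param dir optional output directory; when given, one CSV per replicate
#'   and profile plus \code{truth.csv} and the design file are written
#'   (byte-identical for identical config and seed).
#' @return list with \code{records} (combined raw spot records),
#'   \code{truth} (per-master ground truth incl. \code{pattern_truth}),
#'   \code{design} (a [study_design()]), and \code{files} (paths, when
#'   \code{dir} given).
#' @export
generate_study <- function(config = generator_config(), dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  reps <- paste0("r", seq_len(config$n_replicates))
  design <- study_design(replicate_ids = reps)
  grad <- config$gradient
  span <- grad$ph_max - grad$ph_min
  width <- max(3, nchar(config$n_spots))

  rec_list <- list(); truth_list <- list()
  for (i in seq_len(config$n_spots)) {
    id <- sprintf(paste0("S%0", width, "d"), i)
    set.seed(derive_seed(config$seed, id))

    abundance <- min(max(10^stats::rnorm(1, log10(config$abundance_median_ng),
                                         config$abundance_log10_sd), 1), 5000)
    u <- stats::runif(1)
    f <- if (u < config$frac_nonphospho) 0
         else if (u < config$frac_nonphospho + config$frac_full_phospho) 1
         else config$phospho_frac_min +
              stats::runif(1) * (1 - config$phospho_frac_min)
    n_ph <- sample.int(3, 1, prob = c(0.5, 0.3, 0.2))
    pi_ref <- stats::runif(1, grad$ph_min + 0.2, grad$ph_max - 0.5)
    x_ref <- (pi_ref - grad$ph_min) / span
    y_ref <- stats::runif(1, 0.05, 0.95)
    logmr_ref <- log10(200) + y_ref * (log10(15) - log10(200))

    m_phos <- abundance * f
    m_res <- abundance * (1 - f)
    x_shift <- x_ref + n_ph * config$pi_shift_per_phosphate / span
    x_shift <- min(x_shift, 1)

    res_det <- m_res >= config$sypro_limit_ng
    shift_det <- m_phos >= config$sypro_limit_ng
    pattern <-
      if (f == 0) "unchanged"
      else if (res_det) "reduced"
      else if (shift_det && n_ph == 1) "shifted_basic"
      else "disappeared"
    novel_partner <- shift_det && f > 0 && pattern %in% c("reduced",
                                                          "disappeared")

    noise <- function() exp(stats::rnorm(1, 0, config$noise_sigma))
    rows <- list()
    for (r in reps) {
      if (abundance >= config$sypro_limit_ng)
        rows[[length(rows) + 1]] <- data.frame(
          spot_id = id, replicate_id = r, profile = "reference",
          x = x_ref, y = y_ref,
          volume = abundance * .ng_to_volume * noise())
      if (m_phos >= config$proq_limit_ng) {
        v <- m_phos * .ng_to_volume * noise()
        if (!is.null(config$saturation_cap))
          v <- min(v, config$saturation_cap)
        rows[[length(rows) + 1]] <- data.frame(
          spot_id = id, replicate_id = r, profile = "phospho",
          x = x_ref, y = y_ref, volume = v)
      }
      if (res_det)
        rows[[length(rows) + 1]] <- data.frame(
          spot_id = id, replicate_id = r, profile = "dephospho",
          x = x_ref, y = y_ref,
          volume = m_res * .ng_to_volume * noise())
      if (pattern == "shifted_basic")
        rows[[length(rows) + 1]] <- data.frame(
          spot_id = id, replicate_id = r, profile = "dephospho",
          x = x_shift, y = y_ref,
          volume = m_phos * .ng_to_volume * noise())
      if (novel_partner)
        rows[[length(rows) + 1]] <- data.frame(
          spot_id = paste0(id, "N"), replicate_id = r, profile = "dephospho",
          x = x_shift, y = y_ref,
          volume = m_phos * .ng_to_volume * noise())
    }
    rec_list[[i]] <- do.call(rbind, rows)

    truth_list[[i]] <- data.frame(
      spot_id = id, abundance_ng = abundance, phospho_frac = f,
      n_phosphates = n_ph, pi_ref = pi_ref, logmr_ref = logmr_ref,
      pattern_truth = pattern, stringsAsFactors = FALSE)
    if (novel_partner)
      truth_list[[i]] <- rbind(truth_list[[i]], data.frame(
        spot_id = paste0(id, "N"), abundance_ng = m_phos,
        phospho_frac = NA_real_, n_phosphates = 0,
        pi_ref = grad$ph_min + x_shift * span,
        logmr_ref = logmr_ref, pattern_truth = "novel",
        stringsAsFactors = FALSE))
  }
  records <- validate_spot_records(do.call(rbind, rec_list))
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(0)
    for (r in reps) for (prof in .profiles) {
      sel <- records$replicate_id == r & records$profile == prof
      p <- file.path(dir, paste0(prof, "_", r, ".csv"))
      write_spot_table(records[sel, , drop = FALSE], p)
      files <- c(files, p)
    }
    tp <- file.path(dir, "truth.csv")
    utils::write.table(truth, tp, sep = ",", row.names = FALSE,
                       col.names = TRUE, qmethod = "double", quote = TRUE,
                       na = "")
    dp <- file.path(dir, "design.txt")
    write_study_design(design, dp)
    files <- c(files, tp, dp)
  }
  list(records = records, truth = truth, design = design, files = files)
}

#' True phosphorylation rate of a synthetic spot
#'
#' The estimand both PR statistics target in the noise-free limit:
#' 100 x the generating phospho-fraction.
#'
#' @param truth the \code{truth} data frame from [generate_study()].
#' @param spot_id master spot id.
#' @return percent in [0, 100]; \code{NA} for dephospho-only novel
#'   partners, which have no reference volume and hence no rate.
#' @export
expected_pr <- function(truth, spot_id) {
  i <- match(spot_id, truth$spot_id)
  if (anyNA(i)) stop("unknown spot id: ", spot_id[is.na(i)][1])
  100 * truth$phospho_frac[i]
}
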