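# Fixture builders used across test files; everything is generated in code.

# matched_spots from per-spot volume matrices (n_spots x 3 replicates);
# NA encodes an absent volume
mk_matched <- function(Tm, Pm, Dm, design = study_design(), coords = NULL) {
  n <- nrow(Tm)
  ids <- sprintf("s%03d", seq_len(n))
  vol <- data.frame(
    spot_id = rep(ids, each = ncol(Tm)),
    replicate_id = rep(design$replicate_ids, n),
    T = as.vector(t(Tm)), P = as.vector(t(Pm)), D = as.vector(t(Dm)))
  if (!is.null(coords)) coords$spot_id <- ids
  matched_spots(vol, design, coords = coords)
}

const_mat <- function(value, n, reps = 3) {
  matrix(value, nrow = n, ncol = reps)
}

# a study realizing given per-method positive counts out of n_total spots:
# HF-P positives lose half their volume after treatment, negatives keep it
# exactly; phosphostain positives carry P = T/2, negatives have no P
detection_fixture <- function(n_total = 174, n_hfp = 152, n_proq = 44) {
  Tm <- const_mat(100, n_total)
  Dm <- const_mat(100, n_total); Dm[seq_len(n_hfp), ] <- 50
  Pm <- const_mat(NA_real_, n_total); Pm[seq_len(n_proq), ] <- 50
  mk_matched(Tm, Pm, Dm)
}

rand_spot_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    spot_id = replicate(n, paste0(sample(c(letters, ",", "\"", " "), 6,
                                         replace = TRUE), collapse = "")),
    replicate_id = sample(c("r1", "r2", "r3"), n, replace = TRUE),
    profile = sample(c("reference", "phospho", "dephospho"), n,
                     replace = TRUE),
    x = runif(n), y = runif(n),
    volume = round(rlnorm(n, 8, 1), 4),
    stringsAsFactors = FALSE)
}
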