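#' Normalize spot volumes on one gel to a fixed total density
#'
#' Each volume is replaced by \code{volume / sum(volumes) * scale}, the
#' "normalization from total density of valid spots" step of 2-DE image
#' analysis: it removes gel-to-gel differences in load and staining
#' intensity. Background subtraction is assumed already applied upstream by
#' the image-analysis software.
#'
#' @param records spot records from ONE gel (one replicate, one profile).
#' @param scale positive total the normalized volumes sum to (default 1e6).
#' @return the records with normalized volumes.
#' @export
normalize_total_density <- function(records, scale = 1e6) {
  records <- validate_spot_records(records)
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  total <- sum(records$volume)
  if (nrow(records) == 0) return(records)
  if (total <= 0) stop("cannot normalize a gel whose volumes are all zero")
  records$volume <- records$volume / total * scale
  records
}

#' Normalize every gel in a study table
#'
#' Applies [normalize_total_density()] separately to each
#' (replicate, profile) gel in a combined record table. The phosphostain and
#' total-protein images of one double-stained gel are distinct channels and
#' are normalized independently.
#'
#' @param records spot records spanning several gels.
#' @param scale per-gel normalization total.
#' @return records with per-gel normalized volumes, original order preserved.
#' @export
normalize_study <- function(records, scale = 1e6) {
  records <- validate_spot_records(records)
  if (nrow(records) == 0) return(records)
  gel <- paste(records$replicate_id, records$profile, sep = "\r")
  for (g in unique(gel)) {
    idx <- which(gel == g)
    records[idx, ] <- normalize_total_density(records[idx, , drop = FALSE],
                                              scale)
  }
  records
}

#' Replicate detection rule
#'
#' A spot counts as detected on a profile only if it is present in at least
#' \code{min_replicates_detected} biological replicates (the study's
#' "at least two of three" inclusion rule).
#'
#' @param present logical vector of per-replicate presence flags, one per
#'   replicate in the design.
#' @param design a [study_design()].
#' @return single logical.
#' @export
apply_detection_rule <- function(present, design) {
  stopifnot(inherits(design, "study_design"))
  if (length(present) != length(design$replicate_ids))
    stop("presence flags must have one entry per replicate")
  sum(present) >= design$min_replicates_detected
}

#' Assemble matched spots across the three gel profiles
#'
#' Builds one master entry per protein spot with its per-replicate
#' normalized volumes T (reference, total-protein stain), P (phosphostain)
#' and D (after chemical dephosphorylation), plus consensus coordinates per
#' profile. Two modes:
#'
#' \describe{
#'   \item{pre-matched}{every record carries a master \code{spot_id}
#'     (image-analysis software already matched the gels): records are
#'     grouped by id.}
#'   \item{coordinate}{all \code{spot_id} are empty: spots are matched by
#'     gel position with a greedy mutual-nearest-neighbour pairing within a
#'     tolerance box, each spot used at most once, ties broken by smaller
#'     Euclidean distance then input order. Reference spots anchor the
#'     master list; dephospho spots with no reference partner become novel
#'     candidates; phospho spots with no partner are dropped (they have no
#'     denominator T).}
#' }
#'
#' Masters are then filtered by the detection rule: a master is kept if its
#' reference presence passes [apply_detection_rule()], or if it has no
#' reference presence at all but its dephospho presence passes (a novel
#' candidate, a spot appearing only after dephosphorylation).
#'
#' @param records combined normalized spot records (all profiles), or a list
#'   with elements \code{reference}, \code{phospho}, \code{dephospho}.
#' @param design a [study_design()].
#' @param tolerance c(dx, dy) coordinate tolerance box for coordinate mode
#'   (default 0.01, 0.01 — about 0.03 pH units on a 4--7 strip).
#' @return object of class \code{matched_spots}: list with \code{volumes}
#'   (data frame spot_id x replicate with columns T, P, D; NA = absent),
#'   \code{coords} (per-spot consensus x/y per profile), \code{novel}
#'   (logical per spot), and the \code{design}.
#' @export
match_profiles <- function(records, design, tolerance = c(0.01, 0.01)) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  records <- validate_spot_records(records)
  if (!all(records$replicate_id %in% design$replicate_ids))
    stop("records contain replicate ids not in the design")
  has_id <- nzchar(records$spot_id)
  if (nrow(records) && any(has_id) && !all(has_id))
    stop("mixed matching mode: some records have spot ids, some are blank")
  if (nrow(records) == 0 || all(has_id)) {
    matched <- records
  } else {
    matched <- assign_master_ids(records, tolerance)
  }
  build_matched(matched, design)
}

# greedy mutual-nearest-neighbour assignment of master ids in coordinate mode;
# records are first put into a canonical order so the assignment (and the
# master ids) are invariant to input row permutations
#' @keywords internal
assign_master_ids <- function(records, tolerance) {
  records <- records[order(records$replicate_id, records$x, records$y,
                           records$volume), , drop = FALSE]
  ref <- records[records$profile == "reference", , drop = FALSE]
  pho <- records[records$profile == "phospho", , drop = FALSE]
  dep <- records[records$profile == "dephospho", , drop = FALSE]

  # cluster reference spots across replicates into masters
  masters <- data.frame(x = numeric(0), y = numeric(0), n = integer(0))
  ref$master <- rep(NA_integer_, nrow(ref))
  for (rep_id in unique(ref$replicate_id)) {
    idx <- which(ref$replicate_id == rep_id)
    pairs <- greedy_pairs(masters$x, masters$y, ref$x[idx], ref$y[idx],
                          tolerance)
    ref$master[idx[pairs$b]] <- pairs$a
    if (nrow(pairs)) {
      w <- masters$n[pairs$a]
      masters$x[pairs$a] <- (masters$x[pairs$a] * w + ref$x[idx[pairs$b]]) / (w + 1)
      masters$y[pairs$a] <- (masters$y[pairs$a] * w + ref$y[idx[pairs$b]]) / (w + 1)
      masters$n[pairs$a] <- w + 1L
    }
    new_i <- idx[setdiff(seq_along(idx), pairs$b)]
    if (length(new_i)) {
      ref$master[new_i] <- nrow(masters) + seq_along(new_i)
      masters <- rbind(masters, data.frame(x = ref$x[new_i], y = ref$y[new_i],
                                           n = 1L))
    }
  }

  # attach phospho / dephospho spots to reference masters, per replicate
  attach_profile <- function(d) {
    d$master <- rep(NA_integer_, nrow(d))
    for (rep_id in unique(d$replicate_id)) {
      idx <- which(d$replicate_id == rep_id)
      pairs <- greedy_pairs(masters$x, masters$y, d$x[idx], d$y[idx],
                            tolerance)
      d$master[idx[pairs$b]] <- pairs$a
    }
    d
  }
  pho <- attach_profile(pho)
  dep <- attach_profile(dep)

  # unmatched dephospho spots: cluster among themselves -> novel masters
  novel_base <- nrow(masters)
  un <- which(is.na(dep$master))
  if (length(un)) {
    nmast <- data.frame(x = numeric(0), y = numeric(0), n = integer(0))
    for (rep_id in unique(dep$replicate_id)) {
      idx <- un[dep$replicate_id[un] == rep_id]
      if (!length(idx)) next
      pairs <- greedy_pairs(nmast$x, nmast$y, dep$x[idx], dep$y[idx],
                            tolerance)
      dep$master[idx[pairs$b]] <- novel_base + pairs$a
      if (nrow(pairs)) {
        w <- nmast$n[pairs$a]
        nmast$x[pairs$a] <- (nmast$x[pairs$a] * w + dep$x[idx[pairs$b]]) / (w + 1)
        nmast$y[pairs$a] <- (nmast$y[pairs$a] * w + dep$y[idx[pairs$b]]) / (w + 1)
        nmast$n[pairs$a] <- w + 1L
      }
      new_i <- idx[setdiff(seq_along(idx), pairs$b)]
      if (length(new_i)) {
        dep$master[new_i] <- novel_base + nrow(nmast) + seq_along(new_i)
        nmast <- rbind(nmast, data.frame(x = dep$x[new_i], y = dep$y[new_i],
                                         n = 1L))
      }
    }
    masters <- rbind(masters, nmast)
  }

  pho <- pho[!is.na(pho$master), , drop = FALSE]  # no partner -> no T
  out <- rbind(ref, pho, dep)
  width <- max(3, nchar(nrow(masters)))
  out$spot_id <- sprintf(paste0("M%0", width, "d"), out$master)
  out$master <- NULL
  out
}

# all candidate pairs (a_i, b_j) with |dx|<=tol, |dy|<=tol, accepted greedily
# by increasing Euclidean distance (then index order); each point used once
#' @keywords internal
greedy_pairs <- function(ax, ay, bx, by, tolerance) {
  empty <- data.frame(a = integer(0), b = integer(0))
  if (!length(ax) || !length(bx)) return(empty)
  cand <- NULL
  for (j in seq_along(bx)) {
    hit <- which(abs(ax - bx[j]) <= tolerance[1] &
                 abs(ay - by[j]) <= tolerance[2])
    if (length(hit))
      cand <- rbind(cand, data.frame(
        a = hit, b = j,
        d = sqrt((ax[hit] - bx[j])^2 + (ay[hit] - by[j])^2)))
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand$d, cand$a, cand$b), , drop = FALSE]
  used_a <- logical(length(ax)); used_b <- logical(length(bx))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$a[k]] && !used_b[cand$b[k]]) {
      keep[k] <- TRUE
      used_a[cand$a[k]] <- TRUE
      used_b[cand$b[k]] <- TRUE
    }
  }
  cand[keep, c("a", "b"), drop = FALSE]
}

# group id-carrying records into the matched_spots container
#' @keywords internal
build_matched <- function(records, design) {
  reps <- design$replicate_ids
  ids <- sort(unique(records$spot_id))
  key <- paste(records$spot_id, records$replicate_id, records$profile,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate record for the same spot, replicate and profile")
  vol <- function(profile) {
    m <- matrix(NA_real_, length(ids), length(reps),
                dimnames = list(ids, reps))
    sel <- records$profile == profile
    m[cbind(match(records$spot_id[sel], ids),
            match(records$replicate_id[sel], reps))] <- records$volume[sel]
    m
  }
  Tm <- vol("reference"); Pm <- vol("phospho"); Dm <- vol("dephospho")

  cmean <- function(profile, what) {
    sel <- records$profile == profile
    v <- tapply(records[[what]][sel], records$spot_id[sel], mean)
    out <- rep(NA_real_, length(ids))
    out[match(names(v), ids)] <- as.numeric(v)
    out
  }
  coords <- data.frame(
    spot_id = ids,
    x_reference = cmean("reference", "x"), y_reference = cmean("reference", "y"),
    x_phospho   = cmean("phospho", "x"),   y_phospho   = cmean("phospho", "y"),
    x_dephospho = cmean("dephospho", "x"), y_dephospho = cmean("dephospho", "y"),
    stringsAsFactors = FALSE)

  ref_n <- rowSums(!is.na(Tm))
  dep_n <- rowSums(!is.na(Dm))
  min_n <- design$min_replicates_detected
  novel <- ref_n == 0 & dep_n >= min_n
  keep <- ref_n >= min_n | novel

  volumes <- data.frame(
    spot_id = rep(ids, each = length(reps)),
    replicate_id = rep(reps, length(ids)),
    T = as.vector(t(Tm)), P = as.vector(t(Pm)), D = as.vector(t(Dm)),
    stringsAsFactors = FALSE)
  volumes <- volumes[volumes$spot_id %in% ids[keep], , drop = FALSE]
  rownames(volumes) <- NULL
  coords <- coords[keep, , drop = FALSE]
  rownames(coords) <- NULL

  structure(list(volumes = volumes, coords = coords,
                 novel = stats::setNames(novel[keep], ids[keep]),
                 design = design),
            class = "matched_spots")
}

#' @export
print.matched_spots <- function(x, ...) {
  n <- nrow(x$coords)
  cat("Matched 2-DE spots: ", n, " master spots x ",
      length(x$design$replicate_ids), " replicates (",
      sum(x$novel), " novel candidates)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.matched_spots <- function(x, ...) x$volumes

#' Spot ids of a matched set
#' @param matched a \code{matched_spots} object.
#' @return character vector of master spot ids.
#' @export
spot_ids <- function(matched) {
  stopifnot(inherits(matched, "matched_spots"))
  matched$coords$spot_id
}

#' Write the matched-volume table
#'
#' CSV \code{spot_id, replicate_id, T, P, D}; absent volumes are empty cells.
#'
#' @param matched a \code{matched_spots} object.
#' @param path output path.
#' @export
write_matched_table <- function(matched, path) {
  stopifnot(inherits(matched, "matched_spots"))
  utils::write.table(matched$volumes, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = TRUE,
                     na = "")
  invisible(path)
}

#' Build a matched set directly from a volumes data frame
#'
#' Convenience constructor for pre-tabulated data: a data frame with columns
#' \code{spot_id, replicate_id, T, P, D} (NA for absent volumes) and an
#' optional per-spot coordinate table.
#'
#' @param volumes data frame as above.
#' @param design a [study_design()].
#' @param coords optional data frame with \code{spot_id} and any of
#'   \code{x_reference, y_reference, x_phospho, y_phospho, x_dephospho,
#'   y_dephospho}.
#' @return a \code{matched_spots} object (detection-rule filter applied).
#' @export
matched_spots <- function(volumes, design, coords = NULL) {
  need <- c("spot_id", "replicate_id", "T", "P", "D")
  if (!all(need %in% names(volumes)))
    stop("volumes needs columns ", paste(need, collapse = ", "))
  long <- NULL
  for (prof in c("reference", "phospho", "dephospho")) {
    col <- c(reference = "T", phospho = "P", dephospho = "D")[[prof]]
    sel <- !is.na(volumes[[col]])
    if (!any(sel)) next
    xc <- yc <- 0.5
    if (!is.null(coords)) {
      i <- match(volumes$spot_id[sel], coords$spot_id)
      xn <- paste0("x_", prof); yn <- paste0("y_", prof)
      if (xn %in% names(coords)) xc <- coords[[xn]][i]
      if (yn %in% names(coords)) yc <- coords[[yn]][i]
    }
    long <- rbind(long, data.frame(
      spot_id = as.character(volumes$spot_id[sel]),
      replicate_id = as.character(volumes$replicate_id[sel]),
      profile = prof,
      x = ifelse(is.na(xc), 0.5, xc), y = ifelse(is.na(yc), 0.5, yc),
      volume = volumes[[col]][sel], stringsAsFactors = FALSE))
  }
  if (is.null(long)) stop("no volumes present")
  build_matched(validate_spot_records(long), design)
}
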