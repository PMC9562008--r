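#' @name spot_io
#' @title Spot-volume table input/output
#'
#' @description
#' Spot-volume tables are the on-disk currency of the pipeline: one row per
#' detected spot per gel profile per biological replicate, as exported (after
#' renaming) from gel image-analysis software such as PDQuest. The dialect is
#' RFC-4180 CSV (or TSV) with a mandatory header naming exactly the six
#' columns \code{spot_id, replicate_id, profile, x, y, volume}.
#'
#' \itemize{
#'   \item \code{spot_id}: master spot label if gels are pre-matched, else
#'     empty (coordinate-mode matching is then used downstream).
#'   \item \code{replicate_id}: biological replicate label.
#'   \item \code{profile}: one of \code{reference} (total-protein stain,
#'     e.g. Sypro Ruby), \code{phospho} (phosphostain, e.g. Pro-Q Diamond),
#'     \code{dephospho} (total-protein stain after chemical
#'     dephosphorylation with HF-P).
#'   \item \code{x}, \code{y}: gel coordinates as fractions of strip length
#'     and gel height in [0, 1] (acidic-to-basic, top-to-bottom).
#'   \item \code{volume}: non-negative densitometric spot volume, arbitrary
#'     units. A missing spot is encoded by the absence of its row, never by
#'     volume 0; volume 0 means "detected but below quantification".
#' }
NULL

.profiles <- c("reference", "phospho", "dephospho")
.spot_cols <- c("spot_id", "replicate_id", "profile", "x", "y", "volume")

#' Validate a spot-record data frame
#'
#' Checks the column schema and the per-record invariants (volume >= 0,
#' coordinates in [0, 1], known profile label).
#'
#' @param records data frame of spot records.
#' @return the validated data frame, invisibly coerced to canonical column
#'   order and types.
#' @export
validate_spot_records <- function(records) {
  missing <- setdiff(.spot_cols, names(records))
  if (length(missing))
    stop("spot table is missing column(s): ", paste(missing, collapse = ", "))
  records <- records[, .spot_cols]
  records$spot_id <- as.character(records$spot_id)
  records$replicate_id <- as.character(records$replicate_id)
  records$profile <- as.character(records$profile)
  for (col in c("x", "y", "volume")) {
    v <- records[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v) && nrow(records))
      stop("non-numeric '", col, "' at row ",
           paste(which(is.na(v))[1], collapse = ", "))
    records[[col]] <- as.numeric(v)
  }
  bad <- which(records$volume < 0)
  if (length(bad))
    stop("negative volume at row ", bad[1])
  bad <- which(records$x < 0 | records$x > 1 | records$y < 0 | records$y > 1)
  if (length(bad))
    stop("coordinates outside [0, 1] at row ", bad[1])
  bad <- which(!records$profile %in% .profiles)
  if (length(bad))
    stop("unknown profile label '", records$profile[bad[1]], "' at row ",
         bad[1], " (expected one of: ", paste(.profiles, collapse = ", "), ")")
  rownames(records) <- NULL
  records
}

#' Read a spot-volume table
#'
#' @param path path to a CSV or TSV file with header
#'   \code{spot_id, replicate_id, profile, x, y, volume}.
#' @param sep field delimiter; \code{NULL} (default) auto-detects comma
#'   versus tab from the header line.
#' @return a validated data frame of spot records (possibly zero rows), in
#'   file order.
#' @seealso [write_spot_table()]
#' @export
read_spot_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = TRUE, comment.char = "",
                           na.strings = character(0))
  validate_spot_records(raw)
}

#' Write a spot-volume table
#'
#' Writes records so that [read_spot_table()] reproduces them field-for-field
#' (volumes at full double precision; fields containing the delimiter are
#' quoted).
#'
#' @param records validated spot records.
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @export
write_spot_table <- function(records, path, sep = ",") {
  records <- validate_spot_records(records)
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = TRUE)
  invisible(path)
}

#' Study design: replicates, detection rule, normalization scale
#'
#' @param replicate_ids ordered character vector of replicate labels
#'   (length >= 2).
#' @param min_replicates_detected minimum number of replicates a spot must
#'   be detected in to count as present on a profile (the study's
#'   "at least two of three" rule); default 2.
#' @param normalization_scale the per-gel total all normalized volumes sum
#'   to (ppm-style; default 1e6).
#' @return an object of class \code{study_design}.
#' @export
study_design <- function(replicate_ids = c("r1", "r2", "r3"),
                         min_replicates_detected = 2,
                         normalization_scale = 1e6) {
  replicate_ids <- as.character(replicate_ids)
  if (length(replicate_ids) < 2 || anyDuplicated(replicate_ids))
    stop("need >= 2 distinct replicate ids")
  if (!is_count(min_replicates_detected) || min_replicates_detected < 1 ||
      min_replicates_detected > length(replicate_ids))
    stop("min_replicates_detected must be an integer in [1, n replicates]")
  if (!is.numeric(normalization_scale) || normalization_scale <= 0)
    stop("normalization_scale must be positive")
  structure(list(replicate_ids = replicate_ids,
                 min_replicates_detected = as.integer(min_replicates_detected),
                 normalization_scale = as.numeric(normalization_scale)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design: ", length(x$replicate_ids), " replicates (",
      paste(x$replicate_ids, collapse = ", "), "); detection rule >= ",
      x$min_replicates_detected, " of ", length(x$replicate_ids),
      "; normalization scale ", format(x$normalization_scale), "\n", sep = "")
  invisible(x)
}

#' Read / write a study-design key-value file
#'
#' Plain-text config with lines \code{replicates = r1,r2,r3},
#' \code{min_replicates_detected = 2}, \code{normalization_scale = 1e6}.
#' Either \code{=} or \code{:} separates key and value; blank lines and
#' \code{#} comments are ignored.
#'
#' @param path file path.
#' @return [read_study_design()] returns a \code{study_design}.
#' @export
read_study_design <- function(path) {
  kv <- read_keyvalue(path)
  if (is.null(kv$replicates)) stop("design file lacks 'replicates'")
  study_design(
    replicate_ids = trimws(strsplit(kv$replicates, ",")[[1]]),
    min_replicates_detected =
      as.integer(kv$min_replicates_detected %||% 2),
    normalization_scale = as.numeric(kv$normalization_scale %||% 1e6))
}

#' @rdname read_study_design
#' @param design a \code{study_design} object.
#' @export
write_study_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  writeLines(c(
    paste0("replicates = ", paste(design$replicate_ids, collapse = ",")),
    paste0("min_replicates_detected = ", design$min_replicates_detected),
    paste0("normalization_scale = ", format(design$normalization_scale))),
    path)
  invisible(path)
}

# parse "key = value" / "key: value" lines into a named list of strings
#' @keywords internal
read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([^=:]+?)\\s*[=:]\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    out[[m[2]]] <- m[3]
  }
  out
}
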