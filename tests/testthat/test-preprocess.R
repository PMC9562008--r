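one_gel <- function(vols) {
  data.frame(spot_id = sprintf("s%d", seq_along(vols)), replicate_id = "r1",
             profile = "reference", x = 0.5, y = 0.5, volume = vols)
}

test_that("total-density normalization rescales a gel to the target total", {
  expect_equal(normalize_total_density(one_gel(c(10, 30, 60)), 100)$volume,
               c(10, 30, 60))
  expect_equal(normalize_total_density(one_gel(c(1, 1)), 1e6)$volume,
               c(5e5, 5e5))
  out <- normalize_total_density(one_gel(c(2, 3, 5)), 1)
  expect_equal(out$volume, c(0.2, 0.3, 0.5))
  set.seed(2)
  v <- rlnorm(200, 5, 2)
  norm <- normalize_total_density(one_gel(v), 1e6)
  expect_equal(sum(norm$volume), 1e6, tolerance = 1e-9)
  # idempotent at fixed scale
  expect_equal(normalize_total_density(norm, 1e6)$volume, norm$volume)
  expect_error(normalize_total_density(one_gel(c(0, 0)), 1), "all zero|zero")
})

test_that("study-wide normalization is per (replicate, profile) gel", {
  rec <- rbind(one_gel(c(1, 3)),
               transform(one_gel(c(10, 10)), replicate_id = "r2"),
               transform(one_gel(c(5)), profile = "phospho"))
  out <- normalize_study(rec, 100)
  expect_equal(out$volume, c(25, 75, 50, 50, 100))
})

test_that("the replicate detection rule is a simple count threshold", {
  d <- study_design(c("r1", "r2", "r3"), 2)
  expect_true(apply_detection_rule(c(TRUE, TRUE, FALSE), d))
  expect_false(apply_detection_rule(c(TRUE, FALSE, FALSE), d))
  expect_true(apply_detection_rule(c(TRUE, TRUE, TRUE), d))
  expect_error(apply_detection_rule(c(TRUE, TRUE), d), "one entry per")
})

test_that("pre-matched tables group by id and honour the detection filter", {
  des <- study_design()
  rec <- NULL
  for (r in c("r1", "r2", "r3")) for (id in c("s1", "s2"))
    for (p in c("reference", "phospho", "dephospho"))
      rec <- rbind(rec, data.frame(spot_id = id, replicate_id = r,
                                   profile = p, x = 0.5, y = 0.5,
                                   volume = 10))
  # s3 present in only one reference replicate -> filtered out
  rec <- rbind(rec, data.frame(spot_id = "s3", replicate_id = "r1",
                               profile = "reference", x = 0.2, y = 0.2,
                               volume = 5))
  m <- match_profiles(rec, des)
  expect_setequal(spot_ids(m), c("s1", "s2"))
  v <- m$volumes
  expect_true(all(!is.na(v$T) & !is.na(v$P) & !is.na(v$D)))
})

test_that("mixed id/blank input is rejected as ambiguous", {
  rec <- data.frame(spot_id = c("s1", ""), replicate_id = "r1",
                    profile = "reference", x = c(0.1, 0.9), y = 0.5,
                    volume = 1)
  expect_error(match_profiles(rec, study_design()), "mixed matching mode")
})

test_that("coordinate matching pairs within tolerance and flags novel spots", {
  des <- study_design()
  base <- expand.grid(replicate_id = c("r1", "r2", "r3"),
                      i = 1:3, stringsAsFactors = FALSE)
  ref <- data.frame(spot_id = "", replicate_id = base$replicate_id,
                    profile = "reference", x = 0.1 * base$i, y = 0.5,
                    volume = 100)
  # dephospho partner of spot 1 sits 0.001 away (inside the 0.01 box);
  # an extra dephospho-only spot lives far from any reference spot
  dep <- data.frame(spot_id = "", replicate_id = base$replicate_id,
                    profile = "dephospho", x = 0.1 * base$i + 0.001, y = 0.5,
                    volume = 60)
  novel <- data.frame(spot_id = "", replicate_id = c("r1", "r2", "r3"),
                      profile = "dephospho", x = 0.9, y = 0.9, volume = 30)
  m <- match_profiles(rbind(ref, dep, novel), des)
  expect_equal(length(spot_ids(m)), 4)
  expect_equal(sum(m$novel), 1)
  nov_id <- names(m$novel)[m$novel]
  v <- m$volumes
  expect_true(all(is.na(v$T[v$spot_id == nov_id])))
  expect_true(all(v$D[v$spot_id == nov_id] == 30))
  matched_ids <- setdiff(spot_ids(m), nov_id)
  expect_true(all(!is.na(v$T[v$spot_id %in% matched_ids])))
  expect_true(all(v$D[v$spot_id %in% matched_ids] == 60))
})

test_that("matching is injective and invariant to input row order", {
  des <- study_design()
  set.seed(9)
  n <- 25
  xs <- runif(n, 0.05, 0.95); ys <- runif(n, 0.05, 0.95)
  rec <- NULL
  for (r in c("r1", "r2", "r3")) {
    rec <- rbind(rec,
      data.frame(spot_id = "", replicate_id = r, profile = "reference",
                 x = xs + runif(n, -0.003, 0.003),
                 y = ys + runif(n, -0.003, 0.003), volume = rlnorm(n, 4, 1)),
      data.frame(spot_id = "", replicate_id = r, profile = "dephospho",
                 x = xs + runif(n, -0.003, 0.003),
                 y = ys + runif(n, -0.003, 0.003), volume = rlnorm(n, 4, 1)))
  }
  m1 <- match_profiles(rec, des)
  m2 <- match_profiles(rec[sample(nrow(rec)), ], des)
  key <- function(m) {
    v <- m$volumes[order(m$volumes$spot_id, m$volumes$replicate_id), ]
    paste(round(v$T, 9), round(v$D, 9), collapse = "|")
  }
  expect_identical(key(m1), key(m2))
  # injectivity: total matched volumes never exceed input spot counts
  expect_lte(sum(!is.na(m1$volumes$T)), sum(rec$profile == "reference"))
  expect_lte(sum(!is.na(m1$volumes$D)), sum(rec$profile == "dephospho"))
})

test_that("matched tables are written with empty cells for absent volumes", {
  m <- detection_fixture(5, 3, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_matched_table(m, path)
  txt <- readLines(path)
  expect_match(txt[1], "spot_id.*replicate_id.*T.*P.*D")
  expect_equal(length(txt), 16)
  expect_true(any(grepl(",,", txt)))  # absent P on non-phospho spots
})
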