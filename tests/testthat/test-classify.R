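make_results <- function(site_id, condition, summary_log2fc, fdr) {
  data.frame(site_id = site_id, condition = condition,
             summary_log2fc = summary_log2fc, fdr = fdr,
             stringsAsFactors = FALSE)
}

test_that("threshold calibration rounds outward and admits every control", {
  res <- make_results(c("s1", "s2", "s3"), "BRAFi",
                      c(-1.3, -0.9, -0.72), c(0.01, 0.04, 0.09))
  th <- calibrate_thresholds(res, c("s1", "s2", "s3"))
  expect_equal(th$log2fc_down, -0.7)
  expect_equal(th$fdr_call, 0.1)
  expect_equal(th$fdr_specific, 0.05)
  expect_equal(th$log2fc_up, 0.7)
  expect_equal(attr(th, "raw_log2fc"), -0.72)
  expect_equal(attr(th, "raw_fdr"), 0.09)
  # every control passes the strict calls at the calibrated thresholds
  calls <- call_modulation(res, th)
  expect_true(all(calls$call == "down"))

  # single deep control: log2FC kept at its own grid value, tiny FDR
  # still rounds up to the 0.1 grid minimum
  res2 <- make_results("s1", "MEKi", -2.0, 0.001)
  th2 <- calibrate_thresholds(res2, "s1")
  expect_equal(th2$log2fc_down, -2.0)
  expect_equal(th2$fdr_call, 0.1)

  # a control sitting exactly on the grid calibrates to its own value; the
  # strict "<" then leaves that boundary control uncalled
  res3 <- make_results(c("a", "b"), "ERKi", c(-0.7, -1.1), c(0.02, 0.03))
  th3 <- calibrate_thresholds(res3, c("a", "b"))
  expect_equal(th3$log2fc_down, -0.7)
  expect_equal(call_modulation(res3, th3)$call, c("unchanged", "down"))

  expect_error(calibrate_thresholds(res, character()),
               class = "phosfx_calibration_error")
  expect_error(calibrate_thresholds(res, c("s1", "missing_site")),
               "missing_site", class = "phosfx_calibration_error")
})

test_that("modulation calls use strict inequalities at the cutoffs", {
  th <- threshold_set()
  res <- make_results(paste0("s", 1:6), "BRAFi",
                      c(-1.0, -0.7, -2.0, 1.0, 0.7, NA),
                      c(0.05, 0.05, 0.20, 0.05, 0.05, NA))
  calls <- call_modulation(res, th)$call
  expect_equal(calls[1], "down")
  expect_equal(calls[2], "unchanged")  # log2FC exactly -0.7 fails the strict "<"
  expect_equal(calls[3], "unchanged")  # FDR above the cutoff
  expect_equal(calls[4], "up")
  expect_equal(calls[5], "unchanged")  # log2FC exactly +0.7 fails the strict ">"
  expect_true(is.na(calls[6]))
})

test_that("threshold sets validate their ordering constraints", {
  expect_error(threshold_set(log2fc_down = 0.2), class = "phosfx_input_error")
  expect_error(threshold_set(fdr_specific = 0.2, fdr_call = 0.1),
               class = "phosfx_input_error")
})

test_that("effector classes match an exhaustive per-site oracle on the call lattice", {
  th <- threshold_set()
  conds <- c("BRAFi", "MEKi", "ERKi")
  # representative per-condition states: strongly down (passes the specific
  # cut), weakly down (called but above fdr_specific), up, unchanged, NA
  states <- list(
    down_strong = list(fc = -1.2, fdr = 0.01, call = "down"),
    down_weak   = list(fc = -0.9, fdr = 0.07, call = "down"),
    up          = list(fc = 1.2,  fdr = 0.01, call = "up"),
    unchanged   = list(fc = 0.1,  fdr = 0.80, call = "unchanged"),
    missing     = list(fc = NA,   fdr = NA,   call = NA)
  )
  grid <- expand.grid(s1 = names(states), s2 = names(states),
                      s3 = names(states), stringsAsFactors = FALSE)
  rows <- list(); expected <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    st <- lapply(unlist(grid[i, ]), function(nm) states[[nm]])
    names(st) <- conds
    id <- sprintf("site%03d", i)
    rows[[i]] <- data.frame(
      site_id = id, condition = conds,
      summary_log2fc = vapply(st, `[[`, 0, "fc"),
      fdr = vapply(st, `[[`, 0, "fdr"),
      call = vapply(st, function(x) as.character(x$call), ""),
      stringsAsFactors = FALSE
    )
    cl <- vapply(st, function(x) as.character(x$call), "")
    expected[i] <- oracle_classify_one(
      cl, vapply(st, `[[`, 0, "fdr"), vapply(st, `[[`, 0, "fc"), th)
  }
  calls <- do.call(rbind, rows)
  got <- classify_effectors(calls, th)
  expect_equal(got$class[match(sprintf("site%03d", seq_len(nrow(grid))),
                               got$site_id)],
               expected)
  # spot checks of the headline patterns
  pick <- function(a, b, c) {
    i <- which(grid$s1 == a & grid$s2 == b & grid$s3 == c)
    expected[i]
  }
  expect_equal(pick("down_strong", "down_strong", "down_strong"), "shared_effector")
  expect_equal(pick("down_weak", "down_weak", "down_weak"), "shared_effector")
  expect_equal(pick("down_strong", "unchanged", "unchanged"), "specific:BRAFi")
  expect_equal(pick("down_weak", "down_weak", "unchanged"), "partial")
  expect_equal(pick("down_strong", "down_strong", "missing"), "partial")
  expect_equal(pick("unchanged", "unchanged", "unchanged"), "none")
  expect_equal(pick("missing", "missing", "missing"), "none")
})

test_that("classification is an exhaustive partition and shared is the down intersection", {
  th <- threshold_set()
  set.seed(41)
  conds <- c("BRAFi", "MEKi", "ERKi")
  n <- 300
  calls <- do.call(rbind, lapply(conds, function(cond) {
    fc <- rnorm(n, -0.5, 0.8)
    fdr <- runif(n)
    make_results(sprintf("s%03d", 1:n), cond, fc, fdr)
  }))
  calls <- call_modulation(calls, th)
  cl <- classify_effectors(calls, th)
  expect_equal(sort(cl$site_id), sort(sprintf("s%03d", 1:n)))
  expect_true(all(cl$class %in% c("shared_effector", "partial", "none") |
                    startsWith(cl$class, "specific:")))
  # set-algebra oracle: shared set = intersection of per-condition down sets
  downs <- lapply(conds, function(cc)
    calls$site_id[calls$condition == cc & !is.na(calls$call) & calls$call == "down"])
  expect_setequal(cl$site_id[cl$class == "shared_effector"],
                  Reduce(intersect, downs))
  # monotonicity: relaxing fdr_call only grows the per-condition down set
  th_loose <- threshold_set(fdr_call = 0.3, fdr_specific = 0.05)
  loose <- call_modulation(calls[, setdiff(names(calls), "call")], th_loose)
  expect_true(all(calls$site_id[!is.na(calls$call) & calls$call == "down"] %in%
                    loose$site_id[!is.na(loose$call) & loose$call == "down"]))
})

test_that("strict_other_condition tightens specific-effector selection", {
  th <- threshold_set()
  conds <- c("BRAFi", "MEKi", "ERKi")
  # down-called under BRAFi only, but MEKi log2FC is below the down cutoff
  # (just not significant): specific by default, not under the strict rule
  calls <- data.frame(
    site_id = "s1", condition = conds,
    summary_log2fc = c(-1.2, -0.9, 0.0),
    fdr = c(0.01, 0.5, 0.9),
    call = c("down", "unchanged", "unchanged"),
    stringsAsFactors = FALSE
  )
  expect_equal(classify_effectors(calls, th)$class, "specific:BRAFi")
  expect_equal(classify_effectors(calls, th, strict_other_condition = TRUE)$class,
               "partial")
})
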