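mk_groups <- function(values_by_trial) {
  do.call(rbind, lapply(names(values_by_trial), function(g) {
    data.frame(participant = "S01", trial = g, repetition = 1,
               walkingSegment = 1, measure = "yaw_slope",
               value = values_by_trial[[g]])
  }))
}

test_that("variance tests behave under the null and under inflation", {
  set.seed(11)
  null_ok <- 0; het_ok <- 0
  for (i in 1:100) {
    g <- lapply(gait_conditions(), function(x) rnorm(50))
    names(g) <- gait_conditions()
    at <- assumption_tests(mk_groups(g))
    if (at$bartlett$p.value > 0.05) null_ok <- null_ok + 1
    g$RED <- g$RED * 5
    at2 <- assumption_tests(mk_groups(g))
    if (at2$levene$p.value < 0.05) het_ok <- het_ok + 1
  }
  expect_gte(null_ok, 90)
  expect_gte(het_ok, 95)
})

test_that("degenerate constant groups are flagged without crashing", {
  g <- list(baseline = rep(1, 5), supine = rep(1, 5), RED = rep(2, 5),
            LED = rnorm(5))
  at <- assumption_tests(mk_groups(g))
  expect_setequal(at$degenerate, c("baseline", "supine", "RED"))
  expect_true(is.na(at$bartlett$p.value))
  expect_error(assumption_tests(mk_groups(list(baseline = 1:2))), ">= 3")
})

test_that("extreme points beyond 3xIQR are removed, fence-exact retained", {
  x <- c(1, 2, 3, 4, 100)
  # oracle fences by hand: q1 = 2, q3 = 4, iqr = 2 -> keep [-4, 10]
  q <- unname(quantile(x, c(0.25, 0.75)))
  expect_equal(q, c(2, 4))
  expect_equal(remove_extremes(x), c(1, 2, 3, 4))
  # all inside 1.5xIQR: unchanged
  y <- c(2, 3, 4, 5, 6)
  expect_equal(remove_extremes(y), y)
  # boundary: the group {1,2,3,4,F} has q1 = 2, q3 = 4 whenever F >= 4, so
  # its upper fence sits at 10: a point exactly there is retained, one just
  # beyond is not
  expect_true(10 %in% remove_extremes(c(1, 2, 3, 4, 10)))
  expect_false(10.001 %in% remove_extremes(c(1, 2, 3, 4, 10.001)))
  # idempotence
  set.seed(2)
  v <- c(rnorm(40), 25, -30)
  expect_identical(remove_extremes(remove_extremes(v)), remove_extremes(v))
  expect_identical(remove_extremes(numeric(0)), numeric(0))
})

test_that("a balanced noiseless table yields EMMs equal to cell means", {
  d <- simulate_measures_study(n_subjects = 6, n_reps = 2,
                               between_subject_sd = 0, residual_sd = 0,
                               cop_between_sd = 0, cop_residual_sd = 0,
                               seed = 1)
  m <- suppressWarnings(fit_lme(d, "yaw_slope"))
  expect_true(m$singular)
  em <- emm_table(m)
  cond_yaw <- c(baseline = 0.1, supine = 0.2, RED = -0.4, LED = 0.6)
  for (i in seq_len(nrow(em))) {
    expect_equal(em$emmean[i], unname(cond_yaw[as.character(em$trial[i])]),
                 tolerance = 1e-6)
  }
})

test_that("the mixed model recovers injected pairwise condition offsets", {
  d <- simulate_measures_study(n_subjects = 25, n_reps = 3, seed = 42)
  m <- fit_lme(d, "yaw_slope")
  pw <- pairwise_emm(m, ws = 1)
  expect_equal(nrow(pw), 6)               # C(4,2) contrasts
  truth <- c(baseline = 0.1, supine = 0.2, RED = -0.4, LED = 0.6)
  for (i in seq_len(nrow(pw))) {
    pair <- strsplit(as.character(pw$contrast[i]), " - ")[[1]]
    expect_equal(pw$estimate[i], unname(truth[pair[1]] - truth[pair[2]]),
                 tolerance = 0.1, ignore_attr = TRUE)
  }
  # adjusted p never below unadjusted p
  all_pw <- pairwise_emm(m)
  expect_true(all(all_pw$p.value >= all_pw$p.unadjusted - 1e-12))
  # Tukey adjustment is monotone in the unadjusted p within each family
  for (w in 1:3) {
    fam <- all_pw[all_pw$walkingSegment == w, ]
    o <- order(fam$p.unadjusted)
    expect_true(all(diff(fam$p.value[o]) >= -1e-9))
  }
})

test_that("baseline correction subtracts per-subject baseline means", {
  d <- expand.grid(participant = c("S01", "S02"),
                   trial = gait_conditions(), repetition = 1:3,
                   walkingSegment = 1, stringsAsFactors = FALSE)
  d$measure <- "yaw_slope"
  d$value <- ifelse(d$trial == "baseline", 0.1, 0.4)
  bc <- baseline_correct(d)
  expect_equal(bc$value, rep(0.3, nrow(bc)))
  expect_equal(nrow(bc), 2 * 3)          # subjects x adaptation conditions
  # condition identical to baseline -> zero
  d$value <- 0.1
  expect_true(all(baseline_correct(d)$value == 0))
  # full design: 25 subjects x 3 conditions x 2 measures
  full <- simulate_measures_study(seed = 9)
  bcf <- baseline_correct(full)
  expect_equal(sum(bcf$measure == "yaw_slope"), 75)
  expect_equal(sum(bcf$measure == "cop_sym"), 75)
  # a subject without baseline rows is excluded and reported
  d2 <- full[!(full$participant == "S01" & full$trial == "baseline"), ]
  bc2 <- baseline_correct(d2)
  expect_equal(attr(bc2, "excluded"), "S01")
  expect_false("S01" %in% bc2$participant)
})

test_that("correlation is Pearson with exact and null behaviour", {
  x <- seq(-1, 1, length.out = 20)
  corrected <- rbind(
    data.frame(participant = sprintf("S%02d", 1:20), trial = "supine",
               measure = "yaw_slope", value = x),
    data.frame(participant = sprintf("S%02d", 1:20), trial = "supine",
               measure = "cop_sym", value = -2 * x))
  cr <- correlate_measures(corrected)
  expect_equal(cr$r, -1, tolerance = 1e-12)
  expect_equal(cr$n, 20)
  # degenerate input errors
  corrected$value[corrected$measure == "cop_sym"] <- 1
  expect_error(correlate_measures(corrected), "zero variance")
  # independent noise at n = 75 rarely looks correlated
  set.seed(3)
  ok <- 0
  for (i in 1:100) {
    r <- cor(rnorm(75), rnorm(75))
    if (abs(r) < 0.3) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("cell-wise extreme-point filtering preserves table structure", {
  d <- simulate_measures_study(n_subjects = 10, n_reps = 2, seed = 4)
  d$value[1] <- 50                       # gross outlier in one cell
  f <- filter_extremes(d)
  expect_gte(attr(f, "n_removed"), 1L)
  expect_false(50 %in% f$value)
  expect_identical(names(f), names(d))
})
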