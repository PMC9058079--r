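#' Variance-homogeneity and normality checks of a study table
#'
#' Bartlett's and Levene's tests of equal variance across conditions, and
#' Shapiro-Wilk normality per condition group. Purely descriptive: the
#' report does not gate any downstream analysis.
#'
#' @param table a `StudyTable` data frame (columns `participant`, `trial`,
#'   `repetition`, `walkingSegment`, `measure`, `value`).
#' @param measure which measure to test (`"yaw_slope"` or `"cop_sym"`).
#' @return list with `bartlett` (statistic, p), `levene` (statistic, p),
#'   `shapiro` (per-group data frame), `degenerate` (character vector of
#'   zero-variance groups).
#' @export
assumption_tests <- function(table, measure = "yaw_slope") {
  d <- table[table$measure == measure & !is.na(table$value), ]
  d$trial <- factor(d$trial)
  counts <- table(d$trial)
  if (any(counts < 3)) stop("need >= 3 observations per group", call. = FALSE)
  vars <- tapply(d$value, d$trial, stats::var)
  degenerate <- names(vars)[vars == 0]
  bt <- lv <- list(statistic = NA_real_, p.value = NA_real_)
  if (length(degenerate) == 0) {
    b <- stats::bartlett.test(value ~ trial, data = d)
    bt <- list(statistic = unname(b$statistic), p.value = b$p.value)
    l <- car::leveneTest(value ~ trial, data = d)
    lv <- list(statistic = l[1, "F value"], p.value = l[1, "Pr(>F)"])
  }
  shapiro <- do.call(rbind, lapply(levels(d$trial), function(g) {
    v <- d$value[d$trial == g]
    if (stats::var(v) == 0) {
      data.frame(trial = g, W = NA_real_, p.value = NA_real_)
    } else {
      s <- stats::shapiro.test(v)
      data.frame(trial = g, W = unname(s$statistic), p.value = s$p.value)
    }
  }))
  list(bartlett = bt, levene = lv, shapiro = shapiro,
       degenerate = degenerate)
}

#' Drop extreme points from one analysis cell
#'
#' Points farther than 3 x IQR beyond the quartiles of their own group
#' (one condition x walking-segment cell) are classified as extreme and
#' disregarded. Points exactly on the 3 x IQR fence are retained. The
#' operation is idempotent: the fences are computed once from the input
#' group, not re-estimated after removal.
#'
#' @param values numeric vector (one trial x WS cell).
#' @return the values with extreme points removed; `NA`s are preserved.
#' @export
remove_extremes <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 4) return(values)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 3 * iqr
  hi <- q[2] + 3 * iqr
  keep <- is.na(values) | (values >= lo & values <= hi)
  values[keep]
}

# Apply remove_extremes per trial x walkingSegment cell of a StudyTable.
filter_extremes <- function(table) {
  key <- interaction(table$measure, table$trial, table$walkingSegment,
                     drop = TRUE)
  drop <- rep(FALSE, nrow(table))
  for (g in levels(key)) {
    i <- which(key == g)
    v <- table$value[i]
    ok <- !is.na(v)
    if (sum(ok) < 4) next
    q <- stats::quantile(v[ok], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    drop[i] <- ok & (v < q[1] - 3 * iqr | v > q[2] + 3 * iqr)
  }
  out <- table[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Fit the study-level linear mixed-effects model
#'
#' Models one measure as `value ~ trial * walkingSegment` (both factors,
#' with interaction: any adaptation effect may decay over segments) with
#' random intercepts for participant and for walking segment nested within
#' participant (the decay takes different lengths of time for different
#' subjects). Fitting uses `nlme::lme`; degrees of freedom for downstream
#' contrasts use emmeans' containment method, which is recorded in the
#' result.
#'
#' @param table a `StudyTable` data frame; extreme points should already be
#'   removed (see [filter_extremes()]).
#' @param measure which measure to model.
#' @return list of class `gait_lme`: `fit` (the `lme` object), `data`,
#'   `measure`, `emm` (estimated marginal means per trial x WS),
#'   `singular` (logical: any variance component collapsed to ~0),
#'   `df_method`.
#' @export
fit_lme <- function(table, measure = "yaw_slope") {
  d <- table[table$measure == measure & !is.na(table$value), , drop = FALSE]
  stopifnot(nrow(d) > 0)
  d$trial <- factor(d$trial, levels = intersect(gait_conditions(),
                                                unique(d$trial)))
  d$walkingSegment <- factor(d$walkingSegment)
  d$participant <- factor(d$participant)
  fit <- tryCatch(
    nlme::lme(value ~ trial * walkingSegment,
              random = ~ 1 | participant / walkingSegment, data = d,
              control = nlme::lmeControl(returnObject = TRUE)),
    error = function(e) {
      nlme::lme(value ~ trial * walkingSegment,
                random = ~ 1 | participant / walkingSegment, data = d,
                control = nlme::lmeControl(opt = "optim",
                                           returnObject = TRUE))
    })
  vc <- suppressWarnings(nlme::VarCorr(fit))
  sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  singular <- any(sds[is.finite(sds)] < 1e-6)
  if (singular) {
    warning("singular fit: a variance component is effectively zero",
            call. = FALSE)
  }
  emm <- emmeans::emmeans(fit, ~ trial | walkingSegment, data = d)
  structure(list(fit = fit, data = d, measure = measure, emm = emm,
                 singular = singular, df_method = "containment"),
            class = "gait_lme")
}

#' Estimated marginal means of a fitted study model
#'
#' @param model a `gait_lme` from [fit_lme()].
#' @return data frame of EMMs per trial x walking segment.
#' @export
emm_table <- function(model) {
  as.data.frame(summary(model$emm))
}

#' Significance stars at conventional cutoffs
#' @param p numeric p-values.
#' @return character vector: `***` p < 0.001, `**` < 0.01, `*` < 0.05,
#'   `ns` otherwise.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Tukey-adjusted pairwise condition contrasts at one walking segment
#'
#' All C(4,2) = 6 pairwise condition contrasts of the estimated marginal
#' means at the requested walking segment, with Tukey-family multiplicity
#' adjustment.
#'
#' @param model a `gait_lme` from [fit_lme()].
#' @param ws walking-segment index (1-3), or `NULL` for all segments.
#' @return `ContrastResult` data frame: `contrast`, `walkingSegment`,
#'   `estimate`, `SE`, `df`, `p.value` (Tukey-adjusted),
#'   `p.unadjusted`, `stars`.
#' @export
pairwise_emm <- function(model, ws = NULL) {
  adj <- as.data.frame(summary(emmeans::contrast(
    model$emm, method = "pairwise", adjust = "tukey")))
  raw <- as.data.frame(summary(emmeans::contrast(
    model$emm, method = "pairwise", adjust = "none")))
  adj$p.unadjusted <- raw$p.value
  adj$p.value <- pmax(adj$p.value, adj$p.unadjusted)
  adj$stars <- p_stars(adj$p.value)
  adj$walkingSegment <- as.integer(as.character(adj$walkingSegment))
  if (!is.null(ws)) adj <- adj[adj$walkingSegment == ws, , drop = FALSE]
  rownames(adj) <- NULL
  adj[, c("contrast", "walkingSegment", "estimate", "SE", "df",
          "p.value", "p.unadjusted", "stars")]
}

#' Baseline-corrected per-subject condition averages
#'
#' For the yaw-CoP correlation the first walking segment's values are
#' averaged over the repetitions of each condition per subject, and the
#' subject's baseline average is subtracted, leaving one corrected point
#' per subject x adaptation condition (supine, RED, LED) per measure.
#' Subjects without baseline data are excluded and reported.
#'
#' @param table a `StudyTable` data frame.
#' @param ws walking segment to use (default 1).
#' @return data frame `participant`, `trial`, `measure`, `value`
#'   (baseline-corrected mean); attribute `excluded` lists subjects
#'   lacking a baseline mean.
#' @export
baseline_correct <- function(table, ws = 1) {
  d <- table[table$walkingSegment == ws & !is.na(table$value), ,
             drop = FALSE]
  agg <- stats::aggregate(value ~ participant + trial + measure, data = d,
                          FUN = mean)
  base <- agg[agg$trial == "baseline", c("participant", "measure", "value")]
  names(base)[3] <- "baseline"
  out <- merge(agg[agg$trial != "baseline", ], base,
               by = c("participant", "measure"))
  out$value <- out$value - out$baseline
  out$baseline <- NULL
  have_base <- unique(base$participant)
  excluded <- setdiff(unique(agg$participant), have_base)
  out <- out[order(out$measure, out$participant, out$trial),
             c("participant", "trial", "measure", "value")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Pearson correlation between corrected yaw slope and CoP symmetry
#'
#' @param corrected output of [baseline_correct()], containing both
#'   measures; pairs are matched on (participant, trial).
#' @return list `r`, `p.value`, `n`, `conf.int`.
#' @export
correlate_measures <- function(corrected) {
  yaw <- corrected[corrected$measure == "yaw_slope", ]
  cop <- corrected[corrected$measure == "cop_sym", ]
  m <- merge(yaw, cop, by = c("participant", "trial"),
             suffixes = c("_yaw", "_cop"))
  m <- m[stats::complete.cases(m[, c("value_yaw", "value_cop")]), ]
  if (nrow(m) < 3) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::var(m$value_yaw) == 0 || stats::var(m$value_cop) == 0) {
    stop("zero variance in one of the measures", call. = FALSE)
  }
  ct <- stats::cor.test(m$value_yaw, m$value_cop, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = nrow(m),
       conf.int = as.numeric(ct$conf.int))
}
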