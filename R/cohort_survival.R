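# Bulk meta-cohort harmonization and survival stratification.

#' Harmonize bulk cohorts across batches
#'
#' Intersects gene universes, quantile-normalizes samples within each
#' batch, then standardizes each gene within batch to the pooled mean and
#' variance (a ComBat-like location/scale adjustment without empirical-
#' Bayes shrinkage). Batch labels are retained.
#'
#' @param cohorts list of samples x genes matrices (symbol column names),
#'   or a single matrix with `batch` giving per-sample batches.
#' @param batch per-sample batch labels when `cohorts` is one matrix;
#'   ignored otherwise (list names become batches).
#' @return list with `expr` (pooled samples x shared genes) and `batch`.
#' @export
harmonize_batches <- function(cohorts, batch = NULL) {
  if (is.matrix(cohorts) || is.data.frame(cohorts)) {
    if (is.null(batch)) stop_cfg("supply per-sample batch labels")
    m <- as.matrix(cohorts)
    cohorts <- lapply(split(seq_len(nrow(m)), batch),
                      function(ix) m[ix, , drop = FALSE])
  }
  shared <- Reduce(intersect, lapply(cohorts, colnames))
  if (!length(shared)) stop_cfg("empty gene intersection across cohorts")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("batch", seq_along(cohorts))
  qn <- lapply(cohorts, function(x) {
    x <- as.matrix(x)[, shared, drop = FALSE]
    # quantile normalization expects genes x samples
    t(limma::normalizeQuantiles(t(x)))
  })
  pooled <- do.call(rbind, qn)
  mu_p <- colMeans(pooled)
  sd_p <- apply(pooled, 2, sd)
  sd_p[sd_p == 0] <- 1
  adj <- lapply(qn, function(x) {
    mu_b <- colMeans(x)
    sd_b <- apply(x, 2, sd)
    sd_b[sd_b == 0] <- 1
    sweep(sweep(x, 2, mu_b, "-"), 2, sd_b, "/") * rep(sd_p, each = nrow(x)) +
      rep(mu_p, each = nrow(x))
  })
  expr <- do.call(rbind, adj)
  batch_out <- rep(names(cohorts), vapply(qn, nrow, 0L))
  list(expr = expr, batch = batch_out)
}

#' Cox regression, Kaplan-Meier curves and log-rank test by group
#'
#' Cox proportional hazards (Efron ties) with a configurable reference
#' group, per-group hazard ratios with 95% CI and Wald p; Kaplan-Meier
#' estimator with Greenwood confidence bands; log-rank test across groups.
#' Five-year analyses use `horizon = 60` months of administrative
#' censoring.
#'
#' @param time survival time in months (> 0).
#' @param event event indicator in {0, 1}.
#' @param group per-sample group labels (>= 2 groups).
#' @param reference reference group (e.g. "intestinal").
#' @param horizon optional administrative censoring time in months.
#' @return list with `hr` (data.frame: group, HR, lower, upper, wald_p),
#'   `logrank_p`, `km` (data.frame of per-group survival curves), `fit`
#'   (the coxph object), `zero_event_groups` (flagged).
#' @export
fit_cox_km <- function(time, event, group, reference = NULL, horizon = NULL) {
  if (any(time <= 0)) stop_cfg("survival times must be > 0")
  if (!all(event %in% c(0, 1))) stop_cfg("event must be 0/1")
  g <- factor(group)
  if (nlevels(g) < 2L) stop_cfg("need >= 2 groups")
  if (sum(event) < 1L) stop_cfg("need >= 1 event")
  if (!is.null(horizon)) {
    event <- ifelse(time > horizon, 0L, event)
    time <- pmin(time, horizon)
  }
  if (!is.null(reference)) g <- stats::relevel(g, ref = reference)
  ev_by_g <- tapply(event, g, sum)
  zero_ev <- names(ev_by_g)[ev_by_g == 0]

  fit <- survival::coxph(survival::Surv(time, event) ~ g, ties = "efron")
  sm <- summary(fit)
  hr <- data.frame(group = sub("^g", "", rownames(sm$coefficients)),
                   HR = sm$conf.int[, "exp(coef)"],
                   lower = sm$conf.int[, "lower .95"],
                   upper = sm$conf.int[, "upper .95"],
                   wald_p = sm$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  sd_test <- survival::survdiff(survival::Surv(time, event) ~ g)
  logrank_p <- pchisq(sd_test$chisq, df = nlevels(g) - 1L, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ g,
                          conf.type = "log")  # Greenwood SE under log transform
  km <- data.frame(time = sf$time, surv = sf$surv, lower = sf$lower,
                   upper = sf$upper, n_risk = sf$n.risk,
                   group = rep(sub("^g=", "", names(sf$strata)),
                               sf$strata))
  list(hr = hr, logrank_p = logrank_p, km = km, fit = fit,
       zero_event_groups = zero_ev)
}

#' Association between two per-sample score vectors
#'
#' Pearson correlation with p, plus a median split of score A into
#' high/low groups with a two-sample t-test on score B (the iCAF-high vs
#' iCAF-low stemness contrast pattern).
#'
#' @param score_a,score_b numeric vectors over the same samples.
#' @return list with `r`, `p`, `high_low` (data.frame: group means,
#'   difference, t-test p), `flagged` (TRUE when a vector has zero
#'   variance, R undefined).
#' @export
associate_scores <- function(score_a, score_b) {
  if (length(score_a) != length(score_b))
    stop_cfg("score vectors must cover the same samples")
  if (sd(score_a) == 0 || sd(score_b) == 0)
    return(list(r = NA_real_, p = NA_real_, high_low = NULL, flagged = TRUE))
  ct <- cor.test(score_a, score_b)
  hi <- score_a > median(score_a)
  tt <- t.test(score_b[hi], score_b[!hi])
  high_low <- data.frame(mean_high = mean(score_b[hi]),
                         mean_low = mean(score_b[!hi]),
                         difference = mean(score_b[hi]) - mean(score_b[!hi]),
                         p = tt$p.value)
  list(r = unname(ct$estimate), p = ct$p.value, high_low = high_low,
       flagged = FALSE)
}
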