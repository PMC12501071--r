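#' @importFrom survival Surv coxph survfit survdiff concordance
NULL

# Endpoint-appropriate survival frame: DFS in stage I-III, OS in stage I-IV.
# Returns time, event, and the cohort rows kept.
endpoint_frame <- function(cohort, endpoint = c("DFS", "OS")) {
  endpoint <- match.arg(endpoint)
  cl <- cohort$clinical
  if (endpoint == "DFS") {
    keep <- cl$stage %in% c("I", "II", "III")
    time <- cl$time_dfs; event <- cl$event_dfs
  } else {
    keep <- cl$stage %in% c("I", "II", "III", "IV")
    time <- cl$time_os; event <- cl$event_os
  }
  keep <- keep & !is.na(time) & !is.na(event)
  data.frame(sample_id = cl$sample_id[keep], time = time[keep],
             event = event[keep], stringsAsFactors = FALSE)
}

align_covariates <- function(frame, covariates) {
  covariates <- as.data.frame(covariates)
  ids <- rownames(covariates)
  if (is.null(ids)) stopf("covariates need sample-id rownames")
  idx <- match(frame$sample_id, ids)
  if (anyNA(idx)) stopf("covariates missing %d samples", sum(is.na(idx)))
  covariates[idx, , drop = FALSE]
}

standardize_numeric <- function(x) {
  for (j in seq_along(x)) {
    if (is.numeric(x[[j]]) && length(unique(x[[j]])) > 2) {
      s <- sd(x[[j]])
      if (s > 0) x[[j]] <- (x[[j]] - mean(x[[j]])) / s
    }
  }
  x
}

#' Median-split Kaplan-Meier with log-rank test
#'
#' Samples are split at the median score (high: score > median; ties and
#' below go to the low group, a deterministic reading of ">vs <median").
#' DFS is analyzed in stage I-III, OS in stage I-IV. Returns the
#' Kaplan-Meier fit, the log-rank statistic and its two-sided p-value.
#'
#' @param cohort A `BulkCohort`.
#' @param score Named numeric vector (by sample id).
#' @param endpoint `"DFS"` or `"OS"`.
#' @return `list(fit = survfit, group = factor, chisq, p, n, events)`.
#' @export
km_logrank_median <- function(cohort, score, endpoint = c("DFS", "OS")) {
  fr <- endpoint_frame(cohort, endpoint)
  s <- score[fr$sample_id]
  if (anyNA(s)) stopf("score missing for some samples")
  group <- factor(ifelse(s > median(s), "high", "low"),
                  levels = c("low", "high"))
  df <- data.frame(time = fr$time, event = fr$event, group = group)
  fit <- survfit(Surv(time, event) ~ group, data = df)
  ev_by <- tapply(df$event, df$group, sum)
  if (any(ev_by == 0))
    warnf("km_logrank_median: a group has zero events")
  if (length(unique(group)) < 2) stopf("median split produced one group")
  sdf <- survdiff(Surv(time, event) ~ group, data = df)
  p <- pchisq(sdf$chisq, df = 1, lower.tail = FALSE)
  list(fit = fit, group = setNames(group, fr$sample_id), chisq = sdf$chisq,
       p = p, n = nrow(df), events = sum(df$event))
}

#' Batched univariate Cox regression with BH adjustment
#'
#' One Cox proportional-hazards fit per covariate; continuous covariates are
#' standardized so hazard ratios are per SD (the convention is logged).
#' Benjamini-Hochberg adjustment over the batch.
#'
#' @param cohort A `BulkCohort`.
#' @param covariates data.frame / matrix, rownames = sample ids.
#' @param endpoint `"DFS"` or `"OS"`.
#' @return data.frame per covariate: `hr`, `ci_lo`, `ci_hi`, `p`, `p_adj`,
#'   `n`, `events`, `concordance`.
#' @export
cox_univariate <- function(cohort, covariates, endpoint = c("DFS", "OS")) {
  fr <- endpoint_frame(cohort, endpoint)
  x <- standardize_numeric(align_covariates(fr, covariates))
  am_log("cox_univariate: continuous covariates standardized (HR per SD)")
  rows <- lapply(names(x), function(v) {
    df <- data.frame(time = fr$time, event = fr$event, x = x[[v]])
    fit <- coxph(Surv(time, event) ~ x, data = df)
    sm <- summary(fit)
    data.frame(covariate = v, hr = sm$conf.int[1, "exp(coef)"],
               ci_lo = sm$conf.int[1, "lower .95"],
               ci_hi = sm$conf.int[1, "upper .95"],
               p = sm$coefficients[1, "Pr(>|z|)"],
               n = sm$n, events = sm$nevent,
               concordance = sm$concordance[["C"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Stepwise multivariable Cox by backward elimination
#'
#' Starting from the full model over the candidate covariates (typically the
#' univariately significant ones), the covariate with the largest Wald p is
#' removed until all remaining covariates have Wald p below `alpha`.
#' Deterministic; the elimination trace is logged.
#'
#' @param cohort A `BulkCohort`.
#' @param covariates data.frame of candidates, rownames = sample ids.
#' @param endpoint `"DFS"` or `"OS"`.
#' @param alpha Retention threshold (default 0.05).
#' @return `list(fit, retained, dropped, table)`; `table` as in
#'   [cox_univariate()] for the final model's covariates.
#' @export
cox_stepwise <- function(cohort, covariates, endpoint = c("DFS", "OS"),
                         alpha = 0.05) {
  covariates <- as.data.frame(covariates)
  if (!ncol(covariates)) stopf("no significant candidates")
  fr <- endpoint_frame(cohort, endpoint)
  x <- standardize_numeric(align_covariates(fr, covariates))
  current <- names(x)
  dropped <- character()
  repeat {
    df <- cbind(data.frame(time = fr$time, event = fr$event),
                x[, current, drop = FALSE])
    fml <- stats::as.formula(paste("Surv(time, event) ~",
                                   paste0("`", current, "`", collapse = " + ")))
    fit <- tryCatch(
      coxph(fml, data = df),
      warning = function(w) {
        warnf("cox_stepwise: %s", conditionMessage(w))
        suppressWarnings(coxph(fml, data = df))
      })
    sm <- summary(fit)$coefficients
    pv <- sm[, "Pr(>|z|)"]
    bad <- is.na(pv)
    if (any(bad)) {
      drop_v <- current[which(bad)[1]]
      warnf("cox_stepwise: %s did not converge / is aliased, dropped", drop_v)
    } else if (max(pv) >= alpha && length(current) > 1) {
      drop_v <- current[which.max(pv)]
    } else if (max(pv) >= alpha) {
      drop_v <- current[1]
    } else break
    am_log(sprintf("cox_stepwise: dropping %s (p = %.3g)", drop_v,
                   suppressWarnings(pv[match(drop_v, current)])))
    dropped <- c(dropped, drop_v)
    current <- setdiff(current, drop_v)
    if (!length(current)) {
      am_log("cox_stepwise: all candidates eliminated")
      return(list(fit = NULL, retained = character(), dropped = dropped,
                  table = NULL))
    }
  }
  sm <- summary(fit)
  tab <- data.frame(covariate = rownames(sm$conf.int),
                    hr = sm$conf.int[, "exp(coef)"],
                    ci_lo = sm$conf.int[, "lower .95"],
                    ci_hi = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(fit = fit, retained = current, dropped = dropped, table = tab)
}

#' Compare nested Cox models: concordance gain and likelihood-ratio test
#'
#' Fits the base model and the base+added model on the same samples and
#' reports Harrell's C for each, the difference, and the likelihood-ratio
#' test on twice the log-likelihood difference with degrees of freedom equal
#' to the number of added parameters.
#'
#' @param cohort A `BulkCohort`.
#' @param base,added data.frames of covariates (rownames = sample ids);
#'   `added` columns are appended to `base`.
#' @param endpoint `"DFS"` or `"OS"`.
#' @return `list(c_base, c_full, delta_c, lrt_stat, df, p, n, events)`.
#' @export
compare_nested <- function(cohort, base, added, endpoint = c("DFS", "OS")) {
  fr <- endpoint_frame(cohort, endpoint)
  xb <- standardize_numeric(align_covariates(fr, base))
  xa <- standardize_numeric(align_covariates(fr, added))
  dup <- intersect(names(xa), names(xb))
  if (length(dup)) {
    warnf("compare_nested: added covariate(s) duplicate base: %s",
          paste(dup, collapse = ", "))
    names(xa)[match(dup, names(xa))] <- paste0(dup, "_added")
  }
  dfb <- cbind(data.frame(time = fr$time, event = fr$event), xb)
  dff <- cbind(dfb, xa)
  fml <- function(vars) stats::as.formula(paste(
    "Surv(time, event) ~", paste0("`", vars, "`", collapse = " + ")))
  fit_b <- coxph(fml(names(xb)), data = dfb)
  fit_f <- suppressWarnings(coxph(fml(c(names(xb), names(xa))), data = dff))
  if (any(is.na(coef(fit_f))))
    warnf("compare_nested: collinear added covariates (NA coefficients)")
  ll_b <- fit_b$loglik[2]; ll_f <- fit_f$loglik[2]
  df_added <- sum(!is.na(coef(fit_f))) - sum(!is.na(coef(fit_b)))
  lrt <- max(0, 2 * (ll_f - ll_b))
  p <- if (df_added > 0) pchisq(lrt, df_added, lower.tail = FALSE) else 1
  c_b <- concordance(fit_b)$concordance
  c_f <- concordance(fit_f)$concordance
  list(c_base = c_b, c_full = c_f, delta_c = c_f - c_b, lrt_stat = lrt,
       df = df_added, p = p, n = nrow(dfb), events = sum(fr$event))
}
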