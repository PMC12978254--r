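# Cohort-level linear/interaction models and survival stratification.

#' Response-specific association of a feature with MN burden
#'
#' Fits Feature ~ MN x Response (OLS) over responders (TRG 1-2) and
#' nonresponders (TRG 4-5) and extracts the interaction p-value and the
#' slope difference (NR - R). Tumors of other response classes are excluded.
#'
#' @param feature Numeric response variable (e.g. an immune abundance or a
#'   compartment protein level).
#' @param mn Tumor cGAS+ MN scores.
#' @param response Character/factor with levels including "R" and "NR".
#' @return One-row data frame: slope_r, slope_nr, slope_difference,
#'   interaction_p, n_r, n_nr, degenerate.
#' @export
response_interaction <- function(feature, mn, response) {
  keep <- response %in% c("R", "NR")
  d <- data.frame(y = feature[keep], mn = mn[keep],
                  resp = factor(response[keep], levels = c("R", "NR")))
  n_r <- sum(d$resp == "R"); n_nr <- sum(d$resp == "NR")
  if (n_r < 3 || n_nr < 3)
    stop("at least 3 tumors per response class are required")
  degenerate <- stats::sd(d$mn[d$resp == "R"]) == 0 ||
    stats::sd(d$mn[d$resp == "NR"]) == 0
  if (degenerate) {
    warning("MN score constant within a response class; fit degenerate")
    return(data.frame(slope_r = NA_real_, slope_nr = NA_real_,
                      slope_difference = NA_real_, interaction_p = NA_real_,
                      n_r = n_r, n_nr = n_nr, degenerate = TRUE))
  }
  fit <- stats::lm(y ~ mn * resp, data = d)
  cf <- summary(fit)$coefficients
  slope_r <- cf["mn", "Estimate"]
  diff <- cf["mn:respNR", "Estimate"]
  data.frame(slope_r = slope_r, slope_nr = slope_r + diff,
             slope_difference = diff,
             interaction_p = cf["mn:respNR", "Pr(>|t|)"],
             n_r = n_r, n_nr = n_nr, degenerate = FALSE)
}

#' Classify a gene's CIN association by cGAS-STING dependence
#'
#' Fits expression ~ CIN_MN x cGAS_STING + purity + leukocyte fraction and
#' classifies the gene: "enriched_dependent" when the CIN_MN main effect is
#' significantly positive and the interaction significantly positive
#' (steeper CIN scaling at higher cGAS-STING score), "depleted_dependent"
#' for the mirror case, otherwise "not_dependent".
#'
#' @param expression Numeric vector (one gene) or genes x samples matrix.
#' @param cin_mn,cgas_sting,purity,leukocyte Per-sample covariates.
#' @param alpha Significance cutoff for both gates (default 0.05).
#' @return Data frame with per-gene slopes, p-values and class.
#' @export
cin_cgassting_interaction <- function(expression, cin_mn, cgas_sting,
                                      purity, leukocyte, alpha = 0.05) {
  expr <- if (is.matrix(expression)) expression else
    matrix(expression, nrow = 1,
           dimnames = list("gene", names(expression)))
  X <- stats::model.matrix(~ cin_mn * cgas_sting + purity + leukocyte)
  out <- do.call(rbind, lapply(seq_len(nrow(expr)), function(i) {
    fit <- stats::lm.fit(X, expr[i, ])
    cf <- fit$coefficients
    # recover standard errors via the classical formula
    rss <- sum(fit$residuals^2)
    df <- length(fit$residuals) - fit$rank
    XtXinv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                                 drop = FALSE])
    se <- sqrt(diag(XtXinv) * rss / df)
    names(se) <- colnames(X)[fit$qr$pivot[seq_len(fit$rank)]]
    p <- 2 * stats::pt(-abs(cf / se[names(cf)]), df)
    data.frame(cin_slope = cf[["cin_mn"]], cin_p = p[["cin_mn"]],
               interaction_slope = cf[["cin_mn:cgas_sting"]],
               interaction_p = p[["cin_mn:cgas_sting"]])
  }))
  out$class <- with(out, ifelse(
    cin_p <= alpha & cin_slope > 0 & interaction_p <= alpha &
      interaction_slope > 0, "enriched_dependent",
    ifelse(cin_p <= alpha & cin_slope < 0 & interaction_p <= alpha &
             interaction_slope < 0, "depleted_dependent", "not_dependent")))
  rownames(out) <- rownames(expr)
  out
}

#' Covariate-adjusted agreement between CIN scores
#'
#' Regresses an orthogonal CIN measure (e.g. CIN70 or aneuploidy score) on
#' the CIN-MN score with tumor purity and leukocyte fraction as covariates,
#' reporting the CIN-MN coefficient and p-value.
#'
#' @param target_score Orthogonal CIN score vector.
#' @param cin_mn CIN-MN score vector.
#' @param purity,leukocyte Covariates.
#' @return One-row data frame: coefficient, p_value.
#' @export
cin_score_agreement <- function(target_score, cin_mn, purity, leukocyte) {
  fit <- stats::lm(target_score ~ cin_mn + purity + leukocyte)
  cf <- summary(fit)$coefficients
  data.frame(coefficient = cf["cin_mn", "Estimate"],
             p_value = cf["cin_mn", "Pr(>|t|)"])
}

#' Kaplan-Meier curves and log-rank tests
#'
#' Product-limit survival curves per group with the k-group log-rank test,
#' plus pairwise log-rank tests of a reference group against each other
#' group.
#'
#' @param time,event Survival times and event indicators (1 = event).
#' @param group Group labels.
#' @param reference Reference group for pairwise tests (default: first
#'   level).
#' @return List: \code{fit} (survfit object), \code{chisq}, \code{df},
#'   \code{p_value}, and \code{pairwise} (data frame, NULL for 2 groups or
#'   fewer).
#' @export
km_logrank <- function(time, event, group, reference = NULL) {
  group <- factor(group)
  d <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (nlevels(droplevels(group)) < 2)
    return(list(fit = fit, chisq = NA_real_, df = 0, p_value = NA_real_,
                pairwise = NULL))
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd0$n) - 1
  p <- stats::pchisq(sd0$chisq, df, lower.tail = FALSE)
  pairwise <- NULL
  if (nlevels(group) > 2) {
    ref <- if (is.null(reference)) levels(group)[1] else reference
    others <- setdiff(levels(group), ref)
    pairwise <- do.call(rbind, lapply(others, function(g) {
      dd <- d[d$group %in% c(ref, g), ]
      sdp <- survival::survdiff(survival::Surv(time, event) ~ group,
                                data = dd)
      data.frame(reference = ref, group = g, chisq = sdp$chisq,
                 p_value = stats::pchisq(sdp$chisq, 1, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  list(fit = fit, chisq = sd0$chisq, df = df, p_value = p,
       pairwise = pairwise)
}

# Standardized two-group log-rank statistics for many binary groupings at
# once. G: n x K logical matrix (TRUE = high group). Returns z per column.
.logrank_scan <- function(time, event, G) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  G <- G[ord, , drop = FALSE] + 0
  f <- factor(t_s, levels = unique(t_s))
  tab <- as.integer(table(f))
  d_t <- as.numeric(rowsum(e_s, f))
  n_t <- rev(cumsum(rev(tab)))
  d1 <- rowsum(G * e_s, f)
  cnt1 <- rowsum(G, f)
  n1 <- apply(cnt1, 2, function(v) rev(cumsum(rev(v))))
  if (is.null(dim(n1))) n1 <- matrix(n1, ncol = ncol(G))
  ev <- d_t > 0
  frac <- n1[ev, , drop = FALSE] / n_t[ev]
  U <- colSums(d1[ev, , drop = FALSE] - d_t[ev] * frac)
  vt <- d_t[ev] * (n_t[ev] - d_t[ev]) / pmax(n_t[ev] - 1, 1)
  V <- colSums(vt * frac * (1 - frac))
  z <- U / sqrt(V)
  z[V <= 0] <- NA_real_
  z
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans candidate cutpoints of a continuous score between the 10th and
#' 90th percentiles (one candidate per unique value), computes the
#' standardized two-group log-rank statistic of score > cutpoint at each,
#' and selects the cutpoint maximizing |statistic|. The selection-adjusted
#' p-value is obtained by permuting the score labels and re-running the
#' scan.
#'
#' @param score Continuous per-subject score.
#' @param time,event Survival data.
#' @param probs Length-2 quantile range for candidates (default 0.1, 0.9).
#' @param n_perm Number of permutations for the p-value (default 1000).
#' @param seed Integer seed.
#' @return List: cutpoint, statistic (max |z|), p_value, candidates (data
#'   frame of cutpoint and z).
#' @export
maxstat_cutpoint <- function(score, time, event, probs = c(0.1, 0.9),
                             n_perm = 1000, seed = 1L) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  q <- stats::quantile(score, probs)
  cand <- sort(unique(score[score >= q[1] & score < q[2]]))
  cand <- cand[vapply(cand, function(cp)
    any(score > cp) && any(score <= cp), logical(1))]
  if (!length(cand)) stop("no admissible cutpoints in the given range")
  make_G <- function(s) outer(s, cand, ">")
  z_obs <- .logrank_scan(time, event, make_G(score))
  stat <- max(abs(z_obs), na.rm = TRUE)
  best <- cand[which.max(abs(z_obs))]
  p <- with_seed(seed, {
    exceed <- vapply(seq_len(n_perm), function(i) {
      zp <- .logrank_scan(time, event, make_G(sample(score)))
      max(abs(zp), na.rm = TRUE) >= stat
    }, logical(1))
    (1 + sum(exceed)) / (1 + n_perm)
  })
  list(cutpoint = best, statistic = stat, p_value = p,
       candidates = data.frame(cutpoint = cand, z = z_obs))
}

#' Nested median stratification by CIN score and myeloid skew
#'
#' Splits the cohort at the median CIN score, then splits each half at its
#' own median skew, yielding four strata. Values at the median go to the
#' "low" (or lymphoid-dominated) stratum.
#'
#' @param cin_score,skew Numeric vectors.
#' @return Factor with levels CIN_high_My, CIN_high_Ly, CIN_low_My,
#'   CIN_low_Ly.
#' @export
nested_median_stratify <- function(cin_score, skew) {
  stopifnot(length(cin_score) == length(skew))
  high <- cin_score > stats::median(cin_score)
  lab <- character(length(cin_score))
  for (h in c(TRUE, FALSE)) {
    idx <- which(high == h)
    my <- skew[idx] > stats::median(skew[idx])
    lab[idx] <- paste0(ifelse(h, "CIN_high_", "CIN_low_"),
                       ifelse(my, "My", "Ly"))
  }
  factor(lab, levels = c("CIN_high_My", "CIN_high_Ly",
                         "CIN_low_My", "CIN_low_Ly"))
}

#' Univariate Cox proportional-hazards model for a dichotomized covariate
#'
#' Partial-likelihood fit with Efron tie handling; reports the hazard ratio
#' of the "high" group with its Wald confidence interval, alongside the
#' log-rank p-value. The fit is flagged when a group has no events
#' (monotone likelihood).
#'
#' @param high Logical or two-level factor (TRUE / second level = high).
#' @param time,event Survival data.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row data frame: hr, ci_lower, ci_upper, wald_p, logrank_p,
#'   flagged.
#' @export
cox_univariate <- function(high, time, event, conf_level = 0.95) {
  high <- if (is.logical(high)) high else
    as.integer(factor(high)) == 2L
  d <- data.frame(time = time, event = event, high = high)
  flagged <- any(tapply(d$event, d$high, sum) == 0)
  if (flagged) warning("a group has no events; Cox fit does not converge")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ high, data = d,
                    ties = "efron"))
  sm <- summary(fit, conf.int = conf_level)
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ high, data = d)
  data.frame(hr = unname(sm$conf.int[1, "exp(coef)"]),
             ci_lower = unname(sm$conf.int[1, 3]),
             ci_upper = unname(sm$conf.int[1, 4]),
             wald_p = unname(sm$coefficients[1, "Pr(>|z|)"]),
             logrank_p = stats::pchisq(sd0$chisq, 1, lower.tail = FALSE),
             flagged = flagged)
}
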