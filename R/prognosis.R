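# Survival layer: median split, log-rank, Kaplan-Meier and the Cox
# partial-likelihood fit are delegated to the survival package (Breslow
# ties); this module owns the risk-score construction and the
# high/low-risk comparison around them.

#' Median split of a per-patient variable
#'
#' `high = {x > median}`, `low = {x <= median}`: ties at the median go to
#' the low group.
#'
#' @param x Named numeric vector (names are patient/sample ids), length
#'   >= 4.
#' @return Object of class `SurvivalSplit`: list with `group` (named
#'   factor `"high"`/`"low"`) and `split_value`.
#' @export
median_split <- function(x) {
  if (length(x) < 4) stop("need >= 4 patients for a median split", call. = FALSE)
  if (is.null(names(x))) stop("x must be named by patient id", call. = FALSE)
  med <- stats::median(x)
  if (stats::sd(x) == 0)
    stop("constant variable: degenerate split", call. = FALSE)
  grp <- factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
  names(grp) <- names(x)
  if (!all(c("low", "high") %in% grp))
    stop("degenerate split: one group is empty", call. = FALSE)
  structure(list(group = grp, split_value = med), class = "SurvivalSplit")
}

align_split_clinical <- function(split, clin) {
  stopifnot(inherits(split, "SurvivalSplit"), inherits(clin, "ClinicalTable"))
  ids <- intersect(names(split$group), clin$sample_id)
  if (length(ids) < 4)
    stop("fewer than 4 patients with both split and clinical data",
         call. = FALSE)
  clin <- clin[match(ids, clin$sample_id), , drop = FALSE]
  data.frame(sample_id = ids, time = clin$time_days, event = clin$event,
             group = split$group[ids], stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Mantel-Haenszel log-rank: at each event time the observed events per
#' group are compared with their hypergeometric expectation; the summed
#' differences are referred to a chi-square with 1 df.
#'
#' @param split `SurvivalSplit`.
#' @param clin `ClinicalTable` covering the split patients.
#' @return Object of class `LogRankResult`: list with `observed`,
#'   `expected` (per group), `chi_square`, `p`, `n`.
#' @export
logrank_test <- function(split, clin) {
  d <- align_split_clinical(split, clin)
  if (any(tapply(d$event, d$group, sum) == 0))
    warning("a group has zero observed events", call. = FALSE)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chi <- unname(sd_fit$chisq)
  structure(list(
    observed = stats::setNames(as.numeric(sd_fit$obs), levels(d$group)),
    expected = stats::setNames(as.numeric(sd_fit$exp), levels(d$group)),
    chi_square = chi,
    p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
    n = nrow(d)
  ), class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank: chi^2 = %.4g (1 df), p = %.4g; O = (%s), E = (%s)\n",
              x$chi_square, x$p,
              paste(x$observed, collapse = ", "),
              paste(round(x$expected, 2), collapse = ", ")))
  invisible(x)
}

#' Kaplan-Meier curves per split group
#'
#' Product-limit estimator `S(t) = prod(1 - d_t / n_t)` over event times.
#'
#' @param split `SurvivalSplit`.
#' @param clin `ClinicalTable`.
#' @return Data frame with `group`, `time`, `n_risk`, `n_event`, `surv`;
#'   each group's curve starts at `S = 1` and is non-increasing.
#' @export
km_curve <- function(split, clin) {
  d <- align_split_clinical(split, clin)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  grp <- if (is.null(fit$strata))  # a single populated group
    rep(as.character(unique(d$group)), length(fit$time))
  else
    sub("^group=", "", rep(names(fit$strata), fit$strata))
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}

#' Fit a Cox proportional-hazards model on standardized features
#'
#' Partial-likelihood maximization with Breslow tie handling. Features are
#' expected already standardized (mean 0, sd 1 over the included
#' patients) so that coefficients are comparable across RNAs.
#'
#' @param features Numeric matrix, patients x features, rownames = patient
#'   ids, colnames = feature ids.
#' @param clin `ClinicalTable` covering the patients.
#' @return List with `betas` (named), `se`, `converged`, `n`, `n_events`.
#' @export
fit_cox <- function(features, clin) {
  stopifnot(is.matrix(features), inherits(clin, "ClinicalTable"))
  if (is.null(rownames(features)) || is.null(colnames(features)))
    stop("features must carry patient rownames and feature colnames",
         call. = FALSE)
  ids <- intersect(rownames(features), clin$sample_id)
  clin <- clin[match(ids, clin$sample_id), , drop = FALSE]
  X <- features[ids, , drop = FALSE]
  if (sum(clin$event) < 10)
    stop("need >= 10 observed events to fit a Cox model", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("collinear features: ", paste(colnames(X), collapse = ", "),
         call. = FALSE)
  d <- data.frame(time = clin$time_days, event = clin$event, X,
                  check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    bad <- names(beta)[is.na(beta)]
    stop("Cox fit failed for feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  if (any(abs(beta) > 15))
    stop("monotone likelihood (separation) for feature(s): ",
         paste(names(beta)[abs(beta) > 15], collapse = ", "), call. = FALSE)
  list(betas = beta, se = stats::setNames(se, names(beta)),
       converged = fit$iter < 100, n = nrow(d), n_events = sum(d$event))
}

#' Risk score: linear predictor of a fitted Cox model
#'
#' `risk_i = sum_j beta_j * x_ij` over the (standardized) feature values.
#'
#' @param betas Named coefficient vector.
#' @param features Patients x features matrix matching `names(betas)`.
#' @return Named numeric vector of per-patient risk scores.
#' @export
risk_score <- function(betas, features) {
  stopifnot(all(names(betas) %in% colnames(features)))
  drop(features[, names(betas), drop = FALSE] %*% betas)
}

#' Cox risk-score prognosis of one ceRNA triplet
#'
#' Fits a multivariate Cox model on the standardized tumor logCPM of the
#' triplet's lncRNA, miRNA and mRNA, scores each patient with the linear
#' predictor, splits patients at the median risk score and compares
#' high-risk vs low-risk survival with a log-rank test.
#'
#' @param triplet Named list or vector with `lncrna_id`, `mirna_id`,
#'   `mrna_id`.
#' @param lnc_m,mir_m,mrna_m logCPM `ExpressionMatrix` objects.
#' @param clin `ClinicalTable`.
#' @param min_patients Minimum tumor samples with clinical records
#'   (default 20).
#' @return Object of class `RiskModel`: list with `features`, `betas`,
#'   `se`, `risk_scores`, `median_rs`, `split`, `logrank`, `km`, `n`.
#' @export
triplet_risk_analysis <- function(triplet, lnc_m, mir_m, mrna_m, clin,
                                  min_patients = 20L) {
  trip <- as.list(triplet)
  need <- c("lncrna_id", "mirna_id", "mrna_id")
  if (!all(need %in% names(trip)))
    stop("triplet needs ids: ", paste(need, collapse = ", "), call. = FALSE)
  mats <- list(lnc_m, mir_m, mrna_m)
  ids_feat <- unlist(trip[need], use.names = FALSE)
  for (i in 1:3)
    if (!ids_feat[i] %in% gene_ids(mats[[i]]))
      stop("triplet member absent from its matrix: ", ids_feat[i],
           call. = FALSE)
  samples <- Reduce(intersect, lapply(mats, function(m)
    sample_ids(m)[m$group == "tumor"]))
  samples <- intersect(samples, clin$sample_id)
  if (length(samples) < min_patients)
    stop(sprintf("only %d tumor samples with clinical data (need >= %d)",
                 length(samples), min_patients), call. = FALSE)
  X <- cbind(mats[[1]]$values[ids_feat[1], samples],
             mats[[2]]$values[ids_feat[2], samples],
             mats[[3]]$values[ids_feat[3], samples])
  dimnames(X) <- list(samples, ids_feat)
  X <- scale(X)
  if (anyNA(X)) stop("constant expression for a triplet member", call. = FALSE)
  fit <- fit_cox(X, clin)
  rs <- risk_score(fit$betas, X)
  split <- median_split(rs)
  lr <- logrank_test(split, clin)
  structure(list(
    features = ids_feat, betas = fit$betas, se = fit$se,
    risk_scores = rs, median_rs = split$split_value, split = split,
    logrank = lr, km = km_curve(split, clin),
    n = fit$n, n_events = fit$n_events
  ), class = "RiskModel")
}

#' @export
print.RiskModel <- function(x, ...) {
  cat(sprintf(
    "RiskModel [%s]: n = %d (%d events); beta = (%s); log-rank chi^2 = %.3g, p = %.3g\n",
    paste(x$features, collapse = " / "), x$n, x$n_events,
    paste(sprintf("%s %.3f", names(x$betas), x$betas), collapse = ", "),
    x$logrank$chi_square, x$logrank$p))
  invisible(x)
}

#' Kaplan-Meier prognosis of a single RNA
#'
#' Median split of one RNA's tumor expression followed by the log-rank
#' test, as used for hub-RNA survival screening.
#'
#' @param gene Gene id.
#' @param m logCPM `ExpressionMatrix` containing it.
#' @param clin `ClinicalTable`.
#' @return List with `split`, `logrank`, `km`.
#' @export
gene_survival <- function(gene, m, clin) {
  if (!gene %in% gene_ids(m)) stop("gene not in matrix: ", gene, call. = FALSE)
  samples <- intersect(sample_ids(m)[m$group == "tumor"], clin$sample_id)
  x <- stats::setNames(m$values[gene, samples], samples)
  split <- median_split(x)
  list(split = split, logrank = logrank_test(split, clin),
       km = km_curve(split, clin))
}
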