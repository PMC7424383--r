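#' Log2 counts-per-million transform
#'
#' `logCPM[g,s] = log2((count[g,s] + 0.5) / (libsize[s] + 1) * 1e6)`.
#' The half-count offset keeps zeros finite; the +1 on the library size
#' keeps the argument below 1e6 for a gene carrying the whole library.
#'
#' @param m `ExpressionMatrix` on the counts scale.
#' @return `ExpressionMatrix` on the logCPM scale.
#' @export
log_cpm <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "counts") stop("log_cpm expects a counts matrix", call. = FALSE)
  lib <- colSums(m$values)
  if (any(lib == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(m$values)[lib == 0], collapse = ", "), call. = FALSE)
  vals <- log2(sweep(m$values + 0.5, 2, lib + 1, "/") * 1e6)
  expression_matrix(vals, m$rna_class, m$group, scale = "logCPM")
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing target).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Empirical-Bayes variance shrinkage: fit a scaled inverse-chi-square prior
# (d0, s0^2) to the gene-wise residual variances by method of moments on
# log s^2, then return posterior variances (d0*s0^2 + d*s^2) / (d0 + d).
# Genes with s^2 == 0 contribute nothing to the moment fit but still get a
# posterior variance from the prior.
squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2)  # no variance distribution to learn from: no shrinkage
    return(list(df_prior = 0, var_prior = NA_real_, var_post = s2))
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e)
  excess <- evar - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 0) {
    # variances underdispersed relative to chi-square scatter (in practice
    # only for degenerate, near-identical s^2): take their geometric mean
    # as the common value, so identical variances shrink to themselves
    d0 <- Inf
    s02 <- exp(mean(log(s2[ok])))
    post <- rep(s02, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  list(df_prior = d0, var_prior = s02, var_post = post)
}

#' Moderated two-group t-test per gene
#'
#' For each gene, the tumor-minus-normal difference of mean logCPM is the
#' log2 fold change; residual variances are shrunk toward a common prior
#' estimated by empirical Bayes (method of moments on the log variances),
#' and the moderated t uses the posterior variance with augmented degrees
#' of freedom `d_g + d0`.
#'
#' @param m `ExpressionMatrix` on the logCPM scale with >= 2 samples per
#'   group.
#' @return Data frame with columns `gene_id`, `logFC`, `stat`, `p`, plus
#'   attributes `df_prior` and `var_prior`.
#' @export
moderated_t_test <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "logCPM") stop("moderated_t_test expects logCPM", call. = FALSE)
  tum <- m$values[, m$group == "tumor", drop = FALSE]
  nor <- m$values[, m$group == "normal", drop = FALSE]
  n1 <- ncol(tum); n2 <- ncol(nor)
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 samples per group for a residual variance", call. = FALSE)
  df_resid <- n1 + n2 - 2
  mu1 <- rowMeans(tum); mu2 <- rowMeans(nor)
  logfc <- mu1 - mu2
  ss <- rowSums((tum - mu1)^2) + rowSums((nor - mu2)^2)
  s2 <- ss / df_resid
  sq <- squeeze_var(s2, df_resid)
  stderr <- sqrt(sq$var_post * (1 / n1 + 1 / n2))
  stat <- logfc / stderr
  df_total <- df_resid + sq$df_prior
  p <- 2 * stats::pt(-abs(stat), df = df_total)
  out <- data.frame(gene_id = gene_ids(m), logFC = logfc, stat = stat, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a thin validating wrapper around
#' `p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression at the configured thresholds
#'
#' Composes [log_cpm()] (when given counts), [moderated_t_test()] and
#' [bh_adjust()], then assigns status: `up` when `adj_p < de_adj_p` and
#' `logFC > de_abs_logfc`, `down` when `adj_p < de_adj_p` and
#' `logFC < -de_abs_logfc`, otherwise `ns`. Log fold changes are tumor
#' minus normal, so `up` means higher in tumor.
#'
#' @param m `ExpressionMatrix` (counts or logCPM).
#' @param cfg `RunConfig`.
#' @return Data frame with columns `gene_id`, `logFC`, `stat`, `p`, `adj_p`,
#'   `status` for every gene (non-significant rows included).
#' @export
call_de <- function(m, cfg = run_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(cfg, "RunConfig"))
  if (m$scale == "counts") m <- log_cpm(m)
  res <- moderated_t_test(m)
  res$adj_p <- bh_adjust(res$p)
  res$status <- "ns"
  sig <- res$adj_p < cfg$de_adj_p
  res$status[sig & res$logFC > cfg$de_abs_logfc] <- "up"
  res$status[sig & res$logFC < -cfg$de_abs_logfc] <- "down"
  ce_log("DE %s: %d up, %d down of %d genes (adj.P < %g, |logFC| > %g)",
         m$rna_class, sum(res$status == "up"), sum(res$status == "down"),
         nrow(res), cfg$de_adj_p, cfg$de_abs_logfc)
  res
}

#' Differentially expressed gene ids from a DE table
#' @param de Result of [call_de()].
#' @return Character vector of gene ids with status `up` or `down`.
#' @export
de_genes <- function(de) de$gene_id[de$status != "ns"]
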