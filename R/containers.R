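#' Expression matrix for one RNA class
#'
#' Lightweight container holding a genes x samples numeric matrix together
#' with the RNA class it measures, per-sample tumor/normal labels and the
#' scale of the values (raw counts or log2 counts-per-million).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are the gene and sample identifiers and must be unique.
#' @param rna_class One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param group Character vector of `"tumor"`/`"normal"` labels, one per
#'   sample column (recycled names are taken from `colnames(values)` when
#'   unnamed).
#' @param scale `"counts"` (non-negative integers) or `"logCPM"` (reals).
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `rna_class`, `group` (named by sample) and `scale`.
#' @export
expression_matrix <- function(values, rna_class = c("mRNA", "lncRNA", "miRNA"),
                              group, scale = c("counts", "logCPM")) {
  rna_class <- match.arg(rna_class)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene (row) and sample (column) names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  if (length(group) != ncol(values))
    stop("`group` must have one label per sample", call. = FALSE)
  group <- as.character(group)
  if (!all(group %in% c("tumor", "normal")))
    stop("group labels must be 'tumor' or 'normal'", call. = FALSE)
  names(group) <- colnames(values)
  if (anyNA(values)) stop("expression values must not contain NA", call. = FALSE)
  if (scale == "counts") {
    if (any(values < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(values != round(values)))
      stop("counts must be integral", call. = FALSE)
  }
  structure(
    list(values = values, rna_class = rna_class, group = group, scale = scale),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix [%s, %s]: %d genes x %d samples (%d tumor / %d normal)\n",
    x$rna_class, x$scale, nrow(x$values), ncol(x$values),
    sum(x$group == "tumor"), sum(x$group == "normal")
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Subset an ExpressionMatrix by sample ids
#'
#' @param m `ExpressionMatrix`.
#' @param samples Character vector of sample ids to keep (order preserved).
#' @return A new `ExpressionMatrix` restricted to those samples.
#' @export
subset_samples <- function(m, samples) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  missing <- setdiff(samples, sample_ids(m))
  if (length(missing))
    stop("samples not present in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  expression_matrix(m$values[, samples, drop = FALSE], m$rna_class,
                    m$group[samples], m$scale)
}

#' Clinical (survival) table
#'
#' @param df Data frame with columns `sample_id`, `time_days` (positive) and
#'   `event` (1 = death observed, 0 = censored).
#' @return Validated data frame of class `ClinicalTable`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "time_days", "event")
  if (!all(need %in% names(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in clinical table", call. = FALSE)
  if (!is.numeric(df$time_days) || anyNA(df$time_days) || any(df$time_days <= 0))
    stop("time_days must be positive", call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' miRNA-target interaction database
#'
#' Deduplicated records of miRNA to target interactions, each target tagged
#' with its RNA class. Provides the two lookup views used by the ceRNA
#' scoring step.
#'
#' @param df Data frame with columns `mirna`, `target`, `target_class`
#'   (`"lncRNA"` or `"mRNA"`).
#' @return Object of class `InteractionDB`.
#' @export
interaction_db <- function(df) {
  need <- c("mirna", "target", "target_class")
  if (!all(need %in% names(df)))
    stop("interaction table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  for (col in need) df[[col]] <- as.character(df[[col]])
  bad <- setdiff(unique(df$target_class), c("lncRNA", "mRNA"))
  if (length(bad))
    stop("unknown target_class: ", paste(bad, collapse = ", "), call. = FALSE)
  df <- unique(df)
  cls <- tapply(df$target_class, df$target, function(x) length(unique(x)))
  if (any(cls > 1))
    stop("target annotated under two classes: ",
         paste(names(cls)[cls > 1], collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  structure(list(records = df), class = "InteractionDB")
}

#' @export
print.InteractionDB <- function(x, ...) {
  tab <- table(x$records$target_class)
  cat(sprintf("InteractionDB: %d records (%s), %d miRNAs\n",
              nrow(x$records),
              paste(sprintf("%s %s", tab, names(tab)), collapse = ", "),
              length(unique(x$records$mirna))))
  invisible(x)
}

#' Targets of a miRNA
#' @param db `InteractionDB`.
#' @param mirna miRNA id.
#' @param target_class Optional restriction to `"lncRNA"` or `"mRNA"`.
#' @return Character vector of target ids.
#' @export
targets_of <- function(db, mirna, target_class = NULL) {
  r <- db$records
  keep <- r$mirna == mirna
  if (!is.null(target_class)) keep <- keep & r$target_class == target_class
  unique(r$target[keep])
}

#' miRNAs targeting a transcript
#' @param db `InteractionDB`.
#' @param target Target transcript id.
#' @return Character vector of miRNA ids.
#' @export
mirnas_of <- function(db, target) {
  unique(db$records$mirna[db$records$target == target])
}

#' Restrict an InteractionDB to given miRNAs and targets
#'
#' Used by the pipeline to keep only interactions among differentially
#' expressed RNAs before pair scoring.
#'
#' @param db `InteractionDB`.
#' @param mirnas,targets Ids to keep (both must match for a record to stay).
#' @return A new `InteractionDB`.
#' @export
restrict_db <- function(db, mirnas, targets) {
  r <- db$records
  keep <- r$mirna %in% mirnas & r$target %in% targets
  interaction_db(r[keep, , drop = FALSE])
}

#' Run configuration
#'
#' Holds every threshold of the pipeline. Defaults follow the published
#' cut-offs: adjusted P < 0.01 and |logFC| > 1 for differential expression,
#' raw P < 0.05 for the hypergeometric pair test and for Pearson
#' co-expression, regulation similarity > 0, enrichment q < 0.01, and
#' top-10 hubs by degree.
#'
#' @param de_adj_p,de_abs_logfc Differential-expression gates.
#' @param pair_p Hypergeometric shared-miRNA p-value cut-off.
#' @param pcc_p Pearson correlation p-value cut-off (the correlation itself
#'   must also be positive).
#' @param regsim_min Minimum regulation-similarity score (exclusive).
#' @param enrich_q BH q-value cut-off for over-representation analysis.
#' @param alpha Generic significance level (log-rank reporting).
#' @param correlation_sample_set `"tumor"` (default) or `"all"`: samples over
#'   which co-expression and regulation-mode correlations are computed.
#' @param mirna_universe `"de"` (default): hypergeometric universe is the DE
#'   miRNAs present in the interaction DB; `"db"`: all DB miRNAs.
#' @param regsim_exponent `"M"` (default) or `"1"`: exponent applied to each
#'   normalized term of the regulation-similarity score.
#' @param require_negative_mirna_corr If `TRUE`, additionally require the
#'   mean miRNA-lncRNA and miRNA-mRNA correlations to be negative
#'   (canonical sponge direction). Off by default.
#' @param hub_k Number of hub nodes retained by degree ranking.
#' @param rng_seed Integer seed recorded with the run.
#' @param paths Optional named list of input/output paths (used by the
#'   command-line driver).
#' @return Object of class `RunConfig`.
#' @export
run_config <- function(de_adj_p = 0.01, de_abs_logfc = 1.0, pair_p = 0.05,
                       pcc_p = 0.05, regsim_min = 0.0, enrich_q = 0.01,
                       alpha = 0.05,
                       correlation_sample_set = c("tumor", "all"),
                       mirna_universe = c("de", "db"),
                       regsim_exponent = c("M", "1"),
                       require_negative_mirna_corr = FALSE,
                       hub_k = 10, rng_seed = 1L, paths = list()) {
  probs <- c(de_adj_p = de_adj_p, pair_p = pair_p, pcc_p = pcc_p,
             enrich_q = enrich_q, alpha = alpha)
  if (any(probs <= 0 | probs > 1))
    stop("probability thresholds must lie in (0, 1]", call. = FALSE)
  if (de_abs_logfc < 0) stop("de_abs_logfc must be >= 0", call. = FALSE)
  if (regsim_min < 0 || regsim_min >= 1)
    stop("regsim_min must lie in [0, 1)", call. = FALSE)
  if (hub_k < 1) stop("hub_k must be >= 1", call. = FALSE)
  structure(list(
    de_adj_p = de_adj_p, de_abs_logfc = de_abs_logfc, pair_p = pair_p,
    pcc_p = pcc_p, regsim_min = regsim_min, enrich_q = enrich_q, alpha = alpha,
    correlation_sample_set = match.arg(correlation_sample_set),
    mirna_universe = match.arg(mirna_universe),
    regsim_exponent = match.arg(regsim_exponent),
    require_negative_mirna_corr = isTRUE(require_negative_mirna_corr),
    hub_k = as.integer(hub_k), rng_seed = as.integer(rng_seed), paths = paths
  ), class = "RunConfig")
}

#' Read a run configuration from a YAML `key: value` file
#'
#' Unknown keys are rejected so that typos in threshold names cannot
#' silently fall back to defaults.
#'
#' @param path Path to a YAML file whose keys are `run_config()` arguments.
#' @return `RunConfig`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}
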