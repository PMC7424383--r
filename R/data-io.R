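# Readers reject rather than coerce: malformed cells, duplicate ids and
# unmapped samples are hard errors so a run can be audited from its log.

ce_log <- function(...) {
  if (isTRUE(getOption("ceRNAprog.quiet", FALSE))) return(invisible(NULL))
  message("[ceRNAprog] ", sprintf(...))
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Write any result table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts matrix from TSV
#'
#' The file must have a header row of sample ids and gene ids in the first
#' column. Every sample must be mapped to a tumor/normal label via
#' `group_map`; unmapped samples are an error, not silently dropped.
#'
#' @param path TSV file, genes x samples.
#' @param rna_class `"mRNA"`, `"lncRNA"` or `"miRNA"`.
#' @param group_map Named character vector, sample id -> `"tumor"`/`"normal"`.
#' @return `ExpressionMatrix` with `scale = "counts"`.
#' @export
read_expression <- function(path, rna_class, group_map) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) stop("expression file needs gene column + samples", call. = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id in ", path, call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals))
    stop("non-numeric expression cell in ", path, call. = FALSE)
  dimnames(vals) <- list(genes, samples)
  unmapped <- setdiff(samples, names(group_map))
  if (length(unmapped))
    stop("samples missing from group_map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  m <- expression_matrix(vals, rna_class, group_map[samples], scale = "counts")
  ce_log("read %s expression: %d genes x %d samples from %s",
         rna_class, nrow(vals), ncol(vals), path)
  m
}

#' Write an ExpressionMatrix as TSV (inverse of [read_expression()])
#'
#' @param m `ExpressionMatrix`.
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE)
  write_table(df, path)
}

#' Read a miRNA-target interaction table
#'
#' Expects columns `mirna`, `target`, `target_class`; duplicate records are
#' dropped, a target annotated under two classes is an error.
#'
#' @param path TSV file.
#' @return `InteractionDB`.
#' @export
read_interactions <- function(path) {
  df <- read_tsv_checked(path)
  db <- interaction_db(df)
  tab <- table(db$records$target_class)
  ce_log("read interactions: %d records (%s) from %s", nrow(db$records),
         paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
         path)
  db
}

#' Read a clinical survival table
#'
#' @param path TSV with columns `sample_id`, `time_days`, `event`.
#' @return `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  clin <- clinical_table(read_tsv_checked(path))
  ce_log("read clinical: %d patients, %d events from %s",
         nrow(clin), sum(clin$event), path)
  clin
}

#' Write a clinical table
#' @param clin `ClinicalTable`.
#' @param path Output path.
#' @export
write_clinical <- function(clin, path) write_table(as.data.frame(clin), path)

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids. Lines with fewer than three fields are a format error.
#'
#' @param path GMT file.
#' @return Named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("GMT line with fewer than 3 fields (line ",
         paste(which(short), collapse = ", "), ")", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate set name in GMT", call. = FALSE)
  sets
}

#' Write a ceRNA network as edge-list and node-attribute TSVs
#'
#' @param net `CeRNANetwork` from [build_network()].
#' @param edge_path,node_path Output paths.
#' @export
write_network <- function(net, edge_path, node_path) {
  stopifnot(inherits(net, "CeRNANetwork"))
  write_table(net$edges, edge_path)
  write_table(net$nodes, node_path)
  invisible(net)
}

#' Match samples across two assays
#'
#' RNA-seq and miRNA-seq matrices typically cover different sample sets;
#' any operation that correlates across assays uses the intersection of
#' sample ids, optionally restricted to tumor samples, and requires at
#' least `min_per_group` samples.
#'
#' @param m1,m2 `ExpressionMatrix` objects.
#' @param sample_set `"tumor"` or `"all"`.
#' @param min_per_group Minimum matched samples required (default 3).
#' @return Character vector of matched sample ids.
#' @export
matched_samples <- function(m1, m2, sample_set = c("tumor", "all"),
                            min_per_group = 3L) {
  sample_set <- match.arg(sample_set)
  shared <- intersect(sample_ids(m1), sample_ids(m2))
  if (sample_set == "tumor") shared <- shared[m1$group[shared] == "tumor"]
  if (length(shared) < min_per_group)
    stop(sprintf("only %d matched %s samples (need >= %d)",
                 length(shared), sample_set, min_per_group), call. = FALSE)
  shared
}
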