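#' Read a cohort from standard files
#'
#' Counterpart of [write_cohort()] for real data: three count matrices, a
#' sample group map, an interaction table and a clinical table.
#'
#' @param mrna,lncrna,mirna Paths to count TSVs per class.
#' @param groups Path to a TSV with columns `sample_id`, `group`.
#' @param interactions Path to the miRNA-target TSV.
#' @param clinical Path to the clinical TSV.
#' @return List with `mrna`, `lncrna`, `mirna`, `db`, `clinical` (no
#'   truth).
#' @export
read_cohort <- function(mrna, lncrna, mirna, groups, interactions, clinical) {
  gm <- read_tsv_checked(groups)
  if (!all(c("sample_id", "group") %in% names(gm)))
    stop("group map needs columns sample_id, group", call. = FALSE)
  group_map <- stats::setNames(as.character(gm$group),
                               as.character(gm$sample_id))
  list(mrna = read_expression(mrna, "mRNA", group_map),
       lncrna = read_expression(lncrna, "lncRNA", group_map),
       mirna = read_expression(mirna, "miRNA", group_map),
       db = read_interactions(interactions),
       clinical = read_clinical(clinical),
       truth = NULL)
}

#' Run the full ceRNA discovery and prognosis workflow
#'
#' Stages, in order: log-CPM normalization and differential-expression
#' calls per RNA class; restriction of the interaction DB to DE RNAs;
#' three-gate ceRNA pair scoring; network assembly and hub extraction;
#' triplet extraction; Cox risk-score prognosis of each triplet
#' (hub-restricted triplets first) and per-hub-RNA survival screening;
#' optional gene-set over-representation of the DE mRNAs. Output is a
#' pure function of (cohort, cfg), so reruns on the same cohort and
#' config are identical.
#'
#' @param cohort List as returned by [simulate_cohort()] or
#'   [read_cohort()].
#' @param cfg `RunConfig`.
#' @param out_dir Optional directory; when given, all stage tables and a
#'   machine-readable `summary.json` are written there.
#' @param gmt_sets Optional named list of gene sets (from [read_gmt()])
#'   for enrichment of the DE mRNAs.
#' @param max_triplets Cap on the number of triplets taken to survival
#'   analysis (hub-restricted first, then by lexicographic id order).
#' @return List with `de` (per class), `pairs`, `network`, `triplets`,
#'   `risk` (per-triplet log-rank table), `risk_models`, `hub_survival`,
#'   `enrichment` (or NULL) and `summary`.
#' @export
run_all <- function(cohort, cfg = run_config(), out_dir = NULL,
                    gmt_sets = NULL, max_triplets = 20L) {
  stopifnot(inherits(cfg, "RunConfig"))
  logcpm <- list(mrna = log_cpm(cohort$mrna),
                 lncrna = log_cpm(cohort$lncrna),
                 mirna = log_cpm(cohort$mirna))
  de <- lapply(logcpm, call_de, cfg = cfg)

  de_lnc <- de_genes(de$lncrna)
  de_mrna <- de_genes(de$mrna)
  de_mir <- de_genes(de$mirna)
  db_de <- restrict_db(cohort$db,
                       mirnas = if (cfg$mirna_universe == "de") de_mir else
                         unique(cohort$db$records$mirna),
                       targets = c(de_lnc, de_mrna))
  universe <- unique(db_de$records$mirna)
  if (!length(universe))
    stop("stage cerna: no miRNA survives the DE restriction", call. = FALSE)

  pairs <- score_cerna_pairs(db_de, logcpm$lncrna, logcpm$mrna, logcpm$mirna,
                             cfg, universe = universe)
  net <- build_network(pairs, cfg)
  triplets <- extract_triplets(net, pairs)

  ord <- order(!triplets$in_hub_subnet, triplets$lncrna_id,
               triplets$mirna_id, triplets$mrna_id)
  todo <- utils::head(triplets[ord, , drop = FALSE], max_triplets)
  risk_models <- list()
  risk_rows <- list()
  for (i in seq_len(nrow(todo))) {
    tr <- todo[i, ]
    key <- paste(tr$lncrna_id, tr$mirna_id, tr$mrna_id, sep = "|")
    rm_i <- tryCatch(
      triplet_risk_analysis(tr, logcpm$lncrna, logcpm$mirna, logcpm$mrna,
                            cohort$clinical),
      error = function(e) {
        ce_log("triplet %s skipped: %s", key, conditionMessage(e))
        NULL
      })
    risk_models[[key]] <- rm_i
    risk_rows[[i]] <- data.frame(
      lncrna_id = tr$lncrna_id, mirna_id = tr$mirna_id,
      mrna_id = tr$mrna_id, in_hub_subnet = tr$in_hub_subnet,
      beta_lncrna = if (is.null(rm_i)) NA_real_ else unname(rm_i$betas[1]),
      beta_mirna = if (is.null(rm_i)) NA_real_ else unname(rm_i$betas[2]),
      beta_mrna = if (is.null(rm_i)) NA_real_ else unname(rm_i$betas[3]),
      chi_square = if (is.null(rm_i)) NA_real_ else rm_i$logrank$chi_square,
      logrank_p = if (is.null(rm_i)) NA_real_ else rm_i$logrank$p,
      stringsAsFactors = FALSE)
  }
  risk <- if (length(risk_rows)) do.call(rbind, risk_rows) else
    data.frame()

  hub_rows <- lapply(net$hubs, function(h) {
    cls <- net$nodes$class[net$nodes$id == h]
    m <- switch(cls, lncRNA = logcpm$lncrna, miRNA = logcpm$mirna,
                mRNA = logcpm$mrna)
    gs <- tryCatch(gene_survival(h, m, cohort$clinical),
                   error = function(e) NULL)
    data.frame(id = h, class = cls,
               logrank_p = if (is.null(gs)) NA_real_ else gs$logrank$p,
               stringsAsFactors = FALSE)
  })
  hub_survival <- do.call(rbind, hub_rows)

  enr <- NULL
  if (!is.null(gmt_sets))
    enr <- ora(de_mrna, gmt_sets, universe = gene_ids(cohort$mrna), cfg)

  summary <- list(
    config = cfg[setdiff(names(cfg), "paths")],
    de_counts = lapply(de, function(x)
      list(up = sum(x$status == "up"), down = sum(x$status == "down"),
           total = nrow(x))),
    pair_counts = list(candidates = nrow(pairs),
                       pass_overlap = sum(pairs$pass_overlap),
                       pass_pcc = sum(pairs$pass_pcc),
                       pass_all = sum(pairs$passes)),
    network = list(
      nodes = nrow(net$nodes), edges = nrow(net$edges),
      by_class = as.list(table(net$nodes$class)), hubs = net$hubs),
    triplets = list(total = nrow(triplets),
                    hub_restricted = sum(triplets$in_hub_subnet)),
    triplet_logrank_p = stats::setNames(
      as.list(risk$logrank_p),
      paste(risk$lncrna_id, risk$mirna_id, risk$mrna_id, sep = "|")),
    enrichment = if (is.null(enr)) NULL else
      list(tested = nrow(enr), significant = sum(enr$significant))
  )

  res <- list(de = de, pairs = pairs, network = net, triplets = triplets,
              risk = risk, risk_models = risk_models,
              hub_survival = hub_survival, enrichment = enr,
              summary = summary)
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cls in names(res$de))
    write_table(res$de[[cls]], file.path(out_dir, sprintf("de_%s.tsv", cls)))
  write_table(res$pairs, file.path(out_dir, "cerna_pairs.tsv"))
  write_network(res$network, file.path(out_dir, "network_edges.tsv"),
                file.path(out_dir, "network_nodes.tsv"))
  write_table(res$triplets, file.path(out_dir, "triplets.tsv"))
  write_table(res$risk, file.path(out_dir, "triplet_risk.tsv"))
  write_table(res$hub_survival, file.path(out_dir, "hub_survival.tsv"))
  if (!is.null(res$enrichment))
    write_table(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
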