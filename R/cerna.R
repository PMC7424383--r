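# Pair scoring implements the three-step ceRNA screen: (1) hypergeometric
# test on shared miRNAs, (2) positive Pearson co-expression of the
# lncRNA-mRNA pair, (3) regulation-similarity of the shared miRNAs'
# correlation profiles. A pair passes only if it clears all three gates.

#' Upper-tail hypergeometric overlap p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance that two sets
#' of sizes `K` and `n`, drawn from a universe of size `N`, share at least
#' `k` elements. Single code path used by both the shared-miRNA pair test
#' and gene-set over-representation.
#'
#' @param N Universe size.
#' @param K,n Sizes of the two sets (each `<= N`).
#' @param k Observed overlap (`<= min(K, n)`).
#' @return The upper-tail probability.
#' @export
overlap_pvalue <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N)
    stop("need 0 <= K, n <= N", call. = FALSE)
  if (k > min(K, n)) stop("overlap k exceeds min(K, n)", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Shared-miRNA hypergeometric test for one lncRNA-mRNA pair
#'
#' Tests whether the lncRNA and the mRNA share more targeting miRNAs than
#' expected by chance within the given miRNA universe.
#'
#' @param lnc,mrna Transcript ids (must be targets in `db` within the
#'   universe; otherwise an error).
#' @param db `InteractionDB`.
#' @param universe Character vector of miRNA ids defining the universe.
#' @return `NULL` when the pair shares no miRNA (such pairs are not
#'   scored); otherwise a list with `shared`, `overlap_p`, `N`, `K`, `n`,
#'   `k`.
#' @export
shared_mirna_test <- function(lnc, mrna, db, universe) {
  if (!length(universe)) stop("empty miRNA universe", call. = FALSE)
  universe <- unique(universe)
  mir_l <- intersect(mirnas_of(db, lnc), universe)
  mir_g <- intersect(mirnas_of(db, mrna), universe)
  if (!length(mir_l) || !length(mir_g))
    stop(sprintf("pair (%s, %s): no targeting miRNAs within universe", lnc, mrna),
         call. = FALSE)
  shared <- intersect(mir_l, mir_g)
  if (!length(shared)) return(NULL)
  N <- length(universe); K <- length(mir_l); n <- length(mir_g)
  list(shared = sort(shared),
       overlap_p = overlap_pvalue(N, K, n, length(shared)),
       N = N, K = K, n = n, k = length(shared))
}

#' Pearson co-expression of a lncRNA-mRNA pair
#'
#' Pearson r over the matched sample set (tumor-only by default) with a
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param lnc,mrna Transcript ids.
#' @param lnc_m,mrna_m logCPM `ExpressionMatrix` objects containing them.
#' @param cfg `RunConfig` (uses `correlation_sample_set`).
#' @return List with `pcc_r`, `pcc_p`, `n`.
#' @export
coexpression <- function(lnc, mrna, lnc_m, mrna_m, cfg = run_config()) {
  samples <- matched_samples(lnc_m, mrna_m, cfg$correlation_sample_set)
  x <- lnc_m$values[lnc, samples]
  y <- mrna_m$values[mrna, samples]
  pearson_with_p(x, y)
}

pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need >= 3 matched samples for a correlation", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(pcc_r = r, pcc_p = 2 * stats::pt(-abs(tval), df = n - 2), n = n)
}

#' Regulation-similarity score from two correlation profiles
#'
#' For `M` shared miRNAs with correlations `r_l[k] = corr(m_k, lncRNA)` and
#' `r_g[k] = corr(m_k, mRNA)`:
#' `1 - (1/M) * sum_k ( |r_l[k] - r_g[k]| / (|r_l[k]| + |r_g[k]|) )^M`.
#' Each normalized term lies in `[0, 1]`, so the score does too: 1 means
#' the miRNAs relate to both transcripts identically, 0 maximal
#' dissimilarity. A `0/0` term (both correlations exactly zero) counts as
#' 0 (identical null profiles).
#'
#' @param r_l,r_g Numeric vectors of equal length `M >= 1`.
#' @param exponent `"M"` (default, exponent is the number of shared
#'   miRNAs) or `"1"` (plain mean of normalized differences).
#' @return Score in `[0, 1]`.
#' @export
regsim_score <- function(r_l, r_g, exponent = c("M", "1")) {
  exponent <- match.arg(exponent)
  M <- length(r_l)
  if (M < 1 || length(r_g) != M)
    stop("need equal-length correlation vectors, M >= 1", call. = FALSE)
  denom <- abs(r_l) + abs(r_g)
  term <- ifelse(denom == 0, 0, abs(r_l - r_g) / denom)
  expo <- if (exponent == "M") M else 1
  1 - mean(term^expo)
}

#' Regulation similarity of a lncRNA-mRNA pair over its shared miRNAs
#'
#' Computes, for every shared miRNA, its Pearson correlation with the
#' lncRNA and with the mRNA over the matched sample set, and summarises
#' the two profiles with [regsim_score()]. A miRNA whose correlation is
#' undefined (zero variance) is dropped with a warning, reducing `M`;
#' if no miRNA remains the score is an error.
#'
#' @param lnc,mrna Transcript ids.
#' @param shared_mirnas Character vector of shared miRNA ids (`M >= 1`).
#' @param mir_m,lnc_m,mrna_m logCPM `ExpressionMatrix` objects.
#' @param cfg `RunConfig` (`correlation_sample_set`, `regsim_exponent`).
#' @return List with `regsim`, `M`, `corr_lnc`, `corr_mrna` (named by
#'   miRNA).
#' @export
regulation_similarity <- function(lnc, mrna, shared_mirnas,
                                  mir_m, lnc_m, mrna_m, cfg = run_config()) {
  if (!length(shared_mirnas)) stop("M must be >= 1", call. = FALSE)
  s1 <- matched_samples(mir_m, lnc_m, cfg$correlation_sample_set)
  s2 <- matched_samples(mir_m, mrna_m, cfg$correlation_sample_set)
  samples <- intersect(s1, s2)
  if (length(samples) < 3) stop("fewer than 3 matched samples", call. = FALSE)
  lvec <- lnc_m$values[lnc, samples]
  gvec <- mrna_m$values[mrna, samples]
  if (stats::sd(lvec) == 0 || stats::sd(gvec) == 0)
    stop("zero variance in lncRNA or mRNA expression", call. = FALSE)
  r_l <- r_g <- stats::setNames(numeric(0), character(0))
  for (mk in shared_mirnas) {
    mvec <- mir_m$values[mk, samples]
    if (stats::sd(mvec) == 0) {
      warning(sprintf("miRNA %s has zero variance; dropped from M", mk),
              call. = FALSE)
      next
    }
    r_l[mk] <- stats::cor(mvec, lvec)
    r_g[mk] <- stats::cor(mvec, gvec)
  }
  if (!length(r_l))
    stop("no shared miRNA with defined correlations (M reduced to 0)",
         call. = FALSE)
  list(regsim = regsim_score(r_l, r_g, cfg$regsim_exponent),
       M = length(r_l), corr_lnc = r_l, corr_mrna = r_g)
}

#' Score every candidate lncRNA-mRNA pair in an interaction DB
#'
#' Enumerates all (lncRNA, mRNA) target pairs sharing at least one miRNA
#' within the universe and applies the three gates. Pairs whose
#' co-expression or regulation similarity is undefined fail with the
#' reason logged.
#'
#' @param db `InteractionDB` (typically already restricted to DE RNAs).
#' @param lnc_m,mrna_m,mir_m logCPM `ExpressionMatrix` objects.
#' @param cfg `RunConfig`.
#' @param universe miRNA universe for the hypergeometric test; defaults to
#'   all miRNAs in `db`.
#' @return Data frame, one row per scored pair: `lncrna_id`, `mrna_id`,
#'   `M`, `shared_mirnas` (comma-joined), `overlap_p`, `pcc_r`, `pcc_p`,
#'   `regsim`, `passes`, plus gate columns `pass_overlap`, `pass_pcc`.
#' @export
score_cerna_pairs <- function(db, lnc_m, mrna_m, mir_m, cfg = run_config(),
                              universe = NULL) {
  if (is.null(universe)) universe <- unique(db$records$mirna)
  lncs <- sort(unique(db$records$target[db$records$target_class == "lncRNA"]))
  mrnas <- sort(unique(db$records$target[db$records$target_class == "mRNA"]))
  lncs <- intersect(lncs, gene_ids(lnc_m))
  mrnas <- intersect(mrnas, gene_ids(mrna_m))
  rows <- list()
  for (l in lncs) {
    for (g in mrnas) {
      ov <- tryCatch(shared_mirna_test(l, g, db, universe),
                     error = function(e) {
                       ce_log("pair (%s, %s) skipped: %s", l, g,
                              conditionMessage(e))
                       NULL
                     })
      if (is.null(ov)) next
      co <- tryCatch(coexpression(l, g, lnc_m, mrna_m, cfg),
                     error = function(e) NULL)
      rs <- tryCatch(
        suppressWarnings(regulation_similarity(l, g, ov$shared,
                                               mir_m, lnc_m, mrna_m, cfg)),
        error = function(e) NULL)
      pcc_r <- if (is.null(co)) NA_real_ else co$pcc_r
      pcc_p <- if (is.null(co)) NA_real_ else co$pcc_p
      regsim <- if (is.null(rs)) NA_real_ else rs$regsim
      pass_overlap <- ov$overlap_p < cfg$pair_p
      pass_pcc <- pass_overlap && !is.na(pcc_r) &&
        pcc_r > 0 && pcc_p < cfg$pcc_p
      passes <- pass_pcc && !is.na(regsim) && regsim > cfg$regsim_min
      if (passes && cfg$require_negative_mirna_corr)
        passes <- mean(rs$corr_lnc) < 0 && mean(rs$corr_mrna) < 0
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = l, mrna_id = g, M = ov$k,
        shared_mirnas = paste(ov$shared, collapse = ","),
        overlap_p = ov$overlap_p, pcc_r = pcc_r, pcc_p = pcc_p,
        regsim = regsim, pass_overlap = pass_overlap, pass_pcc = pass_pcc,
        passes = passes, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncrna_id = character(0), mrna_id = character(0),
               M = integer(0), shared_mirnas = character(0),
               overlap_p = numeric(0), pcc_r = numeric(0), pcc_p = numeric(0),
               regsim = numeric(0), pass_overlap = logical(0),
               pass_pcc = logical(0), passes = logical(0))
  ce_log("scored %d candidate pairs: %d pass overlap, %d pass PCC, %d pass all",
         nrow(out), sum(out$pass_overlap), sum(out$pass_pcc), sum(out$passes))
  out
}

#' Assemble the ceRNA network from passing pairs
#'
#' Every passing pair contributes edges miRNA-lncRNA and miRNA-mRNA for
#' each of its shared miRNAs (deduplicated), giving a network that is
#' bipartite by construction: every edge has a miRNA endpoint. Hubs are
#' the top `cfg$hub_k` nodes by degree, ties broken lexicographically.
#'
#' @param pairs Result of [score_cerna_pairs()] (rows with `passes` used).
#' @param cfg `RunConfig`.
#' @return Object of class `CeRNANetwork`: list with `nodes` (id, class,
#'   degree, is_hub), `edges` (source = miRNA, target, edge_type), `hubs`
#'   (ids in rank order).
#' @export
build_network <- function(pairs, cfg = run_config()) {
  pairs <- pairs[pairs$passes, , drop = FALSE]
  if (!nrow(pairs))
    stop("no passing ceRNA pair: relax thresholds or check inputs",
         call. = FALSE)
  edges <- list()
  for (i in seq_len(nrow(pairs))) {
    mirs <- strsplit(pairs$shared_mirnas[i], ",", fixed = TRUE)[[1]]
    edges[[i]] <- rbind(
      data.frame(source = mirs, target = pairs$lncrna_id[i],
                 edge_type = "miRNA-lncRNA", stringsAsFactors = FALSE),
      data.frame(source = mirs, target = pairs$mrna_id[i],
                 edge_type = "miRNA-mRNA", stringsAsFactors = FALSE))
  }
  edges <- unique(do.call(rbind, edges))
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE)
  deg <- igraph::degree(g)
  cls <- ifelse(names(deg) %in% edges$source, "miRNA",
                ifelse(names(deg) %in% pairs$lncrna_id, "lncRNA", "mRNA"))
  nodes <- data.frame(id = names(deg), class = cls, degree = as.integer(deg),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$degree, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  hubs <- utils::head(nodes$id, cfg$hub_k)
  nodes$is_hub <- nodes$id %in% hubs
  ce_log("network: %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges; top-%d hubs",
         nrow(nodes), sum(cls == "lncRNA"), sum(cls == "miRNA"),
         sum(cls == "mRNA"), nrow(edges), length(hubs))
  structure(list(nodes = nodes, edges = edges, hubs = hubs),
            class = "CeRNANetwork")
}

#' @export
print.CeRNANetwork <- function(x, ...) {
  cat(sprintf("CeRNANetwork: %d nodes, %d edges; hubs: %s\n",
              nrow(x$nodes), nrow(x$edges), paste(x$hubs, collapse = ", ")))
  invisible(x)
}

#' Extract lncRNA-miRNA-mRNA triplets from the network
#'
#' One triplet per (passing pair, shared miRNA). The full list is always
#' returned; `in_hub_subnet` flags triplets whose three members all belong
#' to the hub set (the hub-restricted sub-network).
#'
#' @param net `CeRNANetwork`.
#' @param pairs Result of [score_cerna_pairs()].
#' @return Data frame with `lncrna_id`, `mirna_id`, `mrna_id`,
#'   `in_hub_subnet`.
#' @export
extract_triplets <- function(net, pairs) {
  stopifnot(inherits(net, "CeRNANetwork"))
  pairs <- pairs[pairs$passes, , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), in_hub_subnet = logical(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    mirs <- strsplit(pairs$shared_mirnas[i], ",", fixed = TRUE)[[1]]
    data.frame(lncrna_id = pairs$lncrna_id[i], mirna_id = mirs,
               mrna_id = pairs$mrna_id[i], stringsAsFactors = FALSE)
  }))
  out$in_hub_subnet <- out$lncrna_id %in% net$hubs &
    out$mirna_id %in% net$hubs & out$mrna_id %in% net$hubs
  out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
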