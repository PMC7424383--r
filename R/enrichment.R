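#' Over-representation analysis of a gene list against gene sets
#'
#' For each set, tests whether the differential list overlaps it more than
#' chance within the universe: `p = P(X >= k)` with
#' `X ~ Hypergeometric(|universe|, |set & universe|, |list|)`, the same
#' hypergeometric code path as the shared-miRNA pair test. q-values are
#' BH-adjusted across all tested sets; a set is significant at
#' `q < cfg$enrich_q`.
#'
#' @param genes Character vector, the differential gene list (must be a
#'   subset of `universe`).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector, the background gene universe.
#' @param cfg `RunConfig`.
#' @return Data frame sorted by p: `set_name`, `overlap_k`, `set_size`,
#'   `list_size`, `universe_size`, `p`, `q`, `significant`.
#' @export
ora <- function(genes, sets, universe, cfg = run_config()) {
  universe <- unique(universe)
  genes <- unique(genes)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(genes)) stop("empty gene list", call. = FALSE)
  if (!all(genes %in% universe))
    stop("gene list must be a subset of the universe", call. = FALSE)
  if (!length(sets)) stop("no gene sets supplied", call. = FALSE)
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, genes))
    p <- if (K == 0) 1 else overlap_pvalue(N, K, n, k)
    data.frame(set_name = nm, overlap_k = k, set_size = K, list_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < cfg$enrich_q
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
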