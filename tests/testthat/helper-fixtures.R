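# Small in-code fixtures shared across test files.

options(ceRNAprog.quiet = TRUE)

tiny_counts <- function(genes = paste0("G", 1:3),
                        samples = paste0("S", 1:4),
                        group = c("tumor", "tumor", "normal", "normal"),
                        seed = 42) {
  set.seed(seed)
  vals <- matrix(rpois(length(genes) * length(samples), 50),
                 nrow = length(genes),
                 dimnames = list(genes, samples))
  expression_matrix(vals, "mRNA", group, "counts")
}

# logCPM matrix wrapping given values directly (for closed-form checks).
logcpm_from <- function(vals, rna_class = "mRNA",
                        group = rep(c("tumor", "normal"),
                                    each = ncol(vals) / 2)) {
  expression_matrix(vals, rna_class, group, "logCPM")
}

tiny_interactions <- function() {
  interaction_db(data.frame(
    mirna = c("miR-1", "miR-1", "miR-2", "miR-2", "miR-3"),
    target = c("L1", "G1", "L1", "G1", "G2"),
    target_class = c("lncRNA", "mRNA", "lncRNA", "mRNA", "mRNA"),
    stringsAsFactors = FALSE))
}

sort_records <- function(db) {
  r <- db$records
  r <- r[order(r$mirna, r$target), ]
  rownames(r) <- NULL
  r
}

random_clinical <- function(n, p_event = 0.7, id_prefix = "P") {
  clinical_table(data.frame(
    sample_id = paste0(id_prefix, seq_len(n)),
    time_days = round(rexp(n, 1 / 500), 3) + 1,
    event = rbinom(n, 1, p_event)))
}
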