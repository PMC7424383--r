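# Synthetic multi-omic cohort with known ground truth. Counts are
# negative binomial with a log2-link mean (Var = mu + phi*mu^2); planted
# differential expression is a fixed tumor-vs-normal log2 shift; planted
# ceRNA triplets couple their members through a per-tumor-sample latent
# factor (raising lncRNA and mRNA, lowering the shared miRNA); survival is
# exponential with hazard h0 * exp(beta' x) driven by one designated
# triplet, with independent uniform censoring.

default_sim_params <- function() {
  h0 <- log(2) / 600  # median survival ~600 days at baseline
  list(
    phi = 0.2,                 # NB dispersion: Var = mu + phi*mu^2
    mean_range = c(20, 2000),  # baseline mean counts, log-uniform
    de_frac = 0.15,            # fraction of genes per class shifted
    logfc = 2.0,               # |log2 FC| of planted DE genes
    latent_sd = 1.0,           # sd of the per-sample ceRNA factor
    latent_loading = 1.0,      # log2-scale loading of the factor
    cox_betas = c(0.7, -0.5, 0.7),  # lncRNA, miRNA, mRNA
    baseline_hazard = h0,
    censor_max = 3.1 / h0      # uniform censoring, ~30% censored
  )
}

#' Draw survival times from a Cox-exponential model
#'
#' Event times are exponential with hazard
#' `h0 * exp(features %*% betas)`; censoring times are independent
#' `Uniform(0, censor_max)`. Uses the current RNG state (set a seed
#' upstream for reproducibility).
#'
#' @param features Patients x features numeric matrix (rownames = ids);
#'   typically standardized expression.
#' @param betas Coefficient vector (length = ncol(features); 0s allowed).
#' @param baseline_hazard Baseline hazard per day.
#' @param censor_max Upper bound of the uniform censoring window.
#' @return `ClinicalTable` for the patients in `features`.
#' @export
simulate_survival <- function(features, betas,
                              baseline_hazard = log(2) / 600,
                              censor_max = 3.1 * 600 / log(2)) {
  stopifnot(is.matrix(features), length(betas) == ncol(features))
  eta <- drop(features %*% betas)
  n <- nrow(features)
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(eta))
  t_cens <- stats::runif(n, 0, censor_max)
  clinical_table(data.frame(
    sample_id = rownames(features),
    time_days = pmax(pmin(t_event, t_cens), 1e-6),
    event = as.integer(t_event <= t_cens)
  ))
}

#' Simulate a tumor/normal multi-omic cohort with planted ceRNA truth
#'
#' Generates negative-binomial count matrices for mRNA, lncRNA and miRNA,
#' a miRNA-target interaction DB (planted + decoy records), a clinical
#' table whose hazards are driven by the first planted triplet, and the
#' full ground truth. Planted triplet members are forced into the
#' differential set (lncRNA/mRNA up, miRNA down) so they survive the DE
#' screen; every planted miRNA targets every planted lncRNA and mRNA, so
#' each planted pair shares `n_triplets` miRNAs. Decoy interactions are
#' drawn uniformly over differential (non-planted) RNAs, the only
#' interactions that reach the pair-scoring stage.
#'
#' @param n_tumor,n_normal Sample counts (each >= 3).
#' @param n_mrna,n_lncrna,n_mirna Genes per class.
#' @param n_triplets Planted triplets (0 allowed for null cohorts).
#' @param n_decoys Decoy interaction records.
#' @param params Named list overriding [simulate_cohort()] defaults:
#'   `phi`, `mean_range`, `de_frac`, `logfc`, `latent_sd`,
#'   `latent_loading`, `cox_betas`, `baseline_hazard`, `censor_max`.
#' @param seed Integer; fully determines all outputs.
#' @return List with `mrna`, `lncrna`, `mirna` (counts
#'   `ExpressionMatrix`), `db` (`InteractionDB`), `clinical`
#'   (`ClinicalTable`) and `truth` (per-class DE table, planted triplets,
#'   Cox betas, designated survival triplet, seed).
#' @export
simulate_cohort <- function(n_tumor = 100, n_normal = 50, n_mrna = 300,
                            n_lncrna = 100, n_mirna = 60, n_triplets = 3,
                            n_decoys = 50, params = list(), seed = 1L) {
  if (n_tumor < 3 || n_normal < 3)
    stop("need >= 3 samples per group", call. = FALSE)
  if (n_triplets < 0) stop("n_triplets must be >= 0", call. = FALSE)
  if (n_triplets > min(n_mrna, n_lncrna, n_mirna))
    stop("n_triplets exceeds a class size", call. = FALSE)
  p <- utils::modifyList(default_sim_params(), params)
  set.seed(as.integer(seed))

  samples <- c(sprintf("T%03d", seq_len(n_tumor)),
               sprintf("N%03d", seq_len(n_normal)))
  group <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
  ids <- list(mRNA = sprintf("MRNA%04d", seq_len(n_mrna)),
              lncRNA = sprintf("LNC%04d", seq_len(n_lncrna)),
              miRNA = sprintf("MIR%04d", seq_len(n_mirna)))
  sizes <- c(mRNA = n_mrna, lncRNA = n_lncrna, miRNA = n_mirna)

  # planted triplet members: the first n_triplets genes of each class
  planted <- if (n_triplets > 0) data.frame(
    lncrna_id = ids$lncRNA[seq_len(n_triplets)],
    mirna_id = ids$miRNA[seq_len(n_triplets)],
    mrna_id = ids$mRNA[seq_len(n_triplets)],
    stringsAsFactors = FALSE
  ) else data.frame(lncrna_id = character(0), mirna_id = character(0),
                    mrna_id = character(0), stringsAsFactors = FALSE)
  planted_of <- list(mRNA = planted$mrna_id, lncRNA = planted$lncrna_id,
                     miRNA = planted$mirna_id)
  planted_sign <- c(mRNA = 1, lncRNA = 1, miRNA = -1)

  # per-tumor-sample latent factor, one per planted triplet
  A <- if (n_triplets > 0)
    matrix(stats::rnorm(n_triplets * n_tumor, sd = p$latent_sd),
           nrow = n_triplets) else NULL

  de_truth <- list()
  mats <- list()
  for (cls in names(ids)) {
    ng <- sizes[[cls]]
    mu <- exp(stats::runif(ng, log(p$mean_range[1]), log(p$mean_range[2])))
    delta <- numeric(ng)
    names(delta) <- ids[[cls]]
    if (p$logfc > 0) {
      n_de <- max(floor(p$de_frac * ng), length(planted_of[[cls]]))
      pool <- setdiff(ids[[cls]], planted_of[[cls]])
      extra <- sample(pool, n_de - length(planted_of[[cls]]))
      delta[extra] <- p$logfc * sample(c(-1, 1), length(extra), replace = TRUE)
      delta[planted_of[[cls]]] <- p$logfc * planted_sign[[cls]]
    }
    log2mu <- matrix(log2(mu), ng, n_tumor + n_normal)
    log2mu[, seq_len(n_tumor)] <- log2mu[, seq_len(n_tumor)] + delta
    if (n_triplets > 0) {
      sgn <- if (cls == "miRNA") -1 else 1
      for (t in seq_len(n_triplets)) {
        g <- match(planted_of[[cls]][t], ids[[cls]])
        log2mu[g, seq_len(n_tumor)] <- log2mu[g, seq_len(n_tumor)] +
          sgn * p$latent_loading * A[t, ]
      }
    }
    counts <- matrix(
      stats::rnbinom(length(log2mu), mu = 2^log2mu, size = 1 / p$phi),
      nrow = ng, dimnames = list(ids[[cls]], samples))
    mats[[cls]] <- expression_matrix(counts, cls, group, scale = "counts")
    de_truth[[cls]] <- data.frame(gene_id = ids[[cls]],
                                  true_logfc = unname(delta),
                                  stringsAsFactors = FALSE)
  }

  # interaction DB: full bipartite wiring over planted members + decoys
  rec <- list()
  if (n_triplets > 0) {
    rec[[1]] <- expand.grid(mirna = planted$mirna_id,
                            target = planted$lncrna_id,
                            stringsAsFactors = FALSE)
    rec[[1]]$target_class <- "lncRNA"
    rec[[2]] <- expand.grid(mirna = planted$mirna_id,
                            target = planted$mrna_id,
                            stringsAsFactors = FALSE)
    rec[[2]]$target_class <- "mRNA"
  }
  de_ids <- lapply(names(ids), function(cls)
    de_truth[[cls]]$gene_id[de_truth[[cls]]$true_logfc != 0])
  names(de_ids) <- names(ids)
  pool_mir <- setdiff(de_ids$miRNA, planted$mirna_id)
  if (!length(pool_mir)) pool_mir <- setdiff(ids$miRNA, planted$mirna_id)
  pool_tgt <- c(setdiff(de_ids$lncRNA, planted$lncrna_id),
                setdiff(de_ids$mRNA, planted$mrna_id))
  if (!length(pool_tgt))
    pool_tgt <- c(setdiff(ids$lncRNA, planted$lncrna_id),
                  setdiff(ids$mRNA, planted$mrna_id))
  combos <- expand.grid(mirna = pool_mir, target = pool_tgt,
                        stringsAsFactors = FALSE)
  n_dec <- min(n_decoys, nrow(combos))
  if (n_dec < n_decoys)
    warning(sprintf("only %d decoy combinations available (asked %d)",
                    n_dec, n_decoys), call. = FALSE)
  decoys <- combos[sample.int(nrow(combos), n_dec), , drop = FALSE]
  decoys$target_class <- ifelse(decoys$target %in% ids$lncRNA,
                                "lncRNA", "mRNA")
  rec[[length(rec) + 1L]] <- decoys
  db <- interaction_db(do.call(rbind, rec))

  # survival driven by the designated (first) triplet's observed expression
  tumor_ids <- samples[seq_len(n_tumor)]
  if (n_triplets > 0) {
    designated <- planted[1, , drop = FALSE]
    members <- c(designated$lncrna_id, designated$mirna_id,
                 designated$mrna_id)
    lc <- lapply(mats[c("lncRNA", "miRNA", "mRNA")], log_cpm)
    X <- cbind(lc$lncRNA$values[members[1], tumor_ids],
               lc$miRNA$values[members[2], tumor_ids],
               lc$mRNA$values[members[3], tumor_ids])
    dimnames(X) <- list(tumor_ids, members)
    X <- scale(X)
    betas <- p$cox_betas
  } else {
    designated <- NULL
    X <- matrix(0, n_tumor, 1, dimnames = list(tumor_ids, "null"))
    betas <- 0
  }
  clinical <- simulate_survival(X, betas, p$baseline_hazard, p$censor_max)

  truth <- list(de = de_truth, planted_triplets = planted,
                cox_betas = p$cox_betas, designated_triplet = designated,
                params = p, rng_seed = as.integer(seed))
  ce_log(paste0("simulated cohort: %d tumor / %d normal; ",
                "%d/%d/%d mRNA/lncRNA/miRNA; %d triplets, %d DB records"),
         n_tumor, n_normal, n_mrna, n_lncrna, n_mirna, n_triplets,
         nrow(db$records))
  list(mrna = mats$mRNA, lncrna = mats$lncRNA, mirna = mats$miRNA,
       db = db, clinical = clinical, truth = truth)
}

#' Write a simulated cohort to a directory of standard files
#'
#' Expression TSVs per class, interaction and clinical TSVs, a sample
#' group map, and the ground truth (planted triplets + per-class DE
#' tables).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$mrna, file.path(dir, "mrna_counts.tsv"))
  write_expression(cohort$lncrna, file.path(dir, "lncrna_counts.tsv"))
  write_expression(cohort$mirna, file.path(dir, "mirna_counts.tsv"))
  write_table(cohort$db$records, file.path(dir, "interactions.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_table(data.frame(sample_id = names(cohort$mrna$group),
                         group = unname(cohort$mrna$group)),
              file.path(dir, "sample_groups.tsv"))
  write_table(cohort$truth$planted_triplets,
              file.path(dir, "truth_triplets.tsv"))
  for (cls in names(cohort$truth$de))
    write_table(cohort$truth$de[[cls]],
                file.path(dir, sprintf("truth_de_%s.tsv", cls)))
  invisible(dir)
}
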