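#' Ground truth for synthetic differential-expression tables
#'
#' Plants genes of the five temporal classes seen when comparing 6 h and
#' 24 h stimulation contrasts: `null` (never regulated),
#' `early_transient` (6 h only), `late_onset` (24 h only), `prolonged`
#' (both timepoints, same direction) and `biphasic` (both, opposite
#' direction). True log2 fold changes are drawn uniformly in
#' `lfc_range` with random sign; baseline abundance is log-normal FPM
#' (fragments per million), so a tail of genes falls below typical
#' abundance filters, as in real data.
#'
#' @param n_genes number of genes.
#' @param class_probs named probabilities over the five classes; must
#'   sum to 1.
#' @param lfc_range magnitude range of true |log2FC| for regulated
#'   genes.
#' @param fpm_meanlog,fpm_sdlog log-normal parameters of baseline FPM.
#' @param biotype_probs named probabilities over
#'   `protein_coding` / `lncRNA`, emulating the >90% / <10% split of
#'   regulated genes.
#' @param seed integer seed.
#' @return `data.frame` with `gene_id`, `biotype`, `class`,
#'   `fpm_baseline`, `lfc_6h`, `lfc_24h`.
#' @export
simulate_de_truth <- function(n_genes = 5000,
                              class_probs = c(null = 0.70,
                                              early_transient = 0.15,
                                              late_onset = 0.05,
                                              prolonged = 0.08,
                                              biphasic = 0.02),
                              lfc_range = c(0.7, 3),
                              fpm_meanlog = log(20), fpm_sdlog = 1.2,
                              biotype_probs = c(protein_coding = 0.92,
                                                lncRNA = 0.08),
                              seed = 1L) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-8)
  set.seed(as.integer(seed))
  cls <- sample(names(class_probs), n_genes, replace = TRUE,
                prob = class_probs)
  mag <- runif(n_genes, lfc_range[1], lfc_range[2]) *
    sample(c(-1, 1), n_genes, replace = TRUE)
  lfc6 <- ifelse(cls %in% c("early_transient", "prolonged", "biphasic"),
                 mag, 0)
  lfc24 <- ifelse(cls %in% c("late_onset", "prolonged"), mag,
                  ifelse(cls == "biphasic", -mag, 0))
  data.frame(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    biotype = sample(names(biotype_probs), n_genes, replace = TRUE,
                     prob = biotype_probs),
    class = cls,
    fpm_baseline = rlnorm(n_genes, fpm_meanlog, fpm_sdlog),
    lfc_6h = lfc6,
    lfc_24h = lfc24,
    stringsAsFactors = FALSE
  )
}

#' Ground truth for single-agonist vs co-stimulation DE contrasts
#'
#' Plants, at one timepoint, genes regulated by agonist A only, by B
#' only, by both, and genes recruited only under co-stimulation. Genes
#' already regulated by a single agonist keep their direction under
#' co-stimulation and are enhanced by a common multiplicative `slope`
#' on the log2FC scale, which is what the overlap regression downstream
#' should recover.
#'
#' @inheritParams simulate_de_truth
#' @param p_a,p_b marginal probabilities that a gene responds to A / B
#'   alone (drawn independently, so some genes respond to both).
#' @param p_recruit probability that an otherwise-null gene is recruited
#'   under co-stimulation.
#' @param slope true enhancement factor of combined over single log2FC.
#' @return `data.frame` with `gene_id`, `biotype`, `fpm_baseline`,
#'   `lfc_A`, `lfc_B`, `lfc_AB`.
#' @export
simulate_synergy_de_truth <- function(n_genes = 3000, p_a = 0.05,
                                      p_b = 0.10, p_recruit = 0.15,
                                      slope = 1.4,
                                      lfc_range = c(0.7, 3),
                                      fpm_meanlog = log(20),
                                      fpm_sdlog = 1.2,
                                      biotype_probs = c(protein_coding = 0.92,
                                                        lncRNA = 0.08),
                                      seed = 1L) {
  set.seed(as.integer(seed))
  in_a <- runif(n_genes) < p_a
  in_b <- runif(n_genes) < p_b
  sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
  mag_a <- runif(n_genes, lfc_range[1], lfc_range[2])
  mag_b <- runif(n_genes, lfc_range[1], lfc_range[2])
  lfc_a <- ifelse(in_a, sgn * mag_a, 0)
  # shared sign: co-regulated genes move the same way under both agonists
  lfc_b <- ifelse(in_b, sgn * mag_b, 0)
  single <- ifelse(in_a & in_b, (lfc_a + lfc_b) / 2,
                   ifelse(in_a, lfc_a, lfc_b))
  recruited <- !(in_a | in_b) & runif(n_genes) < p_recruit
  lfc_rec <- sgn * runif(n_genes, lfc_range[1], lfc_range[2])
  lfc_ab <- ifelse(in_a | in_b, slope * single,
                   ifelse(recruited, lfc_rec, 0))
  data.frame(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    biotype = sample(names(biotype_probs), n_genes, replace = TRUE,
                     prob = biotype_probs),
    fpm_baseline = rlnorm(n_genes, fpm_meanlog, fpm_sdlog),
    lfc_A = lfc_a, lfc_B = lfc_b, lfc_AB = lfc_ab,
    stringsAsFactors = FALSE
  )
}

#' Simulate two DE callers' result tables from a planted truth
#'
#' Emulates the outputs of two differential-expression callers run on
#' the same experiment: shared gene ids and abundances, per-caller noisy
#' log2 fold changes, and per-caller FDR values. One table pair is
#' produced per `lfc_*` column of `truth` (timepoints `lfc_6h`,
#' `lfc_24h` of [simulate_de_truth()], or conditions `lfc_A`, `lfc_B`,
#' `lfc_AB` of [simulate_synergy_de_truth()]).
#'
#' FDR model: with `fdr_model = "stochastic"`, truly regulated
#' gene/contrast pairs get `10^-U(3, 8)` and null pairs an independent
#' `U(0, 1)` per caller (so the chance a null gene clears FDR 0.01 in
#' both callers is 1e-4). With `"deterministic"` (the default whenever
#' both `sd_log2fc` are 0) regulated pairs get 1e-4 and null pairs 1,
#' and log2FC equals truth exactly, so the tables reproduce the truth.
#'
#' @param truth a truth table from [simulate_de_truth()] or
#'   [simulate_synergy_de_truth()].
#' @param sd_log2fc length-2 numeric, per-caller SD of additive log2FC
#'   noise.
#' @param fdr_model `"stochastic"` or `"deterministic"` (see above).
#' @param callers names of the two callers.
#' @param seed integer seed.
#' @return named list of `data.frame`s, one per caller, each with
#'   columns `gene_id`, `biotype`, `contrast`, `log2fc`, `fdr`,
#'   `fpm_control`, `fpm_treated`.
#' @export
simulate_de_tables <- function(truth, sd_log2fc = c(0.1, 0.1),
                               fdr_model = if (all(sd_log2fc == 0))
                                 "deterministic" else "stochastic",
                               callers = c("deseq2", "edger"),
                               seed = 1L) {
  fdr_model <- match.arg(fdr_model, c("stochastic", "deterministic"))
  stopifnot(length(sd_log2fc) == 2, all(sd_log2fc >= 0))
  lfc_cols <- grep("^lfc_", names(truth), value = TRUE)
  if (length(lfc_cols) == 0) stop("truth has no lfc_* columns")
  set.seed(as.integer(seed))
  n <- nrow(truth)
  out <- list()
  for (k in 1:2) {
    rows <- list()
    for (col in lfc_cols) {
      true_lfc <- truth[[col]]
      regulated <- true_lfc != 0
      lfc <- true_lfc + if (sd_log2fc[k] > 0) rnorm(n, 0, sd_log2fc[k]) else 0
      fdr <- if (fdr_model == "stochastic") {
        ifelse(regulated, 10^-runif(n, 3, 8), runif(n))
      } else {
        ifelse(regulated, 1e-4, 1)
      }
      rows[[col]] <- data.frame(
        gene_id = truth$gene_id,
        biotype = truth$biotype,
        contrast = sub("^lfc_", "", col),
        log2fc = lfc,
        fdr = fdr,
        fpm_control = truth$fpm_baseline,
        fpm_treated = truth$fpm_baseline * 2^true_lfc,
        stringsAsFactors = FALSE
      )
    }
    out[[callers[k]]] <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  out
}
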