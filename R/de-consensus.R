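#' Thresholds of the two-caller consensus DE filter
#'
#' A gene counts as regulated only if both differential-expression
#' callers agree: FDR at most `fdr_max` in both, concordant direction,
#' consensus |log2FC| of at least `min_abs_log2fc`, and a
#' direction-dependent abundance requirement — more than `min_fpm` FPM
#' on average in the control arm for downregulated genes and in the
#' treated arm for upregulated ones (low-abundance transcription noise
#' is filtered on the side where the gene must actually be expressed).
#'
#' @param fdr_max per-caller FDR cut-off (default 0.01).
#' @param min_abs_log2fc minimal |consensus log2FC|
#'   (default `log2(1.5)`).
#' @param min_fpm abundance threshold in FPM, exceeded strictly
#'   (default 5).
#' @return an object of class `consensus_thresholds`.
#' @export
consensus_thresholds <- function(fdr_max = 0.01,
                                 min_abs_log2fc = log2(1.5),
                                 min_fpm = 5) {
  stopifnot(fdr_max > 0, fdr_max <= 1, min_abs_log2fc > 0, min_fpm > 0)
  structure(list(fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc,
                 min_fpm = min_fpm),
            class = "consensus_thresholds")
}

#' Apply the two-caller consensus filter
#'
#' Retains a gene iff (i) FDR <= `fdr_max` in both callers, (ii) the
#' two callers agree on the direction of change, (iii) the consensus
#' log2FC — the arithmetic mean of the two callers' estimates — has
#' magnitude >= `min_abs_log2fc`, and (iv) the FPM side rule holds
#' (treated-arm mean > `min_fpm` for up, control-arm mean for down).
#' Genes significant in both callers but with opposite signs are
#' excluded and reported in the `"discordant"` attribute, never
#' silently dropped.
#'
#' @param tables named list of the two callers' result tables
#'   (`data.frame`s with `gene_id`, `log2fc`, `fdr`, `fpm_control`,
#'   `fpm_treated`, optionally `biotype` and `contrast`), e.g. from
#'   [simulate_de_tables()] or read from TSV.
#' @param thresholds a [consensus_thresholds()].
#' @param contrast optional value to subset each table's `contrast`
#'   column (condition/timepoint) before filtering.
#' @return `data.frame` of retained genes: `gene_id`, `biotype`,
#'   per-caller `log2fc_1`/`log2fc_2` and `fdr_1`/`fdr_2`,
#'   `consensus_log2fc`, `direction` (`"up"`/`"down"`), mean
#'   `fpm_control`/`fpm_treated`. Attributes: `"discordant"` (excluded
#'   sign-conflict genes), `"thresholds"`.
#' @export
apply_consensus_filter <- function(tables, thresholds = consensus_thresholds(),
                                   contrast = NULL) {
  stopifnot(length(tables) == 2)
  t1 <- tables[[1]]; t2 <- tables[[2]]
  if (!is.null(contrast)) {
    t1 <- t1[t1$contrast == contrast, , drop = FALSE]
    t2 <- t2[t2$contrast == contrast, , drop = FALSE]
  }
  need <- c("gene_id", "log2fc", "fdr", "fpm_control", "fpm_treated")
  stopifnot(all(need %in% names(t1)), all(need %in% names(t2)))
  if (anyDuplicated(t1$gene_id) || anyDuplicated(t2$gene_id))
    stop("duplicated gene ids within a table; subset by contrast first")

  m <- merge(t1, t2, by = "gene_id", suffixes = c("_1", "_2"))
  biotype <- if ("biotype_1" %in% names(m)) m$biotype_1
             else if ("biotype" %in% names(m)) m$biotype
             else rep(NA_character_, nrow(m))

  sig_both <- m$fdr_1 <= thresholds$fdr_max & m$fdr_2 <= thresholds$fdr_max
  sgn1 <- sign(m$log2fc_1); sgn2 <- sign(m$log2fc_2)
  concordant <- sgn1 == sgn2 & sgn1 != 0
  consensus <- (m$log2fc_1 + m$log2fc_2) / 2
  big <- abs(consensus) >= thresholds$min_abs_log2fc
  fpm_ctrl <- (m$fpm_control_1 + m$fpm_control_2) / 2
  fpm_trt <- (m$fpm_treated_1 + m$fpm_treated_2) / 2
  fpm_ok <- ifelse(consensus > 0, fpm_trt > thresholds$min_fpm,
                   fpm_ctrl > thresholds$min_fpm)

  keep <- sig_both & concordant & big & fpm_ok
  out <- data.frame(
    gene_id = m$gene_id[keep],
    biotype = biotype[keep],
    log2fc_1 = m$log2fc_1[keep], log2fc_2 = m$log2fc_2[keep],
    fdr_1 = m$fdr_1[keep], fdr_2 = m$fdr_2[keep],
    consensus_log2fc = consensus[keep],
    direction = ifelse(consensus[keep] > 0, "up", "down"),
    fpm_control = fpm_ctrl[keep], fpm_treated = fpm_trt[keep],
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL

  disc <- sig_both & !concordant & (sgn1 != 0 | sgn2 != 0)
  attr(out, "discordant") <- data.frame(
    gene_id = m$gene_id[disc],
    log2fc_1 = m$log2fc_1[disc], log2fc_2 = m$log2fc_2[disc],
    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}

#' Temporal classification of regulated genes
#'
#' Classifies every gene regulated at either timepoint:
#' `early_transient` (6 h only), `late_onset` (24 h only), `prolonged`
#' (both timepoints, same direction), `biphasic` (both, opposite
#' direction). The classes partition the union of the two sets exactly.
#' The intersection is reported relative to the 24 h set (the
#' convention used when quoting "x% of the late genes were already
#' regulated early") and, secondarily, relative to the 6 h set.
#'
#' @param set_6h,set_24h retained-gene tables from
#'   [apply_consensus_filter()] run with identical thresholds at the two
#'   timepoints.
#' @return `data.frame` with `gene_id`, `class`, `log2fc_6h`,
#'   `log2fc_24h`; attribute `"overlap"` is a list with `n_6h`, `n_24h`,
#'   `n_both`, `fraction_of_24h`, `fraction_of_6h` (fractions `NA` and
#'   flagged when the denominator set is empty).
#' @export
classify_temporal <- function(set_6h, set_24h) {
  g6 <- set_6h$gene_id; g24 <- set_24h$gene_id
  all_genes <- sort(union(g6, g24))
  l6 <- set_6h$consensus_log2fc[match(all_genes, g6)]
  l24 <- set_24h$consensus_log2fc[match(all_genes, g24)]
  in6 <- all_genes %in% g6
  in24 <- all_genes %in% g24
  cls <- ifelse(in6 & !in24, "early_transient",
         ifelse(!in6 & in24, "late_onset",
         ifelse(sign(l6) == sign(l24), "prolonged", "biphasic")))
  n_both <- sum(in6 & in24)
  overlap <- list(
    n_6h = length(g6), n_24h = length(g24), n_both = n_both,
    fraction_of_24h = if (length(g24) > 0) n_both / length(g24) else NA_real_,
    fraction_of_6h = if (length(g6) > 0) n_both / length(g6) else NA_real_,
    flag = if (length(g24) == 0) "empty 24 h set" else "ok")
  out <- data.frame(gene_id = all_genes, class = cls,
                    log2fc_6h = l6, log2fc_24h = l24,
                    stringsAsFactors = FALSE)
  attr(out, "overlap") <- overlap
  out
}

#' Recruited vs enhanced genes under co-stimulation
#'
#' Partitions the combined-condition gene set against the two
#' single-agonist sets: genes regulated only under co-stimulation are
#' `recruited`; genes already regulated by a single agonist and still
#' regulated under co-stimulation form the `overlap`, whose enhancement
#' is quantified as the zero-intercept least-squares slope of combined
#' log2FC on single-agonist log2FC (a slope above 1 means stronger
#' regulation of the same genes); genes regulated singly but lost under
#' co-stimulation are `lost`. Genes whose direction flips between
#' single and combined stimulation are counted separately. A
#' free-intercept slope and a gene-bootstrap CI for the zero-intercept
#' slope are also reported. The slope is invariant to rescaling all
#' log2FC by a common factor.
#'
#' @param set_a,set_b,set_ab retained-gene tables from
#'   [apply_consensus_filter()] for the two single conditions and the
#'   combination, filtered with identical thresholds.
#' @param n_boot gene-bootstrap resamples for the slope CI.
#' @param seed integer seed for the bootstrap.
#' @return list of class `synergy_gene_accounting`: `recruited`,
#'   `overlap`, `lost` (gene id vectors), `n_flipped`, `slope`
#'   (zero-intercept), `slope_ci`, `slope_free_intercept`, and the
#'   overlap regression table `overlap_lfc` (`gene_id`, `single`,
#'   `combined`). With fewer than 3 overlap genes the slope is `NA`
#'   and flagged.
#' @export
synergy_gene_accounting <- function(set_a, set_b, set_ab, n_boot = 200,
                                    seed = 1L) {
  ga <- set_a$gene_id; gb <- set_b$gene_id; gab <- set_ab$gene_id
  singles <- union(ga, gb)
  recruited <- sort(setdiff(gab, singles))
  lost <- sort(setdiff(singles, gab))
  overlap <- sort(intersect(gab, singles))

  # single-agonist log2FC: mean over the single sets containing the gene
  la <- set_a$consensus_log2fc[match(overlap, ga)]
  lb <- set_b$consensus_log2fc[match(overlap, gb)]
  single <- rowMeans(cbind(la, lb), na.rm = TRUE)
  combined <- set_ab$consensus_log2fc[match(overlap, gab)]
  n_flipped <- sum(sign(single) != sign(combined))

  slope <- slope_free <- NA_real_
  slope_ci <- c(NA_real_, NA_real_)
  flag <- "ok"
  if (length(overlap) < 3) {
    flag <- "fewer than 3 overlap genes; slope not computed"
  } else {
    slope <- sum(single * combined) / sum(single^2)
    mx <- mean(single); my <- mean(combined)
    slope_free <- sum((single - mx) * (combined - my)) /
      sum((single - mx)^2)
    if (n_boot > 0) {
      set.seed(as.integer(seed))
      bs <- replicate(n_boot, {
        i <- sample.int(length(overlap), replace = TRUE)
        sum(single[i] * combined[i]) / sum(single[i]^2)
      })
      slope_ci <- quantile(bs, c(0.025, 0.975), names = FALSE)
    }
  }
  structure(list(
    recruited = recruited, overlap = overlap, lost = lost,
    n_flipped = n_flipped, slope = slope, slope_ci = slope_ci,
    slope_free_intercept = slope_free,
    overlap_lfc = data.frame(gene_id = overlap, single = single,
                             combined = combined,
                             stringsAsFactors = FALSE),
    flag = flag
  ), class = "synergy_gene_accounting")
}

#' @export
print.synergy_gene_accounting <- function(x, ...) {
  cat("co-stimulation gene accounting\n")
  cat(sprintf("  recruited: %d, overlap (enhanced): %d, lost: %d, direction flips: %d\n",
              length(x$recruited), length(x$overlap), length(x$lost),
              x$n_flipped))
  if (!is.na(x$slope))
    cat(sprintf("  enhancement slope (through origin): %.3f [%.3f, %.3f]; free intercept: %.3f\n",
                x$slope, x$slope_ci[1], x$slope_ci[2],
                x$slope_free_intercept))
  if (!identical(x$flag, "ok")) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Biotype composition of a gene set
#'
#' Fractions of protein-coding, lncRNA and other genes among a retained
#' set; missing biotypes are reported as `other`. Fractions sum to 1.
#'
#' @param gene_set a retained-gene table with a `biotype` column.
#' @return named numeric vector of fractions over
#'   `protein_coding`, `lncRNA`, `other`.
#' @export
biotype_partition <- function(gene_set) {
  b <- gene_set$biotype
  b[is.na(b) | !(b %in% c("protein_coding", "lncRNA"))] <- "other"
  n <- length(b)
  if (n == 0) return(c(protein_coding = NA_real_, lncRNA = NA_real_,
                       other = NA_real_))
  c(protein_coding = sum(b == "protein_coding") / n,
    lncRNA = sum(b == "lncRNA") / n,
    other = sum(b == "other") / n)
}
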