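# Shared fixtures, all generated in code.

# Small noise-free plate image with well-separated disks inside the
# default gates.
make_clean_image <- function(n_cells = 12, seed = 42, width = 256,
                             height = 256, dose = 100) {
  cfg <- sim_config(n_cells_per_well = n_cells, width = width,
                    height = height, noise_sd = 0,
                    transfection_fraction = 1,
                    radius_range = c(6, 10), rng_seed = seed)
  tab <- simulate_cell_table(cfg, stimulus_model(pmax = 1),
                             dose = dose, avoid_overlap = TRUE)
  img <- render_image_pair(tab, cfg, background = 0, noise_sd = 0)
  list(cfg = cfg, tab = tab, img = img)
}

default_gates <- function() {
  detection_params(threshold_delta = 1000, rolling_ball_radius = 20,
                   min_area = 40, max_area = 700, min_circularity = 0.8)
}

# match detected records to ground-truth table by nearest centroid
match_centroids <- function(cells, tab) {
  vapply(seq_len(nrow(cells)), function(i) {
    d2 <- (tab$x - cells$x[i])^2 + (tab$y - cells$y[i])^2
    which.min(d2)
  }, integer(1))
}

# summaries for a simulated well at given stimulus settings
well_summary_at <- function(model, dose, costim = FALSE, n = 10000,
                            seed = 1, threshold = 500) {
  cfg <- sim_config(n_cells_per_well = n, noise_sd = 0,
                    transfection_fraction = 0.5, rng_seed = seed)
  tab <- simulate_cell_table(cfg, model, dose, costim = costim,
                             seed = seed)
  summarize_well(tab, threshold)
}

# independent brute-force re-implementation of the consensus rules,
# evaluated gene by gene (the oracle for the filter)
brute_force_consensus <- function(t1, t2, fdr_max = 0.01,
                                  min_lfc = log2(1.5), min_fpm = 5) {
  genes <- intersect(t1$gene_id, t2$gene_id)
  keep <- character(0)
  for (g in genes) {
    r1 <- t1[t1$gene_id == g, ]
    r2 <- t2[t2$gene_id == g, ]
    if (r1$fdr > fdr_max) next
    if (r2$fdr > fdr_max) next
    if (sign(r1$log2fc) != sign(r2$log2fc) || r1$log2fc == 0) next
    cons <- (r1$log2fc + r2$log2fc) / 2
    if (abs(cons) < min_lfc) next
    if (cons > 0) {
      if ((r1$fpm_treated + r2$fpm_treated) / 2 <= min_fpm) next
    } else {
      if ((r1$fpm_control + r2$fpm_control) / 2 <= min_fpm) next
    }
    keep <- c(keep, g)
  }
  sort(keep)
}
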