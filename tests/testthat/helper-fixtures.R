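# Small in-code fixtures shared across test files.

# A toy plate + layout for the normalization primitives (these operate on
# plain data frames and do not require a full 384-well plate).
toy_plate <- function(lib, neg = c(1000, 1000), nt = NULL, pos = NULL,
                      plate_id = "p1") {
  rlu <- c(lib, neg, nt, pos)
  role <- c(rep("library", length(lib)), rep("neg_control", length(neg)),
            rep("untreated", length(nt)), rep("pos_control", length(pos)))
  wells <- all_wells()[seq_along(rlu)]
  target <- ifelse(role == "library", paste0("g", seq_along(rlu)), "")
  plate <- data.frame(plate_id = plate_id, sample_id = "s1",
                      replicate_id = "R1", well = wells, rlu = rlu,
                      stringsAsFactors = FALSE)
  layout <- data.frame(plate_id = plate_id, well = wells, role = role,
                       target = target, stringsAsFactors = FALSE)
  list(plate = plate, layout = layout)
}

# A small but complete simulated screen (single plate, default 7 samples).
small_sim <- function(seed, n_genes = 40, ...) {
  simulate_screen(simulation_config(n_genes = n_genes, seed = seed, ...))
}

# Zero-noise, zero-effect configuration: every well reads the plate
# baseline exactly.
flat_config <- function(n_genes = 30, ...) {
  simulation_config(n_genes = n_genes, prop_kill = 0, prop_enhance = 0,
                    null_sd = 0, sigma_well = 0, sigma_screen = 0,
                    sigma_prep = 0, sigma_donor = 0, baseline_log2_sd = 0,
                    theta_pos = 0, n_differential = 0, seed = 1, ...)
}

# Does a k=2 sample partition coincide with the MSC / fibroblast split?
partition_matches_classes <- function(partition, cell_class) {
  is_msc <- cell_class[names(partition)] == "MSC"
  length(unique(partition[is_msc])) == 1 &&
    length(unique(partition[!is_msc])) == 1 &&
    partition[is_msc][1] != partition[!is_msc][1]
}

# All dendrogram-compatible leaf orderings (for the brute-force optimal
# leaf ordering oracle); 2^(n-1) orderings for n leaves.
compatible_orders <- function(hc) {
  rec <- function(id) {
    if (id < 0) return(list(-id))
    a <- rec(hc$merge[id, 1]); b <- rec(hc$merge[id, 2])
    out <- list()
    for (x in a) for (y in b) {
      out[[length(out) + 1L]] <- c(x, y)
      out[[length(out) + 1L]] <- c(y, x)
    }
    out
  }
  rec(nrow(hc$merge))
}

adjacent_cost <- function(ord, dmat) {
  sum(dmat[cbind(ord[-length(ord)], ord[-1])])
}
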