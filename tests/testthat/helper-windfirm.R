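# Shared builders for tests: tiny valid inputs built in code.

toy_tree <- function(id = "T1", species = "spruce", dbh = 30, h = 12,
                     h0 = 5, ew = 6, ns = 6) {
  data.frame(tree_id = id, species = species, dbh_cm = dbh, height_m = h,
             crown_base_m = h0, crown_ew_m = ew, crown_ns_m = ns,
             stringsAsFactors = FALSE)
}

toy_plate <- function(id = "T1", depth = 0.5, len = 2.5, wid = 2.5,
                      vol = NA_real_) {
  data.frame(tree_id = id, depth_m = depth, length_m = len, width_m = wid,
             volume_m3 = vol, stringsAsFactors = FALSE)
}

# random valid trees for property tests (plain data.frame, fixed-seed draws)
random_trees <- function(n, seed) {
  set.seed(seed)
  h0 <- runif(n, 0, 12)
  data.frame(tree_id = paste0("R", seq_len(n)),
             species = sample(c("spruce", "korean_pine"), n, TRUE),
             dbh_cm = runif(n, 10, 90),
             height_m = h0 + runif(n, 1, 20),
             crown_base_m = h0,
             crown_ew_m = runif(n, 1, 12),
             crown_ns_m = runif(n, 1, 12),
             stringsAsFactors = FALSE)
}
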