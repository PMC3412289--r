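# Small shared fixtures built in code.

# A tiny two-pathway network: 60 post cells, CA3-like 80 pre / 12 slots,
# EC-like 120 pre / 8 slots.
tiny_maps <- function(seed = 42) {
  list(
    CA3 = build_projection(
      pathway_spec("CA3", n_pre = 80, synapses_per_post = 12,
                   fanout = fanout_of(60, 12, 80)),
      n_post = 60, seed = seed),
    EC = build_projection(
      pathway_spec("EC", n_pre = 120, synapses_per_post = 8,
                   fanout = fanout_of(60, 8, 120)),
      n_post = 60, seed = seed + 1)
  )
}

tiny_model <- function(theta = 3, seed = 7, ...) {
  threshold_surrogate(tiny_maps(), theta = theta, seed = seed, ...)
}

# Brute-force Hamming-distance law over all equal-count partners of a fixed
# pattern (uniform over partners), used as the enumeration oracle.
enumerate_hd_distribution <- function(n, k) {
  a <- seq_len(k) # wlog by symmetry
  partners <- utils::combn(n, k)
  hd <- apply(partners, 2, function(b) k - length(intersect(a, b)))
  tab <- table(2 * hd) / ncol(partners)
  data.frame(hd = as.integer(names(tab)), prob = as.numeric(tab))
}

# A fast reduced desk configuration for pipeline tests that do not need the
# default pair count or sweeps.
quick_config <- function(seed = 1, n_pairs = 6) {
  make_desk_config(seed, n_pairs_per_condition = n_pairs,
                   run_sweep = FALSE, calib_patterns = 30)
}
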