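# One shared scan of the default-condition synthetic dataset (95 sequences,
# 733 columns, groups 65/30), computed lazily and reused across test files.

.default_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.default_cache$sim))
    .default_cache$sim <- simulate_alignment(sim_config(seed = 42))
  .default_cache$sim
}

default_scan <- function() {
  if (is.null(.default_cache$scan))
    .default_cache$scan <- cryptic_scan(default_sim()$alignment,
                                        seed = 2024, gap_b = 100,
                                        nmf_nrun = 20)
  .default_cache$scan
}
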