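# scatter simulations reused across acceptance checks (same beam, seed
# and scale), keyed so distinct settings never collide
.mc_cache <- new.env(parent = emptyenv())

scatter_cached <- function(kv, cu, n_histories = 2e6, seed) {
  key <- sprintf("s_%g_%g_%g_%d", kv, cu, n_histories, seed)
  if (is.null(.mc_cache[[key]]))
    .mc_cache[[key]] <- simulate_scatter(beam_al_cu(kv, cu),
                                         n_histories = n_histories,
                                         seed = seed)
  .mc_cache[[key]]
}

# printed scatter-beam lead TVLs: for each incident beam (rows of
# reference_tvl_table()) the (TVL1, TVL1+2) pairs at 45, 90 and 135 deg
reference_scatter_tvl <- function() list(
  list(c(.15, .36), c(.11, .28), c(.09, .22)),
  list(c(.16, .38), c(.14, .32), c(.11, .27)),
  list(c(.17, .41), c(.15, .35), c(.13, .30)),
  list(c(.18, .43), c(.17, .39), c(.15, .33)),
  list(c(.26, .74), c(.20, .56), c(.15, .41)),
  list(c(.28, .78), c(.23, .63), c(.19, .48)),
  list(c(.30, .83), c(.26, .69), c(.22, .54)),
  list(c(.33, .90), c(.30, .75), c(.25, .60)),
  list(c(.33, .94), c(.27, .82), c(.21, .62)),
  list(c(.35, .99), c(.31, .90), c(.26, .71)),
  list(c(.37, 1.03), c(.35, .98), c(.30, .80)),
  list(c(.40, 1.09), c(.39, 1.06), c(.35, .89)))
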