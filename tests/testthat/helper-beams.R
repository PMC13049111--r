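# shared fixtures: the published beam-quality reference values and a
# compact beam constructor (3 mm Al inherent filtration plus added Cu)

beam_al_cu <- function(kv, cu_mm = 0, al_mm = 3.0) {
  f <- data.frame(material = c("Al", "Cu"), thickness_mm = c(al_mm, cu_mm))
  beam_spec(kv, filters = f[f$thickness_mm > 0, ])
}

# tube voltage, added Cu, first Al HVL (mm), homogeneity h
reference_hvl_table <- function() rbind(
  data.frame(kv = 60,  cu = c(0, .2, .5, 1), hvl = c(2.3, 4.2, 5.6, 6.6),
             h = c(.74, .87, .93, .97)),
  data.frame(kv = 81,  cu = c(0, .2, .5, 1), hvl = c(3.1, 5.7, 7.5, 8.9),
             h = c(.69, .84, .92, .96)),
  data.frame(kv = 90,  cu = c(0, .2, .5, 1), hvl = c(3.4, 6.3, 8.2, 9.6),
             h = c(.67, .83, .91, .96)),
  data.frame(kv = 100, cu = c(0, .2, .5, 1), hvl = c(3.8, 6.9, 8.8, 10),
             h = c(.66, .83, .91, .96)),
  data.frame(kv = 121, cu = c(0, .2, .5, 1), hvl = c(4.7, 7.9, 9.9, 11),
             h = c(.66, .84, .91, .95)))

# incident-beam lead TVL1 / TVL1+2 (mm Pb) for 10% / 1% transmission
reference_tvl_table <- function() rbind(
  data.frame(kv = 60,  cu = c(0, .2, .5, 1), tvl1 = c(.10, .17, .22, .26),
             tvl12 = c(.30, .41, .49, .56)),
  data.frame(kv = 90,  cu = c(0, .2, .5, 1), tvl1 = c(.22, .35, .45, .54),
             tvl12 = c(.73, .97, 1.13, 1.27)),
  data.frame(kv = 120, cu = c(0, .2, .5, 1), tvl1 = c(.30, .42, .49, .54),
             tvl12 = c(.91, 1.09, 1.20, 1.29)))
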