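# Shared fixtures: tiny trees and exact traces built in code.

tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
star3 <- function() ape::read.tree(text = "(A:2,B:2,C:2);")

# exact linear trace: po2 = intercept + slope * t
make_trace <- function(slope, intercept = 20.6, times = seq(0, 24, 0.5),
                       chamber_id = "c1", species = "spA",
                       volume_ul = 1500, n_seeds = 10, temp_c = 20,
                       pressure_kpa = 101.325, noise = 0) {
  po2 <- intercept + slope * times
  if (noise > 0) po2 <- po2 + rnorm(length(times), sd = noise)
  data.frame(chamber_id = chamber_id, species = species, time_h = times,
             po2_kpa = po2, volume_ul = volume_ul, n_seeds = n_seeds,
             temp_c = temp_c, pressure_kpa = pressure_kpa)
}

# random ultrametric tree with unit-diagonal BM correlation, plus a draw
rcoal_unit <- function(n) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

# one multivariate-normal draw with covariance V
rmvn1 <- function(V) drop(t(chol(V)) %*% rnorm(nrow(V)))
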