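# Shared fixtures: tiny phantoms and noiseless single-voxel signals built
# in code at test time.

tinyPhantom <- function(seed = 7L, grid = c(8, 8, 2), nRegions = 2L, ...) {
  makePhantom(phantomSpec(gridShape = grid, nRegions = nRegions,
                          seed = seed, ...))
}

ivimSignal <- function(b, S0 = 1000, f = 0.1, D = 1e-3, Dstar = 10e-3) {
  S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))
}

utePoolSignal <- function(te, S0s = 1000, S0l = 800,
                          T2short = 0.5, T2long = 20) {
  (S0s - S0l) * exp(-te / T2short) + S0l * exp(-te / T2long)
}

spgrPair <- function(S0 = 850, T1 = 1.2, tr = 0.015,
                     flips = c(4, 24)) {
  a <- flips * pi / 180
  E1 <- exp(-tr / T1)
  S0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

relErr <- function(x, truth) abs(x / truth - 1)
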