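## Frozen reference values, computed once with an arbitrary-precision
## library (30 significant digits) and truncated to double precision.
LOGISTIC_17 <- 0.845534734916465   # 1/(1+exp(-1.7))
LOGISTIC_59 <- 0.997268039236989   # 1/(1+exp(-5.9))
ENTROPY_08 <- 0.721928094887362    # binary entropy of p = 0.8, in bits

## belief with chosen parameters (trained, false)
belief_with <- function(aT, bT, aF, bF) {
  b <- init_belief()
  b$alpha_T <- aT; b$beta_T <- bT; b$alpha_F <- aF; b$beta_F <- bF
  b
}

## brute-force argmax of a function over a grid (independent of the
## package's tie-breaking helper)
brute_argmax <- function(f, grid) grid[which.max(vapply(grid, f, 0))]
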