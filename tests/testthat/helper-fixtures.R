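# Shared fixtures and independent oracles.

# exact Michaelis-Menten data on the assay's substrate grid
mm_exact <- function(Km = 2, Vmax = 50, S = c(0.625, 1.25, 2.5, 5, 10, 20)) {
  data.frame(substrate = S, velocity = Vmax * S / (Km + S))
}

# closed-form ordinary least squares, independent of lm()
ols_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# brute-force grid search over (Km, Vmax): the minimum residual sum of
# squares on an n x n grid, used as an upper-bound oracle for the NLS
# objective
mm_grid_rss <- function(S, v, n = 400,
                        km_range = c(0.05, 25), vmax_range = NULL) {
  if (is.null(vmax_range)) vmax_range <- c(0.2, 2) * max(v)
  kms <- seq(km_range[1], km_range[2], length.out = n)
  vms <- seq(vmax_range[1], vmax_range[2], length.out = n)
  best <- Inf
  for (vm in vms) {
    pred <- outer(S, kms, function(s, k) vm * s / (k + s))
    rss <- colSums((pred - v)^2)
    best <- min(best, min(rss))
  }
  best
}

# reference protein indices computed independently with Biopython's
# ProtParam (frozen values; same published mass/pKa/DIWV tables)
protparam_reference <- list(
  peptide = list(seq = "MKWVTFISLLLLFSSAYS", mw = 2106.5243, pI = 8.344739,
                 instability = 17.566667, gravy = 1.288889, aliphatic = 130),
  # the acidic pI is the verified zero of the reference charge function
  # (its net charge at pH 3.1913 is +0.0025); the reference package's
  # own pI search is bounded below at 4.05 and cannot reach it
  acidic  = list(seq = "DDEEDDEEGG", mw = 1108.9235, pI = 3.1913,
                 instability = 105.8, gravy = -2.88, aliphatic = 0),
  mixA    = list(seq = "ACDEFGHIKLMNPQRSTVWY", mw = 2395.7134, pI = 6.784552,
                 instability = 84.74, gravy = -0.49, aliphatic = 58.5),
  rand60  = list(seq = "PAGFRQVCKAFMAEPMFNTATQHEYHCCTPTRMYINTPVNRAFGCFDGPIIFGWPPEREI",
                 mw = 6896.8903, pI = 7.181629, instability = 42.996667,
                 gravy = -0.253333, aliphatic = 44)
)
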