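# Shared fixtures and independent oracles for the test suite.

# single-voxel DWI series from a signal vector
voxel_series <- function(signal, protocol = make_protocol()) {
  dwi_series(array(signal, dim = c(1, 1, 1, length(signal))), protocol)
}

# protocol whose b-values bypass the b[1] == 0 acquisition constraint,
# for white-box checks of the fitting algebra on arbitrary b pairs
raw_protocol <- function(b_values) {
  p <- make_protocol()
  p$b_values <- b_values
  p
}

# Unconstrained four-parameter biexponential fit by multi-start
# Nelder-Mead on transformed parameters; the brute-force oracle for the
# segmented IVIM estimates. Independent of the package's fitting path.
brute_force_ivim <- function(b, sig) {
  obj <- function(par) {
    m0 <- exp(par[1]); fp <- stats::plogis(par[2])
    dp <- exp(par[3]); dt <- exp(par[4])
    sum((sig - m0 * (fp * exp(-b * dp) + (1 - fp) * exp(-b * dt)))^2)
  }
  best <- NULL
  for (fp0 in c(0.05, 0.15, 0.35)) {
    for (dp0 in c(5e-3, 15e-3, 60e-3)) {
      for (dt0 in c(0.5e-3, 1e-3, 2e-3)) {
        o <- stats::optim(c(log(max(sig[1], 1e-6)), stats::qlogis(fp0),
                            log(dp0), log(dt0)),
                          obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14))
        if (is.null(best) || o$value < best$value) best <- o
      }
    }
  }
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-15))
  list(m0 = exp(best$par[1]), fp = stats::plogis(best$par[2]),
       dp = exp(best$par[3]), dt = exp(best$par[4]), sse = best$value)
}

# Pearson r per replicate of a replicated cohort, vectorized
replicate_cor <- function(df, x, y) {
  g <- factor(df$replicate)
  n <- tabulate(g)
  sx <- rowsum(df[[x]], g); sy <- rowsum(df[[y]], g)
  sxx <- rowsum(df[[x]]^2, g); syy <- rowsum(df[[y]]^2, g)
  sxy <- rowsum(df[[x]] * df[[y]], g)
  num <- sxy - sx * sy / n
  den <- sqrt((sxx - sx^2 / n) * (syy - sy^2 / n))
  as.numeric(num / den)
}
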