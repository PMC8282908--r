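# Fast IIR filtering primitives.
#
# signal::filter / signal::filtfilt carry heavy time-series bookkeeping per
# call; simulation and epoch filtering make tens of thousands of calls, so
# these helpers run the same difference equations through stats::filter's C
# loops (zero initial conditions, like signal::filter).

# y[n] = sum_k b[k] x[n-k+1] - sum_j a[j+1] y[n-j],  x[<1] = 0
iir_filter <- function(b, a, x) {
  as.numeric(iir_filter_cpp(b, a, x))
}

# Zero-phase forward-backward filtering with reflected edge padding (three
# filter lengths), so group delay cancels and edge transients are damped.
iir_filtfilt <- function(b, a, x) {
  n <- length(x)
  np <- min(3L * (max(length(a), length(b)) - 1L) * 4L, n - 1L)
  xp <- c(2 * x[1] - x[np:1 + 1], x, 2 * x[n] - x[n - (1:np)])
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(np + 1):(np + n)]
}

# Coefficients of a Butterworth design from signal::butter, as plain vectors.
butter_ba <- function(order, w, type) {
  bf <- signal::butter(order, w, type = type)
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}
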