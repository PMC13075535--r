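# shared builders for small synthetic scenarios

quick_model <- function(amp = 10, sd = 1, seed = 1L) {
  signal_model(burst_amplitude = c(BBL = amp, TBL = amp, BRD = amp, PDT = amp),
               baseline_noise_sd = sd, seed = seed)
}

quick_schedule <- function(cycles = 2) burst_schedule(cycle_count = cycles)

# band-pass a plain numeric series with the default spec at 500 Hz
filter_series <- function(x, rate = 500) {
  bf <- signal::butter(4, c(20, 200) / (rate / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# magnitude response of the default zero-phase chain at frequency f (Hz):
# |H|^2 of the order-4 Butterworth band-pass, evaluated from the designed
# coefficients by direct polynomial evaluation (independent of filtering)
default_chain_gain <- function(f, rate = 500) {
  bf <- signal::butter(4, c(20, 200) / (rate / 2), type = "pass")
  z <- exp(-1i * 2 * pi * f / rate)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
    sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(H)^2
}

# brute-force Pearson r per the printed summation formula
pearson_brute <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sum((x - xm) * (y - ym)) /
    sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}
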