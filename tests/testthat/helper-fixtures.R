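# In-code fixtures shared across the suite.

make_corner_rec <- function(tl, tr, bl, br, rate = 40, t0 = 0) {
  n <- max(length(tl), length(tr), length(bl), length(br), 5L)
  raw_recording("corner_board", t0 + (seq_len(n) - 1) / rate,
                list(tl = rep_len(tl, n), tr = rep_len(tr, n),
                     bl = rep_len(bl, n), br = rep_len(br, n)), rate)
}

make_wrench_rec <- function(fx = 0, fy = 0, fz = 800, mx = 0, my = 0, mz = 0,
                            n = 5, rate = 100) {
  raw_recording("wrench_plate", (seq_len(n) - 1) / rate,
                list(fx = rep_len(fx, n), fy = rep_len(fy, n),
                     fz = rep_len(fz, n), mx = rep_len(mx, n),
                     my = rep_len(my, n), mz = rep_len(mz, n)), rate)
}

# noise-free, lag-free simulator configuration (ideal devices)
clean_sim_config <- function(...) {
  defaults <- list(device_lag_s = 0, jitter_board_ms = 0, jitter_plate_ms = 0,
                   noise_board_n = 0, noise_plate_n = 0, ml_noise_board_n = 0)
  do.call(sway_sim_config, utils::modifyList(defaults, list(...)))
}

# band-limited random sway-like series for filter/downsample properties
bandlimited_series <- function(n, rate, bw = 4) {
  x <- cumsum(rnorm(n + 200))
  x <- lowpass_zero_phase(x, rate, bw, 4)
  x[101:(100 + n)]
}

# two-way random-effects measurement matrix with known ICC(A,1)
random_effects_matrix <- function(n, k, sd_subject, sd_session, sd_error) {
  outer(rnorm(n, 0, sd_subject), rep(1, k)) +
    outer(rep(1, n), rnorm(k, 0, sd_session)) +
    matrix(rnorm(n * k, 0, sd_error), n, k)
}

# independent ANOVA route via stats::aov for cross-checking mean squares
aov_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   sess = factor(rep(seq_len(k), each = n)))
  one <- anova(stats::lm(y ~ subj, df))
  two <- anova(stats::lm(y ~ subj + sess, df))
  list(msr = two["subj", "Mean Sq"], msw = one["Residuals", "Mean Sq"],
       msc = two["sess", "Mean Sq"], mse = two["Residuals", "Mean Sq"])
}
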