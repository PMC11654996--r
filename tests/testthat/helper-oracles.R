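# Independent oracles used to freeze expected values. These deliberately do
# not reuse the package's algorithms: brute-force enumeration and direct
# arithmetic only.

# Brute-force one-to-one beat matching: enumerate every assignment of
# measured beats to reference beats (or to "unmatched"), keep assignments
# where every pair is within tol after removing a given offset, and return
# the one with the most matches (ties broken by smallest total absolute
# error). Exponential; only for tiny fixtures.
oracle_match <- function(ref, meas, tol, offset = 0) {
  meas <- meas - offset
  best <- list(n = -1, cost = Inf, pairs = NULL)
  n_meas <- length(meas)
  assign_next <- function(j, used_ref, pairs) {
    if (j > n_meas) {
      n <- nrow(pairs)
      cost <- if (n > 0) sum(abs(pairs$meas - pairs$ref)) else 0
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost, pairs = pairs)
      }
      return(invisible())
    }
    # leave meas j unmatched
    assign_next(j + 1, used_ref, pairs)
    for (i in seq_along(ref)) {
      if (!(i %in% used_ref) && abs(meas[j] - ref[i]) <= tol) {
        assign_next(j + 1, c(used_ref, i),
                    rbind(pairs, data.frame(ref_index = i, ref = ref[i],
                                            meas = meas[j])))
      }
    }
  }
  assign_next(1, integer(), data.frame(ref_index = integer(), ref = numeric(),
                                       meas = numeric()))
  best
}

# Exact signed-rank null distribution by enumeration of all 2^m sign
# assignments over the non-zero ranks (zeros ranked first, Pratt style).
# Returns the observed statistic and the exact p-values.
oracle_signed_rank <- function(d) {
  r <- rank(abs(d))
  nz <- d != 0
  v_obs <- sum(r[d > 0])
  ranks <- r[nz]
  m <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  v_null <- as.numeric(signs %*% ranks)
  list(
    statistic = v_obs,
    p_greater = mean(v_null >= v_obs),
    p_less = mean(v_null <= v_obs)
  )
}

# FFT amplitude of a sinusoid component in a signal segment.
oracle_fft_amplitude <- function(x, fs, freq_hz) {
  n <- length(x)
  sp <- abs(fft(x)) / n * 2
  bin <- round(freq_hz * n / fs) + 1
  max(sp[max(1, bin - 1):min(n, bin + 1)])
}

# Direct arithmetic relative interval RMSE on already-paired interval
# vectors.
oracle_rmse_percent <- function(ref_intervals, meas_intervals) {
  100 * sqrt(mean(((meas_intervals - ref_intervals) / ref_intervals)^2))
}

# A clean rendered recording with known truth, shared across tests.
make_recording <- function(duration_s = 60, hr = 60, hrv = 0.03, seed = 1,
                           noise = NULL) {
  truth <- simulate_beat_times(hr, hrv, duration_s, seed = seed)
  list(
    truth = truth,
    ppg = render_ppg(truth, noise = noise, duration_s = duration_s),
    ecg = render_ecg(truth, duration_s = duration_s)
  )
}
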