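# Wrap a raw sample vector as a segmented pulse (foot at the first sample).
as_pulse <- function(samples, fs = 256, start_index = 0L) {
  structure(
    list(samples = as.numeric(samples), fs = fs,
         start_index = as.integer(start_index), foot_index = 0L,
         systolic_peak_index = NA_integer_,
         diastolic_peak_index = NA_integer_,
         quality = NA_character_, valid = TRUE),
    class = "ppg_pulse")
}

# Closed-form two-Gaussian beat evaluated at arbitrary times (seconds).
two_gauss <- function(t, amp_sys, c_sys, w_sys, amp_dia, c_dia, w_dia) {
  amp_sys * exp(-(t - c_sys)^2 / (2 * w_sys^2)) +
    amp_dia * exp(-(t - c_dia)^2 / (2 * w_dia^2))
}

# A small cohort's feature matrix with ground-truth responses.
cohort_features <- function(n_subjects, seed0, duration = 60,
                            quality = "excellent") {
  set.seed(seed0)
  profs <- lapply(seq_len(n_subjects), function(i) {
    repeat {
      sbp <- runif(1, 95, 165); dbp <- runif(1, 60, 100)
      if (sbp - dbp >= 25) break
    }
    subject_profile(paste0("c", i), sbp, dbp,
                    heart_rate = runif(1, 55, 95),
                    resp_rate = runif(1, 12, 18))
  })
  recs <- lapply(seq_along(profs), function(i) {
    synth_recording(profs[[i]], duration, quality, rng_seed = seed0 + i)
  })
  X <- build_feature_matrix(recs)
  info <- attr(X, "info")
  list(X = X, sbp = info$sbp, dbp = info$dbp)
}

# Dense-inverse GP posterior oracle: standardizes with the model's stored
# constants, then does the textbook computation with solve() and scalar
# kernel evaluations -- independent of the package's cached-Cholesky path.
gp_oracle <- function(model, xstar) {
  p <- model$params
  Xt <- model$X_train
  n <- nrow(Xt)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- exp_kernel(Xt[i, ], Xt[j, ], p)
  }
  diag(K) <- diag(K) + p$noise_std^2 + 1e-8 * p$signal_std^2
  xs <- (as.numeric(xstar) - model$center) / model$scale
  ks <- vapply(seq_len(n), function(i) exp_kernel(Xt[i, ], xs, p), numeric(1))
  Kinv <- solve(K)
  mu <- model$mean_const + sum(ks * (Kinv %*% (model$y_train - model$mean_const)))
  var_y <- p$signal_std^2 - as.numeric(t(ks) %*% Kinv %*% ks) + p$noise_std^2
  c(mean = mu, sd = sqrt(max(var_y, 0)))
}

# A complete simulated week of readings for n subjects (protocol testing).
complete_log <- function(n_subjects, week = 1, seed = 1) {
  set.seed(seed)
  truth <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n_subjects)),
    sbp = runif(n_subjects, 100, 160),
    dbp = runif(n_subjects, 60, 95))
  simulate_session_log(truth, week = week, seed = seed)
}
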