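# shared fixtures, built in code

# small phantom used across modules; memoized per (noise, seed)
small_phantom <- local({
  cache <- list()
  function(noise_sd = 0.05, seed = 11, n = c(CON = 4L, LS = 4L)) {
    key <- paste(noise_sd, seed, paste(n, collapse = ","))
    if (is.null(cache[[key]])) {
      cache[[key]] <<- make_phantom_cohort(phantom_config(
        grid_shape = c(24L, 36L, 18L), n_subjects_per_group = n,
        noise_sd = noise_sd, seed = seed))
    }
    cache[[key]]
  }
})

# hand-built activity trace from an explicit inactivity mask
trace_from_mask <- function(inactive, frame_rate = 10, threshold = 0.5) {
  n <- length(inactive)
  score <- ifelse(inactive, 0, 1)
  list(subject_id = "T01", group = "CON", session = "F3",
       time_s = (seq_len(n) - 1) / frame_rate,
       activity_score = score, frame_rate = frame_rate)
}

# run-length-encoding bout oracle: maximal TRUE runs >= min_bout_s
rle_bout_oracle <- function(inactive, frame_rate, min_bout_s = 2) {
  out <- data.frame(start_s = numeric(0), duration_s = numeric(0))
  i <- 1; n <- length(inactive)
  while (i <= n) {
    if (inactive[i]) {
      j <- i
      while (j < n && inactive[j + 1]) j <- j + 1
      len <- j - i + 1
      if (len / frame_rate >= min_bout_s) {
        out <- rbind(out, data.frame(start_s = (i - 1) / frame_rate,
                                     duration_s = len / frame_rate))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# tiny synthetic scan-matrix world for ORT tests: planted pattern w with
# F3 shift of size `effect`, gaussian noise
ort_sim <- function(n_sub, effect, noise, seed, n_vox = 150) {
  set.seed(seed)
  w <- stats::rnorm(n_vox)
  w <- w / sqrt(sum(w^2))
  X <- matrix(stats::rnorm(2 * n_sub * n_vox, 0, noise), 2 * n_sub, n_vox)
  cond <- rep(c("F1", "F3"), n_sub)
  X[cond == "F3", ] <- X[cond == "F3", ] +
    matrix(effect * w, n_sub, n_vox, byrow = TRUE)
  list(sm = scan_matrix(X, rep(sprintf("S%02d", seq_len(n_sub)), each = 2),
                        cond),
       w = w)
}

# well-separated two-cluster feature table for classifier tests
cluster_features <- function(n_per_class = 12, delta = 5, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * 8, 0, 1), n_per_class),
             matrix(stats::rnorm(n_per_class * 8, delta, 1), n_per_class))
  out <- data.frame(subject_id = sprintf("S%02d", seq_len(2 * n_per_class)),
                    group = rep(c("CON", "LS"), each = n_per_class))
  out <- cbind(out, as.data.frame(X))
  names(out)[3:10] <- c("BA", "PLC", "ILC", "DH", "VH", "SB", "LEC", "MEC")
  out
}
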