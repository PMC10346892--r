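# Independent oracles, written naively on purpose: plain loops and textbook
# definitions, sharing no code with the package internals.

# nine window features by explicit loops
naive_features <- function(x, median_mode = "sorted") {
  w <- length(x)
  s <- 0
  for (v in x) s <- s + v
  mu <- s / w
  ss <- 0; sa <- 0
  for (v in x) {
    ss <- ss + (v - mu)^2
    sa <- sa + abs(v - mu)
  }
  wl <- 0
  for (n in seq_len(w - 1)) wl <- wl + abs(x[n + 1] - x[n])
  k <- ceiling(w / 2)
  med <- if (median_mode == "sorted") sort(x)[k] else x[k]
  mn <- x[1]; mx <- x[1]
  for (v in x) {
    if (v < mn) mn <- v
    if (v > mx) mx <- v
  }
  c(mean = mu, median = med, sd = sqrt(ss / w), min = mn, max = mx,
    initial = x[1], final = x[w], mav = sa / w, wl = wl)
}

# stride-s sliding-window start positions (the five-pass union must equal it)
naive_sliding_starts <- function(len, w = 25L, s = 5L) {
  p <- 0L
  out <- integer()
  while (p + w <= len) {
    if (p %% s == 0L) out <- c(out, p)
    p <- p + 1L
  }
  out
}

# per-class F1 as the harmonic mean of precision and recall
naive_f1 <- function(cm) {
  k <- nrow(cm)
  out <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    prec_den <- sum(cm[, i])
    rec_den <- sum(cm[i, ])
    if (tp == 0) {
      out[i] <- 0
    } else {
      prec <- tp / prec_den
      rec <- tp / rec_den
      out[i] <- 2 * prec * rec / (prec + rec)
    }
  }
  out
}

# central finite-difference gradient
fd_grad <- function(fn, theta, eps = 1e-5) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    g[i] <- (fn(tp)$cost - fn(tm)$cost) / (2 * eps)
  }
  g
}

# small synthetic dataset for fast end-to-end tests
tiny_dataset <- function(n_subjects = 2, circuits_per_subject = 2,
                         duration_range = c(0.4, 0.6), seed = 11,
                         noise_scale = 1, ...) {
  generate_dataset(generator_config(
    n_subjects = n_subjects, circuits_per_subject = circuits_per_subject,
    duration_range = duration_range, seed = seed,
    noise_scale = noise_scale, ...))
}

tiny_seg <- function(transition_removal = 50L, ...) {
  segmentation_config(transition_removal = transition_removal, ...)
}

# hand-built feature table with recognisable feature values, for stacking
# tests: feature j of row t in group g equals 1000 * g + 10 * t + j
fake_feature_table <- function(group_sizes, width = 4L) {
  metas <- list(); mats <- list()
  for (g in seq_along(group_sizes)) {
    n <- group_sizes[g]
    X <- matrix(0, n, width)
    for (t in seq_len(n)) X[t, ] <- 1000 * g + 10 * t + seq_len(width)
    colnames(X) <- paste0("f", seq_len(width))
    metas[[g]] <- tibble::tibble(
      subject_id = "S01", circuit_id = sprintf("C%02d", g), run_id = 1L,
      pass = 0L, window_index = seq_len(n) - 1L,
      activity = activity_factor(rep("walking", n)))
    mats[[g]] <- X
  }
  out <- dplyr::bind_rows(metas)
  out$features <- do.call(rbind, mats)
  out
}
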