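# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: explicit per-pixel loops and textbook formulas.

# Per-pixel dichromat simulation: scalar matrix products in a double loop.
# Returns the sRGB image (or pre-clip linear RGB), matching simulate_cvd's
# contract but sharing none of its vectorised path.
naive_simulate <- function(image, model, output = "srgb") {
  h <- dim(image)[1]
  w <- dim(image)[2]
  out <- array(0, dim = dim(image))
  decode <- function(u) if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  encode <- function(u) {
    u <- min(max(u, 0), 1)
    if (u <= 0.0031308) u * 12.92 else 1.055 * u^(1 / 2.4) - 0.055
  }
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      rgb_lin <- vapply(1:3, function(ch) decode(image[i, j, ch]), numeric(1))
      if (model$family == "machado") {
        sim <- as.vector(model$rgb_matrix %*% rgb_lin)
      } else {
        lms <- as.vector(model$rgb_to_lms %*% rgb_lin)
        proj <- if (model$condition == "tritanopia") {
          if (sum(model$separating_normal * lms) >= 0) {
            model$projection_1 %*% lms
          } else {
            model$projection_2 %*% lms
          }
        } else {
          model$projection %*% lms
        }
        sim <- as.vector(model$lms_to_rgb %*% proj)
      }
      for (ch in 1:3) {
        out[i, j, ch] <- if (output == "srgb") encode(sim[ch]) else sim[ch]
      }
    }
  }
  out
}

# Textbook two-sample t-test (Welch by default), evaluated from the raw
# formulas rather than stats::t.test.
welch_oracle <- function(a, b, var_equal = FALSE) {
  na <- length(a)
  nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t_stat <- (mean(a) - mean(b)) / se
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

# Monte-Carlo permutation test on the difference of means (two-sided).
permutation_p <- function(a, b, n_perm = 1e4, seed = 42) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  withr::with_seed(seed, {
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pool), na)
      abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
    }, logical(1)))
  })
  (hits + 1) / (n_perm + 1)
}

# Brute-force confusion tally: one explicit pass, one if-chain per pair.
brute_confusion <- function(truth, pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == "melanoma" && pred[i] == "melanoma") tp <- tp + 1L
    else if (truth[i] == "nevus" && pred[i] == "melanoma") fp <- fp + 1L
    else if (truth[i] == "nevus" && pred[i] == "nevus") tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Mean colour in linear RGB via explicit loops, for checking the mock
# backend's distance table.
naive_mean_linear <- function(image) {
  decode <- function(u) if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  out <- numeric(3)
  for (ch in 1:3) {
    v <- 0
    vals <- image[, , ch]
    for (k in seq_along(vals)) v <- v + decode(vals[k])
    out[ch] <- v / length(vals)
  }
  out
}
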