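# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the binomial tail is a direct log-space summation
# (not pbinom), component counting is a hand-written flood fill (not
# EBImage), and the Otsu oracle is a plain R loop over histogram cuts.

# Exact upper-tail P(X >= obs), X ~ Binomial(n, p), by direct summation of
# exponentiated log terms; sums whichever tail is shorter for accuracy.
binom_tail_oracle <- function(obs, n, p) {
  if (obs <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  term <- function(k) exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
  if (obs > n * p) {
    if (obs > n) return(0)
    sum(term(n:obs))          # ascending magnitude toward the mode
  } else {
    1 - sum(term((obs - 1):0))
  }
}

# 8-connected component count of a logical matrix by BFS flood fill.
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && !seen[i, j]) {
      count <- count + 1L
      queue <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(queue)) {
        px <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- px[1] + di; jj <- px[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  count
}

# Exhaustive-search Otsu threshold over a 256-bin histogram of x scaled to
# [0, 1]: plain loop over every cut, maximizing between-class variance.
otsu_oracle <- function(x, levels = 256) {
  rng <- range(x)
  y <- (x - rng[1]) / diff(rng)
  h <- hist(y, breaks = seq(0, 1, length.out = levels + 1), plot = FALSE)
  counts <- h$counts; mids <- h$mids
  best_var <- -Inf; best_t <- NA
  for (t in seq_len(levels - 1)) {
    w0 <- sum(counts[1:t]); w1 <- sum(counts[(t + 1):levels])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / w0
    mu1 <- sum(counts[(t + 1):levels] * mids[(t + 1):levels]) / w1
    v <- w0 * w1 * (mu1 - mu0)^2
    if (v > best_var) { best_var <- v; best_t <- t }
  }
  rng[1] + mids[best_t] * diff(rng)
}

# Balanced nested data: k groups x m mice x r ROIs, mouse effects drawn
# N(0, sd_mouse), ROI noise N(0, sd_roi); group offsets added per level.
make_nested_data <- function(group_means, m = 4, r = 4, sd_mouse = 0,
                             sd_roi = 0, mouse_means = NULL) {
  k <- length(group_means)
  rows <- list()
  mi <- 0
  for (g in seq_len(k)) {
    for (j in seq_len(m)) {
      mi <- mi + 1
      mu <- if (!is.null(mouse_means)) mouse_means[[g]][j] else
        group_means[g] + rnorm(1, 0, sd_mouse)
      for (rr in seq_len(r)) {
        rows[[length(rows) + 1]] <- data.frame(
          roi = sprintf("r%03d_%d", mi, rr),
          mouse = sprintf("m%03d", mi),
          sex = "M", region = "PPN",
          treatment = sprintf("g%d", g),
          outcome = mu + rnorm(1, 0, sd_roi))
      }
    }
  }
  do.call(rbind, rows)
}

# One-way ANOVA F on a numeric outcome ignoring the mouse level entirely
# (the naive ROI-level test used for the inflation demonstration).
naive_anova_p <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g); n <- length(y)
  gm <- tapply(y, g, mean); ng <- tabulate(g)
  ssb <- sum(ng * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

# A mixture whose only latent-positive signal is background: every cell is
# type `neither` and never activated. Used for null-calibration runs.
null_mix <- function(background_rate = 5e-4) {
  ap <- default_activation_prob()
  ap[] <- 0
  cell_type_mix(p_chat_only = 0, p_vglut_only = 0, p_colabel = 0,
                p_neither = 1, activation_prob = ap,
                background_rate = background_rate)
}

# Analyze one table-mode study straight through calling + summaries.
summaries_from_table_study <- function(study, alpha = 0.01) {
  bind_summaries(lapply(study, function(s)
    summarize_roi(call_cells(s$puncta, alpha = alpha), metadata = s$metadata)))
}
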