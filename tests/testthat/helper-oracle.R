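# Independent brute-force oracle: descriptors computed by an explicit double
# loop over all pixel pairs, never touching the co-occurrence matrix path.
brute_features <- function(img, offset, symmetric = FALSE) {
  h <- nrow(img); w <- ncol(img)
  dr <- offset[1L]; dc <- offset[2L]
  ii <- integer(0); jj <- integer(0)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        ii <- c(ii, img[r, c]); jj <- c(jj, img[r2, c2])
      }
    }
  }
  if (length(ii) == 0L) stop("no valid pairs")
  if (symmetric) { tmp <- ii; ii <- c(ii, jj); jj <- c(jj, tmp) }
  n <- length(ii)
  # energy from pair multiplicities
  key <- paste(ii, jj)
  energy <- sum((table(key) / n)^2)
  mu_i <- mean(ii); mu_j <- mean(jj)
  si <- sqrt(mean((ii - mu_i)^2)); sj <- sqrt(mean((jj - mu_j)^2))
  corr <- if (si * sj == 0) NA_real_ else
    mean((ii - mu_i) * (jj - mu_j)) / (si * sj)
  list(contrast = mean((ii - jj)^2),
       correlation = corr,
       energy = energy,
       homogeneity = mean(1 / (1 + abs(ii - jj))),
       mu_i = mu_i, mu_j = mu_j, sigma_i = si, sigma_j = sj)
}

# random quantized test image (values already in 0:(levels-1))
random_image <- function(h, w, levels) {
  structure(matrix(sample.int(levels, h * w, replace = TRUE) - 1L, h, w),
            levels = as.integer(levels))
}

# textbook Student-t interval, written independently of summarize_group
t_interval_oracle <- function(x, conf = 0.95) {
  n <- length(x)
  se <- sd(x) / sqrt(n)
  tcrit <- qt((1 + conf) / 2, n - 1)
  c(mean(x) - tcrit * se, mean(x) + tcrit * se)
}

all_offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                    c(1L, 0L), c(0L, -1L), c(2L, 1L), c(-2L, 2L))
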