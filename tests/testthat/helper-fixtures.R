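# Shared fixtures: all synthetic, generated in code at test time.

# Three 2-D Gaussian blobs with known centres.
make_blobs <- function(n_per = 100L, centers = rbind(c(-0.5, 0), c(0, 0), c(0.5, 0)),
                       sd = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
      cbind(stats::rnorm(n_per, centers[k, 1L], sd),
            stats::rnorm(n_per, centers[k, 2L], sd))
    }))
  })
}

# Empirical (responsibility-free) mixture parameters of labelled blobs,
# used to test the EM fixed point on exactly-separated data.
empirical_model <- function(x, labels) {
  ks <- sort(unique(labels))
  w <- as.numeric(table(labels)) / length(labels)
  mu <- t(vapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]),
                 numeric(2L)))
  covs <- array(0, c(2L, 2L, 3L))
  for (i in seq_along(ks)) {
    xc <- sweep(x[labels == ks[i], , drop = FALSE], 2L, mu[i, ])
    covs[, , i] <- crossprod(xc) / sum(labels == ks[i])
  }
  m <- gmm3_model(w, mu, covs)
  m$loglik <- gmm3_loglik(x, m)
  m
}

# Direct Bayes-posterior oracle: explicit bivariate normal density via the
# closed-form 2x2 inverse, no shared code with the package's chol path.
# Exponents are shifted per point before exponentiation so the ratio is
# computed without underflow even far from all components.
oracle_posterior <- function(model, x) {
  logd <- vapply(1:3, function(k) {
    s <- model$covariances[, , k]
    det_s <- s[1, 1] * s[2, 2] - s[1, 2] * s[2, 1]
    inv <- matrix(c(s[2, 2], -s[1, 2], -s[2, 1], s[1, 1]), 2, 2) / det_s
    apply(x, 1L, function(p) {
      d <- p - model$means[k, ]
      -0.5 * drop(t(d) %*% inv %*% d) - log(2 * pi * sqrt(det_s)) +
        log(model$weights[k])
    })
  }, numeric(nrow(x)))
  if (!is.matrix(logd)) logd <- matrix(logd, nrow = 1L)
  num <- exp(logd - apply(logd, 1L, max))
  num / rowSums(num)
}

# Exhaustive 2^n enumeration of Bernoulli sequences (n small).
enum_binom_tail <- function(k, n, p0 = 0.5) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  succ <- rowSums(grid)
  w <- p0^succ * (1 - p0)^(n - succ)
  sum(w[succ >= k])
}

# Pascal-triangle sequence counting: exact DP over outcome sequences.
pascal_binom_tail <- function(k, n, p0 = 0.5) {
  counts <- 1
  for (i in seq_len(n)) counts <- c(counts, 0) + c(0, counts)
  j <- 0:n
  sum(counts[j >= k] * p0^j[j >= k] * (1 - p0)^(n - j[j >= k]))
}

# A tiny deterministic frame table with prescribed timestamps and yaw.
frames_with_yaw <- function(timestamps, yaw) {
  n <- length(timestamps)
  tab <- as.data.frame(matrix(0, n, length(openface_columns())))
  names(tab) <- openface_columns()
  tab$frame <- seq_len(n)
  tab$timestamp <- timestamps
  tab$success <- 1L
  tab$pose_Ry <- yaw
  tab
}

perfect_params <- function(group) {
  response_model_params(group, responder_prob = 1, correct_side_prob = 1,
                        noise_sd = 0.02, peak_yaw_rad = 0.5)
}
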