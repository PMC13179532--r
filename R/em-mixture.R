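#' Three-component bivariate Gaussian mixture model
#'
#' Constructor/validator for the mixture used to cluster the 2-D trial
#' features into left, centre and right reaction clusters. Each
#' component has a full 2 x 2 covariance, so within-cluster correlation
#' between the two feature axes (e.g. head turn and gaze) is modelled.
#'
#' @param weights Length-3 nonnegative vector summing to 1.
#' @param means 3 x 2 matrix of component means (rows = components).
#' @param covariances 2 x 2 x 3 array of symmetric positive-definite
#'   covariance matrices.
#' @param loglik Total log-likelihood of the fitted data (optional).
#' @param n_restarts_used Restarts consumed by the sign-opposition loop.
#' @param criterion_met Whether the sign-opposition criterion held for
#'   the returned means (NA when the criterion was not applied).
#' @return Object of class `gmm3`.
#' @export
gmm3_model <- function(weights, means, covariances, loglik = NA_real_,
                       n_restarts_used = NA_integer_, criterion_met = NA) {
  weights <- as.numeric(weights)
  means <- as.matrix(means)
  if (length(weights) != 3L || nrow(means) != 3L || ncol(means) != 2L ||
      !all(dim(covariances) == c(2L, 2L, 3L))) {
    stop_input("gmm3 requires 3 weights, 3x2 means and 2x2x3 covariances")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    stop_input("weights must be nonnegative and sum to 1")
  }
  for (k in 1:3) {
    s <- covariances[, , k]
    if (abs(s[1L, 2L] - s[2L, 1L]) > 1e-9 || any(eigen(s, symmetric = TRUE,
        only.values = TRUE)$values <= 0)) {
      stop_input("covariance ", k, " must be symmetric positive-definite")
    }
  }
  structure(
    list(weights = weights, means = unname(means), covariances = covariances,
         loglik = loglik, n_restarts_used = n_restarts_used,
         criterion_met = criterion_met),
    class = "gmm3"
  )
}

# Log-density of a bivariate Gaussian at the rows of x (n x 2).
log_dmvnorm2 <- function(x, mean, sigma) {
  r <- chol(sigma)
  xc <- sweep(x, 2L, mean)
  y <- forwardsolve(t(r), t(xc))
  -log(2 * pi) - sum(log(diag(r))) - 0.5 * colSums(y^2)
}

# Component-wise log(weight * density), n x 3.
log_weighted_dens <- function(x, model) {
  lw <- vapply(1:3, function(k) {
    log(model$weights[k]) + log_dmvnorm2(x, model$means[k, ], model$covariances[, , k])
  }, numeric(nrow(x)))
  if (!is.matrix(lw)) lw <- matrix(lw, nrow = 1L)
  lw
}

#' Total log-likelihood of a dataset under a `gmm3` model
#'
#' @param x Numeric matrix (n x 2).
#' @param model A [gmm3_model()].
#' @return Scalar log-likelihood.
#' @export
gmm3_loglik <- function(x, model) {
  x <- as.matrix(x)
  sum(row_logsumexp(log_weighted_dens(x, model)))
}

#' Posterior responsibilities of the three components
#'
#' The expectation step's quantity: for each point, the posterior
#' probability of each component, proportional to weight times Gaussian
#' density.
#'
#' @inheritParams gmm3_loglik
#' @return Matrix (n x 3) of nonnegative rows summing to 1.
#' @export
gmm3_posterior <- function(model, x) {
  x <- as.matrix(x)
  lw <- log_weighted_dens(x, model)
  exp(lw - row_logsumexp(lw))
}

# M-step from responsibilities; covariance eigenvalues floored at cov_floor.
m_step <- function(x, resp, cov_floor) {
  n <- nrow(x)
  nk <- colSums(resp)
  weights <- nk / n
  means <- t(vapply(1:3, function(k) colSums(resp[, k] * x) / nk[k], numeric(2L)))
  covs <- array(0, c(2L, 2L, 3L))
  floored <- FALSE
  for (k in 1:3) {
    xc <- sweep(x, 2L, means[k, ])
    s <- crossprod(xc * resp[, k], xc) / nk[k]
    s <- (s + t(s)) / 2
    e <- eigen(s, symmetric = TRUE)
    if (any(e$values < cov_floor)) {
      floored <- TRUE
      e$values <- pmax(e$values, cov_floor)
      s <- e$vectors %*% diag(e$values) %*% t(e$vectors)
      s <- (s + t(s)) / 2
    }
    covs[, , k] <- s
  }
  if (floored) warning("covariance eigenvalue(s) floored at cov_floor", call. = FALSE)
  list(weights = weights, means = means, covariances = covs)
}

#' One EM iteration (E-step + M-step)
#'
#' Computes responsibilities under the current parameters, re-estimates
#' weights, means and covariances from them, and records the
#' log-likelihood of the data under the updated parameters. The total
#' log-likelihood is non-decreasing across calls (EM ascent).
#'
#' @inheritParams gmm3_loglik
#' @param cov_floor Absolute lower bound for covariance eigenvalues.
#' @return Updated `gmm3` model.
#' @export
em_iterate <- function(x, model, cov_floor = 1e-10) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop_input("EM requires at least 3 points")
  resp <- gmm3_posterior(model, x)
  p <- m_step(x, resp, cov_floor)
  upd <- gmm3_model(p$weights, p$means, p$covariances)
  upd$loglik <- gmm3_loglik(x, upd)
  upd$n_restarts_used <- model$n_restarts_used
  upd$criterion_met <- model$criterion_met
  upd
}

# EM until the relative change in total loglik drops below tol.
run_em <- function(x, model, tol, max_iter, cov_floor) {
  ll <- if (is.finite(model$loglik)) model$loglik else gmm3_loglik(x, model)
  for (i in seq_len(max_iter)) {
    model <- em_iterate(x, model, cov_floor)
    if (abs(model$loglik - ll) < tol * (abs(ll) + 1e-12)) break
    ll <- model$loglik
  }
  model
}

#' EM configuration
#'
#' Bundles the fitting protocol's tunables: five random short runs for
#' the exhaustive initialisation, short-EM to a relative log-likelihood
#' tolerance of 1e-4, up to 100 restarts under the sign-opposition
#' criterion, then a final EM to convergence.
#'
#' @param n_exhaust_starts Random starts per initialisation (default 5).
#' @param burn_in_iter EM iterations per exhaustive-init candidate.
#' @param short_em_tol Relative log-likelihood tolerance of the short EM.
#' @param final_tol Relative tolerance of the final EM.
#' @param max_iter Iteration cap for short and final EM.
#' @param max_restarts Cap on sign-criterion restarts (default 100).
#' @param apply_sign_criterion Whether the restart loop enforces the
#'   sign-opposition criterion (disabled for the PCA feature set).
#' @param exclude_centre If `TRUE`, the criterion inspects only the two
#'   non-centre cluster means (the literal protocol inspects all three).
#' @param cov_floor_rel Covariance eigenvalue floor, relative to the mean
#'   per-axis data variance.
#' @param seed Base seed; restart r uses seed + r.
#' @return Object of class `em_config`.
#' @export
em_config <- function(n_exhaust_starts = 5L, burn_in_iter = 100L,
                      short_em_tol = 1e-4, final_tol = 1e-6,
                      max_iter = 1000L, max_restarts = 100L,
                      apply_sign_criterion = TRUE, exclude_centre = FALSE,
                      cov_floor_rel = 1e-8, seed = 1L) {
  stopifnot(short_em_tol > 0, final_tol > 0, max_iter >= 1,
            n_exhaust_starts >= 1, max_restarts >= 1, cov_floor_rel > 0)
  structure(
    list(n_exhaust_starts = as.integer(n_exhaust_starts),
         burn_in_iter = as.integer(burn_in_iter),
         short_em_tol = short_em_tol, final_tol = final_tol,
         max_iter = as.integer(max_iter),
         max_restarts = as.integer(max_restarts),
         apply_sign_criterion = isTRUE(apply_sign_criterion),
         exclude_centre = isTRUE(exclude_centre),
         cov_floor_rel = cov_floor_rel, seed = as.integer(seed)),
    class = "em_config"
  )
}

# Random starting model: means at 3 distinct sampled points, shared
# data covariance, uniform weights.
random_start <- function(x, cov_floor) {
  n <- nrow(x)
  idx <- sample.int(n, 3L)
  s <- stats::cov(x)
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  e$values <- pmax(e$values, cov_floor)
  s <- e$vectors %*% diag(e$values) %*% t(e$vectors)
  s <- (s + t(s)) / 2
  m <- gmm3_model(rep(1 / 3, 3L), x[idx, , drop = FALSE],
                  array(rep(s, 3L), c(2L, 2L, 3L)))
  m$loglik <- gmm3_loglik(x, m)
  m
}

#' Exhaustive initialisation: best of several random short runs
#'
#' Runs `n_exhaust_starts` randomly initialised EMs for a capped burn-in
#' and returns the candidate with the highest log-likelihood.
#' Deterministic for a fixed `config$seed`.
#'
#' @param x Numeric matrix (n x 2), n >= 3.
#' @param config An [em_config()].
#' @return The best candidate `gmm3` model.
#' @export
exhaustive_init <- function(x, config = em_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop_input("initialisation requires at least 3 points")
  cov_floor <- config$cov_floor_rel * mean(apply(x, 2L, stats::var))
  best <- NULL
  for (s in seq_len(config$n_exhaust_starts)) {
    cand <- withr::with_seed(derive_seed(config$seed, 7000L + s), {
      m <- random_start(x, cov_floor)
      # candidates are compared at their (capped) short-EM fixed point, so
      # transiently high likelihoods of poor basins cannot win the argmax
      suppressWarnings(
        run_em(x, m, config$short_em_tol, config$burn_in_iter, cov_floor)
      )
    })
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  best
}

#' Sign-opposition criterion on the cluster means
#'
#' Restart-acceptance rule for the fitted means: over all mean
#' coordinates, let `M` be the maximum and `m` the minimum. The criterion
#' holds iff they have opposite sign and each is at least half as large
#' in magnitude as the other -- i.e. the extreme clusters sit on opposite
#' sides of the origin with comparable magnitude, encouraging a
#' left/centre/right geometry without pinning it to a particular axis.
#'
#' @param means 3 x 2 matrix of component means.
#' @param exclude_centre If `TRUE`, drop the mean closest to the origin
#'   before evaluating.
#' @return Logical scalar.
#' @examples
#' sign_opposition_criterion(rbind(c(-1, 0), c(0, 0), c(1, 0)))    # TRUE
#' sign_opposition_criterion(rbind(c(-1, 0), c(0, 0), c(0.4, 0)))  # FALSE
#' @export
sign_opposition_criterion <- function(means, exclude_centre = FALSE) {
  means <- as.matrix(means)
  if (exclude_centre) {
    means <- means[-which.min(rowSums(means^2)), , drop = FALSE]
  }
  co <- as.vector(means)
  M <- max(co); m <- min(co)
  isTRUE(m < 0 && M > 0 && M >= abs(m) / 2 && abs(m) >= M / 2)
}

#' Fit the three-cluster Gaussian mixture with the restart protocol
#'
#' Full fitting loop: exhaustive initialisation (best of
#' `n_exhaust_starts` random short runs), short EM to `short_em_tol`,
#' then -- if `apply_sign_criterion` -- evaluation of the
#' sign-opposition criterion on the short-EM means. On failure the loop
#' restarts with a new derived seed, up to `max_restarts` times; if no
#' restart satisfies the criterion the highest-likelihood candidate is
#' used and flagged (`criterion_met = FALSE`). The accepted model is then
#' polished by a final EM to `final_tol`.
#'
#' @inheritParams exhaustive_init
#' @return A fitted `gmm3` model with `loglik`, `n_restarts_used` and
#'   `criterion_met` populated.
#' @export
fit_gmm3 <- function(x, config = em_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop_input("fitting requires at least 3 points")
  if (nrow(unique(round(x, 12L))) < 3L) {
    stop_input("degenerate data: fewer than 3 distinct points")
  }
  cov_floor <- config$cov_floor_rel * mean(apply(x, 2L, stats::var))
  if (!is.finite(cov_floor) || cov_floor <= 0) {
    stop_input("degenerate data: zero variance")
  }
  best <- NULL
  accepted <- NULL
  n_restarts <- 0L
  for (r in seq_len(if (config$apply_sign_criterion) config$max_restarts else 1L)) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, r - 1L)
    init <- exhaustive_init(x, cfg_r)
    short <- suppressWarnings(
      run_em(x, init, config$short_em_tol, config$max_iter, cov_floor)
    )
    if (is.null(best) || short$loglik > best$loglik) best <- short
    if (!config$apply_sign_criterion ||
        sign_opposition_criterion(short$means, config$exclude_centre)) {
      accepted <- short
      accepted$criterion_met <- if (config$apply_sign_criterion) TRUE else NA
      n_restarts <- r - 1L
      break
    }
  }
  if (is.null(accepted)) {
    warning("sign-opposition criterion not met within max_restarts; ",
            "using highest-likelihood candidate", call. = FALSE)
    accepted <- best
    accepted$criterion_met <- FALSE
    n_restarts <- config$max_restarts
  }
  final <- suppressWarnings(
    run_em(x, accepted, config$final_tol, config$max_iter, cov_floor)
  )
  final$n_restarts_used <- n_restarts
  final$criterion_met <- accepted$criterion_met
  final
}

#' Serialise / restore a fitted mixture model as JSON
#'
#' Writes weights, means, covariances, log-likelihood and restart
#' bookkeeping to a JSON document for audit and reload.
#'
#' @param model A `gmm3` model.
#' @param path Output file path.
#' @return `write_gmm3_json`: `path`, invisibly. `read_gmm3_json`: the
#'   restored `gmm3` model.
#' @export
write_gmm3_json <- function(model, path) {
  doc <- list(
    weights = model$weights,
    means = model$means,
    covariances = lapply(1:3, function(k) model$covariances[, , k]),
    loglik = model$loglik,
    n_restarts_used = model$n_restarts_used,
    criterion_met = model$criterion_met
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gmm3_json
#' @export
read_gmm3_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- array(0, c(2L, 2L, 3L))
  cr <- doc$covariances
  if (is.array(cr) && length(dim(cr)) == 3L) {
    for (k in 1:3) covs[, , k] <- cr[k, , ]
  } else {
    for (k in 1:3) covs[, , k] <- matrix(unlist(cr[[k]]), 2L, 2L)
  }
  means <- matrix(unlist(doc$means), 3L, 2L,
                  byrow = !is.matrix(doc$means))
  if (is.matrix(doc$means)) means <- doc$means
  m <- gmm3_model(doc$weights, means, covs,
                  loglik = doc$loglik %||% NA_real_)
  m$n_restarts_used <- doc$n_restarts_used %||% NA_integer_
  m$criterion_met <- doc$criterion_met %||% NA
  m
}

#' @export
print.gmm3 <- function(x, ...) {
  cat("3-component bivariate Gaussian mixture\n")
  cat("  weights:", format(round(x$weights, 4)), "\n")
  for (k in 1:3) {
    cat(sprintf("  mean %d: (%.4f, %.4f)\n", k, x$means[k, 1L], x$means[k, 2L]))
  }
  cat("  loglik:", format(x$loglik), " restarts:", x$n_restarts_used,
      " criterion:", x$criterion_met, "\n")
  invisible(x)
}
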