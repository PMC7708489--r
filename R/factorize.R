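# Demixing the speckle stack: I_out = W H by non-negative matrix
# factorization (Lee-Seung multiplicative updates), rank estimation from the
# residual curve, and rejection of spurious / duplicate eigen-patterns.

# Gaussian blur of an rows x cols x n array. EBImage::gblur when its brush
# fits inside the frame; otherwise Fourier-domain multiplication with the
# Gaussian OTF (circular boundary).
blur_frames <- function(a, sigma) {
  d <- dim(a)
  if (2 * ceiling(3 * sigma) + 1 <= min(d[1], d[2])) {
    bg <- EBImage::gblur(a, sigma = sigma, boundary = "replicate")
    dim(bg) <- d        # gblur drops unit trailing dims
    return(bg)
  }
  fx <- matrix(fft_freq(d[2]), d[1], d[2], byrow = TRUE)
  fy <- matrix(fft_freq(d[1]), d[1], d[2])
  otf <- exp(-2 * pi^2 * sigma^2 * (fx^2 + fy^2))
  out <- a
  for (k in seq_len(d[3]))
    out[, , k] <- Re(stats::fft(stats::fft(a[, , k]) * otf, inverse = TRUE)) /
      (d[1] * d[2])
  out
}

#' High-pass filter a speckle stack
#'
#' Removes the smooth fluorescence background from every frame by
#' subtracting a Gaussian blur of width `sigma` and clipping negatives at
#' zero (the factorization downstream requires non-negativity). Raises the
#' speckle contrast substantially on low-contrast frames.
#'
#' @param stack a `speckle_stack` (or a frame matrix).
#' @param sigma Gaussian blur width in pixels; must exceed the speckle
#'   grain so the speckle itself survives the filter.
#' @return filtered object of the same type.
#' @export
high_pass_filter <- function(stack, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (inherits(stack, "speckle_stack")) {
    a <- array(stack$images, c(stack$grid[1], stack$grid[2], stack$n_patterns))
    if (sigma >= max(stack$grid)) {
      # blur wider than the frame: the background is the frame mean
      bg <- rep(colMeans(stack$images), each = prod(stack$grid))
    } else {
      bg <- blur_frames(a, sigma)
    }
    out <- pmax(a - bg, 0)
    s <- speckle_stack(matrix(out, nrow(stack$images), stack$n_patterns),
                       stack$grid, seed = stack$seed, H = stack$H)
    return(s)
  }
  m <- as.matrix(stack)
  bg <- if (sigma >= max(dim(m))) mean(m)
        else blur_frames(array(m, c(dim(m), 1)), sigma)[, , 1]
  pmax(m - bg, 0)
}

# One Lee-Seung run. Objective computed cheaply from cached cross-products:
# ||V - WH||_F^2 = ||V||^2 - 2 tr(V' W H) + tr((W'W)(H H')).
nmf_run <- function(V, r, n_iter_max, tol) {
  d <- nrow(V); p <- ncol(V); eps <- 1e-12
  sc <- sqrt(mean(V) / r)
  W <- matrix(stats::runif(d * r, 0.2, 1), d, r) * sc
  H <- matrix(stats::runif(r * p, 0.2, 1), r, p) * sc
  v2 <- sum(V * V)
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(n_iter_max)) {
    HHt <- tcrossprod(H)
    W <- W * (V %*% t(H)) / (W %*% HHt + eps)
    WtV <- crossprod(W, V)
    H <- H * WtV / (crossprod(W) %*% H + eps)
    obj2 <- v2 - 2 * sum(WtV * H) + sum(crossprod(W) * tcrossprod(H))
    obj <- sqrt(max(obj2, 0))
    trace <- c(trace, obj)
    if (is.finite(prev) && prev > 0 && (prev - obj) / prev < tol && it > 5)
      break
    prev <- obj
  }
  list(W = W, H = H, trace = trace, residual = trace[length(trace)])
}

#' Non-negative matrix factorization of a speckle stack
#'
#' Factorizes the (high-passed) stack I ~ W H with elementwise non-negative
#' W (D x r eigen-patterns) and H (r x P excitation time courses) by
#' minimizing the Frobenius objective ||I - WH||_F with Lee-Seung
#' multiplicative updates, which never increase the objective. Runs
#' `n_restarts` seeded random initializations and keeps the best final
#' residual. W columns are normalized to unit maximum, the scale being
#' absorbed into H (the factorization is only defined up to scale and
#' permutation).
#'
#' @param stack a `speckle_stack` (or bare non-negative D x P matrix).
#' @param rank factorization rank r; overestimating the number of emitters
#'   and pruning afterwards with [select_eigenpatterns()] is the recommended
#'   usage.
#' @param n_iter_max maximum multiplicative updates per restart.
#' @param tol stop when the relative objective decrease falls below this.
#' @param n_restarts random restarts; best final residual wins.
#' @param seed seed for the initializations.
#' @return object of class `nmf_fit`: `W`, `H`, `objective_trace` of the
#'   winning run, `residual`, `rank`, `kept` (initially all components),
#'   `flags`, `grid`, and the per-restart residuals.
#' @export
nmf_factorize <- function(stack, rank, n_iter_max = 300, tol = 1e-6,
                          n_restarts = 3, seed = 1L) {
  V <- if (inherits(stack, "speckle_stack")) stack$images else as.matrix(stack)
  grid <- if (inherits(stack, "speckle_stack")) stack$grid else NULL
  if (any(V < 0)) stop("NMF input must be non-negative")
  if (rank < 1 || rank > min(dim(V)))
    stop("rank must be between 1 and min(D, P) = ", min(dim(V)))
  best <- NULL
  restart_residuals <- numeric(n_restarts)
  for (k in seq_len(n_restarts)) {
    run <- with_seed(substream_seed(seed, paste0("nmf", k)),
                     nmf_run(V, rank, n_iter_max, tol))
    restart_residuals[k] <- run$residual
    if (is.null(best) || run$residual < best$residual) best <- run
  }
  # Normalize: W columns to unit max, scale into H.
  mx <- apply(best$W, 2, max)
  mx[mx == 0] <- 1
  W <- sweep(best$W, 2, mx, "/")
  H <- sweep(best$H, 1, mx, "*")
  structure(list(W = W, H = H, objective_trace = best$trace,
                 residual = best$residual, rank = as.integer(rank),
                 restart_residuals = restart_residuals,
                 kept = seq_len(rank), flags = rep("valid", rank),
                 grid = grid, seed = as.integer(seed)),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("<nmf_fit> rank %d | residual %.4g | %d iterations | kept %d/%d\n",
              x$rank, x$residual, length(x$objective_trace),
              length(x$kept), x$rank))
  invisible(x)
}

#' Estimate the factorization rank from the residual curve
#'
#' Runs the NMF for r = 1..r_max and inspects the final Frobenius residual
#' as a function of r. For well-separated emitters the curve shows a change
#' of slope at the true number of sources; the elbow is located at the
#' maximum discrete second difference (ties broken toward the smaller
#' rank). For more than about ten targets the elbow flattens out and cannot
#' be located reliably — the estimate is still returned but flagged with low
#' confidence, and the recommended practice is to overestimate the rank and
#' prune components afterwards.
#'
#' @param stack a `speckle_stack` or non-negative matrix.
#' @param r_max largest rank to try; must be < min(D, P).
#' @param n_iter_max,n_restarts,seed forwarded to [nmf_factorize()].
#' @return list with `r_hat`, `residuals` (length r_max), `second_diff`,
#'   and logical `low_confidence`.
#' @export
estimate_rank <- function(stack, r_max, n_iter_max = 150, n_restarts = 1,
                          seed = 1L) {
  V <- if (inherits(stack, "speckle_stack")) stack$images else as.matrix(stack)
  if (r_max >= min(dim(V)))
    stop("r_max must be < min(D, P) = ", min(dim(V)))
  res <- vapply(seq_len(r_max), function(r)
    nmf_factorize(V, r, n_iter_max = n_iter_max, n_restarts = n_restarts,
                  seed = substream_seed(seed, paste0("rank", r)))$residual,
    numeric(1))
  if (r_max < 3) {
    return(list(r_hat = which.min(res > max(res[1] * 0.01, 1e-9))[1],
                residuals = res, second_diff = NULL, low_confidence = r_max < 3))
  }
  # second difference at r = 2..r_max-1; elbow = max curvature
  d2 <- res[1:(r_max - 2)] - 2 * res[2:(r_max - 1)] + res[3:r_max]
  r_hat <- which.max(d2) + 1L            # ties: which.max takes the first
  # confident only when the curvature peak clearly dominates the curve
  srt <- sort(d2, decreasing = TRUE)
  low_confidence <- length(srt) >= 2 && srt[2] > 0 && srt[1] < 2 * srt[2]
  list(r_hat = r_hat, residuals = res, second_diff = d2,
       low_confidence = low_confidence)
}

#' Flag spurious and duplicate eigen-patterns
#'
#' With an overestimated rank the NMF pads the factorization with spurious
#' components (noise-like, low-contrast patterns that do not focus) and
#' near-duplicates of true eigen-patterns. Duplicates are component pairs
#' whose normalized pattern correlation exceeds `theta_dup` (the
#' lower-contrast one is dropped). Spurious components are those whose
#' eigen-pattern contrast (sd/mean, scale-invariant) sits more than
#' `theta_var` robust z-scores below the median, or whose non-invasive
#' focusing validation failed (`epi_ok = FALSE`), when provided.
#'
#' @param fit an `nmf_fit`.
#' @param theta_dup duplicate threshold on the pattern correlation.
#' @param theta_var spurious threshold in robust z-scores below the median
#'   contrast. The scale is floored at 10% of the median contrast so
#'   tightly clustered contrasts do not produce runaway z-scores.
#' @param epi_ok optional logical vector (length rank): the per-component
#'   verdicts of [epi_variance_validation()]; FALSE marks spurious.
#' @param frames optional D x rank matrix of (high-passed) epi frames
#'   recorded under each component's conjugate focusing pattern, e.g. from
#'   `attr(focus_report(...), "epi_frames")`. When provided, duplicate
#'   detection correlates these frames instead of the W columns: NMF often
#'   splits one emitter across components whose raw columns correlate only
#'   moderately, while their focused frames are near-identical (> 0.99) and
#'   frames of distinct emitters decorrelate within a speckle grain.
#' @return the `nmf_fit` with updated `kept` and `flags`
#'   ("valid" / "spurious" / "duplicate-of-<k>").
#' @export
select_eigenpatterns <- function(fit, theta_dup = 0.8, theta_var = 2,
                                 epi_ok = NULL, frames = NULL) {
  if (!inherits(fit, "nmf_fit")) stop("expected an nmf_fit")
  r <- fit$rank
  if (r == 0 || ncol(fit$W) == 0) stop("empty factorization result")
  W <- fit$W
  contr <- apply(W, 2, function(w) {
    m <- mean(w); if (m <= 0) 0 else stats::sd(w) / m
  })
  flags <- rep("valid", r)
  med <- stats::median(contr)
  sc <- max(stats::mad(contr), 0.1 * abs(med), 1e-12)
  z <- (contr - med) / sc
  flags[z < -theta_var] <- "spurious"
  if (!is.null(epi_ok)) flags[!epi_ok] <- "spurious"
  # duplicates among the survivors; keep the higher-contrast member
  alive <- which(flags == "valid")
  if (length(alive) >= 2) {
    src <- if (is.null(frames)) W else as.matrix(frames)
    cm <- suppressWarnings(stats::cor(src[, alive, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    ord <- alive[order(contr[alive], decreasing = TRUE)]
    for (i in seq_along(ord)) {
      ci <- ord[i]
      if (flags[ci] != "valid") next
      for (cj in ord[-seq_len(i)]) {
        if (flags[cj] != "valid") next
        if (cm[match(ci, alive), match(cj, alive)] > theta_dup)
          flags[cj] <- paste0("duplicate-of-", ci)
      }
    }
  }
  fit$flags <- flags
  fit$kept <- which(flags == "valid")
  fit$contrast <- contr
  fit
}
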