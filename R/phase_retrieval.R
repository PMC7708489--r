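# Intensity-only phase retrieval: recover a field-TM row t from
# h_p = |<t, E_in(p)>|^2 with known patterns, by spectral initialization
# (refined weighting) plus amplitude-flow gradient descent. Solutions are
# defined up to a global phase; all quality metrics are phase-invariant.

#' Phase retrieval configuration
#'
#' @param n_iter_max maximum gradient iterations.
#' @param tol stop when the relative loss decrease falls below this.
#' @param step_rule "backtracking" (monotone, default) or "fixed".
#' @param step fixed-rule step size as a fraction of 1/L, where L is the
#'   spectral norm of (1/P) E E^H.
#' @param init "refined-spectral" (default), "spectral" (unweighted
#'   intensities), or "random".
#' @param trunc lower clip of the refined spectral weights
#'   f(h) = max(1 - 1/h, trunc) on unit-mean h.
#' @param seed seed for random initialization.
#' @return list of class `pr_config`.
#' @export
pr_config <- function(n_iter_max = 200, tol = 1e-9,
                      step_rule = c("backtracking", "fixed"), step = 0.4,
                      init = c("refined-spectral", "spectral", "random"),
                      trunc = -1, seed = 1L) {
  stopifnot(tol > 0, n_iter_max >= 1)
  structure(list(n_iter_max = n_iter_max, tol = tol,
                 step_rule = match.arg(step_rule), step = step,
                 init = match.arg(init), trunc = trunc,
                 seed = as.integer(seed)), class = "pr_config")
}

# Spectral norm of (1/P) E E^H by power iteration (Hermitian PSD).
pattern_lipschitz <- function(E) {
  B <- (E %*% Conj(t(E))) / ncol(E)
  n <- nrow(B)
  v <- complex(real = rep(1, n), imaginary = seq_len(n) / n)  # deterministic
  for (i in 1:30) {
    v <- B %*% v
    v <- v / sqrt(sum(Mod(v)^2))
  }
  Re(sum(Conj(v) * (B %*% v)))
}

#' Spectral initialization for phase retrieval
#'
#' Leading eigenvector of D = (1/P) sum_p f(h_p) E_in(p) E_in(p)^H with a
#' monotone preprocessing f of the (unit-mean normalized) intensities:
#' f(h) = max(1 - 1/h, trunc) for the refined weighting, f(h) = h for the
#' plain spectral method. The eigenvector is scaled so the mean predicted
#' intensity matches mean(h).
#'
#' @param h_row intensity measurements, length P.
#' @param patterns a `phase_patterns` object (or complex N_SLM x P field
#'   matrix E_in).
#' @param config a [pr_config()].
#' @return complex vector of length N_SLM.
#' @export
spectral_init <- function(h_row, patterns, config = pr_config()) {
  E <- if (is.complex(patterns)) patterns else pattern_fields(patterns)
  P <- ncol(E)
  if (length(h_row) != P) stop("length(h_row) must equal the pattern count")
  if (all(h_row == 0)) stop("all-zero intensity row")
  if (P < nrow(E))
    warning("underdetermined: P < N_SLM; the spectral estimate may be poor")
  hn <- h_row / mean(h_row)
  f <- switch(config$init,
    "refined-spectral" = pmax(1 - 1 / pmax(hn, 1e-12), config$trunc),
    "spectral" = hn,
    "random" = NULL)
  if (is.null(f)) {
    v <- with_seed(config$seed, ccg(nrow(E)))
  } else {
    D <- (E %*% (f * Conj(t(E)))) / P
    # for the measurement a_p = sum_s E[s,p] t_s (no conjugate) the
    # leading eigenvector of D estimates conj(t)
    v <- Conj(eigen(D, symmetric = TRUE)$vectors[, 1])
  }
  pred <- Mod(drop(t(E) %*% v))^2
  v * sqrt(mean(h_row) / mean(pred))
}

amp_loss <- function(a, sqh) mean((sqh - Mod(a))^2)

#' Retrieve one field-TM row from intensity measurements
#'
#' Minimizes the amplitude loss (1/P) sum_p (sqrt(h_p) - |<t, E_in(p)>|)^2
#' by gradient descent (amplitude flow) from the spectral initialization.
#' Under the backtracking rule the loss trace is non-increasing. The
#' measurements carry arbitrary scale (NMF rows do): h is normalized to
#' unit mean internally and the scale re-attached to the estimate.
#'
#' @param h_row intensity measurements, length P.
#' @param patterns `phase_patterns` or complex N_SLM x P field matrix.
#' @param config a [pr_config()].
#' @param L optional precomputed Lipschitz constant (spectral norm of
#'   (1/P) E E^H); computed if missing.
#' @return object of class `pr_row`: `t_est` (complex, length N_SLM),
#'   `loss_trace`, `n_iter`, `converged`, and `consistency` (Pearson
#'   correlation between h and the predicted intensities).
#' @export
retrieve_row <- function(h_row, patterns, config = pr_config(), L = NULL) {
  E <- if (is.complex(patterns)) patterns else pattern_fields(patterns)
  P <- ncol(E)
  scale0 <- mean(h_row)
  if (scale0 <= 0) stop("all-zero intensity row")
  hn <- h_row / scale0
  sqh <- sqrt(hn)
  tE <- t(E); cE <- Conj(E)
  if (is.null(L)) L <- pattern_lipschitz(E)
  t_est <- spectral_init(hn, E, config)
  a <- drop(tE %*% t_est)
  loss <- amp_loss(a, sqh)
  trace <- loss
  eta0 <- config$step / L
  fixed <- config$step_rule == "fixed"
  for (it in seq_len(config$n_iter_max)) {
    w <- (1 - sqh / pmax(Mod(a), 1e-12)) * a
    g <- drop(cE %*% w) / P
    if (fixed) {
      t_new <- t_est - eta0 * g
      a_new <- drop(tE %*% t_new)
      new_loss <- amp_loss(a_new, sqh)
      if (!is.finite(new_loss) || new_loss > loss * (1 + 1e-6))
        stop("fixed-step gradient diverged; use step_rule = 'backtracking'")
    } else {
      eta <- eta0 * 2
      repeat {
        t_new <- t_est - eta * g
        a_new <- drop(tE %*% t_new)
        new_loss <- amp_loss(a_new, sqh)
        if (new_loss <= loss || eta < eta0 * 2^-20) break
        eta <- eta / 2
      }
      if (new_loss > loss) { t_new <- t_est; a_new <- a; new_loss <- loss }
    }
    t_est <- t_new; a <- a_new
    trace <- c(trace, new_loss)
    if (loss - new_loss < config$tol * max(loss, 1e-300)) { loss <- new_loss; break }
    loss <- new_loss
  }
  pred <- Mod(a)^2
  consistency <- suppressWarnings(stats::cor(pred, hn))
  structure(list(t_est = t_est * sqrt(scale0), loss_trace = trace,
                 n_iter = length(trace) - 1L,
                 converged = length(trace) - 1L < config$n_iter_max,
                 consistency = consistency), class = "pr_row")
}

#' @export
print.pr_row <- function(x, ...) {
  cat(sprintf("<pr_row> %d segments | %d iters | loss %.3g | consistency %.3f\n",
              length(x$t_est), x$n_iter, x$loss_trace[length(x$loss_trace)],
              x$consistency))
  invisible(x)
}

#' Retrieve the full field-TM from selected excitation rows
#'
#' Applies [retrieve_row()] independently to each row of H (typically the
#' kept components of an NMF fit). Per-row failures are caught and reported;
#' the remaining rows are still retrieved.
#'
#' @param H_kept non-negative matrix (n_rows x P) of excitation intensities.
#' @param patterns `phase_patterns` or complex field matrix.
#' @param config a [pr_config()].
#' @return object of class `field_tm_estimate`: `matrix` (complex
#'   n_rows x N_SLM, NA rows on failure), `consistency`, `status`
#'   (per row: "ok" or the error message), `rows` (the `pr_row` objects).
#' @export
retrieve_field_tm <- function(H_kept, patterns, config = pr_config()) {
  H_kept <- as.matrix(H_kept)
  E <- if (is.complex(patterns)) patterns else pattern_fields(patterns)
  L <- pattern_lipschitz(E)
  n <- nrow(H_kept)
  TT <- matrix(NA_complex_, n, nrow(E))
  status <- character(n); cons <- rep(NA_real_, n)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    res <- tryCatch(retrieve_row(H_kept[k, ], E, config, L = L),
                    error = function(e) e)
    if (inherits(res, "error")) {
      status[k] <- conditionMessage(res)
    } else {
      TT[k, ] <- res$t_est; cons[k] <- res$consistency
      status[k] <- "ok"; rows[[k]] <- res
    }
  }
  structure(list(matrix = TT, consistency = cons, status = status,
                 rows = rows), class = "field_tm_estimate")
}

#' @export
print.field_tm_estimate <- function(x, ...) {
  ok <- sum(x$status == "ok")
  cat(sprintf("<field_tm_estimate> %d/%d rows retrieved | median consistency %.3f\n",
              ok, nrow(x$matrix), stats::median(x$consistency, na.rm = TRUE)))
  invisible(x)
}
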