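# Methods for the fitted mixing-model object.

p_columns <- function(fit) seq_along(fit$sources$names)

#' @export
print.isodiet_fit <- function(x, ...) {
  K <- length(x$sources$names)
  cat("Concentration-dependent Bayesian mixing model fit\n")
  cat(sprintf("  %d sources, %d channels (%s), %d consumers\n",
              K, length(x$channels), paste(x$channels, collapse = ", "),
              nrow(x$consumers)))
  cat(sprintf("  %d stored draws from %d chain(s), thin = %d\n",
              nrow(x$draws), x$config$n_chains, x$thin))
  cat("  posterior mean proportions:\n")
  print(round(coef(x), 3))
  if (x$flagged) cat("  WARNING: flagged as non-mixing\n")
  invisible(x)
}

#' Summarise a mixing-model fit
#'
#' Per-source posterior mean, mode and 50/75/95% highest-density regions,
#' plus residual-SD summaries and convergence diagnostics.
#'
#' @param object An `isodiet_fit`.
#' @param levels HDR levels to report.
#' @param ... Unused.
#' @return A list of class `summary.isodiet_fit` with `proportions`
#'   (data.frame), `sigma` (data.frame), `hdr` (nested list), `diagnostics`.
#' @export
summary.isodiet_fit <- function(object, levels = c(0.50, 0.75, 0.95), ...) {
  nms <- object$sources$names
  hdrs <- lapply(nms, function(g) {
    d <- object$draws[, g]
    setNames(lapply(levels, function(l) hdr(d, l)), paste0("hdr", levels * 100))
  })
  names(hdrs) <- nms
  prop <- data.frame(
    source = nms,
    mean = colMeans(object$draws[, nms, drop = FALSE]),
    mode = vapply(nms, function(g)
      as.numeric(posterior_mode(object$draws[, g])), numeric(1)),
    ess = object$ess[nms],
    rhat = object$rhat[nms], row.names = NULL)
  sig_cols <- paste0("sigma_", object$channels)
  sigma <- data.frame(
    channel = object$channels,
    mean = colMeans(object$draws[, sig_cols, drop = FALSE]),
    sd = apply(object$draws[, sig_cols, drop = FALSE], 2, stats::sd),
    row.names = NULL)
  structure(list(proportions = prop, sigma = sigma, hdr = hdrs,
                 diagnostics = list(acceptance = object$acceptance,
                                    flagged = object$flagged)),
            class = "summary.isodiet_fit")
}

#' @export
print.summary.isodiet_fit <- function(x, ...) {
  cat("Diet proportions (posterior):\n")
  df <- x$proportions
  df$hdr95 <- vapply(df$source, function(g) {
    h <- x$hdr[[g]]$hdr95
    paste(sprintf("[%.3f, %.3f]", h[, "lo"], h[, "hi"]), collapse = " U ")
  }, character(1))
  print(cbind(df[1], round(df[c("mean", "mode")], 3), df["hdr95"],
              round(df[c("ess", "rhat")], c(0, 3))), row.names = FALSE)
  cat("Residual SD (permil):\n")
  print(cbind(x$sigma[1], round(x$sigma[-1], 3)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.isodiet_fit <- function(object, ...) {
  colMeans(object$draws[, object$sources$names, drop = FALSE])
}

# Predicted per-channel consumer mean and SD at given parameters.
predict_channels <- function(fit, p, sigma) {
  pre <- mixing_precompute(fit$consumers, fit$sources, fit$tdf)
  pq <- pre$q * p
  pp <- pq * rep(1 / colSums(pq), each = pre$K)
  list(mean = colSums(pp * pre$M),
       sd = sqrt(colSums(pp^2 * pre$V0) + sigma^2))
}

#' Predicted consumer isotope distribution
#'
#' Per-channel predicted mean and SD of consumer values at the posterior
#' mean of the parameters.
#'
#' @param object An `isodiet_fit`.
#' @param ... Unused.
#' @return A data.frame with `channel`, `mean`, `sd`.
#' @export
predict.isodiet_fit <- function(object, ...) {
  p <- coef(object)
  sigma <- colMeans(object$draws[, paste0("sigma_", object$channels),
                                 drop = FALSE])
  pr <- predict_channels(object, p, sigma)
  data.frame(channel = object$channels, mean = pr$mean, sd = pr$sd,
             row.names = NULL)
}

#' Residuals of a mixing-model fit
#'
#' Observed consumer values minus the predicted channel means at the
#' posterior mean parameters.
#'
#' @param object An `isodiet_fit`.
#' @param ... Unused.
#' @return A numeric matrix (consumers x channels).
#' @export
residuals.isodiet_fit <- function(object, ...) {
  pr <- predict(object)
  sweep(object$consumers, 2, pr$mean, "-")
}

#' Posterior predictive simulation of consumer isotope values
#'
#' Draws parameter vectors from the stored posterior draws and simulates
#' new consumer observations from the model's Gaussian likelihood.
#'
#' @param object An `isodiet_fit`.
#' @param nsim Number of simulated consumers.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A matrix (`nsim` x channels) of simulated values.
#' @export
simulate.isodiet_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  out <- matrix(NA_real_, nsim, length(object$channels),
                dimnames = list(NULL, object$channels))
  for (r in seq_len(nsim)) {
    p <- object$draws[idx[r], p_columns(object)]
    sigma <- object$draws[idx[r], paste0("sigma_", object$channels)]
    pr <- predict_channels(object, p, sigma)
    out[r, ] <- stats::rnorm(length(pr$mean), pr$mean, pr$sd)
  }
  out
}

#' HDR box plot of diet proportions
#'
#' Draws, for each source, nested boxes spanning the 95/75/50% highest
#' density regions of its diet proportion with the posterior mode marked.
#'
#' @param x An `isodiet_fit`.
#' @param levels HDR levels, outermost first.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the summary used for plotting.
#' @export
plot.isodiet_fit <- function(x, levels = c(0.95, 0.75, 0.50), ...) {
  s <- summary(x, levels = levels)
  nms <- s$proportions$source
  K <- length(nms)
  graphics::plot(NA, xlim = c(0.5, K + 0.5), ylim = c(0, 1),
                 xaxt = "n", xlab = "", ylab = "diet proportion", ...)
  graphics::axis(1, at = seq_len(K), labels = nms, las = 2, cex.axis = 0.8)
  wd <- c(0.12, 0.2, 0.28)[seq_along(levels)]
  for (i in seq_len(K)) {
    for (li in seq_along(levels)) {
      h <- s$hdr[[nms[i]]][[paste0("hdr", levels[li] * 100)]]
      for (r in seq_len(nrow(h)))
        graphics::rect(i - wd[li], h[r, "lo"], i + wd[li], h[r, "hi"],
                       col = grDevices::grey(0.9 - 0.25 * li), border = "grey30")
    }
    graphics::segments(i - 0.3, s$proportions$mode[i],
                       i + 0.3, s$proportions$mode[i], lwd = 2)
  }
  invisible(s)
}
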