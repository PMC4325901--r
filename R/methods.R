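#' @export
print.nf_trace <- function(x, ...) {
  m <- attr(x, "meta")
  if (!is.null(m))
    cat(sprintf("Training trace: %s schedule, %d iterations (%s/%s/%s)\n",
                m$schedule_mode, m$n_iter, m$orientation, m$variant,
                m$sigma_dir))
  n <- nrow(x)
  cat(sprintf("  p_T: %.3f -> %.3f   entropy: %.3f -> %.3g bits\n",
              x$p_T[1L], x$p_T[n], x$entropy_bits[1L], x$entropy_bits[n]))
  utils::str(as.data.frame(x), max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' @export
summary.nf_trace <- function(object, ...) {
  n <- nrow(object)
  pick <- unique(pmin(c(1L, 10L, 100L, 1000L, n), n))
  print(as.data.frame(object)[pick, c("iteration", "theta", "sigma", "p_T",
                                      "entropy_bits", "efficiency")],
        row.names = FALSE)
  invisible(object)
}

#' @export
plot.nf_trace <- function(x, ...) {
  graphics::plot(x$iteration, x$entropy_bits, type = "l", log = "x",
                 xlab = "iteration", ylab = "action entropy (bits)", ...)
  invisible(x)
}

#' @export
print.nf_sweep <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "Threshold sweep: %d thresholds in [%g, %g], %d iterations (%s/%s/%s)\n",
    length(x$grid), min(x$grid), max(x$grid), x$n_iter,
    m$orientation, m$variant, m$sigma_dir))
  pk <- deflection_peaks(x)
  cat(sprintf(
    "  argmin-entropy trace: early peak %g (iterations %d-%d), late peak %g (iterations %d-%d)\n",
    pk$early_theta, pk$early_from, pk$early_to,
    pk$late_theta, pk$late_from, pk$late_to))
  invisible(x)
}

#' @export
plot.nf_sweep <- function(x, levels = seq(0.05, 0.95, by = 0.05), ...) {
  graphics::contour(seq_len(x$n_iter), x$grid, x$H, levels = levels,
                    xlab = "iteration", ylab = "threshold",
                    drawlabels = FALSE, ...)
  graphics::lines(seq_len(x$n_iter), x$theta_entropy, col = "blue")
  graphics::lines(seq_len(x$n_iter), x$theta_ie, col = "red")
  graphics::legend("topleft", c("argmin entropy", "argmax efficiency"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
print.nf_compare <- function(x, ...) {
  runs <- attr(x, "exceed_runs")
  fc <- attr(x, "final_crossover")
  cat(sprintf("Entropy-ratio comparison over %d iterations\n", nrow(x)))
  if (nrow(runs)) {
    cat("  test exceeds reference in iteration windows: ",
        paste(sprintf("%d-%d", runs[, 1L], runs[, 2L]), collapse = ", "),
        "\n", sep = "")
    cat(sprintf("  final crossover at iteration %d\n", fc))
  } else {
    cat("  test never exceeds reference\n")
  }
  cat(sprintf("  final relative entropy: %.4g (%.2f dB)\n",
              x$ratio[nrow(x)], x$db[nrow(x)]))
  invisible(x)
}

#' @export
plot.nf_compare <- function(x, ...) {
  graphics::plot(x$iteration, x$db, type = "l", log = "x",
                 xlab = "iteration", ylab = "relative entropy (dB)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
print.nf_ensemble <- function(x, ...) {
  cat(sprintf("Monte-Carlo ensemble: %d runs x %d iterations (seed %s)\n",
              attr(x, "n_runs"), nrow(x), attr(x, "meta")$seed))
  n <- nrow(x)
  cat(sprintf("  mean p_T: %.3f -> %.3f (final sd %.3f)\n",
              x$p_T_mean[1L], x$p_T_mean[n], x$p_T_sd[n]))
  invisible(x)
}

#' @export
plot.nf_ensemble <- function(x, ...) {
  graphics::plot(x$iteration, x$p_T_mean, type = "l", ylim = c(0, 1),
                 xlab = "iteration", ylab = "P(trained action)", ...)
  graphics::lines(x$iteration, x$p_T_mean + x$p_T_sd, lty = 3)
  graphics::lines(x$iteration, pmax(x$p_T_mean - x$p_T_sd, 0), lty = 3)
  invisible(x)
}

#' Stochastic training trajectories from an environment
#'
#' `simulate()` method drawing `nsim` stochastic runs at a fixed threshold;
#' a thin convenience wrapper around [monte_carlo()].
#'
#' @param object an [nf_env].
#' @param nsim number of runs.
#' @param seed integer seed (required).
#' @param theta fixed threshold.
#' @param n_iter iterations per run.
#' @param ... passed on to [monte_carlo()].
#' @return The `nf_ensemble` with per-run probabilities attached.
#' @export
simulate.nf_env <- function(object, nsim = 1, seed = NULL, theta = 0,
                            n_iter = 100L, ...) {
  monte_carlo(object, theta, n_runs = nsim, n_iter = n_iter, seed = seed,
              keep_runs = TRUE, ...)
}
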