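#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SNR estimate into its per-region table
#' @param x an `snr_estimate`.
#' @param ... unused.
#' @return tibble with one row per region pair (mu_b, v_b, mu_s, v_s, snr_db).
#' @export
tidy.snr_estimate <- function(x, ...) x$per_region

#' @rdname tidy.snr_estimate
#' @export
glance.snr_estimate <- function(x, ...) {
  tibble::tibble(mean_db = x$mean_db, n_regions = x$n_regions)
}

#' Tidy a trained restorer into its loss history
#' @param x a `trained_restorer`.
#' @param ... unused.
#' @return tibble (iteration, loss, val_loss).
#' @export
tidy.trained_restorer <- function(x, ...) x$history

#' @rdname tidy.trained_restorer
#' @export
glance.trained_restorer <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    iterations = nrow(h),
    final_loss = h$loss[nrow(h)],
    final_val_loss = rev(h$val_loss[!is.na(h$val_loss)])[1] %||% NA_real_,
    parameters = n_parameters(x),
    depth = x$config$depth,
    base_channels = x$config$base_channels,
    n_train = x$n_train, n_val = x$n_val)
}

#' Tidy offset statistics
#' @param x an `offset_stats`.
#' @param ... unused.
#' @return the per-particle offsets tibble.
#' @export
tidy.offset_stats <- function(x, ...) x$offsets

#' @rdname tidy.offset_stats
#' @export
glance.offset_stats <- function(x, ...) {
  tibble::tibble(n_matched = x$n_matched,
                 n_unmatched = length(x$unmatched_truth),
                 rms_x = x$summary$rms[1], rms_y = x$summary$rms[2],
                 rms_z = x$summary$rms[3])
}

#' Plot a training-loss history
#' @param object a `trained_restorer`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trained_restorer <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(data = h[!is.na(h$val_loss), ],
                        ggplot2::aes(y = .data$val_loss), color = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "loss",
                  title = "Training loss (points: validation)") +
    ggplot2::theme_minimal()
}

#' Plot per-region SNR contributions
#' @param object an `snr_estimate`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.snr_estimate <- function(object, ...) {
  ggplot2::ggplot(object$per_region,
                  ggplot2::aes(x = factor(.data$region), y = .data$snr_db)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_db, linetype = 2) +
    ggplot2::labs(x = "region pair", y = "SNR (dB)",
                  title = sprintf("Region SNR, mean %.2f dB", object$mean_db)) +
    ggplot2::theme_minimal()
}

#' Plot a central slice of a volume
#' @param vol a [density_volume()].
#' @param z slice index (default: central).
#' @return a ggplot raster of the XY slice.
#' @export
plot_slice <- function(vol, z = dim(vol$values)[3] %/% 2 + 1) {
  sl <- vol$values[, , z]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", z)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL
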