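#' RMSE and MAE between measured and predicted signals
#'
#' Computed on de-normalized (physical-unit) signals: both sequences are
#' multiplied by the measured cycle-RMS factor before the error is taken, so
#' the numbers are in N (forces) or N.m (moment). With `denorm_factor = 1`
#' the metrics are on whatever scale the inputs carry.
#'
#' @param measured,predicted Equal-length numeric sequences (typically the
#'   concatenated extended cycle windows).
#' @param denorm_factor Positive scale factor (the measured cycle RMS).
#' @return Named numeric vector `c(rmse = , mae = )`.
#' @export
error_metrics <- function(measured, predicted, denorm_factor = 1) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (length(measured) != length(predicted)) {
    stop("error_metrics: length mismatch", call. = FALSE)
  }
  if (!is.numeric(denorm_factor) || denorm_factor <= 0) {
    stop("error_metrics: denorm_factor must be > 0", call. = FALSE)
  }
  e <- (measured - predicted) * denorm_factor
  c(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' Peak value of a channel over one push phase
#'
#' The maximum over the push phase proper (not the extended window), in
#' physical units; the quantity entering the Bland-Altman and ANOVA
#' peak-level analyses.
#'
#' @param cycle One row of [segment_cycles()] (or a list with `start`,
#'   `end`).
#' @param channel Numeric vector or [time_series()] covering the cycle.
#' @return Scalar peak value.
#' @export
peak_extract <- function(cycle, channel) {
  x <- if (inherits(channel, "time_series")) channel$values else as.numeric(channel)
  if (cycle$end <= cycle$start) {
    stop("peak_extract: empty push phase", call. = FALSE)
  }
  if (cycle$end - 1L > length(x)) {
    stop("peak_extract: cycle exceeds channel", call. = FALSE)
  }
  max(x[cycle$start:(cycle$end - 1L)])
}

#' Bland-Altman limits of agreement
#'
#' Agreement between predicted and measured per-subject mean peak values:
#' differences `d = predicted - measured`, bias = mean(d), limits of
#' agreement = bias +/- 1.96 SD(d) (sample SD, n - 1 denominator). Points
#' outside the limits are flagged.
#'
#' @param measured,predicted Paired numeric vectors (one value per subject),
#'   `n >= 2`.
#' @return An object of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `n`, `means`, `diffs`, `outside` (logical).
#' @export
bland_altman <- function(measured, predicted) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (length(measured) != length(predicted) || length(measured) < 2L) {
    stop("bland_altman: need paired vectors with n >= 2", call. = FALSE)
  }
  d <- predicted - measured
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 means = (measured + predicted) / 2, diffs = d,
                 outside = d < bias - 1.96 * s | d > bias + 1.96 * s,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.4g, LoA = [%.4g, %.4g], %d outside\n",
              x$n, x$bias, x$loa_low, x$loa_high, sum(x$outside)))
  invisible(x)
}

#' Bland-Altman plot
#' @param x A [bland_altman()] result.
#' @param xlab,ylab,main Plot annotations.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, xlab = "Mean of measured and predicted",
                              ylab = "Predicted - measured",
                              main = "Bland-Altman agreement", ...) {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, main = main,
                 pch = 19, ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' One-way ANOVA on peak values
#'
#' Tests the difference between measured and predicted peak levels with a
#' one-way analysis of variance (for two groups the F statistic equals the
#' squared pooled two-sample t statistic).
#'
#' @param measured_peaks,predicted_peaks Numeric vectors, each `n >= 2`.
#' @return Named vector `c(F = , p = )`.
#' @export
anova_peaks <- function(measured_peaks, predicted_peaks) {
  m <- as.numeric(measured_peaks); p <- as.numeric(predicted_peaks)
  if (length(m) < 2L || length(p) < 2L) {
    stop("anova_peaks: each group needs n >= 2", call. = FALSE)
  }
  if (stats::var(m) + stats::var(p) <= 0) {
    if (isTRUE(all.equal(mean(m), mean(p)))) return(c(F = 0, p = 1))
    stop("anova_peaks: zero variance in both groups, statistic undefined",
         call. = FALSE)
  }
  vals <- c(m, p)
  grp <- factor(rep(c("measured", "predicted"), c(length(m), length(p))))
  ow <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
  c(F = unname(ow$statistic), p = unname(ow$p.value))
}

#' Assemble the per-subject error report table
#'
#' Builds the standard results layout: one row per subject, Right/Left
#' sub-columns of RMSE and MAE for each channel (Fx, Fy, Mz), plus a final
#' mean row over subjects.
#'
#' @param results Long-format data frame with columns `subject`, `side`
#'   (`"right"`/`"left"`), `channel` (`"fx"`/`"fy"`/`"mz"`), `rmse`, `mae`.
#' @return An `error_report` data frame in wide layout, last row `"Mean"`.
#' @export
report_tables <- function(results) {
  need <- c("subject", "side", "channel", "rmse", "mae")
  if (!all(need %in% names(results)) || nrow(results) < 1L) {
    stop("report_tables: need columns subject, side, channel, rmse, mae",
         call. = FALSE)
  }
  subjects <- unique(results$subject)
  cols <- list()
  for (ch in c("fx", "fy", "mz")) {
    for (metric in c("rmse", "mae")) {
      for (side in c("right", "left")) {
        nm <- paste(ch, metric, side, sep = "_")
        cols[[nm]] <- vapply(subjects, function(s) {
          row <- results$subject == s & results$side == side &
            results$channel == ch
          if (any(row)) mean(results[[metric]][row]) else NA_real_
        }, numeric(1))
      }
    }
  }
  tab <- data.frame(subject = as.character(subjects), cols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  mean_row <- c(list(subject = "Mean"),
                lapply(tab[-1], function(x) mean(x, na.rm = TRUE)))
  tab <- rbind(tab, as.data.frame(mean_row, check.names = FALSE))
  structure(tab, class = c("error_report", "data.frame"))
}

#' Write an error report as CSV and Markdown
#' @param report An [report_tables()] result.
#' @param stem Output path stem; writes `<stem>.csv` and `<stem>.md`.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, stem) {
  csv <- paste0(stem, ".csv")
  utils::write.csv(report, csv, row.names = FALSE)
  md <- paste0(stem, ".md")
  fmt <- function(x) ifelse(is.na(x), "", formatC(as.numeric(x), digits = 2, format = "f"))
  lines <- c(paste0("| ", paste(names(report), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(report)), collapse = "|"), "|"))
  for (i in seq_len(nrow(report))) {
    vals <- c(report$subject[i], fmt(unlist(report[i, -1])))
    lines <- c(lines, paste0("| ", paste(vals, collapse = " | "), " |"))
  }
  writeLines(lines, md)
  invisible(c(csv, md))
}
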