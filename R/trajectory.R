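#' @export
print.phage_traj <- function(x, ...) {
  n <- nrow(x)
  cat("Bacteria-phage trajectory:", n, "time points over",
      format(x$time[n]), "h\n")
  fmt <- function(v) format(signif(v, 4))
  cat("  N total:     ", fmt(x$N_total[1]), "->", fmt(x$N_total[n]), "\n")
  cat("  phage V:     ", fmt(x$V[1]), "->", fmt(x$V[n]), "\n")
  cat("  N+ frequency:", fmt(x$N_plus_freq[1]), "->", fmt(x$N_plus_freq[n]),
      "\n")
  cat("  f_delta:     ", fmt(x$f_delta[1]), "->", fmt(x$f_delta[n]), "\n")
  invisible(x)
}

#' @export
as.data.frame.phage_traj <- function(x, ...) {
  structure(x, class = "data.frame", params = NULL, settings = NULL,
            hgt = NULL)
}

#' Plot a bacteria-phage trajectory
#'
#' Two stacked base-graphics panels: log10 densities of the five genotypes
#' and free phage, and the derived frequency series (`N_plus_freq`,
#' `f_delta`, overall resistance frequency).
#'
#' @param x A `"phage_traj"`.
#' @param ... Passed to `matplot` for the density panel.
#' @return `x`, invisibly.
#' @export
plot.phage_traj <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  dens <- as.matrix(as.data.frame(x)[, c(state_names)])
  dens[dens <= 0] <- NA
  graphics::matplot(x$time, log10(dens), type = "l", lty = 1,
                    col = c("grey40", "orange", "steelblue", "darkgreen",
                            "purple", "red"),
                    xlab = "time (h)", ylab = "log10 density", ...)
  graphics::legend("bottomright", bty = "n", lty = 1, cex = 0.7,
                   col = c("grey40", "orange", "steelblue", "darkgreen",
                           "purple", "red"),
                   legend = c("S-", "R-", "S+", "R+", "C+", "phage"))
  graphics::matplot(x$time,
                    cbind(x$N_plus_freq, x$f_delta, x$resistance_freq),
                    type = "l", lty = 1,
                    col = c("black", "red", "blue"), ylim = c(-1, 1),
                    xlab = "time (h)", ylab = "frequency / f_delta")
  graphics::abline(h = 0, col = "grey", lty = 3)
  graphics::legend("bottomright", bty = "n", lty = 1, cex = 0.7,
                   col = c("black", "red", "blue"),
                   legend = c("N+ freq", "f_delta", "resistance freq"))
  invisible(x)
}

trajectory_csv_columns <- c("time", "S_minus", "R_minus", "S_plus", "R_plus",
                            "C_plus", "V", "N_total", "N_plus_freq",
                            "f_delta")

#' Write a trajectory to CSV
#'
#' Fixed column set `time,S_minus,R_minus,S_plus,R_plus,C_plus,V,N_total,`
#' `N_plus_freq,f_delta`; UTF-8, comma separated, `.` decimal mark.
#'
#' @param traj A `"phage_traj"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "phage_traj"))
  df <- as.data.frame(traj)[, trajectory_csv_columns]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV file path.
#' @return A data frame with the fixed trajectory columns.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing <- setdiff(trajectory_csv_columns, names(df))
  if (length(missing))
    stop("trajectory CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df[, trajectory_csv_columns]
}
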