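#' Sigmoid fit of a contact-area history
#'
#' Fits a 4-parameter logistic
#' `A(t) = A0 + (Amax - A0) / (1 + exp(-k (t - t_mid)))` by nonlinear
#' least squares.  The spreading speed is the slope at the inflection
#' point, `k (Amax - A0) / 4`; the maximum contact area is the mean of the
#' observed points within 2% of the fitted plateau.  Curves without an
#' interior inflection or plateau (e.g. purely adhesion-driven spreading,
#' which decelerates from the start) fail the fit-quality checks.
#'
#' @param series data frame with columns `t` (s) and `A_c` (um^2), at
#'   least 20 points spanning rise and plateau.
#' @param strict error on a poor fit (default); otherwise return the
#'   summary with `fit_ok = FALSE`.
#' @return object of class `spreading_summary`: `speed` (um^2/s),
#'   `max_contact_area` (um^2), logistic parameters, fit diagnostics.
#' @export
sigmoid_fit <- function(series, strict = TRUE) {
  t <- series$t; A <- series$A_c
  if (length(t) < 20) stop("need at least 20 points", call. = FALSE)
  A0i <- min(A); Ami <- max(A)
  sm <- stats::smooth.spline(t, A, spar = 0.5)
  ds <- stats::predict(sm, t, deriv = 1)$y
  imax <- which.max(ds)
  ki <- max(4 * ds[imax] / (Ami - A0i), 1e-3)
  start <- list(A0 = A0i, Amax = Ami, k = ki, tm = t[imax])
  fit <- tryCatch(
    suppressWarnings(
    stats::nls(A ~ A0 + (Amax - A0) / (1 + exp(-k * (t - tm))),
               data = data.frame(t = t, A = A), start = start,
               algorithm = "port",
               lower = c(A0 = 0, Amax = A0i, k = 1e-4, tm = -Inf),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- as.list(stats::coef(fit))
  } else {
    sse <- function(x) {
      pr <- x[1] + (x[2] - x[1]) / (1 + exp(-x[3] * (t - x[4])))
      sum((pr - A)^2)
    }
    op <- stats::optim(unlist(start), sse,
                       control = list(maxit = 2000, reltol = 1e-12))
    cf <- as.list(op$par)
    names(cf) <- c("A0", "Amax", "k", "tm")
  }
  pred <- cf$A0 + (cf$Amax - cf$A0) / (1 + exp(-cf$k * (t - cf$tm)))
  rel_rms <- sqrt(mean((pred - A)^2)) / max(diff(range(A)), 1e-12)
  plateau_pts <- abs(A - cf$Amax) <= 0.02 * cf$Amax
  fit_ok <- cf$tm > min(t) && cf$tm < max(t) &&
    sum(plateau_pts) >= 3 && rel_rms < 0.05
  if (!fit_ok && strict) {
    stop(sprintf("sigmoid fit of poor quality (inflection at t = %.2f for data on [%.2f, %.2f], %d plateau points, relative RMS %.3f): curve may not be sigmoidal",
                 cf$tm, min(t), max(t), sum(plateau_pts), rel_rms),
         call. = FALSE)
  }
  structure(list(
    speed = cf$k * (cf$Amax - cf$A0) / 4,
    max_contact_area = if (sum(plateau_pts) >= 1)
      mean(A[plateau_pts]) else cf$Amax,
    A0 = cf$A0, Amax = cf$Amax, k = cf$k, t_inflection = cf$tm,
    rel_rms = rel_rms, n_plateau = sum(plateau_pts), fit_ok = fit_ok),
    class = "spreading_summary")
}

#' @export
print.spreading_summary <- function(x, ...) {
  cat(sprintf(
    "spreading_summary: speed %.3f um^2/s (inflection t = %.1f s), max contact area %.2f um^2%s\n",
    x$speed, x$t_inflection, x$max_contact_area,
    if (x$fit_ok) "" else "  [POOR FIT]"))
  invisible(x)
}

#' Default window for the early-phase power-law fit
#'
#' From the first time the contact area exceeds `A_min` until it reaches
#' half of its final value.
#'
#' @param series data frame with `t`, `A_c`.
#' @param A_min lower contact-area bound (um^2).
#' @return numeric `c(t1, t2)`.
#' @export
powerlaw_window <- function(series, A_min = 1) {
  A_fin <- series$A_c[nrow(series)]
  t1 <- series$t[which(series$A_c >= A_min)[1]]
  t2 <- series$t[which(series$A_c >= 0.5 * A_fin)[1]]
  c(t1, t2)
}

#' Log-log slope of early contact-area growth
#'
#' Ordinary least-squares slope of `log A_c` versus `log t` over a time
#' window inside the rising phase; the exponent of the power law
#' `A_c ~ t^alpha`.  Purely adhesion-driven spreading gives an exponent
#' close to 1/2.
#'
#' @param series data frame with `t`, `A_c` (um^2, positive in window).
#' @param window time interval `c(t1, t2)`; default [powerlaw_window()].
#' @return list with `exponent`, `r_squared`, `window` and point count
#'   `n`.  A window reaching into the plateau triggers a warning.
#' @export
loglog_slope <- function(series, window = powerlaw_window(series)) {
  sel <- series$t >= window[1] & series$t <= window[2] & series$A_c > 0 &
    series$t > 0
  if (sum(sel) < 5) stop("fewer than 5 points in the power-law window",
                         call. = FALSE)
  A_fin <- series$A_c[nrow(series)]
  if (any(series$A_c[sel] > 0.9 * A_fin)) {
    warning("power-law window reaches into the plateau", call. = FALSE)
  }
  x <- log(series$t[sel]); y <- log(series$A_c[sel])
  fit <- stats::lm(y ~ x)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(exponent = unname(stats::coef(fit)[2]),
       r_squared = if (sst > 0) 1 - ssr / sst else 1,
       window = window, n = sum(sel))
}

#' Compare a spreading summary against the experimental anchors
#'
#' Tabulates the simulated spreading speed and maximum contact area
#' against the printed benchmarks for neutrophil frustrated phagocytosis
#' (speed about 3 um^2/s regardless of ligand density).  Reporting only;
#' no pass/fail.
#'
#' @param summary a `spreading_summary`, or a list of them (e.g. one per
#'   ligand density); an empty list gives an empty report.
#' @param speed_ref reference spreading speed (um^2/s).
#' @return data frame with one row per summary and quantity.
#' @export
compare_to_benchmarks <- function(summary, speed_ref = 3) {
  if (inherits(summary, "spreading_summary")) summary <- list(summary)
  if (!length(summary)) {
    return(data.frame(case = integer(0), quantity = character(0),
                      simulated = numeric(0), reference = numeric(0),
                      ratio = numeric(0)))
  }
  rows <- lapply(seq_along(summary), function(i) {
    s <- summary[[i]]
    data.frame(case = i,
               quantity = c("spreading_speed", "max_contact_area"),
               simulated = c(s$speed, s$max_contact_area),
               reference = c(speed_ref, NA),
               ratio = c(s$speed / speed_ref, NA))
  })
  do.call(rbind, rows)
}

#' Write / read a spreading time series as plain text
#'
#' CSV with a commented header carrying the run metadata.
#' @param series a `spreading_series` (or plain data frame).
#' @param file path.
#' @export
write_timeseries <- function(series, file) {
  cfg <- attr(series, "config")
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(cfg)) {
    meta <- list(variant = cfg$variant, rho_rel = cfg$rho_rel,
                 rho_l = cfg$rho_l, t_end = cfg$t_end,
                 n_free = cfg$n_free, layers = cfg$layers)
    writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  }
  utils::write.csv(as.data.frame(series), con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_timeseries
#' @return `read_timeseries`: a data frame (metadata, if present, in
#'   attribute `meta`).
#' @export
read_timeseries <- function(file) {
  first <- readLines(file, n = 1)
  meta <- NULL
  if (startsWith(first, "# ")) {
    meta <- jsonlite::fromJSON(sub("^# ", "", first))
  }
  out <- utils::read.csv(file, comment.char = "#")
  attr(out, "meta") <- meta
  out
}

#' Write a contour snapshot as a plain-text table
#'
#' Columns: time, node index, r, z, tag (free/contact/adherent).
#' @param c0 a [cell_contour()].
#' @param file path.
#' @param time simulation time (s) recorded in the table.
#' @export
write_contour <- function(c0, file, time = NA_real_) {
  ci <- c0$contact_index
  n <- length(c0$r)
  tag <- c(rep("free", ci - 1L), "contact",
           rep("adherent", n - ci))
  utils::write.csv(data.frame(t = time, node = seq_len(n),
                              r = c0$r, z = c0$z, tag = tag),
                   file, row.names = FALSE)
  invisible(file)
}
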