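#' Read an IVUS pullback table
#'
#' CSV with columns `frame`, `position` (mm along the pullback), `max_d`,
#' `min_d`, `avg_d` (lumen diameters, mm) and `area` (lumen area, mm^2).
#' Rows violating the frame invariants (min <= avg <= max diameter, positive
#' area) are rejected with a per-row message; non-monotone positions are a
#' hard error.
#'
#' @param path CSV file.
#' @param tol slack for the diameter ordering checks.
#' @return data frame of validated frames.
#' @export
read_pullback <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("pullback table is empty")
  need <- c("frame", "position", "max_d", "min_d", "avg_d", "area")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("pullback table missing column(s): ", paste(miss, collapse = ", "))
  bad <- df$min_d > df$max_d + tol | df$avg_d > df$max_d + tol |
    df$min_d > df$avg_d + tol | df$area <= 0
  if (any(bad)) {
    for (i in which(bad))
      message(sprintf(
        "row %d (frame %s) rejected: diameters %.3g/%.3g/%.3g area %.3g",
        i, df$frame[i], df$min_d[i], df$avg_d[i], df$max_d[i], df$area[i]))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid pullback rows remain")
  if (is.unsorted(df$position))
    stop("pullback positions are not nondecreasing")
  df
}

#' Pair a CT profile with reference pullback frames by arc length
#'
#' Frame positions (plus a landmark `offset`) are mapped onto the profile
#' arc length and the CT area is linearly interpolated at each frame station
#' — the reference sampling is much denser than the CT stations, so CT is
#' interpolated onto the reference positions. Frames outside the overlap, or
#' within `trim` mm of either end (where start-point misalignment dominates),
#' are dropped.
#'
#' @param profile a `csa_profile` (or data frame with `s` and `area`).
#' @param frames data frame from [read_pullback()] (or with `position` and
#'   `area`).
#' @param offset landmark offset added to frame positions, mm.
#' @param trim length trimmed from both ends of the overlap, mm.
#' @return data frame: `position`, `s`, `ref_area`, `ct_area`.
#' @export
align_series <- function(profile, frames, offset = 0, trim = 0) {
  sec <- if (inherits(profile, "csa_profile")) profile$sections else profile
  sec <- sec[!is.na(sec$area), , drop = FALSE]
  if (!is.null(sec$flag)) sec <- sec[sec$flag == "ok", , drop = FALSE]
  if (nrow(sec) < 2) stop("profile has fewer than 2 usable sections")
  s_frame <- frames$position + offset
  lo <- max(min(sec$s), min(s_frame)) + trim
  hi <- min(max(sec$s), max(s_frame)) - trim
  keep <- s_frame >= lo & s_frame <= hi
  if (!any(keep)) stop("no overlap between profile and pullback positions")
  ct <- stats::approx(sec$s, sec$area, xout = s_frame[keep])$y
  data.frame(position = frames$position[keep], s = s_frame[keep],
             ref_area = frames$area[keep], ct_area = ct)
}

#' Signed percent error of a test value against a reference
#'
#' `(ref - test) / ref * 100`; positive when the test underestimates.
#' Scale-invariant: multiplying both by k > 0 leaves it unchanged.
#'
#' @param ref reference value(s), > 0.
#' @param test test value(s).
#' @return percent error(s).
#' @export
percent_error <- function(ref, test) {
  if (any(ref <= 0)) stop("reference values must be > 0")
  (ref - test) / ref * 100
}

#' Root-mean-square error normalized to the reference mean, in percent
#'
#' `sqrt(mean((ref - test)^2)) / mean(ref) * 100`: zero iff the series are
#' identical, symmetric in the sign of the errors.
#'
#' @param ref,test equal-length numeric series (n >= 2).
#' @return normalized RMSE, %.
#' @export
rmse_normalized <- function(ref, test) {
  if (length(ref) != length(test)) stop("series lengths differ")
  if (length(ref) < 2) stop("need at least 2 points")
  sqrt(mean((ref - test)^2)) / mean(ref) * 100
}

#' Ordinary least-squares identity fit of test on reference
#'
#' Regresses `test = slope * ref + intercept`; slope near 1 and intercept
#' near 0 indicate agreement with the identity line. Also reports the
#' mean-normalized RMSE and signed/absolute mean percent errors.
#'
#' @param ref,test equal-length numeric series (n >= 3).
#' @return list: `slope`, `intercept`, `rmse_pct`, `mean_abs_pct_error`,
#'   `mean_signed_pct_error`, `n`, `fit` (the `lm` object).
#' @export
identity_fit <- function(ref, test) {
  if (length(ref) != length(test)) stop("series lengths differ")
  if (length(ref) < 3) stop("need at least 3 points for a fit")
  fit <- stats::lm(test ~ ref)
  pe <- percent_error(ref, test)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rmse_pct = rmse_normalized(ref, test),
       mean_abs_pct_error = mean(abs(pe)),
       mean_signed_pct_error = mean(pe),
       n = length(ref), fit = fit)
}

#' Identity plot of a comparison (reference vs test with y = x)
#'
#' @param ref,test the paired series.
#' @param xlab,ylab axis labels.
#' @param ... passed to `plot`.
#' @return the [identity_fit()] result, invisibly.
#' @export
plot_identity_fit <- function(ref, test, xlab = "reference area (mm²)",
                              ylab = "CT area (mm²)", ...) {
  f <- identity_fit(ref, test)
  plot(ref, test, pch = 16, xlab = xlab, ylab = ylab, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(f$intercept, f$slope, lwd = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "y = %.2fx + %.2g, nRMSE %.1f%%", f$slope, f$intercept, f$rmse_pct))
  invisible(f)
}

#' Summarize a CT profile against a reference series
#'
#' Convenience wrapper: aligns, computes per-point percent errors, the
#' normalized RMSE and the identity fit.
#'
#' @inheritParams align_series
#' @return list: `pairs` (aligned data frame with `pct_error`), `stats`
#'   (the [identity_fit()] summary, without the lm object).
#' @export
compare_to_reference <- function(profile, frames, offset = 0, trim = 0) {
  pairs <- align_series(profile, frames, offset = offset, trim = trim)
  pairs$pct_error <- percent_error(pairs$ref_area, pairs$ct_area)
  st <- identity_fit(pairs$ref_area, pairs$ct_area)
  st$fit <- NULL
  list(pairs = pairs, stats = st)
}
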