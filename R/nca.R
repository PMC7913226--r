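#' Non-compartmental analysis of a concentration-time profile
#'
#' Linear-up/log-down trapezoidal AUC, Cmax and tmax; for `auc_0_inf` the
#' terminal slope (lambda_z) is estimated by log-linear regression on the
#' terminal tail, choosing among the last 3 to 10 post-Cmax points the fit
#' with the best adjusted R-squared, and the extrapolated tail
#' Clast/lambda_z is added.
#'
#' @param time,conc numeric vectors (>= 3 points)
#' @param mode "auc_0_t" or "auc_0_inf"
#' @return list with `auc`, `cmax`, `tmax`, `lambda_z` (NA for auc_0_t),
#'   `auc_extrap_frac`
#' @export
nca <- function(time, conc, mode = c("auc_0_inf", "auc_0_t")) {
  mode <- match.arg(mode)
  stopifnot(length(time) == length(conc), length(time) >= 3,
            !is.unsorted(time))
  conc <- pmax(conc, 0)
  auc <- 0
  for (i in seq_len(length(time) - 1)) {
    dt <- time[i + 1] - time[i]
    c1 <- conc[i]; c2 <- conc[i + 1]
    auc <- auc + if (c2 < c1 && c2 > 0) {
      (c1 - c2) * dt / log(c1 / c2) # log-down
    } else {
      (c1 + c2) * dt / 2            # linear-up
    }
  }
  imax <- which.max(conc)
  cmax <- conc[imax]; tmax <- time[imax]
  lambda_z <- NA_real_; extrap <- 0
  if (mode == "auc_0_inf") {
    if (all(conc == 0)) {
      return(list(auc = 0, cmax = 0, tmax = time[1], lambda_z = NA_real_,
                  auc_extrap_frac = 0))
    }
    # keep the terminal fit above solver noise
    tail_idx <- which(seq_along(time) > imax & conc > cmax * 1e-6)
    if (length(time) == 2 || length(tail_idx) < 2) {
      # fall back: slope from the last two positive points
      pos <- which(conc > cmax * 1e-6)
      if (length(pos) < 2) stop("terminal phase not identifiable")
      i1 <- pos[length(pos) - 1]; i2 <- pos[length(pos)]
      lambda_z <- log(conc[i1] / conc[i2]) / (time[i2] - time[i1])
    } else {
      best <- -Inf
      for (k in seq_len(min(10, length(tail_idx)))[-(1:2)]) {
        idx <- tail_idx[(length(tail_idx) - k + 1):length(tail_idx)]
        if (length(idx) < 3) next
        fit <- lm(log(conc[idx]) ~ time[idx])
        r2 <- suppressWarnings(summary(fit)$adj.r.squared)
        if (is.finite(r2) && r2 > best) {
          best <- r2
          lambda_z <- -coef(fit)[[2]]
        }
      }
      if (!is.finite(lambda_z) && length(tail_idx) >= 2) {
        i1 <- tail_idx[length(tail_idx) - 1]; i2 <- tail_idx[length(tail_idx)]
        lambda_z <- log(conc[i1] / conc[i2]) / (time[i2] - time[i1])
      }
    }
    if (!is.finite(lambda_z) || lambda_z <= 0) {
      stop("terminal phase not identifiable (non-positive lambda_z)")
    }
    clast <- conc[max(which(conc > cmax * 1e-6))]
    extrap <- clast / lambda_z
    auc <- auc + extrap
  }
  list(auc = auc, cmax = cmax, tmax = tmax, lambda_z = lambda_z,
       auc_extrap_frac = extrap / max(auc, .Machine$double.xmin))
}

#' @rdname nca
#' @param profile a `pk_profile` from `simulate_pk()`
#' @param matrix "plasma" or "blood"
#' @export
nca_profile <- function(profile, matrix = "plasma",
                        mode = c("auc_0_inf", "auc_0_t")) {
  col <- if (matrix == "blood") "blood_mg_L" else "plasma_mg_L"
  nca(profile$time_h, profile[[col]], mode = match.arg(mode))
}
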