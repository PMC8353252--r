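#' Survival probability of pore residence
#'
#' For each lag tau, P(tau) is the average over time origins t (with at
#' least one particle inside) of N(t, t+tau) / N(t), where N(t) is the
#' number of tracked particles inside the pore at t.  Under the
#' `"continuous"` convention (default) N(t, t+tau) counts particles inside
#' at t that remain inside at every stored frame of [t, t+tau]; this is
#' the standard strict residence convention and makes P non-increasing with
#' P(0) = 1.  Under `"intermittent"`, a particle need only be inside at both
#' endpoints, so brief exits are forgiven.
#'
#' Origins with N(t) = 0 are excluded from the average, which keeps
#' P(0) = 1 exactly.  Two origin policies are available: `"fixed"` (default)
#' uses the same origin set t <= T - tau_max for every lag, which makes the
#' continuous-convention curve exactly non-increasing; `"per_tau"` admits
#' every origin with t + tau <= T, using more data at short lags at the cost
#' of possible small upticks at long lags where the origin set shrinks.
#'
#' @param res a [residency()].
#' @param tau_max largest lag (ps); must not exceed the trajectory span.
#'   The tau grid is every multiple of the frame spacing up to `tau_max`.
#'   Default: half the trajectory span.
#' @param convention `"continuous"` or `"intermittent"`.
#' @param origins `"fixed"` or `"per_tau"` (see Details).
#' @return A `poredyn_survival`: data frame fields `tau` (ps) and `P`, plus
#'   `tau_half` (ps, `NA` if P never reaches 0.5) and `convention`.
#' @export
survival_probability <- function(res, tau_max = NULL,
                                 convention = c("continuous", "intermittent"),
                                 origins = c("fixed", "per_tau")) {
  convention <- match.arg(convention)
  origins <- match.arg(origins)
  flags <- res$flags
  if (!any(flags)) stop("empty residency: no particle is ever inside")
  nf <- ncol(flags)
  dt <- if (nf > 1) res$times[2] - res$times[1] else 1
  span <- res$times[nf] - res$times[1]
  if (is.null(tau_max)) tau_max <- span / 2
  if (tau_max > span + 1e-9) stop("tau_max exceeds the trajectory span")
  kmax <- max(0L, floor(tau_max / dt + 1e-9))
  Nt <- colSums(flags)
  w <- ifelse(Nt > 0, 1 / Nt, 0)
  num <- numeric(kmax + 2L)   # difference-array accumulators over k = 0..kmax
  den <- numeric(kmax + 2L)
  if (convention == "continuous") {
    # run length of consecutive inside frames starting at each (particle, t)
    run <- matrix(0L, nrow(flags), nf)
    run[, nf] <- as.integer(flags[, nf])
    if (nf > 1) for (t in (nf - 1L):1L)
      run[, t] <- ifelse(flags[, t], run[, t + 1L] + 1L, 0L)
    for (t in seq_len(nf)) {
      if (Nt[t] == 0) next
      k_t <- min(kmax, nf - t)            # origins need t + k <= nf
      if (origins == "fixed" && k_t < kmax) next
      den[1L] <- den[1L] + 1
      den[k_t + 2L] <- den[k_t + 2L] - 1
      r <- run[flags[, t], t]             # particles inside at t
      kp <- pmin(r - 1L, k_t)             # survive lags 0..kp
      tab <- tabulate(kp + 1L, nbins = k_t + 1L)
      # each particle adds w[t] to num[0..kp]
      cum <- rev(cumsum(rev(tab)))        # count surviving >= k for k = 0..k_t
      num[1:(k_t + 1L)] <- num[1:(k_t + 1L)] + w[t] * cum
    }
    if (all(den == 0))
      stop("no valid time origins: shorten tau_max or use origins = 'per_tau'")
    P <- num[1:(kmax + 1L)]
    nden <- cumsum(den)[1:(kmax + 1L)]
  } else {
    P <- numeric(kmax + 1L); nden <- numeric(kmax + 1L)
    for (k in 0:kmax) {
      lim <- if (origins == "fixed") nf - kmax else nf - k
      ts <- which(Nt > 0 & seq_len(nf) <= lim)
      if (!length(ts)) { P[k + 1L] <- NA_real_; next }
      both <- colSums(flags[, ts, drop = FALSE] & flags[, ts + k, drop = FALSE])
      P[k + 1L] <- sum(both / Nt[ts])
      nden[k + 1L] <- length(ts)
    }
  }
  Pv <- ifelse(nden > 0, P / nden, NA_real_)
  curve <- structure(
    list(tau = (0:kmax) * dt, P = Pv, convention = convention,
         origins = origins, n_origins = nden),
    class = "poredyn_survival")
  curve$tau_half <- residence_half_life(curve)
  curve
}

#' @export
print.poredyn_survival <- function(x, ...) {
  cat(sprintf("<poredyn_survival> %s convention, %d lags, tau_half = %s ps\n",
              x$convention, length(x$tau),
              if (is.na(x$tau_half)) "undefined" else format(x$tau_half)))
  invisible(x)
}

#' Residence half-life from a survival curve
#'
#' The residence half-life tau_1/2 is the lag at which P(tau) crosses 0.5,
#' obtained by linear interpolation between the two grid points bracketing
#' the crossing.  If P never reaches 0.5 within the grid the half-life is
#' undefined and `NA` is returned (reported, not an error).
#'
#' @param curve a [survival_probability()] result, or a list with numeric
#'   fields `tau` and `P`.
#' @return tau_1/2 in ps, or `NA_real_`.
#' @export
residence_half_life <- function(curve) {
  tau <- curve$tau; P <- curve$P
  if (!length(tau)) stop("empty survival curve")
  ok <- !is.na(P)
  tau <- tau[ok]; P <- P[ok]
  below <- which(P <= 0.5)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (P[i] == 0.5 || i == 1L) return(tau[i])
  # interpolate between (tau[i-1], P[i-1]) and (tau[i], P[i])
  tau[i - 1] + (P[i - 1] - 0.5) / (P[i - 1] - P[i]) * (tau[i] - tau[i - 1])
}
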