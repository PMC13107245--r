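# Umbrella sampling along a 1-D reaction coordinate and WHAM unbiasing.
# Published-scale defaults: 20 windows, harmonic bias constant 1000
# kcal/(mol A^2), histogram bin width 0.1 A.

#' Umbrella window
#'
#' One harmonically biased window: bias potential `(ki/2) (R - Ri)^2` centred
#' at `Ri`.
#'
#' @param center Window centre `Ri`, reaction-coordinate units.
#' @param k Bias force constant `ki`, kcal/mol per unit^2 (> 0).
#' @param samples Optional reaction-coordinate samples already drawn.
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k = 1000, samples = NULL) {
  if (k <= 0) stop("bias constant k must be > 0")
  if (!is.null(samples) && !all(is.finite(samples)))
    stop("samples must be finite")
  structure(list(center = center, k = k, samples = samples,
                 n_samples = length(samples)),
            class = "umbrella_window")
}

#' Sample one umbrella window
#'
#' Draws reaction-coordinate samples from the biased potential
#' `V(R) + (k/2)(R - Ri)^2` by Metropolis-adjusted overdamped Langevin
#' dynamics (`"mala"`, the default: the Langevin proposal is accepted or
#' rejected so the stationary distribution is exactly Boltzmann),
#' unadjusted overdamped Langevin (`"langevin"`), or a random-walk
#' Metropolis fallback for non-differentiable surfaces (`"metropolis"`).
#'
#' @param surface A 1-D [potential_surface()].
#' @param window An [umbrella_window()].
#' @param n_steps Number of samples to draw (> 0), one per step after
#'   burn-in.
#' @param temperature Temperature, K.
#' @param seed RNG seed (identical seeds give identical samples).
#' @param method Sampler; see Description.
#' @param step Langevin mobility step alpha (drift `-alpha V'`, noise sd
#'   `sqrt(2 alpha kB T)`); default `0.5 / k`, which scales the proposal to
#'   the width of the biased well while keeping successive samples nearly
#'   decorrelated.
#' @param burn_in Discarded equilibration steps.
#' @return The window with `samples` and `n_samples` filled in.
#' @export
run_umbrella_window <- function(surface, window, n_steps, temperature = 300,
                                seed = NULL,
                                method = c("mala", "langevin", "metropolis"),
                                step = NULL, burn_in = 200) {
  stopifnot(inherits(window, "umbrella_window"))
  method <- match.arg(method)
  if (n_steps <= 0) stop("empty-sample error: n_steps must be > 0")
  if (surface$dimension != 1)
    stop("umbrella sampling is implemented for 1-D reaction coordinates")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(step)) step <- 0.5 / window$k
  kbt <- .kB * temperature
  ri <- window$center; k <- window$k
  vb <- function(x) surface$fun(x) + 0.5 * k * (x - ri)^2
  gb <- function(x) surface_gradient(surface, x) + k * (x - ri)
  total <- burn_in + n_steps
  noise_sd <- sqrt(2 * step * kbt)
  xi <- stats::rnorm(total)
  u <- if (method != "langevin") stats::runif(total) else numeric(0)
  out <- numeric(n_steps)
  x <- ri
  if (method == "metropolis") {
    ex <- vb(x)
    for (s in seq_len(total)) {
      xp <- x + noise_sd * xi[s]
      ep <- vb(xp)
      if (u[s] < exp((ex - ep) / kbt)) { x <- xp; ex <- ep }
      if (s > burn_in) out[s - burn_in] <- x
    }
  } else if (method == "langevin") {
    for (s in seq_len(total)) {
      x <- x - step * gb(x) + noise_sd * xi[s]
      if (s > burn_in) out[s - burn_in] <- x
    }
  } else {
    ex <- vb(x); gx <- gb(x)
    for (s in seq_len(total)) {
      mx <- x - step * gx
      xp <- mx + noise_sd * xi[s]
      ep <- vb(xp); gp <- gb(xp)
      mp <- xp - step * gp
      # Metropolis-Hastings ratio with the asymmetric Langevin proposal
      logr <- (ex - ep) / kbt +
        ((xp - mx)^2 - (x - mp)^2) / (4 * step * kbt)
      if (log(u[s]) < logr) { x <- xp; ex <- ep; gx <- gp }
      if (s > burn_in) out[s - burn_in] <- x
    }
  }
  umbrella_window(ri, k, samples = out)
}

#' Place evenly spaced umbrella windows
#'
#' @param from,to Reaction-coordinate range covered by the window centres.
#' @param n Number of windows (default 20).
#' @param k Bias constant for every window, kcal/mol per unit^2.
#' @return List of [umbrella_window()] objects.
#' @export
umbrella_ladder <- function(from, to, n = 20, k = 1000) {
  lapply(seq(from, to, length.out = n), umbrella_window, k = k)
}

#' WHAM: combine umbrella windows into a potential of mean force
#'
#' Standard weighted-histogram self-consistency: with histogram counts
#' `n_lk` of window `l` in bin `k` and bias factors
#' `c_lk = exp(-b_lk / kB T)`, iterate `P_k = sum_l n_lk / sum_l N_l f_l
#' c_lk` and `f_l = 1 / sum_k c_lk P_k` until the window constants change by
#' less than `tolerance`, then report `W_k = -kB T ln P_k`, shifted so the
#' profile minimum is zero. The bias is removed (subtracted), which is the
#' form that recovers a planted free-energy profile.
#'
#' @param windows List of sampled [umbrella_window()]s.
#' @param temperature Temperature, K.
#' @param bin_width Histogram bin width, reaction-coordinate units
#'   (left-closed, right-open bins).
#' @param tolerance Convergence threshold on the maximum relative change of
#'   the window constants.
#' @param max_iterations Iteration cap.
#' @param min_overlap Warn when the smaller of two adjacent windows' shared-
#'   bin sample fractions falls below this.
#' @param min_count Bins with fewer total samples than this are reported as
#'   `NA`: their unbiased probability estimate is dominated by shot noise
#'   amplified by the inverse bias factor, and anchoring the profile on such
#'   a bin would shift the whole curve.
#' @return Object of class `pmf_profile`: `bins` (centres), `w` (free
#'   energy, kcal/mol, min 0), `err` (rough per-bin statistical
#'   uncertainty, `kB T / sqrt(n_k)`), `counts`, `reference_bin`,
#'   `iterations`, `converged`.
#' @export
wham_solve <- function(windows, temperature = 300, bin_width = 0.1,
                       tolerance = 1e-6, max_iterations = 100000,
                       min_overlap = 0.05, min_count = 5) {
  stopifnot(length(windows) >= 1)
  for (w in windows)
    if (is.null(w$samples) || w$n_samples == 0)
      stop("wham_solve: every window must carry samples")
  kbt <- .kB * temperature
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  x0 <- floor(min(all_s) / bin_width) * bin_width
  nbin <- floor((max(all_s) - x0) / bin_width) + 1L
  centers <- x0 + (seq_len(nbin) - 0.5) * bin_width
  l <- length(windows)
  counts <- matrix(0, l, nbin)
  for (i in seq_len(l)) {
    idx <- pmin(nbin, floor((windows[[i]]$samples - x0) / bin_width) + 1L)
    counts[i, ] <- tabulate(idx, nbins = nbin)
  }

  # adjacent-window overlap diagnostics
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  for (a in seq_len(l - 1)) {
    i <- ord[a]; j <- ord[a + 1]
    shared <- counts[i, ] > 0 & counts[j, ] > 0
    if (!any(shared))
      stop("wham_solve: disjoint histograms between windows centred at ",
           format(windows[[i]]$center), " and ", format(windows[[j]]$center))
    ov <- min(sum(counts[i, shared]) / sum(counts[i, ]),
              sum(counts[j, shared]) / sum(counts[j, ]))
    if (ov < min_overlap)
      warning("wham_solve: adjacent windows at ",
              format(windows[[i]]$center), " and ",
              format(windows[[j]]$center), " overlap in only ",
              format(100 * ov, digits = 2), "% of samples")
  }

  bias <- t(vapply(windows, function(w)
    0.5 * w$k * (centers - w$center)^2, numeric(nbin)))
  cmat <- exp(-bias / kbt)
  nl <- rowSums(counts)
  ntot_k <- colSums(counts)
  f <- rep(1, l)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iterations)) {
    denom <- colSums(cmat * (nl * f))
    p <- ifelse(denom > 0, ntot_k / denom, 0)
    fnew <- 1 / as.numeric(cmat %*% p)
    # fix the gauge (free energies are defined up to a constant)
    fnew <- fnew / fnew[1]
    delta <- max(abs(fnew / f - 1))
    f <- fnew
    if (delta < tolerance) { converged <- TRUE; break }
  }
  occupied <- ntot_k >= max(1, min_count)
  w <- rep(NA_real_, nbin)
  w[occupied] <- -kbt * log(p[occupied])
  w <- w - min(w, na.rm = TRUE)
  err <- ifelse(occupied, kbt / sqrt(ntot_k), NA_real_)
  structure(list(bins = centers, w = w, err = err, counts = ntot_k,
                 reference_bin = which.min(w), iterations = it,
                 converged = converged, temperature = temperature,
                 bin_width = bin_width),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("<pmf_profile> ", length(x$bins), " bins over [",
      format(min(x$bins)), ", ", format(max(x$bins)), "], max W = ",
      format(max(x$w, na.rm = TRUE), digits = 5), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Free-energy barrier between two regions of a PMF
#'
#' Finds the free-energy minimum inside each region and returns the highest
#' point between them minus the reactant-region minimum.
#'
#' @param profile A `pmf_profile` from [wham_solve()].
#' @param reactant_region,product_region Length-2 numeric reaction-coordinate
#'   ranges (disjoint, inside the profile).
#' @return Barrier height, kcal/mol.
#' @export
pmf_barrier <- function(profile, reactant_region, product_region) {
  stopifnot(inherits(profile, "pmf_profile"))
  pick <- function(rg) {
    sel <- which(profile$bins >= rg[1] & profile$bins <= rg[2] &
                   !is.na(profile$w))
    if (length(sel) == 0)
      stop("pmf_barrier: region [", rg[1], ", ", rg[2],
           "] lies outside the profile")
    sel
  }
  ra <- pick(reactant_region)
  rb <- pick(product_region)
  if (length(intersect(ra, rb)) > 0)
    stop("pmf_barrier: regions must be disjoint")
  ia <- ra[which.min(profile$w[ra])]
  ib <- rb[which.min(profile$w[rb])]
  span <- seq(min(ia, ib), max(ia, ib))
  max(profile$w[span], na.rm = TRUE) - profile$w[ia]
}

#' Transition-state-theory rate
#'
#' `k = A exp(-dG / kB T)`. With `prefactor = "eyring"` the attempt
#' frequency is `kB T / h` (about 6.25e12 1/s at 300 K); otherwise the
#' supplied numeric prefactor is used, which also serves to reproduce
#' empirical distance-rate mappings whose effective prefactor is far below
#' the Eyring value.
#'
#' @param barrier Free-energy barrier, kcal/mol (>= 0).
#' @param temperature Temperature, K.
#' @param prefactor `"eyring"` or a rate in 1/s.
#' @return Rate in 1/s.
#' @export
tst_rate <- function(barrier, temperature = 300, prefactor = "eyring") {
  if (any(barrier < 0)) stop("tst_rate: barrier must be >= 0")
  a <- if (identical(prefactor, "eyring")) {
    uc <- unit_constants()
    uc$kB_si * temperature / uc$planck_si
  } else as.numeric(prefactor)
  a * exp(-barrier / (.kB * temperature))
}
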