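# Nudged-elastic-band transition-state search on analytic surfaces. The band
# uses the plain (non-projected) elastic force F_i = -grad E(R_i)
# + kappa (R_{i+1} - 2 R_i + R_{i-1}); the climbing image replaces its spring
# force by the true force with the tangential component inverted.

#' NEB settings
#'
#' Defaults follow the published CI-NEB protocol for the C-N bond-formation
#' path: 10 images, spring constant 5.0 eV/A^2, maximum-force tolerance
#' 0.05 eV/A and RMS-force tolerance 0.02 eV/A, all converted once into
#' kcal/mol units (1 eV = 23.0609 kcal/mol).
#'
#' @param n_images Number of images including the fixed endpoints (>= 3).
#' @param spring Spring constant kappa, kcal/(mol A^2).
#' @param fmax Maximum-force convergence tolerance, kcal/(mol A).
#' @param frms RMS-force convergence tolerance, kcal/(mol A).
#' @param climbing Activate the climbing image once the plain band is within
#'   10 x `fmax`.
#' @param max_iterations Iteration cap.
#' @param step_size Initial steepest-descent step, A^2 mol/kcal (displacement
#'   per unit force).
#' @return Object of class `neb_settings`.
#' @export
neb_settings <- function(n_images = 10, spring = 5.0 * 23.0609,
                         fmax = 0.05 * 23.0609, frms = 0.02 * 23.0609,
                         climbing = TRUE, max_iterations = 10000,
                         step_size = 2e-3) {
  if (n_images < 3) stop("n_images must be >= 3")
  if (fmax <= 0 || frms <= 0) stop("force tolerances must be > 0")
  structure(list(n_images = as.integer(n_images), spring = spring,
                 fmax = fmax, frms = frms, climbing = isTRUE(climbing),
                 max_iterations = as.integer(max_iterations),
                 step_size = step_size),
            class = "neb_settings")
}

#' Band forces for a chain of images
#'
#' Plain elastic-band force for interior images; when `climbing_index` is an
#' interior image it instead receives the true force with the component
#' along the chord tangent `(R_{i+1} - R_{i-1})` inverted, and no spring
#' force. Endpoint forces are reported as zero (endpoints are fixed).
#'
#' @param images Matrix n_images x dimension of configurations.
#' @param surface A [potential_surface()].
#' @param settings A [neb_settings()].
#' @param climbing_index Interior image index to treat as the climbing
#'   image, or `NULL`.
#' @return Matrix of per-image forces, same shape as `images`.
#' @export
neb_forces <- function(images, surface, settings, climbing_index = NULL) {
  images <- as.matrix(images)
  m <- nrow(images)
  if (m < 3) stop("neb_forces: need at least 3 images")
  f <- matrix(0, m, ncol(images))
  grads <- t(apply(images, 1, function(x) surface_gradient(surface, as.numeric(x))))
  if (ncol(images) == 1) grads <- matrix(grads, ncol = 1)
  for (i in 2:(m - 1)) {
    if (!is.null(climbing_index) && i == climbing_index &&
        sum((images[i + 1, ] - images[i - 1, ])^2) > 1e-24) {
      tau <- images[i + 1, ] - images[i - 1, ]
      tau <- tau / sqrt(sum(tau^2))
      g <- grads[i, ]
      f[i, ] <- -g + 2 * sum(g * tau) * tau
    } else {
      spring <- settings$spring * (images[i + 1, ] - 2 * images[i, ] + images[i - 1, ])
      f[i, ] <- -grads[i, ] + spring
    }
  }
  f
}

#' Run a (climbing-image) NEB search
#'
#' Images are initialized by linear interpolation between `start` and `end`
#' and relaxed by damped steepest descent (adaptive step halving). The
#' climbing image activates once the plain band's maximum interior force is
#' below 10 x the convergence tolerance, selecting the highest-energy
#' interior image (lowest index on ties).
#'
#' @param start,end Endpoint configurations (approximate minima).
#' @param surface A [potential_surface()].
#' @param settings A [neb_settings()].
#' @return Object of class `neb_result`: `images`, `energies`,
#'   `saddle_index`, `barrier_forward`, `barrier_reverse`, `converged`,
#'   `iterations`.
#' @examples
#' dw <- gen_double_well_surface(surface_spec(barrier = 5))
#' res <- run_neb(-1, 1, dw$surface, neb_settings())
#' res$barrier_forward  # ~5 kcal/mol
#' @export
run_neb <- function(start, end, surface, settings = neb_settings()) {
  start <- as.numeric(start); end <- as.numeric(end)
  m <- settings$n_images
  dim <- length(start)
  images <- t(vapply(seq_len(m), function(i) {
    w <- (i - 1) / (m - 1)
    (1 - w) * start + w * end
  }, numeric(dim)))
  if (dim == 1) images <- matrix(images, ncol = 1)

  step <- settings$step_size
  climbing_index <- NULL
  converged <- FALSE
  it <- 0
  prev_fmax <- Inf
  for (it in seq_len(settings$max_iterations)) {
    f <- neb_forces(images, surface, settings, climbing_index)
    fin <- f[2:(m - 1), , drop = FALSE]
    fmax_now <- max(abs(fin))
    frms_now <- sqrt(mean(fin^2))
    if (fmax_now < settings$fmax && frms_now < settings$frms) {
      if (!settings$climbing || !is.null(climbing_index)) {
        converged <- TRUE
        break
      }
    }
    if (settings$climbing && is.null(climbing_index) &&
        fmax_now < 10 * settings$fmax) {
      e <- .surface_energy_many(surface, images)
      interior <- 2:(m - 1)
      climbing_index <- interior[which.max(e[interior])]
      prev_fmax <- Inf
      next
    }
    # damped steepest descent with adaptive step
    if (fmax_now > prev_fmax * 1.5) step <- step / 2 else step <- min(step * 1.05, settings$step_size * 4)
    prev_fmax <- fmax_now
    images[2:(m - 1), ] <- images[2:(m - 1), , drop = FALSE] + step * fin
  }
  energies <- .surface_energy_many(surface, images)
  saddle_index <- which.max(energies)
  structure(list(images = images, energies = energies,
                 saddle_index = saddle_index,
                 barrier_forward = energies[saddle_index] - energies[1],
                 barrier_reverse = energies[saddle_index] - energies[m],
                 converged = converged, iterations = it),
            class = "neb_result")
}

#' @export
print.neb_result <- function(x, ...) {
  cat("<neb_result> ", nrow(x$images), " images, saddle at image ",
      x$saddle_index, "\n  forward barrier ",
      format(x$barrier_forward, digits = 5), " kcal/mol, reverse ",
      format(x$barrier_reverse, digits = 5), " kcal/mol (",
      if (x$converged) "converged" else "NOT converged", ", ",
      x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Central finite-difference Hessian
#'
#' Symmetric second-derivative matrix of the surface at `point`. Uses the
#' surface gradient (analytic or finite-difference) differenced centrally,
#' then symmetrizes as `(H + t(H))/2`.
#'
#' @param surface A [potential_surface()].
#' @param point Configuration vector.
#' @param step Displacement step (> 0), configuration units.
#' @return Symmetric numeric matrix, kcal/(mol unit^2).
#' @export
finite_difference_hessian <- function(surface, point, step = 1e-4) {
  if (step <= 0) stop("step must be > 0")
  d <- length(point)
  h <- matrix(0, d, d)
  for (i in seq_len(d)) {
    xp <- point; xp[i] <- xp[i] + step
    xm <- point; xm[i] <- xm[i] - step
    h[i, ] <- (surface_gradient(surface, xp) - surface_gradient(surface, xm)) /
      (2 * step)
  }
  (h + t(h)) / 2
}

#' Normal-mode analysis of a Hessian
#'
#' Eigendecomposition of the mass-weighted Hessian
#' `M^{-1/2} H M^{-1/2}`. Negative eigenvalues are reported as imaginary
#' frequencies `omega = conv * sqrt(|lambda|)` in cm^-1, where
#' `conv = 108.5915` converts `sqrt(kcal/(mol A^2 amu))` to wavenumbers.
#' The reduced mass of a mode with normalized mass-weighted eigenvector `w`
#' is `1 / sum(w_i^2 / m_i)`.
#'
#' @param hessian Symmetric matrix from [finite_difference_hessian()].
#' @param masses Mass of each configuration coordinate, amu (recycled;
#'   default 1, i.e. the surface coordinates are already mass-weighted).
#' @param neg_tol Eigenvalues below `-neg_tol` count as imaginary modes.
#' @return Object of class `hessian_result`: `eigenvalues`, `modes`
#'   (columns, mass-weighted), `frequencies_cm` (positive magnitudes),
#'   `imaginary` (logical per mode), `n_imaginary`, `reduced_masses`.
#' @export
normal_modes <- function(hessian, masses = 1, neg_tol = 1e-8) {
  hessian <- as.matrix(hessian)
  if (max(abs(hessian - t(hessian))) > 1e-8 * max(1, max(abs(hessian))))
    stop("normal_modes: Hessian must be symmetric")
  d <- nrow(hessian)
  masses <- rep_len(masses, d)
  invsq <- 1 / sqrt(masses)
  mw <- hessian * outer(invsq, invsq)
  eg <- eigen((mw + t(mw)) / 2, symmetric = TRUE)
  lambda <- eg$values
  modes <- eg$vectors
  imag <- lambda < -neg_tol
  freq <- .FREQ_CM * sqrt(abs(lambda))
  redm <- vapply(seq_len(d), function(k) 1 / sum(modes[, k]^2 / masses),
                 numeric(1))
  structure(list(eigenvalues = lambda, modes = modes, frequencies_cm = freq,
                 imaginary = imag, n_imaginary = sum(imag),
                 reduced_masses = redm, masses = masses),
            class = "hessian_result")
}

#' Classify a stationary point from its normal modes
#'
#' A minimum has no imaginary mode; a transition state has exactly one, and
#' its displacement must lie predominantly on the declared
#' reaction-coordinate degrees of freedom (squared-component overlap >=
#' `overlap_threshold`); anything else is a higher-order saddle. With no
#' declared reaction coordinate the overlap test is skipped.
#'
#' @param modes A `hessian_result` from [normal_modes()].
#' @param reaction_coords Integer indices of the configuration coordinates
#'   forming the reaction coordinate, or `NULL`.
#' @param overlap_threshold Minimum squared overlap (default 0.5).
#' @return One of `"minimum"`, `"transition_state"`,
#'   `"higher_order_saddle"`.
#' @export
classify_stationary_point <- function(modes, reaction_coords = NULL,
                                      overlap_threshold = 0.5) {
  stopifnot(inherits(modes, "hessian_result"))
  if (modes$n_imaginary == 0) return("minimum")
  if (modes$n_imaginary > 1) return("higher_order_saddle")
  if (is.null(reaction_coords)) return("transition_state")
  k <- which(modes$imaginary)
  w <- modes$modes[, k]
  overlap <- sum(w[reaction_coords]^2) / sum(w^2)
  if (overlap >= overlap_threshold) "transition_state" else "higher_order_saddle"
}

#' Steepest-descent paths off a saddle point
#'
#' Launches damped steepest-descent trajectories from `saddle_point +/-
#' displacement * mode_direction` and follows each to a point with gradient
#' norm below `grad_tol`: the toy counterpart of an intrinsic-reaction-
#' coordinate validation that a saddle connects the expected minima.
#'
#' @param surface A [potential_surface()].
#' @param saddle_point Configuration vector of the saddle.
#' @param mode_direction Unstable-mode direction (normalized internally).
#' @param step Initial descent step.
#' @param max_steps Step cap per branch.
#' @param displacement Initial offset along the mode.
#' @param grad_tol Termination threshold on the gradient norm.
#' @return List with elements `forward` and `backward`, each a list of
#'   `path` (matrix of visited points) and `endpoint`.
#' @export
descend_path <- function(surface, saddle_point, mode_direction, step = 1e-2,
                         max_steps = 50000, displacement = 1e-2,
                         grad_tol = 1e-6) {
  mode_direction <- mode_direction / sqrt(sum(mode_direction^2))
  branch <- function(sgn) {
    x <- saddle_point + sgn * displacement * mode_direction
    st <- step
    e <- surface_energy(surface, x)
    path <- list(x)
    fails <- 0
    for (i in seq_len(max_steps)) {
      g <- surface_gradient(surface, x)
      if (sqrt(sum(g^2)) < grad_tol) break
      xn <- x - st * g
      en <- surface_energy(surface, xn)
      if (en <= e + 1e-12) {
        x <- xn; e <- en; st <- st * 1.1; fails <- 0
        path[[length(path) + 1]] <- x
      } else {
        st <- st / 2; fails <- fails + 1
        if (st < 1e-14)
          stop("descend_path: persistent non-descending step below step floor")
      }
    }
    list(path = do.call(rbind, path), endpoint = x)
  }
  list(forward = branch(+1), backward = branch(-1))
}

#' Activation energy from an NEB result
#'
#' Saddle-image energy minus the reactant energy (the first image's energy
#' unless given explicitly). A warning is attached when the band did not
#' converge.
#'
#' @param neb A `neb_result`.
#' @param reactant_energy Reference reactant energy, kcal/mol; defaults to
#'   the first image's energy.
#' @return Activation energy, kcal/mol.
#' @export
activation_energy <- function(neb, reactant_energy = NULL) {
  stopifnot(inherits(neb, "neb_result"))
  if (is.null(reactant_energy)) reactant_energy <- neb$energies[1]
  if (!neb$converged)
    warning("activation_energy: NEB result is not converged")
  neb$energies[neb$saddle_index] - reactant_energy
}
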