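# Geometric hydrogen-bond analysis: a donor-hydrogen-acceptor triple is
# bonded when the donor-acceptor distance is <= 3.5 A AND the D-H...A angle
# (measured at the hydrogen; 180 deg = linear) is >= 150 deg. Both
# boundaries are inclusive.

#' Hydrogen-bond criterion
#'
#' @param distance Maximum donor-acceptor distance, Angstrom (default 3.5).
#' @param angle Minimum D-H...A angle at the hydrogen, degrees (default 150).
#' @return Object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(distance = 3.5, angle = 150) {
  if (distance <= 0) stop("distance cutoff must be > 0")
  if (angle <= 0 || angle > 180) stop("angle cutoff must be in (0, 180]")
  structure(list(distance = distance, angle = angle),
            class = "hbond_criterion")
}

#' Hydrogen bonds in one frame
#'
#' @param positions Numeric matrix (atoms x 3), Angstrom.
#' @param triples Integer matrix with columns donor, hydrogen, acceptor
#'   (1-based atom indices), one row per candidate bond.
#' @param criterion An [hbond_criterion()].
#' @return `data.frame` of accepted events with columns `triple`, `donor`,
#'   `hydrogen`, `acceptor`, `distance`, `angle`; zero rows when nothing
#'   qualifies.
#' @examples
#' pos <- rbind(c(0, 0, 0), c(0.98, 0.15, 0), c(2.9, 0, 0))
#' hbond_filter(pos, cbind(1, 2, 3), hbond_criterion())
#' @export
hbond_filter <- function(positions, triples, criterion = hbond_criterion()) {
  positions <- as.matrix(positions)
  triples <- matrix(as.integer(triples), ncol = 3)
  if (any(triples < 1) || any(triples > nrow(positions)))
    stop("hbond_filter: atom index out of range")
  out <- vector("list", nrow(triples))
  for (r in seq_len(nrow(triples))) {
    d <- positions[triples[r, 1], ]
    h <- positions[triples[r, 2], ]
    a <- positions[triples[r, 3], ]
    if (all(d == h) || all(a == h))
      stop("hbond_filter: degenerate angle, hydrogen coincides with donor ",
           "or acceptor in triple ", r)
    da <- distance(d, a)
    ang <- bond_angle(d, h, a)
    if (da <= criterion$distance && ang >= criterion$angle) {
      out[[r]] <- data.frame(triple = r, donor = triples[r, 1],
                             hydrogen = triples[r, 2],
                             acceptor = triples[r, 3],
                             distance = da, angle = ang)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(triple = integer(0), donor = integer(0),
                      hydrogen = integer(0), acceptor = integer(0),
                      distance = numeric(0), angle = numeric(0)))
  do.call(rbind, out)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Fraction of frames in which each candidate triple satisfies the
#' criterion.
#'
#' @param traj An [md_trajectory()].
#' @param triples Integer matrix with columns donor, hydrogen, acceptor.
#' @param criterion An [hbond_criterion()].
#' @return Numeric vector in \[0, 1\], one entry per triple.
#' @export
hbond_occupancy <- function(traj, triples, criterion = hbond_criterion()) {
  nf <- n_frames(traj)
  if (nf < 1) stop("hbond_occupancy: trajectory has no frames")
  triples <- matrix(as.integer(triples), ncol = 3)
  hits <- numeric(nrow(triples))
  for (f in seq_len(nf)) {
    pos <- matrix(traj$positions[f, , , drop = TRUE],
                  ncol = 3)
    ev <- hbond_filter(pos, triples, criterion)
    if (nrow(ev) > 0) hits[ev$triple] <- hits[ev$triple] + 1
  }
  hits / nf
}
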