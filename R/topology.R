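# Topological observables: writhe (Gauss sum), twist (ladder dihedrals),
# linking number, persistence length and intersegmental-passage detection.

#' Writhe of a bead polyline
#'
#' Discretized Gauss double integral over all non-adjacent segment pairs
#' (pairwise signed solid angles, Klenin-Langowski method). For open chains
#' the sum runs over the open path without artificial closure; a `range`
#' restricts the sum to segment pairs inside a bead range (per-domain
#' writhe; cross-domain terms excluded).
#'
#' @param positions n x 3 bead coordinates (or a `fiber_system` /
#'   `fiber_trajectory` frame).
#' @param closed treat the polyline as closed (adds the closure segment when
#'   the full range is used).
#' @param range optional 1-based inclusive bead range `c(from, to)`.
#' @return writhe in turns; negative for negatively supercoiled fibres.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 33)[-33]
#' circle <- cbind(cos(th), sin(th), 0)
#' writhe(circle, closed = TRUE)  # 0
#' @export
writhe <- function(positions, closed = FALSE, range = NULL) {
  if (inherits(positions, "fiber_system")) {
    closed <- positions$closed
    positions <- positions$positions
  }
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 4) stop("need at least 4 beads")
  seg <- positions[-1, , drop = FALSE] - positions[-n, , drop = FALSE]
  if (any(rowSums(seg^2) < 1e-20)) stop("coincident consecutive beads")
  if (is.null(range)) range <- c(1L, n)
  if (range[1] < 1 || range[2] > n || range[2] - range[1] < 3)
    stop("invalid bead range")
  cpp_writhe(positions, closed, as.integer(range[1]) - 1L,
             as.integer(range[2]) - 1L)
}

#' Twist of the material frame
#'
#' Sum of the signed ladder dihedrals (side site i, bead i, bead i+1, side
#' site i+1) over all bonds, each wrapped to (-pi, pi], divided by 2 pi.
#'
#' @param positions n x 3 bead coordinates, or a `fiber_system` (then
#'   `side_sites`/`closed` are taken from it).
#' @param side_sites n x 3 side-site coordinates.
#' @param closed include the closure bond.
#' @param per_bond return the per-bond dihedral angles instead of the total.
#' @return total twist in turns (or per-bond angles in radians).
#' @export
twist <- function(positions, side_sites = NULL, closed = FALSE,
                  per_bond = FALSE) {
  if (inherits(positions, "fiber_system")) {
    side_sites <- positions$side_sites
    closed <- positions$closed
    positions <- positions$positions
  }
  res <- cpp_twist(as.matrix(positions), as.matrix(side_sites), closed)
  if (per_bond) res$phi else res$turns
}

#' Linking number of a closed torsionally constrained fibre
#'
#' `Lk = Tw + Wr` (Calugareanu-White). Defined only for closed chains
#' without swivel bonds; between intersegmental passages it is conserved and
#' integer-valued to within ~0.02 turns for well-resolved ribbons. A single
#' duplex passage changes it by +/-2.
#'
#' @param system a `fiber_system` (closed, swivel-free), or a list with
#'   `positions`, `side_sites`.
#' @return linking number in turns.
#' @export
linking_number <- function(system) {
  if (inherits(system, "fiber_system")) {
    if (!system$closed) stop("Lk undefined: open chain")
    if (length(system$swivel_bonds) > 0)
      stop("Lk undefined: swivel present (free rotation)")
    pos <- system$positions
    sites <- system$side_sites
  } else {
    pos <- system$positions
    sites <- system$side_sites
  }
  twist(pos, sites, closed = TRUE) + writhe(pos, closed = TRUE)
}

#' Persistence length from tangent correlations
#'
#' Fits `<t_i . t_(i+s)> = exp(-s b / Lp)` over separations `s b <= fit_nm`
#' (default 150 nm), averaging over frames of an equilibrated passive chain.
#'
#' @param traj a `fiber_trajectory` with stored frames, or a list of bead
#'   coordinate matrices.
#' @param b_nm bond length in nm (10 nm).
#' @param fit_nm maximum separation used in the fit.
#' @param discard fraction of initial frames discarded as equilibration.
#' @return persistence length in nm.
#' @export
persistence_length <- function(traj, b_nm = 10, fit_nm = 150, discard = 0.25) {
  frames <- .bead_frames(traj)
  nf <- length(frames)
  frames <- frames[seq.int(max(1, floor(discard * nf) + 1), nf)]
  n <- nrow(frames[[1]])
  smax <- min(floor(fit_nm / b_nm), n - 2)
  corr <- numeric(smax)
  cnt <- numeric(smax)
  for (f in frames) {
    t <- f[-1, , drop = FALSE] - f[-n, , drop = FALSE]
    t <- t / sqrt(rowSums(t^2))
    nb <- nrow(t)
    for (s in seq_len(smax)) {
      corr[s] <- corr[s] + sum(t[seq_len(nb - s), ] * t[s + seq_len(nb - s), ])
      cnt[s] <- cnt[s] + (nb - s)
    }
  }
  cs <- corr / cnt
  s <- seq_len(smax)
  if (sum(cs > 0) < 3) stop("tangent correlations decay too fast to fit")
  # direct least squares on the linear scale: a log fit would let the noisy
  # small-correlation tail dominate
  sse <- function(lam) sum((cs - exp(-s / lam))^2)
  lam <- optimize(sse, c(0.2, 200))$minimum
  lam * b_nm
}

# extract bead frames from trajectory-like inputs
.bead_frames <- function(traj) {
  if (inherits(traj, "fiber_trajectory")) {
    if (is.null(traj$frames)) stop("trajectory has no stored frames")
    nf <- dim(traj$frames)[3]
    lapply(seq_len(nf), function(k) frame_beads(traj, k))
  } else if (is.list(traj)) {
    lapply(traj, as.matrix)
  } else {
    list(as.matrix(traj))
  }
}

#' Detect intersegmental-passage events in a writhe series
#'
#' An event is a jump `|Wr(t+1) - Wr(t)| >= threshold` between consecutive
#' reports; a duplex passage changes writhe by ~2 turns while thermal
#' fluctuations stay below ~1, so the default threshold sits between the two
#' scales.
#'
#' @param wr per-domain writhe series (uniformly sampled).
#' @param threshold jump size in turns (default 1.5).
#' @param steps optional step index per sample (defaults to 0, 1, 2, ...).
#' @param domain domain label attached to the events.
#' @return data frame with `step`, `domain`, `dWr` (signed change).
#' @export
detect_passage_events <- function(wr, threshold = 1.5, steps = NULL,
                                  domain = NA_integer_) {
  if (is.null(steps)) steps <- seq_along(wr) - 1
  d <- diff(wr)
  idx <- which(abs(d) >= threshold)
  data.frame(step = steps[idx + 1], domain = rep(domain, length(idx)),
             dWr = d[idx])
}

#' Writhe change across a constructed intersegmental passage
#'
#' Builds a closed curve with a single close interwound crossing (two lobes
#' crossing at gap `separation` sigma) and displaces the passing segment
#' through the other along their common normal, to the mirror gap, keeping
#' everything else fixed. With twist held fixed, the Gauss-sum writhe changes
#' by ~2 turns -- the topological signature of a duplex passage.
#'
#' @param n beads on the closed curve.
#' @param separation gap between the crossing segments in sigma (before and
#'   after; the moved segment travels 2 x separation).
#' @param lobe_radius lobe radius in sigma; crossing is "close" when
#'   `separation << lobe_radius`.
#' @return list with `wr_before`, `wr_after`, `delta` (signed) and the two
#'   bead matrices.
#' @export
passage_writhe_change <- function(n = 200, separation = 1.1,
                                  lobe_radius = 25) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  R <- lobe_radius
  h <- separation
  base <- cbind(R * sin(t), R * sin(t) * cos(t), (h / 2) * cos(t))
  # displace the strand near t = pi (z = -h/2 at the crossing) upward through
  # the t = 0 strand by 2 * separation, with a smooth localized bump
  bump <- 2 * h * exp(-((t - pi) / 0.45)^2)
  after <- base
  after[, 3] <- after[, 3] + bump
  wr0 <- writhe(base, closed = TRUE)
  wr1 <- writhe(after, closed = TRUE)
  list(wr_before = wr0, wr_after = wr1, delta = wr1 - wr0,
       before = base, after = after)
}
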