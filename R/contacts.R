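# Contact maps from trajectories; binning to Hi-C resolution; domain,
# boundary and ring-depletion scoring.

#' Contact map from a trajectory
#'
#' For every stored frame, increments `M[i, j]` when the minimum-image
#' distance between beads i and j is at most `cutoff` sigma. The matrix is
#' symmetric by construction; the diagonal counts frames (a bead always
#' contacts itself), so diagonal entries are maximal per row. Bonded
#' neighbours (`|i - j| <= 1`) are excluded by default.
#'
#' @param traj a `fiber_trajectory` with frames, a list of bead coordinate
#'   matrices, or a list of trajectories (counts pooled).
#' @param cutoff contact distance in sigma (default 1.5, i.e. 15 nm
#'   surface-proximity criterion).
#' @param exclude_adjacent drop `|i - j| <= 1` pairs.
#' @param box periodic box edge (taken from the trajectory when available).
#' @return object of class `contact_matrix`: `counts` (n x n), `n_frames`,
#'   `cutoff`, `bin_beads = 1`, `bp_per_bin = 400`.
#' @export
contact_map <- function(traj, cutoff = 1.5, exclude_adjacent = TRUE,
                        box = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (inherits(traj, "fiber_trajectory")) {
    if (is.null(box)) box <- traj$system$box
    frames <- .bead_frames(traj)
  } else if (is.list(traj) && length(traj) > 0 &&
             inherits(traj[[1]], "fiber_trajectory")) {
    if (is.null(box)) box <- traj[[1]]$system$box
    frames <- unlist(lapply(traj, .bead_frames), recursive = FALSE)
  } else {
    frames <- .bead_frames(traj)
  }
  if (length(frames) < 1) stop("need at least one frame")
  if (is.null(box)) box <- -1
  n <- nrow(frames[[1]])
  counts <- matrix(0L, n, n)
  for (f in frames)
    counts <- cpp_contact_accum(counts, as.matrix(f), cutoff, box,
                                exclude_adjacent)
  structure(list(counts = counts, n_frames = length(frames), cutoff = cutoff,
                 bin_beads = 1L, bp_per_bin = .BP_PER_BEAD),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d x %d bins (%g kb/bin), %d frames, cutoff %g sigma\n",
              nrow(x$counts), ncol(x$counts), x$bp_per_bin / 1000,
              x$n_frames, x$cutoff))
  invisible(x)
}

#' Bin a contact matrix
#'
#' Block-averages `bin_beads x bin_beads` tiles (25 beads = 10 kb, the usual
#' Hi-C resolution). A trailing partial bin is averaged over its true size,
#' so the global mean of the map is conserved up to edge effects.
#'
#' @param cm a `contact_matrix` (bead resolution).
#' @param bin_beads beads per bin (default 25).
#' @return a `contact_matrix` with averaged (numeric) counts.
#' @export
bin_map <- function(cm, bin_beads = 25) {
  stopifnot(inherits(cm, "contact_matrix"), bin_beads >= 1)
  bin_beads <- as.integer(bin_beads)
  if (bin_beads == 1L) return(cm)
  n <- nrow(cm$counts)
  g <- (seq_len(n) - 1L) %/% bin_beads + 1L
  nb <- max(g)
  m <- matrix(0, nb, nb)
  for (a in seq_len(nb)) {
    ia <- which(g == a)
    for (b in a:nb) {
      ib <- which(g == b)
      m[a, b] <- mean(cm$counts[ia, ib])
      m[b, a] <- m[a, b]
    }
  }
  structure(list(counts = m, n_frames = cm$n_frames, cutoff = cm$cutoff,
                 bin_beads = bin_beads * cm$bin_beads,
                 bp_per_bin = cm$bp_per_bin * bin_beads),
            class = "contact_matrix")
}

#' Intra- vs inter-domain contact scores
#'
#' For each domain, the mean contact frequency between loci inside the
#' domain is compared with the mean frequency across each of its borders at
#' the same genomic separations (the TAD signal: matched-separation intra
#' counts exceed inter counts 2-3x in experimental maps).
#'
#' @param cm a `contact_matrix` at bead resolution.
#' @param domains data frame with `start`, `end` bead ranges (e.g.
#'   `system$domains`).
#' @param min_sep smallest separation included (default 2, skipping bonded
#'   neighbours).
#' @return data frame with `domain`, `intra`, `inter`, `ratio`.
#' @export
domain_contact_scores <- function(cm, domains, min_sep = 2) {
  stopifnot(inherits(cm, "contact_matrix"))
  M <- cm$counts
  n <- nrow(M)
  K <- nrow(domains)
  if (any(domains$start < 1 | domains$end > n)) stop("domains out of range")
  res <- data.frame(domain = seq_len(K), intra = NA_real_, inter = NA_real_,
                    ratio = NA_real_)
  sep_mean <- function(i0, i1, j0, j1, s) {
    # mean of M[i, i + s] with i in [i0, i1], i + s in [j0, j1]; NA entries
    # (e.g. masked bands) are dropped
    i <- max(i0, j0 - s):min(i1, j1 - s)
    i <- i[i >= 1 & i + s <= n]
    if (length(i) < 1) return(NULL)
    v <- M[cbind(i, i + s)]
    v <- v[!is.na(v)]
    if (length(v) < 1) return(NULL)
    v
  }
  for (k in seq_len(K)) {
    a <- domains$start[k]; b <- domains$end[k]
    len <- b - a + 1
    neigh <- c(if (k > 1) k - 1, if (k < K) k + 1)
    smax <- min(len - 1,
                if (length(neigh) > 0)
                  max(domains$end[neigh] - domains$start[neigh] + 1) else len - 1)
    intra <- c(); inter <- c()
    for (s in min_sep:smax) {
      v <- sep_mean(a, b, a, b, s)
      vi <- NULL
      for (j in neigh) {
        if (j > k) vi <- c(vi, sep_mean(a, b, domains$start[j], domains$end[j], s))
        else vi <- c(vi, sep_mean(domains$start[j], domains$end[j], a, b, s))
      }
      if (!is.null(v) && !is.null(vi)) {
        intra <- c(intra, mean(v))
        inter <- c(inter, mean(vi))
      }
    }
    res$intra[k] <- mean(intra)
    res$inter[k] <- mean(inter)
    res$ratio[k] <- if (isTRUE(mean(inter) > 0)) mean(intra) / mean(inter) else
      if (isTRUE(mean(intra) > 0)) Inf else NA_real_
  }
  res
}

#' Insulation-profile boundary calls and coincidence with motor convergence
#'
#' Computes a sliding-diamond insulation profile (mean contact frequency in
#' the `window x window` square touching each bin boundary), calls boundaries
#' at local minima at least `delta` below the profile mean, and -- when a
#' layout is supplied -- reports the distance (in bins) from each called
#' boundary to the nearest motor-convergence position.
#'
#' @param cm a (typically binned) `contact_matrix`.
#' @param convergence optional bead positions of motor convergence (e.g.
#'   `attr(sys, "convergence")`).
#' @param window insulation window in bins (default 5).
#' @param delta minimum relative depth below the profile mean for a call.
#' @return list with `insulation` (per boundary between bins i and i+1),
#'   `boundaries` (bin index i of each call), `distance_bins` (per boundary,
#'   when `convergence` given).
#' @export
boundary_coincidence <- function(cm, convergence = NULL, window = 5,
                                 delta = 0.1) {
  stopifnot(inherits(cm, "contact_matrix"))
  M <- cm$counts
  n <- nrow(M)
  if (n < 2 * window + 2) stop("matrix too small for the insulation window")
  ins <- rep(NA_real_, n - 1)
  for (i in window:(n - window)) {
    ins[i] <- mean(M[(i - window + 1):i, (i + 1):(i + window)])
  }
  mu <- mean(ins, na.rm = TRUE)
  calls <- integer(0)
  for (i in seq_along(ins)) {
    if (is.na(ins[i]) || mu <= 0) next
    lo <- max(1, i - window); hi <- min(length(ins), i + window)
    nbr <- ins[lo:hi]
    if (ins[i] <= min(nbr, na.rm = TRUE) && ins[i] < (1 - delta) * mu) {
      # avoid duplicate flat-minimum calls within one window
      if (length(calls) == 0 || i - calls[length(calls)] > window)
        calls <- c(calls, i)
    }
  }
  out <- list(insulation = ins, boundaries = calls)
  if (!is.null(convergence) && length(calls) > 0) {
    conv_bins <- (convergence - 1) %/% (cm$bin_beads) + 1
    out$distance_bins <- vapply(calls, function(b)
      min(abs(b + 0.5 - conv_bins)), numeric(1))
  }
  out
}

#' Contact depletion at cohesin-ring anchors
#'
#' For each ring anchor, the mean contact count in the anchor's row band is
#' compared with flanking bands at the same genomic offsets; a score below 1
#' indicates contacts shielded by the ring ("depletion lines"). Entries near
#' the diagonal are excluded.
#'
#' @param cm bead-resolution `contact_matrix`.
#' @param anchors anchor bead indices (e.g. `attr(sys, "anchors")`).
#' @param halfwidth half-width of the anchor band in beads.
#' @param flank_offset,flank_width position and width of the flanking bands.
#' @param diag_exclude exclude `|i - j| <=` this from the band means.
#' @return data frame with `anchor`, `band`, `flank`, `score`.
#' @export
depletion_lines <- function(cm, anchors, halfwidth = 1, flank_offset = 4,
                            flank_width = 3, diag_exclude = 5) {
  stopifnot(inherits(cm, "contact_matrix"))
  M <- cm$counts
  n <- nrow(M)
  band_mean <- function(rows) {
    rows <- rows[rows >= 1 & rows <= n]
    tot <- 0; cnt <- 0
    for (i in rows) {
      j <- setdiff(seq_len(n), (i - diag_exclude):(i + diag_exclude))
      tot <- tot + sum(M[i, j]); cnt <- cnt + length(j)
    }
    tot / cnt
  }
  res <- data.frame(anchor = anchors, band = NA_real_, flank = NA_real_,
                    score = NA_real_)
  for (k in seq_along(anchors)) {
    a <- anchors[k]
    bm <- band_mean((a - halfwidth):(a + halfwidth))
    fl <- band_mean(c((a - flank_offset - flank_width + 1):(a - flank_offset),
                      (a + flank_offset):(a + flank_offset + flank_width - 1)))
    res$band[k] <- bm
    res$flank[k] <- fl
    res$score[k] <- if (isTRUE(fl > 0)) bm / fl else NA_real_
  }
  res
}
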