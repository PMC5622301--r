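# Plain-text input/output: XYZ trajectories, topology series, event logs and
# contact matrices (dense and sparse-triplet).

#' Write a trajectory in XYZ format
#'
#' One record per stored frame: bead count, a comment line with the step
#' index, then one `C x y z` line per particle (beads first, then side
#' sites, then ring beads).
#'
#' @param traj a `fiber_trajectory` with stored frames.
#' @param path output file.
#' @param what `"beads"` (default) or `"all"` particles.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, what = c("beads", "all")) {
  what <- match.arg(what)
  stopifnot(inherits(traj, "fiber_trajectory"), !is.null(traj$frames))
  nf <- dim(traj$frames)[3]
  np <- if (what == "beads") traj$system$n_beads else dim(traj$frames)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nf)) {
    m <- matrix(traj$frames[seq_len(np), , k], ncol = 3)
    writeLines(as.character(np), con)
    writeLines(sprintf("step %d", traj$series$step[k]), con)
    writeLines(sprintf("C %.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Write the topology series of a trajectory
#'
#' Tab-separated: step, Rg, Tw, Wr and per-domain writhe columns.
#'
#' @param traj a `fiber_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology_series <- function(traj, path) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  write.table(traj$series, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a passage-event log
#'
#' Tab-separated: step, domain, dWr, type.
#'
#' @param events data frame from [detect_passage_events()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- events
  ev$type <- rep("passage", nrow(ev))
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a contact matrix as whitespace-delimited dense text
#'
#' Metadata (frames, cutoff, bin size) travel in `#`-prefixed header lines.
#'
#' @param cm a `contact_matrix`.
#' @param path file path.
#' @return `write_contact_matrix`: `path` invisibly; `read_contact_matrix`:
#'   a `contact_matrix`.
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_frames %d", cm$n_frames), con)
  writeLines(sprintf("# cutoff %.6g", cm$cutoff), con)
  writeLines(sprintf("# bin_beads %d", cm$bin_beads), con)
  writeLines(sprintf("# bp_per_bin %d", cm$bp_per_bin), con)
  write.table(cm$counts, con, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default) {
    m <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    as.numeric(sub(paste0("^# ", key, " "), "", m[1]))
  }
  counts <- as.matrix(read.table(text = lines[!grepl("^#", lines)]))
  dimnames(counts) <- NULL
  structure(list(counts = counts, n_frames = as.integer(meta("n_frames", 1)),
                 cutoff = meta("cutoff", NA), bin_beads = as.integer(meta("bin_beads", 1)),
                 bp_per_bin = as.integer(meta("bp_per_bin", 400))),
            class = "contact_matrix")
}

#' Export a contact matrix as sparse triplets
#'
#' Tab-separated `bin1 bin2 count` (upper triangle including diagonal,
#' non-zero entries only), compatible with common Hi-C matrix tooling.
#'
#' @param cm a `contact_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contact_triplets <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  M <- cm$counts
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  df <- data.frame(bin1 = idx[, 1], bin2 = idx[, 2], count = M[idx])
  df <- df[order(df$bin1, df$bin2), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
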