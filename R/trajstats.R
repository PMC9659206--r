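# shared: superpose every frame onto the iterated mean structure (2 rounds)
# on the given selection; returns list(frames = fitted full-frame coords,
# mean = mean selection coords after the final round)
fit_to_mean <- function(traj, selection, iterations = 2) {
  frames <- traj$frames
  ref <- frames[[1]][selection, , drop = FALSE]
  for (it in seq_len(iterations)) {
    fitted <- lapply(frames, function(f) {
      sup <- superpose(f[selection, , drop = FALSE], ref)
      apply_superposition(f, sup)
    })
    ref <- Reduce(`+`, lapply(fitted, function(f)
      f[selection, , drop = FALSE])) / length(fitted)
    frames <- fitted
  }
  list(frames = frames, mean = ref)
}

#' Fitted RMSD time series
#'
#' Each frame is least-squares superposed onto the reference frame on the
#' selection before the RMSD is taken, so global rigid-body motion does not
#' register. A plateau summary (mean +/- SD) is reported over a stated
#' window of frames, by default the final 40 percent of the run.
#'
#' @param traj a [trajectory3d].
#' @param selection atom indices used for both fitting and measurement
#'   (e.g. the C-alpha set).
#' @param reference_frame frame number the series is measured against
#'   (default 1).
#' @param units `"nm"` (default) or `"angstrom"`.
#' @param plateau integer vector of frame numbers for the plateau summary;
#'   NULL for the final 40 percent.
#' @return Object of class `rmsd_series`: data.frame `series` (frame,
#'   time_ps, rmsd) plus `plateau_mean`, `plateau_sd`, `plateau_frames`.
#' @export
rmsd_series <- function(traj, selection, reference_frame = 1,
                        units = c("nm", "angstrom"), plateau = NULL) {
  units <- match.arg(units)
  if (!length(selection)) stop("empty selection")
  ref <- traj$frames[[reference_frame]][selection, , drop = FALSE]
  vals <- vapply(traj$frames, function(f)
    rmsd(f[selection, , drop = FALSE], ref, fit = TRUE, units = units),
    numeric(1))
  nf <- length(vals)
  if (is.null(plateau)) plateau <- seq(max(1, ceiling(0.6 * nf)), nf)
  out <- list(series = data.frame(frame = seq_len(nf),
                                  time_ps = (seq_len(nf) - 1) * traj$frame_spacing_ps,
                                  rmsd = vals),
              units = units,
              plateau_frames = range(plateau),
              plateau_mean = mean(vals[plateau]),
              plateau_sd = stats::sd(vals[plateau]))
  class(out) <- "rmsd_series"
  out
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("rmsd_series: %d frames; plateau (frames %d-%d) %.3f +/- %.3f %s\n",
              nrow(x$series), x$plateau_frames[1], x$plateau_frames[2],
              x$plateau_mean, x$plateau_sd, x$units))
  invisible(x)
}

#' Root-mean-square fluctuation profile
#'
#' Frames are iteratively superposed onto the mean structure (2 rounds) on
#' the selection, then RMSF_i = sqrt(mean over frames of |x_i - <x_i>|^2)
#' per selected atom.
#'
#' @param traj a [trajectory3d] with >= 2 frames.
#' @param selection atom indices (fitting set and reported set).
#' @param units `"nm"` (default) or `"angstrom"`.
#' @return Object of class `rmsf_profile`: data.frame `profile` (atom index,
#'   res_id, rmsf) and summary fields `max`, `min`, `mean`, `sd`.
#' @export
rmsf_profile <- function(traj, selection, units = c("nm", "angstrom")) {
  units <- match.arg(units)
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  ft <- fit_to_mean(traj, selection)
  sel_frames <- lapply(ft$frames, function(f) f[selection, , drop = FALSE])
  mean_xyz <- Reduce(`+`, sel_frames) / length(sel_frames)
  msf <- Reduce(`+`, lapply(sel_frames, function(f)
    rowSums((f - mean_xyz)^2))) / length(sel_frames)
  vals <- sqrt(msf)
  if (units == "nm") vals <- vals / 10
  out <- list(profile = data.frame(atom = selection,
                                   res_id = traj$topology$atoms$res_id[selection],
                                   rmsf = unname(vals)),
              units = units, max = max(vals), min = min(vals),
              mean = mean(vals), sd = stats::sd(vals))
  class(out) <- "rmsf_profile"
  out
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("rmsf_profile: %d atoms; max %.4f, min %.4f, mean %.3f +/- %.3f %s\n",
              nrow(x$profile), x$max, x$min, x$mean, x$sd, x$units))
  invisible(x)
}

#' Convert an RMSF profile to crystallographic B-factors
#'
#' The Debye-Waller relation B = (8 pi^2 / 3) * RMSF^2 with RMSF in
#' angstrom; an RMSF of 1 angstrom gives B = 26.32 angstrom^2.
#'
#' @param profile an `rmsf_profile` (any units; converted internally).
#' @return data.frame (atom, res_id, b_factor in angstrom^2).
#' @export
bfactor_from_rmsf <- function(profile) {
  stopifnot(inherits(profile, "rmsf_profile"))
  r_ang <- profile$profile$rmsf * if (profile$units == "nm") 10 else 1
  data.frame(atom = profile$profile$atom, res_id = profile$profile$res_id,
             b_factor = (8 * pi^2 / 3) * r_ang^2)
}

#' Principal component analysis of selected-atom fluctuations
#'
#' Frames are superposed onto the iterated mean structure on the selection,
#' then the 3N x 3N covariance matrix of the selected coordinates over
#' frames is eigendecomposed. Eigenvalue fractions quantify how much of the
#' total fluctuation each collective mode carries; projections are the
#' centred frame coordinates on the leading eigenvectors. The covariance is
#' unweighted by default; `mass_weight` multiplies coordinates by sqrt(mass)
#' (masses taken from the element).
#'
#' @param traj a [trajectory3d] with >= 2 frames.
#' @param selection atom indices (typically the C-alpha set).
#' @param n_modes number of eigenvectors to keep projections for (default 10).
#' @param units `"nm"` (eigenvalues nm^2, default) or `"angstrom"`.
#' @param mass_weight logical (default FALSE).
#' @return Object of class `pca_result`: `eigenvalues` (descending),
#'   `variance_fractions`, `projections` (frames x n_modes), `eigenvectors`
#'   (3N x n_modes, orthonormal), `trace`.
#' @export
pca_ca <- function(traj, selection, n_modes = 10,
                   units = c("nm", "angstrom"), mass_weight = FALSE) {
  units <- match.arg(units)
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  ft <- fit_to_mean(traj, selection)
  X <- t(vapply(ft$frames, function(f)
    as.numeric(t(f[selection, , drop = FALSE])), numeric(3 * length(selection))))
  if (units == "nm") X <- X / 10
  if (mass_weight) {
    masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
    m <- masses[toupper(traj$topology$atoms$element[selection])]
    m[is.na(m)] <- 12
    X <- X * rep(sqrt(m), each = 3)[col(X)]
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  # population covariance (mean over frames), matching the RMSF definition
  # so that sum(eigenvalues) == sum(RMSF^2) under the same superposition
  covm <- crossprod(Xc) / nrow(Xc)
  eig <- eigen(covm, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  k <- min(n_modes, length(ev))
  out <- list(eigenvalues = ev, variance_fractions = ev / sum(ev),
              eigenvectors = eig$vectors[, seq_len(k), drop = FALSE],
              projections = Xc %*% eig$vectors[, seq_len(k), drop = FALSE],
              trace = sum(diag(covm)), units = units)
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3, length(x$variance_fractions))
  cat(sprintf("pca_result: first %d modes carry %s of the fluctuation\n", k,
              paste(sprintf("%.1f%%", 100 * x$variance_fractions[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Displacement-vector field between two frames
#'
#' The later frame is superposed onto the earlier one on the selection; the
#' per-atom displacement vectors (angstrom) are reported, with the set of
#' residues whose displacement magnitude exceeds a threshold (3 angstrom by
#' default) singled out for visualisation.
#'
#' @param traj a [trajectory3d].
#' @param first_frame,last_frame frame numbers (defaults: first and last).
#' @param selection atom indices (typically C-alpha); fitting and reporting
#'   set.
#' @param threshold angstrom (default 3).
#' @return Object of class `displacement_field`: data.frame `field` (atom,
#'   res_id, dx, dy, dz, magnitude), `threshold`, `exceeding` (res_ids).
#' @export
displacement_field <- function(traj, first_frame = 1,
                               last_frame = n_frames(traj), selection,
                               threshold = 3) {
  f0 <- traj$frames[[first_frame]][selection, , drop = FALSE]
  f1 <- traj$frames[[last_frame]][selection, , drop = FALSE]
  sup <- superpose(f1, f0)
  d <- apply_superposition(f1, sup) - f0
  mag <- sqrt(rowSums(d^2))
  res <- traj$topology$atoms$res_id[selection]
  out <- list(field = data.frame(atom = selection, res_id = res,
                                 dx = d[, 1], dy = d[, 2], dz = d[, 3],
                                 magnitude = mag),
              threshold = threshold,
              exceeding = sort(unique(res[mag > threshold])))
  class(out) <- "displacement_field"
  out
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field: %d atoms, %d residues exceed %.1f A\n",
              nrow(x$field), length(x$exceeding), x$threshold))
  invisible(x)
}

#' Write a displacement field as a plain-text vector file
#' @param field a `displacement_field`.
#' @param path output path (TSV: res_id dx dy dz magnitude).
#' @return `path`, invisibly.
#' @export
write_displacement_field <- function(field, path) {
  utils::write.table(field$field[, c("res_id", "dx", "dy", "dz", "magnitude")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Addison tau time series over a trajectory
#'
#' At every frame the metal's coordination sphere is re-detected and tau
#' computed; frames where the coordination number is not 5 are reported as
#' undefined (NA) with the observed coordination number, not silently
#' dropped. The summary (mean, SD, SEM, max) is over the defined frames.
#'
#' @param traj a [trajectory3d].
#' @param metal atom index of the metal in the topology (or element symbol
#'   if unique).
#' @param cutoff donor cutoff in angstrom (default 2.6).
#' @return Object of class `tau_series`: data.frame `series` (frame, tau,
#'   n_ligands, defined) and `mean`, `sd`, `sem`, `max`, `n_defined`,
#'   `n_undefined`.
#' @export
tau_series <- function(traj, metal, cutoff = 2.6) {
  s <- traj$topology
  if (is.character(metal)) {
    hit <- which(toupper(s$atoms$element) == toupper(metal))
    if (length(hit) != 1) stop("metal element must match exactly one atom")
    metal <- hit
  }
  rows <- lapply(seq_len(n_frames(traj)), function(k) {
    sk <- set_coords(s, traj$frames[[k]])
    sph <- suppressWarnings(find_coordination_sphere(sk, metal, cutoff))
    nl <- length(sph$ligands)
    tau <- if (nl == 5) addison_tau(sph)$tau else NA_real_
    data.frame(frame = k, tau = tau, n_ligands = nl, defined = nl == 5)
  })
  ser <- do.call(rbind, rows)
  def <- ser$tau[ser$defined]
  out <- list(series = ser,
              mean = if (length(def)) mean(def) else NA_real_,
              sd = if (length(def) > 1) stats::sd(def) else NA_real_,
              sem = if (length(def) > 1) stats::sd(def) / sqrt(length(def)) else NA_real_,
              max = if (length(def)) max(def) else NA_real_,
              n_defined = sum(ser$defined), n_undefined = sum(!ser$defined))
  class(out) <- "tau_series"
  out
}

#' @export
print.tau_series <- function(x, ...) {
  cat(sprintf("tau_series: %d frames (%d undefined); mean %.3f (SD %.3f, SEM %.3f), max %.3f\n",
              nrow(x$series), x$n_undefined, x$mean, x$sd, x$sem, x$max))
  invisible(x)
}

#' Rotamer time series with run segmentation
#'
#' Classifies the side-chain rotamer of one residue at every frame and
#' reports maximal runs of a constant code as (code, first_frame,
#' last_frame), frames numbered from 1. Runs shorter than `min_run` frames
#' are merged and labelled `"mobile"`, capturing stretches of rapid
#' code-flipping between stable rotamers.
#'
#' @param traj a [trajectory3d].
#' @param res_id residue with a chi-definable (lysine-like) side chain.
#' @param min_run minimum frames for a stable run (default 5).
#' @param distorted_above passed to [classify_rotamer()].
#' @return Object of class `rotamer_series`: `codes` (per-frame), `chi`
#'   (frames x n_chi matrix), `runs` (data.frame code/first_frame/
#'   last_frame/length, with mobile stretches labelled `"mobile"`).
#' @export
rotamer_series <- function(traj, res_id, min_run = 5, distorted_above = 40) {
  s <- traj$topology
  states <- lapply(seq_len(n_frames(traj)), function(k) {
    sk <- set_coords(s, traj$frames[[k]])
    chi <- chi_angles(sk, res_id)
    if (!length(chi)) stop("residue ", res_id, " has no chi-definable side chain")
    classify_rotamer(chi, distorted_above)
  })
  codes <- vapply(states, `[[`, character(1), "code")
  chi_mat <- t(vapply(states, `[[`, numeric(length(states[[1]]$chi)), "chi"))
  r <- rle(codes)
  ends <- cumsum(r$lengths)
  runs <- data.frame(code = r$values,
                     first_frame = ends - r$lengths + 1,
                     last_frame = ends, length = r$lengths)
  runs$code[runs$length < min_run] <- "mobile"
  # merge adjacent mobile stretches
  if (nrow(runs) > 1) {
    keep <- c(TRUE, !(runs$code[-1] == "mobile" &
                        runs$code[-nrow(runs)] == "mobile"))
    merged <- runs[keep, , drop = FALSE]
    j <- 0
    for (i in seq_len(nrow(runs))) {
      if (keep[i]) j <- j + 1 else {
        merged$last_frame[j] <- runs$last_frame[i]
        merged$length[j] <- merged$last_frame[j] - merged$first_frame[j] + 1
      }
    }
    runs <- merged
  }
  rownames(runs) <- NULL
  out <- list(codes = codes, chi = chi_mat, runs = runs, min_run = min_run)
  class(out) <- "rotamer_series"
  out
}

#' @export
print.rotamer_series <- function(x, ...) {
  cat(sprintf("rotamer_series: %d frames, %d runs\n", length(x$codes),
              nrow(x$runs)))
  print(x$runs, row.names = FALSE)
  invisible(x)
}
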