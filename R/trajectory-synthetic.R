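#' Toy trajectories with programmed plasticity
#'
#' @description
#' Trajectory metrics are validated on idealized coarse backbone
#' (N, CA, O) chains whose fluctuation amplitudes and native-contact
#' loss are programmed, so every metric can be checked against known
#' ground truth. The default topology is a small beta-grasp-like fold:
#' two antiparallel strand pairs forming a sheet ladder plus a helix.
#' These toys emulate the geometry needed by the metrics (contacts,
#' backbone hydrogen bonds, fluctuations), not force-field dynamics.
#'
#' @name toy_trajectory
NULL

ATOM_MASSES <- c(N = 14.007, CA = 12.011, O = 15.999)

# idealized backbone geometry: strands paired antiparallel 4.8 A apart,
# N/O offset 1.0 A toward the partner strand so cross-strand N...O
# distances are 2.8 A (native hydrogen bonds); helix appended away from
# the sheet
build_toy_topology <- function(n_residues = 28) {
  stopifnot(n_residues >= 16)
  coords <- list(); topo <- list()
  add_res <- function(res, ca, n_off, o_off, chain = "A") {
    topo[[length(topo) + 1]] <<- data.frame(
      atom = c("N", "CA", "O"), residue = res, chain = chain,
      mass = unname(ATOM_MASSES[c("N", "CA", "O")]))
    coords[[length(coords) + 1]] <<- rbind(ca + n_off, ca, ca + o_off)
  }
  # strand 1 (res 1-8) at y = 0, strand 2 (res 9-16) antiparallel at y = 4.8
  for (i in 1:8)
    add_res(i, c(3.8 * i, 0, 0), c(0.3, 1.0, 0), c(-0.3, 1.0, 0))
  for (i in 9:16)
    add_res(i, c(3.8 * (17 - i), 4.8, 0), c(0.3, -1.0, 0), c(-0.3, -1.0, 0))
  # remaining residues: helix displaced in +z, no sheet contacts
  n_hel <- n_residues - 16
  for (k in seq_len(n_hel)) {
    ang <- 100 * pi / 180 * k
    ca <- c(30 + 2.3 * cos(ang), 2.4 + 2.3 * sin(ang), 12 + 1.5 * k)
    add_res(16 + k, ca, c(0, 0, 1.0), c(0, 0, -1.0))
  }
  list(topology = do.call(rbind, topo),
       reference = do.call(rbind, coords))
}

#' Specification of a synthetic toy trajectory
#'
#' @param n_residues chain length (>= 16; default 28).
#' @param fluct_amplitudes per-residue isotropic Gaussian displacement
#'   sd (Angstrom); scalar recycled.
#' @param unfold_schedule optional numeric vector of length `n_frames`
#'   giving the target retained fraction of native contacts per frame;
#'   must be monotone non-increasing.
#' @param break_region optional residue subset from which contact
#'   breaking may recruit residues (default: any residue).
#' @param n_frames number of frames.
#' @param tag optional list(`near_residues`, `offset`) adding a pseudo
#'   tag chain ("T") with one atom per entry, placed `offset` Angstrom
#'   (+z, default 5) from the CA of each named substrate residue and
#'   tracking it through the trajectory.
#' @param reference optional user topology: list(topology, reference)
#'   as from an external structure; replaces the idealized fold.
#' @param seed RNG seed; frame noise is drawn residue-major so the
#'   output is bit-reproducible.
#' @return A `toy_trajectory_spec`.
#' @export
toy_trajectory_spec <- function(n_residues = 28, fluct_amplitudes = 0,
                                unfold_schedule = NULL, break_region = NULL,
                                n_frames = 50, tag = NULL,
                                reference = NULL, seed = 1L) {
  if (any(fluct_amplitudes < 0)) spec_error("fluct_amplitudes must be >= 0")
  if (!is.null(unfold_schedule)) {
    if (length(unfold_schedule) != n_frames)
      spec_error("unfold_schedule must have one entry per frame")
    if (any(diff(unfold_schedule) > 1e-12))
      spec_error("unfold_schedule must be monotone non-increasing")
  }
  structure(list(n_residues = n_residues,
                 fluct_amplitudes = rep_len(fluct_amplitudes, n_residues),
                 unfold_schedule = unfold_schedule,
                 break_region = break_region,
                 n_frames = n_frames, tag = tag, reference = reference,
                 seed = as.integer(seed)),
            class = "toy_trajectory_spec")
}

new_trajectory <- function(topology, reference, frames, truth = NULL) {
  structure(list(topology = topology, reference = reference,
                 frames = frames, truth = truth),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms (%d residues), %d frames\n",
              nrow(x$topology), length(unique(x$topology$residue)),
              length(x$frames)))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Generate a toy trajectory
#'
#' Frames are the reference coordinates plus per-residue isotropic
#' Gaussian displacements (the whole residue moves rigidly, so the CA
#' fluctuation limit is sigma * sqrt(3)). If an unfold schedule is
#' given, residues are displaced out of the native environment
#' (detached along +z) one by one until the retained fraction of
#' native contacts reaches the scheduled value; because residues are
#' broken at residue granularity, the achieved fraction per frame is
#' stored in `truth$alpha_true`. An optional tag chain tracks chosen
#' substrate residues.
#'
#' @param spec a [toy_trajectory_spec()].
#' @param cutoff_a,min_separation contact definition used when
#'   realizing an unfold schedule (see [define_native_contacts()]).
#' @return A `trajectory`; `truth` carries the spec and, under a
#'   schedule, the realized per-frame contact fraction.
#' @export
gen_toy_trajectory <- function(spec, cutoff_a = 7.0, min_separation = 4) {
  stopifnot(inherits(spec, "toy_trajectory_spec"))
  base <- if (is.null(spec$reference)) build_toy_topology(spec$n_residues)
          else spec$reference
  topo <- base$topology; ref <- base$reference
  residues <- sort(unique(topo$residue))
  # optional tag chain: one pseudo-atom per tracked substrate residue
  if (!is.null(spec$tag)) {
    off <- if (is.null(spec$tag$offset)) 5 else spec$tag$offset
    for (r in spec$tag$near_residues) {
      ca <- ref[topo$residue == r & topo$atom == "CA", , drop = FALSE][1, ]
      topo <- rbind(topo, data.frame(atom = "CA", residue = r,
                                     chain = "T", mass = ATOM_MASSES[["CA"]]))
      ref <- rbind(ref, ca + c(0, 0, off))
    }
  }
  # realize the unfold schedule: detach residues until the retained
  # contact fraction drops to the target
  sched_coords <- NULL
  alpha_true <- rep(1, spec$n_frames)
  if (!is.null(spec$unfold_schedule)) {
    contacts <- define_native_contacts(
      new_trajectory(topo[topo$chain != "T", ], ref[topo$chain != "T", ], list()),
      cutoff_a, min_separation)
    pool <- unique(c(contacts$i, contacts$j))
    if (!is.null(spec$break_region)) pool <- intersect(pool, spec$break_region)
    if (length(pool) == 0)
      stop("unfold schedule cannot be realized: no native contacts ",
           "involve the requested residues")
    set.seed(spec$seed)
    pool <- sample(pool)
    # retained fraction after detaching the first k residues of the pool
    frac_after <- function(coords) {
      d <- contact_pair_distances(coords, topo, contacts)
      mean(d <= cutoff_a)
    }
    detach <- function(coords, res, rank) {
      idx <- topo$residue == res & topo$chain != "T"
      coords[idx, 3] <- coords[idx, 3] + 40 + 25 * rank
      coords
    }
    staged <- list(ref)
    fracs <- frac_after(ref)
    cur <- ref
    for (k in seq_along(pool)) {
      cur <- detach(cur, pool[k], k)
      staged[[k + 1]] <- cur
      fracs[k + 1] <- frac_after(cur)
    }
    sched_coords <- lapply(seq_len(spec$n_frames), function(f) {
      k <- which(fracs <= spec$unfold_schedule[f] + 1e-12)[1]
      if (is.na(k)) k <- length(fracs)
      alpha_true[f] <<- fracs[k]
      staged[[k]]
    })
  }
  set.seed(spec$seed + 1L)
  frames <- lapply(seq_len(spec$n_frames), function(f) {
    coords <- if (is.null(sched_coords)) ref else sched_coords[[f]]
    for (ri in seq_along(residues)) {
      sdv <- spec$fluct_amplitudes[ri]
      if (sdv > 0) {
        disp <- rnorm(3, 0, sdv)
        idx <- topo$residue == residues[ri] & topo$chain != "T"
        coords[idx, ] <- sweep(coords[idx, , drop = FALSE], 2, disp, "+")
      }
    }
    # tag atoms track their target residue's displacement
    tidx <- which(topo$chain == "T")
    for (ti in tidx) {
      r <- topo$residue[ti]
      sel <- topo$residue == r & topo$atom == "CA" & topo$chain != "T"
      ca_ref <- ref[sel, , drop = FALSE][1, ]
      ca_now <- coords[sel, , drop = FALSE][1, ]
      coords[ti, ] <- ref[ti, ] + (ca_now - ca_ref)
    }
    coords
  })
  truth <- list(spec = spec, alpha_true = alpha_true)
  new_trajectory(topo, ref, frames, truth)
}
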