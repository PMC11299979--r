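#' Trajectory plasticity metrics
#'
#' @description
#' Structural plasticity of a protein along a trajectory is quantified
#' by: the fraction of native contacts retained per frame (alpha), the
#' fraction of native beta-sheet backbone hydrogen bonds per strand
#' pair (eta), per-residue RMSF and per-frame RMSD after least-squares
#' superposition, mass-weighted radii of gyration with (Rog) and
#' without (Rgyr) long loops, Boltzmann-inverted 2D free-energy
#' landscapes over (RMSD, Rgyr), principal component analysis of the
#' CA covariance, and contact-disruption / tag-occupancy maps for
#' tag-substrate conjugates.
#'
#' @name traj_plasticity
NULL

atom_indices <- function(topology, residue) which(topology$residue == residue)

# minimum inter-atom distance between two residue atom sets
min_pair_dist <- function(coords, idx_i, idx_j) {
  a <- coords[idx_i, , drop = FALSE]
  b <- coords[idx_j, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

# vector of minimum distances for every pair in a contact set; the
# atom lookup is keyed on chain:residue so tag chains that reuse
# substrate numbering cannot collide
contact_pair_distances <- function(coords, topology, contacts) {
  lut <- attr(contacts, "atom_idx")
  ki <- paste(contacts$chain_i, contacts$i)
  kj <- paste(contacts$chain_j, contacts$j)
  vapply(seq_len(nrow(contacts)), function(k) {
    min_pair_dist(coords, lut[[ki[k]]], lut[[kj[k]]])
  }, 0)
}

#' Define native contacts from a reference structure
#'
#' Residue pairs whose minimum heavy-atom distance in the reference
#' frame is within the cutoff, excluding pairs closer than
#' `min_separation` in sequence (within a chain). Pairs spanning two
#' chains are classed `"tag-substrate"`, intra-chain pairs
#' `"native-intra"`.
#'
#' @param traj a `trajectory` (only topology and reference are used).
#' @param cutoff_a distance cutoff (Angstrom), default 7.
#' @param min_separation minimum sequence separation for intra-chain
#'   pairs, default 4.
#' @return A `contact_set`: data frame (i, j, chain_i, chain_j, class,
#'   ref_dist) with the per-residue atom index lookup and the cutoff
#'   stored as attributes.
#' @export
define_native_contacts <- function(traj, cutoff_a = 7.0, min_separation = 4) {
  topo <- traj$topology; ref <- traj$reference
  if (nrow(topo) == 0) stop("no atoms in topology")
  res_tab <- unique(topo[, c("residue", "chain")])
  res_tab <- res_tab[order(res_tab$chain, res_tab$residue), ]
  key <- paste(res_tab$chain, res_tab$residue)
  idx <- lapply(seq_len(nrow(res_tab)), function(k)
    which(topo$residue == res_tab$residue[k] & topo$chain == res_tab$chain[k]))
  n <- nrow(res_tab)
  rows <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      same <- res_tab$chain[a] == res_tab$chain[b]
      if (same && abs(res_tab$residue[a] - res_tab$residue[b]) < min_separation)
        next
      d <- min_pair_dist(ref, idx[[a]], idx[[b]])
      if (d <= cutoff_a)
        rows[[length(rows) + 1]] <- data.frame(
          i = res_tab$residue[a], j = res_tab$residue[b],
          chain_i = res_tab$chain[a], chain_j = res_tab$chain[b],
          class = if (same) "native-intra" else "tag-substrate",
          ref_dist = d)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(), chain_i = character(),
               chain_j = character(), class = character(),
               ref_dist = numeric())
  lut <- list()
  for (k in seq_len(nrow(res_tab))) lut[[key[k]]] <- idx[[k]]
  structure(out, atom_idx = lut, cutoff = cutoff_a,
            min_separation = min_separation,
            class = c("contact_set", "data.frame"))
}

#' Fraction of native contacts per frame (alpha)
#'
#' For every frame, the fraction of native residue pairs whose minimum
#' heavy-atom distance is still within the cutoff used to define them.
#'
#' @param traj a `trajectory` (same topology as the contact set).
#' @param contacts a `contact_set` from [define_native_contacts()].
#' @return Numeric vector, one alpha in \[0, 1\] per frame.
#' @export
contact_fraction <- function(traj, contacts) {
  check_contacts_topology(traj, contacts)
  cutoff <- attr(contacts, "cutoff")
  vapply(traj$frames, function(coords) {
    mean(contact_pair_distances(coords, traj$topology, contacts) <= cutoff)
  }, 0)
}

check_contacts_topology <- function(traj, contacts) {
  lut <- attr(contacts, "atom_idx")
  maxidx <- max(unlist(lut))
  if (maxidx > nrow(traj$topology))
    stop("contact set refers to atoms absent from this topology")
  invisible(TRUE)
}

#' Average a per-frame metric across replica trajectories
#'
#' @param values_list list of equal-length numeric vectors (one per
#'   replica).
#' @return Data frame (frame, mean, sem).
#' @export
replica_average <- function(values_list) {
  stopifnot(length(values_list) >= 1)
  m <- do.call(cbind, values_list)
  data.frame(frame = seq_len(nrow(m)),
             mean = rowMeans(m),
             sem = apply(m, 1, sd) / sqrt(ncol(m)))
}

#' Fraction of native beta-sheet backbone hydrogen bonds (eta)
#'
#' Native donor-acceptor pairs are backbone N...O pairs across each
#' strand pair within the cutoff in the reference; eta per frame is the
#' fraction still within the cutoff. No angle term is applied.
#'
#' @param traj a `trajectory` with backbone N and O atoms.
#' @param strand_pairs named list, each element
#'   `list(a = <residues>, b = <residues>)`.
#' @param cutoff_a N...O distance cutoff (Angstrom), default 3.5.
#' @return Matrix frames x strand pairs; native pair counts in
#'   attribute `"n_native"`.
#' @export
hbond_fraction <- function(traj, strand_pairs, cutoff_a = 3.5) {
  topo <- traj$topology
  if (!all(c("N", "O") %in% topo$atom))
    stop("topology lacks backbone N/O atoms")
  pair_atoms <- lapply(strand_pairs, function(sp) {
    ni_a <- which(topo$atom == "N" & topo$residue %in% sp$a & topo$chain != "T")
    o_a  <- which(topo$atom == "O" & topo$residue %in% sp$a & topo$chain != "T")
    ni_b <- which(topo$atom == "N" & topo$residue %in% sp$b & topo$chain != "T")
    o_b  <- which(topo$atom == "O" & topo$residue %in% sp$b & topo$chain != "T")
    cand <- rbind(expand.grid(d = ni_a, a = o_b), expand.grid(d = ni_b, a = o_a))
    dd <- sqrt(rowSums((traj$reference[cand$d, , drop = FALSE] -
                        traj$reference[cand$a, , drop = FALSE])^2))
    cand[dd <= cutoff_a, , drop = FALSE]
  })
  n_native <- vapply(pair_atoms, nrow, 0L)
  if (all(n_native == 0))
    stop("no native backbone hydrogen bonds found for the given strand pairs")
  eta <- t(vapply(traj$frames, function(coords) {
    vapply(seq_along(pair_atoms), function(p) {
      pa <- pair_atoms[[p]]
      if (nrow(pa) == 0) return(NA_real_)
      dd <- sqrt(rowSums((coords[pa$d, , drop = FALSE] -
                          coords[pa$a, , drop = FALSE])^2))
      mean(dd <= cutoff_a)
    }, 0)
  }, numeric(length(pair_atoms))))
  if (length(pair_atoms) == 1) eta <- matrix(eta, ncol = 1)
  colnames(eta) <- names(strand_pairs)
  attr(eta, "n_native") <- n_native
  eta
}

# Kabsch least-squares superposition: rotation + translation mapping
# moving onto target (both n x 3)
kabsch_fit <- function(moving, target) {
  cm <- colMeans(moving); ct <- colMeans(target)
  p <- sweep(moving, 2, cm); q <- sweep(target, 2, ct)
  s <- svd(crossprod(p, q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = rot, center_moving = cm, center_target = ct)
}

apply_fit <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$center_moving) %*% t(fit$rotation),
        2, fit$center_target, "+")
}

#' RMSF and RMSD after least-squares superposition
#'
#' Each frame is superposed onto the reference by the Kabsch algorithm
#' over the fit selection (CA atoms by default). RMSD per frame is
#' computed against the reference over the report selection; RMSF per
#' residue is the fluctuation of its CA about the mean superposed
#' structure.
#'
#' @param traj a `trajectory` with >= 2 frames.
#' @param selection atom indices to report RMSD over (default: CA of
#'   non-tag chains).
#' @param fit_selection atom indices for the superposition (default:
#'   same CA set; >= 3 atoms).
#' @return List with `rmsd` (per frame, Angstrom), `rmsf` (per residue)
#'   and `fitted` (list of superposed full coordinate sets).
#' @export
rmsf_rmsd <- function(traj, selection = NULL, fit_selection = NULL) {
  stopifnot(n_frames(traj) >= 2)
  topo <- traj$topology
  ca <- which(topo$atom == "CA" & topo$chain != "T")
  if (is.null(selection)) selection <- ca
  if (is.null(fit_selection)) fit_selection <- ca
  if (length(fit_selection) < 3) stop("need >= 3 atoms to superpose")
  fitted <- lapply(traj$frames, function(coords) {
    fit <- kabsch_fit(coords[fit_selection, , drop = FALSE],
                      traj$reference[fit_selection, , drop = FALSE])
    apply_fit(coords, fit)
  })
  rmsd <- vapply(fitted, function(coords) {
    sqrt(mean(rowSums((coords[selection, , drop = FALSE] -
                       traj$reference[selection, , drop = FALSE])^2)))
  }, 0)
  ca_stack <- vapply(fitted, function(coords) coords[ca, , drop = FALSE],
                     matrix(0, length(ca), 3))
  mean_ca <- apply(ca_stack, c(1, 2), mean)
  rmsf <- sqrt(rowMeans(vapply(seq_len(dim(ca_stack)[3]), function(f)
    rowSums((ca_stack[, , f] - mean_ca)^2), numeric(length(ca)))))
  names(rmsf) <- topo$residue[ca]
  list(rmsd = rmsd, rmsf = rmsf, fitted = fitted)
}

#' Radii of gyration per frame
#'
#' Mass-weighted radius of gyration sqrt(sum m_i |r_i - r_bar|^2 /
#' sum m_i). `rog` uses every (non-tag) atom; `rgyr` excludes the
#' residues in `loop_mask`, mirroring the convention of reporting a
#' loop-free radius alongside the whole-protein one.
#'
#' @param traj a `trajectory`.
#' @param loop_mask residues to exclude from `rgyr` (default none, so
#'   rgyr = rog).
#' @return Data frame (frame, rgyr, rog).
#' @export
gyration <- function(traj, loop_mask = integer()) {
  topo <- traj$topology
  all_idx <- which(topo$chain != "T")
  core_idx <- which(topo$chain != "T" & !(topo$residue %in% loop_mask))
  if (length(core_idx) == 0) stop("loop mask excludes every atom")
  rg <- function(coords, idx) {
    m <- topo$mass[idx]
    x <- coords[idx, , drop = FALSE]
    cen <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(x, 2, cen)^2)) / sum(m))
  }
  data.frame(frame = seq_len(n_frames(traj)),
             rgyr = vapply(traj$frames, rg, 0, idx = core_idx),
             rog = vapply(traj$frames, rg, 0, idx = all_idx))
}

#' Boltzmann-inverted 2D free-energy landscape
#'
#' Bins the two structural coordinates into a 2D histogram and converts
#' populations to free energies: dG_i = -k_B T ln(N_i / N_0), with N_0
#' the most populated bin (so min dG = 0). Empty bins are NA (masked),
#' not zero.
#'
#' @param x,y equal-length coordinate series (e.g. RMSD and Rgyr).
#' @param temperature_k temperature (K), default 300.
#' @param bins number of bins per axis (default 50) or a list of two
#'   breakpoint vectors.
#' @return A `fel_grid`: list with `x_breaks`, `y_breaks`, `counts`,
#'   `dg` (kcal/mol) and `temperature_k`.
#' @export
fel_2d <- function(x, y, temperature_k = 300, bins = 50) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0) stop("empty coordinate series")
  mk_breaks <- function(v, nb) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = nb + 1)
  }
  if (is.list(bins)) {
    xb <- bins[[1]]; yb <- bins[[2]]
  } else {
    xb <- mk_breaks(x, bins); yb <- mk_breaks(y, bins)
  }
  xi <- findInterval(x, xb, rightmost.closed = TRUE, all.inside = TRUE)
  yi <- findInterval(y, yb, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, length(xb) - 1, length(yb) - 1)
  for (k in seq_along(xi)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1L
  n0 <- max(counts)
  dg <- matrix(NA_real_, nrow(counts), ncol(counts))
  nz <- counts > 0
  dg[nz] <- -GAS_CONSTANT_KCAL * temperature_k * log(counts[nz] / n0)
  structure(list(x_breaks = xb, y_breaks = yb, counts = counts, dg = dg,
                 temperature_k = temperature_k),
            class = "fel_grid")
}

#' Principal component analysis of CA fluctuations
#'
#' Frames are superposed onto the reference (Kabsch over CA), the
#' 3N-dimensional CA coordinate covariance is eigen-decomposed, and
#' per-frame projections onto the components are returned. Variances
#' are non-increasing and sum to the total positional variance of the
#' fitted coordinates.
#'
#' @param traj a `trajectory`.
#' @param selection atom indices (default: CA of non-tag chains).
#' @return List with `components` (3N x k), `variances`, `projections`
#'   (frames x k) and `mean` (the mean fitted coordinates).
#' @export
traj_pca <- function(traj, selection = NULL) {
  topo <- traj$topology
  if (is.null(selection)) selection <- which(topo$atom == "CA" & topo$chain != "T")
  fitted <- rmsf_rmsd(traj, selection, selection)$fitted
  mat <- t(vapply(fitted, function(coords)
    as.numeric(t(coords[selection, , drop = FALSE])),
    numeric(3 * length(selection))))
  if (nrow(mat) < ncol(mat))
    warning("fewer frames than coordinate dimensions; covariance is rank-",
            "deficient and trailing components are truncated", call. = FALSE)
  mu <- colMeans(mat)
  cen <- sweep(mat, 2, mu)
  cv <- crossprod(cen) / (nrow(mat) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  k <- min(nrow(mat) - 1, ncol(mat))
  vals <- pmax(eig$values[seq_len(k)], 0)
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  list(components = vecs, variances = vals,
       projections = cen %*% vecs, mean = mu)
}

#' Interpolated structures along the first principal component
#'
#' Returns coordinate sets stepping between the extreme projections
#' observed along PC1, i.e. between the most dissimilar structures in
#' the distribution.
#'
#' @param pca result of [traj_pca()].
#' @param n number of interpolation steps.
#' @return List of n coordinate matrices (atoms x 3).
#' @export
pc1_interpolation <- function(pca, n = 10) {
  pr <- range(pca$projections[, 1])
  lapply(seq(pr[1], pr[2], length.out = n), function(t) {
    v <- pca$mean + t * pca$components[, 1]
    matrix(v, ncol = 3, byrow = TRUE)
  })
}

#' Contact-disruption and tag-occupancy maps
#'
#' Compares the long-range intra-substrate native contacts of a free
#' substrate trajectory with those of a tag-conjugated one: per
#' substrate residue, (a) the mean number of retained long-range native
#' contacts in each run and their difference normalized to \[0, 1\]
#' (the disruption map), and (b) the fraction of conjugate frames in
#' which any tag-chain atom lies within the cutoff of the residue (the
#' tag-occupancy map).
#'
#' @param traj_conjugate trajectory containing substrate plus tag chain
#'   `"T"`.
#' @param traj_free trajectory of the free substrate (same residue
#'   numbering).
#' @param contacts optional intra-substrate `contact_set`; defaults to
#'   contacts of the free reference.
#' @param cutoff_a contact cutoff (Angstrom), default 7.
#' @param min_separation minimum sequence separation defining
#'   "long-range", default 4.
#' @return Data frame (residue, contacts_free, contacts_conj,
#'   disruption, tag_occupancy).
#' @export
contact_disruption <- function(traj_conjugate, traj_free, contacts = NULL,
                               cutoff_a = 7.0, min_separation = 4) {
  sub_res <- sort(unique(traj_free$topology$residue))
  conj_res <- sort(unique(
    traj_conjugate$topology$residue[traj_conjugate$topology$chain != "T"]))
  if (!all(sub_res == conj_res))
    stop("substrate residue numbering differs between the two trajectories")
  if (is.null(contacts))
    contacts <- define_native_contacts(traj_free, cutoff_a, min_separation)
  per_res_counts <- function(traj, cset) {
    cutoff <- attr(cset, "cutoff")
    acc <- setNames(numeric(length(sub_res)), sub_res)
    for (coords in traj$frames) {
      d <- contact_pair_distances(coords, traj$topology, cset)
      ok <- d <= cutoff
      for (k in which(ok)) {
        acc[as.character(cset$i[k])] <- acc[as.character(cset$i[k])] + 1
        acc[as.character(cset$j[k])] <- acc[as.character(cset$j[k])] + 1
      }
    }
    acc / n_frames(traj)
  }
  # the conjugate shares substrate numbering, so the free-reference
  # contact set is re-keyed onto the conjugate topology
  contacts_conj <- rekey_contacts(contacts, traj_conjugate$topology)
  free_counts <- per_res_counts(traj_free, contacts)
  conj_counts <- per_res_counts(traj_conjugate, contacts_conj)
  raw <- free_counts - conj_counts
  disruption <- pmax(raw, 0)
  if (max(disruption) > 0) disruption <- disruption / max(disruption)
  tag_idx <- which(traj_conjugate$topology$chain == "T")
  occupancy <- setNames(numeric(length(sub_res)), sub_res)
  if (length(tag_idx) > 0) {
    topo <- traj_conjugate$topology
    for (coords in traj_conjugate$frames) {
      for (r in sub_res) {
        ridx <- which(topo$residue == r & topo$chain != "T")
        if (min_pair_dist(coords, ridx, tag_idx) <= cutoff_a)
          occupancy[as.character(r)] <- occupancy[as.character(r)] + 1
      }
    }
    occupancy <- occupancy / n_frames(traj_conjugate)
  }
  data.frame(residue = sub_res,
             contacts_free = unname(free_counts),
             contacts_conj = unname(conj_counts),
             disruption = unname(disruption),
             tag_occupancy = unname(occupancy))
}

# rebuild the atom-index lookup of a contact set against a different
# topology (same substrate residues, possibly extra tag atoms)
rekey_contacts <- function(contacts, topology) {
  lut <- list()
  for (k in seq_len(nrow(contacts))) {
    for (side in c("i", "j")) {
      ch <- contacts[[paste0("chain_", side)]][k]
      r <- contacts[[side]][k]
      lut[[paste(ch, r)]] <- which(topology$residue == r &
                                     topology$chain == ch)
    }
  }
  structure(contacts, atom_idx = lut)
}
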