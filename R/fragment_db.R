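## Per-segment backbone-conformation databases: geometric graft-and-close
## of homolog fragments into the template context, the closure-rmsd
## acceptance gate, sequence-independent rmsd clustering, and persistence.

.DB_VERSION <- "fragstitch-db-1"

## --- internal NeRF chain builders -----------------------------------------

## Forward build of n residues from a preceding context frame.
## ctx: 3x3 (N,CA,C) of the previous residue; psi_prev/omega_prev its torsions.
## phi/psi/omega: fragment torsions (phi[1] used, psi/omega[n] unused).
.forward_chain <- function(ctx, psi_prev, omega_prev, phi, psi, omega, n) {
  g <- ideal_geometry()
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ]  <- nerf_place(ctx[1, ], ctx[2, ], ctx[3, ], g$b_c_n, g$a_ca_c_n, psi_prev)
  CA[1, ] <- nerf_place(ctx[2, ], ctx[3, ], N[1, ], g$b_n_ca, g$a_c_n_ca, omega_prev)
  C[1, ]  <- nerf_place(ctx[3, ], N[1, ], CA[1, ], g$b_ca_c, g$a_n_ca_c, phi[1])
  if (n > 1) for (i in 2:n) {
    N[i, ]  <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], g$b_n_ca, g$a_c_n_ca, omega[i - 1])
    C[i, ]  <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  list(N = N, CA = CA, C = C)
}

## Backward build: residue n is fixed at end_frame (N,CA,C); residues
## n-1 .. stop_at are placed by reversed-chain NeRF with the same ideal
## internal coordinates (a dihedral is invariant under atom-order reversal).
.backward_chain <- function(end_frame, phi, psi, omega, n, stop_at = 1) {
  g <- ideal_geometry()
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[n, ] <- end_frame[1, ]; CA[n, ] <- end_frame[2, ]; C[n, ] <- end_frame[3, ]
  if (n > stop_at) for (i in n:(stop_at + 1)) {
    C[i - 1, ]  <- nerf_place(C[i, ], CA[i, ], N[i, ], g$b_c_n, g$a_c_n_ca, phi[i])
    CA[i - 1, ] <- nerf_place(CA[i, ], N[i, ], C[i - 1, ], g$b_ca_c, g$a_ca_c_n, omega[i - 1])
    N[i - 1, ]  <- nerf_place(N[i, ], C[i - 1, ], CA[i - 1, ], g$b_n_ca, g$a_n_ca_c, psi[i - 1])
  }
  list(N = N, CA = CA, C = C)
}

## --- CCD closure -----------------------------------------------------------

## Optimal rotation angle (radians) about an axis that brings moving atoms
## closest to targets, by the closed-form cyclic-coordinate-descent solution.
.ccd_angle <- function(moving, target, axis_point, axis_dir) {
  u <- axis_dir / sqrt(sum(axis_dir^2))
  a <- b <- 0
  for (j in seq_len(nrow(moving))) {
    v <- moving[j, ] - axis_point
    oj <- axis_point + sum(v * u) * u
    r <- moving[j, ] - oj
    s <- sqrt(sum(r^2))
    if (s < 1e-9) next
    rh <- r / s
    sh <- .cross3(u, rh)
    f <- target[j, ] - oj
    a <- a + s * sum(f * rh)
    b <- b + s * sum(f * sh)
  }
  atan2(b, a)
}

## Coarse closure stage: CCD sweeps over the phi/psi torsions of residues
## 1..mid bring a forward-built chain (plus a virtual residue mid+1) near a
## fixed target frame. Greedy and robust from many Angstroms away, but it
## does not stay close to the starting torsions; the fine stage below does.
.ccd_close <- function(fwd, target, mid, tol = 0.05, max_sweeps = 200,
                       max_step_deg = 10, adjust = seq_len(mid)) {
  cap <- .deg2rad(max_step_deg)
  adjust <- intersect(adjust, seq_len(mid))
  mismatch <- function() {
    mv <- rbind(fwd$N[mid + 1, ], fwd$CA[mid + 1, ], fwd$C[mid + 1, ])
    sqrt(mean(rowSums((mv - target)^2)))
  }
  rot_downstream <- function(axis_point, axis_dir, theta, from_res, incl_C_of) {
    rows <- (from_res):(mid + 1)
    for (nm in c("N", "CA", "C"))
      fwd[[nm]][rows, ] <<- .rotate_about_axis(fwd[[nm]][rows, , drop = FALSE],
                                               axis_point, axis_dir, theta)
    if (!is.na(incl_C_of))
      fwd$C[incl_C_of, ] <<- c(.rotate_about_axis(rbind(fwd$C[incl_C_of, ]),
                                                  axis_point, axis_dir, theta))
  }
  rms <- mismatch()
  if (rms <= tol) return(list(fwd = fwd, rms = rms, sweeps = 0L))
  for (sw in seq_len(max_sweeps)) {
    for (r in adjust) {
      mv <- rbind(fwd$N[mid + 1, ], fwd$CA[mid + 1, ], fwd$C[mid + 1, ])
      th <- .ccd_angle(mv, target, fwd$N[r, ], fwd$CA[r, ] - fwd$N[r, ])
      th <- max(min(th, cap), -cap)
      if (abs(th) > 1e-12)
        rot_downstream(fwd$N[r, ], fwd$CA[r, ] - fwd$N[r, ], th, r + 1, r)
      mv <- rbind(fwd$N[mid + 1, ], fwd$CA[mid + 1, ], fwd$C[mid + 1, ])
      th <- .ccd_angle(mv, target, fwd$CA[r, ], fwd$C[r, ] - fwd$CA[r, ])
      th <- max(min(th, cap), -cap)
      if (abs(th) > 1e-12)
        rot_downstream(fwd$CA[r, ], fwd$C[r, ] - fwd$CA[r, ], th, r + 1, NA)
    }
    rms <- mismatch()
    if (rms <= tol) return(list(fwd = fwd, rms = rms, sweeps = sw))
  }
  list(fwd = fwd, rms = rms, sweeps = max_sweeps)
}

## Fine closure stage: damped least-squares (Levenberg-Marquardt) updates of
## the adjustable phi/psi torsions. Each iteration solves for the
## minimum-norm torsion change that moves the cut atoms onto the target, so
## small end-frame mismatches are absorbed by small, evenly distributed
## per-torsion adjustments and the closed fragment stays maximally close to
## its source conformation.
## `tor` holds phi[1..mid+1], psi[1..mid], omega[1..mid] for the moving part;
## `build` rebuilds its coordinates (residues 1..mid+1) from those torsions.
.dls_close <- function(build, tor, adjust, mid, target, tol = 0.05,
                       max_iter = 200) {
  dof <- rbind(cbind(res = adjust, ang = 1), cbind(res = adjust, ang = 2))
  dof <- dof[order(dof[, 1], dof[, 2]), , drop = FALSE]
  fwd <- build(tor)
  mv <- function(f) rbind(f$N[mid + 1, ], f$CA[mid + 1, ], f$C[mid + 1, ])
  resid <- function(f) as.vector(t(target - mv(f)))
  rms_of <- function(r) sqrt(mean(rowSums(matrix(r, 3, 3, byrow = TRUE)^2)))
  r <- resid(fwd)
  rms <- rms_of(r)
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    if (rms <= tol) break
    J <- matrix(0, 9, nrow(dof))
    atoms <- mv(fwd)
    for (k in seq_len(nrow(dof))) {
      rr <- dof[k, 1]
      if (dof[k, 2] == 1) { p <- fwd$N[rr, ]; u <- fwd$CA[rr, ] - p }
      else { p <- fwd$CA[rr, ]; u <- fwd$C[rr, ] - p }
      u <- u / sqrt(sum(u^2))
      # +d(torsion) is a right-hand rotation about the bond axis
      for (j in 1:3)
        J[(3 * j - 2):(3 * j), k] <- .cross3(u, atoms[j, ] - p)
    }
    improved <- FALSE
    for (try in 1:8) {
      A <- J %*% t(J) + lambda * diag(9)
      dth <- try(as.vector(t(J) %*% solve(A, r)), silent = TRUE)
      if (inherits(dth, "try-error")) { lambda <- lambda * 10; next }
      step <- .rad2deg(dth)
      smax <- max(abs(step))
      if (smax > 30) step <- step * (30 / smax)
      cand <- tor
      for (k in seq_len(nrow(dof))) {
        rr <- dof[k, 1]
        if (dof[k, 2] == 1) cand$phi[rr] <- .wrap_angle(cand$phi[rr] + step[k])
        else cand$psi[rr] <- .wrap_angle(cand$psi[rr] + step[k])
      }
      f2 <- build(cand)
      r2 <- resid(f2)
      rms2 <- rms_of(r2)
      if (rms2 < rms) {
        tor <- cand; fwd <- f2; r <- r2; rms <- rms2
        lambda <- max(lambda / 4, 1e-9)
        improved <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) break
  }
  list(tor = tor, fwd = fwd, rms = rms, iters = it)
}

## --- graft and close -------------------------------------------------------

## Idealized N,CA,C,O coordinates of a fragment conformation, stacked
## (4 rows per residue), for rmsd comparisons.
.fragment_ideal_coords <- function(frag) {
  tor <- frag$torsions
  m <- nrow(tor)
  mod <- rebuild_backbone(tor, strsplit(frag$seq, "")[[1]],
                          source_id = frag$source_id)
  .stack_bb(mod$atoms, seq_len(m))
}

.stack_bb <- function(atoms, idx) {
  out <- matrix(NA_real_, 4 * length(idx), 3)
  for (k in seq_along(idx)) {
    i <- idx[k]
    out[4 * k - 3, ] <- atoms$N[i, ]
    out[4 * k - 2, ] <- atoms$CA[i, ]
    out[4 * k - 1, ] <- atoms$C[i, ]
    out[4 * k, ]     <- atoms$O[i, ]
  }
  out
}

#' Graft a fragment into the template and close the chain
#'
#' Replaces a template segment's torsions with a homolog fragment's, then
#' geometrically closes the chain: the fragment is rebuilt forward from the
#' upstream anchor frame and backward from the downstream anchor frame with
#' a cut at its middle residue, and deterministic cyclic-coordinate-descent
#' sweeps over the fragment's phi/psi angles close the cut (omega held
#' planar). Terminal-tail segments are bounded by a single anchor and need
#' no closure. The closure rmsd is the backbone (N, CA, C, O) RMSD between
#' the closed fragment and its source conformation after optimal
#' superposition; it is the quantity gated (strictly below `gate`) before a
#' fragment enters the database.
#'
#' @param template An idealized `backbone_model` (see [idealize_model()]).
#' @param fragment A `fragment` for one of the scheme's segments.
#' @param scheme The `segmentation_scheme` (indices on the template).
#' @param gate Acceptance threshold in Angstrom (default 0.2, strict `<`).
#' @param tol Closure tolerance on the cut atoms in Angstrom.
#' @param max_sweeps CCD sweep budget.
#' @param fail_tol Cut mismatch above which closure is declared failed and
#'   the record rejected outright.
#' @return A `fragment_record`: list with `fragment` (torsions updated to the
#'   closed conformation), `model` (the full grafted `backbone_model`),
#'   `closure_rmsd`, `cut_rms`, `accepted`.
#' @export
graft_and_close <- function(template, fragment, scheme, gate = 0.2,
                            tol = 0.05, max_sweeps = 200, fail_tol = 0.5) {
  seg <- .get_segment(scheme, fragment$segment_name)
  .graft_close_at(template, fragment, seg$start, seg$end, seg$type,
                  gate = gate, tol = tol, max_sweeps = max_sweeps,
                  fail_tol = fail_tol)
}

.graft_close_at <- function(model, fragment, sa, ea, type, gate = 0.2,
                            tol = 0.05, max_sweeps = 200, fail_tol = 0.5,
                            cut = NULL, adjust = NULL, max_step_deg = 10) {
  Tm <- extract_torsions(model)
  L <- n_residues(model)
  m <- fragment$n_res
  ft <- fragment$torsions
  fseq <- strsplit(fragment$seq, "")[[1]]
  cut_rms <- 0
  closed_tor <- ft

  if (type == "internal") {
    if (m < 2) stop("internal fragment must span both anchors")
    target <- rbind(model$atoms$N[ea, ], model$atoms$CA[ea, ], model$atoms$C[ea, ])
    mid <- if (is.null(cut)) max(1L, min(m - 1L, m %/% 2L)) else
      max(1L, min(m - 1L, as.integer(cut)))
    if (is.null(adjust)) adjust <- seq_len(mid)
    bwd <- .backward_chain(target, ft$phi, ft$psi, ft$omega, m, stop_at = mid + 1)
    # the moving part is residues 1..mid of the forward build plus a virtual
    # residue mid+1, whose target position comes from the backward build
    tgt <- rbind(bwd$N[mid + 1, ], bwd$CA[mid + 1, ], bwd$C[mid + 1, ])
    phi1 <- if (sa > 1) { if (is.na(ft$phi[1])) Tm$phi[sa] else ft$phi[1] } else 0
    fwd_tor <- data.frame(phi = c(phi1, ft$phi[2:(mid + 1)]),
                          psi = ft$psi[seq_len(mid + 1)],
                          omega = ft$omega[seq_len(mid + 1)])
    build <- if (sa > 1) {
      ctx <- rbind(model$atoms$N[sa - 1, ], model$atoms$CA[sa - 1, ],
                   model$atoms$C[sa - 1, ])
      function(tor) .forward_chain(ctx, Tm$psi[sa - 1], Tm$omega[sa - 1],
                                   tor$phi, tor$psi, tor$omega, mid + 1)
    } else {
      frame1 <- rbind(model$atoms$N[1, ], model$atoms$CA[1, ], model$atoms$C[1, ])
      function(tor) .forward_chain_from_frame(frame1, tor, mid + 1)
    }
    init <- build(fwd_tor)
    init_mv <- rbind(init$N[mid + 1, ], init$CA[mid + 1, ], init$C[mid + 1, ])
    init_rms <- sqrt(mean(rowSums((init_mv - tgt)^2)))
    if (init_rms > 3) {
      # far from closed: a short coarse CCD stage first brings the cut
      # within reach of the least-squares refinement
      fwdc <- lapply(init, function(x) x[seq_len(mid + 1), , drop = FALSE])
      cc <- .ccd_close(fwdc, tgt, mid, tol = tol,
                       max_sweeps = min(max_sweeps, 50),
                       max_step_deg = max(max_step_deg, 30), adjust = adjust)
      fwd_tor <- .moving_part_torsions(cc$fwd, fwd_tor, mid,
                                       if (sa > 1) model$atoms$C[sa - 1, ] else NULL)
    }
    cl <- .dls_close(build, fwd_tor, adjust, mid, tgt, tol = tol,
                     max_iter = max_sweeps)
    cut_rms <- cl$rms
    # combined coordinates of the closed fragment
    N <- rbind(cl$fwd$N[seq_len(mid), , drop = FALSE],
               bwd$N[(mid + 1):m, , drop = FALSE])
    CA <- rbind(cl$fwd$CA[seq_len(mid), , drop = FALSE],
                bwd$CA[(mid + 1):m, , drop = FALSE])
    C <- rbind(cl$fwd$C[seq_len(mid), , drop = FALSE],
               bwd$C[(mid + 1):m, , drop = FALSE])
    # closed torsions from the combined chain (context atoms for phi[1])
    closed_tor <- ft
    if (sa > 1)
      closed_tor$phi[1] <- dihedral_angle(model$atoms$C[sa - 1, ], N[1, ],
                                          CA[1, ], C[1, ])
    for (r in seq_len(m - 1)) {
      closed_tor$psi[r] <- dihedral_angle(N[r, ], CA[r, ], C[r, ], N[r + 1, ])
      closed_tor$omega[r] <- dihedral_angle(CA[r, ], C[r, ], N[r + 1, ], CA[r + 1, ])
      closed_tor$phi[r + 1] <- dihedral_angle(C[r, ], N[r + 1, ], CA[r + 1, ],
                                              C[r + 1, ])
    }
    closed_tor$psi[m] <- Tm$psi[ea]
    closed_tor$omega[m] <- Tm$omega[ea]
  } else if (type == "tail_c") {
    closed_tor$psi[m] <- NA; closed_tor$omega[m] <- NA
  } else if (type == "tail_n") {
    closed_tor$phi[1] <- NA
  }

  # assemble the full torsion table and rebuild
  up <- if (sa > 1) Tm[seq_len(sa - 1), , drop = FALSE] else NULL
  down <- if (ea < L) Tm[(ea + 1):L, , drop = FALSE] else NULL
  if (type == "internal") {
    if (is.na(closed_tor$psi[m])) closed_tor$psi[m] <- Tm$psi[ea]
    if (is.na(closed_tor$omega[m])) closed_tor$omega[m] <- Tm$omega[ea]
    if (is.na(closed_tor$phi[1]) && sa > 1) closed_tor$phi[1] <- Tm$phi[sa]
  }
  full_tor <- rbind(up, closed_tor, down)
  rownames(full_tor) <- NULL
  full_seq <- c(if (sa > 1) model$aa[seq_len(sa - 1)] else NULL, fseq,
                if (ea < L) model$aa[(ea + 1):L] else NULL)
  nL <- nrow(full_tor)
  full_tor$phi[1] <- NA
  full_tor$psi[nL] <- NA; full_tor$omega[nL] <- NA

  if (type == "tail_n") {
    # the new chain's first residue position follows from building the tail
    # backward from the template's single bounding anchor
    end_frame <- rbind(model$atoms$N[ea, ], model$atoms$CA[ea, ],
                       model$atoms$C[ea, ])
    bwd <- .backward_chain(end_frame, ft$phi, ft$psi, ft$omega, m, stop_at = 1)
    frame1 <- rbind(bwd$N[1, ], bwd$CA[1, ], bwd$C[1, ])
  } else {
    frame1 <- rbind(model$atoms$N[1, ], model$atoms$CA[1, ], model$atoms$C[1, ])
  }
  new_model <- rebuild_backbone(full_tor, full_seq, anchor_frame = frame1,
                                source_id = model$source_id)

  closed <- cut_rms <= fail_tol
  span <- sa:(sa + m - 1)
  closed_frag <- fragment
  closed_frag$torsions <- closed_tor
  closed_frag$atoms <- lapply(new_model$atoms,
                              function(x) x[span, , drop = FALSE])
  # the terminal residue's O direction depends on the *next* residue's
  # placement (template context vs source context); exclude it so the rmsd
  # measures the fragment conformation itself
  drop_last_o <- function(x) x[-nrow(x), , drop = FALSE]
  closure_rmsd <- if (!closed) Inf else
    superposed_rmsd(drop_last_o(.stack_bb(new_model$atoms, span)),
                    drop_last_o(.fragment_ideal_coords(fragment)))
  rec <- structure(list(fragment = closed_frag, model = new_model,
                        closure_rmsd = closure_rmsd, cut_rms = cut_rms,
                        accepted = is.finite(closure_rmsd) && closure_rmsd < gate),
                   class = "fragment_record")
  rec
}

## Re-extract the moving part's torsions from coarse-closed coordinates
## (rotations preserve bond geometry, so the extraction is exact).
.moving_part_torsions <- function(f, tor, mid, c_prev) {
  n <- mid + 1
  for (r in seq_len(n)) {
    cp <- if (r == 1) c_prev else f$C[r - 1, ]
    if (!is.null(cp))
      tor$phi[r] <- dihedral_angle(cp, f$N[r, ], f$CA[r, ], f$C[r, ])
    if (r < n) {
      tor$psi[r] <- dihedral_angle(f$N[r, ], f$CA[r, ], f$C[r, ], f$N[r + 1, ])
      tor$omega[r] <- dihedral_angle(f$CA[r, ], f$C[r, ], f$N[r + 1, ],
                                     f$CA[r + 1, ])
    }
  }
  tor
}

## Forward chain when the fragment starts the model (no upstream context):
## residue 1 is pinned to the given frame.
.forward_chain_from_frame <- function(frame1, ft, m) {
  g <- ideal_geometry()
  N <- CA <- C <- matrix(NA_real_, m, 3)
  N[1, ] <- frame1[1, ]; CA[1, ] <- frame1[2, ]; C[1, ] <- frame1[3, ]
  if (m > 1) for (i in 2:m) {
    N[i, ]  <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$b_c_n, g$a_ca_c_n, ft$psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], g$b_n_ca, g$a_c_n_ca, ft$omega[i - 1])
    C[i, ]  <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], g$b_ca_c, g$a_n_ca_c, ft$phi[i])
  }
  list(N = N, CA = CA, C = C)
}

#' Apply the acceptance gate to a fragment record
#'
#' A record is accepted iff its closure rmsd is strictly below the threshold.
#'
#' @param record A `fragment_record`.
#' @param threshold Gate in Angstrom (default 0.2).
#' @return The record with `accepted` updated.
#' @export
gate_fragment <- function(record, threshold = 0.2) {
  record$accepted <- is.finite(record$closure_rmsd) &&
    record$closure_rmsd < threshold
  record
}

#' Idealize a structure
#'
#' Rebuilds a model from its own torsions with ideal bond lengths and angles,
#' anchored at its first residue's frame. Requires a break-free chain.
#'
#' @param model A `backbone_model`.
#' @return An idealized `backbone_model`.
#' @export
idealize_model <- function(model) {
  if (length(model$breaks) > 0)
    stop("cannot idealize a model with chain breaks")
  tor <- extract_torsions(model)
  frame1 <- rbind(model$atoms$N[1, ], model$atoms$CA[1, ], model$atoms$C[1, ])
  out <- rebuild_backbone(tor, model$aa, anchor_frame = frame1,
                          source_id = model$source_id)
  out$seqnum <- model$seqnum
  out$icode <- model$icode
  out$chain <- model$chain
  out
}

## --- fragment rmsd and clustering -----------------------------------------

#' Sequence-independent backbone RMSD between two fragments
#'
#' Equal-length fragments: backbone (N, CA, C, O) RMSD after Kabsch
#' superposition of their idealized conformations. Unequal lengths: the
#' minimum RMSD over all contiguous ungapped placements of the shorter
#' fragment within the longer; the length difference is attached as
#' attribute `length_diff`.
#'
#' @param a,b `fragment` objects (nonempty).
#' @return RMSD in Angstrom, with attribute `length_diff`.
#' @export
fragment_rmsd <- function(a, b) {
  if (a$n_res < 1 || b$n_res < 1) stop("empty fragment")
  ca <- .fragment_ideal_coords(a)
  cb <- .fragment_ideal_coords(b)
  .coords_rmsd_offset(ca, cb, a$n_res, b$n_res)
}

.coords_rmsd_offset <- function(ca, cb, na, nb) {
  if (na == nb) {
    r <- superposed_rmsd(ca, cb)
    attr(r, "length_diff") <- 0L
    return(r)
  }
  if (na > nb) { tmp <- ca; ca <- cb; cb <- tmp; t2 <- na; na <- nb; nb <- t2 }
  best <- Inf
  for (off in 0:(nb - na)) {
    rows <- (4 * off + 1):(4 * (off + na))
    r <- superposed_rmsd(ca, cb[rows, , drop = FALSE])
    if (r < best) best <- r
  }
  attr(best, "length_diff") <- abs(nb - na)
  best
}

#' Cluster fragments by backbone RMSD
#'
#' Agglomerative hierarchical clustering with complete (maximum) linkage on
#' the pairwise [fragment_rmsd()] matrix, cut at the given radius. Each
#' cluster's representative is the member with minimum mean RMSD to its
#' cluster (ties broken by lexicographically smallest `source_id`).
#'
#' @param fragments Nonempty list of `fragment` objects (one segment).
#' @param radius Cut height in Angstrom (default 1.0).
#' @return Object of class `cluster_assignment`: list with `segment_name`,
#'   `labels` (integer per fragment), `representatives` (named integer vector,
#'   cluster id to fragment index), `dist` (the RMSD matrix).
#' @export
cluster_fragments <- function(fragments, radius = 1.0) {
  n <- length(fragments)
  if (n < 1) stop("no fragments to cluster")
  seg <- fragments[[1]]$segment_name
  if (n == 1) {
    return(structure(list(segment_name = seg, labels = 1L,
                          representatives = c("1" = 1L),
                          dist = matrix(0, 1, 1)),
                     class = "cluster_assignment"))
  }
  coords <- lapply(fragments, .fragment_ideal_coords)
  sizes <- vapply(fragments, function(f) f$n_res, 1L)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- as.numeric(
      .coords_rmsd_offset(coords[[i]], coords[[j]], sizes[i], sizes[j]))
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  labels <- stats::cutree(hc, h = radius)
  reps <- vapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == 1) return(idx)
    meand <- vapply(idx, function(i) mean(D[i, idx]), 0)
    ids <- vapply(fragments[idx], function(f) f$source_id, "")
    idx[order(meand, ids)][1]
  }, 1L)
  names(reps) <- sort(unique(labels))
  structure(list(segment_name = seg, labels = as.integer(labels),
                 representatives = reps, dist = D),
            class = "cluster_assignment")
}

## --- database construction and persistence ---------------------------------

#' Build a per-segment fragment database
#'
#' Aligns each homolog to the template, extracts every segment's fragment,
#' grafts and closes it in the template context, and gates on closure rmsd.
#' The template's own fragments are included (they close exactly). Rejected
#' homologs and fragments are recorded in the build log.
#'
#' @param template An idealized `backbone_model`.
#' @param homologs List of `backbone_model` objects.
#' @param scheme The `segmentation_scheme`.
#' @param gate Acceptance threshold in Angstrom (default 0.2).
#' @param include_template Include the template's own fragments (default TRUE).
#' @param ... Passed to [graft_and_close()].
#' @return Object of class `fragment_database`: per-segment record lists,
#'   metadata, and a build `log` data frame.
#' @export
build_fragment_db <- function(template, homologs, scheme, gate = 0.2,
                              include_template = TRUE, ...) {
  segs <- scheme$segments$name
  records <- stats::setNames(vector("list", length(segs)), segs)
  for (s in segs) records[[s]] <- list()
  log <- list()
  note <- function(id, seg, status, rmsd = NA_real_)
    log[[length(log) + 1]] <<- data.frame(homolog = id, segment = seg,
                                          status = status, closure_rmsd = rmsd)
  sources <- homologs
  alns <- vector("list", length(sources))
  for (k in seq_along(sources)) {
    alns[[k]] <- tryCatch(align_to_template(sources[[k]], template, scheme),
                          error = function(e) e)
    if (inherits(alns[[k]], "error"))
      note(sources[[k]]$source_id, "*", conditionMessage(alns[[k]]))
  }
  if (include_template) {
    sources <- c(list(template), sources)
    alns <- c(list(self_alignment(template, scheme)), alns)
  }
  for (k in seq_along(sources)) {
    if (inherits(alns[[k]], "error")) next
    for (s in segs) {
      frag <- withCallingHandlers(
        extract_fragment(sources[[k]], alns[[k]], s, scheme),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(frag)) {
        note(sources[[k]]$source_id, s, "break in span")
        next
      }
      rec <- graft_and_close(template, frag, scheme, gate = gate, ...)
      note(sources[[k]]$source_id, s,
           if (rec$accepted) "accepted" else "rejected", rec$closure_rmsd)
      records[[s]][[length(records[[s]]) + 1]] <- rec
    }
  }
  structure(list(template_id = template$source_id, scheme = scheme,
                 gate = gate, segments = records,
                 log = do.call(rbind, log)),
            class = "fragment_database")
}

#' @export
print.fragment_database <- function(x, ...) {
  cat(sprintf("fragment_database (template '%s', gate %.2f A)\n",
              x$template_id, x$gate))
  for (s in names(x$segments)) {
    recs <- x$segments[[s]]
    cat(sprintf("  %s: %d fragments, %d accepted\n", s, length(recs),
                sum(vapply(recs, function(r) r$accepted, TRUE))))
  }
  invisible(x)
}

#' Accepted records of a segment
#' @param db A `fragment_database`.
#' @param segment Segment name.
#' @return List of accepted `fragment_record`s.
#' @export
accepted_records <- function(db, segment) {
  recs <- db$segments[[segment]]
  if (is.null(recs)) stop("no segment '", segment, "' in database")
  Filter(function(r) isTRUE(r$accepted), recs)
}

#' Reduce a database to cluster representatives
#'
#' Clusters the accepted fragments of every segment with
#' [cluster_fragments()] and keeps one representative per cluster.
#'
#' @param db A `fragment_database`.
#' @param radius Cluster radius in Angstrom (default 1.0).
#' @return The reduced database; cluster assignments are attached as
#'   `clusters` (per segment).
#' @export
reduce_to_representatives <- function(db, radius = 1.0) {
  clusters <- list()
  for (s in names(db$segments)) {
    recs <- accepted_records(db, s)
    if (length(recs) == 0) next
    ca <- cluster_fragments(lapply(recs, function(r) r$fragment), radius)
    clusters[[s]] <- ca
    db$segments[[s]] <- recs[sort(ca$representatives)]
  }
  db$clusters <- clusters
  db
}

#' Save a fragment database to a directory
#'
#' One JSON-lines file per segment (source, sequence, torsions to 0.001
#' degree, closure rmsd, gate flag) plus a JSON metadata file. With a fixed
#' `created` stamp the output is byte-identical across rebuilds from the
#' same inputs.
#'
#' @param db A `fragment_database`.
#' @param path Directory to create/write.
#' @param created Metadata timestamp string; fixed default for determinism.
#' @return Invisibly, `path`.
#' @export
save_db <- function(db, path, created = "unset") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(version = .DB_VERSION, template_id = db$template_id,
               gate = db$gate, created = created,
               anchors = db$scheme$anchors,
               template_length = db$scheme$template_length,
               segment_names = db$scheme$segments$name)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "metadata.json"))
  for (s in names(db$segments)) {
    lines <- vapply(db$segments[[s]], function(r) {
      fr <- r$fragment
      jsonlite::toJSON(list(
        source_id = fr$source_id, segment = fr$segment_name, seq = fr$seq,
        src_start = fr$src_start,
        phi = round(fr$torsions$phi, 3), psi = round(fr$torsions$psi, 3),
        omega = round(fr$torsions$omega, 3),
        closure_rmsd = round(r$closure_rmsd, 6), accepted = r$accepted),
        auto_unbox = TRUE, digits = NA, na = "null")
    }, "")
    writeLines(lines, file.path(path, paste0("segment_", s, ".jsonl")))
  }
  invisible(path)
}

#' Load a fragment database from a directory
#'
#' @param path Directory written by [save_db()].
#' @return A `fragment_database` (fragments carry torsions and sequences;
#'   grafted models are not persisted and are rebuilt on demand).
#' @export
load_db <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file)) stop("no metadata.json under ", path)
  meta <- jsonlite::fromJSON(readLines(meta_file))
  if (!identical(meta$version, .DB_VERSION))
    stop("database version mismatch: file has '", meta$version,
         "', this package reads '", .DB_VERSION, "'")
  scheme <- segmentation_scheme(meta$template_id, meta$anchors,
                                meta$template_length,
                                segment_names = meta$segment_names)
  records <- list()
  for (s in meta$segment_names) {
    f <- file.path(path, paste0("segment_", s, ".jsonl"))
    if (!file.exists(f)) stop("missing segment file for '", s, "'")
    recs <- lapply(readLines(f), function(ln) {
      x <- jsonlite::fromJSON(ln)
      tor <- data.frame(phi = as.numeric(x$phi), psi = as.numeric(x$psi),
                        omega = as.numeric(x$omega))
      frag <- structure(list(source_id = x$source_id, segment_name = x$segment,
                             seq = x$seq, torsions = tor, n_res = nrow(tor),
                             end_frames = list(start = NULL, end = NULL),
                             src_start = x$src_start, atoms = NULL),
                        class = "fragment")
      structure(list(fragment = frag, model = NULL,
                     closure_rmsd = x$closure_rmsd,
                     cut_rms = NA_real_, accepted = x$accepted),
                class = "fragment_record")
    })
    records[[s]] <- recs
  }
  structure(list(template_id = meta$template_id, scheme = scheme,
                 gate = meta$gate, segments = records, log = NULL),
            class = "fragment_database")
}
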