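## Synthetic toy families and MSAs with known ground truth: idealized
## backbones sharing helical anchor stretches, with variable-length loops
## drawn from planted conformational groups. Every pipeline stage is
## testable against these fixtures without downloading structures.

.HELIX <- c(phi = -57, psi = -47)

## Distinct loop torsion motifs; planted conformational groups draw their
## base conformation from this library (group 1 is the template's own loop).
.MOTIF_LIBRARY <- list(
  c(phi = -57, psi = -47),    # alpha helix
  c(phi = -139, psi = 135),   # extended beta
  c(phi = 57, psi = 47),      # left-handed helix
  c(phi = -75, psi = 145),    # polyproline II
  c(phi = -90, psi = 0),
  c(phi = -120, psi = 60))

## Torsion rows for a group's base loop: group 1 reuses the template motif
## (a regular repeat); other groups draw per-position torsions from the
## motif library wells, which gives loop shapes several Angstrom apart once
## loops are longer than a handful of residues.
.group_loop_rows <- function(g, n) {
  if (g == 1) return(.motif_rows(.MOTIF_LIBRARY[[1]], n))
  picks <- sample(seq_along(.MOTIF_LIBRARY), n, replace = TRUE)
  data.frame(phi = vapply(picks, function(k) .MOTIF_LIBRARY[[k]]["phi"], 0),
             psi = vapply(picks, function(k) .MOTIF_LIBRARY[[k]]["psi"], 0),
             omega = rep(180, n))
}

.AA_POOL <- setdiff(.AA_ORDER, "C")  # no cysteines in toy sequences

.rand_seq <- function(n) paste(sample(.AA_POOL, n, replace = TRUE), collapse = "")

.mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  k <- round(rate * length(v))
  if (k > 0) {
    pos <- sample(length(v), k)
    v[pos] <- vapply(v[pos], function(a) sample(setdiff(.AA_POOL, a), 1), "")
  }
  paste(v, collapse = "")
}

.motif_rows <- function(motif, n) {
  data.frame(phi = rep(motif["phi"], n), psi = rep(motif["psi"], n),
             omega = rep(180, n))
}

.random_frame <- function() {
  # random proper rotation + translation applied to the default frame
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  tr <- stats::runif(3, -20, 20)
  sweep(.default_anchor_frame() %*% t(q), 2, tr, "+")
}

#' Generate a toy homolog family with known ground truth
#'
#' Builds a template plus homologs that share identical helical anchor
#' stretches while each loop segment adopts one of a small number of planted
#' conformational groups. Group base conformations are distinct torsion
#' motifs geometrically closed onto the template's anchor frames (so every
#' fragment attaches to the shared fold), and homologs perturb the loop
#' torsions of their group's base by Gaussian noise (clipped at 2.5 sigma to
#' keep fragments closable). Loop sequences mutate within a group; anchor
#' sequences are family-invariant. Homologs are emitted in random rigid
#' frames. A fixed seed makes the output, including written PDB files,
#' byte-identical across runs.
#'
#' @param n_structures Number of homologs (template excluded).
#' @param n_segments Number of loop-bearing internal segments.
#' @param loop_length_range Integer (min, max) loop length per segment group.
#' @param n_groups Planted conformational groups per segment (max 6).
#' @param torsion_noise Loop torsion noise s.d. in degrees.
#' @param seed Integer seed.
#' @param anchor_len Residues per anchor stretch (odd; anchor at its center).
#' @param tails If `TRUE` (default) anchors sit at stretch centers and the
#'   chain ends form terminal-tail segments; if `FALSE` the first and last
#'   anchors are the chain termini, so the scheme has exactly `n_segments`
#'   loop-bearing segments and no tails.
#' @param dir Optional directory: PDB files and an alignment sidecar are
#'   written there.
#' @return List with `template`, `homologs` (list of `backbone_model`),
#'   `scheme`, `ground_truth` (group labels, anchor maps, loop spans,
#'   catalytic positions, group lengths), and `files` (paths if written).
#' @export
make_toy_family <- function(n_structures = 8, n_segments = 2,
                            loop_length_range = c(12, 16), n_groups = 3,
                            torsion_noise = 2, seed = 1, anchor_len = 5,
                            tails = TRUE, dir = NULL) {
  if (n_groups > n_structures)
    stop("n_groups must not exceed n_structures")
  if (loop_length_range[1] > loop_length_range[2] || loop_length_range[1] < 3)
    stop("invalid loop_length_range")
  if (anchor_len %% 2 == 0) stop("anchor_len must be odd")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  n_stretch <- n_segments + 1
  half <- (anchor_len + 1) %/% 2
  # group loop lengths per segment; group 1 is the template's loop. Groups
  # of one segment get distinct lengths whenever the range allows, mirroring
  # the length diversity of natural loop families.
  len_pool <- loop_length_range[1]:loop_length_range[2]
  lens <- vapply(seq_len(n_segments), function(s)
    sample(len_pool, n_groups, replace = length(len_pool) < n_groups),
    integer(n_groups))
  lens <- matrix(lens, n_groups, n_segments)

  # template block structure: stretch, loop, stretch, ..., stretch
  stretch_tor <- .motif_rows(.HELIX, anchor_len)
  template_blocks <- list()
  for (s in seq_len(n_segments)) {
    template_blocks[[2 * s - 1]] <- stretch_tor
    template_blocks[[2 * s]] <- .motif_rows(.MOTIF_LIBRARY[[1]], lens[1, s])
  }
  template_blocks[[2 * n_segments + 1]] <- stretch_tor
  t_tor <- do.call(rbind, template_blocks)
  rownames(t_tor) <- NULL
  Lt <- nrow(t_tor)
  t_tor$phi[1] <- NA; t_tor$psi[Lt] <- NA; t_tor$omega[Lt] <- NA

  # block boundaries on the template
  block_len <- vapply(template_blocks, nrow, 1L)
  block_end <- cumsum(block_len)
  block_start <- block_end - block_len + 1
  anchors <- block_start[seq(1, 2 * n_segments + 1, by = 2)] + half - 1
  if (!tails) { anchors[1] <- 1L; anchors[n_stretch] <- Lt }
  loop_start_t <- block_start[seq(2, 2 * n_segments, by = 2)]

  stretch_seq <- vapply(seq_len(n_stretch), function(i) .rand_seq(anchor_len), "")
  loop_seq_groups <- matrix("", n_groups, n_segments)
  for (g in seq_len(n_groups)) for (s in seq_len(n_segments))
    loop_seq_groups[g, s] <- .rand_seq(lens[g, s])
  t_seq_blocks <- character(2 * n_segments + 1)
  t_seq_blocks[seq(1, 2 * n_segments + 1, by = 2)] <- stretch_seq
  t_seq_blocks[seq(2, 2 * n_segments, by = 2)] <- loop_seq_groups[1, ]
  t_seq <- paste(t_seq_blocks, collapse = "")

  template <- rebuild_backbone(t_tor, t_seq, source_id = "template")
  scheme <- segmentation_scheme("template", anchors, Lt)

  # close each non-template group motif onto the template anchor frames,
  # adjusting loop torsions only, so all groups share the global fold
  seg_rows <- function(s) anchors[s]:anchors[s + 1]
  group_base <- vector("list", n_segments)
  for (s in seq_len(n_segments)) {
    group_base[[s]] <- vector("list", n_groups)
    rows <- seg_rows(s)
    seg_tor_t <- t_tor[rows, , drop = FALSE]
    loop_lo <- loop_start_t[s] - anchors[s] + 1       # loop start within segment
    left <- seg_tor_t[seq_len(loop_lo - 1), , drop = FALSE]
    right_from <- loop_lo + lens[1, s]
    right <- seg_tor_t[right_from:nrow(seg_tor_t), , drop = FALSE]
    group_base[[s]][[1]] <- seg_tor_t
    for (g in seq_len(n_groups)[-1]) {
      raw <- rbind(left, .group_loop_rows(g, lens[g, s]), right)
      rownames(raw) <- NULL
      frag <- structure(list(source_id = sprintf("group%d", g),
                             segment_name = scheme$segments$name[
                               match(s, which(scheme$segments$type == "internal"))],
                             seq = .rand_seq(nrow(raw)), torsions = raw,
                             n_res = nrow(raw),
                             end_frames = list(start = NULL, end = NULL),
                             src_start = 1L, atoms = NULL),
                        class = "fragment")
      segname <- scheme$segments$name[scheme$segments$type == "internal"][s]
      frag$segment_name <- segname
      # cut after the last loop residue: the whole loop is adjustable and
      # only anchor rows lie beyond the cut, so the target is always within
      # reach of the loop's torsions
      cut <- (loop_lo - 1) + lens[g, s]
      adj <- loop_lo:cut
      rec <- .graft_close_at(template, frag,
                             scheme$segments$start[scheme$segments$name == segname],
                             scheme$segments$end[scheme$segments$name == segname],
                             "internal", gate = Inf, tol = 0.02,
                             max_sweeps = 1000, fail_tol = 0.5,
                             cut = cut, adjust = adj, max_step_deg = 180)
      if (!is.finite(rec$closure_rmsd) && rec$cut_rms > 0.5)
        stop("could not close group ", g, " motif for segment ", s,
             "; widen loop_length_range")
      group_base[[s]][[g]] <- rec$fragment$torsions
    }
  }

  labels <- matrix(0L, n_structures, n_segments)
  for (h in seq_len(n_structures)) for (s in seq_len(n_segments))
    labels[h, s] <- ((h - 1 + s - 1) %% n_groups) + 1L

  homologs <- vector("list", n_structures)
  anchor_maps <- vector("list", n_structures)
  for (h in seq_len(n_structures)) {
    # N tail up to (but excluding) the first anchor; identical to template
    tor_blocks <- list(t_tor[seq_len(anchors[1] - 1), , drop = FALSE])
    seq_parts <- substr(t_seq, 1, anchors[1] - 1)
    h_anchors <- integer(n_stretch)
    h_anchors[1] <- anchors[1]
    for (s in seq_len(n_segments)) {
      g <- labels[h, s]
      segt <- group_base[[s]][[g]]
      loop_lo <- loop_start_t[s] - anchors[s] + 1   # loop start within segment
      lr <- loop_lo:(loop_lo + lens[g, s] - 1)
      if (torsion_noise > 0) {
        clip <- 2.5 * torsion_noise
        noise <- matrix(stats::rnorm(2 * length(lr), 0, torsion_noise), ncol = 2)
        noise <- pmin(pmax(noise, -clip), clip)
        segt$phi[lr] <- .wrap_angle(segt$phi[lr] + noise[, 1])
        segt$psi[lr] <- .wrap_angle(segt$psi[lr] + noise[, 2])
        # real homolog loops connect the same conserved anchors; restore
        # that property by re-closing the perturbed loop onto the shared
        # anchor frames (minimal-norm, so the perturbation survives in the
        # closure null space as intra-group conformational variation)
        segt <- .reclose_segment(template, scheme, s, segt, lr)
      }
      loop_seq <- .mutate_seq(loop_seq_groups[g, s], 0.25)
      seg_seq <- paste0(substr(t_seq, anchors[s], loop_start_t[s] - 1),
                        loop_seq,
                        substr(t_seq, loop_start_t[s] + lens[1, s], anchors[s + 1]))
      if (s > 1) {  # shared anchor residue belongs to the left block
        segt <- segt[-1, , drop = FALSE]
        seg_seq <- substr(seg_seq, 2, nchar(seg_seq))
      }
      tor_blocks[[length(tor_blocks) + 1]] <- segt
      seq_parts <- paste0(seq_parts, seg_seq)
      h_anchors[s + 1] <- h_anchors[s] + nrow(segt) - if (s > 1) 0L else 1L
    }
    if (anchors[n_stretch] < Lt) {
      tail_rows <- (anchors[n_stretch] + 1):Lt
      tor_blocks[[length(tor_blocks) + 1]] <- t_tor[tail_rows, , drop = FALSE]
      seq_parts <- paste0(seq_parts, substr(t_seq, anchors[n_stretch] + 1, Lt))
    }
    htor <- do.call(rbind, tor_blocks)
    rownames(htor) <- NULL
    nh <- nrow(htor)
    htor$phi[1] <- NA; htor$psi[nh] <- NA; htor$omega[nh] <- NA
    homologs[[h]] <- rebuild_backbone(htor, seq_parts,
                                      anchor_frame = .random_frame(),
                                      source_id = sprintf("hom%02d", h))
    anchor_maps[[h]] <- stats::setNames(h_anchors, anchors)
  }

  catalytic <- c(anchors[1], anchors[2])
  gt <- list(labels = labels, anchors = anchors, anchor_maps = anchor_maps,
             catalytic = catalytic, group_lengths = lens,
             loop_start_template = loop_start_t,
             loop_seq_groups = loop_seq_groups)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(file.path(dir, "template.pdb"),
               vapply(homologs, function(m)
                 file.path(dir, paste0(m$source_id, ".pdb")), ""))
    write_pdb(template, files[1])
    for (k in seq_along(homologs)) write_pdb(homologs[[k]], files[k + 1])
    gt_file <- file.path(dir, "ground_truth.json")
    writeLines(jsonlite::toJSON(list(labels = labels, anchors = anchors,
                                     catalytic = catalytic,
                                     group_lengths = lens),
                                digits = NA), gt_file)
    files <- c(files, gt_file)
  }
  list(template = template, homologs = homologs, scheme = scheme,
       ground_truth = gt, files = files)
}

## Close a perturbed segment's loop torsions back onto the template's anchor
## frames (internal generator step; minimal-norm, loop rows only).
.reclose_segment <- function(template, scheme, s_internal, segt, loop_rows) {
  segname <- scheme$segments$name[scheme$segments$type == "internal"][s_internal]
  i <- match(segname, scheme$segments$name)
  frag <- structure(list(source_id = "reclose", segment_name = segname,
                         seq = strrep("A", nrow(segt)), torsions = segt,
                         n_res = nrow(segt),
                         end_frames = list(start = NULL, end = NULL),
                         src_start = 1L, atoms = NULL),
                    class = "fragment")
  rec <- .graft_close_at(template, frag, scheme$segments$start[i],
                         scheme$segments$end[i], "internal", gate = Inf,
                         tol = 0.01, max_sweeps = 300,
                         cut = max(loop_rows), adjust = loop_rows)
  rec$fragment$torsions
}

#' Generate a toy MSA with planted pairwise identities
#'
#' Mutates the reference at randomly chosen positions so each emitted
#' sequence realizes its identity target to within 2 percentage points
#' (exact when the reference is long enough); insertions are not used, so
#' the rows align column-to-column.
#'
#' @param reference Reference amino-acid sequence (row 1 of the MSA).
#' @param identity_targets Fractions in [0, 1], one per generated sequence.
#' @param seed Integer seed.
#' @return List with `msa` (reference first) and `ground_truth` data frame
#'   of target and realized identities.
#' @export
make_toy_msa <- function(reference, identity_targets, seed = 1) {
  if (any(identity_targets < 0 | identity_targets > 1))
    stop("identity targets must lie in [0, 1]")
  L <- nchar(reference)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- character(length(identity_targets))
  realized <- numeric(length(identity_targets))
  for (i in seq_along(identity_targets)) {
    t <- identity_targets[i]
    k <- round((1 - t) * L)
    realized[i] <- 1 - k / L
    if (abs(realized[i] - t) > 0.02)
      stop("identity target ", t, " unreachable on a reference of length ", L)
    v <- strsplit(reference, "")[[1]]
    if (k > 0) {
      pos <- sample(L, k)
      v[pos] <- vapply(v[pos], function(a) sample(setdiff(.AA_POOL, a), 1), "")
    }
    rows[i] <- paste(v, collapse = "")
  }
  out <- msa(c(reference, rows),
             names = c("reference", sprintf("target%02d", seq_along(rows))),
             reference_row = 1)
  list(msa = out,
       ground_truth = data.frame(name = sprintf("target%02d", seq_along(rows)),
                                 target = identity_targets,
                                 realized = realized))
}
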