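## Segmentation of homologous structures at conserved anchors: template
## alignment, segment definition, fragment extraction and end alignment.

#' Define a segmentation scheme on a template
#'
#' Anchors are user-chosen template residue indices of maximal structural
#' conservation. Consecutive anchors bound internal segments (anchor-inclusive
#' at both ends, so adjacent segments share their boundary anchor); residues
#' before the first anchor form an N-terminal tail segment and residues after
#' the last anchor a C-terminal tail, each bounded by a single anchor.
#'
#' @param template_id Identifier of the template structure.
#' @param anchors Strictly increasing template residue indices (1-based).
#' @param template_length Number of residues in the template.
#' @param segment_names Optional names, one per segment (tails included when
#'   present). Defaults to "nterm", "s1", "s2", ..., "cterm".
#' @return Object of class `segmentation_scheme` with a `segments` data frame
#'   (`name`, `start`, `end`, `type` in tail_n/internal/tail_c).
#' @export
segmentation_scheme <- function(template_id, anchors, template_length,
                                segment_names = NULL) {
  anchors <- as.integer(anchors)
  if (is.unsorted(anchors, strictly = TRUE))
    stop("anchors must be strictly increasing")
  if (anchors[1] < 1 || anchors[length(anchors)] > template_length)
    stop("anchors out of template range")
  if (length(anchors) < 2 && (anchors[1] == 1 || anchors[1] == template_length))
    stop("scheme must define at least one segment")
  segs <- data.frame(name = character(0), start = integer(0),
                     end = integer(0), type = character(0),
                     stringsAsFactors = FALSE)
  if (anchors[1] > 1)
    segs <- rbind(segs, data.frame(name = "nterm", start = 1L,
                                   end = anchors[1], type = "tail_n"))
  if (length(anchors) > 1)
    for (i in seq_len(length(anchors) - 1))
      segs <- rbind(segs, data.frame(name = paste0("s", i), start = anchors[i],
                                     end = anchors[i + 1], type = "internal"))
  if (anchors[length(anchors)] < template_length)
    segs <- rbind(segs, data.frame(name = "cterm",
                                   start = anchors[length(anchors)],
                                   end = as.integer(template_length),
                                   type = "tail_c"))
  if (!is.null(segment_names)) {
    if (length(segment_names) != nrow(segs))
      stop("need ", nrow(segs), " segment names, got ", length(segment_names))
    segs$name <- segment_names
  }
  structure(list(template_id = template_id, anchors = anchors,
                 template_length = as.integer(template_length),
                 segments = segs),
            class = "segmentation_scheme")
}

#' @export
print.segmentation_scheme <- function(x, ...) {
  cat(sprintf("segmentation_scheme on '%s': %d anchors, %d segments\n",
              x$template_id, length(x$anchors), nrow(x$segments)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

.get_segment <- function(scheme, name) {
  i <- match(name, scheme$segments$name)
  if (is.na(i)) stop("no segment named '", name, "' in scheme")
  scheme$segments[i, ]
}

.seq_string <- function(model) paste(model$aa, collapse = "")

## Column-wise residue pairs (homolog index, template index) from a global
## Needleman-Wunsch alignment of the two sequences.
.alignment_pairs <- function(hom_seq, temp_seq) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(hom_seq), Biostrings::AAString(temp_seq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  hi <- ti <- 0L
  pairs <- matrix(0L, 0, 2)
  out <- vector("list", length(p))
  k <- 0L
  for (j in seq_along(p)) {
    if (p[j] != "-") hi <- hi + 1L
    if (s[j] != "-") ti <- ti + 1L
    if (p[j] != "-" && s[j] != "-") { k <- k + 1L; out[[k]] <- c(hi, ti) }
  }
  do.call(rbind, out[seq_len(k)])
}

## Maximum-weight monotone (sequence-order-preserving) matching of homolog
## CAs to template CAs among pairs within `cutoff` of each other, by
## LCS-style dynamic programming. Pairs are weighted by proximity
## (cutoff - distance) so the correct register beats marginal off-register
## pairings. Deterministic; remaining ties resolved in sequence order.
.monotone_pairs <- function(hom_ca, temp_ca, cutoff = 3.5) {
  nh <- nrow(hom_ca); nt <- nrow(temp_ca)
  d2 <- outer(rowSums(hom_ca^2), rowSums(temp_ca^2), "+") -
    2 * hom_ca %*% t(temp_ca)
  d2[d2 < 0] <- 0
  w <- cutoff - sqrt(d2)
  w[w < 0] <- 0
  L <- matrix(0, nh + 1, nt + 1)
  for (i in seq_len(nh)) for (j in seq_len(nt)) {
    best <- max(L[i, j + 1], L[i + 1, j])
    if (w[i, j] > 0) best <- max(best, L[i, j] + w[i, j])
    L[i + 1, j + 1] <- best
  }
  i <- nh; j <- nt
  out <- list()
  while (i > 0 && j > 0) {
    if (w[i, j] > 0 && abs(L[i + 1, j + 1] - (L[i, j] + w[i, j])) < 1e-9) {
      out[[length(out) + 1]] <- c(i, j); i <- i - 1; j <- j - 1
    } else if (L[i, j + 1] >= L[i + 1, j]) i <- i - 1 else j <- j - 1
  }
  if (length(out) == 0) return(matrix(0L, 0, 2))
  matrix(as.integer(do.call(rbind, rev(out))), ncol = 2)
}

#' Align a homolog to the template
#'
#' Sequence-guided structural alignment: a global sequence alignment seeds
#' residue pairs, then CA-based Kabsch superposition and re-derivation of
#' the residue correspondence (maximum sequence-order-preserving matching of
#' CA atoms within 3.5 Angstrom) are iterated until the pair set is stable.
#' Every anchor of the scheme must end up mapped, otherwise the homolog is
#' rejected with an error naming the missing anchor.
#'
#' @param homolog,template `backbone_model` objects.
#' @param scheme A `segmentation_scheme` on the template.
#' @param max_iter Maximum refinement iterations.
#' @return Object of class `template_alignment` with `pairs` (n x 2 matrix of
#'   homolog/template indices), `anchor_map` (named integer vector, names are
#'   template anchor indices), and the final superposition `fit`.
#' @export
align_to_template <- function(homolog, template, scheme, max_iter = 20) {
  hseq <- strsplit(.seq_string(homolog), "")[[1]]
  tseq <- strsplit(.seq_string(template), "")[[1]]
  seed <- .alignment_pairs(.seq_string(homolog), .seq_string(template))
  if (is.null(seed) || nrow(seed) < 3)
    stop("homolog '", homolog$source_id, "' rejected: too few alignable residues")
  # high-confidence seed: runs of >= 3 consecutive identical residue pairs
  # (the sequence-conserved anchor neighborhoods); the full seed is the
  # fallback when a family is too diverged for such runs
  ident <- hseq[seed[, 1]] == tseq[seed[, 2]]
  consec <- c(TRUE, diff(seed[, 1]) == 1 & diff(seed[, 2]) == 1)
  run_id <- cumsum(!(ident & consec))
  run_len <- ave(seq_len(nrow(seed)), run_id, FUN = length)
  blocks <- seed[ident & run_len >= 3, , drop = FALSE]
  pairs <- if (nrow(blocks) >= 3) blocks else seed
  fit <- NULL
  new_pairs <- pairs
  for (it in seq_len(max_iter)) {
    fit <- kabsch_superpose(homolog$atoms$CA[pairs[, 1], , drop = FALSE],
                            template$atoms$CA[pairs[, 2], , drop = FALSE])
    moved_all <- apply_transform(homolog$atoms$CA, fit)
    new_pairs <- .monotone_pairs(moved_all, template$atoms$CA, cutoff = 3.5)
    if (nrow(new_pairs) < 3) break  # keep the previous fit
    # refit only on tightly superposed pairs so structurally diverged loops
    # cannot drag the frame off register
    d <- sqrt(rowSums((moved_all[new_pairs[, 1], , drop = FALSE] -
                       template$atoms$CA[new_pairs[, 2], , drop = FALSE])^2))
    tight <- new_pairs[d <= 1.5, , drop = FALSE]
    refit <- if (nrow(tight) >= 3) tight else new_pairs
    if (identical(refit, pairs)) break
    pairs <- refit
  }
  pairs <- new_pairs
  anchor_map <- pairs[match(scheme$anchors, pairs[, 2]), 1]
  names(anchor_map) <- scheme$anchors
  if (any(is.na(anchor_map))) {
    missing <- scheme$anchors[is.na(anchor_map)]
    stop("homolog '", homolog$source_id, "' rejected: anchor(s) ",
         paste(missing, collapse = ", "), " unmapped")
  }
  structure(list(homolog_id = homolog$source_id, pairs = pairs,
                 anchor_map = anchor_map, fit = fit),
            class = "template_alignment")
}

#' Identity alignment of the template to itself
#'
#' @param template A `backbone_model`.
#' @param scheme Its `segmentation_scheme`.
#' @return A `template_alignment` mapping every residue to itself.
#' @export
self_alignment <- function(template, scheme) {
  n <- n_residues(template)
  am <- scheme$anchors
  names(am) <- scheme$anchors
  structure(list(homolog_id = template$source_id,
                 pairs = cbind(seq_len(n), seq_len(n)),
                 anchor_map = am,
                 fit = list(rotation = diag(3), translation = c(0, 0, 0),
                            rmsd = 0)),
            class = "template_alignment")
}

#' Extract a segment fragment from a homolog
#'
#' The fragment spans the homolog residues between the mapped bounding
#' anchors, inclusive of the anchor residues (a single anchor bounds
#' terminal-tail segments). Torsions come from [extract_torsions()] on the
#' homolog; the anchor N/CA/C coordinate frames at both ends are recorded.
#' A chain break inside the span rejects the fragment (returns `NULL` with
#' a warning).
#'
#' @param homolog A `backbone_model`.
#' @param alignment Its `template_alignment`.
#' @param segment Segment name in the scheme.
#' @param scheme The `segmentation_scheme`.
#' @return Object of class `fragment`, or `NULL` if the span contains a break.
#' @export
extract_fragment <- function(homolog, alignment, segment, scheme) {
  seg <- .get_segment(scheme, segment)
  amap <- alignment$anchor_map
  n <- n_residues(homolog)
  if (seg$type == "tail_n") {
    hb <- amap[as.character(seg$end)]; ha <- 1L
  } else if (seg$type == "tail_c") {
    ha <- amap[as.character(seg$start)]; hb <- n
  } else {
    ha <- amap[as.character(seg$start)]; hb <- amap[as.character(seg$end)]
  }
  if (any(is.na(c(ha, hb))))
    stop("alignment does not map the bounding anchor(s) of segment ", segment)
  ha <- as.integer(ha); hb <- as.integer(hb)
  if (hb <= ha) stop("degenerate segment span in homolog")
  if (any(homolog$breaks >= ha & homolog$breaks < hb)) {
    warning("fragment ", segment, " of '", homolog$source_id,
            "' rejected: chain break inside span")
    return(NULL)
  }
  tor <- extract_torsions(homolog)[ha:hb, , drop = FALSE]
  rownames(tor) <- NULL
  frame_of <- function(i) rbind(N = homolog$atoms$N[i, ],
                                CA = homolog$atoms$CA[i, ],
                                C = homolog$atoms$C[i, ])
  end_frames <- list(
    start = if (seg$type == "tail_n") NULL else frame_of(ha),
    end   = if (seg$type == "tail_c") NULL else frame_of(hb))
  atoms <- lapply(homolog$atoms, function(m) m[ha:hb, , drop = FALSE])
  structure(list(source_id = homolog$source_id, segment_name = segment,
                 seq = paste(homolog$aa[ha:hb], collapse = ""),
                 torsions = tor, n_res = hb - ha + 1L,
                 end_frames = end_frames, src_start = ha, atoms = atoms),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("fragment '%s' segment %s: %d residues\n",
              x$source_id, x$segment_name, x$n_res))
  invisible(x)
}

.fragment_anchor_atoms <- function(frag) {
  do.call(rbind, Filter(Negate(is.null), frag$end_frames))
}

#' Rigidly align fragment ends onto a reference
#'
#' Superposes each fragment's combined anchor backbone atoms (N, CA, C of
#' both end residues; one end for terminal tails) onto the reference
#' fragment's, so that all fragments of a segment have identically positioned
#' ends. Torsions are untouched (rigid-body motion only).
#'
#' @param fragments List of `fragment` objects of one segment.
#' @param reference A `fragment` providing the target end frames.
#' @return The fragments, transformed, each with an `end_align_rmsd` field
#'   (post-transform anchor-atom RMSD in Angstrom).
#' @export
align_fragment_ends <- function(fragments, reference) {
  ref_atoms <- .fragment_anchor_atoms(reference)
  lapply(fragments, function(fr) {
    if (fr$segment_name != reference$segment_name)
      stop("all fragments must belong to the same segment")
    mob <- .fragment_anchor_atoms(fr)
    fit <- kabsch_superpose(mob, ref_atoms)
    fr$atoms <- lapply(fr$atoms, function(m) {
      ok <- stats::complete.cases(m)
      m[ok, ] <- apply_transform(m[ok, , drop = FALSE], fit)
      m
    })
    fr$end_frames <- lapply(fr$end_frames, function(f)
      if (is.null(f)) NULL else apply_transform(f, fit))
    fr$end_align_rmsd <- fit$rmsd
    fr
  })
}

#' Per-position structural deviation across homologs
#'
#' Helper for choosing anchors: after aligning each homolog to the template,
#' reports for every template position the mean CA-CA deviation over the
#' homologs in which that position is mapped. Low-deviation positions mapped
#' in all homologs are good anchor candidates.
#'
#' @param template A `backbone_model`.
#' @param homologs List of `backbone_model` objects.
#' @param scheme A `segmentation_scheme` (used only for its anchors during
#'   alignment; pass a permissive scheme when scanning).
#' @return Data frame with `position`, `mean_dev` (Angstrom), `n_mapped`.
#' @export
anchor_deviation_scan <- function(template, homologs, scheme) {
  n <- n_residues(template)
  dev_sum <- dev_n <- numeric(n)
  for (hom in homologs) {
    aln <- align_to_template(hom, template, scheme)
    moved <- apply_transform(hom$atoms$CA[aln$pairs[, 1], , drop = FALSE],
                             aln$fit)
    d <- sqrt(rowSums((moved -
                       template$atoms$CA[aln$pairs[, 2], , drop = FALSE])^2))
    ti <- aln$pairs[, 2]
    dev_sum[ti] <- dev_sum[ti] + d
    dev_n[ti] <- dev_n[ti] + 1
  }
  data.frame(position = seq_len(n),
             mean_dev = ifelse(dev_n > 0, dev_sum / pmax(dev_n, 1), NA_real_),
             n_mapped = dev_n)
}
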