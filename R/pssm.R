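## Evolutionary sequence constraints: homolog filtering and PSSM
## construction from multiple sequence alignments.

.AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## BLOSUM62 marginal (background) amino-acid frequencies, the standard
## values used by PSI-BLAST-style log-odds scoring.
.BLOSUM62_BG <- c(
  A = 0.0742, R = 0.0516, N = 0.0446, D = 0.0536, C = 0.0247,
  Q = 0.0342, E = 0.0543, G = 0.0741, H = 0.0262, I = 0.0679,
  L = 0.0989, K = 0.0582, M = 0.0250, F = 0.0474, P = 0.0388,
  S = 0.0572, T = 0.0509, W = 0.0131, Y = 0.0321, V = 0.0729)

.SCORE_CAP <- 13L  # half-bit cap guarding log(0) with zero pseudocounts

#' Pairwise identity and coverage of a candidate against a query
#'
#' Global (Needleman-Wunsch) alignment via Biostrings; identity is matches
#' over aligned columns excluding terminal gap blocks, coverage is the
#' fraction of query residues aligned to a candidate residue.
#'
#' @param query,candidate Amino-acid strings.
#' @return Named numeric vector with `identity` and `coverage`.
#' @export
pairwise_identity <- function(query, candidate) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(candidate), Biostrings::AAString(query),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  nongap_p <- which(p != "-"); nongap_s <- which(s != "-")
  core <- max(min(nongap_p), min(nongap_s)):min(max(nongap_p), max(nongap_s))
  matches <- sum(p[core] == s[core] & p[core] != "-")
  ident <- matches / length(core)
  cover <- sum(p != "-" & s != "-") / nchar(query)
  c(identity = ident, coverage = cover)
}

#' Filter homolog sequences by identity and coverage
#'
#' Retains candidates meeting both thresholds against the query (>= in both
#' cases), sorted by identity descending and truncated to `max_sequences`.
#' The defaults are the standard homolog-collection cutoffs: 35 percent
#' identity, 75 percent coverage, top 3,000 sequences.
#'
#' @param query Query (template/design) sequence.
#' @param candidates Character vector of candidate sequences (named or not).
#' @param min_identity Identity threshold in [0,1] (default 0.35).
#' @param min_coverage Coverage threshold in [0,1] (default 0.75).
#' @param max_sequences Maximum retained (default 3000).
#' @return Retained sequences (named character vector) with a `stats`
#'   attribute data frame of identity/coverage for every candidate.
#' @export
filter_homologs <- function(query, candidates, min_identity = 0.35,
                            min_coverage = 0.75, max_sequences = 3000) {
  if (nchar(query) == 0) stop("empty query")
  if (length(candidates) == 0) {
    warning("no candidate sequences supplied")
    out <- character(0)
    attr(out, "stats") <- data.frame(identity = numeric(0),
                                     coverage = numeric(0))
    return(out)
  }
  if (is.null(names(candidates)))
    names(candidates) <- paste0("seq", seq_along(candidates))
  st <- t(vapply(candidates, function(x) pairwise_identity(query, x),
                 c(identity = 0, coverage = 0)))
  keep <- st[, "identity"] >= min_identity & st[, "coverage"] >= min_coverage
  out <- candidates[keep]
  out <- out[order(-st[keep, "identity"], names(out))]
  if (length(out) > max_sequences) out <- out[seq_len(max_sequences)]
  attr(out, "stats") <- data.frame(identity = st[, "identity"],
                                   coverage = st[, "coverage"],
                                   retained = names(candidates) %in% names(out))
  out
}

#' Construct an MSA object
#'
#' @param rows Character vector of equal-length aligned sequences
#'   (20 amino acids plus '-').
#' @param names Sequence names.
#' @param reference_row Index of the template/design sequence (no ambiguous
#'   characters allowed in it).
#' @return Object of class `msa`.
#' @export
msa <- function(rows, names = paste0("seq", seq_along(rows)),
                reference_row = 1) {
  rows <- unname(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("all MSA rows must have equal length")
  ref <- rows[reference_row]
  if (grepl("[^ARNDCQEGHILKMFPSTWYV-]", ref))
    stop("reference row contains ambiguous characters")
  structure(list(rows = rows, names = names,
                 reference_row = as.integer(reference_row), width = w),
            class = "msa")
}

#' Read an aligned FASTA file as an MSA
#'
#' @param path Aligned FASTA file.
#' @param reference_row Index of the reference sequence (default 1).
#' @return An `msa`.
#' @export
read_msa <- function(path, reference_row = 1) {
  ss <- Biostrings::readAAStringSet(path)
  msa(as.character(ss), names = names(ss), reference_row = reference_row)
}

#' Write an MSA as aligned FASTA
#' @param x An `msa`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa <- function(x, path) {
  writeLines(as.vector(rbind(paste0(">", x$names), x$rows)), path)
  invisible(path)
}

## Position-based (Henikoff-Henikoff) sequence weights. Gap symbols
## contribute nothing.
.henikoff_weights <- function(mat) {
  n <- nrow(mat)
  w <- numeric(n)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    obs <- col[col != "-"]
    if (length(obs) == 0) next
    tab <- table(obs)
    r <- length(tab)
    idx <- which(col != "-")
    w[idx] <- w[idx] + 1 / (r * as.numeric(tab[col[idx]]))
  }
  if (sum(w) == 0) rep(1 / n, n) else w / sum(w)
}

#' Build a position-specific scoring matrix from an MSA
#'
#' Per ungapped reference position: weighted residue frequencies (position-
#' based Henikoff-Henikoff sequence weights), mixed with BLOSUM62 marginal
#' background frequencies via `pseudocount_weight` effective pseudocounts,
#' scored as half-bit log-odds `2*log2(p/bg)` rounded to integer and capped
#' at +/-13 (which also guards the zero-frequency, zero-pseudocount case).
#'
#' @param x An `msa`.
#' @param pseudocount_weight Effective pseudocount observations (default 50).
#' @return Object of class `pssm`: integer matrix positions x 20 (columns in
#'   the order A R N D C Q E G H I L K M F P S T W Y V), with attributes
#'   `ref_seq` (ungapped reference) and `positions`.
#' @export
build_pssm <- function(x, pseudocount_weight = 50) {
  stopifnot(inherits(x, "msa"))
  mat <- do.call(rbind, strsplit(x$rows, ""))
  ref <- mat[x$reference_row, ]
  ref_cols <- which(ref != "-")
  if (length(ref_cols) == 0) stop("reference row is all gaps")
  w <- .henikoff_weights(mat)
  n_obs <- nrow(mat)
  B <- pseudocount_weight
  scores <- matrix(0L, length(ref_cols), 20,
                   dimnames = list(NULL, .AA_ORDER))
  for (k in seq_along(ref_cols)) {
    col <- mat[, ref_cols[k]]
    use <- col != "-" & col %in% .AA_ORDER
    f <- stats::setNames(numeric(20), .AA_ORDER)
    if (any(use))
      for (i in which(use)) f[col[i]] <- f[col[i]] + w[i] / sum(w[use])
    p <- (n_obs * f + B * .BLOSUM62_BG) / (n_obs + B)
    sc <- ifelse(p > 0, 2 * log2(p / .BLOSUM62_BG), -Inf)
    sc <- pmin(pmax(round(sc), -.SCORE_CAP), .SCORE_CAP)
    scores[k, ] <- as.integer(sc)
  }
  structure(scores, ref_seq = paste(ref[ref_cols], collapse = ""),
            positions = seq_along(ref_cols), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("pssm: %d positions x 20 residues (ref %s...)\n", nrow(x),
              substr(attr(x, "ref_seq"), 1, 12)))
  invisible(x)
}

#' Slice a PSSM
#'
#' Rows `start .. start+n-1` (1-based reference positions), renumbered 1..n.
#'
#' @param pssm A `pssm`.
#' @param start First reference position of the slice.
#' @param n Number of positions.
#' @return A `pssm` of `n` rows.
#' @export
slice_pssm <- function(pssm, start, n) {
  if (start < 1 || start + n - 1 > nrow(pssm))
    stop("slice [", start, ", ", start + n - 1, "] out of PSSM range 1..",
         nrow(pssm))
  rows <- start:(start + n - 1)
  structure(unclass(pssm)[rows, , drop = FALSE],
            ref_seq = substr(attr(pssm, "ref_seq"), start, start + n - 1),
            positions = seq_len(n), class = "pssm")
}

#' Concatenate PSSM slices
#' @param ... `pssm` objects in order.
#' @return A single `pssm`, positions renumbered consecutively.
#' @export
concat_pssm <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !inherits(parts[[1]], "pssm"))
    parts <- parts[[1]]
  m <- do.call(rbind, lapply(parts, unclass))
  structure(m, ref_seq = paste(vapply(parts, function(p) attr(p, "ref_seq"), ""),
                               collapse = ""),
            positions = seq_len(nrow(m)), class = "pssm")
}

#' Residues allowed at a position
#'
#' Residues scoring at least `threshold` at the given position; rarely
#' observed residues (below threshold) are thereby eliminated from the
#' design alphabet. Never empty: if nothing passes, the single best-scoring
#' residue is returned with a warning.
#'
#' @param pssm A `pssm`.
#' @param position Reference position (1-based).
#' @param threshold Minimum half-bit score (default 0).
#' @return Character vector of one-letter residues.
#' @export
allowed_residues <- function(pssm, position, threshold = 0) {
  if (position < 1 || position > nrow(pssm)) stop("position out of range")
  row <- unclass(pssm)[position, ]
  out <- names(row)[row >= threshold]
  if (length(out) == 0) {
    warning("no residue reaches threshold ", threshold, " at position ",
            position, "; returning the best-scoring residue")
    out <- names(row)[which.max(row)]
  }
  out
}

#' Write a PSSM in PSI-BLAST ASCII form
#'
#' Header row with the 20-letter alphabet, then one row per position:
#' index, reference residue, 20 integer scores.
#'
#' @param pssm A `pssm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pssm <- function(pssm, path) {
  ref <- strsplit(attr(pssm, "ref_seq"), "")[[1]]
  hdr <- paste0("    ", paste(sprintf("%3s", .AA_ORDER), collapse = ""))
  rows <- vapply(seq_len(nrow(pssm)), function(i)
    paste0(sprintf("%4d %1s", i, ref[i]),
           paste(sprintf("%3d", unclass(pssm)[i, ]), collapse = "")), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Accepts the dialect written by [write_pssm()] and the PSI-BLAST
#' `-out_ascii_pssm` layout (the first 20 score columns are used).
#'
#' @param path Input path.
#' @return A `pssm`.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_i <- grep("^\\s*A\\s+R\\s+N\\s+D", lines)[1]
  if (is.na(hdr_i)) stop("no PSSM alphabet header found in ", path)
  body <- lines[-seq_len(hdr_i)]
  body <- body[grepl("^\\s*\\d+\\s+[A-Z]", body)]
  parts <- strsplit(trimws(body), "\\s+")
  ref <- vapply(parts, `[`, "", 2)
  sc <- t(vapply(parts, function(p) as.integer(p[3:22]), integer(20)))
  colnames(sc) <- .AA_ORDER
  structure(sc, ref_seq = paste(ref, collapse = ""),
            positions = seq_len(nrow(sc)), class = "pssm")
}
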