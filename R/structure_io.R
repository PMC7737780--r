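## Backbone models: PDB input/output, torsion extraction, and idealized
## reconstruction from torsions. The torsion-space contract of the whole
## pipeline lives here: every design operation downstream manipulates
## phi/psi/omega only, and coordinates are regenerated with ideal bond
## lengths and angles.

#' Construct a backbone model
#'
#' The central container of the package: an ordered single-chain protein
#' backbone with per-residue N, CA, C (O and CB optional) coordinates.
#'
#' @param source_id Identifier of the originating structure or fixture.
#' @param aa Character vector of one-letter amino-acid codes ('X' for
#'   nonstandard residues).
#' @param atoms Named list of n x 3 coordinate matrices; must contain
#'   `N`, `CA`, `C`; may contain `O` and `CB` (rows of NA where absent).
#' @param chain Chain identifier (single chain per model).
#' @param seqnum Author residue numbers (defaults to 1..n).
#' @param icode Insertion codes (defaults to "").
#' @param breaks Integer indices i marking a chain discontinuity between
#'   residues i and i+1. If `NULL`, detected from the peptide C-N distance
#'   criterion (outside [1.2, 1.5] Angstrom).
#' @return Object of class `backbone_model`.
#' @export
backbone_model <- function(source_id, aa, atoms, chain = "A",
                           seqnum = seq_along(aa), icode = rep("", length(aa)),
                           breaks = NULL) {
  n <- length(aa)
  stopifnot(n >= 1, all(c("N", "CA", "C") %in% names(atoms)))
  for (nm in names(atoms)) {
    atoms[[nm]] <- as.matrix(atoms[[nm]])
    if (nrow(atoms[[nm]]) != n)
      stop("atom matrix '", nm, "' must have one row per residue")
  }
  if (!all(is.finite(atoms$N)) || !all(is.finite(atoms$CA)) || !all(is.finite(atoms$C)))
    stop("N/CA/C coordinates must be finite for every residue")
  if (is.null(atoms$O)) atoms$O <- matrix(NA_real_, n, 3)
  m <- structure(
    list(source_id = source_id, aa = aa, chain = chain,
         seqnum = as.integer(seqnum), icode = icode, atoms = atoms,
         breaks = integer(0)),
    class = "backbone_model")
  m$breaks <- if (is.null(breaks)) detect_breaks(m) else sort(unique(as.integer(breaks)))
  m
}

#' @export
print.backbone_model <- function(x, ...) {
  cat(sprintf("backbone_model '%s': %d residues, chain %s, %d break(s)\n",
              x$source_id, length(x$aa), x$chain, length(x$breaks)))
  invisible(x)
}

#' Number of residues in a backbone model
#' @param model A `backbone_model`.
#' @return Integer residue count.
#' @export
n_residues <- function(model) length(model$aa)

#' Detect chain discontinuities
#'
#' A peptide bond between residues i and i+1 is intact when the C(i)-N(i+1)
#' distance lies in [1.2, 1.5] Angstrom; anything else marks a break.
#'
#' @param model A `backbone_model`.
#' @return Integer vector of break indices (break between i and i+1).
#' @export
detect_breaks <- function(model) {
  n <- n_residues(model)
  if (n < 2) return(integer(0))
  d <- sqrt(rowSums((model$atoms$C[-n, , drop = FALSE] -
                     model$atoms$N[-1, , drop = FALSE])^2))
  which(d < 1.2 | d > 1.5)
}

#' Read a single protein chain from a PDB file
#'
#' Parses ATOM records (HETATM ignored) for one chain, resolving alternate
#' locations by highest occupancy (ties broken in favor of altloc 'A').
#' Residues missing any of N, CA, C are dropped with a warning and a chain
#' break is recorded at the gap; breaks are additionally detected from the
#' peptide C-N distance criterion.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier. May be omitted only for single-chain files;
#'   for multi-chain files an error lists the available chains.
#' @return A `backbone_model`.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  chains <- sort(unique(at$chain))
  if (is.null(chain)) {
    if (length(chains) > 1)
      stop("multiple chains present; specify one of: ", paste(chains, collapse = ", "))
    chain <- chains[1]
  }
  if (!chain %in% chains)
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  rid <- paste(at$resno, at$insert, sep = "|")
  res_ids <- unique(rid)  # file order

  want <- c("N", "CA", "C", "O", "CB")
  n <- length(res_ids)
  atoms <- lapply(want, function(x) matrix(NA_real_, n, 3))
  names(atoms) <- want
  aa <- character(n); seqnum <- integer(n); icode <- character(n)
  for (i in seq_len(n)) {
    rows <- at[rid == res_ids[i], , drop = FALSE]
    aa[i] <- suppressWarnings(bio3d::aa321(rows$resid[1]))
    if (is.na(aa[i]) || !aa[i] %in% c(LETTERS)) aa[i] <- "X"
    seqnum[i] <- rows$resno[1]; icode[i] <- rows$insert[1]
    for (nm in intersect(want, unique(rows$elety))) {
      cand <- rows[rows$elety == nm, , drop = FALSE]
      # altloc rule: highest occupancy wins; ties resolved toward 'A'
      cand <- cand[order(-cand$o, cand$alt), , drop = FALSE]
      atoms[[nm]][i, ] <- as.numeric(cand[1, c("x", "y", "z")])
    }
  }

  complete <- !is.na(atoms$N[, 1]) & !is.na(atoms$CA[, 1]) & !is.na(atoms$C[, 1])
  if (any(!complete)) {
    warning("dropping ", sum(!complete), " residue(s) missing N/CA/C in ",
            basename(path), " chain ", chain,
            " (residues ", paste(seqnum[!complete], collapse = ","), ")")
    keep <- which(complete)
    aa <- aa[keep]; seqnum <- seqnum[keep]; icode <- icode[keep]
    atoms <- lapply(atoms, function(m) m[keep, , drop = FALSE])
  }
  if (length(aa) == 0) stop("no complete residues for chain ", chain)
  backbone_model(source_id = sub("\\.pdb$", "", basename(path)),
                 aa = aa, atoms = atoms, chain = chain,
                 seqnum = seqnum, icode = icode)
}

#' Extract backbone torsions
#'
#' Computes phi, psi, omega for every residue by the standard four-atom
#' convention: phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) = N(i)-CA(i)-C(i)-N(i+1),
#' omega(i) = CA(i)-C(i)-N(i+1)-CA(i+1). Angles are IUPAC-signed degrees in
#' (-180, 180]. phi is undefined (NA) at the first residue, psi and omega at
#' the last, and any torsion spanning a recorded chain break is NA.
#'
#' @param model A `backbone_model` with at least 2 residues.
#' @return Data frame with columns `phi`, `psi`, `omega`, one row per residue.
#' @export
extract_torsions <- function(model) {
  n <- n_residues(model)
  if (n < 2) stop("need at least 2 residues to define torsions")
  N <- model$atoms$N; CA <- model$atoms$CA; C <- model$atoms$C
  phi <- psi <- omega <- rep(NA_real_, n)
  brk <- model$breaks
  for (i in seq_len(n)) {
    if (i > 1 && !((i - 1) %in% brk))
      phi[i] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < n && !(i %in% brk)) {
      psi[i]   <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
      omega[i] <- dihedral_angle(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ])
    }
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}

.default_anchor_frame <- function() {
  g <- ideal_geometry()
  th <- .deg2rad(g$a_n_ca_c)
  rbind(N  = c(0, 0, 0),
        CA = c(g$b_n_ca, 0, 0),
        C  = c(g$b_n_ca - g$b_ca_c * cos(th), g$b_ca_c * sin(th), 0))
}

## Virtual CB from backbone frame (standard L-chirality construction).
.place_cb <- function(N, CA, C) {
  b <- CA - N; cc <- C - CA; a <- .cross3(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + CA
}

#' Rebuild an idealized backbone from torsions
#'
#' Sequential natural-extension-of-reference-frame (NeRF) construction with
#' fixed ideal bond lengths and angles (see [ideal_geometry()]). The result
#' is the idealized-geometry model of the input torsion string:
#' [extract_torsions()] on the output reproduces the input to within
#' numerical precision. Carbonyl O is placed anti to the next residue's N;
#' CB is placed with standard L-chirality for all residues except glycine.
#'
#' @param torsions Data frame with `phi`, `psi`, `omega` columns (degrees);
#'   NA allowed only where chain ends leave an angle undefined.
#' @param seq Amino-acid string or character vector, same length as torsions.
#' @param anchor_frame Optional 3 x 3 matrix (rows N, CA, C of the first
#'   residue) placing the chain in space; identity frame if omitted.
#' @param source_id Identifier for the resulting model.
#' @return A `backbone_model` with no breaks.
#' @export
rebuild_backbone <- function(torsions, seq, anchor_frame = NULL,
                             source_id = "rebuilt") {
  if (is.character(seq) && length(seq) == 1) seq <- strsplit(seq, "")[[1]]
  n <- nrow(torsions)
  if (length(seq) != n) stop("seq and torsions must have the same length")
  if (n < 1) stop("empty torsion list")
  if (n > 1) {
    if (any(is.na(torsions$phi[-1])))
      stop("undefined interior phi torsion")
    if (any(is.na(torsions$psi[-n])) || any(is.na(torsions$omega[-n])))
      stop("undefined interior psi/omega torsion")
  }
  g <- ideal_geometry()
  if (is.null(anchor_frame)) anchor_frame <- .default_anchor_frame()
  anchor_frame <- as.matrix(anchor_frame)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- anchor_frame[1, ]; CA[1, ] <- anchor_frame[2, ]; C[1, ] <- anchor_frame[3, ]
  for (i in seq_len(n)[-1]) {
    N[i, ]  <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          g$b_c_n, g$a_ca_c_n, torsions$psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, torsions$omega[i - 1])
    C[i, ]  <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                          g$b_ca_c, g$a_n_ca_c, torsions$phi[i])
  }
  for (i in seq_len(n)) {
    o_tor <- if (!is.na(torsions$psi[i])) torsions$psi[i] + 180 else 180
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, o_tor)
    if (seq[i] != "G") CB[i, ] <- .place_cb(N[i, ], CA[i, ], C[i, ])
  }
  backbone_model(source_id = source_id, aa = seq,
                 atoms = list(N = N, CA = CA, C = C, O = O, CB = CB),
                 breaks = integer(0))
}

#' Write a backbone model as a PDB file
#'
#' Emits fixed-width ATOM records (coordinates to 3 decimals) with a TER
#' record at every recorded chain break and at chain end. Atoms with missing
#' coordinates are skipped.
#'
#' @param model A `backbone_model` with at least one residue.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(model, path) {
  if (n_residues(model) == 0) stop("cannot write an empty model")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  lines <- character(0)
  aa3 <- vapply(model$aa, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r) || nchar(r) != 3) "UNK" else r
  }, "")
  order_names <- c("N", "CA", "C", "O", "CB")
  for (i in seq_len(n_residues(model))) {
    for (nm in order_names) {
      xyz <- model$atoms[[nm]]
      if (is.null(xyz) || any(is.na(xyz[i, ]))) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, aa3[i], model$chain, model$seqnum[i],
        ifelse(model$icode[i] == "", " ", model$icode[i]),
        xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 0.0, substr(nm, 1, 1)))
    }
    if (i %in% model$breaks) {
      serial <- serial + 1L
      lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                                serial, aa3[i], model$chain, model$seqnum[i]))
    }
  }
  serial <- serial + 1L
  n <- n_residues(model)
  lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                            serial, aa3[n], model$chain, model$seqnum[n]), "END")
  writeLines(lines, con)
  invisible(path)
}
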