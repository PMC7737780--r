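## Combinatorial backbone assembly: recipe enumeration/sampling, per-segment
## torsion grafting onto the template, PSSM recomposition, catalytic-residue
## fixation check, and a simplified steric clash screen.

#' Number of unique assemblies a database supports
#'
#' Product over segments of the accepted-fragment counts (e.g. 20 accepted
#' fragments in each of 4 segments give 20^4 = 160,000 unique backbones).
#'
#' @param db A `fragment_database`.
#' @return Numeric count (may exceed integer range).
#' @export
count_assemblies <- function(db) {
  counts <- vapply(db$scheme$segments$name,
                   function(s) length(accepted_records(db, s)), 1L)
  if (any(counts == 0))
    stop("segment(s) with no accepted fragments: ",
         paste(db$scheme$segments$name[counts == 0], collapse = ", "))
  prod(as.numeric(counts))
}

#' Enumerate or sample assembly recipes
#'
#' If the database supports at most `n` assemblies, all recipes are returned
#' in lexicographic order (first segment most significant). Otherwise `n`
#' recipes are drawn uniformly without replacement from the mixed-radix
#' recipe index space under the given seed.
#'
#' @param db A `fragment_database`.
#' @param n Maximum number of recipes.
#' @param seed Integer seed for the sampling branch.
#' @return List of recipes; each recipe is a named integer vector mapping
#'   segment name to an accepted-fragment index.
#' @export
enumerate_or_sample <- function(db, n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  segs <- db$scheme$segments$name
  counts <- vapply(segs, function(s) length(accepted_records(db, s)), 1L)
  if (any(counts == 0))
    stop("segment(s) with no accepted fragments: ",
         paste(segs[counts == 0], collapse = ", "))
  total <- prod(as.numeric(counts))
  decode <- function(idx0) {
    out <- integer(length(counts))
    for (k in rev(seq_along(counts))) {
      out[k] <- (idx0 %% counts[k]) + 1
      idx0 <- idx0 %/% counts[k]
    }
    stats::setNames(as.integer(out), segs)
  }
  if (total <= n) {
    return(lapply(0:(total - 1), decode))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- sample.int(total, n) - 1
  lapply(idx, decode)
}

#' Assemble a design candidate from a recipe
#'
#' Applies the recipe segment by segment in N-to-C order: each chosen
#' fragment is grafted and closed in the current model context (see
#' [graft_and_close()]); segments assigned `"template"` are left untouched.
#' The composed PSSM takes each designed position's row from the chosen
#' fragment's source PSSM, with shared boundary anchors contributed by the
#' left segment.
#'
#' @param template An idealized `backbone_model`.
#' @param db A `fragment_database` built on the same template and scheme.
#' @param recipe Named vector mapping each segment name to an
#'   accepted-fragment index or the string `"template"`.
#' @param scheme The `segmentation_scheme` (defaults to the database's).
#' @param pssms Optional named list of `pssm` objects keyed by source id
#'   (must include the template's) for PSSM composition.
#' @param gate,... Passed to the per-segment graft/close.
#' @return Object of class `design_candidate`: `recipe`, `model`, `pssm`,
#'   `closure_rmsds`, `template_map` (template residue to model residue,
#'   NA inside replaced segments), `catalytic_ok` (NA until checked),
#'   `steric_score` (NA until screened), `feature_values`, `failed`.
#' @export
assemble <- function(template, db, recipe, scheme = db$scheme, pssms = NULL,
                     gate = db$gate, ...) {
  segs <- scheme$segments
  if (!setequal(names(recipe), segs$name))
    stop("recipe must name every segment of the scheme exactly once")
  cur <- idealize_model(template)
  L <- n_residues(cur)
  tmap <- seq_len(L)
  bounds <- segs[, c("start", "end")]
  closure_rmsds <- stats::setNames(rep(NA_real_, nrow(segs)), segs$name)
  failed <- NULL
  chosen <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs$name[i]
    ch <- recipe[[s]]
    if (identical(ch, "template")) { chosen[[s]] <- "template"; next }
    recs <- accepted_records(db, s)
    ch <- as.integer(ch)
    if (ch < 1 || ch > length(recs))
      stop("recipe index ", ch, " out of range for segment ", s)
    frag <- recs[[ch]]$fragment
    chosen[[s]] <- frag
    sa <- bounds$start[i]; ea <- bounds$end[i]
    rec <- .graft_close_at(cur, frag, sa, ea, segs$type[i], gate = gate, ...)
    closure_rmsds[s] <- rec$closure_rmsd
    # a graft that cannot close, or closes only by deforming beyond the
    # database gate, fails the whole candidate
    if (!is.finite(rec$closure_rmsd) || rec$closure_rmsd >= gate) {
      failed <- s
      break
    }
    cur <- rec$model
    m <- frag$n_res
    delta <- m - (ea - sa + 1L)
    # template residues strictly inside the replaced span lose their image;
    # residues from the end anchor on shift by the length difference
    t_sa <- segs$start[i]; t_ea <- segs$end[i]
    if (t_ea - t_sa > 1) tmap[(t_sa + 1):(t_ea - 1)] <- NA_integer_
    if (delta != 0) {
      later <- which(!is.na(tmap) & seq_along(tmap) >= t_ea)
      tmap[later] <- tmap[later] + delta
      later_segs <- seq_len(nrow(segs)) > i
      bounds$start[later_segs] <- bounds$start[later_segs] + delta
      bounds$end[later_segs] <- bounds$end[later_segs] + delta
    }
  }
  comp_pssm <- NULL
  if (!is.null(pssms) && is.null(failed)) {
    tpssm <- pssms[[template$source_id]]
    if (is.null(tpssm)) stop("pssms must include the template's PSSM under '",
                             template$source_id, "'")
    slices <- list()
    for (i in seq_len(nrow(segs))) {
      s <- segs$name[i]
      if (identical(chosen[[s]], "template")) {
        sl <- slice_pssm(tpssm, segs$start[i], segs$end[i] - segs$start[i] + 1L)
      } else {
        frag <- chosen[[s]]
        sp <- pssms[[frag$source_id]]
        if (is.null(sp)) stop("no PSSM supplied for source '",
                              frag$source_id, "'")
        sl <- slice_pssm(sp, frag$src_start, frag$n_res)
      }
      if (i > 1) sl <- slice_pssm(sl, 2, nrow(sl) - 1L)  # shared anchor: left wins
      slices[[i]] <- sl
    }
    comp_pssm <- concat_pssm(slices)
    if (nrow(comp_pssm) != n_residues(cur))
      stop("composed PSSM rows (", nrow(comp_pssm),
           ") do not match model length (", n_residues(cur), ")")
  }
  structure(list(recipe = recipe, model = cur, pssm = comp_pssm,
                 closure_rmsds = closure_rmsds, template_map = tmap,
                 catalytic_ok = NA, steric_score = NA_real_,
                 feature_values = numeric(0), failed = failed),
            class = "design_candidate")
}

#' @export
print.design_candidate <- function(x, ...) {
  ch <- vapply(names(x$recipe), function(s) as.character(x$recipe[[s]]), "")
  cat(sprintf("design_candidate [%s]: %d residues%s\n",
              paste(paste0(names(x$recipe), "=", ch), collapse = ", "),
              n_residues(x$model),
              if (!is.null(x$failed)) paste0(" FAILED at ", x$failed) else ""))
  invisible(x)
}

#' Check catalytic-residue fixation
#'
#' Superposes the candidate onto the template via the backbone atoms of the
#' scheme anchors (the framework positions present in every assembly), then
#' verifies that every constrained residue's N/CA/C atoms lie within
#' `tolerance` of their template positions. The result is recorded in the
#' candidate's `catalytic_ok`.
#'
#' @param candidate A `design_candidate`.
#' @param template The idealized template `backbone_model`.
#' @param positions Template residue indices of the catalytic residues.
#' @param scheme The `segmentation_scheme`.
#' @param tolerance Angstrom (default 0.5).
#' @return The candidate with `catalytic_ok` set (attribute `reason` on
#'   failure).
#' @export
check_catalytic <- function(candidate, template, positions, scheme,
                            tolerance = 0.5) {
  tmap <- candidate$template_map
  reason <- NULL
  q <- tmap[positions]
  if (any(is.na(q))) {
    candidate$catalytic_ok <- FALSE
    attr(candidate$catalytic_ok, "reason") <-
      paste("constrained position(s) removed by assembly:",
            paste(positions[is.na(q)], collapse = ", "))
    return(candidate)
  }
  anch_t <- scheme$anchors
  anch_c <- tmap[anch_t]
  stack <- function(model, idx)
    do.call(rbind, lapply(idx, function(i)
      rbind(model$atoms$N[i, ], model$atoms$CA[i, ], model$atoms$C[i, ])))
  fit <- kabsch_superpose(stack(candidate$model, anch_c), stack(template, anch_t))
  moved <- apply_transform(stack(candidate$model, q), fit)
  ref <- stack(template, positions)
  dev <- sqrt(rowSums((moved - ref)^2))
  ok <- all(dev <= tolerance)
  candidate$catalytic_ok <- ok
  if (!ok)
    attr(candidate$catalytic_ok, "reason") <-
      sprintf("max backbone deviation %.2f A exceeds %.2f A", max(dev), tolerance)
  candidate
}

#' Count steric clashes in a backbone model
#'
#' Number of backbone/CB atom pairs from residues at sequence separation of
#' at least 3 that lie closer than `cutoff`. A deliberately simple
#' feasibility filter, not an energy.
#'
#' @param x A `design_candidate` or `backbone_model`.
#' @param cutoff Clash distance in Angstrom (default 2.5).
#' @return Integer clash count (also stored in the candidate when one is
#'   given; in that case the updated candidate is returned invisibly via
#'   attribute).
#' @export
steric_screen <- function(x, cutoff = 2.5) {
  model <- if (inherits(x, "design_candidate")) x$model else x
  coords <- NULL; res <- NULL
  for (nm in c("N", "CA", "C", "O", "CB")) {
    m <- model$atoms[[nm]]
    if (is.null(m)) next
    ok <- stats::complete.cases(m)
    coords <- rbind(coords, m[ok, , drop = FALSE])
    res <- c(res, which(ok))
  }
  n <- nrow(coords)
  if (n < 2) return(0L)
  d <- as.matrix(stats::dist(coords))
  sep <- abs(outer(res, res, "-"))
  clash <- d < cutoff & sep >= 3
  as.integer(sum(clash[upper.tri(clash)]))
}
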