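## End-to-end orchestration: simulate or load a family, build and cluster
## the fragment database, derive PSSM constraints, assemble candidates,
## screen and rank them, and write a self-describing output manifest.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], populated
#' with the pipeline's standard defaults: closure gate 0.2 Angstrom,
#' cluster radius 1.0 Angstrom, homolog filters 35 percent identity /
#' 75 percent coverage / top 3000, pseudocount weight 50.
#'
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @return Named list of configuration values; override fields as needed.
#' @export
pipeline_config <- function(out_dir = "fragstitch_run", seed = 1) {
  list(
    out_dir = out_dir, seed = seed,
    simulate = list(n_structures = 8, n_segments = 2,
                    loop_length_range = c(12, 16), n_groups = 3,
                    torsion_noise = 2),
    template_pdb = NULL, homolog_pdbs = NULL, chain = NULL, anchors = NULL,
    gate = 0.2, cluster_radius = 1.0,
    min_identity = 0.35, min_coverage = 0.75, max_sequences = 3000,
    pseudocount_weight = 50,
    n_assemblies = 20, catalytic = NULL, catalytic_tolerance = 0.5,
    clash_cutoff = 2.5, rank_mode = "fuzzy")
}

.config_hash <- function(config) {
  config$out_dir <- NULL  # the scientific configuration, not the destination
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  sprintf("%08x", sum(utf8ToInt(js) * (seq_len(nchar(js)) %% 251)) %% 4294967296)
}

#' Run the full assembly-and-design pipeline
#'
#' Executes segment -> build-db -> cluster -> pssm -> assemble -> rank on
#' either a simulated toy family (`config$simulate`) or user-supplied PDB
#' files plus anchors. Every stage's outputs land under `config$out_dir`;
#' a manifest TSV lists them, and each header carries the config hash so a
#' rerun with the same configuration is bit-identical.
#'
#' @param config List as produced by [pipeline_config()].
#' @return Invisibly, a list with the manifest data frame and the main
#'   in-memory products (db, pssms, candidates, ranking report).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  manifest <- list()
  emit <- function(stage, file) manifest[[length(manifest) + 1]] <<-
    data.frame(stage = stage, output = file)
  logf <- file.path(config$out_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon), add = TRUE)
  say <- function(...) writeLines(paste0(...), logcon)
  say("fragstitch pipeline, config ", hash, ", seed ", config$seed)

  # --- inputs: simulate or load ------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    fam <- make_toy_family(n_structures = sim$n_structures,
                           n_segments = sim$n_segments,
                           loop_length_range = sim$loop_length_range,
                           n_groups = sim$n_groups,
                           torsion_noise = sim$torsion_noise,
                           seed = config$seed,
                           dir = file.path(config$out_dir, "structures"))
    template <- fam$template; homologs <- fam$homologs; scheme <- fam$scheme
    catalytic <- if (is.null(config$catalytic)) fam$ground_truth$catalytic else
      config$catalytic
    for (f in fam$files) emit("simulate", f)
    say("simulated family: ", length(homologs), " homologs, ",
        nrow(scheme$segments), " segments")
  } else {
    if (is.null(config$template_pdb) || is.null(config$anchors))
      stop("stage segment: need template_pdb and anchors (or simulate)")
    template <- idealize_model(read_pdb(config$template_pdb, config$chain))
    homologs <- lapply(config$homolog_pdbs, read_pdb, chain = config$chain)
    homologs <- lapply(homologs, idealize_model)
    scheme <- segmentation_scheme(template$source_id, config$anchors,
                                  n_residues(template))
    catalytic <- config$catalytic
  }

  # --- build-db -----------------------------------------------------------
  db <- build_fragment_db(template, homologs, scheme, gate = config$gate)
  if (!is.null(db$log)) {
    logfile <- file.path(config$out_dir, "db_build_log.tsv")
    .write_tsv(db$log, logfile, hash)
    emit("build-db", logfile)
  }
  counts <- vapply(scheme$segments$name,
                   function(s) length(accepted_records(db, s)), 1L)
  say("db: accepted per segment: ",
      paste(scheme$segments$name, counts, sep = "=", collapse = ", "))
  if (any(counts == 0))
    stop("stage assemble: segment(s) without accepted fragments: ",
         paste(scheme$segments$name[counts == 0], collapse = ", "))

  # --- cluster ------------------------------------------------------------
  db <- reduce_to_representatives(db, radius = config$cluster_radius)
  cl_rows <- do.call(rbind, lapply(names(db$clusters), function(s) {
    ca <- db$clusters[[s]]
    data.frame(segment = s, fragment = seq_along(ca$labels),
               cluster = ca$labels,
               representative = seq_along(ca$labels) %in% ca$representatives)
  }))
  clfile <- file.path(config$out_dir, "clusters.tsv")
  .write_tsv(cl_rows, clfile, hash)
  emit("cluster", clfile)
  dbdir <- file.path(config$out_dir, "fragment_db")
  save_db(db, dbdir, created = hash)
  emit("build-db", file.path(dbdir, "metadata.json"))

  # --- pssm ---------------------------------------------------------------
  tseq <- .seq_string(template)
  cand_seqs <- stats::setNames(vapply(homologs, .seq_string, ""),
                               vapply(homologs, function(m) m$source_id, ""))
  kept <- filter_homologs(tseq, cand_seqs, config$min_identity,
                          config$min_coverage, config$max_sequences)
  say("pssm: ", length(kept), " of ", length(cand_seqs),
      " homolog sequences retained")
  rows <- c(tseq, unname(.pad_to(kept, tseq)))
  fam_msa <- msa(rows, names = c(template$source_id, names(kept)))
  pssm_t <- build_pssm(fam_msa, config$pseudocount_weight)
  pssm_file <- file.path(config$out_dir, "template.pssm")
  write_pssm(pssm_t, pssm_file)
  emit("pssm", pssm_file)
  pssms <- stats::setNames(list(pssm_t), template$source_id)
  for (m in c(list(template), homologs))
    if (is.null(pssms[[m$source_id]]))
      pssms[[m$source_id]] <- .source_pssm(m, config$pseudocount_weight)

  # --- assemble -----------------------------------------------------------
  recipes <- enumerate_or_sample(db, config$n_assemblies, seed = config$seed)
  candidates <- list()
  for (r in recipes) {
    cand <- assemble(template, db, r, pssms = pssms)
    if (!is.null(cand$failed)) { say("assembly failed at ", cand$failed); next }
    if (!is.null(catalytic))
      cand <- check_catalytic(cand, template, catalytic, scheme,
                              config$catalytic_tolerance)
    cand$steric_score <- steric_screen(cand, config$clash_cutoff)
    cand$feature_values <- c(clashes = cand$steric_score,
                             closure = max(cand$closure_rmsds, na.rm = TRUE))
    candidates[[length(candidates) + 1]] <- cand
  }
  say("assembled ", length(candidates), " candidates")
  pdb_dir <- file.path(config$out_dir, "designs")
  dir.create(pdb_dir, showWarnings = FALSE)
  man_rows <- list()
  for (k in seq_along(candidates)) {
    f <- file.path(pdb_dir, sprintf("design_%03d.pdb", k))
    write_pdb(candidates[[k]]$model, f)
    man_rows[[k]] <- data.frame(
      design = sprintf("design_%03d", k),
      recipe = .recipe_key(candidates[[k]]),
      catalytic_ok = isTRUE(candidates[[k]]$catalytic_ok),
      clashes = candidates[[k]]$steric_score,
      max_closure_rmsd = max(candidates[[k]]$closure_rmsds, na.rm = TRUE))
  }
  manfile <- file.path(config$out_dir, "designs.tsv")
  .write_tsv(do.call(rbind, man_rows), manfile, hash)
  emit("assemble", manfile)

  # --- rank ---------------------------------------------------------------
  crits <- list(criterion("clashes", "desirable"),
                criterion("closure", "desirable"))
  # a criterion that is constant over the ensemble carries no information
  # (and has sigma 0); drop it before ranking
  crits <- Filter(function(cr) {
    v <- vapply(candidates, function(cand) cand$feature_values[cr$name], 0)
    length(unique(v[is.finite(v)])) >= 2
  }, crits)
  rfile <- file.path(config$out_dir, "ranking.tsv")
  if (length(crits) > 0) {
    ranked <- rank_designs(candidates, mode = config$rank_mode,
                           criteria = crits)
    .write_tsv(attr(ranked, "report"), rfile, hash)
  } else {
    ranked <- candidates
    say("all criteria constant over the ensemble; emitting unranked report")
    .write_tsv(data.frame(recipe = vapply(candidates, .recipe_key, ""),
                          objective = NA_real_), rfile, hash)
  }
  emit("rank", rfile)

  mandf <- do.call(rbind, manifest)
  .write_tsv(mandf, file.path(config$out_dir, "manifest.tsv"), hash)
  say("done")
  invisible(list(manifest = mandf, db = db, pssms = pssms,
                 candidates = candidates, ranked = ranked,
                 template = template, scheme = scheme))
}

.write_tsv <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Pad retained homolog sequences to the reference length (the toy filter
## path has no indels; real inputs should supply an aligned MSA instead).
.pad_to <- function(seqs, ref) {
  L <- nchar(ref)
  vapply(seqs, function(s) {
    if (nchar(s) == L) s
    else if (nchar(s) < L) paste0(s, strrep("-", L - nchar(s)))
    else substr(s, 1, L)
  }, "")
}

## Single-structure PSSM for a source: its own sequence as a one-row MSA.
.source_pssm <- function(model, pseudocount_weight) {
  build_pssm(msa(.seq_string(model), names = model$source_id),
             pseudocount_weight)
}
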