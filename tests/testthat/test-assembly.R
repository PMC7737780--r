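# Combinatorial assembly, recipe enumeration, catalytic fixation, and the
# steric screen.

all_template_recipe <- function(scheme)
  stats::setNames(rep(list("template"), nrow(scheme$segments)),
                  scheme$segments$name)

test_that("the identity recipe reproduces the template and its PSSM", {
  fam <- fam_small()
  db <- db_small()
  tm <- idealize_model(fam$template)
  pssms <- stats::setNames(
    list(build_pssm(msa(paste(tm$aa, collapse = "")))), tm$source_id)
  cand <- assemble(fam$template, db, all_template_recipe(fam$scheme),
                   pssms = pssms)
  expect_null(cand$failed)
  fit <- kabsch_superpose(do.call(rbind, cand$model$atoms[c("N", "CA", "C")]),
                          do.call(rbind, tm$atoms[c("N", "CA", "C")]))
  expect_lt(fit$rmsd, 1e-3)
  expect_equal(unclass(cand$pssm), unclass(pssms[[1]]))
  expect_equal(cand$template_map, seq_len(n_residues(tm)))
})

test_that("assembly is segment-local", {
  fam <- fam_small()
  db <- db_small()
  # choose a non-template fragment for s1 only
  recs <- accepted_records(db, "s1")
  pick <- which(vapply(recs, function(r) r$fragment$source_id, "") != "template")[1]
  recipe <- all_template_recipe(fam$scheme)
  recipe[["s1"]] <- pick
  cand <- assemble(fam$template, db, recipe)
  expect_null(cand$failed)
  expect_length(cand$model$breaks, 0)
  tor_new <- extract_torsions(cand$model)
  tor_old <- extract_torsions(idealize_model(fam$template))
  tmap <- cand$template_map
  seg <- fam$scheme$segments[fam$scheme$segments$name == "s1", ]
  outside <- setdiff(which(!is.na(tmap)), seg$start:seg$end)
  for (i in outside[-c(1, length(outside))]) {
    j <- tmap[i]
    expect_equal(tor_new$psi[j], tor_old$psi[i], tolerance = 1e-6)
    expect_equal(tor_new$phi[j], tor_old$phi[i], tolerance = 1e-6)
  }
})

test_that("model residue count is the fragment-length sum minus shared anchors", {
  fam <- fam_small()
  db <- db_small()
  set.seed(2)
  for (k in 1:3) {
    recipe <- lapply(fam$scheme$segments$name, function(s)
      sample(length(accepted_records(db, s)), 1))
    names(recipe) <- fam$scheme$segments$name
    cand <- assemble(fam$template, db, recipe)
    expect_null(cand$failed)
    lens <- vapply(fam$scheme$segments$name, function(s)
      accepted_records(db, s)[[recipe[[s]]]]$fragment$n_res, 1L)
    shared <- nrow(fam$scheme$segments) - 1L
    expect_equal(n_residues(cand$model), sum(lens) - shared)
    expect_length(cand$model$breaks, 0)
  }
})

test_that("count_assemblies is the product of accepted counts", {
  db <- db_small()
  counts <- vapply(db$scheme$segments$name,
                   function(s) length(accepted_records(db, s)), 1L)
  expect_equal(count_assemblies(db), prod(counts))
  # product arithmetic on a thinned database
  db2 <- db
  db2$segments[[1]] <- db2$segments[[1]][1:3]
  db2$segments[[2]] <- db2$segments[[2]][1:5]
  db2$segments[[3]] <- db2$segments[[3]][1:2]
  db2$segments[[4]] <- db2$segments[[4]][1]
  expect_equal(count_assemblies(db2), 3 * 5 * 2 * 1)
  db3 <- db
  for (s in names(db3$segments)) db3$segments[[s]] <- db3$segments[[s]][1]
  expect_equal(count_assemblies(db3), 1)
  db2$segments[[1]] <- list()
  expect_error(count_assemblies(db2), "no accepted fragments")
})

test_that("enumeration is lexicographic and sampling is seeded and distinct", {
  db <- db_small()
  db2 <- db
  for (s in names(db2$segments)) db2$segments[[s]] <- db2$segments[[s]][1:2]
  rec <- enumerate_or_sample(db2, n = 100)
  expect_length(rec, 16)  # 2^4 full enumeration
  keys <- vapply(rec, paste, "", collapse = "|")
  expect_equal(keys, sort(keys))  # lexicographic
  expect_equal(rec[[1]], stats::setNames(rep(1L, 4), names(db2$segments)))
  # seeded sampling: reproducible and without replacement
  s1 <- enumerate_or_sample(db, n = 25, seed = 7)
  s2 <- enumerate_or_sample(db, n = 25, seed = 7)
  expect_identical(s1, s2)
  k1 <- vapply(s1, paste, "", collapse = "|")
  expect_length(unique(k1), 25)
  s3 <- enumerate_or_sample(db, n = 25, seed = 8)
  expect_false(identical(s1, s3))
})

test_that("catalytic residues on framework anchors stay fixed", {
  fam <- fam_small()
  db <- db_small()
  tm <- idealize_model(fam$template)
  cat_pos <- fam$ground_truth$catalytic
  cand <- assemble(fam$template, db, all_template_recipe(fam$scheme))
  cand <- check_catalytic(cand, tm, cat_pos, fam$scheme)
  expect_true(cand$catalytic_ok)
  # any recipe keeps anchor-borne catalytic residues in place
  set.seed(5)
  recipe <- lapply(fam$scheme$segments$name, function(s)
    sample(length(accepted_records(db, s)), 1))
  names(recipe) <- fam$scheme$segments$name
  cand2 <- assemble(fam$template, db, recipe)
  cand2 <- check_catalytic(cand2, tm, cat_pos, fam$scheme)
  expect_true(cand2$catalytic_ok)
  # infinite tolerance always passes
  cand3 <- check_catalytic(cand2, tm, cat_pos, fam$scheme, tolerance = Inf)
  expect_true(cand3$catalytic_ok)
  # a constrained position inside a replaced segment is reported missing
  seg <- fam$scheme$segments[fam$scheme$segments$name == "s1", ]
  inside <- seg$start + 3
  cand4 <- check_catalytic(cand2, tm, inside, fam$scheme)
  expect_false(cand4$catalytic_ok)
  expect_match(attr(cand4$catalytic_ok, "reason"), "removed by assembly")
})

test_that("steric screen counts match the all-pairs oracle", {
  n <- 20
  ext <- data.frame(phi = rep(-139, n), psi = rep(135, n), omega = rep(180, n))
  ext$phi[1] <- NA; ext$psi[n] <- NA; ext$omega[n] <- NA
  m <- rebuild_backbone(ext, strrep("A", n))
  expect_equal(steric_screen(m), 0)
  # force an overlap: residue 8 moved onto residue 1
  m2 <- m
  for (nm in names(m2$atoms))
    m2$atoms[[nm]][8, ] <- m$atoms[[nm]][1, ] + 0.3
  expect_gte(steric_screen(structure(m2, class = "backbone_model")), 1)
  # random compact fixtures against the brute-force oracle
  set.seed(12)
  for (k in 1:4) {
    nn <- 25
    tor <- random_torsions(nn)
    mm <- rebuild_backbone(tor, strrep("A", nn))
    for (cutoff in c(2.5, 4)) {
      expect_equal(steric_screen(mm, cutoff), bf_clash_count(mm, cutoff))
    }
  }
})

test_that("assemblies marked failed name the failing segment", {
  fam <- fam_small()
  db <- db_small()
  recs <- accepted_records(db, "s2")
  bad <- recs[[1]]
  mid <- bad$fragment$n_res %/% 2
  bad$fragment$torsions$psi[mid] <-
    fragstitch:::.wrap_angle(bad$fragment$torsions$psi[mid] + 150)
  db$segments[["s2"]] <- c(db$segments[["s2"]], list(bad))
  recipe <- all_template_recipe(fam$scheme)
  recipe[["s2"]] <- length(accepted_records(db, "s2"))
  cand <- assemble(fam$template, db, recipe)
  expect_equal(cand$failed, "s2")
})
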