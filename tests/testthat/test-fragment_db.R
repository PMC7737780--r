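# Graft-and-close, the acceptance gate, fragment RMSD, clustering, and
# database persistence.

test_that("grafting the template's own fragment closes exactly", {
  fam <- fam_small()
  tm <- fam$template; sc <- fam$scheme
  aln <- self_alignment(tm, sc)
  for (s in sc$segments$name) {
    fr <- extract_fragment(tm, aln, s, sc)
    rec <- graft_and_close(tm, fr, sc)
    expect_lt(rec$closure_rmsd, 1e-6)
    expect_true(rec$accepted)
    expect_length(rec$model$breaks, 0)
  }
})

test_that("small-perturbation homolog fragments pass the gate", {
  db <- db_gate()
  cl <- db$log$closure_rmsd[db$log$segment %in% c("s1", "s2")]
  expect_true(all(is.finite(cl)))
  expect_gte(mean(cl <= 0.2), 0.95)
  for (s in c("s1", "s2"))
    for (r in accepted_records(db, s))
      expect_lt(r$closure_rmsd, 0.2)
})

test_that("fragments with incompatible end frames are rejected", {
  fam <- fam_small()
  tm <- fam$template; sc <- fam$scheme
  aln <- self_alignment(tm, sc)
  fr <- extract_fragment(tm, aln, "s1", sc)
  # a large mid-fragment torsion spike swings the fragment's end several
  # Angstrom away from the template's downstream anchor frame
  mid <- fr$n_res %/% 2
  fr$torsions$psi[mid] <- fragstitch:::.wrap_angle(fr$torsions$psi[mid] + 150)
  end0 <- rebuild_backbone(fr$torsions, strsplit(fr$seq, "")[[1]])
  rec <- graft_and_close(tm, fr, sc)
  expect_false(rec$accepted)
})

test_that("the gate is a strict inequality on closure rmsd", {
  rec <- structure(list(closure_rmsd = 0.19, accepted = NA),
                   class = "fragment_record")
  expect_true(gate_fragment(rec, 0.2)$accepted)
  rec$closure_rmsd <- 0.2
  expect_false(gate_fragment(rec, 0.2)$accepted)
  rec$closure_rmsd <- 0
  expect_false(gate_fragment(rec, 0)$accepted)
  rec$closure_rmsd <- Inf
  expect_false(gate_fragment(rec, 10)$accepted)
})

test_that("fragment rmsd is a sequence-independent metric", {
  fam <- fam_small()
  tm <- fam$template; sc <- fam$scheme
  aln <- self_alignment(tm, sc)
  a <- extract_fragment(tm, aln, "s1", sc)
  expect_equal(as.numeric(fragment_rmsd(a, a)), 0, tolerance = 1e-8)
  # rigid motion of the stored atoms is irrelevant: the metric compares
  # idealized conformations rebuilt from torsions
  b <- a
  for (nm in names(b$atoms))
    b$atoms[[nm]] <- b$atoms[[nm]] %*% t(random_rotation())
  expect_equal(as.numeric(fragment_rmsd(a, b)), 0, tolerance = 1e-8)
  # a different sequence with the same torsions is conformationally identical
  b$seq <- paste(rev(strsplit(a$seq, "")[[1]]), collapse = "")
  expect_equal(as.numeric(fragment_rmsd(a, b)), 0, tolerance = 1e-8)
})

test_that("unequal-length rmsd equals the best offset alignment", {
  set.seed(21)
  mk_frag <- function(n, id) {
    tor <- random_torsions(n)
    structure(list(source_id = id, segment_name = "s", seq = strrep("A", n),
                   torsions = tor, n_res = n,
                   end_frames = list(start = NULL, end = NULL),
                   src_start = 1L, atoms = NULL), class = "fragment")
  }
  a <- mk_frag(5, "a"); b <- mk_frag(7, "b")
  got <- fragment_rmsd(a, b)
  expect_equal(attr(got, "length_diff"), 2L)
  ca <- fragstitch:::.fragment_ideal_coords(a)
  cb <- fragstitch:::.fragment_ideal_coords(b)
  # brute-force oracle: all 3 placements of the 5-mer within the 7-mer
  offs <- vapply(0:2, function(off)
    kabsch_superpose(ca, cb[(4 * off + 1):(4 * (off + 5)), ])$rmsd, 0)
  expect_equal(as.numeric(got), min(offs), tolerance = 1e-10)
})

test_that("clustering matches a brute-force complete-linkage oracle", {
  fam <- fam_small()
  db <- db_small()
  for (s in c("s1", "s2")) {
    frs <- lapply(accepted_records(db, s), function(r) r$fragment)
    frs <- frs[seq_len(min(8, length(frs)))]
    for (radius in c(0.5, 1.0, 2.5)) {
      ca <- cluster_fragments(frs, radius)
      expect_equal(labels_to_partition(ca$labels),
                   bf_complete_clusters(ca$dist, radius))
      # representative belongs to its cluster
      for (cl in names(ca$representatives))
        expect_equal(ca$labels[ca$representatives[[cl]]], as.integer(cl))
    }
  }
})

test_that("clustering recovers planted groups and ignores input order", {
  fam <- fam_small()
  db <- db_small()
  hom_ids <- vapply(fam$homologs, function(h) h$source_id, "")
  for (si in 1:2) {
    s <- c("s1", "s2")[si]
    recs <- accepted_records(db, s)
    frs <- lapply(recs, function(r) r$fragment)
    ids <- vapply(frs, function(f) f$source_id, "")
    truth <- ifelse(ids == "template", 1L,
                    fam$ground_truth$labels[match(ids, hom_ids), si])
    ca <- cluster_fragments(frs, 1.0)
    expect_equal(labels_to_partition(ca$labels), labels_to_partition(truth))
    # permutation invariance of the partition
    set.seed(4)
    perm <- sample(length(frs))
    ca2 <- cluster_fragments(frs[perm], 1.0)
    expect_equal(labels_to_partition(ca2$labels),
                 labels_to_partition(truth[perm]))
  }
  # single fragment: itself the representative
  one <- cluster_fragments(list(lapply(db$segments$s1, function(r)
    r$fragment)[[1]]), 1.0)
  expect_equal(one$labels, 1L)
  expect_equal(unname(one$representatives), 1L)
})

test_that("databases persist losslessly and deterministically", {
  db <- db_small()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  save_db(db, d1, created = "fixed")
  db2 <- load_db(d1)
  expect_equal(db2$gate, db$gate)
  expect_equal(names(db2$segments), names(db$segments))
  for (s in names(db$segments)) {
    expect_length(db2$segments[[s]], length(db$segments[[s]]))
    for (k in seq_along(db$segments[[s]])) {
      a <- db$segments[[s]][[k]]; b <- db2$segments[[s]][[k]]
      expect_equal(b$fragment$seq, a$fragment$seq)
      expect_equal(b$accepted, a$accepted)
      dd <- abs(as.matrix(b$fragment$torsions) - as.matrix(a$fragment$torsions))
      expect_lt(max(dd, na.rm = TRUE), 0.001)
    }
  }
  # byte-identical rebuild with fixed metadata stamp
  save_db(db, d2, created = "fixed")
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # version and missing-segment errors
  meta <- jsonlite::fromJSON(file.path(d1, "metadata.json"))
  meta$version <- "other-2"
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), file.path(d1, "metadata.json"))
  expect_error(load_db(d1), "version mismatch.*other-2")
  meta$version <- fragstitch:::.DB_VERSION
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), file.path(d1, "metadata.json"))
  file.remove(file.path(d1, "segment_s1.jsonl"))
  expect_error(load_db(d1), "missing segment")
})
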