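# Segmentation schemes, template alignment, fragment extraction and
# end alignment.

test_that("segmentation schemes validate anchors and tile the template", {
  expect_error(segmentation_scheme("t", c(10, 5), 20), "strictly increasing")
  expect_error(segmentation_scheme("t", c(0, 5), 20), "out of template range")
  sc <- segmentation_scheme("t", c(3, 10, 17), 20)
  expect_equal(sc$segments$type, c("tail_n", "internal", "internal", "tail_c"))
  # anchor-inclusive tiling: adjacent segments share exactly the anchor
  expect_equal(sc$segments$end[-nrow(sc$segments)],
               sc$segments$start[-1])
  sc2 <- segmentation_scheme("t", c(1, 10, 20), 20)
  expect_equal(sc2$segments$type, c("internal", "internal"))
})

test_that("template fragments concatenate back to the template sequence", {
  fam <- fam_small()
  tm <- fam$template; sc <- fam$scheme
  aln <- self_alignment(tm, sc)
  frs <- lapply(sc$segments$name, function(s) extract_fragment(tm, aln, s, sc))
  seqs <- vapply(seq_along(frs), function(i) {
    s <- frs[[i]]$seq
    if (i > 1) substr(s, 2, nchar(s)) else s  # shared anchor: left segment keeps it
  }, "")
  expect_equal(paste(seqs, collapse = ""), paste(tm$aa, collapse = ""))
})

test_that("kabsch superposition is exact on rigid copies and matches the
           quaternion oracle", {
  set.seed(33)
  p <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(p, p)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # +90 deg about z
  q <- p %*% t(rz)
  fit2 <- kabsch_superpose(q, p)
  expect_lt(fit2$rmsd, 1e-10)
  expect_equal(fit2$rotation, t(rz), tolerance = 1e-8)
  for (k in 1:25) {
    a <- matrix(rnorm(30, sd = 3), 10, 3)
    b <- matrix(rnorm(30, sd = 3), 10, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, horn_rmsd(a, b),
                 tolerance = 1e-8)
  }
  expect_error(kabsch_superpose(p[1:2, ], p[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("the template aligns to itself with the identity mapping", {
  fam <- fam_small()
  aln <- align_to_template(fam$template, fam$template, fam$scheme)
  expect_true(all(aln$pairs[, 1] == aln$pairs[, 2]))
  expect_equal(unname(aln$anchor_map), fam$scheme$anchors)
})

test_that("anchors are recovered for homologs with loop insertions", {
  fam <- fam_small()
  for (h in seq_along(fam$homologs)) {
    aln <- align_to_template(fam$homologs[[h]], fam$template, fam$scheme)
    expect_equal(unname(aln$anchor_map),
                 unname(as.integer(fam$ground_truth$anchor_maps[[h]])))
  }
})

test_that("a homolog lacking an anchor region is rejected naming the anchor", {
  fam <- fam_small()
  hom <- fam$homologs[[1]]
  # delete the second anchor stretch: rebuild without those rows
  a2_hom <- fam$ground_truth$anchor_maps[[1]][2]
  tor <- extract_torsions(hom)
  drop <- (a2_hom - 2):(a2_hom + 2)
  tor2 <- tor[-drop, ]
  n <- nrow(tor2)
  tor2$phi[1] <- NA; tor2$psi[n] <- NA; tor2$omega[n] <- NA
  hom2 <- rebuild_backbone(tor2, paste(hom$aa[-drop], collapse = ""),
                           source_id = "broken")
  expect_error(align_to_template(hom2, fam$template, fam$scheme),
               "anchor")
})

test_that("fragment extraction spans mapped anchors and rejects broken spans", {
  fam <- fam_small()
  tm <- fam$template; sc <- fam$scheme
  aln <- self_alignment(tm, sc)
  fr <- extract_fragment(tm, aln, "s1", sc)
  seg <- sc$segments[sc$segments$name == "s1", ]
  expect_equal(fr$n_res, seg$end - seg$start + 1)
  expect_equal(fr$seq, paste(tm$aa[seg$start:seg$end], collapse = ""))
  expect_equal(fr$src_start, seg$start)
  # an insertion fixture is longer than the template span by the planted amount
  hom <- fam$homologs[[1]]
  haln <- align_to_template(hom, tm, sc)
  hfr <- extract_fragment(hom, haln, "s1", sc)
  g <- fam$ground_truth$labels[1, 1]
  diff_len <- fam$ground_truth$group_lengths[g, 1] -
    fam$ground_truth$group_lengths[1, 1]
  expect_equal(hfr$n_res - fr$n_res, diff_len)
  # break inside the span
  broken <- tm
  for (nm in names(broken$atoms))
    broken$atoms[[nm]][(seg$start + 2):n_residues(tm), ] <-
      broken$atoms[[nm]][(seg$start + 2):n_residues(tm), ] + 30
  broken <- backbone_model("broken", broken$aa, broken$atoms)
  expect_warning(out <- extract_fragment(broken, aln, "s1", sc), "break")
  expect_null(out)
})

test_that("end alignment superposes anchor frames and never hurts the fit", {
  fam <- fam_small()
  tm <- fam$template; sc <- fam$scheme
  aln <- self_alignment(tm, sc)
  ref <- extract_fragment(tm, aln, "s1", sc)
  out <- align_fragment_ends(list(ref), ref)
  expect_lt(out[[1]]$end_align_rmsd, 1e-10)
  expect_equal(out[[1]]$atoms$CA, ref$atoms$CA, tolerance = 1e-8)
  # rigid motions are exactly undone
  set.seed(9)
  shifted <- ref
  rot <- random_rotation()
  for (nm in names(shifted$atoms))
    shifted$atoms[[nm]] <- shifted$atoms[[nm]] %*% t(rot) +
      matrix(c(10, 0, 0), nrow(shifted$atoms[[nm]]), 3, byrow = TRUE)
  shifted$end_frames <- list(
    start = rbind(shifted$atoms$N[1, ], shifted$atoms$CA[1, ], shifted$atoms$C[1, ]),
    end = rbind(shifted$atoms$N[ref$n_res, ], shifted$atoms$CA[ref$n_res, ],
                shifted$atoms$C[ref$n_res, ]))
  out2 <- align_fragment_ends(list(shifted), ref)
  expect_lt(out2[[1]]$end_align_rmsd, 1e-8)
  # homolog fragments: aligned anchor rmsd never exceeds the unaligned one
  hom_frags <- lapply(fam$homologs[1:3], function(h) {
    haln <- align_to_template(h, tm, sc)
    extract_fragment(h, haln, "s1", sc)
  })
  pre_rmsd <- vapply(hom_frags, function(fr)
    sqrt(mean(rowSums((fragstitch:::.fragment_anchor_atoms(fr) -
                       fragstitch:::.fragment_anchor_atoms(ref))^2))), 0)
  aligned <- align_fragment_ends(hom_frags, ref)
  post_rmsd <- vapply(aligned, function(fr) fr$end_align_rmsd, 0)
  expect_true(all(post_rmsd <= pre_rmsd + 1e-9))
})
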