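# Independent oracles used to cross-check the package's numerics, plus
# cached synthetic fixtures shared across test files.

# Quaternion (Horn) superposition oracle: minimal RMSD via the maximum
# eigenvalue of the 4x4 key matrix. Entirely independent of the SVD route.
horn_rmsd <- function(mobile, fixed) {
  n <- nrow(mobile)
  x <- sweep(mobile, 2, colMeans(mobile))
  y <- sweep(fixed, 2, colMeans(fixed))
  S <- t(x) %*% y
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(x^2) + sum(y^2) - 2 * lmax)) / n)
}

# Signed dihedral by the acos-of-plane-normals formulation with a triple
# product for the sign -- a different route than the package's atan2 form.
dihedral_oracle <- function(a, b, c, d) {
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  u1 <- b - a; u2 <- c - b; u3 <- d - c
  n1 <- cr(u1, u2); n2 <- cr(u2, u3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  if (sum(cr(n1, n2) * u2) < 0) ang <- -ang
  ang
}

# Brute-force agglomerative complete-linkage clustering: exhaustively merge
# the closest cluster pair (complete linkage) while that distance is within
# the radius. Returns a canonical partition (list of sorted member sets).
bf_complete_clusters <- function(D, radius) {
  clusters <- as.list(seq_len(nrow(D)))
  repeat {
    if (length(clusters) < 2) break
    bestd <- Inf; bi <- bj <- 0
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < bestd) { bestd <- d; bi <- i; bj <- j }
    }
    if (bestd > radius) break
    clusters[[bi]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bj]] <- NULL
  }
  canonical_partition(clusters)
}

canonical_partition <- function(clusters) {
  clusters <- lapply(unname(clusters), function(x) sort(unname(x)))
  unname(clusters[order(vapply(clusters, `[`, 1, 1))])
}

labels_to_partition <- function(labels) {
  canonical_partition(split(seq_along(labels), labels))
}

# All-pairs clash oracle: plain double loop over backbone/CB atoms.
bf_clash_count <- function(model, cutoff = 2.5) {
  coords <- NULL; res <- NULL
  for (nm in c("N", "CA", "C", "O", "CB")) {
    m <- model$atoms[[nm]]
    if (is.null(m)) next
    for (i in seq_len(nrow(m))) if (!anyNA(m[i, ])) {
      coords <- rbind(coords, m[i, ]); res <- c(res, i)
    }
  }
  count <- 0L
  for (i in seq_len(nrow(coords) - 1)) for (j in (i + 1):nrow(coords)) {
    if (abs(res[i] - res[j]) >= 3 &&
        sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff)
      count <- count + 1L
  }
  count
}

# Random torsion table with the chain-end NA pattern.
random_torsions <- function(n) {
  tor <- data.frame(phi = runif(n, -180, 180), psi = runif(n, -180, 180),
                    omega = runif(n, 150, 180) * sample(c(-1, 1), n, TRUE))
  tor$phi[1] <- NA; tor$psi[n] <- NA; tor$omega[n] <- NA
  tor
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Shared fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fam_small <- function() cached("fam_small",
  make_toy_family(n_structures = 6, n_segments = 2, n_groups = 3,
                  torsion_noise = 2, seed = 42))

db_small <- function() cached("db_small",
  build_fragment_db(fam_small()$template, fam_small()$homologs,
                    fam_small()$scheme))

fam_gate <- function() cached("fam_gate",
  make_toy_family(n_structures = 12, n_segments = 2, n_groups = 1,
                  torsion_noise = 2, seed = 11))

db_gate <- function() cached("db_gate",
  build_fragment_db(fam_gate()$template, fam_gate()$homologs,
                    fam_gate()$scheme))

# small helical template used by several structure-level tests
helical_template <- function(n = 24, seed = 5) cached(
  paste0("helix", n, "_", seed), {
    set.seed(seed)
    tor <- data.frame(phi = rep(-57, n) + runif(n, -3, 3),
                      psi = rep(-47, n) + runif(n, -3, 3),
                      omega = rep(180, n))
    tor$phi[1] <- NA; tor$psi[n] <- NA; tor$omega[n] <- NA
    rebuild_backbone(tor, paste(sample(LETTERS[c(1, 4, 5, 6, 7)], n, TRUE),
                                collapse = ""), source_id = "helix")
  })
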