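test_that("MSA filtering applies the gap and identity thresholds", {
  base <- strsplit(paste(rep("ACDEFGHIKL", 10), collapse = ""), "")[[1]]
  gappy <- base
  gappy[1:26] <- "-"   # 26% gaps: discarded
  edge <- base
  edge[1:25] <- "-"    # exactly 25% gaps: kept by the gap filter
  edge[26:40] <- "W"   # and diverged enough to survive redundancy removal
  m <- msa(rbind(base, base, gappy, edge))
  out <- msa_filter(m)
  expect_equal(nrow(out), 2)  # one of the duplicates + the edge case
  expect_true(any(rowMeans(unclass(out) == "-") == 0.25))
})

test_that("greedy redundancy reduction matches a brute-force clustering oracle", {
  set.seed(8)
  aa <- setdiff(aa_alphabet(), "-")
  L <- 100
  ref <- sample(aa, L, replace = TRUE)
  # craft 10 sequences with controlled distances to the reference
  n_mut <- c(0, 2, 4, 5, 6, 10, 30, 50, 3, 7)
  seqs <- t(vapply(n_mut, function(k) {
    s <- ref
    pos <- sample(L, k)
    for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1)
    s
  }, character(L)))
  m <- msa(seqs)
  out <- msa_filter(m, max_gap_frac = 1, max_identity = 0.95)
  # brute-force greedy oracle over exhaustive pairwise identities
  keep <- integer(0)
  for (i in 1:10) {
    dup <- any(vapply(keep, function(j)
      mean(seqs[i, ] == seqs[j, ]) >= 0.95, logical(1)))
    if (!dup) keep <- c(keep, i)
  }
  expect_equal(nrow(out), length(keep))
  expect_equal(unclass(out), unclass(m)[keep, ], ignore_attr = TRUE)
  # idempotent and independent of column order
  expect_equal(nrow(msa_filter(out, 1, 0.95)), nrow(out))
  perm <- sample(L)
  out_perm <- msa_filter(msa(seqs[, perm]), 1, 0.95)
  expect_equal(nrow(out_perm), length(keep))
})

test_that("one-hot encoding is bijective with unit channel sums", {
  fam <- gen_msa(n = 20, seed = 4)
  arr <- onehot_encode(fam)
  expect_equal(dim(arr), c(20, ncol(fam), 21))
  expect_true(all(apply(arr, c(1, 2), sum) == 1))
  back <- onehot_decode(arr)
  expect_equal(unclass(back), unclass(fam), ignore_attr = TRUE)
  # column frequencies equal the mean encoding
  freq <- colMeans(arr[, 3, ])
  tab <- table(factor(unclass(fam)[, 3], levels = aa_alphabet()))
  expect_equal(unname(freq), as.numeric(tab) / 20)
  expect_error(msa("ACDZ"), "unknown alignment character")
})

test_that("VAE training improves the ELBO and replays deterministically", {
  fam <- msa_filter(gen_msa(n = 120, n_invariant = 4, n_coupled = 6,
                            n_free = 10, seed = 21))
  arch <- vae_arch(encoder = 32, latent = 4, epochs = 150, lr = 5e-3,
                   seed = 9)
  v <- train_vae(fam, arch)
  expect_gt(utils::tail(v$elbo_trace, 1), v$elbo_trace[1])
  v2 <- train_vae(fam, arch)
  expect_equal(utils::tail(v$elbo_trace, 1), utils::tail(v2$elbo_trace, 1),
               tolerance = 1e-6)
})

test_that("a single-sequence family is reconstructed as the argmax everywhere", {
  aa <- setdiff(aa_alphabet(), "-")
  set.seed(33)
  s <- sample(aa, 20, replace = TRUE)
  fam <- msa(matrix(rep(s, each = 40), 40, 20))
  v <- train_vae(fam, vae_arch(encoder = 24, latent = 2, epochs = 250,
                               lr = 1e-2, seed = 2))
  # decode from the prior mean
  p <- v$params
  z <- matrix(0, 1, v$arch$latent)
  hd <- coldlac:::.mlp_forward(z, p$dec)
  logits <- hd[[length(hd)]] %*% p$out$W + rep(p$out$b, each = 1)
  probs <- coldlac:::.softmax_positions(logits, v$L, v$A)
  recon <- vapply(seq_len(v$L), function(j)
    aa_alphabet()[which.max(probs[1, ((j - 1) * 21 + 1):(j * 21)])],
    character(1))
  expect_equal(recon, s)
})

test_that("identical-residue mutations score zero and mismatches are named", {
  fam <- msa_filter(gen_msa(n = 60, seed = 13))
  v <- train_vae(fam, vae_arch(encoder = 24, latent = 3, epochs = 60,
                               seed = 3))
  wt <- attr(gen_msa(n = 60, seed = 13), "consensus")
  expect_equal(mutation_fitness(v, wt, paste0(wt[2], 2, wt[2])), 0)
  wrong <- setdiff(setdiff(aa_alphabet(), "-"), wt[2])[1]
  expect_error(mutation_fitness(v, wt, paste0(wrong, 2, "A")),
               "mismatch")
})

test_that("mutating conserved columns scores less fit than free columns", {
  hits <- vapply(1:20, function(rep) {
    fam <- gen_msa(n = 100, n_invariant = 4, n_coupled = 4, n_free = 10,
                   gap_prob = 0, seed = 400 + rep)
    cls <- attr(fam, "column_class")
    wt <- attr(fam, "consensus")
    v <- train_vae(fam, vae_arch(encoder = 32, latent = 4, epochs = 120,
                                 lr = 8e-3, seed = rep))
    aa <- setdiff(aa_alphabet(), "-")
    inv <- which(cls == "invariant")[1]
    fre <- which(cls == "free")[1]
    minv <- paste0(wt[inv], inv, setdiff(aa, wt[inv])[1])
    mfre <- paste0(wt[fre], fre, setdiff(aa, wt[fre])[1])
    s_inv <- mutation_fitness(v, wt, minv, n_posterior_samples = 200,
                              seed = rep)
    s_fre <- mutation_fitness(v, wt, mfre, n_posterior_samples = 200,
                              seed = rep)
    s_inv > s_fre
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("conserved-coupled positions separate from free positions (AUC >= 0.9)", {
  fam <- gen_msa(n = 250, n_invariant = 3, n_coupled = 8, n_free = 8,
                 gap_prob = 0, seed = 77)
  cls <- attr(fam, "column_class")
  wt <- attr(fam, "consensus")
  v <- train_vae(fam, vae_arch(encoder = 48, latent = 6, epochs = 250,
                               lr = 5e-3, seed = 7))
  aa <- setdiff(aa_alphabet(), "-")
  score_pos <- function(j) {
    muts <- setdiff(aa, wt[j])[1:3]
    mean(vapply(muts, function(m)
      mutation_fitness(v, wt, paste0(wt[j], j, m),
                       n_posterior_samples = 300, seed = j), numeric(1)))
  }
  coup <- vapply(which(cls == "coupled"), score_pos, numeric(1))
  free <- vapply(which(cls == "free"), score_pos, numeric(1))
  auc <- mean(outer(coup, free, ">")) +
    0.5 * mean(outer(coup, free, "=="))
  expect_gte(auc, 0.9)
})

test_that("score variance shrinks with the posterior sample count", {
  fam <- msa_filter(gen_msa(n = 80, seed = 55))
  v <- train_vae(fam, vae_arch(encoder = 24, latent = 4, epochs = 80,
                               seed = 5))
  wt <- attr(gen_msa(n = 80, seed = 55), "consensus")
  aa <- setdiff(aa_alphabet(), "-")
  mut <- paste0(wt[1], 1, setdiff(aa, wt[1])[1])
  s_small <- vapply(1:24, function(k)
    mutation_fitness(v, wt, mut, n_posterior_samples = 125, seed = k),
    numeric(1))
  s_big <- vapply(1:24, function(k)
    mutation_fitness(v, wt, mut, n_posterior_samples = 2000,
                     seed = 1000 + k), numeric(1))
  ratio <- stats::sd(s_small) / stats::sd(s_big)
  # expected sqrt(2000/125) = 4; allow a broad band around it
  expect_gt(ratio, 1.5)
})

test_that("interface contacts honor the distance cutoff at the boundary", {
  at <- data.frame(chain = c("A", "B"), resno = c(1, 1),
                   elety = c("CA", "CA"),
                   x = c(0, 5.4), y = 0, z = 0)
  expect_equal(nrow(interface_contacts(at)$pairs), 1)
  at$x[2] <- 5.6
  expect_equal(nrow(interface_contacts(at)$pairs), 0)
  expect_error(interface_contacts(at[1, ]), "2 chains")
  # hydrogens are excluded
  ath <- data.frame(chain = c("A", "B"), resno = c(1, 1),
                    elety = c("H", "CA"), x = c(0, 3), y = 0, z = 0)
  expect_error(interface_contacts(ath), "2 chains")
})

test_that("grid-based contacts equal the brute force on a toy dimer", {
  at <- toy_two_chain_atoms(n_res = 200, offset = c(6, 1, 0), seed = 6)
  g <- interface_contacts(at)
  b <- interface_contacts_brute(at)
  expect_equal(g$pairs, b$pairs, tolerance = 1e-12)
  expect_identical(g$interface_residues, b$interface_residues)
  expect_gt(nrow(g$pairs), 0)
})

test_that("interface ranking reproduces the published top candidates", {
  tab <- fitness_fixture()
  interface <- c(648, 702, 742, 745, 744, 748, 743, 967, 740, 741, 968)
  top3 <- rank_interface_mutations(tab, interface, top_k = 3)
  expect_equal(top3$mutation, c("V648E", "F702L", "T742V"))
  # permuted input gives identical output; empty interface empties the table
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(rank_interface_mutations(perm, interface, 3)$mutation,
               top3$mutation)
  expect_equal(nrow(rank_interface_mutations(tab, integer(0))), 0)
  # interface filtering drops positions outside the set
  expect_equal(nrow(rank_interface_mutations(tab, c(648))), 1)
})

test_that("buried surface fraction matches the sphere-cap overlap oracle", {
  # two single-atom chains: spheres of radius r = vdw + probe
  at <- data.frame(chain = c("A", "B"), resno = 1, elety = "CA",
                   x = c(0, 4), y = 0, z = 0)
  r <- 1.7 + 1.4
  h <- r - 4 / 2
  analytic <- 100 * h / (2 * r)   # buried fraction of two sphere caps
  got <- buried_surface_fraction(at)
  expect_equal(got, analytic, tolerance = 0.05)
  # far-apart chains bury nothing
  at2 <- at; at2$x[2] <- 50
  expect_equal(buried_surface_fraction(at2), 0)
  # rigid-motion invariance
  at3 <- at
  at3$y <- at3$y + 20
  expect_equal(buried_surface_fraction(at3), got, tolerance = 1e-10)
})
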