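# Shared fixtures built in code.

RT25 <- physical_constants()$R_cal * 298.15

# small bead dimer + noiseless curve with tight sigmas, for refinement tests
small_dimer <- function(spacing = 10, nq = 40) {
  bd <- gen_bead_dimer(spacing = spacing,
                       q_grid = seq(0.01, 0.3, length.out = nq))
  bd$curve$sigma <- 0.002 * bd$curve$I
  bd
}

# rotate one part of a bead structure about the global center
rotate_part <- function(st, part, axis = c(0, 0, 1), deg = 10) {
  R <- coldlac:::.rot_mat(axis, deg * pi / 180)
  idx <- which(st$part == part)
  ctr <- colMeans(st$xyz)
  st$xyz[idx, ] <- sweep(sweep(st$xyz[idx, , drop = FALSE], 2, ctr) %*%
                           t(R), 2, ctr, "+")
  st
}

# two-chain toy atom table: n residues per chain, 3 heavy atoms each,
# chains offset so that a few residues touch across the interface
toy_two_chain_atoms <- function(n_res = 30, offset = c(8, 0, 0), seed = 1) {
  set.seed(seed)
  one_chain <- function(chain, shift) {
    res <- do.call(rbind, lapply(seq_len(n_res), function(r) {
      base <- c(r * 3.5, 5 * sin(r / 3), 5 * cos(r / 3))
      at <- base + matrix(stats::rnorm(9, 0, 0.8), 3, 3)
      data.frame(chain = chain, resno = r,
                 elety = c("CA", "CB", "O"),
                 x = at[, 1] + shift[1], y = at[, 2] + shift[2],
                 z = at[, 3] + shift[3])
    }))
    res
  }
  rbind(one_chain("A", c(0, 0, 0)), one_chain("B", offset))
}

# tiny mutation fitness table mirroring published interface-ranking output
fitness_fixture <- function() {
  data.frame(
    mutation = c("V648E", "F702L", "T742V", "T745P", "V744A", "R748E",
                 "K743A", "L967S", "L740V", "P741K", "P968S"),
    score = c(-2.53, -1.97, -1.08, -0.94, -0.87, -0.21, 0.47, 1.75,
              2.62, 3.77, 4.16)
  )
}
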