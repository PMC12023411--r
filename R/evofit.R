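#' Amino-acid alphabet with gap
#'
#' The 20 standard residues plus `-` (gap), the alphabet of every MSA in
#' the package. The gap is its own one-hot channel.
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

#' Multiple sequence alignment container
#'
#' @param seqs Character vector of aligned sequences (equal lengths) over
#'   the 20 amino acids plus gap, or a character matrix (one row per
#'   sequence).
#' @param ids Sequence identifiers (default seq1, seq2, ...).
#' @param weights Optional per-sequence weights.
#' @return Object of class `"coldlac_msa"`: a character matrix with one
#'   column per alignment position.
#' @export
msa <- function(seqs, ids = NULL, weights = NULL) {
  if (is.matrix(seqs)) m <- seqs
  else {
    L <- unique(nchar(seqs))
    if (length(L) != 1) stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  m[m == "."] <- "-"
  bad <- setdiff(unique(as.vector(m)), aa_alphabet())
  if (length(bad)) stop("unknown alignment character(s): ",
                        paste(bad, collapse = " "))
  rownames(m) <- ids %||% paste0("seq", seq_len(nrow(m)))
  structure(m, class = c("coldlac_msa", "matrix"),
            weights = weights %||% rep(1, nrow(m)))
}

#' @export
print.coldlac_msa <- function(x, ...) {
  cat("MSA:", nrow(x), "sequences x", ncol(x), "columns\n")
  invisible(x)
}

#' Read an MSA from FASTA or A2M
#'
#' In A2M mode lowercase characters mark insert states relative to the
#' match columns and are dropped, as are `.` insert gaps; the remaining
#' uppercase/`-` characters are the match alignment.
#'
#' @param path File path.
#' @param format `"fasta"` (default) or `"a2m"`.
#' @return A [msa()].
#' @export
read_msa <- function(path, format = c("fasta", "a2m")) {
  format <- match.arg(format)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  if (format == "a2m") seqs <- gsub("[a-z.]", "", seqs)
  L <- nchar(seqs)
  if (length(unique(L)) != 1)
    stop("mixed alignment lengths after parsing ", path)
  msa(seqs, ids = names(ss))
}

#' Write an MSA to FASTA
#' @param x A [msa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  seqs <- apply(unclass(x), 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Filter an MSA by gap fraction and redundancy
#'
#' Two sequential filters matching standard family-model preprocessing:
#' first, sequences with a gap fraction above `max_gap_frac` are discarded
#' (strictly greater; a sequence at exactly the threshold is kept); second,
#' greedy redundancy reduction in input order (Hobohm-1 style) keeps the
#' first representative of every cluster of sequences at or above
#' `max_identity` pairwise identity. Identity is matches divided by
#' compared columns where both sequences are non-gap. Deterministic given
#' the input order; an empty result is flagged with a warning, not an
#' error.
#'
#' @param x A [msa()].
#' @param max_gap_frac Maximum tolerated gap fraction (default 0.25).
#' @param max_identity Identity threshold for redundancy removal
#'   (default 0.95).
#' @return Filtered [msa()].
#' @export
msa_filter <- function(x, max_gap_frac = 0.25, max_identity = 0.95) {
  m <- unclass(x)
  stopifnot(nrow(m) >= 1)
  gapfrac <- rowMeans(m == "-")
  m <- m[gapfrac <= max_gap_frac, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(m))) {
    dup <- FALSE
    for (j in keep) {
      if (seq_identity(m[i, ], m[j, ]) >= max_identity) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  if (!length(keep)) {
    warning("all sequences removed by filtering")
    return(msa(m[0, , drop = FALSE]))
  }
  msa(m[keep, , drop = FALSE], ids = rownames(m)[keep])
}

#' Pairwise sequence identity over mutually non-gap columns
#'
#' @param a,b Character vectors (rows of an MSA) of equal length.
#' @return Matches / compared columns; `NA` if no column is comparable.
#' @export
seq_identity <- function(a, b) {
  comp <- a != "-" & b != "-"
  if (!any(comp)) return(NA_real_)
  mean(a[comp] == b[comp])
}

#' One-hot encode an MSA
#'
#' @param x A [msa()].
#' @return Numeric array n_seq x L x 21 (channels in [aa_alphabet()]
#'   order); each position's channel vector sums to 1. The encoding is
#'   bijective; see [onehot_decode()].
#' @export
onehot_encode <- function(x) {
  m <- unclass(x)
  ab <- aa_alphabet()
  idx <- match(as.vector(m), ab)
  if (anyNA(idx)) stop("unknown character in MSA")
  arr <- array(0, dim = c(nrow(m), ncol(m), length(ab)),
               dimnames = list(rownames(m), NULL, ab))
  arr[cbind(rep(seq_len(nrow(m)), ncol(m)),
            rep(seq_len(ncol(m)), each = nrow(m)), idx)] <- 1
  arr
}

#' @rdname onehot_encode
#' @param arr An n x L x 21 one-hot array.
#' @export
onehot_decode <- function(arr) {
  ab <- aa_alphabet()
  n <- dim(arr)[1]; L <- dim(arr)[2]
  m <- matrix("", n, L)
  for (j in seq_len(L))
    m[, j] <- ab[apply(arr[, j, , drop = FALSE], 1, which.max)]
  msa(m, ids = dimnames(arr)[[1]])
}

# ---- variational autoencoder -----------------------------------------------
# Plain matrix-backprop VAE over one-hot encoded alignments: tanh hidden
# layers, Gaussian latent with reparameterization, per-position softmax
# output, Adam updates. Sized for small synthetic families; larger
# architectures are accepted but slow in pure R.

#' VAE architecture and training settings
#'
#' Defaults are a scaled-down configuration suitable for small synthetic
#' families; family-scale settings (encoder 2000/1000/300, latent 50,
#' tens of thousands of epochs) are accepted but slow without GPU support.
#'
#' @param encoder Integer vector of encoder hidden sizes (default c(64)).
#' @param decoder Integer vector of decoder hidden sizes (default
#'   rev(encoder)).
#' @param latent Latent dimension (default 8).
#' @param epochs Training epochs (default 200).
#' @param lr Adam learning rate (default 1e-3).
#' @param kl_weight Weight on the KL term (default 1).
#' @param seed RNG seed (mandatory).
#' @return List of class `"vae_arch"`.
#' @export
vae_arch <- function(encoder = c(64), decoder = rev(encoder), latent = 8,
                     epochs = 200, lr = 1e-3, kl_weight = 1, seed = 1) {
  stopifnot(all(encoder >= 1), all(decoder >= 1), latent >= 1, epochs >= 1)
  structure(list(encoder = encoder, decoder = decoder, latent = latent,
                 epochs = epochs, lr = lr, kl_weight = kl_weight,
                 seed = seed), class = "vae_arch")
}

.vae_init_layer <- function(nin, nout) {
  list(W = matrix(stats::rnorm(nin * nout, 0, sqrt(1 / nin)), nin, nout),
       b = rep(0, nout))
}

# forward through tanh MLP; returns list of activations
.mlp_forward <- function(X, layers) {
  hs <- list(X)
  for (l in layers) hs[[length(hs) + 1]] <- tanh(hs[[length(hs)]] %*% l$W +
                                                   rep(l$b, each = nrow(X)))
  hs
}

# backprop through tanh MLP; dtop is gradient wrt the top activation
.mlp_backward <- function(hs, layers, dtop) {
  grads <- vector("list", length(layers))
  d <- dtop
  for (li in rev(seq_along(layers))) {
    h <- hs[[li + 1]]
    d <- d * (1 - h^2)              # through tanh
    grads[[li]] <- list(W = crossprod(hs[[li]], d), b = colSums(d))
    d <- d %*% t(layers[[li]]$W)
  }
  list(grads = grads, dinput = d)
}

.adam_step <- function(p, g, m, v, t, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

# fast flatten/unflatten of the nested parameter list (leaves are W
# matrices and b vectors); avoids unlist()'s name mangling in the hot loop
.flatten <- function(x) {
  if (is.list(x)) unlist(lapply(x, .flatten), use.names = FALSE)
  else as.numeric(x)
}

.unflatten <- function(vec, template, pos = 1L) {
  if (is.list(template)) {
    out <- template
    for (i in seq_along(template)) {
      r <- .unflatten(vec, template[[i]], pos)
      out[[i]] <- r$value
      pos <- r$pos
    }
    list(value = out, pos = pos)
  } else {
    n <- length(template)
    v <- vec[pos:(pos + n - 1L)]
    if (!is.null(dim(template))) dim(v) <- dim(template)
    list(value = v, pos = pos + n)
  }
}

# per-position softmax over flattened (L*21) logits; rows = sequences
.softmax_positions <- function(logits, L, A = 21) {
  out <- logits
  for (j in seq_len(L)) {
    cols <- ((j - 1) * A + 1):(j * A)
    z <- logits[, cols, drop = FALSE]
    z <- z - apply(z, 1, max)
    e <- exp(z)
    out[, cols] <- e / rowSums(e)
  }
  out
}

#' Train a variational autoencoder on an MSA
#'
#' Maximizes the evidence lower bound (categorical reconstruction
#' log-likelihood per alignment position plus KL of the approximate
#' posterior to the standard-normal prior) by full-batch Adam steps with
#' the reparameterization trick. Reproducible given the architecture seed
#' and a fixed thread count; training aborts with diagnostics on
#' non-finite loss.
#'
#' @param x A (filtered) [msa()].
#' @param arch A [vae_arch()].
#' @return Object of class `"coldlac_vae"` with the learned parameters,
#'   the architecture and `elbo_trace` (per-epoch mean ELBO per sequence).
#' @export
train_vae <- function(x, arch = vae_arch()) {
  stopifnot(inherits(x, "coldlac_msa"), inherits(arch, "vae_arch"))
  set.seed(arch$seed)
  A <- 21
  L <- ncol(x)
  X <- onehot_encode(x)
  n <- dim(X)[1]
  # flatten to position-major blocks of 21 channels
  Xf <- matrix(0, n, L * A)
  for (j in seq_len(L)) Xf[, ((j - 1) * A + 1):(j * A)] <- X[, j, ]

  din <- L * A
  enc <- lapply(seq_along(arch$encoder), function(i)
    .vae_init_layer(if (i == 1) din else arch$encoder[i - 1],
                    arch$encoder[i]))
  top <- utils::tail(arch$encoder, 1)
  mu_l <- .vae_init_layer(top, arch$latent)
  lv_l <- .vae_init_layer(top, arch$latent)
  dec <- lapply(seq_along(arch$decoder), function(i)
    .vae_init_layer(if (i == 1) arch$latent else arch$decoder[i - 1],
                    arch$decoder[i]))
  out_l <- .vae_init_layer(utils::tail(arch$decoder, 1), din)

  params <- list(enc = enc, mu = mu_l, lv = lv_l, dec = dec, out = out_l)
  theta <- .flatten(params)
  adam_m <- numeric(length(theta))
  adam_v <- numeric(length(theta))
  elbo_trace <- numeric(arch$epochs)

  for (epoch in seq_len(arch$epochs)) {
    he <- .mlp_forward(Xf, params$enc)
    htop <- he[[length(he)]]
    mu <- htop %*% params$mu$W + rep(params$mu$b, each = n)
    lv <- htop %*% params$lv$W + rep(params$lv$b, each = n)
    lv <- pmin(pmax(lv, -10), 10)
    eps <- matrix(stats::rnorm(n * arch$latent), n, arch$latent)
    z <- mu + eps * exp(0.5 * lv)
    hd <- .mlp_forward(z, params$dec)
    logits <- hd[[length(hd)]] %*% params$out$W +
      rep(params$out$b, each = n)
    probs <- .softmax_positions(logits, L, A)
    rec <- sum(Xf * log(probs + 1e-12))
    kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv))
    elbo <- (rec - arch$kl_weight * kl) / n
    if (!is.finite(elbo))
      stop("VAE training diverged at epoch ", epoch,
           " (non-finite loss); lower the learning rate")
    elbo_trace[epoch] <- elbo

    # gradients of -ELBO/n
    dlogits <- (probs - Xf) / n
    gout <- list(W = crossprod(hd[[length(hd)]], dlogits),
                 b = colSums(dlogits))
    bd <- .mlp_backward(hd, params$dec, dlogits %*% t(params$out$W))
    dz <- bd$dinput
    dmu <- dz + arch$kl_weight * mu / n
    dlv <- dz * eps * 0.5 * exp(0.5 * lv) +
      arch$kl_weight * (-0.5) * (1 - exp(lv)) / n
    gmu <- list(W = crossprod(htop, dmu), b = colSums(dmu))
    glv <- list(W = crossprod(htop, dlv), b = colSums(dlv))
    dhtop <- dmu %*% t(params$mu$W) + dlv %*% t(params$lv$W)
    be <- .mlp_backward(he, params$enc, dhtop)

    grads <- list(enc = be$grads, mu = gmu, lv = glv, dec = bd$grads,
                  out = gout)
    st <- .adam_step(theta, .flatten(grads), adam_m, adam_v, epoch,
                     arch$lr)
    theta <- st$p; adam_m <- st$m; adam_v <- st$v
    params <- .unflatten(theta, params)$value
  }

  structure(list(params = params, arch = arch, L = L, A = A,
                 alphabet = aa_alphabet(), elbo_trace = elbo_trace),
            class = "coldlac_vae")
}

#' @export
print.coldlac_vae <- function(x, ...) {
  cat(sprintf("VAE: L = %d, latent = %d, %d epochs, final ELBO %.3f\n",
              x$L, x$arch$latent, x$arch$epochs,
              utils::tail(x$elbo_trace, 1)))
  invisible(x)
}

# flatten one sequence (character vector) to 1 x (L*21) one-hot row
.seq_onehot_row <- function(seq, A = 21) {
  ab <- aa_alphabet()
  idx <- match(seq, ab)
  if (anyNA(idx)) stop("unknown character in sequence")
  L <- length(seq)
  x <- numeric(L * A)
  x[(seq_len(L) - 1) * A + idx] <- 1
  matrix(x, 1)
}

# importance-weighted log-likelihood estimate of one sequence under the
# VAE; eps (n_samples x latent) supplies common random numbers
.vae_loglik <- function(model, seqrow, eps) {
  p <- model$params
  n <- nrow(eps)
  he <- .mlp_forward(seqrow, p$enc)
  htop <- he[[length(he)]]
  mu <- as.numeric(htop %*% p$mu$W + p$mu$b)
  lv <- as.numeric(htop %*% p$lv$W + p$lv$b)
  lv <- pmin(pmax(lv, -10), 10)
  z <- sweep(sweep(eps, 2, exp(0.5 * lv), "*"), 2, mu, "+")
  hd <- .mlp_forward(z, p$dec)
  logits <- hd[[length(hd)]] %*% p$out$W + rep(p$out$b, each = n)
  probs <- .softmax_positions(logits, model$L, model$A)
  logpxz <- as.numeric(log(probs + 1e-12) %*% t(seqrow))
  logpz <- rowSums(stats::dnorm(z, log = TRUE))
  logqz <- rowSums(stats::dnorm(z, rep(mu, each = n),
                                rep(exp(0.5 * lv), each = n), log = TRUE))
  lw <- logpxz + logpz - logqz
  m <- max(lw)
  m + log(mean(exp(lw - m)))
}

#' Evolutionary fitness score of a point mutation
#'
#' Estimates -[log p(mutant) - log p(wild type)] by importance-weighted
#' posterior sampling from the trained VAE (the same posterior draws are
#' used for mutant and wild type to cancel sampling noise). Lower scores
#' mean higher evolutionary fitness; a mutation to the identical residue
#' scores exactly 0.
#'
#' @param model A trained [train_vae()] model.
#' @param wt_sequence Wild-type sequence (string or character vector) of
#'   the model's alignment length.
#' @param mutation Mutation label like `"V648E"` (wild-type residue,
#'   1-based alignment position, mutant residue).
#' @param n_posterior_samples Posterior draws (default 2000).
#' @param seed RNG seed (default 1).
#' @return Numeric score (unitless; lower = fitter).
#' @export
mutation_fitness <- function(model, wt_sequence, mutation,
                             n_posterior_samples = 2000, seed = 1) {
  wt <- if (length(wt_sequence) == 1) strsplit(wt_sequence, "")[[1]]
        else wt_sequence
  stopifnot(length(wt) == model$L)
  m <- parse_mutation(mutation)
  if (m$pos > model$L) stop("mutation position outside the alignment")
  if (wt[m$pos] != m$wt)
    stop("wild-type mismatch at position ", m$pos, ": sequence has ",
         wt[m$pos], ", mutation says ", m$wt)
  if (m$wt == m$mut) return(0)
  mut <- wt
  mut[m$pos] <- m$mut
  set.seed(seed)
  eps <- matrix(stats::rnorm(n_posterior_samples * model$arch$latent),
                n_posterior_samples, model$arch$latent)
  ll_wt <- .vae_loglik(model, .seq_onehot_row(wt), eps)
  ll_mut <- .vae_loglik(model, .seq_onehot_row(mut), eps)
  -(ll_mut - ll_wt)
}

#' Parse a mutation label
#'
#' @param mutation Label like `"V648E"`.
#' @return List with `wt`, `pos`, `mut`.
#' @export
parse_mutation <- function(mutation) {
  m <- regmatches(mutation,
                  regexec("^([A-Y])([0-9]+)([A-Y])$", mutation))[[1]]
  if (length(m) != 4) stop("cannot parse mutation label: ", mutation)
  list(wt = m[2], pos = as.integer(m[3]), mut = m[4])
}

# ---- interface geometry -----------------------------------------------------

#' Inter-chain residue contacts by heavy-atom distance
#'
#' A residue pair (one residue per chain) is in contact when any pair of
#' heavy (non-hydrogen) atoms lies closer than `cutoff`. Distances are
#' computed with a spatial binning grid of cell size `cutoff` and agree
#' exactly with the all-pairs brute force (see
#' [interface_contacts_brute()]).
#'
#' @param atoms Data frame with columns `chain`, `resno`, `elety` (atom
#'   name) or `element`, `x`, `y`, `z`; or a `bio3d` pdb object. At least
#'   two chains are required.
#' @param cutoff Contact cutoff, Angstrom (default 5.5).
#' @return List with `pairs` (data frame resno_A, resno_B, chain_A,
#'   chain_B, min_dist) and `interface_residues` (sorted unique residue
#'   numbers involved, across chains).
#' @export
interface_contacts <- function(atoms, cutoff = 5.5) {
  at <- .as_atom_table(atoms)
  chains <- unique(at$chain)
  if (length(chains) < 2) stop("need at least 2 chains for an interface")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  cell <- pmax(cutoff, 1e-6)
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  kid <- paste(key[, 1], key[, 2], key[, 3])
  cells <- split(seq_len(nrow(at)), kid)
  ckey <- do.call(rbind, strsplit(names(cells), " "))
  ckey <- matrix(as.integer(ckey), ncol = 3)
  hits <- new.env(parent = emptyenv())
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cellmap <- stats::setNames(seq_along(cells), names(cells))
  for (ci in seq_along(cells)) {
    ids_i <- cells[[ci]]
    for (o in seq_len(nrow(offs))) {
      nb <- ckey[ci, ] + offs[o, ]
      cj <- cellmap[paste(nb[1], nb[2], nb[3])]
      if (is.na(cj) || cj < ci) next
      ids_j <- cells[[cj]]
      for (i in ids_i) {
        js <- if (cj == ci) ids_j[ids_j > i] else ids_j
        if (!length(js)) next
        dif <- xyz[js, , drop = FALSE] -
          matrix(xyz[i, ], length(js), 3, byrow = TRUE)
        dd <- sqrt(rowSums(dif^2))
        ok <- js[dd < cutoff & at$chain[js] != at$chain[i]]
        ddok <- dd[dd < cutoff & at$chain[js] != at$chain[i]]
        for (k in seq_along(ok)) {
          j <- ok[k]
          a <- if (at$chain[i] < at$chain[j]) i else j
          b <- if (at$chain[i] < at$chain[j]) j else i
          id <- paste(at$chain[a], at$resno[a], at$chain[b], at$resno[b])
          prev <- hits[[id]]
          if (is.null(prev) || ddok[k] < prev$d)
            hits[[id]] <- list(ca = at$chain[a], ra = at$resno[a],
                               cb = at$chain[b], rb = at$resno[b],
                               d = ddok[k])
        }
      }
    }
  }
  ks <- ls(hits)
  pairs <- if (length(ks)) {
    do.call(rbind, lapply(ks, function(k) {
      h <- hits[[k]]
      data.frame(chain_A = h$ca, resno_A = h$ra, chain_B = h$cb,
                 resno_B = h$rb, min_dist = h$d)
    }))
  } else data.frame(chain_A = character(), resno_A = integer(),
                    chain_B = character(), resno_B = integer(),
                    min_dist = numeric())
  pairs <- pairs[order(pairs$chain_A, pairs$resno_A, pairs$resno_B), ]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       interface_residues = sort(unique(c(pairs$resno_A, pairs$resno_B))))
}

#' @rdname interface_contacts
#' @export
interface_contacts_brute <- function(atoms, cutoff = 5.5) {
  at <- .as_atom_table(atoms)
  if (length(unique(at$chain)) < 2) stop("need at least 2 chains")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  res <- list()
  idx <- which(outer(at$chain, at$chain, "<") & dm < cutoff, arr.ind = TRUE)
  if (nrow(idx)) {
    key <- paste(at$chain[idx[, 1]], at$resno[idx[, 1]],
                 at$chain[idx[, 2]], at$resno[idx[, 2]])
    agg <- tapply(dm[idx], key, min)
    parts <- do.call(rbind, strsplit(names(agg), " "))
    res <- data.frame(chain_A = parts[, 1],
                      resno_A = as.integer(parts[, 2]),
                      chain_B = parts[, 3],
                      resno_B = as.integer(parts[, 4]),
                      min_dist = as.numeric(agg))
    res <- res[order(res$chain_A, res$resno_A, res$resno_B), ]
    rownames(res) <- NULL
  } else {
    res <- data.frame(chain_A = character(), resno_A = integer(),
                      chain_B = character(), resno_B = integer(),
                      min_dist = numeric())
  }
  list(pairs = res,
       interface_residues = sort(unique(c(res$resno_A, res$resno_B))))
}

# normalize atoms input; drop hydrogens
.as_atom_table <- function(atoms) {
  if (inherits(atoms, "pdb")) atoms <- atoms$atom
  at <- as.data.frame(atoms)
  stopifnot(all(c("chain", "resno", "x", "y", "z") %in% names(at)))
  elem <- if ("element" %in% names(at) && !all(is.na(at$element)))
    at$element else substr(trimws(at$elety %||% "C"), 1, 1)
  at[toupper(elem) != "H", , drop = FALSE]
}

#' Rank interface mutations by evolutionary fitness
#'
#' Filters a fitness table to mutations at interface positions, sorts
#' ascending by score (lower = fitter) with stable ties broken by position
#' then mutant residue, and returns the top k.
#'
#' @param scores Data frame with columns `mutation` and `score`.
#' @param interface Integer vector of interface residue positions.
#' @param top_k Number of rows to return (default all).
#' @return The filtered, sorted data frame.
#' @export
rank_interface_mutations <- function(scores, interface, top_k = Inf) {
  stopifnot(nrow(scores) >= 1)
  parsed <- lapply(scores$mutation, parse_mutation)
  pos <- vapply(parsed, `[[`, integer(1), "pos")
  mut <- vapply(parsed, `[[`, character(1), "mut")
  keep <- pos %in% interface
  d <- scores[keep, , drop = FALSE]
  if (!nrow(d)) return(d)
  o <- order(d$score, pos[keep], mut[keep])
  d <- d[o, , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, top_k)
}

# ---- buried surface area ----------------------------------------------------

.vdw_radius <- function(element) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# quasi-uniform sphere points (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley SASA of an atom table (A^2)
.sasa <- function(at, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(at[, c("x", "y", "z")])
  elem <- if ("element" %in% names(at)) at$element else
    substr(trimws(at$elety), 1, 1)
  rad <- .vdw_radius(elem) + probe
  sp <- .sphere_points(n_points)
  total <- 0
  n <- nrow(xyz)
  for (i in seq_len(n)) {
    pts <- sweep(sp * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    d0 <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(d0 < rad + rad[i] & seq_len(n) != i)
    for (j in nb) {
      d <- sqrt(rowSums(sweep(pts, 2, xyz[j, ])^2))
      acc <- acc & d >= rad[j]
      if (!any(acc)) break
    }
    total <- total + 4 * pi * rad[i]^2 * mean(acc)
  }
  total
}

#' Buried surface fraction of a complex
#'
#' 100 * (sum of chain SASAs alone - SASA of the complex) / (sum of chain
#' SASAs alone), with solvent-accessible surface area computed by
#' Shrake-Rupley point sampling (default 960 points per atom, probe
#' radius 1.4 Angstrom). Invariant to rigid motion of the whole complex.
#'
#' @param atoms Atom table or `bio3d` pdb with at least two chains (see
#'   [interface_contacts()]).
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param n_points Sampling points per atom (default 960).
#' @return Percentage of surface buried on complex formation.
#' @export
buried_surface_fraction <- function(atoms, probe = 1.4, n_points = 960) {
  at <- .as_atom_table(atoms)
  chains <- unique(at$chain)
  if (length(chains) < 2) stop("need at least 2 chains")
  alone <- sum(vapply(chains, function(ch)
    .sasa(at[at$chain == ch, , drop = FALSE], probe, n_points),
    numeric(1)))
  complex <- .sasa(at, probe, n_points)
  100 * (alone - complex) / alone
}
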