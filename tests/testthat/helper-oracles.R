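# Independent oracles and random-fixture builders shared across tests.
# The oracles deliberately use naive explicit loops so they share no code
# with the implementation paths they check.

# O(n^2) double-loop sum of reversed PAE over both inter-chain blocks
oc_oracle <- function(reversed, length_a, length_b) {
  s <- 0
  for (i in seq_len(length_a)) {
    for (j in seq_len(length_b)) {
      s <- s + reversed[i, length_a + j] + reversed[length_a + j, i]
    }
  }
  s
}

# textbook OLS on (x, y): slope = S_xy / S_xx
ols_oracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(slope = slope, intercept = yb - slope * xb)
}

# all-against-all heavy-atom scan: per residue pair, min distance over
# explicit atom loops
contact_oracle <- function(model, chain_a, chain_b, cutoff) {
  a <- model[model$chain == chain_a & toupper(model$elesy) != "H", ]
  b <- model[model$chain == chain_b & toupper(model$elesy) != "H", ]
  out <- list()
  for (ra in unique(a$resno)) {
    for (rb in unique(b$resno)) {
      at_a <- a[a$resno == ra, ]
      at_b <- b[b$resno == rb, ]
      dmin <- Inf
      for (i in seq_len(nrow(at_a))) {
        for (j in seq_len(nrow(at_b))) {
          d <- sqrt((at_a$x[i] - at_b$x[j])^2 + (at_a$y[i] - at_b$y[j])^2 +
                      (at_a$z[i] - at_b$z[j])^2)
          dmin <- min(dmin, d)
        }
      }
      if (dmin <= cutoff)
        out[[length(out) + 1L]] <- data.frame(resno_a = ra, resno_b = rb,
                                              distance = dmin)
    }
  }
  if (length(out) == 0L)
    return(data.frame(resno_a = integer(), resno_b = integer(),
                      distance = numeric()))
  o <- do.call(rbind, out)
  o[order(o$resno_a, o$resno_b), , drop = FALSE]
}

# random two-chain PAE prediction with uniform values
random_pae_prediction <- function(length_a, length_b, max_pae = 31.75) {
  n <- length_a + length_b
  m <- matrix(stats::runif(n * n, 0, max_pae), n, n)
  part <- chain_partition(
    tibble::tibble(chain = c("A", "B"), length = c(length_a, length_b)),
    bait = "A", prey = "B")
  complex_prediction("A__B", "A", "B",
                     pae_matrix(m, max_pae = max_pae), part)
}

# random two-chain toy structure: residues of 2-4 atoms in a 15 A box,
# with occasional hydrogens to exercise the heavy-atom filter
random_toy_structure <- function(n_res_a = 5, n_res_b = 6, box = 15) {
  mk_chain <- function(chain, n_res) {
    do.call(rbind, lapply(seq_len(n_res), function(r) {
      n_at <- sample(2:4, 1)
      elety <- c("CA", sample(c("CB", "N", "O", "HB"), n_at - 1))
      data.frame(chain = chain, resno_auth = r, resid = "ALA",
                 elety = elety, elesy = substr(elety, 1, 1),
                 x = stats::runif(n_at, 0, box), y = stats::runif(n_at, 0, box),
                 z = stats::runif(n_at, 0, box))
    }))
  }
  structure_model(rbind(mk_chain("A", n_res_a), mk_chain("B", n_res_b)))
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid_motion <- function(model, rotation, translation) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rotation)
  model$x <- xyz[, 1] + translation[1]
  model$y <- xyz[, 2] + translation[2]
  model$z <- xyz[, 3] + translation[3]
  model
}

# standard planted-contact table covering all three classes
planted_contacts_spec <- function() {
  tibble::tibble(
    res_a = c("ASP", "GLN", "ALA"),
    atom_a = c("OD1", "NE2", "CB"),
    res_b = c("LYS", "PHE", "LEU"),
    atom_b = c("NZ", "O", "CD1"),
    distance = c(3.5, 3.2, 4.0),
    class = c("salt_bridge", "polar", "generic"))
}
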