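# Shared fixture builders. Everything is generated in code, seeded, and
# small enough to run in seconds.

# Brute-force donor-H-acceptor enumeration: the cubic-loop oracle the cell
# list implementation must reproduce on small inputs.
brute_force_triplets <- function(atoms, flavor, reach = 4.5) {
  fl <- pammotif::hb_flavors()
  fl <- fl[fl$flavor == flavor, ]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  out <- 0L
  don <- which(atoms$element == fl$donor)
  acc <- which(atoms$element == fl$acceptor)
  hyd <- which(atoms$element == "H")
  for (d in don) for (a in acc) for (h in hyd) {
    if (d == a) next
    d_dh <- sqrt(sum((xyz[d, ] - xyz[h, ])^2))
    d_ah <- sqrt(sum((xyz[a, ] - xyz[h, ])^2))
    if (d_dh <= reach && d_ah <= reach) out <- out + 1L
  }
  out
}

brute_force_filtered <- function(atoms, flavor, max_reach = 4.5) {
  fl <- pammotif::hb_flavors()
  fl <- fl[fl$flavor == flavor, ]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  out <- 0L
  don <- which(atoms$element == fl$donor)
  acc <- which(atoms$element == fl$acceptor)
  hyd <- which(atoms$element == "H")
  for (d in don) for (a in acc) for (h in hyd) {
    if (d == a) next
    d_dh <- sqrt(sum((xyz[d, ] - xyz[h, ])^2))
    d_ah <- sqrt(sum((xyz[a, ] - xyz[h, ])^2))
    if (d_dh + d_ah <= max_reach && d_dh < d_ah) out <- out + 1L
  }
  out
}

# A small random cloud of N/O/H atoms for enumeration tests.
random_noh_atoms <- function(n_n = 3, n_o = 3, n_h = 4, seed = 1, spread = 3) {
  set.seed(seed)
  n <- n_n + n_o + n_h
  tibble::tibble(
    eleno = seq_len(n),
    name = c(rep("N", n_n), rep("O", n_o), rep("H", n_h)),
    altloc = "", resname = "UNK", chain = "A",
    resno = seq_len(n), insert = "",
    x = stats::runif(n, 0, spread),
    y = stats::runif(n, 0, spread),
    z = stats::runif(n, 0, spread),
    occupancy = 1,
    element = c(rep("N", n_n), rep("O", n_o), rep("H", n_h)),
    is_hetero = FALSE
  )
}

# Minimal hand-written PDB fixtures.
write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1.0, element = substr(name, 1, 1),
                          altloc = " ", record = "ATOM") {
  sprintf("%-6s%5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resno,
          x, y, z, occ, 0, element)
}

# Independent torsion oracle: projection onto the plane normal to the
# central bond, then the signed angle via acos and a sign from the triple
# product (a different route than the atan2 implementation).
torsion_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  b2u <- b2 / sqrt(sum(b2^2))
  u <- b1 - sum(b1 * b2u) * b2u
  w <- b3 - sum(b3 * b2u) * b2u
  ang <- acos(max(-1, min(1, -sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
  s <- sum(pammotif:::pracma_cross(u, w) * b2u)
  if (s > 0) -ang else ang
}

three_class_modes <- function(sigma = 10) {
  tibble::tibble(
    code = c("H", "E", "C"),
    phi = c(-60, -135, 60), psi = c(-45, 135, 45),
    sigma = sigma, weight = rep(1 / 3, 3)
  )
}

three_gauss_pool <- function(n_per, sep = 6, sd = 1, seed = 71) {
  set.seed(seed)
  mk <- function(n, mu, lab) tibble::tibble(
    f1 = stats::rnorm(n, mu[1], sd), f2 = stats::rnorm(n, mu[2], sd), label = lab)
  dplyr::bind_rows(mk(n_per, c(0, 0), "H"),
                   mk(n_per, c(sep, 0), "E"),
                   mk(n_per, c(0, sep), "C"))
}

rotation_matrix <- function(th) {
  Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2])), 3, 3)
  Ry <- matrix(c(cos(th[3]), 0, sin(th[3]), 0, 1, 0, -sin(th[3]), 0, cos(th[3])), 3, 3)
  Rz %*% Rx %*% Ry
}

# A synthetic chain with persistent (run-structured) labels: neighbouring
# residues usually share a class, so widening a dihedral window adds real
# information about the center label.
run_labeled_chain <- function(n_res, sigma = 45, run_length = 20, seed = 1) {
  set.seed(seed)
  cm <- three_class_modes(sigma = sigma)
  labels <- character(n_res)
  i <- 1L
  while (i <= n_res) {
    len <- 1L + stats::rgeom(1, 1 / run_length)
    code <- sample(cm$code, 1)
    labels[i:min(n_res, i + len - 1L)] <- code
    i <- i + len
  }
  k <- match(labels, cm$code)
  tibble::tibble(
    chain = "A", resno = seq_len(n_res), insert = "", resname = "GLY",
    phi = pammotif:::wrap_principal(stats::rnorm(n_res, cm$phi[k], sigma), 360),
    psi = pammotif:::wrap_principal(stats::rnorm(n_res, cm$psi[k], sigma), 360),
    complete = TRUE,
    linked_next = c(rep(TRUE, n_res - 1L), FALSE),
    label = labels
  )
}
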