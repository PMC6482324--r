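#' Signed torsion angle of four points
#'
#' IUPAC convention: looking down the b2 = p3 - p2 axis, the angle from the
#' plane (p1, p2, p3) to the plane (p2, p3, p4), positive clockwise, in
#' `(-180, 180]` degrees.
#'
#' @param p1,p2,p3,p4 3-vectors (or matrices with one point per row).
#' @return Torsion angle(s) in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1L)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (any(rowSums(n1 * n1) < 1e-20) || any(rowSums(n2 * n2) < 1e-20)) {
    stop("degenerate torsion: three consecutive points are collinear", call. = FALSE)
  }
  b2n <- b2 / sqrt(rowSums(b2 * b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  if (length(ang) == 1L) as.numeric(ang) else as.numeric(ang)
}

# First matching backbone atom per residue (prefers blank altloc, then 'A').
backbone_table <- function(atoms) {
  bb <- atoms[atoms$name %in% c("N", "CA", "C") & !atoms$is_hetero, , drop = FALSE]
  pref <- match(bb$altloc, c("", "A"))
  pref[is.na(pref)] <- 3L
  bb <- bb[order(match(bb$chain, unique(bb$chain)), bb$resno, bb$insert, pref), , drop = FALSE]
  key <- paste(bb$chain, bb$resno, bb$insert, bb$name)
  bb[!duplicated(key), , drop = FALSE]
}

#' Backbone dihedral angles per residue
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i); psi(i) is
#' N(i)-CA(i)-C(i)-N(i+1). Chain termini, residues with missing backbone
#' atoms and residues flanking a chain break (peptide C-N distance above
#' `break_distance`) are returned with `complete = FALSE` and `NA` angles
#' rather than fabricated values.
#'
#' @param structure a `protein_structure` (or its atoms tibble).
#' @param break_distance C(i)-N(i+1) distance (Angstrom) above which two
#'   consecutively listed residues are treated as a chain break.
#' @return Tibble with one row per residue: `chain`, `resno`, `insert`,
#'   `resname`, `phi`, `psi` (degrees in `(-180, 180]`), `complete`
#'   (both angles defined) and `linked_next` (peptide bond to the next
#'   listed residue intact).
#' @export
phi_psi <- function(structure, break_distance = 2.5) {
  atoms <- if (inherits(structure, "protein_structure")) structure$atoms else structure
  bb <- backbone_table(atoms)
  if (nrow(bb) == 0L) {
    return(tibble::tibble(chain = character(0), resno = integer(0),
                          insert = character(0), resname = character(0),
                          phi = numeric(0), psi = numeric(0),
                          complete = logical(0), linked_next = logical(0)))
  }
  res <- bb[!duplicated(paste(bb$chain, bb$resno, bb$insert)),
            c("chain", "resno", "insert", "resname")]
  nres <- nrow(res)
  coord <- function(name) {
    i <- match(paste(res$chain, res$resno, res$insert, name),
               paste(bb$chain, bb$resno, bb$insert, bb$name))
    out <- matrix(NA_real_, nres, 3L)
    ok <- !is.na(i)
    out[ok, ] <- as.matrix(bb[i[ok], c("x", "y", "z")])
    out
  }
  N <- coord("N"); CA <- coord("CA"); C <- coord("C")
  have <- rowSums(is.na(N) + is.na(CA) + is.na(C)) == 0
  same_chain_next <- c(res$chain[-1] == res$chain[-nres], FALSE)
  linked_next <- rep(FALSE, nres)
  idx <- which(same_chain_next)
  if (length(idx) > 0L) {
    dCN <- sqrt(rowSums((C[idx, , drop = FALSE] - N[idx + 1L, , drop = FALSE])^2))
    linked_next[idx] <- have[idx] & have[idx + 1L] & !is.na(dCN) & dCN <= break_distance
  }
  phi <- rep(NA_real_, nres); psi <- rep(NA_real_, nres)
  iphi <- which(c(FALSE, linked_next[-nres]) & have)
  if (length(iphi) > 0L) {
    phi[iphi] <- dihedral_angle(C[iphi - 1L, , drop = FALSE],
                                N[iphi, , drop = FALSE],
                                CA[iphi, , drop = FALSE],
                                C[iphi, , drop = FALSE])
  }
  ipsi <- which(linked_next & have)
  if (length(ipsi) > 0L) {
    psi[ipsi] <- dihedral_angle(N[ipsi, , drop = FALSE],
                                CA[ipsi, , drop = FALSE],
                                C[ipsi, , drop = FALSE],
                                N[ipsi + 1L, , drop = FALSE])
  }
  tibble::tibble(
    chain = res$chain, resno = res$resno, insert = res$insert,
    resname = res$resname, phi = phi, psi = psi,
    complete = !is.na(phi) & !is.na(psi), linked_next = linked_next
  )
}

#' Windows of consecutive-residue dihedrals
#'
#' Builds one 2w-dimensional feature row per center residue that sits in a
#' run of `w` consecutive, chain-linked residues with both angles defined.
#' Feature columns are `phi_1, psi_1, ..., phi_w, psi_w` in chain order;
#' the center residue's identity (and, if present, its `label` column) is
#' carried along.
#'
#' @param records output of [phi_psi()], optionally with a `label` column.
#' @param w window length: 1, 3 or 5 residues (2, 6 or 10 dimensions).
#' @return Tibble of windows.
#' @export
dihedral_windows <- function(records, w = 1L) {
  stopifnot(w %in% c(1L, 3L, 5L))
  h <- (w - 1L) %/% 2L
  feat_names <- paste0(rep(c("phi_", "psi_"), w), rep(seq_len(w), each = 2L))
  out <- list()
  for (ch in unique(records$chain)) {
    r <- records[records$chain == ch, , drop = FALSE]
    n <- nrow(r)
    if (n < w) next
    centers <- seq_len(n)
    ok <- rep(TRUE, n)
    for (off in -h:h) {
      j <- centers + off
      valid <- j >= 1L & j <= n
      ok <- ok & valid
      ok[valid] <- ok[valid] & r$complete[j[valid]]
    }
    if (h > 0L) {
      for (off in -h:(h - 1L)) {
        j <- centers + off
        valid <- j >= 1L & j <= n
        ok <- ok & valid
        ok[valid] <- ok[valid] & r$linked_next[j[valid]]
      }
    }
    centers <- centers[ok]
    if (length(centers) == 0L) next
    feat <- matrix(0, length(centers), 2L * w)
    col <- 0L
    for (off in -h:h) {
      feat[, col + 1L] <- r$phi[centers + off]
      feat[, col + 2L] <- r$psi[centers + off]
      col <- col + 2L
    }
    colnames(feat) <- feat_names
    tb <- tibble::tibble(chain = ch, resno = r$resno[centers],
                         insert = r$insert[centers])
    tb <- dplyr::bind_cols(tb, tibble::as_tibble(feat))
    if ("label" %in% names(r)) tb$label <- r$label[centers]
    out[[length(out) + 1L]] <- tb
  }
  if (length(out) == 0L) {
    return(tibble::as_tibble(stats::setNames(
      c(list(character(0), integer(0), character(0)),
        rep(list(numeric(0)), 2L * w)),
      c("chain", "resno", "insert", feat_names))))
  }
  dplyr::bind_rows(out)
}
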