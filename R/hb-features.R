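#' The four hydrogen-bond flavors
#'
#' A putative hydrogen bond is a donor-hydrogen-acceptor triplet; donor and
#' acceptor are each N or O, giving four flavors.
#'
#' @return Tibble with columns `flavor`, `donor`, `acceptor`.
#' @export
hb_flavors <- function() {
  tibble::tibble(
    flavor = c("N-H...N", "N-H...O", "O-H...O", "O-H...N"),
    donor = c("N", "N", "O", "O"),
    acceptor = c("N", "O", "O", "N")
  )
}

parse_flavor <- function(flavor) {
  fl <- hb_flavors()
  i <- match(flavor, fl$flavor)
  if (is.na(i)) {
    stop("unknown hydrogen-bond flavor '", flavor, "'; one of: ",
         paste(fl$flavor, collapse = ", "), call. = FALSE)
  }
  fl[i, ]
}

# All index pairs (i in A, j in B) with |A_i - B_j| <= cutoff, via a cell
# list on B so enumeration stays linear in the number of atoms. Returns a
# two-column integer matrix.
radius_pairs <- function(A, B, cutoff) {
  if (nrow(A) == 0L || nrow(B) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  origin <- apply(rbind(A, B), 2L, min)
  cell_of <- function(M) {
    ix <- floor(sweep(M, 2L, origin, "-") / cutoff)
    ix[, 1] * 73856093 + ix[, 2] * 19349663 + ix[, 3] * 83492791
  }
  keyB <- cell_of(B)
  lookup <- split(seq_len(nrow(B)), keyB)
  ixA <- floor(sweep(A, 2L, origin, "-") / cutoff)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- vector("list", nrow(A))
  for (i in seq_len(nrow(A))) {
    cells <- sweep(offsets, 2L, as.numeric(ixA[i, ]), "+")
    keys <- as.character(cells[, 1] * 73856093 + cells[, 2] * 19349663 +
                           cells[, 3] * 83492791)
    cand <- unlist(lookup[keys], use.names = FALSE)
    if (length(cand) == 0L) next
    d2 <- (B[cand, 1] - A[i, 1])^2 + (B[cand, 2] - A[i, 2])^2 +
      (B[cand, 3] - A[i, 3])^2
    hit <- cand[d2 <= cutoff^2]
    if (length(hit) > 0L) out_i[[i]] <- cbind(i, hit)
  }
  out <- do.call(rbind, out_i)
  if (is.null(out)) matrix(integer(0), ncol = 2L) else out
}

#' Enumerate putative hydrogen-bond triplets of one flavor
#'
#' Every donor-hydrogen-acceptor combination whose donor and acceptor
#' elements match the flavor and whose hydrogen lies within `reach` of both
#' donor and acceptor is produced exactly once. No covalent-bond
#' information is used: triplets of chemically bonded atoms are enumerated
#' too, and it is the job of the downstream density analysis (or of
#' [filter_hb_triplets()]) to deal with them.
#'
#' @param atoms atom tibble (e.g. from [select_atoms()]) with columns
#'   `element`, `x`, `y`, `z` and residue metadata.
#' @param flavor one of `"N-H...N"`, `"N-H...O"`, `"O-H...O"`, `"O-H...N"`.
#' @param reach neighbour-search radius (Angstrom) around each hydrogen;
#'   with the default 4.5 no triplet passing the `d_DH + d_AH <= 4.5`
#'   filter can be missed.
#' @return Tibble with one row per triplet: atom row indices
#'   (`donor_idx`, `hydrogen_idx`, `acceptor_idx`), residue metadata for
#'   donor and acceptor, the three distances `d_DA`, `d_AH`, `d_DH`
#'   (Angstrom) and `angle_ADH` (degrees, at the donor between the
#'   donor-acceptor and donor-hydrogen directions).
#' @export
hb_triplets <- function(atoms, flavor = "N-H...O", reach = 4.5) {
  fl <- parse_flavor(flavor)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  hyd <- which(atoms$element == "H")
  don <- which(atoms$element == fl$donor)
  acc <- which(atoms$element == fl$acceptor)
  empty <- tibble::tibble(
    flavor = character(0), donor_idx = integer(0), hydrogen_idx = integer(0),
    acceptor_idx = integer(0), donor_chain = character(0),
    donor_resno = integer(0), acceptor_chain = character(0),
    acceptor_resno = integer(0), d_DA = numeric(0), d_AH = numeric(0),
    d_DH = numeric(0), angle_ADH = numeric(0)
  )
  if (length(hyd) == 0L || length(don) == 0L || length(acc) == 0L) return(empty)
  hd <- radius_pairs(xyz[hyd, , drop = FALSE], xyz[don, , drop = FALSE], reach)
  ha <- radius_pairs(xyz[hyd, , drop = FALSE], xyz[acc, , drop = FALSE], reach)
  if (nrow(hd) == 0L || nrow(ha) == 0L) return(empty)
  hd_by_h <- split(don[hd[, 2]], hd[, 1])
  ha_by_h <- split(acc[ha[, 2]], ha[, 1])
  rows <- list()
  for (h_key in intersect(names(hd_by_h), names(ha_by_h))) {
    h <- hyd[as.integer(h_key)]
    dd <- hd_by_h[[h_key]]
    aa <- ha_by_h[[h_key]]
    grid <- expand.grid(donor = dd, acceptor = aa)
    grid <- grid[grid$donor != grid$acceptor, , drop = FALSE]
    if (nrow(grid) == 0L) next
    rows[[length(rows) + 1L]] <- cbind(grid, hydrogen = h)
  }
  if (length(rows) == 0L) return(empty)
  tri <- do.call(rbind, rows)
  D <- xyz[tri$donor, , drop = FALSE]
  A <- xyz[tri$acceptor, , drop = FALSE]
  H <- xyz[tri$hydrogen, , drop = FALSE]
  d_DA <- sqrt(rowSums((D - A)^2))
  d_AH <- sqrt(rowSums((A - H)^2))
  d_DH <- sqrt(rowSums((D - H)^2))
  va <- A - D; vh <- H - D
  cosang <- rowSums(va * vh) / (d_DA * d_DH)
  cosang <- pmin(1, pmax(-1, cosang))
  tibble::tibble(
    flavor = fl$flavor,
    donor_idx = tri$donor, hydrogen_idx = tri$hydrogen,
    acceptor_idx = tri$acceptor,
    donor_chain = atoms$chain[tri$donor],
    donor_resno = atoms$resno[tri$donor],
    acceptor_chain = atoms$chain[tri$acceptor],
    acceptor_resno = atoms$resno[tri$acceptor],
    d_DA = d_DA, d_AH = d_AH, d_DH = d_DH,
    angle_ADH = acos(cosang) * 180 / pi
  )
}

#' Geometric pre-filter for hydrogen-bond triplets
#'
#' Keeps triplets with `d_DH + d_AH <= max_reach` and `d_DH < d_AH`. The
#' second condition removes the duplicate role assignment: a triplet with
#' the hydrogen closer to the "acceptor" is the same geometry with donor
#' and acceptor labels interchanged, and survives under the opposite
#' flavor instead. Exact ties `d_DH == d_AH` are discarded (both role
#' assignments would be ambiguous) and reported.
#'
#' @param triplets tibble from [hb_triplets()].
#' @param max_reach maximum value of `d_DH + d_AH` (Angstrom).
#' @return The filtered tibble.
#' @export
filter_hb_triplets <- function(triplets, max_reach = 4.5) {
  ties <- sum(triplets$d_DH == triplets$d_AH)
  if (ties > 0L) message("discarding ", ties, " exact d_DH == d_AH tie(s)")
  triplets[triplets$d_DH + triplets$d_AH <= max_reach &
             triplets$d_DH < triplets$d_AH, , drop = FALSE]
}

#' Kabsch-Sander electrostatic hydrogen-bond energy
#'
#' The DSSP estimate for a backbone (C=O, N-H) pair:
#' `E = 27.888 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)` kcal/mol, where
#' 27.888 kcal*A/mol is the product of the partial charges (0.42 e, 0.20 e)
#' and the electrostatic conversion factor 332. Pairs with `E < -0.5`
#' kcal/mol count as hydrogen bonds. Distances at or below `guard` produce
#' `NA` (singular geometry) with a warning.
#'
#' @param d_ON,d_CH,d_OH,d_CN the four inter-atomic distances (Angstrom);
#'   vectorized.
#' @param guard minimal physical distance (Angstrom).
#' @return Energy in kcal/mol (`NA` where singular).
#' @export
kabsch_sander_energy <- function(d_ON, d_CH, d_OH, d_CN, guard = 0.5) {
  bad <- d_ON <= guard | d_CH <= guard | d_OH <= guard | d_CN <= guard
  if (any(bad)) {
    warning(sum(bad), " quadruplet(s) with a distance <= ", guard,
            " A flagged singular", call. = FALSE)
  }
  e <- 27.888 * (1 / d_ON + 1 / d_CH - 1 / d_OH - 1 / d_CN)
  e[bad] <- NA_real_
  e
}

#' Enumerate backbone DSSP quadruplets
#'
#' Pairs every backbone carbonyl group (atoms named `C`, `O`) with every
#' backbone amide group (atoms named `N`, `H`) for which all four atoms
#' pass the occupancy threshold, computes the four Kabsch-Sander distances
#' and the electrostatic energy, and maps each quadruplet into
#' `(d_AH, d_DA)` space as (oxygen-hydrogen, nitrogen-oxygen). Same-residue
#' and directly bonded pairs are not pre-excluded.
#'
#' @param structure a `protein_structure` or an atoms tibble.
#' @param min_occupancy occupancy threshold applied to all four atoms.
#' @param max_d_on optional cap on the O..N distance (Angstrom) to bound
#'   the enumeration; `Inf` enumerates all pairs.
#' @return Tibble with donor/acceptor residue metadata, the four distances,
#'   `energy` (kcal/mol), `hbond` (`energy < -0.5`), `d_AH` and `d_DA`.
#' @export
dssp_quadruplets <- function(structure, min_occupancy = 0.95, max_d_on = Inf) {
  atoms <- if (inherits(structure, "protein_structure")) structure$atoms else structure
  atoms <- atoms[!atoms$is_hetero & atoms$occupancy >= min_occupancy, , drop = FALSE]
  pick <- function(nm, el) which(atoms$name == nm & atoms$element == el)
  res_key <- paste(atoms$chain, atoms$resno, atoms$insert)
  groups <- function(i1, i2) {
    # match two backbone atoms within the same residue
    k1 <- res_key[i1]; k2 <- res_key[i2]
    m <- match(k1, k2)
    ok <- !is.na(m)
    cbind(i1[ok], i2[m[ok]])
  }
  co <- groups(pick("C", "C"), pick("O", "O"))
  nh <- groups(pick("N", "N"), pick("H", "H"))
  empty <- tibble::tibble(
    acceptor_chain = character(0), acceptor_resno = integer(0),
    donor_chain = character(0), donor_resno = integer(0),
    seq_sep = integer(0), d_ON = numeric(0), d_CH = numeric(0),
    d_OH = numeric(0), d_CN = numeric(0), energy = numeric(0),
    hbond = logical(0), d_AH = numeric(0), d_DA = numeric(0)
  )
  if (nrow(co) == 0L || nrow(nh) == 0L) return(empty)
  pairs <- expand.grid(i = seq_len(nrow(co)), j = seq_len(nrow(nh)))
  ci <- co[pairs$i, 1]; oi <- co[pairs$i, 2]
  ni <- nh[pairs$j, 1]; hi <- nh[pairs$j, 2]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dist2 <- function(a, b) sqrt(rowSums((xyz[a, , drop = FALSE] - xyz[b, , drop = FALSE])^2))
  d_ON <- dist2(oi, ni)
  keep <- d_ON <= max_d_on
  ci <- ci[keep]; oi <- oi[keep]; ni <- ni[keep]; hi <- hi[keep]; d_ON <- d_ON[keep]
  if (length(ci) == 0L) return(empty)
  d_CH <- dist2(ci, hi); d_OH <- dist2(oi, hi); d_CN <- dist2(ci, ni)
  energy <- kabsch_sander_energy(d_ON, d_CH, d_OH, d_CN)
  tibble::tibble(
    acceptor_chain = atoms$chain[oi], acceptor_resno = atoms$resno[oi],
    donor_chain = atoms$chain[ni], donor_resno = atoms$resno[ni],
    seq_sep = ifelse(atoms$chain[oi] == atoms$chain[ni],
                     atoms$resno[ni] - atoms$resno[oi], NA_integer_),
    d_ON = d_ON, d_CH = d_CH, d_OH = d_OH, d_CN = d_CN,
    energy = energy, hbond = !is.na(energy) & energy < -0.5,
    d_AH = d_OH, d_DA = d_ON
  )
}
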