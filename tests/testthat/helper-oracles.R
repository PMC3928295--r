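## Independent brute-force oracles, deliberately written without reusing the
## package's internal helpers, plus small fixture builders.

ANG_PER_BOHR <- 0.52917721067
KCAL_PER_HARTREE <- 627.509474

## Brute-force minimum interatomic distance (Angstrom) between two atom sets.
oracle_min_dist_ang <- function(geometry, atoms_i, atoms_j) {
  xyz <- geometry$coords * ANG_PER_BOHR
  best <- Inf
  for (a in atoms_i) for (b in atoms_j) {
    best <- min(best, sqrt(sum((xyz[a, ] - xyz[b, ])^2)))
  }
  best
}

## Brute-force domain assignment by explicit pairwise distance enumeration:
## A = fragments within r_active of the center fragment; b = remaining
## fragments within r_buffer of any A fragment; F = the rest.
oracle_assign_domains <- function(geometry, groups, center, r_active,
                                  r_buffer) {
  n <- length(groups)
  d_center <- vapply(seq_len(n), function(k)
    oracle_min_dist_ang(geometry, groups[[k]], groups[[center]]), 1.0)
  A <- which(d_center <= r_active)
  A <- sort(union(A, center))
  rest <- setdiff(seq_len(n), A)
  d_A <- vapply(rest, function(k)
    min(vapply(A, function(a)
      oracle_min_dist_ang(geometry, groups[[k]], groups[[a]]), 1.0)), 1.0)
  b <- rest[d_A <= r_buffer]
  list(A = A, b = sort(b), F = sort(setdiff(rest, b)))
}

## Independent evaluation of the mock cross-fragment pair interaction
## (Lennard-Jones + Coulomb) between two atom groups, using the documented
## parameter tables through their exported accessors only.
oracle_cross_energy <- function(geometry, atoms_i, atoms_j, q_i, q_j) {
  mp <- fragopt:::.mock_elements
  par <- function(el, what) {
    i <- match(el, mp$element)
    if (is.na(i)) fragopt:::.mock_default[[what]] else mp[[what]][i]
  }
  e <- 0
  for (a in seq_along(atoms_i)) for (b in seq_along(atoms_j)) {
    ia <- atoms_i[a]; jb <- atoms_j[b]
    r <- sqrt(sum((geometry$coords[ia, ] - geometry$coords[jb, ])^2))
    sig <- 0.5 * (par(geometry$elements[ia], "sigma") +
                  par(geometry$elements[jb], "sigma"))
    eps <- sqrt(par(geometry$elements[ia], "eps") *
                par(geometry$elements[jb], "eps"))
    sr6 <- (sig / r)^6
    e <- e + 4 * eps * (sr6^2 - sr6) + q_i[a] * q_j[b] / r
  }
  e
}

## Dense linear-solve polarization oracle: mu = (diag(1/alpha) - T)^-1 F,
## E = -1/2 mu.F, with T restricted to inter-fragment site pairs.
oracle_pol_energy <- function(coords, q, alpha, frag) {
  n <- nrow(coords)
  field <- matrix(0, n, 3)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (frag[j] == frag[i]) next
    d <- coords[i, ] - coords[j, ]
    r <- sqrt(sum(d * d))
    field[i, ] <- field[i, ] + q[j] * d / r^3
  }
  pol <- which(alpha > 0)
  if (length(pol) == 0) return(0)
  m <- length(pol)
  B <- diag(rep(1 / alpha[pol], each = 3))
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a == b) next
    ia <- pol[a]; jb <- pol[b]
    if (frag[ia] == frag[jb]) next
    d <- coords[ia, ] - coords[jb, ]
    r <- sqrt(sum(d * d))
    Tij <- (3 * tcrossprod(d) / r^2 - diag(3)) / r^3
    B[(a - 1) * 3 + 1:3, (b - 1) * 3 + 1:3] <- -Tij
  }
  mu <- solve(B, as.numeric(t(field[pol, , drop = FALSE])))
  mu <- matrix(mu, ncol = 3, byrow = TRUE)
  -0.5 * sum(mu * field[pol, , drop = FALSE])
}

## Full-coverage partition with every fragment active.
all_active_partition <- function(fragments, high_level = fragments$id[1]) {
  domain_partition(integer(0), integer(0), fragments$id, high_level,
                   fragments)
}

## A tiny three-residue PDB written in fixed-column format.
write_test_pdb <- function(path, altloc_on_atom = NA) {
  rec <- function(serial, name, alt, resname, chain, resno, x, y, z, el) {
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, resname, chain, resno, x, y, z, 1, 0, el)
  }
  lines <- character(0)
  serial <- 0
  for (res in 1:3) {
    for (at in 1:2) {
      serial <- serial + 1
      alt <- " "
      if (!is.na(altloc_on_atom) && serial == altloc_on_atom) alt <- "A"
      lines <- c(lines, rec(serial, c("N", "CA")[at], alt, "GLY", "A", res,
                            res * 3.0, at * 1.2, 0, c("N", "C")[at]))
      if (!is.na(altloc_on_atom) && serial == altloc_on_atom) {
        lines <- c(lines, rec(serial, c("N", "CA")[at], "B", "GLY", "A", res,
                              res * 3.0 + 0.3, at * 1.2, 0, c("N", "C")[at]))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
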