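# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral point set (no RNG), and the SASA-difference buried
# interface area between two parts of a complex.

# n approximately-uniform points on the unit sphere (golden spiral);
# deterministic, so SASA values are exactly reproducible
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Approximates each atom's solvent-accessible surface area by placing
#' `n_sphere_points` quasi-uniform test points on the solvent-expanded
#' sphere of radius `r_atom + probe_radius` and counting the points not
#' buried inside any neighbouring atom's expanded sphere:
#' `area = accessible/total * 4 * pi * (r_atom + probe)^2`. The point set
#' is a deterministic golden spiral, so results carry no sampling
#' randomness.
#'
#' @param x a [Structure()].
#' @param probe_radius solvent probe radius, angstrom (default 1.4, a
#'   water molecule).
#' @param n_sphere_points test points per atom (default 960; accuracy
#'   improves roughly with the square root of this count).
#' @param radii optional named vector of per-element vdW radii (angstrom);
#'   defaults to the Bondi set of [vdw_radii()], unknown elements 1.7 with
#'   a warning.
#' @return an object of class `SasaResult`: list with `per_atom` (numeric
#'   vector, one area per atom), `per_residue` (data frame `key`, `chain`,
#'   `resno`, `resn`, `sasa`), `probe_radius`, `n_sphere_points`,
#'   `radii_set_name`.
#' @examples
#' cfg <- generator_config(seed = 1, n_residues = 20,
#'                         entrance_window = c(5, 12))
#' res <- shrake_rupley(make_receptor(cfg))
#' head(res$per_residue)
#' @export
shrake_rupley <- function(x, probe_radius = 1.4, n_sphere_points = 960,
                          radii = NULL) {
  stopifnot(inherits(x, "Structure"), probe_radius >= 0,
            n_sphere_points >= 12)
  xyz <- coords(x)
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (is.null(radii)) {
    r <- vdw_radii(x$atoms$element)
    radii_name <- "bondi"
  } else {
    r <- unname(radii[x$atoms$element])
    if (anyNA(r)) {
      warning("no radius supplied for element(s) ",
              paste(unique(x$atoms$element[is.na(r)]), collapse = ", "),
              "; using 1.7 A")
      r[is.na(r)] <- 1.7
    }
    radii_name <- "custom"
  }
  rs <- r + probe_radius               # solvent-expanded radii
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  # neighbour lists from the cell grid: atoms whose expanded spheres
  # can intersect (centre distance < rs_i + rs_j)
  nb <- contact_pairs(xyz, xyz, cutoff = 1e-9, surface = TRUE,
                      ra = rs, rb = rs)
  nb <- nb[nb[, "i"] != nb[, "j"], , drop = FALSE]
  nb_of <- split(nb[, "i"], nb[, "j"])
  per_atom <- numeric(n)
  for (j in seq_len(n)) {
    p <- sweep(pts * rs[j], 2, xyz[j, ], "+")
    neigh <- nb_of[[as.character(j)]]
    acc <- n_sphere_points
    if (!is.null(neigh) && length(neigh)) {
      free <- rep(TRUE, n_sphere_points)
      for (k in neigh) {
        if (!any(free)) break
        d2 <- (p[free, 1] - xyz[k, 1])^2 + (p[free, 2] - xyz[k, 2])^2 +
          (p[free, 3] - xyz[k, 3])^2
        free[free] <- d2 >= rs[k]^2
      }
      acc <- sum(free)
    }
    per_atom[j] <- acc / n_sphere_points * 4 * pi * rs[j]^2
  }
  keys <- atom_residue_keys(x)
  rt <- residue_table(x)
  per_res <- data.frame(rt[, c("key", "chain", "resno", "resn")],
                        sasa = as.numeric(tapply(per_atom, keys,
                                                 sum)[rt$key]),
                        row.names = NULL)
  structure(list(per_atom = per_atom, per_residue = per_res,
                 probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii_set_name = radii_name),
            class = "SasaResult")
}

#' @export
print.SasaResult <- function(x, ...) {
  cat("SasaResult: ", length(x$per_atom), " atoms, total ",
      round(sum(x$per_atom), 1), " A^2 (probe ", x$probe_radius,
      " A, ", x$n_sphere_points, " points, ", x$radii_set_name,
      " radii)\n", sep = "")
  invisible(x)
}

#' Buried interface (contact) area between two parts of a complex
#'
#' The standard SASA-difference definition:
#' `(SASA(A alone) + SASA(B alone) - SASA(A and B together)) / 2`,
#' i.e. the area of either molecule's surface buried by the other. It is
#' symmetric in A and B and non-negative up to numerical tolerance.
#'
#' @param complex a [Structure()] holding both molecules.
#' @param part_a,part_b disjoint integer atom-index selections into
#'   `complex` (see [atom_select()]).
#' @inheritParams shrake_rupley
#' @return buried area in square angstrom (single number).
#' @export
contact_area <- function(complex, part_a, part_b, probe_radius = 1.4,
                         n_sphere_points = 960, radii = NULL) {
  stopifnot(inherits(complex, "Structure"))
  if (length(intersect(part_a, part_b)))
    stop("selections overlap: contact area needs disjoint parts")
  if (!length(part_a) || !length(part_b)) stop("empty selection")
  sasa_of <- function(idx)
    sum(shrake_rupley(subset_structure(complex, idx),
                      probe_radius = probe_radius,
                      n_sphere_points = n_sphere_points,
                      radii = radii)$per_atom)
  (sasa_of(part_a) + sasa_of(part_b) -
      sasa_of(c(part_a, part_b))) / 2
}
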