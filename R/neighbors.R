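# Cell-list (spatial grid) neighbour search used by every contact
# statistic. Atoms are binned into cubic cells at least as wide as the
# effective cutoff; only the 27 cells around a query atom's cell need to
# be examined, giving near-linear scaling in atom count. Correctness is
# pinned to an all-pairs brute-force oracle in the test suite.

#' Van der Waals radii (Bondi) used for surface-gap contacts and SASA
#'
#' @param elements character vector of element symbols.
#' @param default radius (angstrom) for elements absent from the table;
#'   a warning names the unknown elements.
#' @return numeric vector of radii, angstrom.
#' @export
vdw_radii <- function(elements, default = 1.7) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  r <- tab[toupper(elements)]
  if (anyNA(r)) {
    warning("no van der Waals radius for element(s) ",
            paste(unique(elements[is.na(r)]), collapse = ", "),
            "; using ", default, " A")
    r[is.na(r)] <- default
  }
  unname(r)
}

# All (i, j) pairs with A[i,] within `cutoff` of B[j,].
# surface = TRUE measures the gap d - ra[i] - rb[j] instead of the
# centre-centre distance d (both strictly < cutoff).
# Returns a 2-column integer matrix (i = A index, j = B index).
contact_pairs <- function(A, B, cutoff, surface = FALSE,
                          ra = NULL, rb = NULL) {
  stopifnot(cutoff > 0, is.matrix(A), is.matrix(B))
  if (surface && (is.null(ra) || is.null(rb)))
    stop("surface mode needs per-atom radii for both sides")
  h <- if (surface) cutoff + max(ra) + max(rb) else cutoff
  org <- pmin(suppressWarnings(apply(A, 2, min)),
              suppressWarnings(apply(B, 2, min)))
  cA <- floor(sweep(A, 2, org) / h)
  cB <- floor(sweep(B, 2, org) / h)
  keyA <- paste(cA[, 1], cA[, 2], cA[, 3], sep = ",")
  binsA <- split(seq_len(nrow(A)), keyA)
  envA <- list2env(binsA, hash = TRUE, size = max(29L, length(binsA)))
  groupsB <- split(seq_len(nrow(B)), paste(cB[, 1], cB[, 2], cB[, 3],
                                           sep = ","))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- vector("list", length(groupsB))
  out_j <- vector("list", length(groupsB))
  g <- 0L
  for (jb in groupsB) {
    g <- g + 1L
    cc <- cB[jb[1L], ]
    keys <- paste(cc[1] + offs[, 1], cc[2] + offs[, 2], cc[3] + offs[, 3],
                  sep = ",")
    cand <- unlist(mget(keys, envir = envA, ifnotfound = list(NULL)),
                   use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    # squared distances, |B-group| x |candidates|
    d2 <- outer(rowSums(B[jb, , drop = FALSE]^2),
                rowSums(A[cand, , drop = FALSE]^2), "+") -
      2 * B[jb, , drop = FALSE] %*% t(A[cand, , drop = FALSE])
    d2[d2 < 0] <- 0
    if (surface) {
      gap <- sqrt(d2) - outer(rb[jb], ra[cand], "+")
      hit <- which(gap < cutoff, arr.ind = TRUE)
    } else {
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    }
    if (nrow(hit)) {
      out_i[[g]] <- cand[hit[, 2L]]
      out_j[[g]] <- jb[hit[, 1L]]
    }
  }
  cbind(i = as.integer(unlist(out_i)), j = as.integer(unlist(out_j)))
}

# resolve the contact-mode switch: the sub-2 A "close contact" criteria
# used for MD trajectories are only meaningful as a surface (vdW gap)
# distance, so "auto" selects surface mode for cutoffs below 2 A
resolve_contact_mode <- function(contact_mode, cutoff) {
  contact_mode <- match.arg(contact_mode, c("auto", "center", "surface"))
  if (contact_mode == "auto") {
    mode <- if (cutoff < 2) "surface" else "center"
    message("contact cutoff ", cutoff, " A interpreted as ",
            if (mode == "surface") "surface (vdW-gap)" else "atom-centre",
            " distance")
    mode
  } else contact_mode
}
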