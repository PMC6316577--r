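#' D2 dispersion parameters
#'
#' Pairwise \eqn{-C_6/r^6} dispersion with sigmoidal damping. \code{c6} and
#' \code{r_vdw} are named per element; \code{s6} is the global
#' functional-dependent scale, \code{d} the damping steepness, and
#' \code{cutoff} the real-space truncation for lattice sums.
#'
#' @param c6 named numeric, J nm\eqn{^6} mol\eqn{^{-1}} per element
#' @param r_vdw named numeric, van der Waals radii, Angstrom
#' @param s6 global scale factor (0.75 for the PBE functional)
#' @param d damping steepness (20 in the original scheme)
#' @param cutoff real-space cutoff for periodic sums, Angstrom
#' @return object of class \code{d2_params}
#' @export
d2_params <- function(c6, r_vdw, s6 = 0.75, d = 20, cutoff = 30) {
  if (is.null(names(c6)) || is.null(names(r_vdw)))
    stop("c6 and r_vdw must be named by element symbol")
  if (any(c6 < 0)) stop("C6 coefficients must be >= 0")
  if (any(r_vdw <= 0)) stop("van der Waals radii must be positive")
  if (s6 <= 0 || d <= 0 || cutoff <= 0) stop("s6, d and cutoff must be positive")
  out <- list(c6 = c6, r_vdw = r_vdw, s6 = s6, d = d, cutoff = cutoff)
  class(out) <- "d2_params"
  out
}

#' Load the bundled published D2 parameter set
#'
#' Grimme (2006) \eqn{C_6} coefficients and van der Waals radii for H, C, N,
#' O and Si with the PBE \eqn{s_6 = 0.75}, read from the versioned JSON file
#' shipped with the package. User overrides go through [d2_params()].
#'
#' @param path optional alternative JSON parameter file
#' @return a [d2_params()]
#' @export
load_d2_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "d2_params.json", package = "adsorbIR")
  raw <- jsonlite::fromJSON(path)
  d2_params(c6 = unlist(raw$c6), r_vdw = unlist(raw$r_vdw),
            s6 = raw$s6, d = raw$d, cutoff = raw$cutoff %||% 30)
}

# J nm^6 mol^-1 / A^6 -> kJ mol^-1  (1 nm^6 = 1e6 A^6, 1 J = 1e-3 kJ)
.C6_UNIT <- 1e3

.d2_lookup <- function(elems, params) {
  missing <- setdiff(unique(elems), names(params$c6))
  missing <- union(missing, setdiff(unique(elems), names(params$r_vdw)))
  if (length(missing))
    stop("no D2 parameters for element(s) ", paste(missing, collapse = ", "),
         "; supported: ", paste(intersect(names(params$c6),
                                          names(params$r_vdw)), collapse = ", "))
}

#' Pairwise D2 dispersion energy
#'
#' \deqn{E = -s_6 \frac{\sqrt{C_6^i C_6^j}}{r^6} f_{dmp}(r), \qquad
#'       f_{dmp}(r) = \frac{1}{1 + e^{-d\,(r/R_r - 1)}}}
#' with \eqn{R_r} the sum of the two elemental van der Waals radii.
#'
#' @param elem_i,elem_j element symbols
#' @param r interatomic distance, Angstrom, > 0
#' @param params a [d2_params()]
#' @return dispersion energy, kJ mol\eqn{^{-1}} (always \eqn{\le 0})
#' @export
pair_dispersion <- function(elem_i, elem_j, r, params) {
  if (any(r <= 0)) stop("interatomic distance must be positive")
  .d2_lookup(c(elem_i, elem_j), params)
  c6ij <- sqrt(params$c6[[elem_i]] * params$c6[[elem_j]]) * .C6_UNIT
  rr <- params$r_vdw[[elem_i]] + params$r_vdw[[elem_j]]
  fdmp <- 1 / (1 + exp(-params$d * (r / rr - 1)))
  -params$s6 * c6ij / r^6 * fdmp
}

# 2D lattice translation vectors (x,y,0) within the cutoff, excluding origin
.lattice_translations <- function(cell, cutoff) {
  gamma <- cell[3] * pi / 180
  a1 <- c(cell[1], 0)
  a2 <- c(cell[2] * cos(gamma), cell[2] * sin(gamma))
  nmax1 <- ceiling(cutoff / (cell[1] * abs(sin(gamma)))) + 1L
  nmax2 <- ceiling(cutoff / (cell[2] * abs(sin(gamma)))) + 1L
  grid <- expand.grid(n1 = -nmax1:nmax1, n2 = -nmax2:nmax2)
  grid <- grid[grid$n1 != 0 | grid$n2 != 0, , drop = FALSE]
  tx <- grid$n1 * a1[1] + grid$n2 * a2[1]
  ty <- grid$n1 * a1[2] + grid$n2 * a2[2]
  cbind(tx, ty, 0)
}

#' Total D2 dispersion energy of a structure
#'
#' Sum of [pair_dispersion()] over unique atom pairs. For 2D-periodic
#' structures (cell present) the sum runs over lattice translations within
#' the real-space cutoff; central-cell pairs are counted once and image
#' contributions carry the conventional factor 1/2 to avoid double counting
#' of \eqn{(i,j,T)} with \eqn{(j,i,-T)}.
#'
#' @param s a [structure3d()]
#' @param params a [d2_params()]
#' @return total dispersion energy, kJ mol\eqn{^{-1}}
#' @export
total_dispersion <- function(s, params) {
  stopifnot(inherits(s, "structure3d"), inherits(params, "d2_params"))
  .d2_lookup(s$elements, params)
  n <- length(s$elements)
  e <- 0
  if (n > 1L) {
    dmat <- as.matrix(stats::dist(s$xyz))
    pairs <- which(upper.tri(dmat), arr.ind = TRUE)
    r <- dmat[pairs]
    if (any(r < 0.1))
      stop("overlapping atoms (r < 0.1 A): check the structure")
    for (k in seq_len(nrow(pairs)))
      e <- e + pair_dispersion(s$elements[pairs[k, 1]],
                               s$elements[pairs[k, 2]], r[k], params)
  }
  if (!is.null(s$cell)) {
    trans <- .lattice_translations(s$cell, params$cutoff)
    c6 <- params$c6[s$elements] * .C6_UNIT
    rr <- params$r_vdw[s$elements]
    for (t in seq_len(nrow(trans))) {
      shifted <- sweep(s$xyz, 2, trans[t, ], `+`)
      for (i in seq_len(n)) {
        dv <- sweep(shifted, 2, s$xyz[i, ], `-`)
        r <- sqrt(rowSums(dv^2))
        if (any(r < 0.1)) stop("overlapping atoms across images (r < 0.1 A)")
        keep <- r <= params$cutoff
        if (!any(keep)) next
        c6ij <- sqrt(c6[i] * c6[keep])
        rsum <- rr[i] + rr[keep]
        fdmp <- 1 / (1 + exp(-params$d * (r[keep] / rsum - 1)))
        e <- e - 0.5 * params$s6 * sum(c6ij / r[keep]^6 * fdmp)
      }
    }
  }
  unname(e)
}

#' Dispersion component of an interaction energy
#'
#' \eqn{\Delta E_{disp} = E_{disp}(complex) - E_{disp}(A) - E_{disp}(B)}
#' with all geometries fixed at the complex geometry. Computed both by that
#' subtraction and as the direct inter-fragment pair sum; the two routes are
#' asserted to agree, which guards the bookkeeping.
#'
#' @param complex the full [structure3d()]
#' @param fragA,fragB [structure3d()]s that partition the complex's atoms at
#'   identical coordinates (same cell, if any); \code{NULL} stands for an
#'   empty fragment
#' @param params a [d2_params()]
#' @return \eqn{\Delta E_{disp}}, kJ mol\eqn{^{-1}} (negative = attractive)
#' @export
dispersion_component <- function(complex, fragA, fragB, params) {
  stopifnot(inherits(complex, "structure3d"))
  nA <- length(fragA$elements)
  nB <- if (is.null(fragB)) 0L else length(fragB$elements)
  if (nA + nB != length(complex$elements))
    stop("fragments must partition the complex's atoms (counts differ)")
  # match fragment atoms to complex rows by coordinates + element
  key <- function(el, xyz) paste(el, sprintf("%.6f %.6f %.6f",
                                             xyz[, 1], xyz[, 2], xyz[, 3]))
  kc <- key(complex$elements, complex$xyz)
  ka <- key(fragA$elements, fragA$xyz)
  kb <- if (nB > 0) key(fragB$elements, fragB$xyz) else character(0)
  if (anyDuplicated(c(ka, kb)) || !setequal(c(ka, kb), kc))
    stop("fragments overlap or miss atoms of the complex")
  if (nB == 0L) return(0)
  e_sub <- total_dispersion(complex, params) -
    total_dispersion(fragA, params) - total_dispersion(fragB, params)
  # direct inter-fragment route
  e_int <- 0
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    r <- sqrt(sum((fragA$xyz[i, ] - fragB$xyz[j, ])^2))
    e_int <- e_int + pair_dispersion(fragA$elements[i], fragB$elements[j],
                                     r, params)
  }
  if (!is.null(complex$cell)) {
    trans <- .lattice_translations(complex$cell, params$cutoff)
    for (t in seq_len(nrow(trans))) {
      shiftB <- sweep(fragB$xyz, 2, trans[t, ], `+`)
      for (i in seq_len(nA)) {
        dv <- sweep(shiftB, 2, fragA$xyz[i, ], `-`)
        r <- sqrt(rowSums(dv^2))
        keep <- r <= params$cutoff
        for (j in which(keep))
          e_int <- e_int + pair_dispersion(fragA$elements[i],
                                           fragB$elements[j], r[j], params)
      }
    }
  }
  if (abs(e_sub - e_int) > 1e-8 * max(1, abs(e_sub)))
    stop("dispersion decomposition routes disagree (",
         format(e_sub, digits = 10), " vs ", format(e_int, digits = 10),
         "); fragments likely inconsistent with the complex")
  e_int
}
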