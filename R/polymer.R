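#' Polymer segments of the pulling construct
#'
#' A pulling construct is a series of mechanical elements: double-stranded DNA
#' handles (extensible worm-like chains with an enthalpic stretch term),
#' unfolded polypeptide (inextensible worm-like chain), and folded protein
#' structure treated as a rigid axial rod. `polymer_segment()` builds one such
#' element; `dna_segment()`, `peptide_segment()` and `folded_segment()` are
#' convenience constructors with the package's pinned parameters (dsDNA:
#' persistence length 45 nm, 0.338 nm/bp, stretch modulus 1200 pN;
#' polypeptide: persistence length 0.6 nm, 0.365 nm/residue).
#'
#' @param kind One of `"dsDNA-WLC"`, `"polypeptide-WLC"`, `"folded-axial"`.
#' @param n Number of monomers (base pairs or residues); ignored for
#'   `"folded-axial"`.
#' @param persistence_length Persistence length in nm (> 0).
#' @param contour_per_unit Contour length per monomer in nm (> 0).
#' @param stretch_modulus Enthalpic stretch modulus in pN (dsDNA only);
#'   `Inf` for an inextensible chain.
#' @param length_nm Fixed axial length in nm for `"folded-axial"` segments.
#' @return An object of class `polymer_segment`.
#' @examples
#' handle <- dna_segment(bp = 1020)
#' wlc_extension(14, handle)
#' @export
polymer_segment <- function(kind = c("dsDNA-WLC", "polypeptide-WLC", "folded-axial"),
                            n = NULL, persistence_length = NULL,
                            contour_per_unit = NULL, stretch_modulus = Inf,
                            length_nm = NULL) {
  kind <- match.arg(kind)
  if (kind == "folded-axial") {
    if (is.null(length_nm) || length_nm < 0) {
      abort("folded-axial segments need a force-independent length_nm >= 0")
    }
    return(structure(list(kind = kind, length_nm = length_nm),
                     class = "polymer_segment"))
  }
  stopifnot(is.numeric(n), n >= 0,
            persistence_length > 0, contour_per_unit > 0,
            stretch_modulus > 0)
  structure(list(kind = kind, n = n,
                 persistence_length = persistence_length,
                 contour_per_unit = contour_per_unit,
                 stretch_modulus = stretch_modulus,
                 contour_length = n * contour_per_unit),
            class = "polymer_segment")
}

#' @rdname polymer_segment
#' @param bp Base pairs of double-stranded DNA.
#' @export
dna_segment <- function(bp, persistence_length = 45, contour_per_unit = 0.338,
                        stretch_modulus = 1200) {
  polymer_segment("dsDNA-WLC", n = bp, persistence_length = persistence_length,
                  contour_per_unit = contour_per_unit,
                  stretch_modulus = stretch_modulus)
}

#' @rdname polymer_segment
#' @param n_residues Residues of unstructured polypeptide.
#' @export
peptide_segment <- function(n_residues, persistence_length = 0.6,
                            contour_per_unit = 0.365) {
  polymer_segment("polypeptide-WLC", n = n_residues,
                  persistence_length = persistence_length,
                  contour_per_unit = contour_per_unit)
}

#' @rdname polymer_segment
#' @export
folded_segment <- function(length_nm) {
  polymer_segment("folded-axial", length_nm = length_nm)
}

#' @export
print.polymer_segment <- function(x, ...) {
  if (x$kind == "folded-axial") {
    cat(sprintf("<polymer_segment> folded-axial, %.2f nm\n", x$length_nm))
  } else {
    cat(sprintf("<polymer_segment> %s, n = %g, L = %.2f nm, P = %.2f nm\n",
                x$kind, x$n, x$contour_length, x$persistence_length))
  }
  invisible(x)
}

# Marko-Siggia interpolation g(l) = F P / kBT as a function of the entropic
# fractional extension l = x/L - F/K. Strictly increasing on [0, 1).
.ms_g <- function(l) 1 / (4 * (1 - l)^2) - 0.25 + l

# Invert g to the fractional extension at a given force; vectorized over force.
# Bracketed root-finding, absolute tolerance 1e-12 in l.
.ms_fraction <- function(force, persistence_length, kBT = kBT_pN_nm()) {
  target <- force * persistence_length / kBT
  vapply(target, function(tt) {
    if (tt <= 0) return(0)
    uniroot(function(l) .ms_g(l) - tt, lower = 0, upper = 1 - 1e-12,
            tol = 1e-12)$root
  }, numeric(1))
}

#' Worm-like chain extension and force
#'
#' `wlc_extension()` returns the unique end-to-end extension of a polymer
#' segment at a given force, solving the Marko-Siggia interpolation (with the
#' enthalpic stretch term `F/K` for extensible dsDNA):
#' `F P / kBT = 1/(4 (1 - l)^2) - 1/4 + l`, with `l = x/L - F/K`.
#' `wlc_force()` is the forward relation, recovering the force that produces a
#' given extension. Both are vectorized over their first argument; folded-axial
#' segments return their fixed length at any force.
#'
#' @param force Applied force in pN (>= 0).
#' @param extension End-to-end extension in nm.
#' @param segment A [polymer_segment()].
#' @param kBT Thermal energy in pN nm.
#' @return Extension in nm, or force in pN.
#' @export
wlc_extension <- function(force, segment, kBT = kBT_pN_nm()) {
  stopifnot(inherits(segment, "polymer_segment"))
  if (any(force < 0)) abort("force must be >= 0")
  if (segment$kind == "folded-axial") {
    return(rep(segment$length_nm, length(force)))
  }
  l <- .ms_fraction(force, segment$persistence_length, kBT)
  segment$contour_length * (l + force / segment$stretch_modulus)
}

#' @rdname wlc_extension
#' @export
wlc_force <- function(extension, segment, kBT = kBT_pN_nm()) {
  stopifnot(inherits(segment, "polymer_segment"),
            segment$kind != "folded-axial")
  if (any(extension < 0)) abort("extension must be >= 0")
  vapply(extension, function(x) {
    if (x == 0) return(0)
    f_of <- function(F) wlc_extension(F, segment, kBT) - x
    upper <- 1
    while (f_of(upper) < 0 && upper < 1e6) upper <- upper * 2
    uniroot(f_of, lower = 0, upper = upper, tol = 1e-12)$root
  }, numeric(1))
}

# Fractional extension of the unit polypeptide coil at the given force(s);
# coil extension = n_residues * nm_per_residue * fraction. Computing the
# fraction once lets per-state extensions share a single root-solve per force.
.coil_fraction <- function(force, persistence_length = 0.6, kBT = kBT_pN_nm()) {
  .ms_fraction(force, persistence_length, kBT)
}
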