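#' Contour length of a polypeptide chain
#'
#' Fully extended chain length: residues times the backbone residue
#' spacing (0.38 nm by default).
#'
#' @param nResidues number of amino acids (>= 0).
#' @param residueSpacing nm per residue.
#' @return contour length in nm.
#' @examples
#' contourLength(2174)   # full PEVK domain, 826.12 nm (826 nm to 3 s.f.)
#' contourLength(733)    # the PEVKII fragment
#' @export
contourLength <- function(nResidues, residueSpacing = 0.38) {
    if (any(nResidues < 0) || any(residueSpacing < 0))
        stop("nResidues and residueSpacing must be >= 0")
    nResidues * residueSpacing
}

#' Mean end-to-end distance of an ideal worm-like chain
#'
#' The conformationally relaxed (ideal-chain limit) end-to-end distance
#' \code{R = sqrt(Lc * Lp)}.  Note some texts use \code{sqrt(2 * Lc * Lp)};
#' the convention here is fixed by the package's reference values
#' (826 nm, 1 nm -> 28.7 nm).
#'
#' @param Lc contour length (nm).
#' @param Lp persistence length (nm); about 1 nm for the PEVK domain.
#' @return end-to-end distance in nm.
#' @export
endToEnd <- function(Lc, Lp) {
    if (any(Lc < 0) || any(Lp < 0)) stop("Lc and Lp must be >= 0")
    sqrt(Lc * Lp)
}

#' Radius of gyration of an ideal chain
#'
#' Radius of the sphere containing the chain's mass, \code{R / sqrt(6)}.
#'
#' @param R end-to-end distance (nm).
#' @return radius of gyration in nm.
#' @export
radiusOfGyration <- function(R) {
    if (any(R < 0)) stop("R must be >= 0")
    R / sqrt(6)
}

#' Worm-like-chain geometry of a disordered domain
#'
#' Convenience wrapper combining \code{\link{contourLength}},
#' \code{\link{endToEnd}} and \code{\link{radiusOfGyration}}.
#'
#' @param nResidues number of amino acids.
#' @param persistenceLength nm.
#' @param residueSpacing nm per residue.
#' @return a \code{\link{ChainGeometry-class}} object; its show method
#'   reports values to 3 significant figures while full precision is kept
#'   in the slots.
#' @examples
#' chainGeometry(2174, 1)
#' @export
chainGeometry <- function(nResidues, persistenceLength = 1,
                          residueSpacing = 0.38) {
    Lc <- contourLength(nResidues, residueSpacing)
    R <- endToEnd(Lc, persistenceLength)
    new("ChainGeometry", nResidues = as.numeric(nResidues),
        residueSpacing = as.numeric(residueSpacing),
        persistenceLength = as.numeric(persistenceLength),
        contourLength = Lc, endToEnd = R,
        radiusOfGyration = radiusOfGyration(R))
}

#' Sarcomere-lattice reach of a relaxed chain
#'
#' In the ideal vertebrate hexagonal double-lattice, thin filaments sit at
#' the trigonal positions of the thick-filament lattice, so the nearest
#' thick-to-thin distance is \code{2 * d10 / 3}.  The reach margin is the
#' chain's radius of gyration minus that distance: positive means the
#' relaxed chain spans the gap.  This construction is an interpretation of
#' the lattice schematic, not a measured quantity.
#'
#' @param RG radius of gyration (nm).
#' @param d10 thick-filament 1,0 lattice spacing (nm; 37.4 nm default).
#' @return a \code{\link{LatticeGeometry-class}} object.
#' @examples
#' latticeReach(11.7)
#' @export
latticeReach <- function(RG, d10 = 37.4) {
    if (d10 <= 0) stop("d10 must be > 0")
    if (RG < 0) stop("RG must be >= 0")
    dist <- 2 * d10 / 3
    new("LatticeGeometry", d10 = as.numeric(d10), thickThinDistance = dist,
        reachMargin = RG - dist, radiusOfGyration = as.numeric(RG))
}
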