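#' Fusiform aneurysm radius profile
#'
#' Radius of the dilated segment as a function of normalized axial position,
#' \code{r(x) = r0 * sqrt(1 + (aSl/2) * (1 - cos(2*pi*(x + 0.5))))}: the
#' luminal cross-sectional area rises as a raised cosine from the healthy
#' value at the ends (\code{x = -0.5, 0.5}) to \code{(1 + aSl)} times the
#' healthy area at the centre (\code{x = 0}).
#'
#' @param x normalized axial position in [-0.5, 0.5] (0 at the bump centre)
#' @param r0 healthy inner radius, m
#' @param aSl relative maximum luminal-area increase, in [0, 5.25]
#' @return radius in the same units as \code{r0}
#' @examples
#' aaaRadiusProfile(0, 1, 5.25)    # 2.5: area factor 6.25 at the apex
#' aaaRadiusProfile(0.5, 1, 3)     # 1: healthy at the neck
#' @export
aaaRadiusProfile <- function(x, r0, aSl) {
    if (any(x < -0.5 - 1e-12 | x > 0.5 + 1e-12))
        stop("x must lie in [-0.5, 0.5]")
    if (aSl < 0 || aSl > 5.25) stop("aSl must lie in [0, 5.25]")
    r0 * sqrt(1 + (aSl / 2) * (1 - cos(2 * pi * (x + 0.5))))
}

#' Volumetric severity index from aneurysm geometry
#'
#' The relative volume excess of the dilated segment over its healthy
#' counterpart is \code{V/V0 - 1 = lAaa * aSl / 2} (exact integral of the
#' raised-cosine area profile), and the volumetric severity index normalizes
#' it by its maximum attainable value 2.625 (reached at \code{lAaa = 1},
#' \code{aSl = 5.25}):
#' \code{VSI = 100 * (lAaa * aSl / 2) / 2.625} percent.
#'
#' @param lAaa fraction of the host segment spanned by the dilation, (0, 1]
#' @param aSl relative maximum luminal-area increase, [0, 5.25]
#' @return VSI in percent, in [0, 100]
#' @examples
#' vsiFromGeometry(1, 5.25)   # 100
#' vsiFromGeometry(1, 1.575)  # 30
#' @export
vsiFromGeometry <- function(lAaa, aSl) {
    if (any(lAaa <= 0 | lAaa > 1)) stop("lAaa must lie in (0, 1]")
    if (any(aSl < 0 | aSl > 5.25)) stop("aSl must lie in [0, 5.25]")
    100 * (lAaa * aSl / 2) / 2.625
}

#' Maximum area parameter for a target severity
#'
#' Inverts the severity definition: given a target VSI and an aneurysm
#' length fraction, returns the relative maximum luminal-area increase
#' \code{aSl = 5.25 * (vsi/100) / lAaa}.  Feasibility requires
#' \code{lAaa >= vsi/100}, otherwise \code{aSl} would exceed its physical
#' ceiling of 5.25.
#'
#' @param vsi volumetric severity index, percent
#' @param lAaa aneurysm length fraction
#' @return \code{aSl}, round-tripping with [vsiFromGeometry()] to machine
#'   precision
#' @examples
#' solveAsl(100, 1)    # 5.25
#' solveAsl(30, 0.6)   # 2.625
#' @export
solveAsl <- function(vsi, lAaa) {
    if (any(vsi < 0 | vsi > 100)) stop("vsi must lie in [0, 100]")
    if (any(lAaa < vsi / 100))
        stop("infeasible: lAaa must be at least vsi/100")
    ifelse(vsi == 0, 0, 5.25 * (vsi / 100) / lAaa)
}

#' Maximum diameter increase implied by an aneurysm geometry
#'
#' Percent increase of the maximum radius over the healthy radius,
#' \code{100 * (sqrt(1 + aSl) - 1)}, the diameter-based severity metric used
#' for comparison with the volumetric index.
#'
#' @param aSl relative maximum luminal-area increase
#' @return percent diameter increase
#' @export
maxDiameterIncrease <- function(aSl) 100 * (sqrt(1 + aSl) - 1)

#' Construct an aneurysm specification
#'
#' Any two of \code{vsi}, \code{lAaa}, \code{aSl} determine the third via the
#' severity identity; supply either (\code{vsi}, \code{lAaa}) or
#' (\code{lAaa}, \code{aSl}).
#'
#' @param vsi volumetric severity index, percent
#' @param lAaa aneurysm length fraction in (0, 1]
#' @param aSl relative maximum luminal-area increase (computed from
#'   \code{vsi} when missing)
#' @param kE Young's-modulus scaling of the aneurysmal wall
#' @param nSubsegments number of uniform discretization cells (>= 8)
#' @return an [AneurysmSpec-class]
#' @examples
#' aneurysmSpec(vsi = 30, lAaa = 0.6, kE = 1.8)
#' @export
aneurysmSpec <- function(vsi = NULL, lAaa, aSl = NULL, kE = 1,
                         nSubsegments = 16L) {
    if (is.null(aSl)) {
        if (is.null(vsi)) stop("supply vsi or aSl")
        aSl <- solveAsl(vsi, lAaa)
    }
    if (is.null(vsi)) vsi <- vsiFromGeometry(lAaa, aSl)
    new("AneurysmSpec", lAaa = lAaa, aSl = aSl, kE = kE, vsi = vsi,
        nSubsegments = as.integer(nSubsegments))
}

#' Insert an aneurysm into the arterial tree
#'
#' Replaces the infrarenal abdominal aorta (the segment referenced by site
#' \code{TL_31}) with a chain of uniform transmission-line cells: a healthy
#' proximal stub, \code{nSubsegments} cells whose radii sample the
#' raised-cosine profile at cell midpoints and whose Young's modulus is
#' scaled by \code{kE}, and a healthy distal stub.  The dilation is centred
#' within the host segment and total length is preserved.  With
#' \code{aSl = 0} and \code{kE = 1} the result is hemodynamically identical
#' to the input (a uniform line split into sub-lines).
#'
#' @param model an [ArterialModel-class] containing a \code{TL_31} site
#' @param spec an [AneurysmSpec-class]
#' @return a new [ArterialModel-class]; its \code{TL_31} site points at the
#'   apex cell
#' @export
insertAneurysm <- function(model, spec) {
    st <- model@sites
    i31 <- match("TL_31", st$site)
    if (is.na(i31)) stop("model has no TL_31 site")
    hostId <- st$id[i31]
    seg <- model@segments
    j <- match(hostId, seg$id)
    if (is.na(j)) stop("TL_31 site references a missing segment")
    L0 <- seg$length[j]; r0 <- seg$radius[j]; h0 <- seg$thickness[j]
    E0 <- seg$youngs[j]
    n <- spec@nSubsegments
    lA <- spec@lAaa * L0
    stub <- (L0 - lA) / 2
    mid <- -0.5 + (seq_len(n) - 0.5) / n
    rCell <- aaaRadiusProfile(mid, r0, spec@aSl)
    newIdBase <- max(seg$id)
    mk <- function(id, name, parent, l, r, E) data.frame(
        id = id, name = name, parent = parent, length = l, radius = r,
        thickness = h0, youngs = E, terminal = FALSE,
        stringsAsFactors = FALSE)
    rows <- list()
    prev <- seg$parent[j]
    if (stub > 1e-9) {
        id <- newIdBase + 1L
        rows[[length(rows) + 1L]] <-
            mk(id, "TL31_prox_stub", prev, stub, r0, E0)
        prev <- id
    }
    cellIds <- newIdBase + 100L + seq_len(n)
    for (k in seq_len(n)) {
        rows[[length(rows) + 1L]] <- mk(cellIds[k],
            sprintf("TL31_aaa_%02d", k), prev, lA / n, rCell[k],
            E0 * spec@kE)
        prev <- cellIds[k]
    }
    if (stub > 1e-9) {
        id <- newIdBase + 2L
        rows[[length(rows) + 1L]] <-
            mk(id, "TL31_dist_stub", prev, stub, r0, E0)
        prev <- id
    }
    newRows <- do.call(rbind, rows)
    ## reattach former children of the host segment to the chain end
    seg$parent[!is.na(seg$parent) & seg$parent == hostId] <- prev
    seg <- rbind(seg[-j, , drop = FALSE], newRows)
    ## the TL_31 site now points at the apex cell
    st$id[i31] <- cellIds[which.max(rCell)]
    st$position[i31] <- 0.5
    new("ArterialModel", segments = seg, loads = model@loads, sites = st,
        blood = model@blood)
}
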