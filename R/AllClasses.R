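#' @import methods
#' @importFrom stats approx coef cor cor.test fft lm optimize quantile rnorm
#'   runif sd var setNames rlnorm integrate ks.test median
#' @importFrom utils head tail read.csv write.csv modifyList
#' @useDynLib PulseAAA, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Arterial network model
#'
#' An \code{ArterialModel} holds a rooted network of uniform, linear
#' transmission-line segments describing the systemic arterial tree, the
#' three-element Windkessel loads terminating its distal segments, named
#' measurement sites, and blood properties.
#'
#' @slot segments \code{data.frame} with columns \code{id}, \code{name},
#'   \code{parent} (\code{NA} for the root), \code{length} (m), \code{radius}
#'   (inner radius, m), \code{thickness} (wall thickness, m), \code{youngs}
#'   (Young's modulus, Pa) and \code{terminal} (logical).
#' @slot loads \code{data.frame} with columns \code{id}, \code{r_total}
#'   (Pa s/m^3), \code{compliance} (m^3/Pa) and \code{proximal_fraction},
#'   one row per terminal segment.
#' @slot sites \code{data.frame} with columns \code{site}, \code{id} and
#'   \code{position} (fractional axial position in [0, 1]).
#' @slot blood named numeric vector with \code{density} (kg/m^3) and
#'   \code{viscosity} (Pa s).
#'
#' @seealso [defaultArterialTree()], [insertAneurysm()], [simulatePressures()]
#' @export
setClass("ArterialModel",
    representation(
        segments = "data.frame",
        loads = "data.frame",
        sites = "data.frame",
        blood = "numeric"
    )
)

setValidity("ArterialModel", function(object) {
    seg <- object@segments
    msgs <- character()
    need <- c("id", "name", "parent", "length", "radius", "thickness",
              "youngs", "terminal")
    if (!all(need %in% names(seg)))
        return(paste("segments must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(seg$id)) msgs <- c(msgs, "duplicated segment ids")
    if (sum(is.na(seg$parent)) != 1L)
        msgs <- c(msgs, "exactly one root (parent = NA) required")
    nonroot <- seg$parent[!is.na(seg$parent)]
    if (!all(nonroot %in% seg$id))
        msgs <- c(msgs, "every parent id must refer to a segment")
    if (any(seg$length <= 0) || any(seg$radius <= 0) ||
        any(seg$thickness <= 0) || any(seg$youngs <= 0))
        msgs <- c(msgs, "length, radius, thickness, youngs must be positive")
    if (any(seg$thickness >= seg$radius))
        msgs <- c(msgs, "wall thickness must be smaller than radius")
    ## acyclicity / connectivity: walk each segment to the root
    idx <- match(seg$parent, seg$id)
    for (i in seq_len(nrow(seg))) {
        j <- i; steps <- 0L
        while (!is.na(idx[j])) {
            j <- idx[j]; steps <- steps + 1L
            if (steps > nrow(seg)) {
                msgs <- c(msgs, "cycle detected in segment graph")
                break
            }
        }
        if (steps > nrow(seg)) break
    }
    term <- seg$id[seg$terminal]
    if (!all(term %in% object@loads$id))
        msgs <- c(msgs, "every terminal segment needs a Windkessel load")
    if (nrow(object@loads)) {
        ld <- object@loads
        if (any(ld$r_total <= 0) || any(ld$compliance <= 0))
            msgs <- c(msgs, "terminal resistances and compliances must be positive")
        if (any(ld$proximal_fraction <= 0 | ld$proximal_fraction >= 1))
            msgs <- c(msgs, "proximal_fraction must lie in (0, 1)")
    }
    if (!all(c("density", "viscosity") %in% names(object@blood)) ||
        any(object@blood[c("density", "viscosity")] <= 0))
        msgs <- c(msgs, "blood must have positive density and viscosity")
    if (nrow(object@sites) && !all(object@sites$id %in% seg$id))
        msgs <- c(msgs, "sites must reference existing segments")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn ArterialModel-class number of transmission-line segments
#' @param x,object an \code{ArterialModel}
#' @export
setMethod("length", "ArterialModel", function(x) nrow(x@segments))

setMethod("show", "ArterialModel", function(object) {
    seg <- object@segments
    cat("ArterialModel with", nrow(seg), "transmission-line segments\n")
    cat("  terminals:", sum(seg$terminal),
        " (3-element Windkessel loads)\n")
    cat("  sites:", paste(object@sites$site, collapse = ", "), "\n")
    cat("  blood: density", object@blood[["density"]], "kg/m^3, viscosity",
        object@blood[["viscosity"]], "Pa s\n")
})

#' Segment table accessor
#' @param x an \code{ArterialModel}
#' @return \code{data.frame} of segment geometry and stiffness
#' @export
arterialSegments <- function(x) x@segments

#' Terminal load accessor
#' @param x an \code{ArterialModel}
#' @return \code{data.frame} of Windkessel loads
#' @export
terminalLoads <- function(x) x@loads

#' Measurement site accessor
#' @param x an \code{ArterialModel}
#' @return \code{data.frame} of named measurement sites
#' @export
measurementSites <- function(x) x@sites

#' Aneurysm geometry specification
#'
#' Parameterizes a fusiform dilation of the infrarenal abdominal aorta
#' (segment \code{TL_31}) by its fractional length \code{lAaa}, relative
#' maximum luminal-area increase \code{aSl}, wall-stiffness scaling \code{kE},
#' and the resulting volumetric severity index \code{vsi} (%).  The identity
#' \code{vsi = 100 * (lAaa * aSl / 2) / 2.625} is enforced on construction.
#'
#' @slot lAaa fraction of the host segment length spanned by the dilation,
#'   in [0.4, 1] for sampled subjects (any value in (0, 1] is accepted).
#' @slot aSl relative maximum luminal-area increase, in [0, 5.25].
#' @slot kE Young's-modulus scaling of the dilated wall.
#' @slot vsi volumetric severity index in percent, in [0, 100].
#' @slot nSubsegments number of uniform cells used to discretize the bump.
#'
#' @seealso [aneurysmSpec()], [vsiFromGeometry()], [solveAsl()]
#' @export
setClass("AneurysmSpec",
    representation(
        lAaa = "numeric", aSl = "numeric", kE = "numeric",
        vsi = "numeric", nSubsegments = "integer"
    )
)

setValidity("AneurysmSpec", function(object) {
    msgs <- character()
    if (object@lAaa <= 0 || object@lAaa > 1)
        msgs <- c(msgs, "lAaa must lie in (0, 1]")
    if (object@aSl < 0 || object@aSl > 5.25)
        msgs <- c(msgs, "aSl must lie in [0, 5.25]")
    if (object@kE <= 0) msgs <- c(msgs, "kE must be positive")
    if (object@nSubsegments < 8L)
        msgs <- c(msgs, "nSubsegments must be at least 8")
    v <- vsiFromGeometry(object@lAaa, object@aSl)
    if (abs(v - object@vsi) > 1e-9)
        msgs <- c(msgs, "vsi inconsistent with (lAaa, aSl)")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "AneurysmSpec", function(object) {
    cat(sprintf(
        "AneurysmSpec: VSI %.1f%% (lAaa = %.3f, aSl = %.3f, kE = %.2f, %d cells)\n",
        object@vsi, object@lAaa, object@aSl, object@kE, object@nSubsegments))
})

#' Waveform cohort container
#'
#' A \code{PulseCohort} is a \code{SummarizedExperiment} whose assays are
#' site-wise waveform matrices (one 256-sample column per record; assay names
#' such as \code{bp_carotid}, \code{bp_femoral}, \code{bp_brachial},
#' \code{bp_tibial}, \code{pvr_brachial}, \code{pvr_tibial}) and whose
#' \code{colData} carries per-record annotation: \code{subject_id},
#' \code{sample_id}, \code{age} (y), \code{height} (cm), \code{hr} (bpm), and
#' for labeled cohorts \code{vsi} (%) and \code{max_diameter_increase} (%).
#'
#' @seealso [generateCohort()]
#' @export
setClass("PulseCohort", contains = "SummarizedExperiment")

#' VSI label accessor
#' @param x a \code{PulseCohort}
#' @return numeric vector of reference VSI labels (%), or \code{NULL} for an
#'   unlabeled cohort
#' @export
vsiLabels <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("vsi" %in% names(cd)) as.numeric(cd$vsi) else NULL
}

#' Sampling frequency accessor
#' @param x a \code{PulseCohort}
#' @return sampling frequency in Hz
#' @export
samplingRate <- function(x) S4Vectors::metadata(x)$fs

#' CPAR-regularized network state
#'
#' Holds the parameters of the convolutional feature extractor
#' (\code{thetaF}), the VSI regression head (\code{thetaL}) and the two
#' adversarial regressor heads for height and age (\code{thetaH},
#' \code{thetaA}), together with the architecture/training configuration,
#' input/target standardization statistics, and the per-epoch training
#' history.  Inference uses only \code{thetaF} and \code{thetaL}.
#'
#' @slot thetaF list of feature-extractor parameter arrays
#' @slot thetaL list of VSI-head parameter arrays
#' @slot thetaH list of height-head parameter arrays
#' @slot thetaA list of age-head parameter arrays
#' @slot config network architecture configuration list
#' @slot training training configuration list
#' @slot norm standardization statistics for the adversarial targets
#' @slot history \code{data.frame} of per-epoch losses
#' @slot trained logical, whether [trainCpar()] has been run
#'
#' @seealso [buildNetwork()], [trainCpar()], [predictVsi()]
#' @export
setClass("CparModel",
    representation(
        thetaF = "list", thetaL = "list", thetaH = "list", thetaA = "list",
        config = "list", training = "list", norm = "list",
        history = "data.frame", trained = "logical"
    )
)

setMethod("show", "CparModel", function(object) {
    np <- function(p) sum(vapply(p, length, 1L))
    cat("CparModel (1-D CNN with CBAM attention + CPAR heads)\n")
    cat("  feature extractor:", np(object@thetaF), "parameters\n")
    cat("  heads (VSI / height / age):", np(object@thetaL), "/",
        np(object@thetaH), "/", np(object@thetaA), "parameters\n")
    cat("  trained:", object@trained,
        if (nrow(object@history)) sprintf("(%d epochs)", nrow(object@history))
        else "", "\n")
})

#' Training history accessor
#' @param x a \code{CparModel}
#' @return \code{data.frame} with one row per epoch: label loss, the two
#'   disturbance losses, and validation label loss
#' @export
trainingHistory <- function(x) x@history
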