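## Default 55-artery anatomy (Avolio-type multi-branched table).
## Dimensions are representative published values for this model family:
## lengths/radii/thicknesses in cm here (converted to SI on construction),
## Young's moduli in MPa (0.4 central elastic, 0.8 muscular, 1.6 distal leg).
## The infrarenal abdominal aorta (between the renal arteries and the
## inferior mesenteric artery) carries id 31 and is the aneurysm host.

.SEGMENT_TABLE <- function() {
    txt <- "
name,parent,l_cm,r_cm,h_cm,E_MPa,terminal
ascending_aorta,NA,4.0,1.45,0.163,0.4,0
aortic_arch_a,ascending_aorta,2.0,1.12,0.132,0.4,0
innominate,aortic_arch_a,3.4,0.62,0.080,0.4,0
r_subclavian,innominate,3.4,0.42,0.067,0.4,0
r_vertebral,r_subclavian,14.8,0.19,0.045,0.8,1
r_axillary,r_subclavian,12.0,0.36,0.062,0.4,0
r_brachial,r_axillary,22.3,0.28,0.055,0.4,0
r_radial,r_brachial,23.5,0.16,0.043,0.8,1
r_ulnar,r_brachial,22.9,0.18,0.046,0.8,1
r_common_carotid_a,innominate,8.9,0.39,0.064,0.4,0
r_common_carotid_b,r_common_carotid_a,8.9,0.37,0.063,0.4,0
r_internal_carotid,r_common_carotid_b,11.3,0.18,0.045,0.8,1
r_external_carotid,r_common_carotid_b,11.3,0.15,0.042,0.8,1
aortic_arch_b,aortic_arch_a,3.9,1.07,0.127,0.4,0
l_common_carotid_a,aortic_arch_b,10.4,0.39,0.064,0.4,0
l_common_carotid_b,l_common_carotid_a,10.4,0.37,0.063,0.4,0
l_internal_carotid,l_common_carotid_b,11.3,0.18,0.045,0.8,1
l_external_carotid,l_common_carotid_b,11.3,0.15,0.042,0.8,1
l_subclavian,aortic_arch_b,3.4,0.42,0.067,0.4,0
l_vertebral,l_subclavian,14.8,0.19,0.045,0.8,1
l_axillary,l_subclavian,12.0,0.36,0.062,0.4,0
l_brachial,l_axillary,22.3,0.28,0.055,0.4,0
l_radial,l_brachial,23.5,0.16,0.043,0.8,1
l_ulnar,l_brachial,22.9,0.18,0.046,0.8,1
thoracic_aorta_a,aortic_arch_b,5.2,1.12,0.128,0.4,0
intercostals,thoracic_aorta_a,8.0,0.20,0.049,0.4,1
thoracic_aorta_b,thoracic_aorta_a,5.2,1.07,0.124,0.4,0
thoracic_aorta_c,thoracic_aorta_b,5.2,1.03,0.121,0.4,0
thoracic_aorta_d,thoracic_aorta_c,5.2,1.00,0.119,0.4,0
abdominal_aorta_a,thoracic_aorta_d,5.3,0.98,0.116,0.4,0
celiac,abdominal_aorta_a,2.0,0.39,0.064,0.4,1
abdominal_aorta_b,abdominal_aorta_a,1.5,0.95,0.113,0.4,0
superior_mesenteric,abdominal_aorta_b,5.9,0.43,0.069,0.4,1
abdominal_aorta_c,abdominal_aorta_b,1.5,0.93,0.111,0.4,0
r_renal,abdominal_aorta_c,3.2,0.26,0.053,0.4,1
l_renal,abdominal_aorta_c,3.2,0.26,0.053,0.4,1
infrarenal_abdominal_aorta,abdominal_aorta_c,9.0,0.90,0.108,0.4,0
inferior_mesenteric,infrarenal_abdominal_aorta,5.0,0.16,0.043,0.4,1
abdominal_aorta_d,infrarenal_abdominal_aorta,2.0,0.85,0.104,0.4,0
r_common_iliac,abdominal_aorta_d,5.8,0.58,0.081,0.4,0
l_common_iliac,abdominal_aorta_d,5.8,0.58,0.081,0.4,0
r_internal_iliac,r_common_iliac,5.0,0.28,0.054,1.6,1
r_external_iliac,r_common_iliac,14.4,0.41,0.067,0.8,0
r_femoral,r_external_iliac,12.7,0.31,0.056,0.8,0
r_deep_femoral,r_femoral,12.6,0.28,0.054,0.8,1
r_popliteal,r_femoral,18.8,0.27,0.053,0.8,0
r_anterior_tibial,r_popliteal,34.3,0.13,0.039,1.6,1
r_posterior_tibial,r_popliteal,32.1,0.18,0.045,1.6,1
l_internal_iliac,l_common_iliac,5.0,0.28,0.054,1.6,1
l_external_iliac,l_common_iliac,14.4,0.41,0.067,0.8,0
l_femoral,l_external_iliac,12.7,0.31,0.056,0.8,0
l_deep_femoral,l_femoral,12.6,0.28,0.054,0.8,1
l_popliteal,l_femoral,18.8,0.27,0.053,0.8,0
l_anterior_tibial,l_popliteal,34.3,0.13,0.039,1.6,1
l_posterior_tibial,l_popliteal,32.1,0.18,0.045,1.6,1
"
    read.csv(text = txt, stringsAsFactors = FALSE, na.strings = "NA")
}

## fractions of cardiac output drained by each terminal bed
.TERMINAL_FLOW_FRACTIONS <- c(
    r_vertebral = 0.015, l_vertebral = 0.015,
    r_internal_carotid = 0.045, l_internal_carotid = 0.045,
    r_external_carotid = 0.020, l_external_carotid = 0.020,
    r_radial = 0.020, l_radial = 0.020,
    r_ulnar = 0.025, l_ulnar = 0.025,
    intercostals = 0.040,
    celiac = 0.120, superior_mesenteric = 0.100, inferior_mesenteric = 0.020,
    r_renal = 0.095, l_renal = 0.095,
    r_internal_iliac = 0.030, l_internal_iliac = 0.030,
    r_deep_femoral = 0.035, l_deep_femoral = 0.035,
    r_anterior_tibial = 0.035, l_anterior_tibial = 0.035,
    r_posterior_tibial = 0.040, l_posterior_tibial = 0.040
)

#' Default 55-segment arterial tree
#'
#' Constructs the nominal systemic arterial network: 55 uniform linear
#' transmission-line segments with an Avolio-type anatomy, 24 three-element
#' Windkessel terminal loads sized from typical regional flow fractions
#' (net DC resistance about 1.45e8 Pa s/m^3 at a mean pressure near 95 mmHg),
#' and named measurement sites at the ascending aorta, carotid, brachial,
#' femoral and tibial arteries plus the aneurysm host segment \code{TL_31}
#' (infrarenal abdominal aorta).
#'
#' @param stiffnessScale global multiplier applied to all Young's moduli.
#'   The default is calibrated so that the cohort's carotid-femoral pulse
#'   wave velocity spans roughly 5-15 m/s over the stiffness variability
#'   range (0.7-1.6) and ages 40-80.
#' @param density blood density, kg/m^3
#' @param viscosity blood dynamic viscosity, Pa s
#' @param proximalFraction Windkessel proximal-resistance share of the total
#'   terminal resistance
#' @param tau Windkessel distal time constant R2*C in seconds, used to size
#'   terminal compliances
#' @param meanPressure target mean aortic pressure (Pa) used to size terminal
#'   resistances
#' @param cardiacOutput reference cardiac output (m^3/s) used to size terminal
#'   resistances
#' @return an [ArterialModel-class]
#' @examples
#' tree <- defaultArterialTree()
#' tree
#' @export
defaultArterialTree <- function(stiffnessScale = 1.7,
                                density = 1050, viscosity = 4e-3,
                                proximalFraction = 0.2, tau = 1.4,
                                meanPressure = 95 * 133.322,
                                cardiacOutput = 75 / 60 * 70e-6) {
    tab <- .SEGMENT_TABLE()
    n <- nrow(tab)
    ids <- seq_len(n)
    ## the infrarenal abdominal aorta must carry id 31
    i31 <- which(tab$name == "infrarenal_abdominal_aorta")
    ids[c(i31, 31L)] <- ids[c(31L, i31)]
    seg <- data.frame(
        id = ids,
        name = tab$name,
        parent = ids[match(tab$parent, tab$name)],
        length = tab$l_cm / 100,
        radius = tab$r_cm / 100,
        thickness = tab$h_cm / 100,
        youngs = tab$E_MPa * 1e6 * stiffnessScale,
        terminal = tab$terminal == 1,
        stringsAsFactors = FALSE
    )
    fr <- .TERMINAL_FLOW_FRACTIONS
    stopifnot(abs(sum(fr) - 1) < 1e-12,
              setequal(names(fr), seg$name[seg$terminal]))
    rTotalNet <- meanPressure / cardiacOutput
    rT <- rTotalNet / fr[seg$name[seg$terminal]]
    loads <- data.frame(
        id = seg$id[seg$terminal],
        r_total = as.numeric(rT),
        compliance = tau / ((1 - proximalFraction) * as.numeric(rT)),
        proximal_fraction = proximalFraction
    )
    sites <- data.frame(
        site = c("ascending_aorta", "carotid", "brachial", "femoral",
                 "tibial", "TL_31"),
        id = seg$id[match(c("ascending_aorta", "l_common_carotid_b",
                            "l_brachial", "l_femoral", "l_posterior_tibial",
                            "infrarenal_abdominal_aorta"), seg$name)],
        position = c(0.5, 1.0, 0.5, 0.5, 0.9, 0.5),
        stringsAsFactors = FALSE
    )
    new("ArterialModel", segments = seg, loads = loads, sites = sites,
        blood = c(density = density, viscosity = viscosity))
}

#' Read an arterial tree from a YAML configuration
#'
#' The file must contain a \code{blood} mapping (\code{density},
#' \code{viscosity}), a \code{segments} list (fields \code{id}, \code{name},
#' \code{parent} — absent or \code{~} for the root — \code{length},
#' \code{radius}, \code{thickness}, \code{youngs}, and for terminal segments
#' \code{r_total}, \code{compliance}, \code{proximal_fraction}), and a
#' \code{sites} list (\code{site}, \code{id}, \code{position}).  All units SI.
#'
#' @param path YAML file path
#' @return an [ArterialModel-class]
#' @seealso [writeArterialTree()]
#' @export
readArterialTree <- function(path) {
    y <- yaml::read_yaml(path)
    segs <- y$segments
    get <- function(f, default = NA) vapply(segs, function(s)
        if (is.null(s[[f]])) default else as.numeric(s[[f]]), numeric(1))
    seg <- data.frame(
        id = as.integer(get("id")),
        name = vapply(segs, function(s) as.character(s$name), character(1)),
        parent = as.integer(get("parent")),
        length = get("length"), radius = get("radius"),
        thickness = get("thickness"), youngs = get("youngs"),
        terminal = !is.na(get("r_total")),
        stringsAsFactors = FALSE
    )
    term <- seg$terminal
    loads <- data.frame(
        id = seg$id[term],
        r_total = get("r_total")[term],
        compliance = get("compliance")[term],
        proximal_fraction = get("proximal_fraction")[term]
    )
    sites <- do.call(rbind, lapply(y$sites, function(s)
        data.frame(site = s$site, id = as.integer(s$id),
                   position = as.numeric(s$position),
                   stringsAsFactors = FALSE)))
    new("ArterialModel", segments = seg, loads = loads, sites = sites,
        blood = c(density = as.numeric(y$blood$density),
                  viscosity = as.numeric(y$blood$viscosity)))
}

#' Write an arterial tree to a YAML configuration
#'
#' @param model an [ArterialModel-class]
#' @param path output file path
#' @return \code{path}, invisibly
#' @seealso [readArterialTree()]
#' @export
writeArterialTree <- function(model, path) {
    seg <- model@segments
    loads <- model@loads
    segs <- lapply(seq_len(nrow(seg)), function(i) {
        s <- list(id = seg$id[i], name = seg$name[i],
                  length = seg$length[i], radius = seg$radius[i],
                  thickness = seg$thickness[i], youngs = seg$youngs[i])
        if (!is.na(seg$parent[i])) s$parent <- seg$parent[i]
        if (seg$terminal[i]) {
            j <- match(seg$id[i], loads$id)
            s$r_total <- loads$r_total[j]
            s$compliance <- loads$compliance[j]
            s$proximal_fraction <- loads$proximal_fraction[j]
        }
        s
    })
    sites <- lapply(seq_len(nrow(model@sites)), function(i)
        as.list(model@sites[i, , drop = FALSE]))
    yaml::write_yaml(list(
        blood = as.list(model@blood),
        segments = segs,
        sites = lapply(sites, function(s) {
            names(s) <- c("site", "id", "position"); s
        })
    ), path)
    invisible(path)
}

## Compile an ArterialModel into flat vectors + topological order for the
## frequency-domain solver.  Called once per simulation.
.compileTree <- function(model) {
    seg <- model@segments
    n <- nrow(seg)
    pidx <- match(seg$parent, seg$id)
    root <- which(is.na(pidx))
    ## topological order by repeated sweeps (tree depth is small)
    depth <- rep.int(NA_integer_, n)
    depth[root] <- 0L
    repeat {
        todo <- which(is.na(depth) & !is.na(depth[pidx]))
        if (!length(todo)) break
        depth[todo] <- depth[pidx[todo]] + 1L
    }
    ord <- order(depth)                  # root first
    children <- split(seq_len(n), factor(pidx, levels = seq_len(n)))
    ldm <- match(seg$id, model@loads$id)
    list(
        n = n, root = root, parent = pidx, order = ord,
        children = children,
        L = seg$length, r = seg$radius, h = seg$thickness, E = seg$youngs,
        terminal = seg$terminal,
        rT = model@loads$r_total[ldm],
        cT = model@loads$compliance[ldm],
        pf = model@loads$proximal_fraction[ldm],
        rho = model@blood[["density"]], mu = model@blood[["viscosity"]],
        siteSeg = match(model@sites$id, seg$id),
        sitePos = model@sites$position,
        siteName = model@sites$site
    )
}

#' Path length from the aortic root to a named measurement site
#'
#' Sums segment lengths along the unique root-to-site path, including the
#' fractional axial position within the site's own segment.  The
#' carotid-femoral PWV path length is the femoral path minus the carotid path.
#'
#' @param model an [ArterialModel-class]
#' @param site site name present in \code{measurementSites(model)}
#' @return length in metres
#' @export
sitePathLength <- function(model, site) {
    st <- model@sites
    i <- match(site, st$site)
    if (is.na(i)) stop("unknown site: ", site)
    seg <- model@segments
    j <- match(st$id[i], seg$id)
    total <- seg$length[j] * st$position[i]
    pidx <- match(seg$parent, seg$id)
    j <- pidx[j]
    while (!is.na(j)) {
        total <- total + seg$length[j]
        j <- pidx[j]
    }
    total
}
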