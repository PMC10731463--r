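## occupancy module: hetero-oligomer nucleotide stoichiometry.

#' Construct an OctamerModel
#'
#' General hetero-oligomer occupancy model: slots filled by subunits (with
#' optional within-slot mixtures, e.g. a terminal slot shared by Cdc11 and
#' Shs1 at a fixed ratio), a GTP-bound fraction per subunit, and 1:1
#' nucleotide:protein pocket occupancy. Complex size is the sum of slot
#' copies, so hexamers and tetramers are expressible too.
#'
#' @param subunits data.frame(slot, subunit, copies, weight, gtp_fraction).
#'   `weight` is the within-slot mixture weight; weights must sum to 1 per
#'   slot (single-occupant slots use weight 1).
#' @return an [OctamerModel].
#' @export
octamerModel <- function(subunits) {
    s <- as.data.frame(subunits)
    size <- sum(vapply(split(s, s$slot), function(r) r$copies[1], numeric(1)))
    new("OctamerModel", subunits = s, size = as.integer(size))
}

#' The budding-yeast septin hetero-octamer
#'
#' Default model: 2 copies each of Cdc3, Cdc10 and Cdc12 plus two terminal
#' slots shared by Cdc11 and Shs1 at the given molar ratio. Default GTP-bound
#' fractions encode the worked occupancy scenario for the 2.2:1 bulk GDP:GTP
#' ratio: Cdc3 permanently GTP-bound (it cannot hydrolyze), Cdc10 and Cdc12
#' GDP-bound, 40% of Cdc11 GTP-bound, Shs1 GDP-bound.
#'
#' @param cdc11Shs1Ratio molar ratio of Cdc11 to Shs1 at the terminal slot
#'   (default 1.6).
#' @param gtpFractions named vector of per-subunit GTP-bound fractions.
#' @return an [OctamerModel].
#' @export
yeastOctamer <- function(cdc11Shs1Ratio = 1.6,
                         gtpFractions = c(Cdc3 = 1, Cdc10 = 0, Cdc12 = 0,
                                          Cdc11 = 0.4, Shs1 = 0)) {
    w11 <- cdc11Shs1Ratio / (cdc11Shs1Ratio + 1)
    g <- function(s) unname(gtpFractions[s])
    octamerModel(data.frame(
        slot = c("terminal", "terminal", "cdc12", "cdc3", "cdc10"),
        subunit = c("Cdc11", "Shs1", "Cdc12", "Cdc3", "Cdc10"),
        copies = c(2, 2, 2, 2, 2),
        weight = c(w11, 1 - w11, 1, 1, 1),
        gtp_fraction = c(g("Cdc11"), g("Shs1"), g("Cdc12"), g("Cdc3"),
                         g("Cdc10"))))
}

#' Bulk GDP:GTP ratio of an occupancy model
#'
#' Expected GTP per complex is the sum over subunits of copies x mixture
#' weight x GTP fraction; with 1:1 pocket occupancy, GDP per complex is the
#' complex size minus that. The ratio GDP/GTP is returned with full
#' precision; an all-GDP model is flagged (`defined = FALSE`, ratio `Inf`)
#' rather than silently returning a number, and an all-GTP model gives
#' ratio 0.
#'
#' @param model an [OctamerModel].
#' @return list(gtp_per_complex, gdp_per_complex, ratio, defined).
#' @export
nucleotideRatio <- function(model) {
    stopifnot(is(model, "OctamerModel"))
    validObject(model)
    s <- model@subunits
    gtp <- sum(s$copies * s$weight * s$gtp_fraction)
    gdp <- model@size - gtp
    if (gtp <= 0)
        return(list(gtp_per_complex = 0, gdp_per_complex = gdp, ratio = Inf,
                    defined = FALSE))
    list(gtp_per_complex = gtp, gdp_per_complex = gdp, ratio = gdp / gtp,
         defined = TRUE)
}

#' Solve for an unknown GTP-bound fraction from a target GDP:GTP ratio
#'
#' Closed-form inversion of [nucleotideRatio()] in the single free
#' parameter: with fixed contributions G0 from the other subunits and
#' effective copy number c for the free subunit, the target ratio t gives
#' f = (size/(1+t) - G0) / c. Errors when the target is not attainable for
#' f in `[0, 1]`, stating the attainable interval.
#'
#' @param model an [OctamerModel].
#' @param subunit name of the subunit whose GTP fraction is unknown.
#' @param target target GDP:GTP ratio.
#' @return fraction in `[0, 1]`; `nucleotideRatio()` on the model with the
#'   solved fraction reproduces the target to 1e-9.
#' @export
solveFraction <- function(model, subunit, target) {
    stopifnot(is(model, "OctamerModel"), target >= 0)
    s <- model@subunits
    free <- s$subunit == subunit
    if (!any(free)) stop("no subunit named '", subunit, "' in the model")
    cEff <- sum(s$copies[free] * s$weight[free])
    g0 <- sum(s$copies[!free] * s$weight[!free] * s$gtp_fraction[!free])
    f <- (model@size / (1 + target) - g0) / cEff
    if (f < -1e-9 || f > 1 + 1e-9) {
        at <- function(fr) {
            gt <- g0 + cEff * fr
            if (gt <= 0) Inf else (model@size - gt) / gt
        }
        stop(sprintf(
            "target ratio %.4g not attainable; fractions in [0,1] give ratios in [%.4g, %.4g]",
            target, at(1), at(0)))
    }
    min(1, max(0, f))
}

#' Set a subunit's GTP-bound fraction
#'
#' @param model an [OctamerModel].
#' @param subunit subunit name.
#' @param fraction new GTP-bound fraction in `[0, 1]`.
#' @return the modified [OctamerModel].
#' @export
setGtpFraction <- function(model, subunit, fraction) {
    s <- model@subunits
    if (!any(s$subunit == subunit)) stop("no subunit named '", subunit, "'")
    s$gtp_fraction[s$subunit == subunit] <- fraction
    octamerModel(s)
}

#' Monte-Carlo ensemble of complexes under an occupancy model
#'
#' Samples `n` complexes: each mixed slot draws its occupant from the
#' mixture weights, and each subunit copy is GTP-bound with its subunit's
#' fraction. Used as a sampling cross-check of the analytic ratio.
#'
#' @param model an [OctamerModel].
#' @param n number of complexes.
#' @param seed integer seed.
#' @return list(ratio, gtp_total, gdp_total, se_ratio) where `se_ratio` is a
#'   delta-method standard error of the sampled ratio.
#' @export
sampleOctamers <- function(model, n = 1e5, seed = 1L) {
    stopifnot(is(model, "OctamerModel"))
    set.seed(seed)
    s <- model@subunits
    gtpPer <- numeric(n)
    for (sl in unique(s$slot)) {
        rows <- s[s$slot == sl, ]
        copies <- rows$copies[1]
        for (cp in seq_len(copies)) {
            occIdx <- if (nrow(rows) == 1L) rep(1L, n)
                      else sample.int(nrow(rows), n, replace = TRUE,
                                      prob = rows$weight)
            frac <- rows$gtp_fraction[occIdx]
            gtpPer <- gtpPer + (runif(n) < frac)
        }
    }
    G <- sum(gtpPer)
    total <- as.numeric(model@size) * n
    ratio <- (total - G) / G
    seG <- sd(gtpPer) * sqrt(n)
    list(ratio = ratio, gtp_total = G, gdp_total = total - G,
         se_ratio = total / G^2 * seG)
}
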