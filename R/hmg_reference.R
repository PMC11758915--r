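#' Reference glycoside hydrolase families for human milk glycan utilization
#'
#' The bundled profiling target set: 13 glycoside hydrolase (GH) families
#' implicated in the breakdown of human milk glycans (HMGs) by
#' \emph{Bifidobacterium longum} — 8 acting on free human milk oligosaccharides
#' (HMOs) and 5 on milk glycoprotein N-glycans. Family-level activities follow
#' the CAZy classification (e.g. GH95/GH29 alpha-L-fucosidases, GH33
#' sialidases, GH20 beta-hexosaminidases, GH112 lacto-N-biose phosphorylases,
#' GH38/GH125 alpha-mannosidases, GH5 subfamily 18 beta-mannosidase, GH85/GH18
#' endo-beta-N-acetylglucosaminidases).
#'
#' @return A data.frame with columns \code{family}, \code{substrate}
#'   (\code{"HMO"} or \code{"N-glycan"}) and \code{activity}.
#' @seealso [hmg_transporters()]
#' @export
hmg_gh_families <- function() {
  data.frame(
    family = c("GH2", "GH20", "GH29", "GH33", "GH42", "GH95", "GH112",
               "GH136",
               "GH5_18", "GH18", "GH38", "GH85", "GH125"),
    substrate = c(rep("HMO", 8), rep("N-glycan", 5)),
    activity = c(
      "beta-galactosidase",
      "beta-hexosaminidase",
      "alpha-L-fucosidase",
      "sialidase",
      "beta-galactosidase",
      "alpha-L-fucosidase",
      "lacto-N-biose phosphorylase",
      "lacto-N-biosidase",
      "beta-mannosidase",
      "endo-beta-N-acetylglucosaminidase",
      "alpha-mannosidase",
      "endo-beta-N-acetylglucosaminidase",
      "alpha-mannosidase"),
    stringsAsFactors = FALSE
  )
}

#' Reference glycan-transporter gene set
#'
#' The bundled transporter target set: 37 genes collectively encoding 14 glycan
#' uptake systems — 11 for HMOs (LNB/GNB importers GltABC and GltFGH,
#' fucosyllactose transporters FL1/FL2, the nahS solute-binding protein, and
#' the hmo family of type-II HMO ABC transporters) and 3 for N-glycans
#' (MnaABC, NgtABC and the AfcT permease). System names follow the
#' bifidobacterial glycan-transport literature; the per-system gene breakdown
#' is a synthetic reconstruction (this package ships no third-party reference
#' sequences) constrained to the documented totals.
#'
#' @return A data.frame with one row per gene: columns \code{gene},
#'   \code{system} and \code{substrate} (\code{"HMO"} or \code{"N-glycan"}).
#' @export
hmg_transporters <- function() {
  sys3 <- function(system, stems) {
    data.frame(gene = stems, system = system, stringsAsFactors = FALSE)
  }
  hmo <- rbind(
    sys3("gltABC", c("gltA", "gltB", "gltC")),
    sys3("gltFGH", c("gltF", "gltG", "gltH")),
    sys3("FL1",    c("fl1A", "fl1B", "fl1C")),
    sys3("FL2",    c("fl2A", "fl2B", "fl2C")),
    sys3("nahS",   "nahS"),
    sys3("hmoABC",    c("hmoA", "hmoB", "hmoC")),
    sys3("hmoA2B2C2", c("hmoA2", "hmoB2", "hmoC2")),
    sys3("hmoA3B3C3", c("hmoA3", "hmoB3", "hmoC3")),
    sys3("hmoA4B4C4", c("hmoA4", "hmoB4", "hmoC4")),
    sys3("hmoA5B5C5", c("hmoA5", "hmoB5", "hmoC5")),
    sys3("hmoA6",     c("hmoA6", "hmoB6"))
  )
  hmo$substrate <- "HMO"
  ngly <- rbind(
    sys3("mnaABC", c("mnaA", "mnaB", "mnaC")),
    sys3("ngtABC", c("ngtA", "ngtB", "ngtC")),
    sys3("afcT",   "afcT")
  )
  ngly$substrate <- "N-glycan"
  rbind(hmo, ngly)
}

#' Default HMG-utilization archetypes
#'
#' Three mean copy-number vectors over GH sequence variants (family_vN) of
#' the reference families and the transporter uptake systems, one per
#' HMG-utilization type observed among \emph{B. longum} genomes:
#' \describe{
#'   \item{BLinfantis-HMG}{broad HMO and N-glycan repertoire — fucosidase
#'     (GH29/GH95), sialidase (GH33) and hexosaminidase (GH20) variants,
#'     shared parts of the oligomannose module, and the full HMO/N-glycan
#'     transporter arsenal.}
#'   \item{BLlongum-HMGcomplex}{core HMO repertoire extended with the
#'     oligomannose N-glycan module (GH5_18, GH38_v1, GH85_v1/v2, GH125) and
#'     N-glycan uptake (mnaABC, ngtABC), plus lineage-specific variants of the
#'     shared HMO families.}
#'   \item{BLlongum-HMGsimple}{core HMO repertoire only (GH2/GH42
#'     galactosidases, GH112/GH136 LNB pathway, gltABC uptake), with its own
#'     lineage-specific variants of those families.}
#' }
#' The two BLlongum lineages carry partly disjoint sequence variants of the
#' shared HMO families (as in per-family homology clustering of real
#' genomes), which is what separates them in profile space.
#'
#' @return A named list of three equal-length named numeric vectors
#'   (GH variant / transporter system -> mean copy number).
#' @export
default_archetypes <- function() {
  # each entry: c(BLlongum-HMGsimple, BLlongum-HMGcomplex, BLinfantis-HMG)
  cols <- list(
    GH2_v1 = c(2, 2, 3), GH2_v2 = c(1, 0, 0), GH2_v3 = c(0, 1, 1),
    GH2_v4 = c(1, 0, 0), GH2_v5 = c(0, 1, 0), GH2_v6 = c(0, 1, 0),
    GH2_v7 = c(1, 0, 0),
    GH42_v1 = c(1, 0, 0), GH42_v2 = c(0, 1, 1), GH42_v3 = c(0, 1, 0),
    GH42_v4 = c(2, 1, 0), GH42_v5 = c(1, 0, 0),
    GH112_v1 = c(1, 1, 2), GH112_v2 = c(1, 0, 0), GH112_v3 = c(0, 1, 0),
    GH136_v1 = c(1, 1, 0), GH136_v2 = c(0, 1, 0), GH136_v3 = c(1, 0, 0),
    GH5_18 = c(0, 2, 1), GH38_v1 = c(0, 2, 2), GH85_v1 = c(0, 2, 0),
    GH85_v2 = c(0, 1, 0), GH125 = c(0, 2, 1),
    GH20_v1 = c(0, 0, 2), GH20_v3 = c(0, 0, 1),
    GH29_v1 = c(0, 0, 2), GH29_v2 = c(0, 0, 1),
    GH33_v1 = c(0, 0, 2), GH95 = c(0, 0, 1), GH18 = c(0, 0, 1),
    GH38_v2 = c(0, 0, 1),
    gltABC = c(1, 1, 0), mnaABC = c(0, 1, 1), ngtABC = c(0, 1, 0),
    gltFGH = c(0, 0, 1), FL1 = c(0, 0, 1), FL2 = c(0, 0, 1),
    nahS = c(0, 0, 1), hmoABC = c(0, 0, 1), hmoA2B2C2 = c(0, 0, 1),
    hmoA3B3C3 = c(0, 0, 1), hmoA4B4C4 = c(0, 0, 1), hmoA5B5C5 = c(0, 0, 1),
    hmoA6 = c(0, 0, 1), afcT = c(0, 0, 1))
  genes <- names(cols)
  pick <- function(i) setNames(vapply(cols, `[`, numeric(1), i), genes)
  list(`BLinfantis-HMG` = pick(3),
       `BLlongum-HMGcomplex` = pick(2),
       `BLlongum-HMGsimple` = pick(1))
}
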