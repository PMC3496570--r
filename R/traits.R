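#' Default dairy trait catalog
#'
#' The 31 routinely evaluated U.S. Holstein traits: 13 production, health
#' and reproduction traits and 18 body conformation traits, with each
#' trait's direction of favorability. Low PTA values are favorable for
#' somatic cell score, service-sire calving ease, daughter calving ease,
#' service-sire stillbirth and (by analogy, overridable) daughter
#' stillbirth; all other traits are high-favorable.
#'
#' @param low_favorable traits whose favorable direction is downward.
#' @return data.frame with columns \code{trait}, \code{name},
#'   \code{direction} ("high"/"low") and \code{block}
#'   ("production_health_reproduction" or "conformation").
#' @export
default_trait_catalog <- function(low_favorable = c("SCS", "SCE", "DCE",
                                                    "SSB", "DSB")) {
  phr <- c(MY = "milk yield", FY = "fat yield", PY = "protein yield",
           FPC = "fat percentage", PPC = "protein percentage",
           PL = "productive life", SCS = "somatic cell score",
           DPR = "daughter pregnancy rate",
           SCE = "service-sire calving ease", DCE = "daughter calving ease",
           SSB = "service-sire stillbirth", DSB = "daughter stillbirth",
           NM = "net merit")
  conf <- c(STA = "stature", STR = "strength", BD = "body depth",
            RW = "rump width", DF = "dairy form", RA = "rump angle",
            FUA = "fore udder attachment", RUH = "rear udder height",
            UD = "udder depth", UC = "udder cleft",
            FTP = "front teat placement", RTP = "rear teat placement",
            TL = "teat length", FA = "foot angle",
            RLS = "rear legs (side view)", RLR = "rear legs (rear view)",
            FL = "feet/legs score", FS = "final score")
  tr <- c(names(phr), names(conf))
  data.frame(trait = tr,
             name = unname(c(phr, conf)),
             direction = ifelse(tr %in% low_favorable, "low", "high"),
             block = rep(c("production_health_reproduction", "conformation"),
                         c(length(phr), length(conf))),
             stringsAsFactors = FALSE)
}
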