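#' AAL-90 region labels
#'
#' Region-of-interest labels for the 90-region automated anatomical
#' labeling (AAL) parcellation (45 cortical/subcortical regions per
#' hemisphere, cerebellum excluded), as conventionally abbreviated in
#' connectomics studies. Each abbreviation is suffixed with `_L` / `_R`
#' for the left and right hemisphere.
#'
#' @return Character vector of 90 unique ROI labels, region-major
#'   (`PreCG_L`, `PreCG_R`, `SFGdor_L`, ...).
#' @export
#' @examples
#' head(aal90_labels())
aal90_labels <- function() {
  regions <- c(
    "PreCG", "SFGdor", "SFGorb", "MFG", "MFGorb", "IFGoperc", "IFGtriang",
    "IFGorb", "ROL", "SMA", "OLF", "SFGmed", "SFGmedO", "REC", "INS",
    "ACC", "MCC", "PCC", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "STGP",
    "MTG", "MTGP", "ITG"
  )
  paste0(rep(regions, each = 2L), c("_L", "_R"))
}

#' Default perturbation ROI sets
#'
#' `default_focal_rois()` is the default-mode-network core (posterior
#' cingulate, precuneus, angular, parahippocampal and hippocampal
#' regions plus medial orbitofrontal cortex, both hemispheres; 12 ROIs):
#' the set whose severe focal decoupling emulates an MCI-like scattered
#' impairment. `default_diffuse_rois()` extends it with lateral
#' temporal, inferior frontal, insular and parietal regions (30 ROIs),
#' over which a milder perturbation emulates the diffuse AD-like
#' pattern.
#'
#' @return Character vector of ROI labels (subset of [aal90_labels()]).
#' @export
default_focal_rois <- function() {
  paste0(rep(c("PCC", "PCUN", "ANG", "PHG", "HIP", "SFGmedO"), each = 2L),
         c("_L", "_R"))
}

#' @rdname default_focal_rois
#' @export
default_diffuse_rois <- function() {
  extra <- c("IFGtriang", "IFGoperc", "MTG", "ITG", "STG", "SMG", "IPL",
             "REC", "INS")
  c(default_focal_rois(), paste0(rep(extra, each = 2L), c("_L", "_R")))
}
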