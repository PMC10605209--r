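#' AAL90 region abbreviations
#'
#' The 90 cortical/subcortical region abbreviations of the Automated
#' Anatomical Labeling atlas, in the standard interleaved left/right order
#' (PreCG.L, PreCG.R, SFGdor.L, ...). These are the default node labels of a
#' 90-region structural covariance network.
#'
#' @return character vector of length 90.
#' @examples
#' head(aal90Labels())
#' @export
aal90Labels <- function() {
  base <- c("PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc",
            "IFGtriang", "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed",
            "REC", "INS", "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL",
            "CUN", "LING", "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL",
            "SMG", "ANG", "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES",
            "STG", "TPOsup", "MTG", "TPOmid", "ITG")
  as.vector(rbind(paste0(base, ".L"), paste0(base, ".R")))
}

.defaultRegionLabels <- function(n) {
  if (n == 90L) aal90Labels() else sprintf("R%03d", seq_len(n))
}
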