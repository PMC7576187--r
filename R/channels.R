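#' Standard 64-channel scalp montage labels
#'
#' Electrode labels following the extended international 10/20 system, as used
#' by common 64-channel caps (mastoids excluded; see
#' [rereference_mastoids()] for recordings that include them). Ordered roughly
#' front to back.
#'
#' @return Character vector of 64 labels.
#' @export
montage_64 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "Oz", "O2", "CB1", "CB2")
}

#' Default fronto-central channel set
#'
#' The channel group over which forward-model TRF weights are averaged before
#' extracting P1/N1/P2 components. User-overridable everywhere it is used.
#'
#' @return Character vector of channel labels.
#' @export
frontocentral_channels <- function() {
  c("Fz", "FCz", "Cz", "FC1", "FC2", "F1", "F2", "C1", "C2")
}
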