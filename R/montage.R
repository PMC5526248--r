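#' Standard 64-channel extended 10-20 montage labels
#'
#' Channel labels of a 64-electrode cap laid out on the extended
#' International 10-20 system, including the two mastoid electrodes
#' (`M1`, `M2`) used for off-line re-referencing. Scalp analyses that
#' exclude the mastoids therefore run on 62 electrodes.
#'
#' @return Character vector of 64 channel labels.
#' @export
#' @examples
#' length(montage_64())
montage_64 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "M1",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "M2",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "CB1", "O1", "Oz", "O2", "CB2")
}

#' Channels used for speller feature extraction
#'
#' The fixed 10-channel set with the highest window-averaged
#' classifiability in audiovisual oddball data: central/parietal sites
#' carrying P3, occipito-parietal sites carrying the early posterior
#' response, and fronto-central sites carrying N2.
#'
#' @return Character vector of 10 channel labels.
#' @export
speller_channels <- function() {
  c("Cz", "Pz", "CPz", "Oz", "PO7", "PO8", "FC1", "FC2", "FC5", "FC6")
}

# Smooth scalp gain map: 1 at the named peak electrodes, falling off over
# the listed neighbours. Gains are unitless in [0, 1]; channels absent
# from the map contribute nothing.
.topo <- function(peak, near = character(), far = character()) {
  g <- c(stats::setNames(rep(1, length(peak)), peak),
         stats::setNames(rep(0.7, length(near)), near),
         stats::setNames(rep(0.35, length(far)), far))
  g[!duplicated(names(g))]
}

#' Built-in component topographies
#'
#' Unitless per-channel gain maps for the four evoked components the
#' simulator models: a centro-parietal P3 peaking at `Pz`, a
#' fronto-central/posterior N2, a posterior N4 and a late posterior P5.
#'
#' @param name One of `"N2"`, `"P3"`, `"N4"`, `"P5"`.
#' @return Named numeric vector of gains in `[0, 1]`.
#' @export
component_topography <- function(name) {
  switch(match.arg(name, c("N2", "P3", "N4", "P5")),
    N2 = .topo(peak = "Cz",
               near = c("FCz", "C1", "C2", "CPz", "FC1", "FC2", "Fz"),
               far  = c("FC5", "FC6", "C3", "C4", "Pz", "POz", "Oz")),
    P3 = .topo(peak = "Pz",
               near = c("CPz", "P1", "P2", "POz", "Cz", "CP1", "CP2"),
               far  = c("P3", "P4", "PO3", "PO4", "Oz", "C1", "C2")),
    N4 = .topo(peak = "POz",
               near = c("Pz", "PO3", "PO4", "Oz", "O1", "O2"),
               far  = c("PO7", "PO8", "P1", "P2", "CPz")),
    P5 = .topo(peak = "POz",
               near = c("Oz", "O1", "O2", "PO3", "PO4", "PO7", "PO8"),
               far  = c("Pz", "P3", "P4", "CB1", "CB2")))
}
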