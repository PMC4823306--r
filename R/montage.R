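#' Default electrode montage
#'
#' The recording montage used throughout the package: 29 EEG channels over
#' fronto-central to parieto-occipital sites plus 3 EOG channels, a set of 13
#' bipolar derivations above the somatosensory cortex used for SSSEP
#' analysis, the 7-pair subset used for screening tuning-curve maps, and 10
#' monopolar channels used for P300 analysis.  Only FC3-CP3, FC4-CP4 (bipolar)
#' and Fz, Cz, Pz (monopolar) are fixed by design; the remaining members of
#' each set are a declared, configurable approximation of a symmetric
#' fronto-central to centro-parietal grid.
#'
#' @return object of class `bci_montage`: a list with `eeg_channels`,
#'   `eog_channels`, `sssep_pairs` (13 x 2 character matrix),
#'   `screening_pairs` (7 x 2), and `p300_channels` (length 10).
#' @export
default_montage <- function() {
  eeg <- c("Fz",
           "FC3", "FC1", "FCz", "FC2", "FC4",
           "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
           "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
           "P5", "P3", "P1", "Pz", "P2", "P4", "P6",
           "PO3", "PO4")
  eog <- c("EOGL", "EOGR", "EOGC")
  sssep <- rbind(
    c("FC3", "CP3"), c("FC1", "CP1"), c("FCz", "CPz"),
    c("FC2", "CP2"), c("FC4", "CP4"),
    c("C5", "P5"), c("C3", "P3"), c("C1", "P1"), c("Cz", "Pz"),
    c("C2", "P2"), c("C4", "P4"), c("C6", "P6"),
    c("Cz", "CPz"))
  screening <- rbind(
    c("FC3", "CP3"), c("FC1", "CP1"), c("FCz", "CPz"),
    c("FC2", "CP2"), c("FC4", "CP4"), c("C3", "P3"), c("C4", "P4"))
  p300 <- c("Fz", "FCz", "Cz", "CPz", "Pz", "C3", "C4", "CP1", "CP2", "P1")
  structure(list(eeg_channels = eeg, eog_channels = eog,
                 sssep_pairs = sssep, screening_pairs = screening,
                 p300_channels = p300),
            class = "bci_montage")
}

validate_montage <- function(montage, channel_labels) {
  need <- unique(c(montage$sssep_pairs, montage$p300_channels))
  missing <- setdiff(need, channel_labels)
  if (length(missing)) {
    stopf("montage channels not present in recording: %s",
          paste(missing, collapse = ", "))
  }
  if (any(montage$sssep_pairs[, 1] == montage$sssep_pairs[, 2])) {
    stopf("bipolar pair members must be distinct")
  }
  invisible(TRUE)
}

bipolar_labels <- function(pairs) paste(pairs[, 1], pairs[, 2], sep = "-")

#' Read / write a montage file
#'
#' Plain-text montage exchange format: one entry per line; bipolar pairs as
#' `anode-cathode`, monopolar channels as bare labels, section headers
#' `[sssep]`, `[screening]`, `[p300]`.
#'
#' @param file path.
#' @param montage a `bci_montage`.
#' @return `read_montage` returns a `bci_montage` (EEG/EOG channel lists are
#'   taken from [default_montage()]).
#' @export
write_montage <- function(montage, file) {
  lines <- c("[sssep]", bipolar_labels(montage$sssep_pairs),
             "[screening]", bipolar_labels(montage$screening_pairs),
             "[p300]", montage$p300_channels)
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_montage
#' @export
read_montage <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  m <- default_montage()
  section <- NULL
  acc <- list(sssep = character(), screening = character(), p300 = character())
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", ln)
    } else {
      acc[[section]] <- c(acc[[section]], ln)
    }
  }
  split_pairs <- function(x) {
    do.call(rbind, strsplit(x, "-", fixed = TRUE))
  }
  if (length(acc$sssep)) m$sssep_pairs <- split_pairs(acc$sssep)
  if (length(acc$screening)) m$screening_pairs <- split_pairs(acc$screening)
  if (length(acc$p300)) m$p300_channels <- acc$p300
  m
}
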