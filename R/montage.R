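#' Canonical 10-20 montage channels
#'
#' The 19 scalp electrodes of the International 10-20 system used throughout
#' the package, in the canonical order that fixes the feature layout:
#' prefrontal, frontal, central, parietal, temporal, occipital.
#'
#' @return Character vector of 19 electrode labels.
#' @examples
#' montageChannels()
#' @export
montageChannels <- function() {
    c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
      "C3", "C4", "Cz", "P3", "P4", "Pz",
      "T3", "T4", "T5", "T6", "O1", "O2")
}

# Normalize a raw channel label to a canonical 10-20 name, or NA if the
# label does not belong to the montage. Matching is case-insensitive; an
# "EEG " prefix and reference suffixes such as "-A1", "-A2", "-REF" are
# stripped before matching.
.normalizeLabel <- function(label) {
    x <- trimws(label)
    x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
    x <- sub("[-_](A1|A2|REF|LE|AVG)$", "", x, ignore.case = TRUE)
    canon <- montageChannels()
    hit <- match(toupper(x), toupper(canon))
    ifelse(is.na(hit), NA_character_, canon[hit])
}

# Reorder a labelled signal matrix into canonical montage order, dropping
# channels outside the montage (with a warning naming them).
.canonicalizeSignal <- function(mat, labels) {
    norm <- .normalizeLabel(labels)
    keep <- !is.na(norm)
    if (!any(keep))
        stop("no channels match the 10-20 montage (labels: ",
             paste(labels, collapse = ", "), ")")
    if (any(!keep))
        warning("dropping non-montage channels: ",
                paste(labels[!keep], collapse = ", "))
    mat <- mat[, keep, drop = FALSE]
    norm <- norm[keep]
    if (anyDuplicated(norm))
        stop("duplicated montage channels after normalization: ",
             paste(norm[duplicated(norm)], collapse = ", "))
    ord <- order(match(norm, montageChannels()))
    mat <- mat[, ord, drop = FALSE]
    colnames(mat) <- norm[ord]
    mat
}
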