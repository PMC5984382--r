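# Minimal European Data Format (EDF) support: continuous 16-bit recordings,
# one sampling rate across the montage channels. Enough for reading typical
# clinical exports and for round-tripping the package's own files; EDF+
# annotations and discontinuous files are out of scope.

.edf_pad <- function(x, width) {
    x <- as.character(x)
    if (nchar(x) > width) x <- substr(x, 1, width)
    formatC(x, width = width, flag = "-")
}

# Read an EDF file into a list(labels, fs, data) where data is a
# samples-by-channels double matrix in physical units. Channels whose
# sampling rate differs from the majority rate are dropped with a warning.
.readEDF <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
    version <- hdr(8)
    hdr(80); hdr(80); hdr(8); hdr(8)          # patient, recording, date, time
    hdr(8)                                     # header length
    hdr(44)                                    # reserved
    n_rec <- as.integer(hdr(8))
    rec_dur <- as.numeric(hdr(8))
    ns <- as.integer(hdr(4))
    if (is.na(ns) || ns < 1) stop("not a valid EDF file: ", path)
    field <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
    labels <- field(16)
    field(80); field(8)                        # transducer, physical dimension
    pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
    dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
    field(80)                                  # prefiltering
    spr <- as.integer(field(8))                # samples per record
    field(32)                                  # reserved
    raw <- matrix(0, nrow = n_rec * max(spr), ncol = ns)
    counts <- integer(ns)
    for (r in seq_len(n_rec)) {
        for (s in seq_len(ns)) {
            v <- readBin(con, "integer", n = spr[s], size = 2,
                         signed = TRUE, endian = "little")
            raw[counts[s] + seq_along(v), s] <- v
            counts[s] <- counts[s] + length(v)
        }
    }
    gain <- (pmax - pmin) / (dmax - dmin)
    data <- lapply(seq_len(ns), function(s)
        gain[s] * (raw[seq_len(counts[s]), s] - dmin[s]) + pmin[s])
    fs <- spr / rec_dur
    fs_main <- as.numeric(names(sort(table(fs), decreasing = TRUE))[1])
    ok <- fs == fs_main
    if (any(!ok))
        warning("dropping channels with deviating sampling rate: ",
                paste(labels[!ok], collapse = ", "))
    list(labels = labels[ok], fs = fs_main,
         data = do.call(cbind, data[ok]))
}

# Write a Recording as a minimal EDF file. Uses 1-second data records when
# the sample count divides evenly, otherwise a single record.
.writeEDF <- function(rec, path) {
    sig <- signalMatrix(rec)
    fs <- samplingRate(rec)
    n <- nrow(sig); ns <- ncol(sig)
    if (n %% fs == 0 && fs == round(fs)) {
        spr <- as.integer(fs); n_rec <- n %/% fs; rec_dur <- 1
    } else {
        spr <- n; n_rec <- 1L; rec_dur <- n / fs
    }
    pmin <- apply(sig, 2, min); pmax <- apply(sig, 2, max)
    flat <- pmax - pmin < 1e-12
    pmax[flat] <- pmin[flat] + 1
    dmin <- -32768; dmax <- 32767
    dig <- round(sweep(sweep(sig, 2, pmin), 2, (pmax - pmin) / (dmax - dmin),
                       "/")) + dmin
    con <- file(path, "wb")
    on.exit(close(con))
    put <- function(x, w) writeBin(charToRaw(.edf_pad(x, w)), con)
    put("0", 8)
    put("X X X X", 80); put("Startdate X X X X", 80)
    put("01.01.00", 8); put("00.00.00", 8)
    put(256 * (ns + 1), 8); put("", 44)
    put(n_rec, 8); put(format(rec_dur, digits = 10), 8); put(ns, 4)
    labs <- channelLabels(rec)
    for (l in labs) put(l, 16)
    for (l in labs) put("", 80)
    for (l in labs) put("uV", 8)
    for (v in pmin) put(format(v, digits = 7), 8)
    for (v in pmax) put(format(v, digits = 7), 8)
    for (l in labs) put(dmin, 8)
    for (l in labs) put(dmax, 8)
    for (l in labs) put("", 80)
    for (l in labs) put(spr, 8)
    for (l in labs) put("", 32)
    for (r in seq_len(n_rec)) {
        idx <- ((r - 1) * spr + 1):(r * spr)
        for (s in seq_len(ns))
            writeBin(as.integer(dig[idx, s]), con, size = 2,
                     endian = "little")
    }
    invisible(path)
}
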