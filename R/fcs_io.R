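# Minimal FCS 3.0/3.1 support. List-mode datasets only; DATATYPE F (float),
# D (double) and I (16/32-bit unsigned integer); both byte orders. This
# covers the files clinical instruments export for the panels this package
# targets; it is not a general cytometry I/O layer.

fcs_read_text <- function(con, begin, end) {
  seek(con, begin)
  raw_txt <- readBin(con, "raw", n = end - begin + 1L)
  txt <- rawToChar(raw_txt)
  delim <- substr(txt, 1L, 1L)
  body <- substr(txt, 2L, nchar(txt))
  # the delimiter may be escaped by doubling inside values; the panels we
  # read do not use that, so a plain split is applied
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  parts <- parts[seq_len(length(parts) - length(parts) %% 2L)]
  keys <- trimws(parts[seq(1L, length(parts), by = 2L)])
  vals <- trimws(parts[seq(2L, length(parts), by = 2L)])
  names(vals) <- toupper(keys)
  vals
}

#' Read an FCS 3.0/3.1 file
#'
#' Parses the header, TEXT and DATA segments of a list-mode FCS file.
#' Channels are named by the stain keyword `$PnS` when present, falling
#' back to the short name `$PnN`. When a panel is supplied, columns are
#' matched case-insensitively against those names and returned in panel
#' order; a panel channel absent from the file is an error naming it.
#'
#' @param path path to the FCS file.
#' @param panel optional [marker_panel()] used to select/order channels.
#' @return an [event_matrix()] with `$TOT` rows.
#' @export
read_fcs <- function(path, panel = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", n = 58L))
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stopf("%s: not an FCS 3.0/3.1 file (header '%s')", path, version)
  off <- suppressWarnings(as.numeric(
    substring(header, seq(11L, 51L, by = 8L), seq(18L, 58L, by = 8L))))
  if (anyNA(off[1:2])) stopf("%s: malformed FCS header offsets", path)
  kw <- fcs_read_text(con, off[1], off[2])
  need <- function(k) {
    v <- kw[[k]]
    if (is.null(v) || is.na(v)) stopf("%s: missing keyword %s", path, k)
    v
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  data_begin <- off[3]
  if (is.na(data_begin) || data_begin == 0)
    data_begin <- as.numeric(need("$BEGINDATA"))
  bits <- as.integer(kw[paste0("$P", seq_len(n_par), "B")])
  seek(con, data_begin)
  n_values <- n_par * n_tot
  vals <- switch(dtype,
    F = readBin(con, "numeric", n = n_values, size = 4L, endian = endian),
    D = readBin(con, "numeric", n = n_values, size = 8L, endian = endian),
    I = {
      if (length(unique(bits)) != 1L || !unique(bits) %in% c(16L, 32L))
        stopf("%s: only uniform 16/32-bit integer data supported", path)
      as.numeric(readBin(con, "integer", n = n_values,
                         size = unique(bits) / 8L, endian = endian,
                         signed = unique(bits) == 32L))
    },
    stopf("%s: unsupported $DATATYPE '%s'", path, dtype))
  if (length(vals) != n_values)
    stopf("%s: truncated DATA segment (%d of %d values)",
          path, length(vals), n_values)
  m <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  pns <- kw[paste0("$P", seq_len(n_par), "S")]
  pnn <- kw[paste0("$P", seq_len(n_par), "N")]
  chan <- ifelse(is.na(pns) | pns == "", pnn, pns)
  chan[is.na(chan)] <- paste0("P", which(is.na(chan)))
  colnames(m) <- chan
  sample_id <- kw[["$SRC"]] %||% sub("\\.[^.]*$", "", basename(path))
  if (!is.null(panel)) {
    idx <- integer(panel_size(panel))
    for (d in seq_along(panel$names)) {
      hit <- which(toupper(chan) == toupper(panel$names[d]) |
                   toupper(pnn) == toupper(panel$names[d]))
      if (length(hit) == 0L)
        stopf("%s: panel channel '%s' not found in file", path, panel$names[d])
      idx[d] <- hit[1]
    }
    m <- m[, idx, drop = FALSE]
    colnames(m) <- panel$names
  }
  event_matrix(sample_id, m)
}

#' Write a minimal FCS 3.1 file (test fixtures)
#'
#' Emits a single list-mode dataset with 32-bit float data, little-endian.
#' Intended for constructing round-trip fixtures, not for production export.
#'
#' @param events an [event_matrix()].
#' @param path destination file.
#' @param stain_names optional `$PnS` names (defaults to column names).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, stain_names = NULL) {
  stopifnot(inherits(events, "event_matrix"))
  v <- events$values
  n_par <- ncol(v); n_tot <- nrow(v)
  chan <- stain_names %||% colnames(v) %||% paste0("P", seq_len(n_par))
  d <- "/"
  kvs <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
           "$PAR", as.character(n_par), "$TOT", as.character(n_tot),
           "$NEXTDATA", "0", "$SRC", events$sample_id,
           "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%")
  for (p in seq_len(n_par)) {
    kvs <- c(kvs, sprintf("$P%dN", p), sprintf("P%d", p),
             sprintf("$P%dS", p), chan[p],
             sprintf("$P%dB", p), "32", sprintf("$P%dE", p), "0,0",
             sprintf("$P%dR", p), "262144")
  }
  text <- paste0(d, paste0(kvs, collapse = d), d)
  # offsets are written fixed-width so the TEXT length is known in advance
  text_len <- nchar(text) - nchar("%BD%") - nchar("%ED%") + 16L
  data_begin <- 58L + text_len
  data_end <- data_begin + 4L * n_par * n_tot - 1L
  text <- sub("%BD%", sprintf("%08d", data_begin), text, fixed = TRUE)
  text <- sub("%ED%", sprintf("%08d", data_end), text, fixed = TRUE)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    58L, 58L + text_len - 1L, data_begin, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(v)), con, size = 4L, endian = "little")
  invisible(path)
}
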