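# Minimal FCS 3.0/3.1 support: list-mode float data only, which covers
# cytometer exports of fluorescence event tables. The HEADER carries ASCII
# byte offsets to the TEXT and DATA segments; TEXT is delimiter-separated
# keyword/value pairs; DATA is a $TOT x $PAR matrix of $DATATYPE values.

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    abort(paste0("unsupported FCS version: ", version))
  off <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)

  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keywords <- setNames(as.list(parts[seq(2, length(parts), 2)]),
                       parts[seq(1, length(parts), 2)])

  npar <- as.integer(keywords[["$PAR"]])
  ntot <- as.integer(keywords[["$TOT"]])
  dtype <- keywords[["$DATATYPE"]]
  if (!identical(dtype, "F"))
    abort(paste0("only float ($DATATYPE F) FCS data supported, got ", dtype))
  byteord <- keywords[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.numeric(keywords[["$BEGINDATA"]])
    data_end <- as.numeric(keywords[["$ENDDATA"]])
  }
  seek(con, data_start)
  vals <- readBin(con, "numeric", n = npar * ntot, size = 4, endian = endian)
  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(npar), function(i)
    keywords[[paste0("$P", i, "N")]] %||% paste0("P", i), character(1))
  list(data = mat, keywords = keywords)
}

# Writer used to build synthetic FCS fixtures in tests; emits FCS3.0 with
# little-endian float32 list-mode data and an optional $VOL keyword (uL).
write_fcs <- function(mat, path, volume_ul = NULL) {
  mat <- as.matrix(mat)
  npar <- ncol(mat); ntot <- nrow(mat)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(npar), "$TOT", as.character(ntot),
          "$NEXTDATA", "0")
  for (i in seq_len(npar))
    kw <- c(kw, paste0("$P", i, "N"), colnames(mat)[i],
            paste0("$P", i, "B"), "32",
            paste0("$P", i, "R"), "262144",
            paste0("$P", i, "E"), "0,0")
  if (!is.null(volume_ul)) kw <- c(kw, "$VOL", as.character(volume_ul))
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  text_start <- 58
  text_end <- text_start + nchar(text) - 1
  data_start <- text_end + 1
  data_end <- data_start + 4 * npar * ntot - 1
  pad <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.0    ", pad(text_start), pad(text_end),
                   pad(data_start), pad(data_end), pad(0), pad(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}
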