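# Minimal reader for MATLAB Level-5 MAT files, restricted to what the SVHN
# cropped-digits files contain: little-endian files with (possibly
# zlib-compressed) numeric arrays. Not a general .mat parser: cell arrays,
# structs, sparse and complex matrices are not supported.

.MI_TYPES <- list( # miTYPE code -> readBin arguments
  `1` = list(what = "integer", size = 1L, signed = TRUE),   # miINT8
  `2` = list(what = "integer", size = 1L, signed = FALSE),  # miUINT8
  `3` = list(what = "integer", size = 2L, signed = TRUE),   # miINT16
  `4` = list(what = "integer", size = 2L, signed = FALSE),  # miUINT16
  `5` = list(what = "integer", size = 4L, signed = TRUE),   # miINT32
  `6` = list(what = "integer", size = 4L, signed = TRUE),   # miUINT32 (< 2^31)
  `7` = list(what = "numeric", size = 4L, signed = TRUE),   # miSINGLE
  `9` = list(what = "numeric", size = 8L, signed = TRUE)    # miDOUBLE
)

.mat5_uint32 <- function(raw, pos) {
  v <- readBin(raw[pos:(pos + 3L)], "integer", 1L, size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# Read one element tag at `pos`. Returns type, nbytes, data start, position
# of the next element (handles the packed small-element format).
.mat5_tag <- function(raw, pos) {
  t <- .mat5_uint32(raw, pos)
  small_len <- t %/% 65536
  if (small_len > 0) {
    list(type = t %% 65536, nbytes = small_len, data = pos + 4L,
         nxt = pos + 8L)
  } else {
    nbytes <- .mat5_uint32(raw, pos + 4L)
    list(type = t, nbytes = nbytes, data = pos + 8L,
         nxt = pos + 8L + as.integer(ceiling(nbytes / 8) * 8))
  }
}

.mat5_numeric <- function(raw, tag) {
  spec <- .MI_TYPES[[as.character(tag$type)]]
  if (is.null(spec)) stop("unsupported MAT data type: ", tag$type)
  n <- tag$nbytes %/% spec$size
  readBin(raw[tag$data:(tag$data + tag$nbytes - 1L)], spec$what, n,
          size = spec$size, signed = spec$signed, endian = "little")
}

# Parse one miMATRIX payload; returns list(name, value) or NULL for
# unsupported array classes.
.mat5_matrix <- function(raw, pos) {
  flags_tag <- .mat5_tag(raw, pos)
  flags <- .mat5_uint32(raw, flags_tag$data)
  cls <- flags %% 256
  dims_tag <- .mat5_tag(raw, flags_tag$nxt)
  dims <- .mat5_numeric(raw, dims_tag)
  name_tag <- .mat5_tag(raw, dims_tag$nxt)
  name <- if (name_tag$nbytes > 0)
    rawToChar(raw[name_tag$data:(name_tag$data + name_tag$nbytes - 1L)])
  else ""
  if (!cls %in% 6:13) return(list(name = name, value = NULL)) # numeric only
  data_tag <- .mat5_tag(raw, name_tag$nxt)
  values <- .mat5_numeric(raw, data_tag)
  if (length(values) != prod(dims))
    stop("MAT array size mismatch for variable '", name, "'")
  list(name = name, value = array(values, dims))
}

# Read all top-level numeric variables of a little-endian MAT v5 file.
.read_mat5 <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 136) stop("not a MAT v5 file (too short): ", path)
  raw <- readBin(path, "raw", sz)
  endian <- rawToChar(raw[127:128])
  if (endian == "MI") stop("big-endian MAT files are not supported: ", path)
  if (endian != "IM") stop("not a MAT v5 file (bad endian marker): ", path)

  out <- list()
  pos <- 129L
  while (pos + 7L <= sz) {
    tag <- .mat5_tag(raw, pos)
    if (tag$type == 15) { # miCOMPRESSED: zlib stream wrapping one element
      inner <- memDecompress(raw[tag$data:(tag$data + tag$nbytes - 1L)],
                             type = "gzip")
      itag <- .mat5_tag(inner, 1L)
      if (itag$type == 14) {
        v <- .mat5_matrix(inner, itag$data)
        if (!is.null(v$value)) out[[v$name]] <- v$value
      }
      tag$nxt <- tag$data + tag$nbytes # compressed elements are not padded
    } else if (tag$type == 14) { # miMATRIX
      v <- .mat5_matrix(raw, tag$data)
      if (!is.null(v$value)) out[[v$name]] <- v$value
    } # other top-level types are skipped
    pos <- tag$nxt
  }
  out
}
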