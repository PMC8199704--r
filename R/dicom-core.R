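# Minimal DICOM codec: Explicit VR Little Endian read/write of the element
# subset the RT objects need. A dataset is a named list keyed "GGGGEEEE"
# (upper-case hex); each element is list(group, element, vr, value) with
# value decoded per VR (character for string VRs, numeric for DS, integer
# for IS/US/UL, raw for OB/OW, list of datasets for SQ).

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_RTDOSE  <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_RTPLAN  <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_CT      <- "1.2.840.10008.5.1.4.1.1.2"

# VRs using the 4-byte length form
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
STRING_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST",
                "TM", "UI", "UT")

tag_key <- function(group, element) sprintf("%04X%04X", group, element)

uid_counter <- local({ n <- 0L; function() { n <<- n + 1L; n } })

new_uid <- function() {
  # org-root style UID; suffix from wall clock + process + counter
  sprintf("1.2.826.0.1.3680043.10.424.%d.%d.%d",
          Sys.getpid() %% 100000L,
          as.integer(as.numeric(Sys.time())) %% 100000000L,
          uid_counter())
}

dcm_el <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

raw16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
raw32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
int16_at <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}
int32_at <- function(buf, pos) {
  as.numeric(buf[pos]) + 256 * as.numeric(buf[pos + 1L]) +
    65536 * as.numeric(buf[pos + 2L]) + 16777216 * as.numeric(buf[pos + 3L])
}

encode_value <- function(vr, value) {
  if (vr %in% c("OB", "OW", "UN")) {
    v <- as.raw(value)
    if (length(v) %% 2L == 1L) v <- c(v, as.raw(0))
    return(v)
  }
  if (vr == "US") {
    v <- as.integer(value)
    return(as.raw(as.vector(rbind(v %% 256L, v %/% 256L))))
  }
  if (vr == "UL") {
    return(do.call(c, lapply(as.numeric(value), raw32)))
  }
  if (vr == "DS") {
    s <- paste(vapply(as.numeric(value),
                      function(x) formatC(x, digits = 10, format = "g"),
                      character(1)), collapse = "\\")
  } else if (vr == "IS") {
    s <- paste(format(as.integer(value), scientific = FALSE, trim = TRUE),
               collapse = "\\")
  } else {
    s <- paste(as.character(value), collapse = "\\")
  }
  v <- charToRaw(s)
  if (length(v) %% 2L == 1L) {
    v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  v
}

encode_element <- function(el) {
  if (el$vr == "SQ") {
    body <- raw(0)
    for (item in el$value) {
      item_bytes <- encode_dataset(item)
      body <- c(body, raw16(0xFFFE), raw16(0xE000), raw32(length(item_bytes)),
                item_bytes)
    }
  } else {
    body <- encode_value(el$vr, el$value)
  }
  head <- c(raw16(el$group), raw16(el$element), charToRaw(el$vr))
  if (el$vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), raw32(length(body)), body)
  } else {
    if (length(body) > 65534) {
      stop_secrisk("Element too long for short-form VR.", "secrisk_format")
    }
    c(head, raw16(length(body)), body)
  }
}

encode_dataset <- function(ds) {
  # elements must be written in ascending tag order
  keys <- names(ds)
  ds <- ds[order(keys)]
  do.call(c, c(list(raw(0)), lapply(ds, encode_element)))
}

decode_value <- function(vr, bytes) {
  if (vr %in% c("OB", "OW", "UN", "OF")) return(bytes)
  if (vr == "US") {
    if (length(bytes) == 0L) return(integer(0))
    m <- matrix(as.integer(bytes), nrow = 2L)
    return(m[1L, ] + 256L * m[2L, ])
  }
  if (vr == "UL") {
    n <- length(bytes) %/% 4L
    return(vapply(seq_len(n), function(i) int32_at(bytes, 4L * (i - 1L) + 1L),
                  numeric(1)))
  }
  s <- rawToChar(bytes[bytes != as.raw(0)])
  s <- sub("[ ]+$", "", s)
  if (vr == "DS") {
    if (!nzchar(s)) return(numeric(0))
    return(as.numeric(strsplit(s, "\\", fixed = TRUE)[[1L]]))
  }
  if (vr == "IS") {
    if (!nzchar(s)) return(integer(0))
    return(as.integer(strsplit(s, "\\", fixed = TRUE)[[1L]]))
  }
  strsplit(s, "\\", fixed = TRUE)[[1L]] %||% s
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# parse elements in buf[pos..end]; returns list(ds, pos). stop_at_item_end:
# stop when an item delimiter (FFFE,E00D) is consumed (undefined-length item).
parse_dataset <- function(buf, pos, end) {
  ds <- list()
  while (pos <= end - 7L) {
    group <- int16_at(buf, pos); element <- int16_at(buf, pos + 2L)
    if (group == 0xFFFE && element == 0xE00D) { # item delimiter
      pos <- pos + 8L
      return(list(ds = ds, pos = pos, delimited = TRUE))
    }
    if (group == 0xFFFE && element == 0xE0DD) { # sequence delimiter (caller)
      return(list(ds = ds, pos = pos, delimited = FALSE))
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop_secrisk("Unsupported transfer syntax (implicit VR or corrupt stream).",
                   "secrisk_format")
    }
    if (vr %in% LONG_VRS) {
      len <- int32_at(buf, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- int16_at(buf, pos + 6L)
      pos <- pos + 8L
    }
    if (vr == "SQ") {
      parsed <- parse_sequence(buf, pos, len, end)
      value <- parsed$items
      pos <- parsed$pos
    } else {
      if (len == 4294967295) {
        stop_secrisk("Undefined-length non-sequence element unsupported.",
                     "secrisk_format")
      }
      value <- decode_value(vr, if (len > 0) buf[pos:(pos + len - 1L)] else raw(0))
      pos <- pos + len
    }
    ds[[tag_key(group, element)]] <- dcm_el(group, element, vr, value)
  }
  list(ds = ds, pos = pos, delimited = FALSE)
}

parse_sequence <- function(buf, pos, len, end) {
  items <- list()
  seq_end <- if (len == 4294967295) end else pos + len - 1L
  while (pos <= seq_end - 7L) {
    group <- int16_at(buf, pos); element <- int16_at(buf, pos + 2L)
    item_len <- int32_at(buf, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) { # end of undefined-length SQ
      return(list(items = items, pos = pos))
    }
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop_secrisk("Malformed sequence: expected item tag.", "secrisk_format")
    }
    if (item_len == 4294967295) {
      parsed <- parse_dataset(buf, pos, seq_end)
      if (!isTRUE(parsed$delimited)) {
        stop_secrisk("Unterminated undefined-length item.", "secrisk_format")
      }
    } else {
      parsed <- parse_dataset(buf, pos, pos + item_len - 1L)
      parsed$pos <- pos + item_len
    }
    items[[length(items) + 1L]] <- parsed$ds
    pos <- parsed$pos
  }
  list(items = items, pos = pos)
}

ds_value <- function(ds, group, element, required = FALSE, what = NULL) {
  el <- ds[[tag_key(group, element)]]
  if (is.null(el)) {
    if (required) {
      stop_secrisk(sprintf("Required DICOM element (%04X,%04X)%s is missing.",
                           group, element,
                           if (is.null(what)) "" else paste0(" [", what, "]")),
                   "secrisk_format")
    }
    return(NULL)
  }
  el$value
}

write_dicom_file <- function(ds, sop_class_uid, sop_instance_uid, path) {
  meta <- list()
  add_meta <- function(group, element, vr, value) {
    meta[[tag_key(group, element)]] <<- dcm_el(group, element, vr, value)
  }
  add_meta(0x0002, 0x0001, "OB", as.raw(c(0, 1)))
  add_meta(0x0002, 0x0002, "UI", sop_class_uid)
  add_meta(0x0002, 0x0003, "UI", sop_instance_uid)
  add_meta(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE)
  add_meta(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.10.424.1")
  meta_bytes <- encode_dataset(meta)
  group_len <- encode_element(dcm_el(0x0002, 0x0000, "UL", length(meta_bytes)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta_bytes, encode_dataset(ds)), con)
  invisible(path)
}

read_dicom_file <- function(path) {
  if (!file.exists(path)) {
    stop_secrisk(sprintf("No such file: %s", path), "secrisk_io")
  }
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 160L ||
      !identical(rawToChar(buf[129:132]), "DICM")) {
    stop_secrisk(sprintf("Not a DICOM file: %s", path), "secrisk_type")
  }
  pos <- 133L
  # file meta group is always explicit VR LE; read its group length
  if (!(int16_at(buf, pos) == 0x0002)) {
    stop_secrisk("Missing DICOM file meta group.", "secrisk_format")
  }
  meta_len <- int32_at(buf, pos + 8L)
  pos <- pos + 12L
  meta <- parse_dataset(buf, pos, pos + meta_len - 1L)$ds
  ts <- ds_value(meta, 0x0002, 0x0010, required = TRUE, "transfer syntax")
  if (!identical(ts, UID_EXPLICIT_VR_LE)) {
    stop_secrisk(sprintf("Unsupported transfer syntax %s (only Explicit VR Little Endian).",
                         ts), "secrisk_format")
  }
  pos <- pos + meta_len
  parse_dataset(buf, pos, length(buf))$ds
}

common_elements <- function(ds, modality, sop_class_uid, sop_instance_uid) {
  add <- function(group, element, vr, value) {
    ds[[tag_key(group, element)]] <<- dcm_el(group, element, vr, value)
  }
  add(0x0008, 0x0016, "UI", sop_class_uid)
  add(0x0008, 0x0018, "UI", sop_instance_uid)
  add(0x0008, 0x0060, "CS", modality)
  add(0x0010, 0x0010, "PN", "SYNTHETIC^PHANTOM")
  add(0x0010, 0x0020, "LO", "SECRISK-000")
  ds
}

check_modality <- function(ds, expected, path) {
  modality <- ds_value(ds, 0x0008, 0x0060) %||% "unknown"
  if (!identical(modality, expected)) {
    stop_secrisk(sprintf("%s: expected modality %s, found %s.",
                         path, expected, modality), "secrisk_type")
  }
  invisible(TRUE)
}
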