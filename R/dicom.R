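# Minimal DICOM codec (Explicit VR Little Endian only), covering the subset of
# RTDOSE / RTSTRUCT / multi-frame CT-geometry attributes this pipeline uses.
# Written files carry the standard 128-byte preamble + "DICM", a group-0002
# file-meta header, and defined-length sequences; the reader additionally
# accepts undefined-length sequences/items with delimitation tags.

UID_TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
UID_SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_IMPL <- "1.2.826.0.1.3680043.9.7435.1.0"
UID_ROOT <- "1.2.826.0.1.3680043.9.7435"

# ---- low-level byte emitters -------------------------------------------------

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# VRs using the 2-byte length form; everything else gets reserved + 4-byte form
SHORT_VRS <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
               "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL", "US")

dcm_element <- function(group, elem, vr, payload) {
  head <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% SHORT_VRS) {
    if (length(payload) > 65534) stop("payload too long for short VR form")
    c(head, u16le(length(payload)), payload)
  } else {
    c(head, as.raw(c(0, 0)), u32le(length(payload)), payload)
  }
}

dcm_str <- function(group, elem, vr, value) {
  pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
  dcm_element(group, elem, vr, pad_even(charToRaw(as.character(value)), pad))
}

dcm_num_str <- function(group, elem, vr, values, digits = 10) {
  s <- paste(vapply(values, function(v) format_ds(v, digits), character(1)),
             collapse = "\\")
  dcm_str(group, elem, vr, s)
}

# DS values are limited to 16 bytes; %.10g stays within that for |x| < 1e10
format_ds <- function(v, digits = 10) {
  s <- sprintf("%.*g", digits, v)
  if (nchar(s) > 16) s <- sprintf("%.8g", v)
  s
}

dcm_us <- function(group, elem, value) dcm_element(group, elem, "US", u16le(value))

dcm_at <- function(group, elem, tag_group, tag_elem) {
  dcm_element(group, elem, "AT", c(u16le(tag_group), u16le(tag_elem)))
}

dcm_sq <- function(group, elem, items) {
  body <- do.call(c, c(lapply(items, function(it) {
    c(u16le(0xFFFE), u16le(0xE000), u32le(length(it)), it)
  }), list(raw(0))))
  dcm_element(group, elem, "SQ", body)
}

dcm_int_pixels <- function(values_int) {
  dcm_element(0x7FE0, 0x0010, "OW",
              writeBin(as.integer(values_int), raw(), size = 4,
                       endian = "little"))
}

file_meta <- function(sop_class, sop_instance) {
  elems <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", sop_class),
    dcm_str(0x0002, 0x0003, "UI", sop_instance),
    dcm_str(0x0002, 0x0010, "UI", UID_TRANSFER_SYNTAX_ELE),
    dcm_str(0x0002, 0x0012, "UI", UID_IMPL)
  )
  c(dcm_element(0x0002, 0x0000, "UL", u32le(length(elems))), elems)
}

write_dicom_file <- function(path, sop_class, sop_instance, dataset_bytes) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(file_meta(sop_class, sop_instance), con)
  writeBin(dataset_bytes, con)
  invisible(path)
}

# ---- parser ------------------------------------------------------------------

tag_key <- function(group, elem) sprintf("%04X%04X", group, elem)

new_cursor <- function(bytes, pos = 1L) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes; env$pos <- pos
  env
}

take <- function(cur, n) {
  if (cur$pos + n - 1L > length(cur$bytes)) {
    stop("DICOM format error: unexpected end of file", call. = FALSE)
  }
  out <- cur$bytes[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + n
  out
}

take_u16 <- function(cur) {
  readBin(take(cur, 2L), "integer", size = 2, signed = FALSE, endian = "little")
}

take_u32 <- function(cur) {
  # returns -1 for the undefined-length marker 0xFFFFFFFF
  readBin(take(cur, 4L), "integer", size = 4, endian = "little")
}

trim_padding <- function(payload) {
  pad <- as.raw(c(0x00, 0x20))
  while (length(payload) && payload[length(payload)] %in% pad) {
    payload <- payload[-length(payload)]
  }
  rawToChar(payload)
}

decode_value <- function(vr, payload) {
  switch(vr,
    UI = , SH = , CS = , LO = , ST = , LT = , PN = , AE = , AS = ,
    DA = , TM = , DT = {
      trim_padding(payload)
    },
    DS = {
      s <- trim_padding(payload)
      if (!nzchar(s)) numeric(0) else as.numeric(strsplit(s, "\\\\")[[1]])
    },
    IS = {
      s <- trim_padding(payload)
      if (!nzchar(s)) integer(0) else as.integer(strsplit(s, "\\\\")[[1]])
    },
    US = readBin(payload, "integer", n = length(payload) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    UL = readBin(payload, "integer", n = length(payload) / 4, size = 4,
                 endian = "little"),
    FL = readBin(payload, "double", n = length(payload) / 4, size = 4,
                 endian = "little"),
    FD = readBin(payload, "double", n = length(payload) / 8, size = 8,
                 endian = "little"),
    payload  # OB/OW/AT/UN: keep raw
  )
}

parse_elements <- function(cur, stop_at = NA_integer_) {
  out <- list()
  repeat {
    if (cur$pos > length(cur$bytes)) break
    if (!is.na(stop_at) && cur$pos >= stop_at) break
    group <- take_u16(cur); elem <- take_u16(cur)
    if (group == 0xFFFE && elem == 0xE00D) { take_u32(cur); break }  # item end
    vr <- rawToChar(take(cur, 2L))
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("DICOM format error: implicit VR or corrupt element header",
           call. = FALSE)
    }
    if (vr %in% SHORT_VRS) {
      len <- take_u16(cur)
    } else {
      take(cur, 2L)
      len <- take_u32(cur)
    }
    value <- if (vr == "SQ") {
      parse_sequence(cur, len)
    } else {
      if (len < 0) stop("DICOM format error: undefined length on non-SQ element",
                        call. = FALSE)
      decode_value(vr, take(cur, len))
    }
    out[[tag_key(group, elem)]] <- list(vr = vr, value = value)
  }
  out
}

parse_sequence <- function(cur, len) {
  end <- if (len < 0) NA_integer_ else cur$pos + len
  items <- list()
  repeat {
    if (!is.na(end) && cur$pos >= end) break
    if (cur$pos > length(cur$bytes)) {
      if (is.na(end)) stop("DICOM format error: unterminated sequence",
                           call. = FALSE)
      break
    }
    group <- take_u16(cur); elem <- take_u16(cur)
    ilen <- take_u32(cur)
    if (group == 0xFFFE && elem == 0xE0DD) break        # sequence delimiter
    if (!(group == 0xFFFE && elem == 0xE000)) {
      stop("DICOM format error: expected sequence item tag", call. = FALSE)
    }
    items[[length(items) + 1L]] <-
      if (ilen < 0) parse_elements(cur)                  # until item delimiter
      else parse_elements(cur, stop_at = cur$pos + ilen)
  }
  items
}

read_dicom_dataset <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM") {
    stop("DICOM format error: missing DICM magic marker", call. = FALSE)
  }
  cur <- new_cursor(bytes, 133L)
  # file meta group (always explicit LE); its group length bounds the header
  meta <- parse_meta_group(cur)
  ts <- meta[["00020010"]]
  if (!is.null(ts) && !identical(ts$value, UID_TRANSFER_SYNTAX_ELE)) {
    stop(sprintf("unsupported transfer syntax '%s' (only Explicit VR LE)",
                 ts$value), call. = FALSE)
  }
  parse_elements(cur)
}

parse_meta_group <- function(cur) {
  out <- list()
  repeat {
    if (cur$pos + 8L > length(cur$bytes)) break
    peek_group <- readBin(cur$bytes[cur$pos:(cur$pos + 1L)], "integer",
                          size = 2, signed = FALSE, endian = "little")
    if (peek_group != 0x0002) break
    group <- take_u16(cur); elem <- take_u16(cur)
    vr <- rawToChar(take(cur, 2L))
    len <- if (vr %in% SHORT_VRS) take_u16(cur) else { take(cur, 2L); take_u32(cur) }
    out[[tag_key(group, elem)]] <- list(vr = vr, value = decode_value(vr, take(cur, len)))
  }
  out
}

ds_required <- function(ds, key, name) {
  el <- ds[[key]]
  if (is.null(el)) {
    stop(sprintf("DICOM format error: missing required tag %s (%s)", key, name),
         call. = FALSE)
  }
  el$value
}
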